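#' Configuration for the coupled respiration simulator
#'
#' The simulator is a stochastic Kuramoto system: each singer's breathing
#' is a noisy phase oscillator with its own base rate, optionally pulled
#' toward the others' phases. It is a stand-in for belt-recorded breathing
#' whose one contract is controllable pairwise phase coupling inside the
#' analysis band (0.025-0.40 Hz).
#'
#' @param n_singers number of oscillators.
#' @param duration trace length in seconds.
#' @param sampling_rate sampling rate in Hz; must exceed twice the upper
#'   analysis frequency (0.40 Hz). Default 10 Hz.
#' @param base_frequency_mean,base_frequency_sd mean and SD (Hz) of the
#'   per-singer base breathing rates. Default 0.25 +/- 0.03 Hz, the centre
#'   of the adult quiet-breathing range.
#' @param coupling_strength kappa, in rad/s: either a scalar (each
#'   oscillator's total pull from the rest; divided by `n_singers - 1` to
#'   give pairwise gains) or a full `n_singers x n_singers` matrix of
#'   pairwise gains with zero diagonal. Must be non-negative.
#' @param phase_noise_sd SD of the phase diffusion, rad/sqrt(s).
#' @param amplitude_noise_sd SD of additive white noise on the signal.
#' @param slow_modulation length-2 numeric `c(amplitude, frequency)`: each
#'   singer's instantaneous rate wanders sinusoidally by `amplitude` Hz at
#'   `frequency` Hz (random phase), emulating slow breathing-rate drift.
#' @param seed integer RNG seed; identical seed gives identical traces.
#' @return A list of class `resp_sim_config`.
#' @export
resp_sim_config <- function(n_singers = 8, duration = 420,
                            sampling_rate = 10,
                            base_frequency_mean = 0.25,
                            base_frequency_sd = 0.03,
                            coupling_strength = 0.3,
                            phase_noise_sd = 0.15,
                            amplitude_noise_sd = 0.05,
                            slow_modulation = c(amplitude = 0.02,
                                                frequency = 0.01),
                            seed = 1L) {
  if (duration <= 0) stop("duration must be positive")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (sampling_rate <= 2 * 0.40)
    stop("sampling_rate must exceed the Nyquist rate for the 0.40 Hz band edge")
  if (any(coupling_strength < 0)) stop("coupling_strength must be >= 0")
  if (is.matrix(coupling_strength) &&
      !all(dim(coupling_strength) == n_singers))
    stop("coupling matrix must be n_singers x n_singers")
  structure(list(n_singers = as.integer(n_singers), duration = duration,
                 sampling_rate = sampling_rate,
                 base_frequency_mean = base_frequency_mean,
                 base_frequency_sd = base_frequency_sd,
                 coupling_strength = coupling_strength,
                 phase_noise_sd = phase_noise_sd,
                 amplitude_noise_sd = amplitude_noise_sd,
                 slow_modulation = slow_modulation,
                 seed = as.integer(seed)),
            class = "resp_sim_config")
}

# Pairwise coupling-gain matrix from a scalar or matrix specification.
coupling_matrix <- function(config) {
  n <- config$n_singers
  k <- config$coupling_strength
  if (is.matrix(k)) {
    K <- k
  } else {
    K <- matrix(if (n > 1) k / (n - 1) else 0, n, n)
  }
  diag(K) <- 0
  K
}

#' Simulate an ensemble of coupled respiration traces
#'
#' Integrates `dphi_i/dt = omega_i(t) + sum_j K_ij sin(phi_j - phi_i)` plus
#' phase diffusion by fixed-step Euler-Maruyama at the sampling rate, and
#' returns `s_i(t) = sin(phi_i(t))` plus amplitude noise.
#'
#' @param config a [resp_sim_config()].
#' @param singers optional character labels for the traces.
#' @return A `respiration_ensemble`: list with `time` (seconds), `samples`
#'   (time x singer matrix), `sampling_rate`, `singers`.
#' @export
generate_respiration_ensemble <- function(config, singers = NULL) {
  stopifnot(inherits(config, "resp_sim_config"))
  n <- config$n_singers
  fs <- config$sampling_rate
  dt <- 1 / fs
  nt <- floor(config$duration * fs)
  if (is.null(singers)) singers <- paste0("singer_", seq_len(n))
  stopifnot(length(singers) == n)
  set.seed(config$seed)
  f_base <- pmax(0.02, stats::rnorm(n, config$base_frequency_mean,
                                    config$base_frequency_sd))
  K <- coupling_matrix(config)
  mod_amp <- config$slow_modulation[[1]]
  mod_freq <- config$slow_modulation[[2]]
  mod_phase <- stats::runif(n, 0, 2 * pi)
  phi <- stats::runif(n, 0, 2 * pi)
  sqdt <- sqrt(dt)
  phases <- matrix(0, nt, n)
  tvec <- (seq_len(nt) - 1L) * dt
  for (it in seq_len(nt)) {
    phases[it, ] <- phi
    f_inst <- f_base + mod_amp * sin(2 * pi * mod_freq * tvec[it] + mod_phase)
    drift <- 2 * pi * f_inst
    if (n > 1) {
      dmat <- outer(phi, phi, "-")       # dmat[i, j] = phi_i - phi_j
      drift <- drift + rowSums(K * (-sin(dmat)))
    }
    phi <- phi + drift * dt + config$phase_noise_sd * sqdt * stats::rnorm(n)
  }
  samples <- sin(phases) +
    matrix(stats::rnorm(nt * n, 0, config$amplitude_noise_sd), nt, n)
  colnames(samples) <- singers
  structure(list(time = tvec, samples = samples, sampling_rate = fs,
                 singers = singers),
            class = "respiration_ensemble")
}

#' Extract one singer's trace from an ensemble
#' @param ensemble a `respiration_ensemble`.
#' @param singer singer label or column index.
#' @return A `respiration_trace` (list: `singer`, `samples`,
#'   `sampling_rate`, `start_time`).
#' @export
get_trace <- function(ensemble, singer) {
  stopifnot(inherits(ensemble, "respiration_ensemble"))
  structure(list(singer = if (is.character(singer)) singer
                 else ensemble$singers[singer],
                 samples = ensemble$samples[, singer],
                 sampling_rate = ensemble$sampling_rate,
                 start_time = ensemble$time[1]),
            class = "respiration_trace")
}

#' Configuration for the unison performance simulator
#'
#' Two singers render the same score line. Both share a smooth expressive
#' timing component (a random walk over events, common to the pair, so
#' between-singer onset differences are unaffected by interpretation);
#' each adds independent Gaussian onset jitter, cents-scale pitch jitter,
#' a linear pitch drift and a constant pitch offset; occasional notes are
#' corrupted by gross errors (a substitution of at least one semitone, or
#' an onset displacement beyond 300 ms) or omitted.
#'
#' Defaults target the accuracy scale reported for professional ensembles:
#' `onset_jitter_sd = 0.046` s makes the expected absolute between-singer
#' onset difference `2 * sd / sqrt(pi)` come out near 52 ms, and
#' `pitch_jitter_sd = 14.5` cents puts the expected absolute pitch
#' difference near 16.4 cents.
#'
#' @param onset_jitter_sd SD (s) of each singer's independent onset jitter.
#' @param shared_timing_sd SD (s) of the shared expressive-timing walk over
#'   a stream (total displacement scale, not per-step).
#' @param pitch_jitter_sd SD (cents) of independent per-note pitch jitter.
#' @param drift_slope linear pitch drift, cents per second, applied per
#'   singer.
#' @param pitch_offset constant per-singer pitch offset in cents.
#' @param gross_pitch_error_rate,gross_onset_error_rate per-note
#'   probabilities of a gross pitch substitution (1-2 semitones) or a
#'   gross onset displacement (0.35-0.60 s).
#' @param omission_rate per-note, per-singer probability of omission.
#' @param tempo beats per second; must be positive.
#' @param seed integer RNG seed.
#' @return A list of class `perf_sim_config`.
#' @export
perf_sim_config <- function(onset_jitter_sd = 0.046,
                            shared_timing_sd = 0.05,
                            pitch_jitter_sd = 14.5,
                            drift_slope = 0.1,
                            pitch_offset = 0,
                            gross_pitch_error_rate = 0.01,
                            gross_onset_error_rate = 0.006,
                            omission_rate = 0,
                            tempo = 2,
                            seed = 1L) {
  sds <- c(onset_jitter_sd, shared_timing_sd, pitch_jitter_sd)
  if (any(sds < 0)) stop("all jitter SDs must be >= 0")
  rates <- c(gross_pitch_error_rate, gross_onset_error_rate, omission_rate)
  if (any(rates < 0 | rates > 1)) stop("error rates must be in [0, 1]")
  if (tempo <= 0) stop("tempo must be positive")
  structure(list(onset_jitter_sd = onset_jitter_sd,
                 shared_timing_sd = shared_timing_sd,
                 pitch_jitter_sd = pitch_jitter_sd,
                 drift_slope = drift_slope,
                 pitch_offset = pitch_offset,
                 gross_pitch_error_rate = gross_pitch_error_rate,
                 gross_onset_error_rate = gross_onset_error_rate,
                 omission_rate = omission_rate,
                 tempo = tempo, seed = as.integer(seed)),
            class = "perf_sim_config")
}

#' Render one score line as two unison note-event streams
#'
#' @param score data.frame with columns `event_index`, `midi_pitch`,
#'   `onset_beats`, `duration_beats` for a single voice and piece (extra
#'   identifying columns are carried through).
#' @param config a [perf_sim_config()].
#' @param singers length-2 character vector of singer labels.
#' @return data.frame of note events for both singers: `singer`,
#'   `event_index`, `onset_s`, `duration_s`, `f0_hz`.
#' @export
generate_unison_performance <- function(score, config,
                                        singers = c("a", "b")) {
  stopifnot(inherits(config, "perf_sim_config"))
  if (nrow(score) == 0) stop("score must be non-empty")
  if (anyDuplicated(score$event_index))
    stop("score event_index values must be unique within a voice/piece")
  set.seed(config$seed)
  n <- nrow(score)
  base_onset <- score$onset_beats / config$tempo
  shared <- cumsum(stats::rnorm(n, 0, config$shared_timing_sd / sqrt(n)))
  one_singer <- function(label) {
    onset <- base_onset + shared +
      stats::rnorm(n, 0, config$onset_jitter_sd)
    cents <- stats::rnorm(n, 0, config$pitch_jitter_sd) +
      config$drift_slope * base_onset + config$pitch_offset
    midi <- score$midi_pitch + cents / 100
    gp <- stats::runif(n) < config$gross_pitch_error_rate
    if (any(gp))
      midi[gp] <- midi[gp] +
        sample(c(-1, 1), sum(gp), replace = TRUE) * stats::runif(sum(gp), 1, 2)
    go <- stats::runif(n) < config$gross_onset_error_rate
    if (any(go))
      onset[go] <- onset[go] +
        sample(c(-1, 1), sum(go), replace = TRUE) *
        stats::runif(sum(go), 0.35, 0.60)
    keep <- stats::runif(n) >= config$omission_rate
    data.frame(singer = label,
               event_index = score$event_index,
               onset_s = onset,
               duration_s = score$duration_beats / config$tempo,
               f0_hz = midi_to_hz(midi),
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  out <- rbind(one_singer(singers[1]), one_singer(singers[2]))
  rownames(out) <- NULL
  out
}

#' Generate a small plausible polyphonic score for a design
#'
#' Builds a deterministic pseudo-score: for every (piece, voice) with a
#' non-zero repeat count, `events_per_piece` notes on a diatonic random
#' walk inside that voice's range, with durations drawn from common note
#' values. The default of 96 notes per voice per piece makes a full
#' default-design study produce about 65,000 tone events across its 672
#' files, the annotation volume typical of a session of this shape. A
#' synthetic stand-in for an engraved score; the file format (`voice,
#' piece, event_index, midi_pitch, onset_beats, duration_beats`) also
#' loads real scores via [read_score()], and a compact bundled example
#' lives at `extdata/score_default.csv`.
#'
#' @param design a `study_design`.
#' @param events_per_piece notes per voice per piece.
#' @param seed integer RNG seed.
#' @return data.frame score.
#' @export
example_score <- function(design = default_design(), events_per_piece = 96,
                          seed = 20061L) {
  ranges <- list(soprano = c(60, 79), altus = c(55, 74),
                 tenor = c(48, 67), bassus = c(41, 60))
  set.seed(seed)
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(design$pieces))) {
    piece <- design$pieces$piece[i]
    for (v in design$voices) {
      if (design$pieces[[v]][i] == 0) next
      rng <- if (v %in% names(ranges)) ranges[[v]] else c(48, 72)
      pitch <- numeric(events_per_piece)
      pitch[1] <- round(mean(rng))
      steps <- sample(c(-2, -1, 1, 2), events_per_piece - 1, replace = TRUE)
      for (e in seq_len(events_per_piece - 1))
        pitch[e + 1] <- min(max(pitch[e] + steps[e], rng[1]), rng[2])
      dur <- sample(c(0.5, 1, 1, 2), events_per_piece, replace = TRUE)
      k <- k + 1L
      out[[k]] <- data.frame(voice = v, piece = piece,
                             event_index = seq_len(events_per_piece),
                             midi_pitch = pitch,
                             onset_beats = cumsum(c(0, dur[-events_per_piece])),
                             duration_beats = dur,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a score file
#' @param path CSV with columns `voice, piece, event_index, midi_pitch,
#'   onset_beats, duration_beats`.
#' @return data.frame score.
#' @export
read_score <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("voice", "piece", "event_index", "midi_pitch", "onset_beats",
            "duration_beats")
  missing_cols <- setdiff(need, names(sc))
  if (length(missing_cols) > 0)
    stop("score file lacks columns: ", paste(missing_cols, collapse = ", "))
  sc
}

# Derive independent child seeds from a master seed (kept below 2^31).
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Shift a config's numeric fields by named per-condition offsets.
apply_condition_effects <- function(config, condition_effects, condition) {
  if (is.null(condition_effects)) return(config)
  for (field in names(condition_effects)) {
    offs <- condition_effects[[field]]
    if (condition %in% names(offs) && !is.null(config[[field]]))
      config[[field]] <- pmax(0, config[[field]] + offs[[condition]])
  }
  config
}

#' Generate a full synthetic study data set
#'
#' Produces one respiration ensemble per (block x condition) trial and one
#' unison note-event stream pair per (piece repeat x voice x condition),
#' matching the design's recording enumeration. Per-condition offsets on
#' coupling strength or accuracy SDs let tests construct worlds where, for
#' example, touch increases respiration coupling.
#'
#' @param design a `study_design`.
#' @param resp_cfg a [resp_sim_config()] (its `n_singers` and `seed` are
#'   overridden per trial).
#' @param perf_cfg a [perf_sim_config()] (its `seed` is overridden per
#'   stream).
#' @param score a score data.frame; default [example_score()] for the
#'   design.
#' @param condition_effects optional named list of per-condition additive
#'   offsets on config fields, e.g.
#'   `list(coupling_strength = c(touch = 0.3))`.
#' @param seed master seed; all child seeds derive from it.
#' @param include_respiration set FALSE to skip the respiration trials
#'   (fast note-only worlds for accuracy calibration studies).
#' @return list with `design`, `score`, `respiration` (data.frame `block`,
#'   `condition` + list-column of ensembles), `notes` (one data.frame of
#'   all note events with identifying columns).
#' @export
generate_study_dataset <- function(design, resp_cfg = resp_sim_config(),
                                   perf_cfg = perf_sim_config(),
                                   score = NULL,
                                   condition_effects = NULL,
                                   seed = 1L,
                                   include_respiration = TRUE) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(score)) score <- example_score(design)
  recs <- enumerate_recordings(design)
  # unison streams: one per (piece, voice, condition, repeat), singers paired
  streams <- unique(recs[, c("piece", "unit", "block", "voice", "condition",
                             "repeat_index")])
  rownames(streams) <- NULL
  n_blocks <- length(design$blocks)
  n_cond <- length(design$conditions)
  seeds <- derive_seeds(seed, n_blocks * n_cond + nrow(streams))
  resp_seeds <- seeds[seq_len(n_blocks * n_cond)]
  perf_seeds <- seeds[-seq_len(n_blocks * n_cond)]

  labels <- singer_labels(design)
  resp_rows <- expand.grid(block = seq_len(n_blocks),
                           condition = design$conditions,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  respiration <- NULL
  if (include_respiration) {
    ensembles <- vector("list", nrow(resp_rows))
    for (i in seq_len(nrow(resp_rows))) {
      cfg <- apply_condition_effects(resp_cfg, condition_effects,
                                     resp_rows$condition[i])
      cfg$n_singers <- length(labels)
      cfg$seed <- resp_seeds[i]
      ensembles[[i]] <- generate_respiration_ensemble(cfg, singers = labels)
    }
    respiration <- resp_rows
    respiration$ensemble <- ensembles
  }

  notes <- vector("list", nrow(streams))
  for (i in seq_len(nrow(streams))) {
    cfg <- apply_condition_effects(perf_cfg, condition_effects,
                                   streams$condition[i])
    cfg$seed <- perf_seeds[i]
    v <- streams$voice[i]
    line <- score[score$voice == v & score$piece == streams$piece[i], ]
    if (nrow(line) == 0)
      stop("score has no events for voice ", v, ", piece ",
           streams$piece[i])
    ev <- generate_unison_performance(line, cfg,
                                      singers = paste0(v, "_", 1:2))
    ev$voice <- v
    ev$piece <- streams$piece[i]
    ev$unit <- streams$unit[i]
    ev$block <- streams$block[i]
    ev$condition <- streams$condition[i]
    ev$repeat_index <- streams$repeat_index[i]
    notes[[i]] <- ev
  }
  notes <- do.call(rbind, notes)
  rownames(notes) <- NULL
  list(design = design, score = score, respiration = respiration,
       notes = notes)
}
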