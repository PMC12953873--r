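#' Wavelet specification for respiration phase extraction
#'
#' @param f_min,f_max analysis band edges in Hz; default 0.025-0.40 Hz,
#'   bracketing spontaneous adult breathing rates.
#' @param n_components number of frequency components across the band.
#' @param omega0 Morlet mother-wavelet parameter (dimensionless centre
#'   frequency); 6 balances time and frequency resolution.
#' @param spacing `"logarithmic"` (default; the band spans more than a
#'   decade) or `"linear"`.
#' @return A list of class `wavelet_spec`.
#' @export
wavelet_spec <- function(f_min = 0.025, f_max = 0.40, n_components = 10,
                         omega0 = 6, spacing = c("logarithmic", "linear")) {
  spacing <- match.arg(spacing)
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  if (n_components < 1) stop("n_components must be >= 1")
  structure(list(f_min = f_min, f_max = f_max,
                 n_components = as.integer(n_components),
                 omega0 = omega0, spacing = spacing),
            class = "wavelet_spec")
}

#' Component centre frequencies of a wavelet spec
#' @param spec a [wavelet_spec()].
#' @return numeric vector of frequencies (Hz), ascending.
#' @export
component_frequencies <- function(spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (spec$n_components == 1) return(sqrt(spec$f_min * spec$f_max))
  if (spec$spacing == "logarithmic") {
    exp(seq(log(spec$f_min), log(spec$f_max),
            length.out = spec$n_components))
  } else {
    seq(spec$f_min, spec$f_max, length.out = spec$n_components)
  }
}

#' Frequency-band membership of components
#'
#' Partition used for band-split coupling predictors, following the
#' autonomic-frequency convention: very low < 0.04 Hz, low 0.04-0.15 Hz,
#' high 0.15-0.40 Hz; membership by component centre frequency.
#'
#' @param freqs numeric frequencies in Hz.
#' @return character vector in `c("very_low", "low", "high")`.
#' @export
frequency_band <- function(freqs) {
  ifelse(freqs < 0.04, "very_low", ifelse(freqs < 0.15, "low", "high"))
}

#' Clip a respiration trace to a maximum duration
#'
#' Respiration trials are clipped to a common window (360 s in the
#' reference analysis) so coupling indices are comparable across trials.
#'
#' @param trace a `respiration_trace` ([get_trace()]) or
#'   `respiration_ensemble`.
#' @param max_duration window length in seconds.
#' @return The clipped object, with exactly
#'   `floor(max_duration * sampling_rate)` samples from the start.
#' @export
clip_trace <- function(trace, max_duration = 360) {
  n_keep <- floor(max_duration * trace$sampling_rate)
  if (inherits(trace, "respiration_ensemble")) {
    if (nrow(trace$samples) < n_keep)
      stop("ensemble shorter than ", max_duration, " s")
    trace$samples <- trace$samples[seq_len(n_keep), , drop = FALSE]
    trace$time <- trace$time[seq_len(n_keep)]
    return(trace)
  }
  stopifnot(inherits(trace, "respiration_trace"))
  if (length(trace$samples) < n_keep)
    stop("trace for singer '", trace$singer, "' shorter than ",
         max_duration, " s")
  trace$samples <- trace$samples[seq_len(n_keep)]
  trace
}

# Analytic Morlet scale for a Fourier frequency (Torrence & Compo):
# period = 4*pi*s / (omega0 + sqrt(2 + omega0^2)).
morlet_scale <- function(freq, omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freq)
}

#' Instantaneous phases by Morlet continuous wavelet transform
#'
#' Computes the complex analytic Morlet transform of a (detrended,
#' standardized) respiration trace by FFT and returns the coefficient
#' argument at each time and frequency component, together with a
#' cone-of-influence mask flagging samples closer to a series edge than
#' the wavelet's e-folding time (sqrt(2) x scale), where phases are
#' edge-contaminated.
#'
#' @param trace a `respiration_trace`, or a plain numeric vector (then
#'   `sampling_rate` must be given).
#' @param spec a [wavelet_spec()].
#' @param sampling_rate sampling rate in Hz when `trace` is a bare vector.
#' @return list of class `wavelet_phases`: `phase` (time x component
#'   matrix, radians in (-pi, pi]), `valid` (logical matrix, TRUE inside
#'   the cone of influence), `freqs`, `sampling_rate`.
#' @export
morlet_phases <- function(trace, spec = wavelet_spec(),
                          sampling_rate = NULL) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (inherits(trace, "respiration_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
  } else {
    x <- as.numeric(trace)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare numeric trace")
  }
  if (fs <= 2 * spec$f_max)
    stop("sampling rate ", fs, " Hz is below the Nyquist rate for f_max = ",
         spec$f_max, " Hz")
  n <- length(x)
  dt <- 1 / fs
  # linear detrend + standardize: belt units/offset are arbitrary and the
  # indices are phase-based
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  sdx <- stats::sd(x)
  if (sdx > 0) x <- x / sdx
  xhat <- stats::fft(x)
  k <- seq_len(n) - 1L
  omega <- 2 * pi * ifelse(k <= n / 2, k, k - n) / (n * dt)
  freqs <- component_frequencies(spec)
  phase <- matrix(0, n, length(freqs))
  valid <- matrix(TRUE, n, length(freqs))
  tsec <- (tt - 1L) * dt
  total <- (n - 1L) * dt
  for (j in seq_along(freqs)) {
    s <- morlet_scale(freqs[j], spec$omega0)
    psi_hat <- ifelse(omega > 0,
                      exp(-0.5 * (s * omega - spec$omega0)^2), 0)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / n
    phase[, j] <- Arg(w)
    efold <- sqrt(2) * s
    valid[, j] <- tsec >= efold & tsec <= total - efold
  }
  structure(list(phase = phase, valid = valid, freqs = freqs,
                 sampling_rate = fs),
            class = "wavelet_phases")
}

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_phase <- function(x) {
  w <- atan2(sin(x), cos(x))
  # atan2 maps the cut to +pi except for -0 artefacts; pin exact -pi to +pi
  w[w == -pi] <- pi
  w
}

#' Pairwise phase differences between two wavelet-phase objects
#'
#' @param phases_a,phases_b `wavelet_phases` on the same time base and
#'   spec.
#' @return list of class `phase_differences`: `delta` (time x component,
#'   wrapped to (-pi, pi], oriented a minus b), `valid` (both inputs
#'   inside their cones of influence), `freqs`.
#' @export
phase_differences <- function(phases_a, phases_b) {
  stopifnot(inherits(phases_a, "wavelet_phases"),
            inherits(phases_b, "wavelet_phases"))
  if (!identical(dim(phases_a$phase), dim(phases_b$phase)) ||
      !isTRUE(all.equal(phases_a$freqs, phases_b$freqs)))
    stop("phase arrays differ in length or frequency components")
  structure(list(delta = wrap_phase(phases_a$phase - phases_b$phase),
                 valid = phases_a$valid & phases_b$valid,
                 freqs = phases_a$freqs),
            class = "phase_differences")
}

check_valid_points <- function(delta) {
  if (length(delta) == 0)
    stop("no valid phase-difference points (all masked by the cone of influence)")
  delta
}

#' Absolute coupling index
#'
#' Fraction of valid phase-difference points inside the phase-locking
#' window `|delta| <= pi/4` (closed interval). Under independent phases
#' (uniform differences) the expectation is 1/4.
#'
#' @param delta numeric vector of phase differences in (-pi, pi] (valid
#'   points only).
#' @return value in [0, 1].
#' @export
aci <- function(delta) {
  delta <- check_valid_points(delta)
  mean(abs(delta) <= pi / 4)
}

#' Phase synchronization index
#'
#' Circular concentration of the phase differences: the mean resultant
#' length `|mean(exp(i * delta))|`. Unlike [aci()], every point
#' contributes, with larger phase differences pulling the index down
#' smoothly. Under uniform differences the expectation scales as
#' `n^(-1/2)`.
#'
#' @inheritParams aci
#' @return value in [0, 1].
#' @export
psi <- function(delta) {
  delta <- check_valid_points(delta)
  Mod(mean(exp(1i * delta)))
}

#' Integrative coupling index (directional)
#'
#' Fraction of valid phase-difference points in the positive half of the
#' locking window, `delta in (0, +pi/4]`, for `delta` oriented a minus b:
#' the asymmetric companion of [aci()], counting only points where a
#' leads b within the locking range. Under uniform differences the
#' expectation is 1/8.
#'
#' @inheritParams aci
#' @return value in [0, 1].
#' @export
ici <- function(delta) {
  delta <- check_valid_points(delta)
  mean(delta > 0 & delta <= pi / 4)
}

#' Pairwise coupling indices for a respiration ensemble
#'
#' Clips the ensemble, extracts Morlet phases per singer, and computes
#' ACI, PSI and ICI for every ordered singer pair at every frequency
#' component (ACI and PSI are symmetric and repeated on both orientations;
#' ICI is directional, `singer_a` leading).
#'
#' @param ensemble a `respiration_ensemble`.
#' @param spec a [wavelet_spec()].
#' @param clip_duration seconds to clip to before analysis (NULL to skip).
#' @return data.frame: `singer_a`, `singer_b`, `frequency`, `aci`, `psi`,
#'   `ici`.
#' @export
ensemble_coupling <- function(ensemble, spec = wavelet_spec(),
                              clip_duration = 360) {
  stopifnot(inherits(ensemble, "respiration_ensemble"))
  if (!is.null(clip_duration))
    ensemble <- clip_trace(ensemble, clip_duration)
  singers <- ensemble$singers
  phases <- lapply(singers, function(s)
    morlet_phases(get_trace(ensemble, s), spec))
  names(phases) <- singers
  out <- list()
  k <- 0L
  for (ia in seq_along(singers)) {
    for (ib in seq_along(singers)) {
      if (ia == ib) next
      dp <- phase_differences(phases[[ia]], phases[[ib]])
      for (j in seq_along(dp$freqs)) {
        d <- dp$delta[dp$valid[, j], j]
        k <- k + 1L
        out[[k]] <- data.frame(singer_a = singers[ia],
                               singer_b = singers[ib],
                               frequency = dp$freqs[j],
                               aci = aci(d), psi = psi(d), ici = ici(d),
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate pairwise coupling to singer and voice means
#'
#' Each singer's coupling is the mean of their indices with all other
#' singers (7 partners in the default ensemble), averaged over the
#' frequency components of the requested band; a voice's coupling is the
#' mean of its two singers' values.
#'
#' @param pairwise data.frame from [ensemble_coupling()].
#' @param design a `study_design` (provides singer/voice membership).
#' @param band `"all"` or one of `"very_low"`, `"low"`, `"high"` (see
#'   [frequency_band()]).
#' @return list of class `coupling_result`: `singer_means` (singer x
#'   index), `voice_means` (voice x index), `band`.
#' @export
aggregate_coupling <- function(pairwise, design, band = "all") {
  labels <- singer_labels(design)
  have <- unique(pairwise[, c("singer_a", "singer_b")])
  expected <- expand.grid(singer_a = labels, singer_b = labels,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- expected[expected$singer_a != expected$singer_b, ]
  miss <- !paste(expected$singer_a, expected$singer_b) %in%
    paste(have$singer_a, have$singer_b)
  if (any(miss))
    stop("missing singer pair(s): ",
         paste(paste0(expected$singer_a[miss], "-", expected$singer_b[miss]),
               collapse = ", "))
  if (band != "all") {
    keep <- frequency_band(pairwise$frequency) == band
    if (!any(keep)) stop("no frequency components in band '", band, "'")
    pairwise <- pairwise[keep, ]
  }
  idx_cols <- c("aci", "psi", "ici")
  singer_means <- do.call(rbind, lapply(labels, function(s) {
    rows <- pairwise[pairwise$singer_a == s, ]
    cbind(data.frame(singer = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(rows[, idx_cols]))))
  }))
  voice_of <- rep(design$voices, each = design$singers_per_voice)
  names(voice_of) <- labels
  singer_means$voice <- voice_of[singer_means$singer]
  voice_means <- do.call(rbind, lapply(design$voices, function(v) {
    rows <- singer_means[singer_means$voice == v, ]
    cbind(data.frame(voice = v, stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(rows[, idx_cols]))))
  }))
  rownames(singer_means) <- rownames(voice_means) <- NULL
  structure(list(singer_means = singer_means, voice_means = voice_means,
                 band = band),
            class = "coupling_result")
}

#' Intercorrelations of the three coupling indices
#'
#' Pearson correlations (with p-values) between ACI, PSI and ICI across
#' matched observation units.
#'
#' @param values data.frame with columns `aci`, `psi`, `ici`, one row per
#'   matched unit.
#' @return data.frame: `index_a`, `index_b`, `r`, `p`, `n`.
#' @export
index_correlations <- function(values) {
  idx <- c("aci", "psi", "ici")
  stopifnot(all(idx %in% names(values)))
  if (nrow(values) < 3)
    stop("need at least 3 matched observations to correlate indices")
  combs <- utils::combn(idx, 2)
  out <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    ct <- stats::cor.test(values[[a]], values[[b]], method = "pearson")
    data.frame(index_a = a, index_b = b,
               r = unname(ct$estimate), p = ct$p.value, n = nrow(values),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
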