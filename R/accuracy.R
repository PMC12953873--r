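#' Convert fundamental frequency to fractional MIDI pitch
#'
#' Concert tuning: a' = 440 Hz = MIDI 69; `69 + 12 * log2(f0 / 440)`.
#'
#' @param f0 frequency in Hz; must be positive.
#' @return fractional MIDI pitch.
#' @export
hz_to_midi <- function(f0) {
  if (any(f0 <= 0)) stop("f0 must be positive")
  69 + 12 * log2(f0 / 440)
}

#' Convert fractional MIDI pitch to frequency
#' @param midi fractional MIDI pitch.
#' @return frequency in Hz.
#' @export
midi_to_hz <- function(midi) {
  440 * 2^((midi - 69) / 12)
}

#' Interval between two pitches in cents
#'
#' One equal-tempered semitone is 1 MIDI unit = 100 cents (so 0.5 MIDI =
#' 50 cents).
#'
#' @param midi_a,midi_b fractional MIDI pitches.
#' @return `100 * (midi_a - midi_b)` in cents.
#' @export
cents_between <- function(midi_a, midi_b) {
  100 * (midi_a - midi_b)
}

#' The Pythagorean comma in cents
#'
#' The gap between twelve pure fifths and seven octaves,
#' `1200 * log2(3^12 / 2^19)`, about 23.46 cents; it bounds the
#' discrepancy between equal-tempered and just scale targets.
#'
#' @return the comma in cents.
#' @export
pythagorean_comma <- function() {
  1200 * log2(3^12 / 2^19)
}

# Recording-instance grouping key shared by the cascade stages.
recording_key <- function(events) {
  interaction(events$voice, events$piece, events$condition, events$block,
              events$repeat_index, drop = TRUE)
}

#' Link note events to their score targets
#'
#' Joins events to the score by (voice, piece, event_index), derives
#' fractional MIDI pitch from f0 and the pitch deviation from the score
#' target in fractional MIDI units.
#'
#' @param events note-event data.frame (columns `singer`, `voice`,
#'   `piece`, `condition`, `block`, `repeat_index`, `event_index`,
#'   `onset_s`, `f0_hz`).
#' @param score score data.frame (see [example_score()]).
#' @return events with added `midi_pitch`, `score_midi`, `score_beats`,
#'   `deviation`.
#' @export
link_score <- function(events, score) {
  key_e <- paste(events$voice, events$piece, events$event_index, sep = "\r")
  key_s <- paste(score$voice, score$piece, score$event_index, sep = "\r")
  idx <- match(key_e, key_s)
  if (anyNA(idx)) {
    bad <- utils::head(unique(key_e[is.na(idx)]), 3)
    stop("event(s) without score target, e.g.: ",
         paste(gsub("\r", "/", bad), collapse = "; "))
  }
  events$midi_pitch <- hz_to_midi(events$f0_hz)
  events$score_midi <- score$midi_pitch[idx]
  events$score_beats <- score$onset_beats[idx]
  events$deviation <- events$midi_pitch - events$score_midi
  events
}

#' Remove gross singing errors
#'
#' Drops events at least one semitone (1.0 fractional MIDI) away from the
#' score pitch, or more than 300 ms away from the event's reference onset.
#' The reference onset is either the median onset of that event index
#' across the singers of the recording (`"ensemble_median"`, robust and
#' score-timeline-free, the default) or a score-predicted time
#' (`"score"`): the recording's nominal beat times mapped to performance
#' time by an OLS beat-to-seconds fit, or by a known `tempo`.
#'
#' @param events linked events (see [link_score()]).
#' @param pitch_threshold fractional-MIDI cutoff (removed when
#'   `abs(deviation) >= pitch_threshold`); default 1 semitone.
#' @param onset_threshold seconds (removed when strictly exceeded);
#'   default 0.300 s.
#' @param reference `"ensemble_median"` or `"score"`.
#' @param tempo beats per second for `reference = "score"`; when NULL the
#'   beat-to-time map is fitted per recording.
#' @return list: `events` (kept rows), `report` (counts and fractions
#'   removed at each rule).
#' @export
remove_gross_errors <- function(events, pitch_threshold = 1.0,
                                onset_threshold = 0.300,
                                reference = c("ensemble_median", "score"),
                                tempo = NULL) {
  reference <- match.arg(reference)
  if (is.null(events$deviation))
    stop("events must be linked to the score first (see link_score)")
  gross_pitch <- abs(events$deviation) >= pitch_threshold
  ref_onset <- rep(NA_real_, nrow(events))
  grp <- recording_key(events)
  for (g in levels(grp)) {
    rows <- which(grp == g)
    e <- events[rows, ]
    if (reference == "ensemble_median") {
      med <- tapply(e$onset_s, e$event_index, stats::median)
      ref_onset[rows] <- med[as.character(e$event_index)]
    } else if (!is.null(tempo)) {
      ref_onset[rows] <- e$score_beats / tempo
    } else {
      fit <- stats::lm.fit(cbind(1, e$score_beats), e$onset_s)
      ref_onset[rows] <- fit$coefficients[1] + fit$coefficients[2] * e$score_beats
    }
  }
  gross_onset <- abs(events$onset_s - ref_onset) > onset_threshold
  keep <- !(gross_pitch | gross_onset)
  report <- data.frame(
    n_total = nrow(events),
    n_removed_pitch = sum(gross_pitch),
    n_removed_onset = sum(gross_onset & !gross_pitch),
    n_removed = sum(!keep),
    fraction_removed = mean(!keep))
  list(events = events[keep, , drop = FALSE], report = report)
}

#' Remove pitch drift by linear regression
#'
#' Within each singer x recording instance, ordinary least squares of the
#' pitch deviation on onset time; the fitted line (drift plus constant
#' offset) is subtracted, leaving `residual_deviation`. Applied exactly
#' once: a processing flag guards against re-detrending.
#'
#' @param events linked events surviving gross-error removal.
#' @return events with added `residual_deviation` and attribute
#'   `detrended = TRUE`.
#' @export
detrend_pitch <- function(events) {
  if (isTRUE(attr(events, "detrended")))
    stop("events have already been detrended")
  if (is.null(events$deviation))
    stop("events must be linked to the score first (see link_score)")
  grp <- interaction(recording_key(events), events$singer, drop = TRUE)
  res <- rep(NA_real_, nrow(events))
  for (g in levels(grp)) {
    rows <- which(grp == g)
    t <- events$onset_s[rows]
    d <- events$deviation[rows]
    if (length(rows) >= 3) {
      if (stats::sd(t) == 0)
        stop("degenerate regression group (all onsets equal): ", g)
      res[rows] <- stats::residuals(stats::lm.fit(cbind(1, t), d))
    } else {
      # too short to estimate a slope; absorb the constant offset only
      res[rows] <- d - mean(d)
    }
  }
  events$residual_deviation <- res
  attr(events, "detrended") <- TRUE
  events
}

#' Match two singers' note streams by score event
#'
#' @param stream_a,stream_b detrended event data.frames for the two
#'   singers of one (voice, piece, recording instance).
#' @return data.frame of matched pairs: `event_index`, `onset_a`,
#'   `onset_b`, `residual_a`, `residual_b`. Events present in only one
#'   stream yield no pair.
#' @export
match_pairs <- function(stream_a, stream_b) {
  if (anyDuplicated(stream_a$event_index) ||
      anyDuplicated(stream_b$event_index))
    stop("duplicate event_index within a stream")
  common <- intersect(stream_a$event_index, stream_b$event_index)
  ia <- match(common, stream_a$event_index)
  ib <- match(common, stream_b$event_index)
  data.frame(event_index = common,
             onset_a = stream_a$onset_s[ia],
             onset_b = stream_b$onset_s[ib],
             residual_a = stream_a$residual_deviation[ia],
             residual_b = stream_b$residual_deviation[ib])
}

#' Match unison pairs across a whole event table
#'
#' Splits the table by recording instance, pairs the two singers' streams
#' with [match_pairs()], and carries the identifying columns.
#'
#' @param events detrended events for exactly two singers per recording
#'   instance.
#' @return data.frame of pairs with identifying columns `voice`, `piece`,
#'   `unit`, `condition`, `block`, `repeat_index`.
#' @export
build_pairs <- function(events) {
  grp <- recording_key(events)
  out <- lapply(levels(grp), function(g) {
    e <- events[grp == g, ]
    singers <- sort(unique(e$singer))
    if (length(singers) != 2) return(NULL)
    p <- match_pairs(e[e$singer == singers[1], ], e[e$singer == singers[2], ])
    if (nrow(p) == 0) return(NULL)
    id <- e[1, intersect(c("voice", "piece", "unit", "condition", "block",
                           "repeat_index"), names(e)), drop = FALSE]
    cbind(id[rep(1, nrow(p)), , drop = FALSE], p, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Apply the pair-level accuracy filters
#'
#' Flags each matched pair for the two analyses independently: the
#' intonation set drops pairs whose residual pitch difference exceeds 2.5
#' semitones (voice splits, reading errors); the timing set drops pairs
#' whose onsets differ by more than 300 ms (deemed singing errors). A
#' pair can survive one filter and not the other. The 1.5 x IQR outlier
#' diagnostic on onset gaps is computed and reported, but not used as a
#' filter.
#'
#' @param pairs data.frame from [build_pairs()] / [match_pairs()].
#' @param pitch_threshold fractional-MIDI cutoff (default 2.5 semitones),
#'   removal when strictly exceeded.
#' @param onset_threshold seconds (default 0.300), removal when strictly
#'   exceeded.
#' @return list: `pairs` (with logical `kept_intonation`, `kept_timing`),
#'   `intonation` and `timing` (the filtered subsets), `report` (counts,
#'   fractions, and the IQR diagnostic in seconds).
#' @export
filter_pairs <- function(pairs, pitch_threshold = 2.5,
                         onset_threshold = 0.300) {
  pitch_gap <- abs(pairs$residual_a - pairs$residual_b)
  onset_gap <- abs(pairs$onset_a - pairs$onset_b)
  pairs$kept_intonation <- pitch_gap <= pitch_threshold
  pairs$kept_timing <- onset_gap <= onset_threshold
  q <- stats::quantile(onset_gap, c(0.25, 0.75), na.rm = TRUE)
  iqr_criterion <- unname(q[2] + 1.5 * (q[2] - q[1]))
  report <- data.frame(
    n_pairs = nrow(pairs),
    n_removed_intonation = sum(!pairs$kept_intonation),
    fraction_removed_intonation = mean(!pairs$kept_intonation),
    n_removed_timing = sum(!pairs$kept_timing),
    fraction_removed_timing = mean(!pairs$kept_timing),
    iqr_onset_criterion_s = iqr_criterion)
  list(pairs = pairs,
       intonation = pairs[pairs$kept_intonation, , drop = FALSE],
       timing = pairs[pairs$kept_timing, , drop = FALSE],
       report = report)
}

# One accuracy record from already-filtered intonation/timing pair sets.
accuracy_from_sets <- function(intonation, timing) {
  mape <- if (nrow(intonation) > 0)
    mean(abs(intonation$residual_a - intonation$residual_b)) * 100 else NA_real_
  moe <- if (nrow(timing) > 0)
    mean(abs(timing$onset_a - timing$onset_b)) else NA_real_
  data.frame(
    MAPE = mape, MOE = moe,
    LMAPE = ifelse(!is.na(mape) & mape > 0, -log(mape / 100), NA_real_),
    LMOE = ifelse(!is.na(moe) & moe > 0, -log(moe), NA_real_),
    n_pairs_intonation = nrow(intonation),
    n_pairs_timing = nrow(timing))
}

#' Accuracy records at an aggregation level
#'
#' MAPE is the mean absolute residual pitch difference between the two
#' singers (reported in cents); MOE the mean absolute onset difference
#' (seconds). LMAPE and LMOE are their negative natural logarithms, taken
#' on fractional-MIDI and second scales respectively, so higher values
#' mean higher accuracy; they are undefined (NA, flagged) for empty or
#' zero-error groups.
#'
#' @param filtered result of [filter_pairs()] on pairs carrying
#'   identifying columns.
#' @param level `"piece"` (one record per piece repeat x voice x
#'   condition) or `"recording_unit"` (one per voice x block x condition).
#' @return data.frame of accuracy records with the level's identifying
#'   columns.
#' @export
accuracy_table <- function(filtered, level = c("piece", "recording_unit")) {
  level <- match.arg(level)
  pairs <- filtered$pairs
  id_cols <- if (level == "piece")
    c("voice", "piece", "unit", "condition", "block", "repeat_index")
  else c("voice", "unit", "condition", "block")
  grp <- interaction(pairs[, intersect(id_cols, names(pairs))], drop = TRUE)
  out <- lapply(levels(grp), function(g) {
    p <- pairs[grp == g, ]
    rec <- accuracy_from_sets(p[p$kept_intonation, , drop = FALSE],
                              p[p$kept_timing, , drop = FALSE])
    cbind(p[1, intersect(id_cols, names(p)), drop = FALSE], rec,
          row.names = NULL)
  })
  res <- do.call(rbind, out)
  empty <- is.na(res$MAPE) | is.na(res$MOE)
  if (any(empty))
    warning(sum(empty), " group(s) with an empty intonation or timing set; ",
            "records flagged NA and excluded downstream")
  res
}

#' Run the full accuracy cascade on a note-event table
#'
#' Fixed stage order: score linking, gross-error removal, per-singer pitch
#' detrending, unison pair matching, pair filters, then aggregation to the
#' piece-level and recording-unit-level accuracy tables.
#'
#' @param events raw note events (see [generate_study_dataset()]).
#' @param score the score data.frame.
#' @param gross_pitch_threshold,gross_onset_threshold gross-error cutoffs
#'   (1 semitone; 0.300 s).
#' @param pair_pitch_threshold,pair_onset_threshold pair-filter cutoffs
#'   (2.5 semitones; 0.300 s).
#' @param reference,tempo passed to [remove_gross_errors()].
#' @return list: `piece_table`, `unit_table`, `pairs`, `report` (gross +
#'   pair-filter reports).
#' @export
compute_accuracy <- function(events, score,
                             gross_pitch_threshold = 1.0,
                             gross_onset_threshold = 0.300,
                             pair_pitch_threshold = 2.5,
                             pair_onset_threshold = 0.300,
                             reference = "ensemble_median",
                             tempo = NULL) {
  linked <- link_score(events, score)
  gross <- remove_gross_errors(linked,
                               pitch_threshold = gross_pitch_threshold,
                               onset_threshold = gross_onset_threshold,
                               reference = reference, tempo = tempo)
  detrended <- detrend_pitch(gross$events)
  pairs <- build_pairs(detrended)
  filtered <- filter_pairs(pairs,
                           pitch_threshold = pair_pitch_threshold,
                           onset_threshold = pair_onset_threshold)
  list(piece_table = accuracy_table(filtered, "piece"),
       unit_table = accuracy_table(filtered, "recording_unit"),
       pairs = filtered$pairs,
       report = list(gross_errors = gross$report,
                     pair_filters = filtered$report))
}
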