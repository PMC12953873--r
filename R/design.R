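#' Study design for an ensemble hyperscanning recording session
#'
#' Encodes the lattice of voices, pieces, recording units, blocks and
#' spatial conditions that shapes every downstream data set: which pieces
#' were sung how many times by which voice in which condition, and how the
#' repeated recording units were arranged into blocks.
#'
#' The default design (see [default_design()]) is the eight-singer,
#' four-voice Renaissance-ensemble session: eight musical pieces grouped
#' into three recording units ("Agnus" x3, "Kyrie" x2, "Josquin" x3 blocks),
#' three spatial arrangements (modern, touch, no_touch), two singers per
#' voice, and per-voice repeat counts summing to 31/25/25/31.
#'
#' @param voices character vector of voice labels.
#' @param singers_per_voice integer, singers performing each voice in unison.
#' @param conditions character vector of spatial-arrangement labels.
#' @param pieces data.frame with columns `piece`, `unit`, and one integer
#'   repeat-count column per voice (repeats per condition).
#' @param blocks character vector of recording-unit labels, one per block,
#'   in performance order.
#' @param n_frequency_components number of wavelet frequency components
#'   used by the respiration analysis (bookkeeping for grid counts).
#' @return An object of class `study_design`.
#' @examples
#' d <- default_design()
#' nrow(enumerate_recordings(d))  # 672
#' @export
study_design <- function(voices, singers_per_voice, conditions, pieces,
                         blocks, n_frequency_components = 10L) {
  stopifnot(is.character(voices), length(voices) >= 1,
            is.character(conditions), length(conditions) >= 1,
            is.data.frame(pieces))
  singers_per_voice <- as.integer(singers_per_voice)
  if (singers_per_voice < 1) stop("singers_per_voice must be >= 1")
  need <- c("piece", "unit", voices)
  missing_cols <- setdiff(need, names(pieces))
  if (length(missing_cols) > 0)
    stop("pieces table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(pieces$piece))
    stop("each piece must belong to exactly one recording unit (duplicated piece rows)")
  rep_mat <- as.matrix(pieces[, voices, drop = FALSE])
  if (any(rep_mat < 0) || any(rep_mat != round(rep_mat)))
    stop("repeat counts must be non-negative integers")
  if (!all(pieces$unit %in% blocks))
    stop("every piece's unit must appear in the block list")
  if (!all(blocks %in% pieces$unit))
    stop("every block's unit must own at least one piece")
  design <- structure(
    list(voices = voices,
         singers_per_voice = singers_per_voice,
         conditions = conditions,
         pieces = pieces,
         blocks = blocks,
         n_frequency_components = as.integer(n_frequency_components)),
    class = "study_design")
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$voices), "voices x",
      x$singers_per_voice, "singers/voice,",
      length(x$conditions), "conditions,",
      nrow(x$pieces), "pieces in", length(unique(x$blocks)),
      "recording units /", length(x$blocks), "blocks\n")
  cat("Per-voice repeat sums:",
      paste(x$voices, colSums(x$pieces[, x$voices, drop = FALSE]),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of singers in a design
#' @param design a `study_design`.
#' @return integer count of singers.
#' @export
n_singers <- function(design) {
  length(design$voices) * design$singers_per_voice
}

#' Singer labels for a design
#'
#' Labels are `<voice>_1`, `<voice>_2`, ... in voice order.
#' @param design a `study_design`.
#' @return character vector of singer labels.
#' @export
singer_labels <- function(design) {
  as.vector(vapply(design$voices, function(v)
    paste0(v, "_", seq_len(design$singers_per_voice)),
    character(design$singers_per_voice)))
}

#' The default session design
#'
#' Reads the bundled design file (`extdata/design_default.json`), an
#' editable JSON description of the default eight-singer session; other
#' study shapes can be described in the same schema and loaded with
#' [read_design()].
#'
#' @return A `study_design`.
#' @export
default_design <- function() {
  path <- system.file("extdata", "design_default.json", package = "choirsync",
                      mustWork = TRUE)
  read_design(path)
}

#' Read a study design from a JSON file
#'
#' Schema: `{voices, singers_per_voice, conditions,
#' pieces: [{name, unit, repeats_per_voice: {voice: n, ...}}, ...],
#' blocks: [unit, ...], n_frequency_components}`.
#'
#' @param path path to a design JSON file.
#' @return A `study_design`.
#' @export
read_design <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  voices <- unlist(j$voices)
  pieces <- do.call(rbind, lapply(j$pieces, function(p) {
    reps <- p$repeats_per_voice
    row <- data.frame(piece = p$name, unit = p$unit,
                      stringsAsFactors = FALSE)
    for (v in voices) row[[v]] <- if (is.null(reps[[v]])) 0L else as.integer(reps[[v]])
    row
  }))
  study_design(voices = voices,
               singers_per_voice = j$singers_per_voice,
               conditions = unlist(j$conditions),
               pieces = pieces,
               blocks = unlist(j$blocks),
               n_frequency_components =
                 if (is.null(j$n_frequency_components)) 10L
                 else j$n_frequency_components)
}

# Round-robin assignment of a piece's per-condition repeats to the blocks
# of its recording unit: repeats r over b blocks gives ceiling/floor shares
# (e.g. 4 repeats over 3 blocks -> 2/1/1). Returns integer block indices
# (into design$blocks), one per repeat.
assign_repeats_to_blocks <- function(design, piece, n_repeats) {
  unit <- design$pieces$unit[design$pieces$piece == piece]
  block_idx <- which(design$blocks == unit)
  if (n_repeats == 0) return(integer(0))
  block_idx[((seq_len(n_repeats) - 1L) %% length(block_idx)) + 1L]
}

#' Enumerate every expected audio recording
#'
#' Expands the design into one descriptor per recorded file: each
#' (piece repeat x voice-with-part x singer-in-voice x condition)
#' combination. For the default design this is
#' (31 + 25 + 25 + 31) x 2 singers x 3 conditions = 672 files.
#'
#' @param design a `study_design`.
#' @return data.frame with columns `piece`, `unit`, `block`, `voice`,
#'   `singer`, `condition`, `repeat_index` (repeat number of that piece for
#'   that voice within a condition).
#' @export
enumerate_recordings <- function(design) {
  stopifnot(inherits(design, "study_design"))
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(design$pieces))) {
    piece <- design$pieces$piece[i]
    for (v in design$voices) {
      r <- design$pieces[[v]][i]
      if (r == 0) next
      blocks <- assign_repeats_to_blocks(design, piece, r)
      for (cond in design$conditions) {
        for (s in seq_len(design$singers_per_voice)) {
          k <- k + 1L
          out[[k]] <- data.frame(
            piece = piece, unit = design$pieces$unit[i],
            block = blocks, voice = v,
            singer = paste0(v, "_", s), condition = cond,
            repeat_index = seq_len(r), stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count analysis observations at a given level
#'
#' Closed-form counting rules for the row counts every downstream table
#' must have. Levels:
#' \describe{
#'   \item{audio_file}{one per recorded file (672 for the default design).}
#'   \item{piece}{one per piece repeat x voice x condition, i.e. per unison
#'     pair of files (112 per condition; 336 for three).}
#'   \item{recording_unit}{one per voice x block x condition (96).}
#'   \item{block_voice_mean}{one per block x voice (32), conditions
#'     collapsed into a paired comparison.}
#'   \item{respiration_grid}{one per block x singer x frequency component
#'     (640), per condition.}
#' }
#'
#' @param design a `study_design`.
#' @param level one of `"audio_file"`, `"piece"`, `"recording_unit"`,
#'   `"block_voice_mean"`, `"respiration_grid"`.
#' @param conditions subset of `design$conditions` to count over (ignored
#'   for the levels that are per-condition or condition-collapsed);
#'   defaults to all.
#' @return integer observation count.
#' @export
observation_count <- function(design, level, conditions = design$conditions) {
  stopifnot(inherits(design, "study_design"))
  if (!all(conditions %in% design$conditions))
    stop("unknown condition(s): ",
         paste(setdiff(conditions, design$conditions), collapse = ", "))
  rep_sum <- sum(as.matrix(design$pieces[, design$voices, drop = FALSE]))
  n_blocks <- length(design$blocks)
  n_voices <- length(design$voices)
  switch(level,
    audio_file = rep_sum * design$singers_per_voice * length(conditions),
    piece = rep_sum * length(conditions),
    recording_unit = n_voices * n_blocks * length(conditions),
    block_voice_mean = n_blocks * n_voices,
    respiration_grid = n_blocks * n_singers(design) *
      design$n_frequency_components,
    stop("unknown observation level: ", level))
}
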