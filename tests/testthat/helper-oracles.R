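# Brute-force reference implementations used as independent oracles.

brute_aci <- function(delta) {
  hits <- 0L
  for (d in delta) if (abs(d) <= pi / 4) hits <- hits + 1L
  hits / length(delta)
}

brute_psi <- function(delta) {
  s <- 0 + 0i
  for (d in delta) s <- s + exp(1i * d)
  Mod(s / length(delta))
}

brute_ici <- function(delta) {
  hits <- 0L
  for (d in delta) if (d > 0 && d <= pi / 4) hits <- hits + 1L
  hits / length(delta)
}

brute_mape <- function(res_a, res_b) {
  s <- 0
  for (i in seq_along(res_a)) s <- s + abs(res_a[i] - res_b[i])
  100 * s / length(res_a)
}

brute_moe <- function(onset_a, onset_b) {
  s <- 0
  for (i in seq_along(onset_a)) s <- s + abs(onset_a[i] - onset_b[i])
  s / length(onset_a)
}

brute_pair_filter <- function(pairs, pitch_thr = 2.5, onset_thr = 0.3) {
  keep_int <- keep_tim <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    keep_int[i] <- abs(pairs$residual_a[i] - pairs$residual_b[i]) <= pitch_thr
    keep_tim[i] <- abs(pairs$onset_a[i] - pairs$onset_b[i]) <= onset_thr
  }
  list(intonation = which(keep_int), timing = which(keep_tim))
}

# Simulated unit-level analysis table with a known coupling -> accuracy
# slope and voice/block random intercepts.
simulate_unit_table <- function(beta, n_blocks = 8, sd_voice = 0.15,
                                sd_block = 0.15, sd_eps = 0.25, seed = 1) {
  set.seed(seed)
  voices <- c("soprano", "altus", "tenor", "bassus")
  conds <- c("modern", "touch", "no_touch")
  tab <- expand.grid(voice = voices, block = seq_len(n_blocks),
                     condition = conds, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  b_voice <- stats::rnorm(length(voices), 0, sd_voice)
  names(b_voice) <- voices
  b_block <- stats::rnorm(n_blocks, 0, sd_block)
  tab$aci <- stats::runif(nrow(tab), 0.2, 0.6)
  tab$LMOE <- 2.8 + beta * tab$aci + b_voice[tab$voice] +
    b_block[tab$block] + stats::rnorm(nrow(tab), 0, sd_eps)
  tab$LMAPE <- tab$LMOE
  tab
}

# A minimal one-voice score line for direct performance-simulation tests.
toy_score <- function(n = 20, pitch = 60, beat_step = 1) {
  data.frame(voice = "soprano", piece = "toy",
             event_index = seq_len(n),
             midi_pitch = pitch,
             onset_beats = (seq_len(n) - 1) * beat_step,
             duration_beats = beat_step,
             stringsAsFactors = FALSE)
}

# Wrap a two-singer stream into the full event-table shape the cascade
# expects.
as_event_table <- function(ev, voice = "soprano", piece = "toy",
                           condition = "touch", block = 1L,
                           repeat_index = 1L) {
  ev$voice <- voice
  ev$piece <- piece
  ev$condition <- condition
  ev$block <- block
  ev$repeat_index <- repeat_index
  ev
}
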