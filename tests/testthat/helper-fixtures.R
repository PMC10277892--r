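# shared fixtures and independent oracles, built in code at test time

toy_locus <- function(flank = 100, unit = "CAG", win = c(70, 150),
                      name = "HTT_CAG") {
  repeat_locus(name, unit, flank, win[1], win[2])
}

mono_locus <- function(flank = 60, win = c(10, 40), name = "mBAT24") {
  repeat_locus(name, "A", flank, win[1], win[2])
}

make_peakset <- function(repeats, heights, locus = toy_locus(),
                         sample_id = "s") {
  repeat_peakset(repeats, heights, locus, sample_id)
}

# Independent brute-force implementation of the instability index:
# main allele -> signal-to-noise cutoff -> retain -> joint normalization ->
# height-weighted repeat displacement, written as plain loops.
oracle_index <- function(repeats, heights, threshold_frac,
                         mode = c("all", "expansion", "contraction")) {
  mode <- match.arg(mode)
  hmax <- -Inf
  for (h in heights) if (h > hmax) hmax <- h
  m <- Inf
  for (i in seq_along(repeats))
    if (heights[i] == hmax && repeats[i] < m) m <- repeats[i]
  cutoff <- threshold_frac * hmax
  tot <- 0
  for (i in seq_along(repeats)) if (heights[i] >= cutoff) tot <- tot + heights[i]
  acc <- 0
  for (i in seq_along(repeats)) {
    if (heights[i] < cutoff) next
    d <- repeats[i] - m
    use <- switch(mode, all = TRUE, expansion = d > 0, contraction = d < 0)
    if (use) acc <- acc + heights[i] / tot * d
  }
  acc
}

# random peak set with <= 12 peaks in the toy locus window
random_peakset <- function(seed) {
  set.seed(seed)
  n <- sample(1:12, 1)
  repeats <- sort(sample(80:140, n))
  heights <- stats::runif(n, 1, 1000)
  make_peakset(repeats, heights, sample_id = paste0("rnd", seed))
}

# noiseless render parameters for exact round-trip checks
clean_render <- function(...) {
  render_params(size_jitter_sd_bp = 0, baseline_sd = 0,
                decay_per_repeat = 1, ...)
}

no_stutter <- function() stutter_params(0, 0, 0)
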