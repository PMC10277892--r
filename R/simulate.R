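#' Parameters of the somatic expansion model
#'
#' The cell-population model for a repeat tract aging in post-mitotic tissue:
#' each expansion-competent cell accrues `Poisson(expansion_rate * months)`
#' one-repeat gains and `Poisson(contraction_rate * months)` one-repeat
#' losses, independently, with the tract floored at 1 repeat. The remaining
#' `1 - expanding_frac` of cells keep the inherited length, which anchors the
#' modal allele of bulk tissue at the inherited repeat — the behaviour seen
#' in striatal electropherograms, where non-expanding cell types retain the
#' inherited peak under an expanding shoulder.
#'
#' @param inherited_repeat Inherited repeat count (e.g. 110 for a knockin
#'   CAG tract, 24 for a mononucleotide marker).
#' @param expansion_rate Expected +1-repeat events per competent cell per
#'   month (>= 0).
#' @param contraction_rate Expected -1-repeat events per competent cell per
#'   month (>= 0).
#' @param months Elapsed time in months (>= 0).
#' @param n_cells Number of cells sampled (>= 1).
#' @param expanding_frac Fraction of cells that are expansion-competent, in
#'   (0, 1].
#' @param seed RNG seed.
#' @return A validated parameter list of class `expansion_params`.
#' @export
expansion_params <- function(inherited_repeat, expansion_rate = 0,
                             contraction_rate = 0, months = 0,
                             n_cells = 1e5, expanding_frac = 1, seed = 1L) {
  if (!is_count(inherited_repeat, 1L))
    stop_input("inherited_repeat must be a positive integer")
  if (!is_number(expansion_rate) || expansion_rate < 0)
    stop_input("expansion_rate must be >= 0")
  if (!is_number(contraction_rate) || contraction_rate < 0)
    stop_input("contraction_rate must be >= 0")
  if (!is_number(months) || months < 0) stop_input("months must be >= 0")
  if (!is_count(n_cells, 1L)) stop_input("n_cells must be a positive integer")
  if (!is_number(expanding_frac) || expanding_frac <= 0 || expanding_frac > 1)
    stop_input("expanding_frac must lie in (0, 1]")
  structure(list(inherited_repeat = as.integer(inherited_repeat),
                 expansion_rate = expansion_rate,
                 contraction_rate = contraction_rate,
                 months = months, n_cells = as.integer(n_cells),
                 expanding_frac = expanding_frac, seed = as.integer(seed)),
            class = "expansion_params")
}

#' Simulate the repeat-length distribution of a cell population
#'
#' @param params An [expansion_params()] object.
#' @return A normalized repeat-length distribution: a named numeric vector,
#'   names = integer repeat counts, values summing to 1. Deterministic for a
#'   fixed seed.
#' @examples
#' p <- expansion_params(110, expansion_rate = 1.5, months = 2, n_cells = 1e4)
#' d <- simulate_cell_population(p)
#' sum(d * as.integer(names(d)))  # ~113
#' @export
simulate_cell_population <- function(params) {
  if (!inherits(params, "expansion_params"))
    stop_input("expected `expansion_params`; see expansion_params()")
  lam_e <- params$expansion_rate * params$months
  lam_c <- params$contraction_rate * params$months
  if (lam_e == 0 && lam_c == 0) {
    out <- 1
    names(out) <- params$inherited_repeat
    return(out)
  }
  n_comp <- round(params$expanding_frac * params$n_cells)
  n_stable <- params$n_cells - n_comp
  with_seed(params$seed, {
    gains <- stats::rpois(n_comp, lam_e) - stats::rpois(n_comp, lam_c)
    repeats <- pmax(1L, params$inherited_repeat + gains)
    if (n_stable > 0) repeats <- c(repeats, rep(params$inherited_repeat, n_stable))
    tab <- table(repeats)
    out <- as.numeric(tab) / params$n_cells
    names(out) <- names(tab)
    out
  })
}

#' PCR stutter parameters
#'
#' Polymerase slippage during amplification spreads each template of length n
#' into a geometric ladder: weight `minus_ratio^k` at n-k and `plus_ratio^k`
#' at n+k for k = 1..`max_steps`, then the distribution is renormalized.
#' Minus stutter dominates for trinucleotide repeats; defaults reflect the
#' typical trinucleotide stutter shape.
#'
#' @param minus_ratio Per-step minus-stutter proportion in `[0, 1)`.
#' @param plus_ratio Per-step plus-stutter proportion in `[0, 1)`.
#' @param max_steps Maximum stutter offset in repeat units (>= 0).
#' @return A parameter list of class `stutter_params`.
#' @export
stutter_params <- function(minus_ratio = 0.15, plus_ratio = 0.01,
                           max_steps = 4L) {
  if (!is_number(minus_ratio) || minus_ratio < 0 || minus_ratio >= 1)
    stop_input("minus_ratio must lie in [0, 1)")
  if (!is_number(plus_ratio) || plus_ratio < 0 || plus_ratio >= 1)
    stop_input("plus_ratio must lie in [0, 1)")
  if (!is_count(max_steps, 0L)) stop_input("max_steps must be a non-negative integer")
  structure(list(minus_ratio = minus_ratio, plus_ratio = plus_ratio,
                 max_steps = as.integer(max_steps)),
            class = "stutter_params")
}

assert_dist <- function(dist) {
  if (!is.numeric(dist) || !length(dist) || is.null(names(dist)))
    stop_input("expected a named numeric repeat distribution")
  r <- suppressWarnings(as.integer(names(dist)))
  if (any(is.na(r))) stop_input("distribution names must be integer repeat counts")
  if (any(dist < 0)) stop_input("distribution weights must be non-negative")
  if (abs(sum(dist) - 1) > 1e-8) stop_input("distribution must be normalized")
  r
}

#' Apply geometric PCR stutter to a repeat distribution
#'
#' @param dist Normalized named numeric vector (repeat -> abundance).
#' @param sp A [stutter_params()] object.
#' @return A normalized distribution with support widened by at most
#'   `max_steps` on each side.
#' @examples
#' d <- c("110" = 1)
#' apply_stutter(d, stutter_params(minus_ratio = 0.2, plus_ratio = 0, max_steps = 2))
#' @export
apply_stutter <- function(dist, sp = stutter_params()) {
  if (!inherits(sp, "stutter_params")) stop_input("expected `stutter_params`")
  r <- assert_dist(dist)
  if (sp$max_steps == 0L || (sp$minus_ratio == 0 && sp$plus_ratio == 0))
    return(dist / sum(dist))
  lo <- min(r) - sp$max_steps
  hi <- max(r) + sp$max_steps
  acc <- numeric(hi - lo + 1L)
  add <- function(at, w) acc[at - lo + 1L] <<- acc[at - lo + 1L] + w
  for (i in seq_along(r)) {
    add(r[i], dist[i])
    for (k in seq_len(sp$max_steps)) {
      if (sp$minus_ratio > 0 && r[i] - k >= 1L) add(r[i] - k, dist[i] * sp$minus_ratio^k)
      if (sp$plus_ratio > 0) add(r[i] + k, dist[i] * sp$plus_ratio^k)
    }
  }
  keep <- acc > 0
  out <- acc[keep] / sum(acc)
  names(out) <- as.character((lo:hi)[keep])
  out
}

#' Trace rendering parameters
#'
#' Controls how an abundance distribution is painted as a capillary
#' electrophoresis trace: Gaussian peaks of width `peak_sigma_bp` centered on
#' the repeat lattice (with per-peak sizing jitter), the tallest peak scaled
#' to `amplitude` RFU, amplitudes attenuated by `decay_per_repeat` for each
#' repeat above the modal allele (longer fragments amplify and inject less
#' efficiently), plus additive Gaussian baseline noise.
#'
#' @param amplitude RFU of the tallest peak.
#' @param peak_sigma_bp Gaussian peak width (bp).
#' @param size_jitter_sd_bp Per-peak sizing error SD (bp).
#' @param baseline_sd Additive baseline noise SD (RFU).
#' @param decay_per_repeat Multiplicative attenuation per repeat above the
#'   modal allele, in `(0, 1]`.
#' @param grid_step_bp Trace grid spacing (bp).
#' @param seed RNG seed for jitter and noise.
#' @return A parameter list of class `render_params`.
#' @export
render_params <- function(amplitude = 4000, peak_sigma_bp = 0.6,
                          size_jitter_sd_bp = 0.05, baseline_sd = 5,
                          decay_per_repeat = 0.99, grid_step_bp = 0.1,
                          seed = 1L) {
  if (!is_number(amplitude) || amplitude <= 0) stop_input("amplitude must be > 0")
  if (!is_number(peak_sigma_bp) || peak_sigma_bp <= 0)
    stop_input("peak_sigma_bp must be > 0")
  if (!is_number(size_jitter_sd_bp) || size_jitter_sd_bp < 0)
    stop_input("size_jitter_sd_bp must be >= 0")
  if (!is_number(baseline_sd) || baseline_sd < 0) stop_input("baseline_sd must be >= 0")
  if (!is_number(decay_per_repeat) || decay_per_repeat <= 0 || decay_per_repeat > 1)
    stop_input("decay_per_repeat must lie in (0, 1]")
  if (!is_number(grid_step_bp) || grid_step_bp <= 0)
    stop_input("grid_step_bp must be > 0")
  structure(list(amplitude = amplitude, peak_sigma_bp = peak_sigma_bp,
                 size_jitter_sd_bp = size_jitter_sd_bp,
                 baseline_sd = baseline_sd, decay_per_repeat = decay_per_repeat,
                 grid_step_bp = grid_step_bp, seed = as.integer(seed)),
            class = "render_params")
}

#' Render a repeat distribution as an electropherogram trace
#'
#' @param dist Normalized repeat distribution (named numeric vector).
#' @param locus A [repeat_locus()] with `flank_bp` set; the grid covers the
#'   locus analysis window with a margin.
#' @param rp A [render_params()] object.
#' @param sample_id Sample label for the trace.
#' @return A calibrated [fa_trace()]. Deterministic for a fixed seed.
#' @export
render_trace <- function(dist, locus, rp = render_params(),
                         sample_id = "sample") {
  r <- assert_dist(dist)
  assert_locus(locus, need_flank = TRUE)
  if (!inherits(rp, "render_params")) stop_input("expected `render_params`")
  main <- r[which.max(dist)]
  x <- seq(locus_size_bp(locus, locus$window_min_repeat) - 2 * locus$unit_len,
           locus_size_bp(locus, locus$window_max_repeat) + 2 * locus$unit_len,
           by = rp$grid_step_bp)
  with_seed(rp$seed, {
    centers <- locus_size_bp(locus, r) +
      stats::rnorm(length(r), 0, rp$size_jitter_sd_bp)
    amps <- rp$amplitude * (dist / max(dist)) * rp$decay_per_repeat^(r - main)
    y <- numeric(length(x))
    for (i in seq_along(r))
      y <- y + amps[i] * exp(-(x - centers[i])^2 / (2 * rp$peak_sigma_bp^2))
    if (rp$baseline_sd > 0) y <- y + stats::rnorm(length(x), 0, rp$baseline_sd)
    fa_trace(x, pmax(y, 0), sample_id = sample_id, calibrated = TRUE)
  })
}

#' Define one group of a synthetic cohort
#'
#' Groups are parameterized by the biologically meaningful quantity — the
#' designed true mean repeat gain over the study window — from which the
#' per-cell expansion rate is derived as
#' `true_gain / (expanding_frac * months)` (plus the contraction rate).
#' Between-animal variability is modeled by drawing each animal's true gain
#' from a Gamma distribution with mean `true_gain` and SD `animal_sd`
#' (animals in a zero-gain group are exactly non-expanding).
#'
#' @param label Unique group label.
#' @param n_animals Animals in the group (>= 1).
#' @param true_gain Designed mean repeat gain over `months` (repeat units,
#'   >= 0).
#' @param months Study window in months.
#' @param inherited_repeat Inherited repeat count.
#' @param animal_sd Between-animal SD of the true gain (repeat units).
#' @param expanding_frac Fraction of expansion-competent cells; see
#'   [expansion_params()].
#' @param contraction_rate Per-cell contraction rate (events/month).
#' @param n_cells Cells sampled per animal.
#' @param stutter A [stutter_params()] object.
#' @param render A [render_params()] object.
#' @return A list of class `cohort_group`.
#' @export
cohort_group <- function(label, n_animals = 6L, true_gain = 0, months = 2,
                         inherited_repeat = 110L, animal_sd = 1.0,
                         expanding_frac = 0.6, contraction_rate = 0,
                         n_cells = 1e5, stutter = stutter_params(),
                         render = render_params()) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop_input("group label must be a non-empty string")
  if (!is_count(n_animals, 1L)) stop_input("n_animals must be >= 1")
  if (!is_number(true_gain) || true_gain < 0) stop_input("true_gain must be >= 0")
  if (!is_number(months) || months < 0) stop_input("months must be >= 0")
  if (!is_number(animal_sd) || animal_sd < 0) stop_input("animal_sd must be >= 0")
  if (!inherits(stutter, "stutter_params")) stop_input("expected `stutter_params`")
  if (!inherits(render, "render_params")) stop_input("expected `render_params`")
  if (true_gain > 0 && months <= 0)
    stop_input("a positive true_gain needs months > 0")
  structure(list(label = label, n_animals = as.integer(n_animals),
                 true_gain = true_gain, months = months,
                 inherited_repeat = as.integer(inherited_repeat),
                 animal_sd = animal_sd, expanding_frac = expanding_frac,
                 contraction_rate = contraction_rate,
                 n_cells = as.integer(n_cells),
                 stutter = stutter, render = render),
            class = "cohort_group")
}

#' Define a synthetic cohort
#'
#' @param groups List of [cohort_group()] objects with unique labels.
#' @param locus A [repeat_locus()] with `flank_bp` set.
#' @param seed Design seed; per-animal seeds are derived deterministically
#'   from it, the group label, and the animal index.
#' @param output `"peaks"` returns [repeat_peakset()] objects built directly
#'   from the stuttered amplicon distribution (amplitude scaling, length
#'   decay and a detection floor applied, no CE noise); `"traces"` returns
#'   rendered [fa_trace()] objects for the full peak-calling path.
#' @param min_height_rfu Detection floor (RFU) in `"peaks"` mode.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(groups, locus, seed = 1L,
                          output = c("peaks", "traces"),
                          min_height_rfu = 20) {
  output <- match.arg(output)
  if (!is.list(groups) || !length(groups) ||
      !all(vapply(groups, inherits, TRUE, "cohort_group")))
    stop_input("groups must be a non-empty list of cohort_group objects")
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop_input("duplicate group labels: ",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  assert_locus(locus, need_flank = TRUE)
  structure(list(groups = groups, locus = locus, seed = as.integer(seed),
                 output = output, min_height_rfu = min_height_rfu),
            class = "cohort_design")
}

# one animal's stuttered amplicon distribution plus its realized true gain
simulate_animal <- function(grp, locus, seed) {
  gain <- grp$true_gain
  if (gain > 0 && grp$animal_sd > 0) {
    shape <- (gain / grp$animal_sd)^2
    gain <- with_seed(seed, stats::rgamma(1L, shape = shape,
                                          rate = shape / gain))
  }
  er <- if (gain > 0) gain / (grp$expanding_frac * grp$months) +
    grp$contraction_rate else grp$contraction_rate
  p <- expansion_params(grp$inherited_repeat, expansion_rate = er,
                        contraction_rate = grp$contraction_rate,
                        months = grp$months, n_cells = grp$n_cells,
                        expanding_frac = grp$expanding_frac,
                        seed = derive_seed(seed, "cells"))
  dist <- apply_stutter(simulate_cell_population(p), grp$stutter)
  true_gain <- grp$expanding_frac * (er - grp$contraction_rate) * grp$months
  list(dist = dist, true_gain = true_gain)
}

# convert a stuttered abundance distribution to a detected peak set
dist_to_peakset <- function(dist, locus, rp, min_height_rfu, sample_id) {
  r <- assert_dist(dist)
  main <- r[which.max(dist)]
  h <- rp$amplitude * (dist / max(dist)) * rp$decay_per_repeat^(r - main)
  keep <- h >= min_height_rfu &
    r >= locus$window_min_repeat & r <= locus$window_max_repeat
  repeat_peakset(r[keep], h[keep], locus, sample_id = sample_id)
}

#' Simulate a full cohort with known ground truth
#'
#' @param design A [cohort_design()].
#' @return A list with `samples` (named list of [repeat_peakset()] or
#'   [fa_trace()] objects, each carrying a `"group"` attribute), `truth`
#'   (data frame `group`, `animal`, `sample_id`, `true_gain` — the realized
#'   per-animal expected gain), and `design`. Bit-reproducible for a fixed
#'   design seed.
#' @examples
#' loc <- repeat_locus("HTT_CAG", "CAG", 100, 70, 150)
#' des <- cohort_design(list(
#'   cohort_group("baseline", n_animals = 2, true_gain = 0, n_cells = 1000),
#'   cohort_group("NTC", n_animals = 2, true_gain = 4, n_cells = 1000)
#' ), loc, seed = 7)
#' sim <- simulate_cohort(des)
#' sim$truth
#' @export
simulate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) stop_input("expected a `cohort_design`")
  samples <- list()
  truth <- list()
  for (grp in design$groups) {
    for (a in seq_len(grp$n_animals)) {
      sid <- sprintf("%s_%02d", grp$label, a)
      seed_a <- derive_seed(design$seed, grp$label, a)
      sim <- simulate_animal(grp, design$locus, seed_a)
      obj <- if (design$output == "peaks") {
        dist_to_peakset(sim$dist, design$locus, grp$render,
                        design$min_height_rfu, sid)
      } else {
        rp <- grp$render
        rp$seed <- derive_seed(seed_a, "render")
        render_trace(sim$dist, design$locus, rp, sample_id = sid)
      }
      attr(obj, "group") <- grp$label
      samples[[sid]] <- obj
      truth[[sid]] <- data.frame(group = grp$label, animal = a,
                                 sample_id = sid, true_gain = sim$true_gain)
    }
  }
  list(samples = samples, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       design = design)
}
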