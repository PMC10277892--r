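#' Main (modal) allele of a repeat peak set
#'
#' The tallest peak in the analysis window is taken as the reference repeat
#' length; ties go to the smaller repeat.
#'
#' @param rps A non-empty [repeat_peakset()].
#' @return The main-allele repeat count (integer).
#' @export
main_allele <- function(rps) {
  if (!inherits(rps, "repeat_peakset")) stop_input("expected a `repeat_peakset`")
  if (!length(rps$repeats)) stop_input("empty peak set has no main allele")
  hmax <- max(rps$heights)
  min(rps$repeats[rps$heights == hmax])
}

#' Somatic instability index of a repeat peak set
#'
#' Quantifies somatic length mosaicism from a fragment-analysis peak series:
#' 1. the main allele `m` is the tallest peak;
#' 2. peaks below `threshold_frac * height(m)` (the signal-to-noise
#'    threshold, 5% by default) are discarded;
#' 3. retained heights are normalized to sum to 1;
#' 4. each peak contributes its normalized height times its repeat change
#'    `repeat - m`.
#'
#' The `all` index is the signed sum (contraction peaks enter with negative
#' sign); `expansion` restricts the sum to peaks longer than the main allele,
#' `contraction` to shorter ones. Because all three share the jointly
#' normalized retained set, `expansion + contraction = all` exactly.
#'
#' @param rps A non-empty [repeat_peakset()].
#' @param threshold_frac Fraction of the main-peak height in `[0, 1)` below
#'   which peaks are excluded.
#' @param mode Which index the `index` field of the result reports; all three
#'   are always computed.
#' @return An object of class `instability_result`: a list with `sample_id`,
#'   `main_allele`, `threshold_frac`, `n_peaks_retained`,
#'   `instability_index`, `expansion_index`, `contraction_index`, and the
#'   mode-selected `index`.
#' @examples
#' loc <- repeat_locus("HTT_CAG", "CAG", 100, 70, 150)
#' rps <- repeat_peakset(108:112, c(5, 10, 100, 50, 25), loc, "demo")
#' instability_index(rps, threshold_frac = 0.05)  # 80/190 = 0.4211
#' @export
instability_index <- function(rps, threshold_frac = 0.05,
                              mode = c("all", "expansion", "contraction")) {
  mode <- match.arg(mode)
  if (!inherits(rps, "repeat_peakset")) stop_input("expected a `repeat_peakset`")
  if (!length(rps$repeats)) stop_input("cannot index an empty peak set")
  if (!is_number(threshold_frac) || threshold_frac < 0 || threshold_frac >= 1)
    stop_input("threshold_frac must lie in [0, 1)")
  m <- main_allele(rps)
  cutoff <- threshold_frac * rps$heights[rps$repeats == m]
  keep <- rps$heights >= cutoff
  h <- rps$heights[keep] / sum(rps$heights[keep])
  d <- rps$repeats[keep] - m
  idx_exp <- sum(h[d > 0] * d[d > 0])
  idx_con <- sum(h[d < 0] * d[d < 0])
  # the main peak contributes 0, so the signed index is exactly the sum of
  # its expansion and contraction parts (additive decomposition)
  idx_all <- idx_exp + idx_con
  out <- list(
    sample_id = rps$sample_id,
    main_allele = m,
    threshold_frac = threshold_frac,
    n_peaks_retained = sum(keep),
    instability_index = idx_all,
    expansion_index = idx_exp,
    contraction_index = idx_con,
    mode = mode,
    index = switch(mode, all = idx_all, expansion = idx_exp,
                   contraction = idx_con)
  )
  class(out) <- "instability_result"
  out
}

#' @export
print.instability_result <- function(x, ...) {
  cat(sprintf(paste0("<instability_result> %s: main allele %d, threshold %.0f%%, ",
                     "%d peak(s) retained\n  instability %+.4f ",
                     "(expansion %+.4f, contraction %+.4f)\n"),
              x$sample_id, x$main_allele, 100 * x$threshold_frac,
              x$n_peaks_retained, x$instability_index,
              x$expansion_index, x$contraction_index))
  invisible(x)
}

#' Instability indices for a cohort of samples
#'
#' Applies [instability_index()] to each peak set and returns one row per
#' sample, carrying group labels through to the statistics stage. Per-sample
#' failures (e.g. empty peak sets) are reported as warnings and yield `NA`
#' rows; they do not abort the batch.
#'
#' @param peak_sets List of [repeat_peakset()] objects. Group labels are taken
#'   from `groups`, or from a `"group"` attribute on each element, else `NA`.
#' @param threshold_frac,mode Passed to [instability_index()].
#' @param groups Optional character vector of group labels, recycled to the
#'   number of samples.
#' @return A `data.frame` with columns `sample_id`, `group`, `main_allele`,
#'   `threshold`, `n_peaks`, `instability_index`, `expansion_index`,
#'   `contraction_index`, `index`.
#' @export
index_cohort <- function(peak_sets, threshold_frac = 0.05,
                         mode = c("all", "expansion", "contraction"),
                         groups = NULL) {
  mode <- match.arg(mode)
  if (!is.list(peak_sets) || !length(peak_sets))
    stop_input("peak_sets must be a non-empty list")
  if (!is.null(groups)) groups <- rep_len(as.character(groups), length(peak_sets))
  rows <- lapply(seq_along(peak_sets), function(i) {
    rps <- peak_sets[[i]]
    grp <- if (!is.null(groups)) groups[i] else
      (attr(rps, "group") %||% NA_character_)
    res <- tryCatch(instability_index(rps, threshold_frac, mode),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("sample %s failed: %s",
                      if (inherits(rps, "repeat_peakset")) rps$sample_id else i,
                      conditionMessage(res)), call. = FALSE)
      return(data.frame(
        sample_id = if (inherits(rps, "repeat_peakset")) rps$sample_id else
          as.character(i),
        group = grp, main_allele = NA_integer_, threshold = threshold_frac,
        n_peaks = NA_integer_, instability_index = NA_real_,
        expansion_index = NA_real_, contraction_index = NA_real_,
        index = NA_real_))
    }
    data.frame(sample_id = res$sample_id, group = grp,
               main_allele = res$main_allele, threshold = res$threshold_frac,
               n_peaks = res$n_peaks_retained,
               instability_index = res$instability_index,
               expansion_index = res$expansion_index,
               contraction_index = res$contraction_index,
               index = res$index)
  })
  do.call(rbind, rows)
}

#' Compare a microsatellite locus against a reference sample
#'
#' Microsatellite instability (Bethesda-style) is assessed as the appearance
#' of a novel main-allele length relative to a reference: the result reports
#' the main-allele shift (sample minus reference, repeat units), the
#' difference of signed instability indices, and an `unstable` flag raised
#' when `|shift| >= min_shift`.
#'
#' @param sample,reference Non-empty [repeat_peakset()] objects at the same
#'   locus.
#' @param threshold_frac Signal-to-noise threshold for both indices.
#' @param min_shift Smallest main-allele displacement (repeat units) called
#'   unstable.
#' @return An object of class `msi_result`: list with `locus`, `sample_id`,
#'   `reference_id`, `main_allele_shift`, `index_difference`, `unstable`.
#' @export
msi_compare <- function(sample, reference, threshold_frac = 0.05,
                        min_shift = 1L) {
  if (!inherits(sample, "repeat_peakset") || !inherits(reference, "repeat_peakset"))
    stop_input("expected `repeat_peakset` objects")
  if (!identical(sample$locus$name, reference$locus$name) ||
      sample$locus$unit_len != reference$locus$unit_len)
    stop_input("sample and reference are at different loci (",
               sample$locus$name, " vs ", reference$locus$name, ")")
  if (!is_count(min_shift, 1L)) stop_input("min_shift must be a positive integer")
  shift <- main_allele(sample) - main_allele(reference)
  diff <- instability_index(sample, threshold_frac)$instability_index -
    instability_index(reference, threshold_frac)$instability_index
  structure(list(locus = sample$locus$name,
                 sample_id = sample$sample_id,
                 reference_id = reference$sample_id,
                 main_allele_shift = as.integer(shift),
                 index_difference = diff,
                 unstable = abs(shift) >= min_shift),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("<msi_result> %s: %s vs %s, shift %+d, index diff %+.4f -> %s\n",
              x$locus, x$sample_id, x$reference_id, x$main_allele_shift,
              x$index_difference, if (x$unstable) "UNSTABLE" else "stable"))
  invisible(x)
}
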