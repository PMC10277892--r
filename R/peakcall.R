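#' Construct a per-sample repeat peak set
#'
#' The input to instability indexing: a mapping from integer repeat count to
#' peak height (RFU) within the locus analysis window.
#'
#' @param repeats Integer repeat counts, unique, within the locus window.
#' @param heights Positive peak heights (RFU), same length.
#' @param locus The [repeat_locus()] the peaks were binned against.
#' @param sample_id Sample label.
#' @return An object of class `repeat_peakset`.
#' @export
repeat_peakset <- function(repeats, heights, locus, sample_id = "sample") {
  assert_locus(locus)
  repeats <- as.integer(repeats); heights <- as.numeric(heights)
  if (length(repeats) != length(heights)) stop_input("repeats/heights length mismatch")
  if (anyDuplicated(repeats)) stop_input("repeat counts must be unique")
  if (length(repeats)) {
    if (any(heights <= 0)) stop_input("peak heights must be positive")
    if (any(repeats < locus$window_min_repeat | repeats > locus$window_max_repeat))
      stop_input("repeats outside the locus analysis window")
    ord <- order(repeats)
    repeats <- repeats[ord]; heights <- heights[ord]
  }
  structure(list(sample_id = sample_id, repeats = repeats, heights = heights,
                 locus = locus),
            class = "repeat_peakset")
}

#' @export
print.repeat_peakset <- function(x, ...) {
  cat(sprintf("<repeat_peakset> %s @ %s: %d peak(s)", x$sample_id,
              x$locus$name, length(x$repeats)))
  if (length(x$repeats))
    cat(sprintf(", repeats %d-%d, main %d", min(x$repeats), max(x$repeats),
                main_allele(x)))
  cat("\n")
  invisible(x)
}

#' @export
length.repeat_peakset <- function(x) length(x$repeats)

# prominence of a local maximum: height above the higher of the two key cols
# (lowest point between the peak and the nearest higher terrain on each side)
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- y[i]
  if (i > 1L) {
    j <- i - 1L; m <- y[j]
    while (j >= 1L && y[j] <= y[i]) { m <- min(m, y[j]); j <- j - 1L }
    left <- m
  }
  right <- y[i]
  if (i < n) {
    j <- i + 1L; m <- y[j]
    while (j <= n && y[j] <= y[i]) { m <- min(m, y[j]); j <- j + 1L }
    right <- m
  }
  y[i] - max(left, right)
}

#' Detect peaks in a calibrated trace
#'
#' Replaces interactive peak picking in fragment-analysis software: the trace
#' is smoothed with a centered moving average, a rolling-minimum baseline is
#' subtracted, local maxima are filtered by height and prominence, and each
#' apex is refined by three-point parabolic interpolation of the smoothed
#' signal for sub-grid sizing.
#'
#' @param trace A calibrated [fa_trace()].
#' @param smooth_window_bp Moving-average window (bp). Must be narrower than
#'   the trace span.
#' @param min_height Minimum apex height (RFU) after baseline subtraction.
#' @param min_prominence Minimum peak prominence (RFU).
#' @param baseline_window_bp Rolling-minimum baseline window (bp); set to
#'   `NULL` or 0 to skip baseline subtraction. Should be much wider than a
#'   peak so that real signal is not eroded.
#' @return A [peak_table()] sorted by size.
#' @export
call_peaks <- function(trace, smooth_window_bp = 0.3, min_height = 20,
                       min_prominence = 10, baseline_window_bp = 20) {
  if (!inherits(trace, "fa_trace")) stop_input("expected an `fa_trace`")
  if (!trace$calibrated) stop_input("trace must be calibrated before peak calling")
  x <- trace$x; y <- trace$y
  span <- x[length(x)] - x[1L]
  if (!is_number(smooth_window_bp) || smooth_window_bp < 0 || smooth_window_bp >= span)
    stop_input("smooth_window_bp must be non-negative and narrower than the trace span")
  dx <- stats::median(diff(x))
  ys <- roll_mean(y, smooth_window_bp / dx)
  if (!is.null(baseline_window_bp) && baseline_window_bp > 0) {
    # clamp to the trace span; at the clamp this is global-minimum subtraction
    ys <- ys - roll_min(ys, min(baseline_window_bp, span) / dx)
  }
  n <- length(ys)
  cand <- which(ys[2L:(n - 1L)] > ys[1L:(n - 2L)] &
                ys[2L:(n - 1L)] >= ys[3L:n]) + 1L
  if (!length(cand)) return(peak_table(numeric(0), numeric(0),
                                       sample_id = trace$sample_id))
  sizes <- heights <- numeric(length(cand))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    a <- ys[i - 1L]; b <- ys[i]; c <- ys[i + 1L]
    denom <- a - 2 * b + c
    delta <- if (denom < 0) 0.5 * (a - c) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    sizes[k] <- x[i] + delta * dx
    heights[k] <- b - 0.25 * (a - c) * delta
    keep[k] <- heights[k] >= min_height &&
      peak_prominence(ys, i) >= min_prominence
  }
  sizes <- sizes[keep]; heights <- heights[keep]
  ord <- order(sizes)
  peak_table(sizes[ord], heights[ord], sample_id = trace$sample_id)
}

#' Bin called peaks to integer repeat counts
#'
#' Each peak is assigned `repeat = round((size_bp - flank_bp) / unit_len)`.
#' Peaks outside the locus analysis window, or whose residual from the repeat
#' lattice exceeds `residual_tol_bp`, are dropped. When two peaks bin to the
#' same repeat the taller one wins (the collision is reported via `message()`).
#' An empty result is returned as an empty `repeat_peakset` (with a warning),
#' distinct from an error.
#'
#' @param peaks A [peak_table()].
#' @param locus A [repeat_locus()] with `flank_bp` set.
#' @param residual_tol_bp Maximum |size - nearest lattice point| in bp; must be
#'   below half the repeat unit length.
#' @return A [repeat_peakset()].
#' @export
bin_to_repeats <- function(peaks, locus, residual_tol_bp = 1.0) {
  if (!inherits(peaks, "peak_table")) stop_input("expected a `peak_table`")
  assert_locus(locus, need_flank = TRUE)
  if (!is_number(residual_tol_bp) || residual_tol_bp <= 0 ||
      residual_tol_bp >= locus$unit_len / 2)
    stop_input("residual_tol_bp must lie in (0, unit_len/2)")
  rep_f <- (peaks$size_bp - locus$flank_bp) / locus$unit_len
  rep_i <- round(rep_f)
  residual <- peaks$size_bp - locus_size_bp(locus, rep_i)
  ok <- abs(residual) <= residual_tol_bp &
    rep_i >= locus$window_min_repeat & rep_i <= locus$window_max_repeat &
    peaks$height > 0
  rep_i <- rep_i[ok]; h <- peaks$height[ok]
  if (anyDuplicated(rep_i)) {
    for (r in unique(rep_i[duplicated(rep_i)]))
      message(sprintf("bin_to_repeats: %d peaks collided at repeat %d in %s; keeping the tallest",
                      sum(rep_i == r), r, peak_sample_id(peaks)))
    keep <- !logical(length(rep_i))
    for (r in unique(rep_i)) {
      at <- which(rep_i == r)
      if (length(at) > 1L) keep[at[-which.max(h[at])]] <- FALSE
    }
    rep_i <- rep_i[keep]; h <- h[keep]
  }
  if (!length(rep_i))
    warning("bin_to_repeats: no peaks survive binning for ",
            peak_sample_id(peaks), call. = FALSE)
  repeat_peakset(rep_i, h, locus, sample_id = peak_sample_id(peaks))
}

#' Estimate the non-repeat flank length from a sample of known repeat count
#'
#' The amplicon flank for a primer pair is rarely documented; it can be fitted
#' from any sample whose main-allele repeat count is known:
#' `flank_bp = tallest-peak size - unit_len * known_repeat`. By construction,
#' binning the same table with the returned flank places the tallest peak
#' exactly at `known_repeat`.
#'
#' @param peaks A non-empty [peak_table()].
#' @param known_repeat The known main-allele repeat count.
#' @param locus A [repeat_locus()] (its `flank_bp` is ignored).
#' @return The estimated flank length in bp.
#' @export
estimate_flank <- function(peaks, known_repeat, locus) {
  if (!inherits(peaks, "peak_table")) stop_input("expected a `peak_table`")
  if (nrow(peaks) == 0L) stop_input("cannot estimate a flank from an empty peak table")
  if (!is_count(known_repeat, 1L)) stop_input("known_repeat must be a positive integer")
  assert_locus(locus)
  peaks$size_bp[which.max(peaks$height)] - locus$unit_len * known_repeat
}
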