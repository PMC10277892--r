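#' Define an amplified repeat locus
#'
#' A repeat locus ties fragment sizes to repeat counts: an amplicon of a tract
#' of `repeat_unit` repeats plus `flank_bp` non-repeat bases (both
#' primer-to-repeat flanks combined) sizes at
#' `flank_bp + nchar(repeat_unit) * repeats` bp. The analysis window
#' `[window_min_repeat, window_max_repeat]` gates which repeat counts enter
#' downstream indices; in heterozygous animals it excludes the unexpanded
#' wild-type allele, which would otherwise dominate the expanded-locus index.
#'
#' @param name Locus label, e.g. `"HTT_CAG"` or `"mBAT24"`.
#' @param repeat_unit Repeat unit sequence (e.g. `"CAG"`, `"A"`); its length
#'   in bases is the sizing lattice spacing.
#' @param flank_bp Total non-repeat amplicon length in bp (may be `NA` until
#'   estimated from a sample of known repeat count, see [estimate_flank()]).
#' @param window_min_repeat,window_max_repeat Integer analysis window.
#' @return An object of class `repeat_locus`.
#' @examples
#' cag <- repeat_locus("HTT_CAG", "CAG", flank_bp = 100,
#'                     window_min_repeat = 70, window_max_repeat = 150)
#' cag
#' @export
repeat_locus <- function(name, repeat_unit, flank_bp = NA_real_,
                         window_min_repeat, window_max_repeat) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_input("`name` must be a non-empty string")
  if (!is.character(repeat_unit) || length(repeat_unit) != 1L || nchar(repeat_unit) < 1L)
    stop_input("`repeat_unit` must be a sequence of at least one base")
  if (!is.na(flank_bp) && (!is_number(flank_bp) || flank_bp < 0))
    stop_input("`flank_bp` must be a non-negative number (or NA)")
  if (!is_count(window_min_repeat, 0L) || !is_count(window_max_repeat, 0L) ||
      window_min_repeat >= window_max_repeat)
    stop_input("analysis window must satisfy window_min_repeat < window_max_repeat")
  structure(list(
    name = name,
    repeat_unit = toupper(repeat_unit),
    unit_len = nchar(repeat_unit),
    flank_bp = as.numeric(flank_bp),
    window_min_repeat = as.integer(window_min_repeat),
    window_max_repeat = as.integer(window_max_repeat)
  ), class = "repeat_locus")
}

#' @export
print.repeat_locus <- function(x, ...) {
  cat(sprintf("<repeat_locus> %s: unit %s (%d bp), flank %s bp, window %d-%d repeats\n",
              x$name, x$repeat_unit, x$unit_len,
              if (is.na(x$flank_bp)) "?" else format(x$flank_bp),
              x$window_min_repeat, x$window_max_repeat))
  invisible(x)
}

# expected fragment size of a given repeat count at this locus
locus_size_bp <- function(locus, repeats) locus$flank_bp + locus$unit_len * repeats

assert_locus <- function(locus, need_flank = FALSE) {
  if (!inherits(locus, "repeat_locus")) stop_input("expected a `repeat_locus` object")
  if (need_flank && is.na(locus$flank_bp))
    stop_input("locus `", locus$name, "` has no flank_bp; supply one or use estimate_flank()")
  invisible(locus)
}
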