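#' Construct an electropherogram trace
#'
#' @param x Strictly increasing grid of fragment sizes (bp) or raw scan units.
#' @param y Fluorescence intensities (RFU, non-negative), same length as `x`.
#' @param sample_id Sample label.
#' @param calibrated `TRUE` when `x` is in calibrated base pairs (the default);
#'   raw scan-unit traces must pass through [calibrate_sizes()] before peak
#'   calling.
#' @return An object of class `fa_trace`.
#' @export
fa_trace <- function(x, y, sample_id = "sample", calibrated = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_input("x and y must have the same length")
  if (length(x) < 2L) stop_input("a trace needs at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_input("trace values must be finite")
  if (any(diff(x) <= 0)) stop_input("trace x grid must be strictly increasing")
  if (any(y < 0)) stop_input("trace intensities must be non-negative")
  structure(list(sample_id = sample_id, x = x, y = y,
                 calibrated = isTRUE(calibrated)),
            class = "fa_trace")
}

#' @export
print.fa_trace <- function(x, ...) {
  cat(sprintf("<fa_trace> %s: %d points, %s %.2f-%.2f, max %.1f RFU\n",
              x$sample_id, length(x$x),
              if (x$calibrated) "bp" else "scan",
              min(x$x), max(x$x), max(x$y)))
  invisible(x)
}

#' Construct a peak table
#'
#' A peak table is the tabular export of fragment-analysis software: one row
#' per detected peak with its size (bp), height (RFU) and optionally area.
#'
#' @param size_bp Peak apex sizes in bp, strictly increasing.
#' @param height Peak heights in RFU, non-negative.
#' @param area Optional peak areas (RFU*bp); `NA` where unknown.
#' @param sample_id Sample label, stored as an attribute.
#' @return A `data.frame` of class `peak_table` with columns
#'   `size_bp`, `height`, `area`.
#' @export
peak_table <- function(size_bp, height, area = NULL, sample_id = "sample") {
  size_bp <- as.numeric(size_bp); height <- as.numeric(height)
  if (length(size_bp) != length(height))
    stop_input("size_bp and height must have the same length")
  if (is.null(area)) area <- rep(NA_real_, length(size_bp))
  area <- as.numeric(area)
  if (length(area) != length(size_bp)) stop_input("area length mismatch")
  if (length(size_bp)) {
    if (any(!is.finite(size_bp)) || any(!is.finite(height)))
      stop_input("sizes and heights must be finite")
    if (any(height < 0)) stop_input("peak heights must be non-negative")
    if (any(diff(size_bp) <= 0)) stop_input("peak sizes must be strictly increasing")
  }
  out <- data.frame(size_bp = size_bp, height = height, area = area)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("peak_table", "data.frame")
  out
}

peak_sample_id <- function(table) attr(table, "sample_id") %||% "sample"

# parse a numeric column strictly, returning NA where unparseable
strict_numeric <- function(x) suppressWarnings(as.numeric(x))

#' Read a peak table from delimited text
#'
#' Two dialects are supported. `"generic"` is this package's own format:
#' comma-separated with header `size_bp,height[,area]`. `"peakscanner"` is a
#' tolerant reader of common fragment-analysis exports (Peak Scanner-style):
#' comma- or tab-delimited, with `Size` / `Height` / `Area` (or
#' `Area under Peak`) columns matched case-insensitively; extra columns such
#' as dye or sample file name are ignored. Rows whose size or height does not
#' parse as a number (e.g. off-ladder peaks) are dropped with a row-numbered
#' warning; a missing size or height column, or non-increasing sizes, is an
#' error.
#'
#' @param path File to read.
#' @param dialect `"generic"` or `"peakscanner"`.
#' @param sample_id Optional sample label; defaults to the file name.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("generic", "peakscanner"),
                            sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop_input("empty peak table file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, quote = "\"",
                           fileEncoding = "UTF-8")
  nm <- tolower(trimws(names(raw)))
  if (dialect == "generic") {
    i_size <- match("size_bp", nm); i_h <- match("height", nm); i_a <- match("area", nm)
  } else {
    i_size <- match("size", nm)
    i_h <- match("height", nm)
    i_a <- which(nm %in% c("area under peak", "area under the peak", "area"))[1]
    if (is.na(i_a)) i_a <- NA_integer_
  }
  if (is.na(i_size) || is.na(i_h))
    stop_input("peak table is missing size/height columns (dialect '", dialect, "'): ", path)
  size <- strict_numeric(raw[[i_size]])
  height <- strict_numeric(raw[[i_h]])
  area <- if (!is.na(i_a)) strict_numeric(raw[[i_a]]) else rep(NA_real_, nrow(raw))
  bad <- which(is.na(size) | is.na(height))
  if (length(bad)) {
    warning(sprintf("dropped %d unparseable row(s) in %s: row %s",
                    length(bad), basename(path),
                    paste(bad, collapse = ", ")), call. = FALSE)
    size <- size[-bad]; height <- height[-bad]; area <- area[-bad]
  }
  if (length(size) && any(diff(size) <= 0))
    stop_input("peak sizes are not strictly increasing in ", path)
  peak_table(size, height, area,
             sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a peak table to delimited text
#'
#' @param table A [peak_table()].
#' @param path Output file.
#' @param dialect See [read_peak_table()]; `"generic"` writes
#'   `size_bp,height,area`, `"peakscanner"` writes `Size,Height,Area under Peak`
#'   plus dye and sample-name columns as fragment-analysis software would.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(table, path, dialect = c("generic", "peakscanner")) {
  dialect <- match.arg(dialect)
  if (!inherits(table, "peak_table")) stop_input("expected a `peak_table`")
  df <- as.data.frame(table)
  if (dialect == "generic") {
    out <- data.frame(size_bp = df$size_bp, height = df$height, area = df$area)
  } else {
    out <- data.frame(
      "Dye/Sample Peak" = sprintf("B,%d", seq_len(nrow(df))),
      "Sample File Name" = rep(peak_sample_id(table), nrow(df)),
      "Size" = df$size_bp,
      "Height" = df$height,
      "Area under Peak" = df$area,
      check.names = FALSE
    )
  }
  ok <- tryCatch({
    # quote character fields in the peakscanner dialect: dye labels like
    # "B,1" contain the delimiter
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       quote = (dialect == "peakscanner"),
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_input("could not write peak table to ", path, ": ",
                              conditionMessage(ok))
  invisible(path)
}

#' Read / write a raw trace
#'
#' Traces are stored as two-column comma-separated text with header `x,y`
#' (size or scan unit, then RFU).
#'
#' @param path File to read or write.
#' @param sample_id Optional label; defaults to the file name.
#' @param calibrated Whether the stored x grid is calibrated bp.
#' @return [read_trace()] returns an [fa_trace()]; [write_trace()] returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, sample_id = NULL, calibrated = TRUE) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (file.size(path) == 0L) stop_input("empty trace file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = ",",
                           colClasses = "character", strip.white = TRUE,
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop_input("trace file needs two columns (x,y): ", path)
  x <- strict_numeric(raw[[1L]]); y <- strict_numeric(raw[[2L]])
  if (any(is.na(x)) || any(is.na(y))) {
    bad <- which(is.na(x) | is.na(y))
    stop_input(sprintf("unparseable trace row(s) in %s: row %s", basename(path),
                       paste(bad, collapse = ", ")))
  }
  fa_trace(x, y, sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
           calibrated = calibrated)
}

#' @param trace An [fa_trace()].
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "fa_trace")) stop_input("expected an `fa_trace`")
  utils::write.table(data.frame(x = trace$x, y = trace$y), path, sep = ",",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Calibrate raw scan units to base pairs with a size standard
#'
#' Maps a raw trace's x grid through the ladder of known fragments by
#' piecewise-linear interpolation between ladder points, extending the first
#' and last segments linearly beyond the ladder range.
#'
#' @param trace_raw An uncalibrated [fa_trace()].
#' @param ladder Two-column matrix or data frame of `(scan_unit, known_bp)`
#'   pairs, strictly increasing in both columns, at least 2 rows.
#' @return A calibrated [fa_trace()].
#' @examples
#' tr <- fa_trace(c(100, 150, 200), c(0, 10, 0), calibrated = FALSE)
#' calibrate_sizes(tr, cbind(c(100, 200), c(50, 100)))$x  # 50 75 100
#' @export
calibrate_sizes <- function(trace_raw, ladder) {
  if (!inherits(trace_raw, "fa_trace")) stop_input("expected an `fa_trace`")
  ladder <- as.matrix(ladder)
  if (!is.numeric(ladder) || ncol(ladder) != 2L)
    stop_input("ladder must be a two-column numeric matrix (scan_unit, known_bp)")
  if (nrow(ladder) < 2L) stop_input("size calibration needs at least 2 ladder points")
  su <- ladder[, 1L]; bp <- ladder[, 2L]
  if (any(diff(su) <= 0) || any(diff(bp) <= 0))
    stop_input("ladder must be strictly increasing in both coordinates")
  x <- trace_raw$x
  seg <- findInterval(x, su, all.inside = TRUE)  # clamp to end segments
  slope <- (bp[seg + 1L] - bp[seg]) / (su[seg + 1L] - su[seg])
  new_x <- bp[seg] + slope * (x - su[seg])
  fa_trace(new_x, trace_raw$y, sample_id = trace_raw$sample_id, calibrated = TRUE)
}
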