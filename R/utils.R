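# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so simulation functions are
#' reproducible without clobbering the global stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a parent seed and string labels
#'
#' Deterministic 31-bit polynomial hash; distinct (group, animal) pairs get
#' distinct streams without seed reuse across groups.
#' @noRd
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# force odd window length (points) for symmetric rolling windows
odd_window <- function(n) {
  n <- max(1L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

# centered moving average with edge replication
roll_mean <- function(y, w) {
  w <- odd_window(w)
  if (w <= 1L) return(y)
  n <- length(y)
  hw <- (w - 1L) %/% 2L
  yp <- c(rep(y[1L], hw), y, rep(y[n], hw))
  as.numeric(stats::filter(yp, rep(1 / w, w), sides = 2))[(hw + 1L):(hw + n)]
}

# centered rolling minimum with edge replication
roll_min <- function(y, w) {
  w <- odd_window(w)
  if (w <= 1L) return(y)
  n <- length(y)
  hw <- (w - 1L) %/% 2L
  yp <- c(rep(y[1L], hw), y, rep(y[n], hw))
  out <- yp[1L:n]
  for (o in 1L:(w - 1L)) out <- pmin(out, yp[(1L + o):(n + o)])
  out
}
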