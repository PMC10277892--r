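check_groups <- function(groups, min_n = 2L) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    stop_input("groups must be a named list of at least 2 numeric vectors")
  for (g in names(groups)) {
    v <- groups[[g]]
    if (!is.numeric(v) || length(v) < min_n || any(!is.finite(v)))
      stop_input("group '", g, "' needs at least ", min_n, " finite values")
  }
  invisible(groups)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition. When every
#' observation is identical (both sums of squares are zero) the convention
#' `F = 0, p = 1` is returned — no evidence of a difference — mirroring the
#' degenerate-variance convention of [t_test()].
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return A list with `F`, `p`, `df_between`, `df_within`.
#' @examples
#' one_way_anova(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(6, 7, 8)))$F  # 21
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  grand <- sum(unlist(groups)) / sum(n)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- sum(n) - length(groups)
  if (ssw == 0 && ssb == 0) return(list(F = 0, p = 1, df_between = df_b,
                                        df_within = df_w))
  if (ssw == 0) return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w))
  f <- (ssb / df_b) / (ssw / df_w)
  list(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}

#' Two-sample t test
#'
#' Student's pooled-variance t test by default; Welch's unequal-variance test
#' with `equal_var = FALSE`. When both groups have zero variance and equal
#' means (data essentially constant) the convention `t = 0, p = 1` is used.
#'
#' @param a,b Numeric vectors of length >= 2.
#' @param equal_var Pool variances (Student) or not (Welch).
#' @return A list with `t`, `p` (two-sided), `df`.
#' @export
t_test <- function(a, b, equal_var = TRUE) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2L || length(b) < 2L)
    stop_input("both samples need at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2L))
  }
  ht <- stats::t.test(a, b, var.equal = equal_var)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Dunnett's many-to-one comparisons versus a control group
#'
#' Each treatment group is compared with the named control using the
#' pooled-variance t statistic; adjusted p values account for the family of
#' correlated contrasts by Monte Carlo evaluation of the joint null
#' distribution of `max |t|` over the correlated multivariate t (which
#' supports unbalanced group sizes directly). With a single treatment group
#' this reduces to the two-sided two-sample pooled t test.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param control_label Name of the control group.
#' @param alpha Family-wise significance level (used for the star rendering).
#' @param n_mc Monte Carlo draws for the null distribution.
#' @param seed RNG seed; adjusted p values are deterministic given it.
#' @return An object of class `group_comparison`: `summary` (per-group label,
#'   n, mean, sd), `anova` (from [one_way_anova()]), `comparisons` (one row
#'   per treatment: estimate = mean difference vs control, `t`, `p_unadj`,
#'   `p_adj`, `mc_se`, `stars`), plus `control`, `alpha`, `df`, `n_mc`,
#'   `seed`.
#' @export
dunnett <- function(groups, control_label, alpha = 0.05, n_mc = 2e5,
                    seed = 1L) {
  check_groups(groups)
  if (!is.character(control_label) || !control_label %in% names(groups))
    stop_input("control group '", control_label, "' not found")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_input("alpha must lie in (0, 1)")
  trt <- setdiff(names(groups), control_label)
  k <- length(trt)
  if (k < 1L) stop_input("need at least one treatment group")
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  N <- sum(n)
  df <- N - length(groups)
  s2 <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df
  n0 <- n[[control_label]]
  se <- sqrt(s2 * (1 / n[trt] + 1 / n0))
  tstat <- (means[trt] - means[control_label]) / se
  # Null distribution of max_j |T_j| for the correlated one-to-many contrasts:
  # T_j = (Z_j/sqrt(n_j) - Z_0/sqrt(n_0)) / (S * sqrt(1/n_j + 1/n_0)),
  # S^2 ~ chi2(df)/df independent of the Z's.
  tmax <- with_seed(seed, {
    z0 <- stats::rnorm(n_mc)
    s <- sqrt(stats::rchisq(n_mc, df) / df)
    m <- rep(0, n_mc)
    for (j in trt) {
      tj <- (stats::rnorm(n_mc) / sqrt(n[[j]]) - z0 / sqrt(n0)) /
        (s * sqrt(1 / n[[j]] + 1 / n0))
      m <- pmax(m, abs(tj))
    }
    m
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(tmax >= t0), 0)
  mc_se <- sqrt(pmax(p_adj * (1 - p_adj), 1 / n_mc) / n_mc)
  p_unadj <- 2 * stats::pt(-abs(tstat), df)
  comparisons <- data.frame(
    group = trt,
    estimate = unname(means[trt] - means[control_label]),
    t = unname(tstat),
    p_unadj = unname(p_unadj),
    p_adj = unname(p_adj),
    mc_se = unname(mc_se),
    stars = p_stars(unname(p_adj)),
    row.names = NULL
  )
  structure(list(
    summary = data.frame(group = names(groups), n = unname(n),
                         mean = unname(means),
                         sd = vapply(groups, stats::sd, 0, USE.NAMES = FALSE),
                         row.names = NULL),
    anova = one_way_anova(groups),
    comparisons = comparisons,
    control = control_label, alpha = alpha, df = df,
    n_mc = n_mc, seed = seed
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA F(%d,%d) = %.3f, p = %.4g; Dunnett vs '%s'\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p,
              x$control))
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Significance stars
#'
#' Renders the conventional figure markers: `*` p <= 0.05, `**` p <= 0.01,
#' `***` p <= 0.001, `****` p <= 0.0001, `ns` otherwise.
#'
#' @param p Vector of p values.
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "****" else if (pi <= 1e-3) "***" else
      if (pi <= 0.01) "**" else if (pi <= 0.05) "*" else "ns"
  }, "")
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`
#' (so the fitted response at `dose = ic50` is exactly `(top + bottom)/2`).
#' Initial values come from the response extremes at the dose-range ends, the
#' dose bracketing the half-response, and a unit Hill slope; optimization uses
#' Levenberg-Marquardt least squares. Non-convergence is reported via the
#' `converged` flag, never silently.
#'
#' @param dose Positive doses, at least 5 distinct values.
#' @param response Responses, same length.
#' @return An object of class `dose_response_fit`: `ic50`, `hill`, `top`,
#'   `bottom`, `rss`, `converged`, and `fitted` values.
#' @export
fit_4pl <- function(dose, response) {
  if (!is.numeric(dose) || !is.numeric(response) ||
      length(dose) != length(response))
    stop_input("dose and response must be numeric vectors of equal length")
  if (any(dose <= 0)) stop_input("doses must be positive")
  if (length(unique(dose)) < 5L) stop_input("need at least 5 distinct doses")
  ord <- order(dose)
  d <- dose[ord]; y <- response[ord]
  lo <- min(d); hi <- max(d)
  top0 <- mean(y[d <= lo * 1.0001])
  bot0 <- mean(y[d >= hi * 0.9999])
  half <- (top0 + bot0) / 2
  below <- if (top0 >= bot0) which(y <= half) else which(y >= half)
  ic50_0 <- if (length(below)) d[below[1L]] else exp(mean(log(range(d))))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (d / ic50)^hill),
      start = list(top = top0, bottom = bot0, ic50 = ic50_0, hill = 1),
      lower = c(-Inf, -Inf, lo / 1e3, -20),
      upper = c(Inf, Inf, hi * 1e3, 20),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, rss = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(dose))),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv) && all(is.finite(cf))
  structure(list(ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
                 top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 rss = sum(stats::resid(fit)^2), converged = conv,
                 fitted = stats::fitted(fit)[order(ord)]),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 %.4g, hill %.3f, top %.4g, bottom %.4g, RSS %.4g%s\n",
              x$ic50, x$hill, x$top, x$bottom, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
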