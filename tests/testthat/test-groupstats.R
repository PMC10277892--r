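test_that("equal group means give F near zero, p near one", {
  g <- list(A = c(1, 2, 3), B = c(1, 2, 3), C = c(3, 2, 1))
  res <- one_way_anova(g)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(2)
  a <- rnorm(6); b <- rnorm(8, 1)
  expect_equal(one_way_anova(list(a = a, b = b))$F,
               t_test(a, b, equal_var = TRUE)$t^2, tolerance = 1e-10)
})

test_that("the three-group toy dataset gives F = 21", {
  res <- one_way_anova(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(6, 7, 8)))
  expect_equal(res$F, 21, tolerance = 1e-12)
  expect_equal(res$p,
               pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("the sum-of-squares decomposition matches stats::oneway.test", {
  for (s in 1:10) {
    set.seed(s)
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), mean = i / 2))
    names(g) <- paste0("g", seq_len(k))
    ref <- stats::oneway.test(
      y ~ lab, data.frame(y = unlist(g), lab = rep(names(g), lengths(g))),
      var.equal = TRUE)
    res <- one_way_anova(g)
    expect_equal(res$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs follow the stated conventions", {
  expect_error(one_way_anova(list(A = 1, B = c(1, 2))), "at least 2")
  allsame <- one_way_anova(list(A = c(2, 2), B = c(2, 2, 2)))
  expect_identical(allsame$F, 0)
  expect_identical(allsame$p, 1)
})

test_that("t_test matches the hand-evaluated pooled formula", {
  res <- t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$p, 2 * pt(-3.674235, 4), tolerance = 1e-5)
})

test_that("identical samples give t = 0, p = 1", {
  res <- t_test(c(5, 5), c(5, 5, 5))
  expect_identical(res$t, 0)
  expect_identical(res$p, 1)
})

test_that("Welch and pooled t agree for equal variances and sizes", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  pooled <- t_test(a, b, equal_var = TRUE)
  welch <- t_test(a, b, equal_var = FALSE)
  expect_equal(pooled$t, welch$t, tolerance = 1e-12)
  expect_equal(pooled$p, welch$p, tolerance = 1e-3)
})

test_that("Dunnett with one treatment reduces to the two-sample t test", {
  set.seed(8)
  g <- list(ctrl = rnorm(6), trt = rnorm(6, 0.8))
  cmp <- dunnett(g, "ctrl", n_mc = 2e5, seed = 5)
  tt <- t_test(g$trt, g$ctrl, equal_var = TRUE)
  expect_equal(cmp$comparisons$p_adj, tt$p,
               tolerance = 3 * max(cmp$comparisons$mc_se, 1e-4))
  expect_equal(cmp$comparisons$t, tt$t, tolerance = 1e-10)
})

test_that("adjusted p is at least the per-contrast unadjusted p", {
  for (s in 1:5) {
    set.seed(s)
    g <- list(c = rnorm(6), t1 = rnorm(5, 0.5), t2 = rnorm(7, 1),
              t3 = rnorm(6))
    cmp <- dunnett(g, "c", n_mc = 5e4, seed = s + 100)$comparisons
    expect_true(all(cmp$p_adj >= cmp$p_unadj - 3 * cmp$mc_se))
  }
})

test_that("adjusted p grows with the number of treatment groups", {
  set.seed(12)
  ctrl <- rnorm(6); t1 <- rnorm(6, 0.9)
  extra1 <- ctrl + 0.01; extra2 <- ctrl - 0.01
  p1 <- dunnett(list(c = ctrl, t1 = t1), "c",
                n_mc = 2e5, seed = 3)$comparisons$p_adj[1]
  p2 <- dunnett(list(c = ctrl, t1 = t1, t2 = extra1), "c",
                n_mc = 2e5, seed = 3)$comparisons
  p3 <- dunnett(list(c = ctrl, t1 = t1, t2 = extra1, t3 = extra2), "c",
                n_mc = 2e5, seed = 3)$comparisons
  expect_gte(p2$p_adj[p2$group == "t1"], p1 - 0.005)
  expect_gte(p3$p_adj[p3$group == "t1"], p2$p_adj[p2$group == "t1"] - 0.005)
})

test_that("Dunnett matches the reference distribution implementation", {
  skip_if_not_installed("multcomp")
  set.seed(9)
  df <- data.frame(y = rnorm(24) + rep(c(0, 0.5, 1, 0), each = 6),
                   g = factor(rep(c("c", "t1", "t2", "t3"), each = 6)))
  ref <- summary(multcomp::glht(stats::aov(y ~ g, df),
                                linfct = multcomp::mcp(g = "Dunnett")))
  mine <- dunnett(split(df$y, df$g), "c", n_mc = 5e5, seed = 2)
  expect_equal(mine$comparisons$p_adj, as.numeric(ref$test$pvalues),
               tolerance = 0.01)
})

test_that("Dunnett is deterministic for a fixed seed and checks its inputs", {
  set.seed(10)
  g <- list(c = rnorm(4), a = rnorm(4), b = rnorm(4))
  r1 <- dunnett(g, "c", n_mc = 1e4, seed = 77)
  r2 <- dunnett(g, "c", n_mc = 1e4, seed = 77)
  expect_identical(r1$comparisons$p_adj, r2$comparisons$p_adj)
  expect_error(dunnett(g, "missing"), "not found")
})

test_that("significance stars follow the figure conventions", {
  expect_identical(p_stars(c(0.2, 0.05, 0.01, 0.001, 1e-5)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("a noiseless 4PL curve is recovered essentially exactly", {
  dose <- 400 / 2^(0:6)
  y <- 10 + (100 - 10) / (1 + (dose / 50)^1.3)
  fit <- fit_4pl(dose, y)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 50, tolerance = 1e-6)
  expect_equal(fit$hill, 1.3, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-5)
  expect_equal(fit$bottom, 10, tolerance = 1e-4)
  # fitted response at the IC50 sits halfway between the plateaus
  mid <- fit$bottom + (fit$top - fit$bottom) / 2
  expect_equal(fit$bottom + (fit$top - fit$bottom) /
                 (1 + (fit$ic50 / fit$ic50)^fit$hill), mid)
})

test_that("monotone noiseless data yield a monotone fitted curve", {
  dose <- 1000 / 2^(0:6)
  y <- 100 / (1 + (dose / 80))
  fit <- fit_4pl(dose, y)
  expect_true(fit$converged)
  grid <- exp(seq(log(min(dose)), log(max(dose)), length.out = 50))
  pred <- fit$bottom + (fit$top - fit$bottom) / (1 + (grid / fit$ic50)^fit$hill)
  expect_true(all(diff(pred) <= 1e-8))
})

test_that("4PL input validation and non-convergence are explicit", {
  expect_error(fit_4pl(c(-1, 1, 2, 4, 8), 1:5), "positive")
  expect_error(fit_4pl(c(1, 2, 2, 1, 2), 1:5), "5 distinct")
  set.seed(1)
  wild <- fit_4pl(2^(0:6), rnorm(7, 0, 1e6))
  expect_true(is.logical(wild$converged))
})
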