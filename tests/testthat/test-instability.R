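test_that("the main allele is the tallest peak, ties to the smaller repeat", {
  expect_identical(main_allele(make_peakset(c(110, 111), c(100, 50))), 110L)
  expect_identical(main_allele(make_peakset(c(110, 112), c(100, 100))), 110L)
  expect_identical(main_allele(make_peakset(c(108, 112), c(10, 90))), 112L)
})

test_that("the main allele survives minus-dominant stutter", {
  for (mr in c(0.1, 0.3, 0.6)) {
    d <- apply_stutter(c("110" = 1), stutter_params(mr, 0.05, 4))
    rps <- make_peakset(as.integer(names(d)), 1000 * as.numeric(d))
    expect_identical(main_allele(rps), 110L)
  }
})

test_that("the worked five-peak example reproduces the hand calculation", {
  rps <- make_peakset(108:112, c(5, 10, 100, 50, 25))
  res <- instability_index(rps, threshold_frac = 0.05)
  expect_equal(res$instability_index, 80 / 190, tolerance = 1e-12)
  expect_equal(res$expansion_index, 100 / 190, tolerance = 1e-12)
  expect_equal(res$contraction_index, -20 / 190, tolerance = 1e-12)
  expect_identical(res$main_allele, 110L)
  expect_identical(res$n_peaks_retained, 5L)
})

test_that("a single-peak sample indexes to zero in every mode", {
  rps <- make_peakset(110, 500)
  for (thr in c(0, 0.05, 0.5)) {
    res <- instability_index(rps, thr)
    expect_identical(res$instability_index, 0)
    expect_identical(res$expansion_index, 0)
    expect_identical(res$contraction_index, 0)
  }
})

test_that("peaks below the signal-to-noise cutoff do not move the index", {
  base <- make_peakset(108:112, c(5, 10, 100, 50, 25))
  plus <- make_peakset(c(108:113), c(5, 10, 100, 50, 25, 4))  # 4 < cutoff 5
  r1 <- instability_index(base, 0.05)
  r2 <- instability_index(plus, 0.05)
  expect_equal(r2$instability_index, r1$instability_index, tolerance = 1e-15)
  expect_equal(r2$expansion_index, r1$expansion_index, tolerance = 1e-15)
  expect_equal(r2$contraction_index, r1$contraction_index, tolerance = 1e-15)
  expect_identical(r2$n_peaks_retained, 5L)
})

test_that("the index matches the brute-force oracle on random peak sets", {
  for (s in 1:100) {
    rps <- random_peakset(s)
    thr <- c(0, 0.05, 0.2, 0.6)[s %% 4 + 1]
    for (mode in c("all", "expansion", "contraction")) {
      got <- instability_index(rps, thr, mode)$index
      expect_equal(got, oracle_index(rps$repeats, rps$heights, thr, mode),
                   tolerance = 1e-13)
    }
  }
})

test_that("threshold zero reduces to the height-weighted mean displacement", {
  for (s in 1:50) {
    rps <- random_peakset(s + 500)
    m <- main_allele(rps)
    closed <- sum(rps$heights / sum(rps$heights) * (rps$repeats - m))
    expect_equal(instability_index(rps, 0)$instability_index, closed,
                 tolerance = 1e-13)
  }
})

test_that("the index is invariant to uniform height rescaling", {
  for (s in 1:20) {
    rps <- random_peakset(s + 900)
    scaled <- make_peakset(rps$repeats, rps$heights * 37.5)
    expect_equal(instability_index(scaled, 0.05)$instability_index,
                 instability_index(rps, 0.05)$instability_index,
                 tolerance = 1e-12)
  }
})

test_that("raising the most-expanded peak never lowers the signed index", {
  # the index is a weighted mean of displacements, so only peaks whose
  # displacement is at least the current index pull it upward; the
  # largest-displacement peak always qualifies
  set.seed(4)
  for (i in 1:20) {
    rps <- random_peakset(i + 300)
    if (max(rps$repeats) <= main_allele(rps)) next
    j <- which.max(rps$repeats)
    h2 <- rps$heights
    h2[j] <- h2[j] * runif(1, 1, 2)
    # keep the main allele fixed for a clean comparison
    if (max(h2) > max(rps$heights)) h2[j] <- max(rps$heights)
    bumped <- make_peakset(rps$repeats, h2)
    expect_gte(instability_index(bumped, 0)$instability_index,
               instability_index(rps, 0)$instability_index - 1e-12)
  }
})

test_that("expansion and contraction indices add to the signed index", {
  for (s in 1:50) {
    rps <- random_peakset(s + 700)
    res <- instability_index(rps, 0.05)
    expect_identical(res$expansion_index + res$contraction_index,
                     res$instability_index)
  }
})

test_that("peak sets symmetric around the main allele index to zero", {
  rps <- make_peakset(c(106, 108, 110, 112, 114), c(20, 60, 100, 60, 20))
  expect_equal(instability_index(rps, 0)$instability_index, 0,
               tolerance = 1e-14)
})

test_that("index_cohort preserves labels and survives per-sample failures", {
  good <- make_peakset(108:112, c(5, 10, 100, 50, 25), sample_id = "ok")
  res <- index_cohort(list(good, good), groups = c("A", "A"))
  expect_equal(res$instability_index[1], res$instability_index[2])
  expect_equal(res$group, c("A", "A"))

  bad <- suppressWarnings(bin_to_repeats(peak_table(101.7, 10), toy_locus()))
  expect_warning(res2 <- index_cohort(list(good, bad), groups = c("A", "B")),
                 "failed")
  expect_equal(nrow(res2), 2L)
  expect_true(is.na(res2$instability_index[2]))
  expect_false(is.na(res2$instability_index[1]))
})

test_that("msi_compare is the identity on matching samples", {
  loc <- mono_locus()
  a <- repeat_peakset(c(23, 24, 25), c(30, 100, 10), loc, "a")
  res <- msi_compare(a, a)
  expect_identical(res$main_allele_shift, 0L)
  expect_identical(res$index_difference, 0)
  expect_false(res$unstable)
})

test_that("a two-repeat main-allele shift is flagged unstable", {
  loc <- mono_locus()
  ref <- repeat_peakset(c(23, 24), c(30, 100), loc, "ref")
  smp <- repeat_peakset(c(25, 26), c(30, 100), loc, "s")
  res <- msi_compare(smp, ref)
  expect_identical(res$main_allele_shift, 2L)
  expect_true(res$unstable)
  # swap symmetry up to sign
  rev <- msi_compare(ref, smp)
  expect_identical(rev$main_allele_shift, -2L)
  expect_equal(rev$index_difference, -res$index_difference)
})

test_that("msi_compare refuses mismatched loci", {
  a <- repeat_peakset(24, 100, mono_locus(), "a")
  b <- repeat_peakset(110, 100, toy_locus(), "b")
  expect_error(msi_compare(a, b), "different loci")
})

test_that("simulated stable mononucleotide cohorts are uniformly stable", {
  loc <- mono_locus()
  sp <- stutter_params(0.25, 0.01, 4)
  des <- cohort_design(list(
    cohort_group("PBS", 2, true_gain = 0, inherited_repeat = 24L,
                 n_cells = 2000, stutter = sp),
    cohort_group("NTC", 2, true_gain = 0, inherited_repeat = 24L,
                 n_cells = 2000, stutter = sp)
  ), loc, seed = 17)
  sim <- simulate_cohort(des)
  ref <- sim$samples[[1]]
  flags <- vapply(sim$samples, function(s) msi_compare(s, ref)$unstable, TRUE)
  expect_false(any(flags))
})
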