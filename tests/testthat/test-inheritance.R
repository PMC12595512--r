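test_that("trio deviations follow the mid-parent decomposition", {
  d <- trioDeviations(mk_trio(4, 2, 5))
  expect_equal(d, list(m = 3, a = 1, d = 2))
  d <- trioDeviations(mk_trio(7, 7, 7))
  expect_equal(d, list(m = 7, a = 0, d = 0))
  # printed fast/slow bred-line growth means
  d <- trioDeviations(mk_trio(4.07, 1.12, 3))
  expect_equal(d$m, 2.595)
  expect_equal(d$a, 1.475)
})

test_that("dominance ratio guards against near-identical parents", {
  expect_equal(dominanceRatio(1, 1), 1.0)
  expect_equal(dominanceRatio(0.5, 1), 0.5)
  expect_true(is.na(dominanceRatio(0.3, 0)))
  expect_true(is.na(dominanceRatio(0.3, 0.05, a_min = 0.1)))
  expect_equal(dominanceRatio(-2, 1), -2)
})

test_that("mode classification reproduces the d/a bins", {
  expect_equal(classifyMode(0), "codominance")
  expect_equal(classifyMode(1.8), "overdominance")
  expect_equal(classifyMode(-1.0), "complete_dominance_low")
  expect_equal(classifyMode(1.0), "complete_dominance_high")
  expect_equal(classifyMode(0.5), "partial_dominance_high")
  expect_equal(classifyMode(-0.5), "partial_dominance_low")
  expect_equal(classifyMode(-1.8), "underdominance")
  # epsilon widens the point bins
  expect_equal(classifyMode(0.09, epsilon = 0.1), "codominance")
  expect_equal(classifyMode(0.11, epsilon = 0.1), "partial_dominance_high")
  expect_equal(classifyMode(1.09, epsilon = 0.1), "complete_dominance_high")
  expect_equal(classifyMode(1.11, epsilon = 0.1), "overdominance")
  # undefined ratio falls back on the sign of d
  expect_equal(classifyMode(NA, d = 0), "undefined_parents_equal")
  expect_equal(classifyMode(NA, d = 2), "overdominance")
  expect_equal(classifyMode(NA, d = -2), "underdominance")
})

test_that("mid-parent heterosis is the percent deviation from the mid-parent", {
  expect_equal(midParentHeterosis(2, 2), 0)
  expect_equal(midParentHeterosis(4, 2), 100)
  expect_equal(midParentHeterosis(3, 2), 50)
  expect_error(midParentHeterosis(1, 0), "undefined MPH")
})

test_that("MPH identity and range equivalence hold on random trios", {
  set.seed(42)
  for (i in 1:500) {
    p1 <- runif(1, -5, 5); p2 <- runif(1, -5, 5); f1 <- runif(1, -8, 8)
    if (abs(p1 - p2) < 1e-6) next
    trio <- mk_trio(p1, p2, f1)
    dev <- trioDeviations(trio)
    if (dev$m != 0)
      expect_equal(midParentHeterosis(f1, dev$m), 100 * dev$d / dev$m,
                   tolerance = 1e-12)
    # |d/a| > 1 iff F1 outside the parental range, sign gives the side
    ratio <- dominanceRatio(dev$d, dev$a)
    outside_hi <- f1 > max(p1, p2)
    outside_lo <- f1 < min(p1, p2)
    expect_equal(ratio > 1, outside_hi)
    expect_equal(ratio < -1, outside_lo)
  }
})

test_that("swapping the parent labels changes nothing", {
  set.seed(9)
  for (i in 1:50) {
    p1 <- runif(1, 0, 10); p2 <- runif(1, 0, 10); f1 <- runif(1, 0, 12)
    a <- inheritanceCall(mk_trio(p1, p2, f1))
    b <- inheritanceCall(mk_trio(p2, p1, f1))
    expect_equal(a$m, b$m)
    expect_equal(a$a, b$a)
    expect_equal(a$d, b$d)
    expect_equal(a$ratio, b$ratio)
    expect_equal(a$mode, b$mode)
    expect_equal(a$mph_percent, b$mph_percent)
  }
})

test_that("transgressive calls need both range exceedance and Welch support", {
  # F1 strictly between the parents: never transgressive
  expect_false(callTransgressive(mk_trio(1, 5, 3))$transgressive)
  # F1 at the high-parent boundary: not outside the range
  expect_false(callTransgressive(mk_trio(1, 5, 5))$transgressive)
  # F1 four SDs above both parents
  tg <- callTransgressive(mk_trio(1, 5, 5 + 4 * 0.2, sd = 0.2, n = 3))
  expect_true(tg$transgressive)
  expect_equal(tg$direction, "above")
  # outside the range but statistically unsupported (huge SD)
  expect_false(callTransgressive(mk_trio(1, 5, 5.5, sd = 10))$transgressive)
  expect_error(callTransgressive(trioPhenotype("t",
    c(mean = 1, n = 1), c(mean = 5, sd = 1, n = 3),
    c(mean = 9, sd = 1, n = 3))), "insufficient replication")
})

test_that("summary-statistic Welch test matches t.test on raw replicates", {
  set.seed(33)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:8, 1), mean = runif(1, 0, 5), sd = runif(1, 0.5, 2))
    ref <- t.test(x, y)
    w <- welchFromSummary(mean(x), sd(x), length(x),
                          mean(y), sd(y), length(y))
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bootstrap is seeded, degenerates correctly and brackets symmetry", {
  trio <- mk_trio(2, 6, 7, sd = 0.3)
  b1 <- bootstrapTrio(trio, B = 500, seed = 4)
  b2 <- bootstrapTrio(trio, B = 500, seed = 4)
  expect_identical(b1, b2)
  # zero SDs: degenerate CIs at the point estimates, full stability
  b0 <- bootstrapTrio(mk_trio(2, 6, 7, sd = 0), B = 200, seed = 1)
  expect_equal(b0$ratio_ci, rep(b0$ratio, 2))
  expect_equal(b0$mph_ci, rep(b0$mph_percent, 2))
  expect_equal(b0$mode_stability, 1)
  # symmetric trio: MPH centred near zero
  bs <- bootstrapTrio(mk_trio(-3, 3, 0, sd = 0.3), B = 2000, seed = 2)
  expect_lt(bs$mph_ci[1], 0)
  expect_gt(bs$mph_ci[2], 0)
  expect_error(bootstrapTrio(mk_trio(1, 2, 3, n = 1)), "insufficient")
})

test_that("bootstrap ratio CI covers the true ratio at roughly its level", {
  # scaled-down coverage experiment: true d/a = 1.5, small replicate noise.
  # n = 10 replicates keeps the plug-in SD stable enough for the percentile
  # interval to be near-nominal; it is still slightly liberal, so the band
  # is wide around the nominal 95%
  true_ratio <- 1.5; a <- 2; m <- 10; sd <- 0.15; n <- 10
  set.seed(88)
  covered <- vapply(1:120, function(i) {
    p1 <- rnorm(n, m + a, sd); p2 <- rnorm(n, m - a, sd)
    f1 <- rnorm(n, m + true_ratio * a, sd)
    trio <- trioPhenotype("t",
      c(mean = mean(p1), sd = sd(p1), n = n),
      c(mean = mean(p2), sd = sd(p2), n = n),
      c(mean = mean(f1), sd = sd(f1), n = n))
    ci <- bootstrapTrio(trio, B = 400, seed = i)$ratio_ci
    ci[1] <= true_ratio && true_ratio <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("the MI table combines calls over a trio set", {
  trios <- list(mk_trio(2, 6, 7, trait = "gA"),
                mk_trio(2, 6, 4, trait = "gB"),
                mk_trio(2, 6, 2, trait = "gC"))
  mi <- miTable(trios)
  expect_equal(nrow(mi), 3L)
  expect_equal(mi$trait_id, c("gA", "gB", "gC"))
  expect_equal(mi$mode,
               c("overdominance", "codominance", "complete_dominance_low"))
  expect_equal(mi$transgressive, c(TRUE, FALSE, FALSE))
  mi_bs <- miTable(trios[1], bootstrap = TRUE, B = 200, seed = 3)
  expect_true(all(c("ratio_lo", "ratio_hi", "mode_stability") %in%
                    names(mi_bs)))
})
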