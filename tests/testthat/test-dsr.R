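## Dirichlet-multinomial bunch model, DSR likelihood-ratio test, PSI.

test_that("DM log-pmf matches closed forms and exchangeability", {
  ## one trial with a uniform ratio: P = alpha_l / sum(alpha) = 1/2
  expect_equal(dmLogpmf(c(1, 0), c(1, 1)), log(0.5))
  ## empty draw has probability one
  expect_equal(dmLogpmf(c(0, 0), c(2, 3)), 0)
  ## symmetric concentrations are exchangeable
  expect_equal(dmLogpmf(c(4, 1, 2), c(2, 2, 2)),
               dmLogpmf(c(2, 1, 4), c(2, 2, 2)))
  expect_error(dmLogpmf(c(1, 0), c(1, -1)), "alpha")
  expect_error(dmLogpmf(c(1), c(1)), "k >= 2")
})

test_that("DM pmf sums to one by exhaustive enumeration", {
  for (case in list(list(k = 2, N = 12, a = c(0.7, 2.5)),
                    list(k = 3, N = 8, a = c(1, 5, 0.3)))) {
    comp <- compositions(case$N, case$k)
    total <- sum(apply(comp, 1, function(y) exp(dmLogpmf(y, case$a))))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("DM fit recovers planted concentration ratios", {
  set.seed(14)
  Y <- rdirmult(40, 400, c(30, 10))  # tight 3:1 ratio
  fit <- fitDm(Y)
  expect_true(fit@converged)
  ratio <- fit@alpha[1] / fit@alpha[2]
  expect_lt(abs(ratio - 3) / 3, 0.05)
  ## all mass on one intron: ratio pinned near 1 despite the floor
  Y1 <- rbind(rep(50L, 10), rep(0L, 10))
  expect_gte(psiFromAlpha(fitDm(Y1)@alpha)[1], 0.99)
  ## single symmetric sample
  f1 <- fitDm(matrix(c(10L, 10L), 2, 1))
  expect_equal(psiFromAlpha(f1@alpha)[1], 0.5, tolerance = 0.02)
  ## all-zero bunch: flagged, not fitted
  expect_false(fitDm(matrix(0L, 2, 5))@converged)
})

test_that("splicing ratios normalize and ignore concentration scale", {
  expect_equal(psiFromAlpha(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(psiFromAlpha(c(7, 7)), c(0.5, 0.5))
  expect_equal(psiFromAlpha(c(3, 1)), c(0.75, 0.25))
  set.seed(2)
  a <- runif(4, 0.1, 9)
  expect_equal(psiFromAlpha(a), psiFromAlpha(13.7 * a))
  expect_equal(sum(psiFromAlpha(a)), 1)
})

test_that("per-sample PSI is column-wise proportions with NA empty columns", {
  Y <- cbind(c(3, 1), c(0, 0), c(10, 0))
  ps <- perSamplePsi(Y)
  expect_equal(ps[, 1], c(0.75, 0.25))
  expect_true(all(is.na(ps[, 2])))
  expect_equal(ps[, 3], c(1, 0))
})

test_that("identical data across conditions give a null DSR result", {
  set.seed(5)
  Y <- rdirmult(10, 50, c(5, 5))
  tst <- lrtDsr(cbind(Y, Y), rep(c("a", "b"), each = 10))
  expect_equal(tst$lr, 0, tolerance = 1e-4)
  expect_gt(tst$p_value, 0.99)
  expect_equal(tst$df, 2L)
  expect_equal(rowSums(tst$psi), c(a = 1, b = 1), tolerance = 1e-9)
})

test_that("a ratio swap is detected with the planted effect size", {
  set.seed(16)
  hits <- 0; dps <- numeric(40)
  for (r in 1:40) {
    Y <- cbind(rdirmult(25, rpois(25, 50), c(8, 2)),
               rdirmult(25, rpois(25, 50), c(2, 8)))
    tst <- lrtDsr(Y, rep(c("a", "b"), each = 25))
    hits <- hits + (tst$p_value < 0.05)
    dps[r] <- max(tst$dpsi)
  }
  expect_gte(hits, 38)
  expect_gt(median(dps), 0.45)
  expect_lt(median(dps), 0.75)
})

test_that("the DSR statistic is invariant to within-condition permutation", {
  set.seed(18)
  Y <- cbind(rdirmult(8, 40, c(6, 2, 2)), rdirmult(8, 40, c(2, 6, 2)))
  lab <- rep(c("a", "b"), each = 8)
  perm <- c(sample(1:8), sample(9:16))
  t1 <- lrtDsr(Y, lab)
  t2 <- lrtDsr(Y[, perm], lab[perm])
  expect_equal(t1$lr, t2$lr, tolerance = 1e-5)
})

test_that("a condition without reads is reported missing, test still runs", {
  Y <- cbind(rdirmult(5, 30, c(5, 5)), matrix(0L, 2, 5),
             rdirmult(5, 30, c(8, 2)))
  tst <- lrtDsr(Y, rep(c("a", "b", "c"), each = 5))
  expect_equal(tst$status, "TEST")
  expect_true(all(is.na(tst$psi["b", ])))
  expect_false(anyNA(tst$psi[c("a", "c"), ]))
  expect_equal(tst$df, 2L)  # k * (m_eff - 1) with two informative conditions
  ## all but one condition empty: nothing to test
  Y2 <- cbind(rdirmult(5, 30, c(5, 5)), matrix(0L, 2, 5))
  expect_equal(lrtDsr(Y2, rep(c("a", "b"), each = 5))$status, "NO-DATA")
})

test_that("runDSR tests every multi-intron bunch and adjusts p-values", {
  set.seed(44)
  tr <- simulateTruth(n_genes = 30, seed = 44)
  jx <- simulateJunctionExperiment(tr, n_per_condition = 12, seed = 45)
  res <- runDSR(jx)
  expect_equal(nrow(res$bunches), 30)
  expect_true(all(res$bunches$k >= 2))
  expect_equal(nrow(res$introns), sum(res$bunches$k))
  fam <- res$bunches$status == "TEST"
  expect_equal(res$bunches$q_value[fam], bhAdjust(res$bunches$p_value[fam]))
  expect_true(all(res$introns$dpsi >= 0 & res$introns$dpsi <= 1,
                  na.rm = TRUE))
})
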