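# Statistics: each procedure against an independent oracle (base R
# implementations, closed forms, frozen cross-implementation values, or
# Monte-Carlo), plus the raw-data/summary-statistics equivalence.

# fixture with unequal variances, reproduced exactly by the seed
.ghFixture <- function() {
  set.seed(4711)
  list(a = round(rnorm(12, 10, 2), 4),
       b = round(rnorm(9, 12, 5), 4),
       c = round(rnorm(15, 15, 1), 4))
}

.iccFixture <- function() {
  set.seed(99)
  truthv <- round(rnorm(10, 50, 10), 4)
  cbind(r1 = round(truthv + rnorm(10, 0, 2), 4),
        r2 = round(truthv + 1.5 + rnorm(10, 0, 2), 4),
        r3 = round(truthv - 0.8 + rnorm(10, 0, 2), 4))
}

test_that("groupSummary reproduces t-based confidence bounds", {
  s <- groupSummary(mean = 33.28, sd = 27.25, n = 71)
  expect_equal(round(c(s$ciLow, s$ciHigh), 2), c(26.83, 39.73))
  s2 <- groupSummary(mean = 54.73, sd = 27.98, n = 41)
  expect_equal(round(c(s2$ciLow, s2$ciHigh), 2), c(45.90, 63.56))
  # constant values collapse the interval onto the mean
  s3 <- groupSummary(values = rep(4.2, 6))
  expect_identical(c(s3$sd, s3$ciLow, s3$ciHigh), c(0, 4.2, 4.2))
  # raw data and its own summaries agree
  set.seed(1); v <- rnorm(40, 5, 2)
  expect_equal(groupSummary(values = v)$ciLow,
               groupSummary(mean = mean(v), sd = sd(v), n = 40)$ciLow,
               tolerance = 1e-12)
})

test_that("Fisher-z interval is symmetric at r = 0 and matches a bootstrap oracle", {
  ci <- pearsonFisherCI(r = 0, n = 50)
  expect_equal(ci$ciLow, -ci$ciHigh, tolerance = 1e-12)
  # degenerate |r| = 1
  d <- pearsonFisherCI(r = 1, n = 30)
  expect_identical(c(d$ciLow, d$ciHigh), c(1, 1))
  # bootstrap oracle on a bivariate normal fixture
  set.seed(8)
  n <- 400
  x <- rnorm(n); y <- 0.7 * x + rnorm(n, 0, sqrt(1 - 0.49))
  fi <- pearsonFisherCI(x = x, y = y)
  boot <- replicate(800, {
    i <- sample.int(n, replace = TRUE)
    cor(x[i], y[i])
  })
  bq <- quantile(boot, c(0.025, 0.975))
  expect_lt(abs(fi$ciLow - bq[1]), 0.04)
  expect_lt(abs(fi$ciHigh - bq[2]), 0.04)
})

test_that("R-squared equals r^2 and linearFit recovers exact fits", {
  expect_equal(round(regressionR2(0.76), 2), 0.58)
  expect_equal(round(regressionR2(0.96), 2), 0.92)
  fit <- suppressWarnings(linearFit(1:10, 2 * (1:10) + 3))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_error(linearFit(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("Levene's test matches car::leveneTest and detects variance ratios", {
  g <- .ghFixture()
  mine <- leveneVarianceTest(g)
  skip_if_not_installed("car")
  y <- unlist(g); f <- factor(rep(names(g), lengths(g)))
  ref <- car::leveneTest(y, f, center = mean)
  expect_equal(mine$W, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # identical groups: W = 0, p = 1
  eq <- leveneVarianceTest(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(eq$W, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1, tolerance = 1e-12)
  # sd ratio 10 at n = 50 is detected decisively
  set.seed(2)
  big <- list(rnorm(50, 0, 1), rnorm(50, 0, 10))
  expect_lt(leveneVarianceTest(big)$p, 0.001)
})

test_that("Welch ANOVA matches oneway.test and the classic F in the homoscedastic limit", {
  g <- .ghFixture()
  mine <- welchAnova(g)
  y <- unlist(g); f <- factor(rep(names(g), lengths(g)))
  ref <- oneway.test(y ~ f, var.equal = FALSE)
  expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df2, unname(ref$parameter[2]), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  # frozen cross-implementation values (pingouin 0.6.1 on this fixture)
  expect_equal(mine$F, 24.41960522, tolerance = 1e-6)
  expect_equal(mine$df2, 14.01619946, tolerance = 1e-6)
  # balanced equal-variance groups: Welch F ~= classic ANOVA F
  set.seed(3)
  h <- lapply(1:3, function(i) rnorm(40, i * 0.2, 1))
  classic <- unname(summary(aov(unlist(h) ~ factor(rep(1:3, each = 40))))[[1]][1, "F value"])
  expect_equal(welchAnova(h)$F, classic, tolerance = 0.05 * classic + 1e-6)
  # identical group means: F ~ 0, p ~ 1
  null <- welchAnova(list(c(1, 2, 3, 4), c(2, 3, 1, 4), c(4, 1, 3, 2)))
  expect_lt(null$F, 0.05)
  expect_gt(null$p, 0.9)
  # summary input equals raw input
  sm <- welchAnova(means = sapply(g, mean), sds = sapply(g, sd),
                   ns = lengths(g))
  expect_equal(sm$F, mine$F, tolerance = 1e-12)
})

test_that("Games-Howell matches a reference implementation and the Tukey limit", {
  g <- .ghFixture()
  gh <- gamesHowell(g)
  # frozen cross-implementation values (pingouin 0.6.1 on this fixture)
  ref <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                    diff = c(-3.93202222, -5.04313333, -1.11111111),
                    se = c(1.31166757, 0.70670483, 1.15323189),
                    df = c(13.37195145, 13.69570285, 8.68858511),
                    t = c(-2.99772770, -7.13612406, -0.96347588),
                    p = c(0.02536796, 0.00001601, 0.61702435))
  expect_equal(gh$mean_diff, ref$diff, tolerance = 1e-6)
  expect_equal(gh$se, ref$se, tolerance = 1e-6)
  expect_equal(gh$df, ref$df, tolerance = 1e-5)
  expect_equal(gh$t, ref$t, tolerance = 1e-6)
  expect_equal(gh$p_adj, ref$p, tolerance = 1e-4)
  # two equal groups -> p ~ 1
  eqp <- gamesHowell(list(x = c(5, 6, 7, 8), y = c(5, 6, 7, 8)))
  expect_gt(eqp$p_adj, 0.99)
  # equal-variance limit: with identical sample variances (shared residual
  # vector) and large groups, Games-Howell collapses onto Tukey HSD to 1e-3
  # (the remaining gap is the Welch-vs-pooled df, which vanishes with n)
  set.seed(12)
  base <- rnorm(200)
  base <- (base - mean(base)) / sd(base)
  h <- lapply(c(0, 0.25, 0.5), function(m) base + m)
  names(h) <- c("g1", "g2", "g3")
  ghp <- gamesHowell(h)
  y <- unlist(h); f <- factor(rep(names(h), each = 200))
  tk <- TukeyHSD(aov(y ~ f))$f
  # order: g2-g1, g3-g1, g3-g2 matches combn order g1g2, g1g3, g2g3
  expect_lt(max(abs(ghp$p_adj - tk[, "p adj"])), 1e-3)
})

test_that("effect sizes reproduce the summary-table pairwise values", {
  tab <- data.frame(mean = c(33.28, 54.73, 85.85, 160.68),
                    sd = c(27.25, 27.98, 41.31, 64.21))
  expect_equal(round(effectSizeRMS(tab$mean[1], tab$sd[1],
                                   tab$mean[2], tab$sd[2]), 2), 0.78)
  expect_equal(round(effectSizeRMS(tab$mean[2], tab$sd[2],
                                   tab$mean[3], tab$sd[3]), 2), 0.88)
  expect_equal(round(effectSizeRMS(tab$mean[1], tab$sd[1],
                                   tab$mean[4], tab$sd[4]), 2), 2.58)
  expect_identical(effectSizeRMS(5, 1, 5, 2), 0)
  expect_error(effectSizeRMS(1, 0, 2, 0), "undefined")
})

test_that("hedgesG applies pooled variance and the small-sample correction", {
  expect_identical(hedgesG(5, 1, 10, 5, 2, 10), 0)
  # equal n, equal sd: equals the RMS variant times the correction factor
  g1 <- hedgesG(10, 2, 15, 12, 2, 15)
  corr <- 1 - 3 / (4 * 30 - 9)
  expect_equal(g1, effectSizeRMS(10, 2, 12, 2) * corr, tolerance = 1e-12)
  # textbook-formula oracle on raw data summaries
  set.seed(7)
  a <- rnorm(20, 1, 2); b <- rnorm(25, 0, 3)
  sp <- sqrt(((20 - 1) * var(a) + (25 - 1) * var(b)) / (20 + 25 - 2))
  oracle <- abs(mean(a) - mean(b)) / sp * (1 - 3 / (4 * 45 - 9))
  expect_equal(hedgesG(mean(a), sd(a), 20, mean(b), sd(b), 25), oracle,
               tolerance = 1e-12)
})

test_that("pairedTTest matches t.test and handles degenerate differences", {
  r <- pairedTTest(meanDiff = 5.59, sdDiff = 16.38, n = 32)
  expect_equal(round(c(r$ciLow, r$ciHigh), 2), c(-0.32, 11.50))
  expect_equal(round(r$effectSize, 2), 0.34)
  expect_equal(round(r$p, 2), 0.06)
  set.seed(4)
  d <- rnorm(25, 0.4, 1)
  mine <- pairedTTest(diffs = d)
  ref <- t.test(d)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(mine$ciLow, mine$ciHigh), as.numeric(ref$conf.int),
               tolerance = 1e-12)
  # all-zero differences
  z <- pairedTTest(diffs = rep(0, 10))
  expect_identical(c(z$t, z$p), c(0, 1))
  # sign flip negates t, keeps p
  m2 <- pairedTTest(diffs = -d)
  expect_equal(m2$t, -mine$t, tolerance = 1e-12)
  expect_equal(m2$p, mine$p, tolerance = 1e-12)
})

test_that("Bland-Altman uses 1.96 SD limits with ~95% coverage", {
  ba <- blandAltman(meanDiff = 5.59, sdDiff = 16.38, n = 32)
  expect_equal(round(c(ba$loaLow, ba$loaHigh), 2), c(-26.51, 37.69))
  expect_true(ba$agreement)  # CI (-0.32, 11.50) includes zero
  # zero-mean differences: symmetric limits
  set.seed(10)
  d <- rnorm(200, 0, 3)
  b2 <- blandAltman(a = d, b = rep(0, 200))
  expect_equal(b2$loaHigh, -b2$loaLow + 2 * b2$meanDiff, tolerance = 1e-10)
  # coverage on a large normal sample
  set.seed(11)
  big <- rnorm(20000, 2, 5)
  b3 <- blandAltman(a = big, b = rep(0, 20000))
  cover <- mean(big >= b3$loaLow & big <= b3$loaHigh)
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("ICC(A,1) matches the mean-squares oracle and known agreement behavior", {
  m <- .iccFixture()
  r <- iccSingleAbsolute(m)
  # frozen cross-implementation values (pingouin 0.6.1 on this fixture)
  expect_equal(r$icc, 0.84134464, tolerance = 1e-6)
  expect_equal(r$ciLow, 0.50891555, tolerance = 1e-4)
  expect_equal(r$ciHigh, 0.95742145, tolerance = 1e-4)
  rc <- iccSingleAbsolute(m, type = "consistency")
  expect_equal(rc$icc, 0.90465188, tolerance = 1e-6)
  # identical columns -> perfect agreement
  v <- matrix(rep(c(1, 5, 9, 13, 17, 21), 2), ncol = 2)
  expect_equal(iccSingleAbsolute(v)$icc, 1, tolerance = 1e-12)
  # constant offset: consistency stays 1, absolute agreement drops
  off <- cbind(v[, 1], v[, 1] + 4)
  expect_equal(iccSingleAbsolute(off, type = "consistency")$icc, 1,
               tolerance = 1e-12)
  expect_lt(iccSingleAbsolute(off)$icc, 1)
  expect_error(iccSingleAbsolute(matrix(1, 10, 2)), "constant")
  expect_error(iccSingleAbsolute(matrix(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), 5)),
               "missing")
  # parameter recovery: two raters, known variance components
  set.seed(20)
  n <- 500
  subj <- rnorm(n, 0, sqrt(8)); err <- matrix(rnorm(2 * n, 0, 1), n, 2)
  est <- iccSingleAbsolute(cbind(subj + err[, 1], subj + err[, 2]))$icc
  expect_lt(abs(est - 8 / 9), 0.02)
})

test_that("SEM follows sd * sqrt(1 - ICC)", {
  expect_identical(semFromICC(10, 1), 0)
  expect_identical(semFromICC(10, 0), 10)
  expect_equal(semFromICC(78.90, 0.99), 7.89, tolerance = 1e-12)
  expect_error(semFromICC(10, 1.2), "\\[0, 1\\]")
})

test_that("power calculators agree with the printed design values", {
  expect_identical(anovaRequiredN(f = 0.25, k = 4), 180L)
  expect_true(abs(pairedTRequiredN(0.34) - 70) <= 1)
  expect_equal(round(pairedTPower(0.34, 32), 1), 0.5)
  # power is monotone in n and d
  pw <- sapply(seq(10, 200, by = 10), function(n) pairedTPower(0.4, n))
  expect_true(all(diff(pw) > 0))
  pw2 <- sapply(seq(0.1, 1.5, by = 0.1), function(d) pairedTPower(d, 30))
  expect_true(all(diff(pw2) > 0))
  pa <- sapply(seq(40, 400, by = 20), function(n) anovaPower(0.25, 4, n))
  expect_true(all(diff(pa) > 0))
  # extreme effect: minimum feasible n
  expect_identical(anovaRequiredN(f = 50, k = 4), 8L)
  # cross-check against base R (power.t.test drops the opposite-tail mass,
  # ~1e-6 here, so the comparison is at 1e-5)
  expect_equal(pairedTPower(0.34, 70),
               power.t.test(n = 70, delta = 0.34, sd = 1,
                            type = "paired")$power, tolerance = 1e-5)
})

test_that("agreementAnalysis composes paired-t, limits of agreement, ICC and SEM", {
  set.seed(15)
  truthv <- runif(40, 0, 200)
  rated <- truthv + 5 + rnorm(40, 0, 12)
  r <- agreementAnalysis(rated, truthv)
  expect_equal(r$meanDiff, mean(rated - truthv), tolerance = 1e-12)
  expect_equal(r$loaHigh - r$loaLow, 2 * 1.96 * sd(rated - truthv),
               tolerance = 1e-10)
  expect_gt(r$icc, 0.9)
  expect_equal(r$sem, sd(c(rated, truthv)) * sqrt(1 - r$icc),
               tolerance = 1e-10)
})

test_that("rotationGroupTable reproduces group summaries in severity order", {
  set.seed(30)
  vals <- c(rnorm(20, 33, 5), rnorm(15, 85, 10))
  grp <- rep(c("minimal", "marked"), c(20, 15))
  tab <- rotationGroupTable(vals, grp)
  expect_identical(tab$group, c("minimal", "marked"))
  expect_equal(tab$mean[1], mean(vals[grp == "minimal"]), tolerance = 1e-12)
})
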