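# Statistics for measurement-model validation: descriptive group summaries,
# correlation with Fisher confidence intervals, Levene / Welch ANOVA /
# Games-Howell for heteroscedastic group comparisons, effect sizes,
# paired-t + Bland-Altman + ICC + SEM agreement analysis, and power /
# sample-size calculators built on the noncentral F and t distributions.
#
# Every closed-form routine accepts either raw data or printed summary
# statistics (mean/sd/n) and returns identical results when the summaries
# are computed from the raw data. Confidence level is 95% by default.

.ciLevel <- function(conf) {
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  1 - (1 - conf) / 2
}

#' Descriptive summary of one group
#'
#' Mean with a t-based confidence interval
#' (\eqn{\bar x \pm t_{0.975, n-1} \, s/\sqrt n}).
#'
#' @param values raw measurements (mm^2); alternatively supply \code{mean},
#'   \code{sd} and \code{n}.
#' @param label group label.
#' @param mean,sd,n summary statistics (used when \code{values} is NULL).
#' @param conf confidence level.
#' @return list with label, n, mean, sd, min, max, ciLow, ciHigh.
#' @examples
#' groupSummary(mean = 33.28, sd = 27.25, n = 71)$ciHigh  # 39.73
#' @export
groupSummary <- function(values = NULL, label = NA_character_, mean = NULL,
                         sd = NULL, n = NULL, conf = 0.95) {
  if (!is.null(values)) {
    n <- length(values)
    if (n < 2L) stop("need at least 2 values")
    m <- base::mean(values); s <- stats::sd(values)
    mn <- min(values); mx <- max(values)
  } else {
    if (is.null(mean) || is.null(sd) || is.null(n))
      stop("supply either values or mean/sd/n")
    if (n < 2L) stop("need n >= 2")
    m <- mean; s <- sd; mn <- NA_real_; mx <- NA_real_
  }
  half <- qt(.ciLevel(conf), n - 1) * s / sqrt(n)
  list(label = label, n = n, mean = m, sd = s, min = mn, max = mx,
       ciLow = m - half, ciHigh = m + half)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' \eqn{z = \mathrm{atanh}(r)}, \eqn{z \pm z_{0.975}/\sqrt{n-3}},
#' back-transformed with tanh. With \eqn{|r| = 1} the interval degenerates to
#' the point \eqn{r}.
#'
#' @param x,y raw paired data; alternatively supply \code{r} and \code{n}.
#' @param r,n correlation and sample size.
#' @param conf confidence level.
#' @return list with r, ciLow, ciHigh, n, p (two-sided, t-based).
#' @examples
#' round(unlist(pearsonFisherCI(r = 0.96, n = 203)[c("ciLow", "ciHigh")]), 2)
#' @export
pearsonFisherCI <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                            conf = 0.95) {
  if (!is.null(x)) {
    if (length(x) != length(y)) stop("x and y lengths differ")
    n <- length(x)
    r <- stats::cor(x, y)
  }
  if (is.null(r) || is.null(n)) stop("supply x/y or r/n")
  if (n < 4L) stop("need n >= 4 for a Fisher interval")
  if (abs(r) >= 1) {
    r <- sign(r)
    return(list(r = r, ciLow = r, ciHigh = r, n = n, p = 0))
  }
  zc <- qnorm(.ciLevel(conf))
  z <- atanh(r)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ciLow = tanh(z - zc / sqrt(n - 3)),
       ciHigh = tanh(z + zc / sqrt(n - 3)), n = n,
       p = 2 * pt(-abs(tstat), n - 2))
}

#' Coefficient of determination from a correlation
#'
#' For simple linear regression, \eqn{R^2 = r^2}.
#'
#' @param r Pearson correlation.
#' @return R-squared.
#' @examples
#' round(regressionR2(0.76), 2)  # 0.58
#' @export
regressionR2 <- function(r) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  r^2
}

#' Simple linear regression summary
#'
#' Least-squares fit of \code{y ~ x} via \code{stats::lm}, returning the
#' pieces used downstream.
#'
#' @param x predictor, \code{y} response.
#' @param y response.
#' @return list with slope, intercept, r, r2, p (slope t-test), n.
#' @export
linearFit <- function(x, y) {
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::var(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(sign(stats::coef(fit)[2]) * sqrt(s$r.squared)),
       r2 = s$r.squared, p = unname(s$coefficients[2, 4]), n = length(x))
}

.asGroupList <- function(values, groups = NULL) {
  g <- if (is.list(values)) values else split(values, groups)
  g <- lapply(g, as.numeric)
  if (length(g) < 2L) stop("need at least 2 groups")
  if (any(lengths(g) < 2L)) stop("every group needs n >= 2")
  g
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group centers (mean by
#' default, median for the Brown-Forsythe variant).
#'
#' @param values numeric vector (or list of group vectors).
#' @param groups group labels when \code{values} is a vector.
#' @param center "mean" or "median".
#' @return list with W (the F statistic), df1, df2, p.
#' @export
leveneVarianceTest <- function(values, groups = NULL, center = c("mean",
                                                                 "median")) {
  center <- match.arg(center)
  g <- .asGroupList(values, groups)
  cf <- if (center == "mean") base::mean else stats::median
  dev <- lapply(g, function(v) abs(v - cf(v)))
  y <- unlist(dev)
  f <- factor(rep(seq_along(dev), lengths(dev)))
  k <- length(g); N <- length(y)
  gm <- mean(y)
  gmeans <- vapply(dev, mean, numeric(1))
  ssb <- sum(lengths(dev) * (gmeans - gm)^2)
  ssw <- sum(unlist(lapply(dev, function(v) (v - mean(v))^2)))
  W <- (ssb / (k - 1)) / (ssw / (N - k))
  list(W = W, df1 = k - 1, df2 = N - k,
       p = pf(W, k - 1, N - k, lower.tail = FALSE))
}

.groupStats <- function(g) {
  list(n = lengths(g), m = vapply(g, mean, numeric(1)),
       v = vapply(g, stats::var, numeric(1)))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Variance-weighted F statistic with Welch-Satterthwaite denominator
#' degrees of freedom; robust to unequal group variances.
#'
#' @param values numeric vector (or list of group vectors); either raw data
#'   or use \code{means}/\code{sds}/\code{ns} for summary input.
#' @param groups labels when \code{values} is a vector.
#' @param means,sds,ns summary statistics (used when \code{values} is NULL).
#' @return list with F, df1, df2, p.
#' @export
welchAnova <- function(values = NULL, groups = NULL, means = NULL, sds = NULL,
                       ns = NULL) {
  if (!is.null(values)) {
    s <- .groupStats(.asGroupList(values, groups))
  } else {
    if (is.null(means) || is.null(sds) || is.null(ns))
      stop("supply values or means/sds/ns")
    s <- list(n = ns, m = means, v = sds^2)
  }
  if (any(s$v <= 0)) stop("zero within-group variance")
  k <- length(s$n)
  w <- s$n / s$v
  W <- sum(w)
  mhat <- sum(w * s$m) / W
  A <- sum(w * (s$m - mhat)^2) / (k - 1)
  lam <- sum((1 - w / W)^2 / (s$n - 1))
  Fst <- A / (1 + 2 * (k - 2) * lam / (k^2 - 1))
  df2 <- (k^2 - 1) / (3 * lam)
  list(F = Fst, df1 = k - 1, df2 = df2,
       p = pf(Fst, k - 1, df2, lower.tail = FALSE))
}

#' Games-Howell post hoc pairwise comparisons
#'
#' For each pair: Welch standard error
#' \eqn{\sqrt{s_a^2/n_a + s_b^2/n_b}}, Welch-Satterthwaite df, and an
#' adjusted p from the studentized range distribution with k groups
#' (\code{stats::ptukey}, evaluated by numerical integration). Each row also
#' carries the RMS-standardized effect size (\code{\link{effectSizeRMS}}) and
#' its post hoc two-sample t power at alpha 0.05.
#'
#' @inheritParams welchAnova
#' @param alpha significance level used for the post hoc power column.
#' @return data.frame: group_a, group_b, mean_diff, se, df, t, p_adj,
#'   effect_size_g, power.
#' @export
gamesHowell <- function(values = NULL, groups = NULL, means = NULL,
                        sds = NULL, ns = NULL, alpha = 0.05) {
  if (!is.null(values)) {
    g <- .asGroupList(values, groups)
    s <- .groupStats(g)
    labs <- names(g)
    if (is.null(labs)) labs <- as.character(seq_along(g))
  } else {
    if (is.null(means) || is.null(sds) || is.null(ns))
      stop("supply values or means/sds/ns")
    s <- list(n = ns, m = means, v = sds^2)
    labs <- names(means)
    if (is.null(labs)) labs <- as.character(seq_along(means))
  }
  if (any(s$v <= 0)) stop("zero within-group variance")
  k <- length(s$n)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(s$v[a] / s$n[a] + s$v[b] / s$n[b])
    df <- se^4 / ((s$v[a] / s$n[a])^2 / (s$n[a] - 1) +
                  (s$v[b] / s$n[b])^2 / (s$n[b] - 1))
    tstat <- (s$m[a] - s$m[b]) / se
    q <- abs(tstat) * sqrt(2)
    padj <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    if (is.na(padj))
      stop("studentized range evaluation failed for pair ", labs[a], "-",
           labs[b])
    es <- effectSizeRMS(s$m[a], sqrt(s$v[a]), s$m[b], sqrt(s$v[b]))
    data.frame(group_a = labs[a], group_b = labs[b],
               mean_diff = s$m[a] - s$m[b], se = se, df = df, t = tstat,
               p_adj = padj, effect_size_g = es,
               power = .twoSampleTPower(es, s$n[a], s$n[b], alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RMS-standardized effect size
#'
#' \eqn{|m_a - m_b| / \sqrt{(s_a^2 + s_b^2)/2}}: the mean difference
#' standardized by the root-mean-square of the two SDs, without weighting by
#' group size or small-sample correction. This is the variant that reproduces
#' published pairwise effect sizes computed from group summary tables; the
#' conventional n-weighted, bias-corrected form is \code{\link{hedgesG}}.
#'
#' @param meanA,sdA,meanB,sdB group summaries.
#' @return non-negative effect size.
#' @examples
#' round(effectSizeRMS(33.28, 27.25, 160.68, 64.21), 2)  # 2.58
#' @export
effectSizeRMS <- function(meanA, sdA, meanB, sdB) {
  if (sdA < 0 || sdB < 0) stop("sds must be >= 0")
  denom <- sqrt((sdA^2 + sdB^2) / 2)
  if (denom == 0) stop("both sds are zero; effect size undefined")
  abs(meanA - meanB) / denom
}

#' Hedges' g (n-weighted, bias corrected)
#'
#' Pooled-variance standardized mean difference times the small-sample
#' correction \eqn{1 - 3/(4(n_a + n_b) - 9)}.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (n >= 2 each).
#' @return non-negative effect size.
#' @export
hedgesG <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (nA < 2 || nB < 2) stop("need n >= 2 in both groups")
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
  if (sp2 == 0) stop("zero pooled variance; effect size undefined")
  d <- abs(meanA - meanB) / sqrt(sp2)
  d * (1 - 3 / (4 * (nA + nB) - 9))
}

#' Paired t-test from differences or their summaries
#'
#' \eqn{t = \bar d / (s_d/\sqrt n)} with \eqn{df = n - 1}, two-sided p,
#' t-based CI for the mean difference, and the within-pair effect size
#' \eqn{\bar d / s_d}.
#'
#' @param diffs raw paired differences; alternatively supply
#'   \code{meanDiff}, \code{sdDiff}, \code{n}.
#' @param meanDiff,sdDiff,n summary statistics.
#' @param conf confidence level.
#' @return list with t, df, p, ciLow, ciHigh, effectSize, meanDiff, sdDiff, n.
#' @examples
#' r <- pairedTTest(meanDiff = 5.59, sdDiff = 16.38, n = 32)
#' round(c(r$ciLow, r$ciHigh, r$effectSize, r$p), 2)  # -0.32 11.50 0.34 0.06
#' @export
pairedTTest <- function(diffs = NULL, meanDiff = NULL, sdDiff = NULL,
                        n = NULL, conf = 0.95) {
  if (!is.null(diffs)) {
    n <- length(diffs)
    if (n < 2L) stop("need n >= 2")
    meanDiff <- mean(diffs); sdDiff <- stats::sd(diffs)
  }
  if (is.null(meanDiff) || is.null(sdDiff) || is.null(n))
    stop("supply diffs or meanDiff/sdDiff/n")
  if (n < 2L) stop("need n >= 2")
  if (sdDiff == 0) {
    # exact data: any nonzero mean is a sure systematic difference
    p <- if (meanDiff == 0) 1 else 0
    return(list(t = if (meanDiff == 0) 0 else Inf * sign(meanDiff),
                df = n - 1, p = p, ciLow = meanDiff, ciHigh = meanDiff,
                effectSize = if (meanDiff == 0) 0 else Inf,
                meanDiff = meanDiff, sdDiff = 0, n = n))
  }
  se <- sdDiff / sqrt(n)
  tstat <- meanDiff / se
  half <- qt(.ciLevel(conf), n - 1) * se
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1),
       ciLow = meanDiff - half, ciHigh = meanDiff + half,
       effectSize = meanDiff / sdDiff, meanDiff = meanDiff, sdDiff = sdDiff,
       n = n)
}

#' Bland-Altman limits of agreement
#'
#' LoA = mean difference +/- 1.96 SD of the differences (1.96 literally, not
#' a t quantile), with a t-based CI for the mean difference. The two methods
#' are declared "in agreement" when that CI includes zero.
#'
#' @param a,b paired measurements by the two methods; alternatively supply
#'   \code{meanDiff}, \code{sdDiff}, \code{n} (differences a - b).
#' @inheritParams pairedTTest
#' @return list with n, meanDiff, sdDiff, loaLow, loaHigh, ciLow, ciHigh,
#'   agreement, and the paired test (t, df, p, effectSize).
#' @examples
#' r <- blandAltman(meanDiff = 5.59, sdDiff = 16.38, n = 32)
#' round(c(r$loaLow, r$loaHigh), 2)  # -26.51 37.69
#' @export
blandAltman <- function(a = NULL, b = NULL, meanDiff = NULL, sdDiff = NULL,
                        n = NULL, conf = 0.95) {
  if (!is.null(a)) {
    if (length(a) != length(b)) stop("a and b lengths differ")
    d <- a - b
    tt <- pairedTTest(diffs = d, conf = conf)
  } else {
    tt <- pairedTTest(meanDiff = meanDiff, sdDiff = sdDiff, n = n,
                      conf = conf)
  }
  list(n = tt$n, meanDiff = tt$meanDiff, sdDiff = tt$sdDiff,
       loaLow = tt$meanDiff - 1.96 * tt$sdDiff,
       loaHigh = tt$meanDiff + 1.96 * tt$sdDiff,
       ciLow = tt$ciLow, ciHigh = tt$ciHigh,
       agreement = tt$ciLow <= 0 && tt$ciHigh >= 0,
       t = tt$t, df = tt$df, p = tt$p, effectSize = tt$effectSize)
}

#' Single-measure absolute-agreement intraclass correlation
#'
#' Two-way model mean squares:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with the F-based 95% confidence interval of McGraw & Wong. A consistency
#' variant is available via \code{type = "consistency"}.
#'
#' @param ratings n x k matrix: n subjects rated by k raters/methods, no
#'   missing cells.
#' @param type "agreement" (absolute agreement, default) or "consistency".
#' @param conf confidence level.
#' @return list with icc, ciLow, ciHigh, msr, msc, mse, n, k, type.
#' @export
iccSingleAbsolute <- function(ratings, type = c("agreement", "consistency"),
                              conf = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  grand <- mean(ratings)
  if (stats::var(as.vector(ratings)) == 0)
    stop("constant ratings table: ICC undefined")
  ssr <- k * sum((rowMeans(ratings) - grand)^2)
  ssc <- n * sum((colMeans(ratings) - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (msr - fl * mse) /
              (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (fu * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * fu * msr))
  }
  list(icc = icc, ciLow = ci[1], ciHigh = ci[2], msr = msr, msc = msc,
       mse = mse, n = n, k = k, type = type)
}

#' Standard error of measurement from reliability
#'
#' \eqn{SEM = sd \sqrt{1 - ICC}}: the within-subject measurement imprecision
#' implied by a reliability coefficient.
#'
#' @param sd measurement SD (same units as the measurements).
#' @param icc reliability in [0, 1].
#' @return SEM in measurement units.
#' @examples
#' semFromICC(78.90, 0.99)  # 7.89
#' @export
semFromICC <- function(sd, icc) {
  if (icc < 0 || icc > 1) stop("icc must lie in [0, 1]")
  if (sd < 0) stop("sd must be >= 0")
  sd * sqrt(1 - icc)
}

#' Full agreement analysis between two measurement methods
#'
#' Combines the paired t-test, Bland-Altman limits of agreement, the
#' single-measure absolute-agreement ICC and the SEM (pooled SD of both
#' methods times \eqn{\sqrt{1 - ICC}}).
#'
#' @param a,b paired measurements (e.g. model vs examiner AOFA, mm^2).
#' @param conf confidence level.
#' @return list with n, meanA/meanB/sdA/sdB, the \code{\link{blandAltman}}
#'   fields, icc, iccCiLow, iccCiHigh, sem.
#' @export
agreementAnalysis <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("a and b lengths differ")
  ba <- blandAltman(a = a, b = b, conf = conf)
  icc <- iccSingleAbsolute(cbind(a, b), conf = conf)
  pooledSD <- stats::sd(c(a, b))
  c(list(meanA = mean(a), meanB = mean(b), sdA = stats::sd(a),
         sdB = stats::sd(b)),
    ba,
    list(icc = icc$icc, iccCiLow = icc$ciLow, iccCiHigh = icc$ciHigh,
         sem = semFromICC(pooledSD, max(0, min(1, icc$icc)))))
}

#' Power of a one-way fixed-effects ANOVA
#'
#' \eqn{P(F' > F_{crit}(\alpha; k-1, n-k))} for the noncentral F with
#' noncentrality \eqn{\lambda = n f^2}.
#'
#' @param f Cohen's f effect size.
#' @param k number of groups.
#' @param n total sample size (equal groups assumed).
#' @param alpha significance level.
#' @return power in [0, 1].
#' @export
anovaPower <- function(f, k, n, alpha = 0.05) {
  if (f <= 0 || k < 2 || n <= k) stop("need f > 0, k >= 2, n > k")
  crit <- qf(1 - alpha, k - 1, n - k)
  pf(crit, k - 1, n - k, ncp = n * f^2, lower.tail = FALSE)
}

#' Required total n for a one-way ANOVA
#'
#' Smallest total n (a multiple of k, equal group sizes) whose noncentral-F
#' power reaches the target.
#'
#' @inheritParams anovaPower
#' @param targetPower required power.
#' @param nMax search bound.
#' @return total sample size.
#' @examples
#' anovaRequiredN(f = 0.25, k = 4)  # 180
#' @export
anovaRequiredN <- function(f, k, alpha = 0.05, targetPower = 0.80,
                           nMax = 100000L) {
  if (f <= 0 || k < 2) stop("need f > 0 and k >= 2")
  k <- as.integer(k)
  for (n in seq(2L * k, as.integer(nMax), by = k)) {
    if (anovaPower(f, k, n, alpha) >= targetPower) return(n)
  }
  stop("target power not reachable below n = ", nMax)
}

#' Power of a two-sided paired t-test
#'
#' Noncentral t with \eqn{ncp = d\sqrt n}, \eqn{df = n - 1}.
#'
#' @param d within-pair effect size (mean difference / SD of differences).
#' @param n number of pairs.
#' @param alpha significance level (two-sided).
#' @return power in [0, 1].
#' @examples
#' round(pairedTPower(0.34, 32), 1)  # 0.5
#' @export
pairedTPower <- function(d, n, alpha = 0.05) {
  if (d <= 0 || n < 2) stop("need d > 0 and n >= 2")
  crit <- qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  pt(crit, n - 1, ncp = ncp, lower.tail = FALSE) + pt(-crit, n - 1, ncp = ncp)
}

#' Required number of pairs for a paired t-test
#'
#' @inheritParams pairedTPower
#' @param targetPower required power.
#' @param nMax search bound.
#' @return smallest n reaching the target power.
#' @examples
#' pairedTRequiredN(0.34)  # 70
#' @export
pairedTRequiredN <- function(d, alpha = 0.05, targetPower = 0.80,
                             nMax = 100000L) {
  if (d <= 0) stop("need d > 0")
  for (n in 2:nMax) {
    if (pairedTPower(d, n, alpha) >= targetPower) return(n)
  }
  stop("target power not reachable below n = ", nMax)
}

# post hoc power of a two-sided two-sample t-test at effect size d
.twoSampleTPower <- function(d, n1, n2, alpha = 0.05) {
  if (d <= 0) return(alpha)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- qt(1 - alpha / 2, df)
  pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
}

#' Descriptive table of AOFA by rotation group
#'
#' Convenience wrapper producing one \code{\link{groupSummary}} row per
#' rotation group, ordered by severity.
#'
#' @param aofaAbs AOFA magnitudes (mm^2).
#' @param groups rotation group labels (as from
#'   \code{\link{classifyRotation}}).
#' @param conf confidence level.
#' @return data.frame: group, n, mean, sd, ci_low, ci_high, min, max.
#' @export
rotationGroupTable <- function(aofaAbs, groups, conf = 0.95) {
  ord <- intersect(rotationGroups()$group, unique(groups))
  rows <- lapply(ord, function(g) {
    s <- groupSummary(aofaAbs[groups == g], label = g, conf = conf)
    data.frame(group = g, n = s$n, mean = s$mean, sd = s$sd,
               ci_low = s$ciLow, ci_high = s$ciHigh, min = s$min, max = s$max)
  })
  do.call(rbind, rows)
}
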