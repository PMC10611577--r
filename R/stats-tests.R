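# Inferential layer: thin, explicit implementations of the tests the
# pipeline reports, with uniform degenerate-input handling. Results are
# "htest"-compatible lists so they print like base R tests.

nfTest <- function(statistic, df, pTwo, pOne, estimate, method, alternative,
                   degenerate = FALSE, extra = list()) {
  p <- switch(alternative,
              two.sided = pTwo,
              greater = pOne,
              less = pOne)
  out <- c(list(statistic = c(t = statistic), parameter = c(df = df),
                p.value = p, p.two.tailed = pTwo, p.one.tailed = pOne,
                estimate = estimate, method = method,
                alternative = alternative, degenerate = degenerate,
                data.name = ""),
           extra)
  class(out) <- "htest"
  out
}

#' Pearson correlation with t conversion
#'
#' Exact r, the t statistic t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2
#' degrees of freedom, and one- and two-tailed Student-t p-values. A
#' perfectly linear pair is reported with an infinite-t degenerate guard.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return an \code{htest}-style list with fields \code{estimate} (r),
#'   \code{statistic}, \code{parameter}, \code{p.value},
#'   \code{p.two.tailed}, \code{p.one.tailed}, \code{n}, \code{degenerate}.
#' @examples
#' pearsonTest(1:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9))
#' @export
pearsonTest <- function(x, y, alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  stopIf(length(x) != length(y), "x and y lengths differ")
  n <- length(x)
  stopIf(n < 3L, "need n >= 3")
  stopIf(any(!is.finite(x)) || any(!is.finite(y)), "inputs must be finite")
  stopIf(stats::sd(x) == 0 || stats::sd(y) == 0,
         "zero variance: correlation undefined")
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1 - 1e-12) {
    tval <- sign(r) * Inf
    pTwo <- 0
    pOne <- if ((alternative == "greater") == (r > 0)) 0 else 1
    return(nfTest(tval, df, pTwo, pOne, c(r = r),
                  "Pearson correlation (degenerate: |r| = 1)", alternative,
                  degenerate = TRUE, extra = list(n = n)))
  }
  tval <- r * sqrt(df) / sqrt(1 - r^2)
  pTwo <- 2 * stats::pt(-abs(tval), df)
  pOne <- if (alternative == "less") stats::pt(tval, df) else
    stats::pt(tval, df, lower.tail = FALSE)
  if (alternative == "two.sided")
    pOne <- stats::pt(tval, df, lower.tail = FALSE)
  nfTest(tval, df, pTwo, pOne, c(r = r), "Pearson correlation",
         alternative, extra = list(n = n))
}

#' Paired t-test
#'
#' Standard paired t on the differences, df = n - 1, with explicit guards:
#' identical vectors give t = 0 with two-tailed p = 1; a constant non-zero
#' difference is reported as an infinite-t degenerate case.
#'
#' @param pre,post equal-length numeric vectors (n >= 2).
#' @param alternative sidedness; "greater" tests post > pre.
#' @return an \code{htest}-style list (see \code{\link{pearsonTest}}).
#' @export
pairedT <- function(pre, post, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopIf(length(pre) != length(post), "pre and post lengths differ")
  n <- length(pre)
  stopIf(n < 2L, "need n >= 2")
  d <- post - pre
  oneSampleT(d, mu = 0, alternative = alternative,
             method = "Paired t-test")
}

#' One-sample t-test
#'
#' Standard one-sample t against a null value, with degenerate-variance
#' guards (constant data equal to the null give t = 0, p = 1; constant data
#' off the null give an infinite-t report).
#'
#' @param x numeric vector (n >= 2).
#' @param mu null value.
#' @param alternative sidedness.
#' @param method report label.
#' @return an \code{htest}-style list (see \code{\link{pearsonTest}}).
#' @export
oneSampleT <- function(x, mu = 0, alternative = c("two.sided", "greater",
                                                  "less"),
                       method = "One-sample t-test") {
  alternative <- match.arg(alternative)
  n <- length(x)
  stopIf(n < 2L, "need n >= 2")
  df <- n - 1L
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    if (m == mu)
      return(nfTest(0, df, 1, 0.5, c(mean = m),
                    paste0(method, " (degenerate: zero variance)"),
                    alternative, degenerate = TRUE, extra = list(n = n)))
    tval <- sign(m - mu) * Inf
    pOne <- if ((alternative == "less") == (m < mu)) 0 else 1
    if (alternative == "two.sided") pOne <- 0
    return(nfTest(tval, df, 0, pOne, c(mean = m),
                  paste0(method, " (degenerate: zero variance)"),
                  alternative, degenerate = TRUE, extra = list(n = n)))
  }
  tval <- (m - mu) / (s / sqrt(n))
  pTwo <- 2 * stats::pt(-abs(tval), df)
  pOne <- if (alternative == "less") stats::pt(tval, df) else
    stats::pt(tval, df, lower.tail = FALSE)
  nfTest(tval, df, pTwo, pOne, c(mean = m), method, alternative,
         extra = list(n = n))
}

#' Intraclass correlation, absolute agreement
#'
#' Two-way mixed-effects, single-rater, absolute-agreement ICC — the
#' conventional test-retest reliability coefficient — from the two-way ANOVA
#' mean squares, with the F-test of the null ICC = 0.
#'
#' @param session1,session2 paired measurements (n >= 3 subjects).
#' @return list: \code{icc}, \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{degenerate}.
#' @export
iccAbsoluteAgreement <- function(session1, session2) {
  n <- length(session1)
  stopIf(length(session2) != n, "sessions differ in length")
  stopIf(n < 3L, "need at least 3 subjects")
  M <- cbind(session1, session2)
  k <- 2L
  grand <- mean(M)
  rowM <- rowMeans(M); colM <- colMeans(M)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sse <- sum((M - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  msr <- ssr / (n - 1L)
  msc <- ssc / (k - 1L)
  mse <- sse / ((n - 1L) * (k - 1L))
  if (msr == 0 && mse == 0)
    return(list(icc = NA_real_, F = NA_real_, df1 = n - 1L,
                df2 = (n - 1L) * (k - 1L), p = NA_real_, degenerate = TRUE))
  icc <- (msr - mse) / (msr + (k - 1L) * mse + (k / n) * (msc - mse))
  Fv <- if (mse > 0) msr / mse else Inf
  p <- stats::pf(Fv, n - 1L, (n - 1L) * (k - 1L), lower.tail = FALSE)
  list(icc = icc, F = Fv, df1 = n - 1L, df2 = (n - 1L) * (k - 1L), p = p,
       degenerate = mse == 0)
}

#' Standardized regression weights from a correlation matrix
#'
#' Closed-form standardized coefficients of the two-predictor regression
#' Y ~ X + M given the three pairwise correlations, with their t statistics:
#' beta_b = (r_MY - r_XY r_XM) / (1 - r_XM^2),
#' beta_c' = (r_XY - r_MY r_XM) / (1 - r_XM^2),
#' SE = sqrt((1 - R^2) / ((1 - r_XM^2) (n - 3))). Also returns beta_a = r_XM
#' and the reconstruction identity r_XY = beta_a * beta_b + beta_c'.
#'
#' @param rXY,rXM,rMY pairwise correlations (|r_XM| < 1; the implied
#'   correlation matrix must be positive semidefinite).
#' @param n sample size (>= 4).
#' @return list: \code{betaA}, \code{betaB}, \code{betaCPrime}, \code{tB},
#'   \code{tCPrime}, \code{se}, \code{r2}.
#' @examples
#' standardizedBetasFromCorr(0.69, -0.67, -0.88, 9)
#' @export
standardizedBetasFromCorr <- function(rXY, rXM, rMY, n) {
  stopIf(n < 4L, "need n >= 4")
  stopIf(abs(rXM) >= 1, "predictors collinear: |r_XM| = 1")
  det3 <- 1 + 2 * rXY * rXM * rMY - rXY^2 - rXM^2 - rMY^2
  stopIf(det3 < -1e-10, "correlation matrix not positive semidefinite")
  denom <- 1 - rXM^2
  betaB <- (rMY - rXY * rXM) / denom
  betaC <- (rXY - rMY * rXM) / denom
  r2 <- (rXY^2 + rMY^2 - 2 * rXY * rMY * rXM) / denom
  se <- sqrt(max(1 - r2, 0) / (denom * (n - 3L)))
  list(betaA = rXM, betaB = betaB, betaCPrime = betaC,
       tB = betaB / se, tCPrime = betaC / se, se = se, r2 = r2)
}

#' Sobel test from path coefficients
#'
#' Classical (uncorrected) Sobel statistic of the indirect effect a*b:
#' z = a b / sqrt(b^2 SE_a^2 + a^2 SE_b^2), with a two-tailed standard
#' normal p-value. The sign of z equals the sign of a*b.
#'
#' @param a,seA unstandardized X -> M path and its standard error.
#' @param b,seB unstandardized M -> Y (given X) path and its standard error.
#' @return list: \code{z}, \code{p}.
#' @examples
#' sobelTest(-0.12, 0.12 / 2.39, -141.75, 141.75 / 3.07)
#' @export
sobelTest <- function(a, seA, b, seB) {
  stopIf(seA <= 0 || seB <= 0, "standard errors must be positive")
  z <- a * b / sqrt(b^2 * seA^2 + a^2 * seB^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
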