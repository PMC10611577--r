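#' Baron-Kenny mediation with the Sobel test
#'
#' Fits the three ordinary least squares regressions of the single-mediator
#' model: the total effect c (Y ~ X), the action path a (M ~ X), and the
#' b and direct c' paths from Y ~ X + M. Reports unstandardized coefficients
#' with standard errors, t statistics and two-tailed p-values, standardized
#' betas (from the same fits on sample-standardized variables), and the
#' classical Sobel test of the indirect effect a*b (delta-method normal z,
#' computed from the unstandardized a and b). The standardized paths satisfy
#' beta_c = beta_a * beta_b + beta_c' exactly, and all standardized fields
#' are invariant to affine rescaling of x, m and y.
#'
#' @param x predictor (e.g. neurofeedback performance).
#' @param m mediator (e.g. seed connectivity change).
#' @param y outcome (e.g. state mindfulness change).
#' @param bootstrapReps optional number of bootstrap resamples for a
#'   percentile CI of the indirect effect (0 = off, the default; the Sobel
#'   test is the primary inference).
#' @param seed seed for the optional bootstrap.
#' @return A \linkS4class{MediationResult}; when \code{bootstrapReps > 0}
#'   the list attribute \code{bootstrap} on the \code{paths} data.frame
#'   carries the indirect-effect CI.
#' @examples
#' coh <- cohortData(simulateBehaviorCohort(200, seed = 3))
#' mediate(coh$nf_performance, coh$conn_change, coh$sms_change)
#' @export
mediate <- function(x, m, y, bootstrapReps = 0, seed = 1) {
  n <- length(x)
  stopIf(length(m) != n || length(y) != n, "x, m, y lengths differ")
  stopIf(n < 4L, "need n >= 4")
  stopIf(stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0,
         "degenerate variance in x, m or y")
  stopIf(abs(stats::cor(x, m)) >= 1 - 1e-12,
         "x and m collinear: paths b and c' undefined")

  fitPath <- function(Y, X) {
    # OLS of Y on columns of X (with intercept); returns coef table
    Xd <- cbind(1, X)
    qrX <- qr(Xd)
    cf <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    df <- n - ncol(Xd)
    sigma2 <- sum(res^2) / df
    covb <- chol2inv(qr.R(qrX)) * sigma2
    se <- sqrt(diag(covb))
    list(b = cf[-1L], se = se[-1L], df = df)
  }
  std <- function(v) (v - mean(v)) / stats::sd(v)

  fc  <- fitPath(y, cbind(x))
  fa  <- fitPath(m, cbind(x))
  fbc <- fitPath(y, cbind(x, m))
  sc  <- fitPath(std(y), cbind(std(x)))
  sa  <- fitPath(std(m), cbind(std(x)))
  sbc <- fitPath(std(y), cbind(std(x), std(m)))

  row <- function(path, b, beta, se, df) {
    tv <- b / se
    data.frame(path = path, b = b, beta = beta, se = se, t = tv, df = df,
               p = 2 * stats::pt(-abs(tv), df))
  }
  paths <- rbind(
    row("c",       fc$b[1L],  sc$b[1L],  fc$se[1L],  fc$df),
    row("a",       fa$b[1L],  sa$b[1L],  fa$se[1L],  fa$df),
    row("b",       fbc$b[2L], sbc$b[2L], fbc$se[2L], fbc$df),
    row("c_prime", fbc$b[1L], sbc$b[1L], fbc$se[1L], fbc$df))
  rownames(paths) <- NULL

  sz <- sobelTest(unname(fa$b[1L]), unname(fa$se[1L]),
                  unname(fbc$b[2L]), unname(fbc$se[2L]))

  if (bootstrapReps > 0) {
    ab <- withSeed(seed, {
      replicate(bootstrapReps, {
        i <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[i]) == 0 || stats::sd(m[i]) == 0 ||
            abs(stats::cor(x[i], m[i])) >= 1 - 1e-12) return(NA_real_)
        fai <- stats::lm.fit(cbind(1, x[i]), m[i])$coefficients[2L]
        fbi <- stats::lm.fit(cbind(1, x[i], m[i]), y[i])$coefficients[3L]
        fai * fbi
      })
    })
    attr(paths, "bootstrap") <-
      list(indirect = fa$b[1L] * fbc$b[2L],
           ci = stats::quantile(ab, c(0.025, 0.975), na.rm = TRUE),
           reps = bootstrapReps)
  }
  new("MediationResult", paths = paths, sobelZ = sz$z, sobelP = sz$p,
      n = as.integer(n))
}
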