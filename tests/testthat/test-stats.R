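test_that("pearsonTest matches the exact t-r identities and cor.test", {
  set.seed(1)
  x <- stats::rnorm(12); y <- 0.5 * x + stats::rnorm(12)
  res <- pearsonTest(x, y)
  r <- unname(res$estimate)
  expect_equal(unname(res$statistic), r * sqrt(10) / sqrt(1 - r^2))
  ct <- stats::cor.test(x, y)
  expect_equal(unname(res$statistic), unname(ct$statistic))
  expect_equal(res$p.value, ct$p.value)
  expect_equal(res$p.one.tailed, res$p.two.tailed / 2)  # effect matches tail

  # a correlation of 0.69 at n = 9 carries t = 2.52 and p close to 0.039
  t69 <- 0.69 * sqrt(7) / sqrt(1 - 0.69^2)
  expect_equal(round(t69, 2), 2.52)
  expect_lt(abs(2 * stats::pt(-t69, 7) - 0.039), 0.001)

  lin <- pearsonTest(1:10, 2 * (1:10) + 3)
  expect_true(lin$degenerate)
  expect_equal(unname(lin$estimate), 1)
  expect_error(pearsonTest(rep(1, 5), stats::rnorm(5)), "zero variance")
  expect_error(pearsonTest(1:2, 1:2), "n >= 3")
})

test_that("pearson test attains nominal type-I error under the null", {
  set.seed(42)
  reps <- 10000
  n <- 9
  X <- matrix(stats::rnorm(n * reps), n)
  Y <- matrix(stats::rnorm(n * reps), n)
  r <- colSums(scale(X) * scale(Y)) / (n - 1)
  tv <- r * sqrt(n - 2) / sqrt(1 - r^2)
  rejected <- 2 * stats::pt(-abs(tv), n - 2) < 0.05
  expect_equal(mean(rejected), 0.05, tolerance = 0.01)
})

test_that("paired and one-sample t tests handle their degenerate limits", {
  same <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  const <- pairedT(c(1, 2, 3), c(2, 3, 4))
  expect_true(const$degenerate)
  expect_true(is.infinite(const$statistic))

  set.seed(2)
  a <- stats::rnorm(9); b <- a + stats::rnorm(9, 0.5)
  mine <- pairedT(a, b)
  ref <- stats::t.test(b, a, paired = TRUE)
  expect_equal(unname(mine$statistic), unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)
  oneT <- pairedT(a, b, alternative = "greater")
  refG <- stats::t.test(b, a, paired = TRUE, alternative = "greater")
  expect_equal(oneT$p.value, refG$p.value)

  # t(8) = 1.90: one-tailed p rounds to 0.047, two-tailed to 0.094
  expect_equal(stats::pt(1.90, 8, lower.tail = FALSE), 0.047,
               tolerance = 5e-4)
  expect_equal(2 * stats::pt(1.90, 8, lower.tail = FALSE), 0.094,
               tolerance = 1e-3)

  os <- oneSampleT(c(0.4, 0.5, 0.6), mu = 0.5)
  expect_equal(unname(os$statistic), 0)
  osc <- oneSampleT(rep(0.7, 5), mu = 0.5)
  expect_true(osc$degenerate)
  expect_true(is.infinite(osc$statistic))
  refO <- stats::t.test(a, mu = 0.2, alternative = "greater")
  mineO <- oneSampleT(a, mu = 0.2, alternative = "greater")
  expect_equal(unname(mineO$statistic), unname(refO$statistic))
  expect_equal(mineO$p.value, refO$p.value)
})

test_that("absolute-agreement ICC recovers known variance structures", {
  s1 <- c(3, 5, 7, 9, 11)
  expect_equal(iccAbsoluteAgreement(s1, s1)$icc, 1)

  set.seed(3)
  # independent re-draws: ICC near zero at large n
  a <- stats::rnorm(4000); b <- stats::rnorm(4000)
  expect_lt(abs(iccAbsoluteAgreement(a, b)$icc), 0.05)

  # subject variance 9, measurement variance 1 in both sessions: ICC ~ 0.9
  truth <- stats::rnorm(4000, sd = 3)
  r1 <- truth + stats::rnorm(4000)
  r2 <- truth + stats::rnorm(4000)
  expect_equal(iccAbsoluteAgreement(r1, r2)$icc, 0.9, tolerance = 0.02)

  expect_error(iccAbsoluteAgreement(1:2, 1:2), "3")
})

test_that("standardized betas from correlations reproduce the closed form", {
  sb <- standardizedBetasFromCorr(0.69, -0.67, -0.88, 9)
  expect_equal(round(sb$betaB, 2), -0.76)
  expect_equal(round(sb$betaCPrime, 2), 0.18)
  expect_equal(round(sb$tCPrime, 2), 0.73)
  expect_equal(sb$tB, sb$betaB / sb$se)

  # orthogonal predictors: betas collapse to the simple correlations
  sb0 <- standardizedBetasFromCorr(0.4, 0, 0.5, 20)
  expect_equal(sb0$betaB, 0.5)
  expect_equal(sb0$betaCPrime, 0.4)

  # reconstruction identity r_XY = beta_a*beta_b + beta_c' for random PSD
  # correlation structures
  set.seed(4)
  for (i in 1:25) {
    L <- matrix(stats::rnorm(9), 3); S <- stats::cov2cor(crossprod(L) +
                                                           diag(3) * 0.1)
    sbi <- standardizedBetasFromCorr(S[1, 3], S[1, 2], S[2, 3], 15)
    expect_equal(sbi$betaA * sbi$betaB + sbi$betaCPrime, S[1, 3],
                 tolerance = 1e-10)
  }
  expect_error(standardizedBetasFromCorr(0.5, 1, 0.5, 9), "collinear")
})

test_that("the Sobel statistic reproduces the delta-method closed form", {
  # printed-table inputs: a and b with SEs recovered from their t values
  so <- sobelTest(-0.12, 0.12 / 2.39, -141.75, 141.75 / 3.07)
  expect_equal(round(so$z, 2), 1.89)
  expect_equal(so$z, 1.886, tolerance = 1e-3)
  expect_equal(so$p, 0.0593, tolerance = 1e-3)
  expect_identical(sign(so$z), sign(-0.12 * -141.75))
  neg <- sobelTest(0.5, 0.1, -0.5, 0.1)
  expect_lt(neg$z, 0)
  expect_error(sobelTest(1, 0, 1, 1), "positive")
})

test_that("mediate satisfies its exact algebraic identities", {
  set.seed(5)
  n <- 40
  x <- stats::rnorm(n)
  m <- -0.6 * x + stats::rnorm(n, sd = 0.8)
  y <- -0.7 * m + 0.2 * x + stats::rnorm(n, sd = 0.5)
  md <- mediate(x, m, y)
  p <- mediationPaths(md)
  beta <- function(nm) p[p$path == nm, "beta"]
  expect_equal(beta("c"), beta("a") * beta("b") + beta("c_prime"),
               tolerance = 1e-10)

  # standardized fields are invariant to affine rescaling of the inputs
  md2 <- mediate(3 * x + 5, -2 * m + 1, 10 * y - 4)
  p2 <- mediationPaths(md2)
  expect_equal(abs(p2$beta), abs(p$beta), tolerance = 1e-10)
  expect_equal(abs(md2@sobelZ), abs(md@sobelZ), tolerance = 1e-10)
  expect_equal(p2$t[-1], p$t[-1] * c(-1, -1, 1), tolerance = 1e-10)

  # dual route: standardized b and c' agree with the correlation-matrix
  # closed form
  sb <- standardizedBetasFromCorr(stats::cor(x, y), stats::cor(x, m),
                                  stats::cor(m, y), n)
  expect_equal(beta("b"), sb$betaB, tolerance = 1e-10)
  expect_equal(beta("c_prime"), sb$betaCPrime, tolerance = 1e-10)
  expect_equal(p[p$path == "b", "t"], sb$tB, tolerance = 1e-10)

  # Sobel from the fitted coefficients equals the closed form
  a <- p[p$path == "a", ]; b <- p[p$path == "b", ]
  expect_equal(md@sobelZ, sobelTest(a$b, a$se, b$b, b$se)$z)

  # noiseless full mediation: c' exactly zero, Sobel sign = sign(ab)
  m0 <- -0.5 * x + stats::rnorm(n, sd = 1e-4)
  y0 <- 2 * m0
  md0 <- mediate(x, m0, y0)
  expect_equal(mediationPaths(md0)[4, "b"], 0, tolerance = 1e-10)
  expect_identical(sign(md0@sobelZ), sign(-0.5 * 2))

  expect_error(mediate(x, 2 * x, y), "collinear")
  expect_error(mediate(x[1:3], m[1:3], y[1:3]), "n >= 4")
})

test_that("mediation bootstrap brackets the indirect effect", {
  set.seed(6)
  n <- 120
  x <- stats::rnorm(n); m <- -0.6 * x + stats::rnorm(n, 0, 0.7)
  y <- -0.7 * m + stats::rnorm(n, 0, 0.6)
  md <- mediate(x, m, y, bootstrapReps = 300, seed = 9)
  bs <- attr(mediationPaths(md), "bootstrap")
  expect_equal(unname(bs$indirect),
               mediationPaths(md)[2, "b"] * mediationPaths(md)[3, "b"])
  expect_true(bs$ci[1] < bs$indirect && bs$indirect < bs$ci[2])
  expect_gt(bs$indirect, 0)   # (-0.6)*(-0.7) > 0
})
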