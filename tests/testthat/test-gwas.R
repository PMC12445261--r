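scan_fixture <- function(n = 50L, m = 8L, seed = 40L) {
  set.seed(seed)
  dos <- replicate(m, rbinom(n, 2, runif(1, 0.2, 0.5)))
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  geno <- toy_genotypes(dos)
  X <- cbind(`(Intercept)` = rep(1, n), cov = rnorm(n))
  rownames(X) <- rownames(dos)
  y <- 0.4 * X[, 2] + 0.5 * scale(dos[, 1])[, 1] + rnorm(n)
  G <- diag(n); dimnames(G) <- list(rownames(dos), rownames(dos))
  list(y = y, X = X, geno = geno, G = G)
}

test_that("with sigma_g2 = 0 the scan reduces to OLS (brute-force oracle)", {
  # with V = sigma_e2 I, GLS equals OLS; fixing sigma_e2 at each variant's
  # OLS residual MS makes the chi2 equal the squared OLS t exactly
  fx <- scan_fixture()
  for (j in seq_len(4)) {
    d <- fx$geno$dosages[, j]
    p <- mean(d) / 2; q <- 1 - p
    xa <- d - 2 * p
    xd <- ifelse(d == 0, -2 * p^2, ifelse(d == 1, 2 * p * q, -2 * q^2))
    sm <- summary(lm(fx$y ~ 0 + fx$X + xa + xd))
    ols <- sm$coefficients
    res <- assoc_scan(fx$y, fx$X,
                      subset_genotypes(fx$geno, variants = j), fx$G,
                      sigma_g2 = 0, sigma_e2 = sm$sigma^2)
    expect_equal(res$beta_a[1], ols["xa", 1], tolerance = 1e-8)
    expect_equal(res$chi2_a[1], ols["xa", 3]^2, tolerance = 1e-8)
    expect_equal(res$beta_d[1], ols["xd", 1], tolerance = 1e-8)
    expect_equal(res$chi2_d[1], ols["xd", 3]^2, tolerance = 1e-8)
  }
})

test_that("spectral and direct V-inversion paths agree to 1e-6", {
  ch <- simulate_founder_cohort(n = 150, m = 600, h2 = 0.6, d2 = 0.1,
                                seed = 41)
  G <- grm_additive(ch$genotypes)
  sp <- mm_spec(ch$traits, "TL", list(G = G))
  fit <- reml_fit(sp)
  g2 <- subset_genotypes(ch$genotypes, variants = 1:100)
  a <- assoc_scan(sp$y, sp$X, g2, G, fit$estimates[1],
                  fit$estimates["sigma_e2"], method = "spectral")
  b <- assoc_scan(sp$y, sp$X, g2, G, fit$estimates[1],
                  fit$estimates["sigma_e2"], method = "direct")
  expect_equal(a$beta_a, b$beta_a, tolerance = 1e-6)
  expect_equal(a$chi2_a, b$chi2_a, tolerance = 1e-6)
  expect_equal(a$chi2_d, b$chi2_d, tolerance = 1e-6)
})

test_that("allele relabeling flips beta_a but leaves both chi2 unchanged", {
  fx <- scan_fixture(seed = 42L)
  res1 <- assoc_scan(fx$y, fx$X, fx$geno, fx$G, 0.3, 0.7)
  flip <- toy_genotypes(2 - fx$geno$dosages)
  res2 <- assoc_scan(fx$y, fx$X, flip, fx$G, 0.3, 0.7)
  expect_equal(res2$beta_a, -res1$beta_a, tolerance = 1e-8)
  expect_equal(res2$chi2_a, res1$chi2_a, tolerance = 1e-8)
  expect_equal(res2$chi2_d, res1$chi2_d, tolerance = 1e-8)
})

test_that("additive and dominance codings are orthogonal under HWE", {
  set.seed(43)
  for (p in c(0.2, 0.5)) {
    d <- rbinom(200000, 2, p)
    q <- 1 - p
    xa <- d - 2 * p
    xd <- ifelse(d == 0, -2 * p^2, ifelse(d == 1, 2 * p * q, -2 * q^2))
    expect_lt(abs(mean(xa * xd)), 4 * sd(xa * xd) / sqrt(length(d)))
  }
})

test_that("absent genotype class: dominance dropped, additive still tested", {
  set.seed(44)
  n <- 60L
  dos <- cbind(rbinom(n, 1, 0.4),            # classes 0/1 only
               rbinom(n, 2, 0.4))
  rownames(dos) <- sprintf("S%03d", 1:n)
  geno <- toy_genotypes(dos)
  X <- matrix(1, n, 1, dimnames = list(rownames(dos), "(Intercept)"))
  G <- diag(n); dimnames(G) <- list(rownames(dos), rownames(dos))
  res <- assoc_scan(rnorm(n), X, geno, G, 0, 1)
  expect_true(is.na(res$beta_d[1]))
  expect_false(is.na(res$beta_a[1]))
  expect_false(is.na(res$p_d[2]))
})

test_that("dominance scan sees an overdominant locus the additive scan misses", {
  set.seed(45)
  n <- 500L
  d <- rbinom(n, 2, 0.5)
  y <- 0.6 * (d == 1) + rnorm(n)   # purely overdominant
  dos <- cbind(d, replicate(4, rbinom(n, 2, 0.5)))
  colnames(dos) <- NULL
  rownames(dos) <- sprintf("S%03d", 1:n)
  geno <- toy_genotypes(dos)
  X <- matrix(1, n, 1, dimnames = list(rownames(dos), "(Intercept)"))
  G <- diag(n); dimnames(G) <- list(rownames(dos), rownames(dos))
  res <- assoc_scan(y, X, geno, G, 0, 1)
  expect_lt(res$p_d[1], 1e-6)
  expect_gt(res$p_a[1], 1e-4)  # additive power ~ type-I level here
})

test_that("inflation factor: constant, scale equivariance, chi2 sampling", {
  expect_equal(inflation_factor(rep(0.4549, 10)),
               0.4549 / qchisq(0.5, 1), tolerance = 1e-4)
  expect_equal(inflation_factor(rep(0.4549, 10)), 1, tolerance = 1e-3)
  x <- c(0.1, 0.5, 1.2, 2.4, 4.1)
  expect_equal(inflation_factor(2 * x), 2 * inflation_factor(x))
  expect_error(inflation_factor(numeric(0)), "no test statistics")
  set.seed(46)
  expect_equal(inflation_factor(rchisq(100000, 1)), 1, tolerance = 0.02)
})

test_that("thresholds from Meff reproduce the worked example", {
  thr <- thresholds_from_meff(477627)
  expect_equal(thr$p_bonf, 1.05e-7, tolerance = 0.005)
  expect_equal(round(thr$mlog10_bonf, 2), 6.98)
  # the suggestive line: -log10(1/477627) = 5.679 (printed 5.67, truncated)
  expect_lt(abs(thr$mlog10_sug - 5.67), 0.015)
  thr2 <- thresholds_from_meff(20)
  expect_equal(thr2$p_bonf, 0.0025)
  expect_equal(thr2$p_sug, 0.05)
  expect_lt(thr2$p_bonf, thr2$p_sug)
  expect_error(thresholds_from_meff(0), "at least 1")
})

test_that("manhattan export tiers and coordinates are correct", {
  thr <- thresholds_from_meff(477627)
  assoc <- data.frame(chr = c("1", "1", "2"), pos = c(100L, 200L, 50L),
                      id = c("v1", "v2", "v3"),
                      freq = 0.3,
                      beta_a = 1, se_a = 1, chi2_a = 1,
                      p_a = c(1e-7, 5e-7, 0.2),
                      beta_d = 1, se_d = 1, chi2_d = 1,
                      p_d = c(0.5, NA, 1e-8))
  class(assoc) <- c("assoc_result", "data.frame")
  mh <- manhattan_export(assoc, thr)
  # -log10(1e-7) = 7.00 > 6.98 -> bonferroni; 5e-7 -> 6.30 -> suggestive
  expect_equal(mh$tier_a, c("bonferroni", "suggestive", "none"))
  expect_equal(mh$tier_d, c("none", NA, "bonferroni"))
  expect_equal(mh$cum_pos, c(100, 200, 250))  # chr2 offset by max(chr1 pos)
  f <- tempfile(fileext = ".png")
  manhattan_plot(mh, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
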