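sample_mixture <- function(n, f, sigma, cc, seed) {
  set.seed(seed)
  is_true <- runif(n) < f
  ifelse(is_true, abs(rnorm(n, 0, sigma)), rexp(n, 1 / cc))
}

test_that("the least-squares fit recovers mixture parameters", {
  z <- sample_mixture(5000, f = 0.6, sigma = 4, cc = 50, seed = 30)
  fit <- fit_z_mixture(z)
  expect_s3_class(fit, "z_mixture_fit")
  expect_true(fit$converged)
  expect_lt(abs(fit$f - 0.6), 0.07)
  expect_lt(abs(fit$sigma - 4), 0.6)
  # c is weakly identified from the truncated histogram: the [0, 50] window
  # discards ~37% of the exponential mass, so per-sample spread is wide
  expect_lt(abs(fit$c - 50) / 50, 0.35)
})

test_that("the maximum-likelihood fit recovers mixture parameters", {
  z <- sample_mixture(5000, f = 0.6, sigma = 4, cc = 50, seed = 31)
  fit <- fit_z_mixture(z, method = "mle")
  expect_true(fit$converged)
  expect_lt(abs(fit$f - 0.6), 0.07)
  expect_lt(abs(fit$sigma - 4), 0.6)
  expect_lt(abs(fit$c - 50) / 50, 0.2)
})

test_that("pure single-component samples do not grow phantom components", {
  z_exp <- sample_mixture(4000, f = 0, sigma = 1, cc = 40, seed = 32)
  expect_warning(fit_e <- fit_z_mixture(z_exp), "near zero")
  expect_equal(fit_e$f, 0)
  expect_lt(abs(fit_e$c - 40) / 40, 0.2)

  z_gauss <- sample_mixture(4000, f = 1, sigma = 5, cc = 1, seed = 33)
  fit_g <- fit_z_mixture(z_gauss)
  expect_equal(fit_g$f, 1)
  expect_lt(abs(fit_g$sigma - 5), 0.5)
})

test_that("a supplied reference width is honored exactly", {
  z <- sample_mixture(1500, f = 0.6, sigma = 4, cc = 15, seed = 34)
  fixed <- fit_z_mixture(z, sigma_fixed = 4)
  expect_equal(fixed$sigma, 4)
  expect_true(fixed$converged)
  expect_lt(abs(fixed$f - 0.6), 0.15)
  fixed_mle <- fit_z_mixture(z, sigma_fixed = 4, method = "mle")
  expect_equal(fixed_mle$sigma, 4)
  expect_lt(abs(fixed_mle$f - 0.6), 0.15)
})

test_that("the closed-form FPR matches numerical quadrature", {
  z <- sample_mixture(5000, f = 0.6, sigma = 4, cc = 50, seed = 35)
  fit <- fit_z_mixture(z)
  for (zq in c(2, 5, 10, 25)) {
    expect_equal(false_positive_rate(fit, zq),
                 quadrature_fpr(fit$f, fit$sigma, fit$c, zq),
                 tolerance = 1e-6)
  }
})

test_that("the FPR curve is bounded and approaches the incorrect fraction", {
  z <- sample_mixture(5000, f = 0.6, sigma = 4, cc = 50, seed = 36)
  fit <- fit_z_mixture(z)
  grid <- seq(0.5, 49.5, by = 0.5)
  fpr <- false_positive_rate(fit, grid)
  expect_true(all(fpr >= 0 & fpr <= 1))
  # once past the correct-pair width, the curve rises toward 1 - f
  rising <- grid > 3 * fit$sigma
  expect_true(all(diff(fpr[rising]) > -1e-12))
  expect_equal(false_positive_rate(fit, 1e4), 1 - fit$f, tolerance = 1e-6)
})

test_that("threshold selection returns the largest z meeting the target", {
  z <- sample_mixture(5000, f = 0.6, sigma = 4, cc = 50, seed = 37)
  fit <- fit_z_mixture(z)
  thr <- select_threshold(fit, target_fpr = 0.2)
  expect_lte(false_positive_rate(fit, thr), 0.2)
  # the next grid point up violates the target (threshold is maximal)
  expect_gt(false_positive_rate(fit, thr + 0.1), 0.2)
})

test_that("unattainable FPR targets produce an informative error", {
  z <- sample_mixture(5000, f = 0.3, sigma = 5, cc = 20, seed = 38)
  fit <- fit_z_mixture(z)
  expect_error(select_threshold(fit, target_fpr = 1e-12), "achievable")
})

test_that("invalid FPR queries are rejected", {
  z <- sample_mixture(2000, f = 0.6, sigma = 4, cc = 50, seed = 39)
  fit <- fit_z_mixture(z)
  expect_error(false_positive_rate(fit, -1))
  expect_error(false_positive_rate(fit, 0))
})

test_that("fit objects expose coef and predict methods", {
  z <- sample_mixture(3000, f = 0.6, sigma = 4, cc = 50, seed = 40)
  fit <- fit_z_mixture(z)
  co <- coef(fit)
  expect_true(all(c("f", "sigma", "c") %in% names(co)))
  dens <- predict(fit, newdata = c(1, 5, 20), type = "density")
  expect_true(all(dens > 0))
  fpr <- predict(fit, newdata = c(1, 5, 20), type = "fpr")
  expect_equal(fpr, false_positive_rate(fit, c(1, 5, 20)))
})

test_that("a suspiciously wide correct-pair component raises a warning", {
  # wide half-normal alone: sigma estimate far above the plausible drift scale
  set.seed(41)
  z <- abs(rnorm(3000, 0, 15))
  expect_warning(fit_z_mixture(z), "sigma|wide|large")
})

test_that("tiny samples are rejected", {
  expect_error(fit_z_mixture(abs(rnorm(10))), "at least|min")
})
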