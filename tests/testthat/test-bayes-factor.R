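test_that("standardized effect sizes transform draw-wise", {
  a <- c(0, 2, -1); s2 <- c(1, 4, 0.25)
  expect_equal(standardized_effect_size(rep(0, 3), s2, 1.7), rep(0, 3))
  expect_equal(standardized_effect_size(a, s2, 1), c(0, 1, -2))
  # doubling the covariate sd doubles beta
  expect_equal(standardized_effect_size(a, s2, 2),
               2 * standardized_effect_size(a, s2, 1))
  expect_error(standardized_effect_size(1:3, 1:2, 1), "matched")
  expect_error(standardized_effect_size(1, -1, 1), "positive")
})

test_that("Cauchy prior density at zero is 1/(pi s)", {
  expect_equal(cauchy_density_at_zero(1), 1 / pi)
  expect_equal(cauchy_density_at_zero(1 / 3), 3 / pi)
  expect_equal(cauchy_density_at_zero(1), dcauchy(0, 0, 1))
  expect_lt(cauchy_density_at_zero(1e6), 1e-6)
  expect_error(cauchy_density_at_zero(0), "positive")
  expect_error(cauchy_density_at_zero(-1), "positive")
})

test_that("density estimator recovers known densities at zero", {
  set.seed(31)
  z <- rnorm(1e5)
  d_ls <- posterior_density_at_zero(z, "logspline")
  d_ke <- posterior_density_at_zero(z, "kernel")
  expect_lt(abs(as.numeric(d_ls) - dnorm(0)), 0.01)
  expect_lt(abs(as.numeric(d_ke) - dnorm(0)), 0.01)
  expect_equal(attr(d_ls, "method"), "logspline")
  # a posterior far from the null has (nearly) no density at zero
  far <- rnorm(1e4, 5)
  expect_lt(as.numeric(posterior_density_at_zero(far)), 1e-4)
  # permutation invariance
  expect_equal(as.numeric(posterior_density_at_zero(z)),
               as.numeric(posterior_density_at_zero(rev(z))))
  expect_error(posterior_density_at_zero(rep(1, 100)), "degenerate")
})

test_that("Savage-Dickey ratio honors its identities", {
  b <- savage_dickey_bf(0.3, 0.3)
  expect_equal(b$bf10, 1)
  expect_equal(savage_dickey_bf(0.3, 0.15)$bf10, 2)
  expect_equal(b$log_bf10, 0)
  sat <- savage_dickey_bf(0.3, 0)
  expect_true(is.infinite(sat$bf10))
  expect_true(sat$saturated)
  expect_error(savage_dickey_bf(0, 0.2), "positive")
})

test_that("analytic JZS Bayes factor satisfies the default-prior desiderata", {
  set.seed(32)
  N <- 100
  x <- cbind(rnorm(N))
  y0 <- rnorm(N)
  bf_null <- jzs_linear_bf(y0, x)
  expect_lt(bf_null, 1) # evidence favors the null when y is independent of x
  # location and scale invariance to 6 digits
  expect_equal(log(jzs_linear_bf(y0 * 3.7, (x + 11) * 0.2)),
               log(bf_null), tolerance = 1e-7)
  # consistency in information: BF grows without bound as R^2 -> 1
  bfs <- vapply(c(1, 0.3, 0.1, 0.03), function(s) {
    set.seed(33)
    log(jzs_linear_bf(x[, 1] + rnorm(N, sd = s), x))
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[4], 100)
  # consistency in N under a true effect (simulated)
  set.seed(34)
  lb <- vapply(c(40, 160, 640), function(n) {
    xx <- rnorm(n); yy <- 0.4 * xx + rnorm(n)
    log(jzs_linear_bf(yy, cbind(xx)))
  }, numeric(1))
  expect_true(all(diff(lb) > 0))
})

test_that("quadrature agrees with an independent Monte-Carlo mixture", {
  set.seed(4)
  N <- 30; x <- rnorm(N); y <- 0.4 * x + rnorm(N)
  bf <- jzs_linear_bf(y, cbind(x))
  # frozen value from a 2e6-draw Monte-Carlo average over g ~ IG(1/2, 1/2)
  expect_equal(as.numeric(bf), 1.358935, tolerance = 2e-3)
  # smaller scale shrinks the prior and (here) raises the Bayes factor
  expect_gt(jzs_linear_bf(y, cbind(x), scale = 1 / 3), bf)
})

test_that("conditional and smooth density estimates agree when chains mix", {
  set.seed(41)
  N <- 120
  x <- cbind(x1 = rnorm(N), x2 = rnorm(N))
  y <- 0.2 * x[, 1] + rnorm(N)
  cfg <- sampler_config(n_chains = 2, n_iterations = 11000, n_burnin = 1000,
                        thin = 1, seed = 41)
  fit <- sample_posterior(regression_spec(1), covariates = x,
                          zp_observed = cbind(z = y), config = cfg)
  bf_ls <- bayes_factors(fit, method = "logspline")
  bf_rb <- bayes_factors(fit, method = "conditional")
  expect_equal(bf_rb$log_bf10, bf_ls$log_bf10, tolerance = 0.1)
  expect_true(all(bf_rb$method == "conditional"))
})

test_that("Savage-Dickey through the sampler matches the analytic oracle", {
  run_sd <- function(seed, b) {
    set.seed(seed)
    N <- 150
    x <- cbind(x1 = rnorm(N))
    y <- b * x[, 1] + rnorm(N)
    cfg <- sampler_config(n_chains = 2, n_iterations = 27000,
                          n_burnin = 2000, thin = 1, seed = seed)
    fit <- sample_posterior(regression_spec(1), covariates = x,
                            zp_observed = cbind(z = y), config = cfg,
                            nuisance = "jeffreys")
    es <- effect_size_draws(fit)
    post0 <- posterior_density_at_zero(es[, 1, 1])
    sd_log <- savage_dickey_bf(cauchy_density_at_zero(1), post0)$log_bf10
    c(sd = sd_log, oracle = attr(jzs_linear_bf(y, x, 1), "log_bf10"))
  }
  r1 <- run_sd(11, 0.25) # moderate evidence for an effect
  expect_equal(r1[["sd"]], r1[["oracle"]], tolerance = 0.1)
  r0 <- run_sd(12, 0)    # evidence for the null
  expect_equal(r0[["sd"]], r0[["oracle"]], tolerance = 0.1)
})
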