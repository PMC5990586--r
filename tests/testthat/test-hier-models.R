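test_that("probit transform is a bijection with the documented anchors", {
  expect_equal(probit_transform(0.5, 1), 0)
  expect_equal(probit_transform(2.5, 5), 0)
  expect_equal(inverse_probit(probit_transform(0.123, 1), 1), 0.123,
               tolerance = 1e-10)
  expect_equal(inverse_probit(probit_transform(3.7, 5), 5), 3.7,
               tolerance = 1e-10)
  z <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(probit_transform(z, 1)) > 0))
  expect_error(probit_transform(0, 1), "strictly inside")
  expect_error(probit_transform(5, 5), "strictly inside")
})

test_that("covariate centering and its degenerate cases behave", {
  d <- center_covariates(cbind(a = c(1, 2, 3), b = c(2, 2, 5)))
  expect_equal(unname(d$centered[, 1]), c(-1, 0, 1))
  expect_equal(colSums(d$centered), c(a = 0, b = 0), tolerance = 1e-10)
  # denominator-N standard deviation, so crossprod(X)/N = diag(s^2) here
  expect_equal(unname(d$sds[1]), sqrt(mean(c(-1, 0, 1)^2)))
  # idempotence on already-centered input
  d2 <- center_covariates(d$centered)
  expect_equal(d2$centered, d$centered)
  expect_error(center_covariates(cbind(c(5, 5, 5))), "degenerate")
  expect_error(center_covariates(cbind(c(1, NA, 3))), "missing")
})

test_that("effect coding dichotomizes at the median with ties going low", {
  expect_equal(unname(effect_code(cbind(c(1, 2, 3, 4)))[, 1]),
               c(-0.5, -0.5, 0.5, 0.5))
  # value exactly at the median is coded -0.5
  expect_equal(unname(effect_code(cbind(c(1, 2, 3)))[, 1]),
               c(-0.5, -0.5, 0.5))
  # codes sum to zero unless ties sit at the median
  set.seed(1)
  for (i in 1:10) {
    x <- cbind(rnorm(10))
    expect_equal(sum(effect_code(x)), 0)
  }
  expect_equal(sum(effect_code(cbind(c(1, 1, 1, 4)))), -1)
})

test_that("mixture-of-g prior densities are proper and scale correctly", {
  # g prior integrates to 1 for s = 1 and s = 1/3
  for (s in c(1, 1 / 3)) {
    val <- integrate(function(g) exp(g_logprior(g, s)), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
  des <- center_covariates(matrix(rnorm(40), 20, 2))
  # alpha = 0 maximizes the conditional normal log-density
  l0 <- regression_logprior(c(0, 0), g = 0.7, sigma2 = 1.3, des)
  for (i in 1:10)
    expect_lt(regression_logprior(rnorm(2, sd = 0.5), 0.7, 1.3, des), l0)
  # doubling g lowers the density at 0 by P/2 * log 2
  expect_equal(regression_logprior(c(0, 0), 1.4, 1.3, des) - l0,
               -2 / 2 * log(2), tolerance = 1e-10)
  # singular design
  xx <- cbind(1:6, (1:6) * 2)
  expect_error(regression_logprior(c(0, 0), 1, 1, center_covariates(xx)),
               "singular|collinear")
})

test_that("joint log-density matches an independent term-by-term oracle", {
  d <- tiny_igt_data()
  xraw <- rbind(tiny_covariates(), c(0.3, -0.6), c(-0.1, 0.2))
  dat4 <- validate_igt_data(data.frame(
    participant = rep(1:4, each = 3), trial = rep(1:3, 4),
    choice = rep(c(1L, 3L, 1L, 2L), 3)[1:12],
    win = rep(c(100, 50, 100, 100), 3)[1:12],
    loss = rep(c(0, -50, -150, 0), 3)[1:12]))
  set.seed(2)
  state <- list(zp = matrix(rnorm(16), 4, 4),
                mu = rnorm(4), sigma2 = runif(4, 0.5, 2),
                alpha = matrix(rnorm(8, sd = 0.5), 2, 4),
                g = runif(4, 0.5, 2))
  spec <- regression_spec(scale = 1)
  got <- joint_logdensity(spec, dat4, xraw, state)

  # oracle: literal recomputation with textbook formulas
  xc <- sweep(xraw, 2, colMeans(xraw))
  M <- crossprod(xc) / 4
  ig <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  want <- 0
  ub <- c(1, 5, 1, 5)
  for (j in 1:4) {
    mean_j <- state$mu[j] + xc %*% state$alpha[, j]
    want <- want + sum(dnorm(state$zp[, j], mean_j, sqrt(state$sigma2[j]),
                             log = TRUE))
    want <- want + dnorm(state$mu[j], 0, 1, log = TRUE)
    want <- want + ig(state$sigma2[j], 2, 1 / 2)
    S <- state$g[j] * state$sigma2[j] * solve(M)
    a_j <- state$alpha[, j]
    want <- want - log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(a_j) %*% solve(S) %*% a_j)
    want <- want + ig(state$g[j], 1 / 2, 1 / 2)
  }
  for (i in 1:4) {
    nat <- ub * pnorm(state$zp[i, ])
    theta <- 3^nat[4] - 1
    ev <- numeric(4); llp <- log(1 / 4)
    rows <- which(dat4$participant == i)
    for (t in seq_along(rows)) {
      k <- dat4$choice[rows[t]]
      if (t > 1) {
        lsm <- theta * ev
        llp <- llp + lsm[k] - max(lsm) - log(sum(exp(lsm - max(lsm))))
      }
      x <- dat4$win[rows[t]] + dat4$loss[rows[t]]
      u <- if (x >= 0) ifelse(x == 0, 0, x^nat[1]) else -nat[2] * abs(x)^nat[1]
      ev[k] <- ev[k] + nat[3] * (u - ev[k])
    }
    want <- want + llp
  }
  expect_equal(got, want, tolerance = 1e-10)

  # with no trials the density reduces to hierarchy plus priors
  got0 <- joint_logdensity(spec, NULL, xraw, state)
  ll_part <- got - got0
  expect_lt(ll_part, 0) # likelihood of 12 choices
})

test_that("regression spec nests the intercept-only hierarchy at alpha = 0", {
  xraw <- rbind(tiny_covariates(), c(0.3, -0.6), c(-0.1, 0.2))
  set.seed(3)
  state <- list(zp = matrix(rnorm(16), 4, 4), mu = rnorm(4),
                sigma2 = runif(4, 0.5, 2),
                alpha = matrix(0, 2, 4), g = rep(1, 4))
  state_ms <- state; state_ms$alpha <- NULL; state_ms$g <- NULL
  state_ms$delta <- matrix(0, 2, 4)
  lr <- joint_logdensity(regression_spec(1), NULL, xraw, state)
  lm_ <- joint_logdensity(median_split_spec(1), NULL, xraw, state_ms)
  # strip the prior terms specific to each spec's effect parameters: what
  # remains is the identical intercept-only hierarchy
  des <- center_covariates(xraw)
  extra_r <- sum(vapply(1:4, function(j)
    regression_logprior(c(0, 0), state$g[j], state$sigma2[j], des) +
      g_logprior(state$g[j], 1), numeric(1)))
  extra_m <- sum(dcauchy(rep(0, 8), 0, 1, log = TRUE))
  expect_equal(lr - extra_r, lm_ - extra_m, tolerance = 1e-10)
})

test_that("shifting a raw covariate changes nothing after re-centering", {
  xraw <- matrix(rnorm(20), 10, 2)
  set.seed(4)
  state <- list(zp = matrix(rnorm(40), 10, 4), mu = rnorm(4),
                sigma2 = runif(4, 0.5, 2),
                alpha = matrix(rnorm(8, sd = 0.3), 2, 4), g = rep(1, 4))
  x2 <- xraw; x2[, 1] <- x2[, 1] + 100
  expect_equal(joint_logdensity(regression_spec(1), NULL, xraw, state),
               joint_logdensity(regression_spec(1), NULL, x2, state),
               tolerance = 1e-9)
  # and the full Savage-Dickey BF is unchanged (same seed, identical design)
  set.seed(5)
  y <- cbind(z = rnorm(12))
  xa <- matrix(rnorm(24), 12, 2)
  xb <- xa; xb[, 2] <- xb[, 2] - 53.1
  cfg <- quick_config()
  f1 <- sample_posterior(regression_spec(1), covariates = xa, zp_observed = y,
                         config = cfg)
  f2 <- sample_posterior(regression_spec(1), covariates = xb, zp_observed = y,
                         config = cfg)
  b1 <- bayes_factors(f1, method = "kernel")
  b2 <- bayes_factors(f2, method = "kernel")
  expect_equal(b1$bf10, b2$bf10, tolerance = 1e-6)
})
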