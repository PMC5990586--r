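test_that("prospect utility matches its closed form and sign structure", {
  expect_equal(pvl_utility(0, 0.5, 2), 0)
  expect_equal(pvl_utility(4, 0.5, 1), 2)
  expect_equal(pvl_utility(-4, 0.5, 1.5), -3)
  expect_equal(pvl_utility(0, 0, 3), 0) # 0^0 corner resolved to 0
  # sign: u(x) >= 0 iff x >= 0; monotone nondecreasing in x
  x <- seq(-300, 300, by = 7)
  u <- pvl_utility(x, 0.6, 2.5)
  expect_true(all((u >= 0) == (x >= 0)))
  expect_true(all(diff(u) >= 0))
  expect_error(pvl_utility(1, 1.2, 1), "A")
  expect_error(pvl_utility(1, 0.5, 6), "w")
})

test_that("delta rule and sensitivity transform are exact", {
  expect_equal(pvl_update(1, 3, 0.5), 2)
  expect_equal(pvl_update(1.7, 9, 0), 1.7)  # slow-forgetting limit
  expect_equal(pvl_update(1.7, 9, 1), 9)    # quick-forgetting limit
  expect_equal(pvl_sensitivity(0), 0)
  expect_equal(pvl_sensitivity(1), 2)
  expect_equal(pvl_sensitivity(5), 242)
  expect_error(pvl_sensitivity(5.5), "c")
})

test_that("softmax probabilities normalize and hit their limits", {
  expect_equal(pvl_choice_prob(c(3, -1, 2, 0), 0), rep(0.25, 4))
  expect_equal(pvl_choice_prob(rep(1.3, 4), 7), rep(0.25, 4))
  for (i in 1:20) {
    ev <- rnorm(4, sd = 10); th <- runif(1, 0, 50)
    p <- pvl_choice_prob(ev, th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # entries may underflow to 0 at extreme theta*Ev but never go negative
    expect_true(all(p >= 0 & is.finite(p)))
    expect_gt(max(p), 0)
  }
  # no overflow at extreme theta * Ev, and the limit concentrates
  p <- pvl_choice_prob(c(1, 0, 0, 0), 1e4)
  expect_true(all(is.finite(p)))
  expect_gt(p[1], 1 - 1e-10)
})

test_that("agent simulation is deterministic and uniform when c = 0", {
  sch <- igt_payoff_schedule(200)
  p <- pvl_params(0.4, 1.2, 0.25, 0.8)
  d1 <- simulate_pvl_agent(p, sch, 150, seed = 9)
  d2 <- simulate_pvl_agent(p, sch, 150, seed = 9)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 150L)
  # c = 0 (theta = 0): long-run choice frequencies uniform
  p0 <- pvl_params(0.4, 1.2, 0.25, 0)
  big <- igt_payoff_schedule(10000)
  d <- simulate_pvl_agent(p0, big, 10000, seed = 1)
  freq <- tabulate(d$choice, 4) / 10000
  # binomial 99.9% band around 0.25 at n = 1e4
  expect_true(all(abs(freq - 0.25) < 3.3 * sqrt(0.25 * 0.75 / 10000)))
  # a = 0: expectancies stay 0, so any c gives uniform choice as well
  pa <- pvl_params(0.9, 4, 0, 3)
  da <- simulate_pvl_agent(pa, big, 10000, seed = 2)
  fa <- tabulate(da$choice, 4) / 10000
  expect_true(all(abs(fa - 0.25) < 3.3 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("simulator choice frequencies match softmax probabilities", {
  # frozen expectancies: simulate many single choices via the model equations
  ev <- c(0.8, -0.3, 0.1, 0.4); theta <- pvl_sensitivity(1.2)
  p <- pvl_choice_prob(ev, theta)
  set.seed(5)
  n <- 1e5
  draws <- sample.int(4, n, replace = TRUE, prob = p)
  obs <- tabulate(draws, 4)
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("log-likelihood matches uniform closed form and R/compiled paths agree", {
  d <- tiny_igt_data()
  p0 <- pvl_params(0.5, 1, 0.3, 0)  # theta = 0: every trial uniform
  ll <- pvl_loglik(p0, d)
  expect_equal(unname(ll), rep(3 * log(1 / 4), 2))
  set.seed(8)
  sch <- igt_payoff_schedule(50)
  sim <- simulate_pvl_agent(pvl_params(0.6, 2, 0.4, 1.5), sch, 50, seed = 3)
  for (i in 1:5) {
    par <- matrix(c(runif(1), runif(1) * 5, runif(1), runif(1) * 5), 1, 4)
    expect_equal(as.numeric(pvl_loglik(par, sim, backend = "cpp")),
                 as.numeric(pvl_loglik(par, sim, backend = "R")),
                 tolerance = 1e-12)
  }
})

test_that("choice-sequence probabilities sum to one over all sequences", {
  # brute force: enumerate all 4^2 choice sequences for T = 2 with the
  # deterministic schedule; total probability must be 1
  sch <- igt_payoff_schedule(10)
  p <- pvl_params(0.7, 2.5, 0.6, 1.8)
  total <- 0
  for (c1 in 1:4) for (c2 in 1:4) {
    drawn <- integer(4)
    drawn[c1] <- 1L
    o1 <- igt_deal(sch, c1, 1)
    d <- data.frame(participant = 1, trial = 1:2, choice = c(c1, c2),
                    win = c(o1[["win"]], NA), loss = c(o1[["loss"]], NA))
    drawn[c2] <- drawn[c2] + 1L
    o2 <- igt_deal(sch, c2, drawn[c2])
    d$win[2] <- o2[["win"]]; d$loss[2] <- o2[["loss"]]
    total <- total + exp(sum(pvl_loglik(p, validate_igt_data(d))))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("likelihood is invariant under a consistent deck relabeling", {
  sch <- igt_payoff_schedule(50)
  p <- pvl_params(0.6, 2, 0.4, 1.5)
  sim <- simulate_pvl_agent(p, sch, 50, seed = 3)
  perm <- c(3L, 1L, 4L, 2L)
  relab <- sim
  relab$choice <- perm[sim$choice]
  # wins/losses observed stay with the same cards, so the likelihood only
  # sees relabeled deck indices
  expect_equal(as.numeric(pvl_loglik(p, validate_igt_data(relab))),
               as.numeric(pvl_loglik(p, sim)), tolerance = 1e-12)
})
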