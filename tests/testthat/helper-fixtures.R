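# Shared fixtures: everything is generated in code at test time.

# A tiny deterministic trial table for two participants, three trials each,
# built by hand so likelihood and joint-density oracles can be recomputed
# term by term.
tiny_igt_data <- function() {
  validate_igt_data(data.frame(
    participant = rep(1:2, each = 3),
    trial = rep(1:3, 2),
    choice = c(1L, 3L, 1L, 2L, 2L, 4L),
    win = c(100, 50, 100, 100, 100, 50),
    loss = c(0, -50, -150, 0, 0, 0)))
}

tiny_covariates <- function() {
  cbind(x1 = c(-1.2, 0.7), x2 = c(0.4, -0.1))
}

# Small simulated dataset for sampler tests (quick to fit).
small_sim <- function(n = 20, t = 40, rho = 0, seed = 42) {
  sc <- scenario_config(n_participants = n, n_trials = t, rho = rho,
                        n_datasets = 1, base_seed = seed)
  generate_igt_dataset(sc, 1)
}

quick_config <- function(n_iterations = 1200, n_burnin = 400, seed = 11,
                         n_chains = 2)
  sampler_config(n_chains = n_chains, n_iterations = n_iterations,
                 n_burnin = n_burnin, thin = 1, seed = seed)
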