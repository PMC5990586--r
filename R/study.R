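#' Generating values for the simulation study
#'
#' Group-level values used to generate synthetic participants: per
#' probit-scale model parameter, the two regression weights (deliberation and
#' intuition covariates), the intercept and the residual spread. The true
#' effects are a weight of 1 of covariate 1 on outcome sensitivity A' and a
#' weight of -0.9 of covariate 2 on loss aversion w'; all other
#' parameter-covariate pairs are null or near-null.
#'
#' @param sd_as_variance Interpret the spread column as a variance instead of
#'   a standard deviation (sensitivity-analysis switch; default `FALSE`).
#' @return Data frame with rownames A, w, a, c and columns `alpha1`, `alpha2`,
#'   `mu`, `sigma` (the residual standard deviation actually used).
#' @export
study_generating_values <- function(sd_as_variance = FALSE) {
  tab <- data.frame(
    alpha1 = c(1, 0, -0.08, -0.02),
    alpha2 = c(0, -0.9, 0.24, -0.05),
    mu = c(0.24, 0.38, 0.30, 1.34),
    sigma = c(1.06, 0.91, 1.58, 0.46),
    row.names = c("A", "w", "a", "c"))
  if (sd_as_variance) tab$sigma <- sqrt(tab$sigma)
  tab
}

#' Simulation scenario configuration
#'
#' Bundles the study conditions: number of synthetic participants and trials,
#' number of covariates and their correlation, the generating values, and the
#' replication count. Defaults are the full-scale study conditions (150
#' participants, 200 trials, 2 covariates, 50 datasets); `reduced_scenario()`
#' gives the desk-scale variant (10 datasets of 60 participants x 100 trials)
#' used for sign-level checks.
#'
#' @param n_participants Participants per dataset.
#' @param n_trials IGT trials per participant.
#' @param rho Covariate correlation (0 or 0.7 in the study scenarios).
#' @param n_datasets Number of replicate datasets.
#' @param base_seed Base seed; dataset `i` uses `base_seed + i`.
#' @param truth Generating values, as from [study_generating_values()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_participants = 150L, n_trials = 200L,
                            rho = 0, n_datasets = 50L, base_seed = 1L,
                            truth = study_generating_values()) {
  stopifnot(abs(rho) < 1, n_participants >= 2, n_trials >= 1,
            n_datasets >= 1, n_trials %% 1 == 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), rho = rho, p = 2L,
                 n_datasets = as.integer(n_datasets),
                 base_seed = as.integer(base_seed), truth = truth),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param ... Overrides passed on to [scenario_config()].
#' @export
reduced_scenario <- function(rho = 0, ...) {
  scenario_config(n_participants = 60L, n_trials = 100L, rho = rho,
                  n_datasets = 10L, ...)
}

#' Generate covariate scores
#'
#' Draws N participant scores on P covariates from a multivariate normal
#' distribution with zero mean, unit variances and constant correlation
#' `rho`.
#'
#' @param n Number of participants.
#' @param rho Pairwise correlation, `|rho| < 1`.
#' @param p Number of covariates.
#' @param seed Optional seed.
#' @return N x P matrix with columns `x1..xP`.
#' @export
generate_covariates <- function(n, rho = 0, p = 2L, seed = NULL) {
  stopifnot(abs(rho) < 1)
  if (!is.null(seed)) set.seed(seed)
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  x <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  colnames(x) <- paste0("x", seq_len(p))
  x
}

#' Generate participant-level PVL-Delta parameters
#'
#' Probit-scale parameters are drawn from the regression structure
#' `z'_i ~ N(mu + x_i' alpha, sigma^2)` at the generating values; natural-scale
#' parameters follow by the inverse probit with the parameter bounds.
#'
#' @param covariates N x 2 covariate matrix (generating mean is 0, so raw
#'   scores are used directly; analysis always re-centers).
#' @param truth Generating values, as from [study_generating_values()].
#' @param seed Optional seed.
#' @return List with `zp` and `natural`, both N x 4 matrices (columns
#'   A, w, a, c).
#' @export
generate_participant_parameters <- function(covariates,
                                            truth = study_generating_values(),
                                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(covariates)
  n <- nrow(x)
  stopifnot(ncol(x) == 2, all(truth$sigma > 0))
  zp <- vapply(1:4, function(j) {
    rnorm(n, truth$mu[j] + x %*% c(truth$alpha1[j], truth$alpha2[j]),
          truth$sigma[j])
  }, numeric(n))
  zp <- matrix(zp, n, 4, dimnames = list(NULL, c("A", "w", "a", "c")))
  natural <- vapply(1:4, function(j) inverse_probit(zp[, j], pvl_bounds[j]),
                    numeric(n))
  natural <- matrix(natural, n, 4, dimnames = dimnames(zp))
  list(zp = zp, natural = natural)
}

#' Generate one synthetic study dataset
#'
#' Draws covariates, participant parameters, and full trial-level IGT choice
#' data for one replicate of a scenario. The per-dataset seed is
#' `base_seed + index`, recorded in the ground-truth block so individual
#' datasets can be regenerated without rerunning the study.
#'
#' @param scenario A `scenario_config`.
#' @param index Dataset index (1-based).
#' @return A list of class `igt_sim` with `data` (an `igt_data` trial table),
#'   `covariates`, and `truth` (seed, probit- and natural-scale parameters).
#' @export
generate_igt_dataset <- function(scenario, index = 1L) {
  stopifnot(inherits(scenario, "scenario_config"))
  seed <- scenario$base_seed + as.integer(index)
  set.seed(seed)
  x <- generate_covariates(scenario$n_participants, scenario$rho, scenario$p)
  pars <- generate_participant_parameters(x, scenario$truth)
  sch <- igt_payoff_schedule(max_draws = 10L * ceiling(scenario$n_trials / 10))
  recs <- lapply(seq_len(scenario$n_participants), function(i) {
    p <- pvl_params(pars$natural[i, "A"], pars$natural[i, "w"],
                    pars$natural[i, "a"], pars$natural[i, "c"])
    simulate_pvl_agent(p, sch, scenario$n_trials, participant = i)
  })
  data <- validate_igt_data(do.call(rbind, recs))
  structure(list(data = data, covariates = x,
                 truth = list(seed = seed, zp = pars$zp,
                              natural = pars$natural,
                              generating = scenario$truth,
                              rho = scenario$rho)),
            class = "igt_sim")
}

#' Fit one analysis to one dataset and compute its Bayes factors
#'
#' Runs the regression or median-split model on a synthetic (or user) dataset
#' and returns the per-cell Savage-Dickey Bayes-factor table together with
#' convergence diagnostics. The fit is flagged as non-converged when any
#' group-level split R-hat exceeds `rhat_gate`.
#'
#' @param sim An `igt_sim` (or a list with `data` and `covariates`).
#' @param analysis `"regression"` or `"median_split"`.
#' @param config A `sampler_config`.
#' @param scale Cauchy prior scale for the effect sizes.
#' @param method Density estimator for the posterior at zero (see
#'   [bayes_factors()]; `"conditional"` is the most stable at desk-scale
#'   chain lengths).
#' @param rhat_gate Convergence gate on group-level split R-hat.
#' @param keep_draws Also return the pooled effect-size draw array.
#' @return List with `bf` (8-row table), `rhat`, `converged`, `analysis`, and
#'   optionally `effect_draws`.
#' @export
run_dataset <- function(sim, analysis = c("regression", "median_split"),
                        config = sampler_config(profile = "test"),
                        scale = 1, method = "logspline", rhat_gate = 1.01,
                        keep_draws = FALSE) {
  analysis <- match.arg(analysis)
  spec <- if (analysis == "regression") regression_spec(scale)
          else median_split_spec(scale)
  fit <- sample_posterior(spec, data = sim$data, covariates = sim$covariates,
                          config = config)
  rh <- gelman_rubin(fit)
  bf <- bayes_factors(fit, method = method)
  out <- list(bf = bf, rhat = rh, converged = all(rh <= rhat_gate),
              analysis = analysis)
  if (keep_draws) out$effect_draws <- effect_size_draws(fit)
  out
}

#' Run a full simulation scenario
#'
#' Generates `n_datasets` replicate datasets and analyzes each with both the
#' regression and the median-split model, collecting one Bayes-factor pair
#' per (model parameter, covariate) cell and dataset. Non-converged fits are
#' recorded and excluded from the summaries.
#'
#' @param scenario A `scenario_config`.
#' @param config A `sampler_config` used for the regression fits.
#' @param ms_config Sampler configuration for the median-split fits; defaults
#'   to `config`. The median-split model mixes faster (its group-difference
#'   conditionals are conjugate and the coupling to the participant level is
#'   weaker), so shorter chains reach the same quality.
#' @param scale Cauchy prior scale.
#' @param method Density estimator for the posterior at zero.
#' @param keep_draws Keep pooled effect-size draws per dataset (needed for
#'   quantile-averaged posterior curves).
#' @param rhat_gate Convergence gate applied to every fit (1.01 at paper
#'   scale; desk-scale runs with short chains use a looser flag, see the
#'   methods vignette).
#' @param quiet Suppress per-dataset progress messages.
#' @return A list of class `pvl_study` with `results` (long data frame of BFs:
#'   dataset, analysis, parameter, covariate, bf10, log_bf10, converged),
#'   `scenario`, `n_excluded`, and optionally `draws`.
#' @export
run_study <- function(scenario, config = sampler_config(profile = "test"),
                      ms_config = config, scale = 1, method = "logspline",
                      keep_draws = FALSE, rhat_gate = 1.01, quiet = TRUE) {
  stopifnot(inherits(scenario, "scenario_config"))
  rows <- list(); dr <- list()
  for (i in seq_len(scenario$n_datasets)) {
    sim <- generate_igt_dataset(scenario, i)
    for (an in c("regression", "median_split")) {
      res <- run_dataset(sim, an,
                         config = if (an == "regression") config else ms_config,
                         scale = scale,
                         method = method, rhat_gate = rhat_gate,
                         keep_draws = keep_draws)
      tab <- res$bf
      tab$dataset <- i
      tab$converged <- res$converged
      tab$max_rhat <- max(res$rhat)
      rows[[length(rows) + 1L]] <- tab
      if (keep_draws) dr[[paste(an, i, sep = ".")]] <- res$effect_draws
      if (!quiet)
        message(sprintf("dataset %d %s: max R-hat %.3f%s", i, an,
                        max(res$rhat),
                        if (res$converged) "" else " [excluded]"))
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, scenario = scenario,
                 n_excluded = length(unique(
                   results$dataset[!results$converged])),
                 draws = if (keep_draws) dr else NULL),
            class = "pvl_study")
}

#' Summarize a simulation scenario
#'
#' Per (model parameter, covariate) cell: the median and mean of
#' `log(BF10_regression) - log(BF10_median-split)` across completed (converged)
#' datasets, together with the linear-scale ratio `exp(median)` and
#' `exp(mean)`. A positive difference means the regression analysis found
#' stronger evidence than the median-split analysis.
#'
#' @param study A `pvl_study` (or its `results` data frame).
#' @return Data frame with one row per cell: `parameter`, `covariate`,
#'   `median_diff`, `mean_diff`, `ratio_median`, `ratio_mean`,
#'   `n_datasets`.
#' @export
summarize_study <- function(study) {
  res <- if (inherits(study, "pvl_study")) study$results else study
  res <- res[res$converged, , drop = FALSE]
  if (nrow(res) == 0L) stop("no completed datasets to summarize", call. = FALSE)
  cells <- unique(res[, c("parameter", "covariate")])
  out <- lapply(seq_len(nrow(cells)), function(r) {
    sub <- res[res$parameter == cells$parameter[r] &
                 res$covariate == cells$covariate[r], ]
    w <- stats::reshape(sub[, c("dataset", "analysis", "log_bf10")],
                        idvar = "dataset", timevar = "analysis",
                        direction = "wide")
    d <- w$`log_bf10.regression` - w$`log_bf10.median-split`
    d <- d[is.finite(d)]
    data.frame(parameter = cells$parameter[r], covariate = cells$covariate[r],
               median_diff = median(d), mean_diff = mean(d),
               ratio_median = exp(median(d)), ratio_mean = exp(mean(d)),
               n_datasets = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quantile-average distributions across replicate datasets
#'
#' Averages the per-dataset quantile functions at a fixed grid of probability
#' levels: at each level the across-dataset mean of the per-dataset empirical
#' quantiles. The result is itself a (monotone) quantile function describing
#' the typical posterior across replicates.
#'
#' @param draws_list List of numeric draw vectors, one per dataset.
#' @param probs Probability grid.
#' @return Data frame with columns `prob` and `quantile`.
#' @export
quantile_average <- function(draws_list,
                             probs = seq(0.001, 0.999, length.out = 199)) {
  stopifnot(length(draws_list) >= 1L)
  qs <- vapply(draws_list, quantile, numeric(length(probs)),
               probs = probs, names = FALSE, type = 7)
  data.frame(prob = probs, quantile = rowMeans(matrix(qs, length(probs))))
}
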