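#' Sampler configuration
#'
#' MCMC run lengths and seeding. Defaults mirror the simulation protocol of
#' the full-scale study (2 chains, 45,000 iterations, 5,000 burn-in, thin 5,
#' leaving 8,000 retained draws per chain). `profile = "test"` gives a
#' desk-scale configuration (2 chains x 6,000 iterations, 2,000 burn-in,
#' thin 1) suitable for interactive use and continuous testing.
#'
#' @param n_chains Number of chains (>= 2 recommended for diagnostics).
#' @param n_iterations Total iterations per chain, burn-in included.
#' @param n_burnin Burn-in iterations discarded from the front of each chain;
#'   adaptation of proposal scales happens only during burn-in.
#' @param thin Thinning interval for retained draws.
#' @param seed Integer base seed; chain `k` uses `seed + k - 1`.
#' @param target_accept Target acceptance rate of the adaptive participant-
#'   level random-walk updates.
#' @param profile Optional shorthand: `"paper"` (the defaults) or `"test"`.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 2L, n_iterations = 45000L,
                           n_burnin = 5000L, thin = 5L, seed = 1L,
                           target_accept = 0.44, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper", "test"))
    if (profile == "test") {
      n_iterations <- 6000L; n_burnin <- 2000L; thin <- 1L
    }
  }
  stopifnot(n_chains >= 1, n_burnin < n_iterations, thin >= 1,
            (n_iterations - n_burnin) %% thin == 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 target_accept = target_accept),
            class = "sampler_config")
}

#' Draw initial values for the latent quantities
#'
#' Group-level means start from standard normal draws, group-level standard
#' deviations from exponential(1) draws, regression weights (and standardized
#' group differences) from normal draws with standard deviation 2, and the
#' mixture-of-g latent at 1. Probit-scale participant parameters start at the
#' implied conditional mean of the hierarchy.
#'
#' @param spec A `pvl_model_spec`.
#' @param n_outcomes Number of probit-scale model parameters (4 for the
#'   PVL-Delta instantiation).
#' @param n_covariates Number of covariates P (0 for the basic spec).
#' @param seed Optional seed.
#' @return Named list with `mu`, `sigma2` and, as the model variant requires,
#'   `alpha`, `g`, `delta`, `lambda`.
#' @export
initialize_latents <- function(spec, n_outcomes = 4L, n_covariates = 0L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- n_outcomes; P <- n_covariates
  # exponential(1) draws for the group spreads, floored away from zero so no
  # chain starts in the degenerate sigma -> 0 corner
  st <- list(mu = rnorm(J), sigma2 = pmax(rexp(J, rate = 1), 0.3)^2)
  if (spec$type == "regression") {
    st$alpha <- matrix(rnorm(P * J, 0, 2), P, J)
    st$g <- rep(1, J)
  } else if (spec$type == "median_split") {
    st$delta <- matrix(rnorm(P * J, 0, 2), P, J)
    st$lambda <- matrix(1, P, J)
  }
  st
}

#' Posterior sampling for the hierarchical model variants
#'
#' Draws from the joint posterior of a `pvl_model_spec` by conjugate Gibbs
#' updates for every group-level quantity (intercepts, residual variances,
#' regression weights and the mixture-of-g latent; Cauchy-distributed
#' standardized group differences via their inverse-gamma scale-mixture
#' representation) combined with adaptive random-walk Metropolis updates of
#' the probit-scale participant parameters against the compiled PVL-Delta
#' likelihood. Two families of non-centered moves are interleaved to break
#' the coupling between group-level and participant-level quantities that
#' slows a purely centered Gibbs scheme: translation moves that shift one
#' group-level coefficient together with every participant's parameter, and
#' scale moves that expand the residual spread and the residuals jointly.
#' All proposal scales adapt toward their target acceptance rates during
#' burn-in only, so the retained chain is a time-homogeneous Markov chain.
#'
#' Three data modes are supported: trial-level IGT data (`data`; the full
#' cognitive-model posterior), directly observed probit-scale outcomes
#' (`zp_observed`; the plain Bayesian linear model, used by the analytic
#' oracle checks), and neither (prior sampling over the hierarchy).
#'
#' @param spec A `pvl_model_spec`.
#' @param data An `igt_data` data.frame of trials, or `NULL`.
#' @param covariates Raw N x P covariate matrix (ignored by the basic spec).
#' @param config A `sampler_config`.
#' @param zp_observed Optional N x K matrix of directly observed outcomes
#'   replacing the latent probit-scale parameters.
#' @param n_participants Number of participants for prior-only sampling when
#'   neither `data` nor `zp_observed` is given.
#' @param fixed_g Optional positive scalar: hold the mixture-of-g latent fixed
#'   (conjugate sub-case used by the shrinkage oracle test).
#' @param nuisance Prior on the intercept and residual variance:
#'   `"hier"` (default; the hierarchical model's N(0,1) and
#'   inverse-gamma(2, 1/2) priors) or `"jeffreys"` (`p(mu, sigma2) ~
#'   1/sigma2`, the reference prior of the analytic linear-model oracle; only
#'   meaningful with `zp_observed`).
#' @param store_individual Keep the full participant-level draws (memory
#'   heavy); posterior means of the probit-scale parameters are always
#'   returned.
#' @return An object of class `pvl_posterior`: list with `draws` (arrays
#'   indexed draw x chain x ...), `accept`, `spec`, `config`, `design`
#'   (covariate design information), `param_names`, and `zp_mean`.
#' @export
sample_posterior <- function(spec, data = NULL, covariates = NULL,
                             config = sampler_config(), zp_observed = NULL,
                             n_participants = NULL, fixed_g = NULL,
                             nuisance = c("hier", "jeffreys"),
                             store_individual = FALSE) {
  stopifnot(inherits(spec, "pvl_model_spec"), inherits(config, "sampler_config"))
  nuisance <- match.arg(nuisance)
  jeff <- nuisance == "jeffreys"
  if (jeff && is.null(zp_observed))
    stop("`nuisance = \"jeffreys\"` requires observed outcomes", call. = FALSE)
  has_lik <- !is.null(data)
  zp_fixed <- !is.null(zp_observed)
  if (has_lik && zp_fixed)
    stop("give either trial `data` or `zp_observed`, not both", call. = FALSE)

  if (has_lik) {
    m <- igt_matrices(data)
    N <- m$n_participants
    J <- 4L
    pn <- c("A", "w", "a", "c")
    netvals <- sort(unique(as.vector(m$net)))
    netidx <- matrix(match(m$net, netvals), nrow(m$net), ncol(m$net))
    lik <- function(par) pvl_loglik_idx_cpp(par, m$choice, netidx, netvals)
    lik_col <- function(nat, j, nat_col)
      pvl_loglik_col_cpp(nat, j, nat_col, m$choice, netidx, netvals)
    ubounds <- unname(pvl_bounds)
  } else if (zp_fixed) {
    zp_observed <- as.matrix(zp_observed)
    N <- nrow(zp_observed); J <- ncol(zp_observed)
    pn <- colnames(zp_observed) %||% paste0("z", seq_len(J))
  } else {
    N <- n_participants %||% nrow(covariates) %||%
      stop("prior-only sampling needs `covariates` or `n_participants`",
           call. = FALSE)
    J <- 4L; pn <- c("A", "w", "a", "c")
  }

  des <- NULL; X <- NULL; D <- NULL; P <- 0L
  if (spec$type == "regression") {
    if (is.null(covariates)) stop("regression spec needs covariates", call. = FALSE)
    des <- center_covariates(covariates)
    if (des$n != N) stop("covariate rows must match participants", call. = FALSE)
    X <- des$centered; P <- des$p
    XtX <- crossprod(X); M <- XtX / N
    # proposal metric for coefficient translations: correlated covariates
    # make the weights anti-correlated a posteriori, so propose along
    # chol((X'X/N)^-1) rather than the axes
    Lm <- t(chol(solve(M)))
  } else if (spec$type == "median_split") {
    if (is.null(covariates)) stop("median-split spec needs covariates", call. = FALSE)
    D <- effect_code(covariates)
    if (nrow(D) != N) stop("covariate rows must match participants", call. = FALSE)
    P <- ncol(D)
    DtD <- crossprod(D)
    Lmd <- t(chol(solve(DtD / N)))
  }
  cn <- if (P > 0) colnames(X %||% D) else character(0)

  cfg <- config
  n_kept <- (cfg$n_iterations - cfg$n_burnin) %/% cfg$thin
  dims2 <- c(n_kept, cfg$n_chains)
  draws <- list(mu = array(NA_real_, c(dims2, J)),
                sigma2 = array(NA_real_, c(dims2, J)))
  if (spec$type == "regression") {
    draws$alpha <- array(NA_real_, c(dims2, P, J))
    draws$g <- array(NA_real_, c(dims2, J))
  } else if (spec$type == "median_split") {
    draws$delta <- array(NA_real_, c(dims2, P, J))
  }
  if (store_individual && !zp_fixed)
    draws$zp <- array(NA_real_, c(dims2, N, J))
  zp_mean <- matrix(0, N, J)
  # Rao-Blackwellized posterior density of each standardized effect size at
  # zero: running mean over retained draws of the exact conditional density
  # (the effect parameters are conditionally Gaussian given everything else)
  rb0 <- if (P > 0 && spec$type != "basic") matrix(0, P, J) else NULL
  accept <- numeric(cfg$n_chains)
  n_dir <- 1L + P # translation directions: intercept plus one per covariate
  # packed identity Cholesky (scaled) for the joint participant proposals
  lpack_init <- function(scale) {
    L <- matrix(0, N, 16)
    for (q in 0:3) L[, q + 4 * q + 1] <- scale
    L
  }

  rmvn_prec <- function(prec, b) {
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), b))
    mu + backsolve(ch, rnorm(length(b)))
  }

  for (chain in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + chain - 1L)
    st <- initialize_latents(spec, J, P)
    if (!is.null(fixed_g) && spec$type == "regression")
      st$g <- rep(fixed_g, J)
    if (zp_fixed) {
      zp <- zp_observed
    } else {
      # conditional mean plus dispersion-matched jitter, so the residual
      # variance conditional starts in a healthy region
      zp <- matrix(rep(st$mu, each = N), N, J)
      if (spec$type == "regression") zp <- zp + X %*% st$alpha
      zp <- zp + matrix(rnorm(N * J), N, J) %*% diag(sqrt(st$sigma2), J)
    }
    if (has_lik) {
      nat <- vapply(1:J, function(j) inverse_probit(zp[, j], pvl_bounds[j]),
                    numeric(N))
      nat <- matrix(nat, N, J)
      ll <- lik(nat)
    } else ll <- numeric(N)
    step_s2 <- rep(0.5, J)          # scale move / basic-sigma step
    step_sh <- matrix(0.3, n_dir, J) # translation moves, one per direction
    # joint participant-level proposal state: per-participant Cholesky of the
    # learned posterior covariance (Welford accumulators) and a scalar step
    Lpack <- lpack_init(0.2)
    step_i <- rep(1, N)
    acc_i <- numeric(N); acc_keep <- numeric(N); keep_try <- 0L
    acc_tr <- numeric(J); acc_sc <- numeric(J) # post-burn-in move acceptance
    # weighted-translation state: per-participant proposal scales (learned
    # posterior spreads), refreshed together with Lpack
    s_hat <- matrix(1, N, J)
    step_wt <- rep(0.3, J); b_wt <- numeric(J); acc_wt <- numeric(J)
    # batched adaptation state for the translation and scale moves: per-batch
    # acceptance counters, clamped multiplicative updates and a hard floor so
    # early-burn-in rejection streaks cannot collapse the steps for good
    b_tr <- numeric(J); b_sc <- numeric(J); b_n <- 0L
    adapt_step <- function(step, rate, target = 0.25)
      pmin(5, pmax(0.02, step * exp(pmin(0.4, pmax(-0.4, rate - target)))))
    w_cnt <- 0L
    w_mn <- matrix(0, N, J)
    w_c <- matrix(0, N, 16)
    k_out <- 0L

    group_mean <- function() {
      mm <- matrix(rep(st$mu, each = N), N, J)
      if (spec$type == "regression") mm <- mm + X %*% st$alpha
      else if (spec$type == "median_split")
        mm <- mm + (D %*% st$delta) %*% diag(sqrt(st$sigma2), J)
      mm
    }

    for (iter in seq_len(cfg$n_iterations)) {
      in_burn <- iter <= cfg$n_burnin
      mean_mat <- group_mean()

      ## --- participant-level updates -------------------------------------
      if (!zp_fixed) {
        if (!has_lik) {
          zp <- mean_mat + matrix(rnorm(N * J), N, J) %*%
            diag(sqrt(st$sigma2), J)
        } else {
          # one compiled joint Metropolis step per participant over all four
          # probit-scale parameters, proposing along the learned posterior
          # covariance (this is what crosses the utility-vs-sensitivity
          # ridge); zp, nat, ll and the acceptance counter update in place
          pvl_zp_joint_cpp(zp, nat, ll, Lpack, step_i, m$choice, netidx,
                           netvals, mean_mat, st$sigma2, ubounds,
                           if (in_burn) acc_i else acc_keep)
          if (!in_burn) keep_try <- keep_try + 1L
          if (in_burn) {
            if (iter %% 50L == 0L) {
              step_i <- step_i * exp(pmin(0.4, pmax(-0.4, acc_i / 50 - 0.25)))
              acc_i <- numeric(N)
            }
            if (iter > 200L) { # accumulate per-participant moments
              w_cnt <- w_cnt + 1L
              d1 <- zp - w_mn
              w_mn <- w_mn + d1 / w_cnt
              d2 <- zp - w_mn
              for (q in 1:4) for (r in 1:q)
                w_c[, q + 4 * (r - 1)] <- w_c[, q + 4 * (r - 1)] +
                  d1[, q] * d2[, r]
              if (w_cnt >= 150L && iter %% 250L == 0L) {
                for (i in seq_len(N)) {
                  S <- matrix(0, 4, 4)
                  for (q in 1:4) for (r in 1:q)
                    S[q, r] <- S[r, q] <- w_c[i, q + 4 * (r - 1)] / (w_cnt - 1)
                  L <- t(chol(S + diag(1e-4, 4)))
                  Lpack[i, ] <- as.vector(L)
                }
                for (q in 1:4)
                  s_hat[, q] <- sqrt(pmax(w_c[, q + 4 * (q - 1)] /
                                            (w_cnt - 1), 1e-4))
              }
            }
          }
        }
      }

      ## --- group-level conjugate updates ---------------------------------
      for (j in seq_len(J)) {
        r <- zp[, j]
        s2 <- st$sigma2[j]
        if (spec$type == "regression") {
          prec <- XtX * (1 + 1 / (N * st$g[j])) / s2
          st$alpha[, j] <- rmvn_prec(prec, crossprod(X, r - st$mu[j]) / s2)
          fit_j <- drop(X %*% st$alpha[, j])
          v <- 1 / (N / s2 + if (jeff) 0 else 1)
          st$mu[j] <- rnorm(1, v * sum(r - fit_j) / s2, sqrt(v))
          ssr <- sum((r - st$mu[j] - fit_j)^2)
          qf <- drop(crossprod(st$alpha[, j], M %*% st$alpha[, j]))
          sh <- (if (jeff) 0 else 2) + N / 2 + P / 2
          ra <- (if (jeff) 0 else 0.5) + ssr / 2 + qf / (2 * st$g[j])
          st$sigma2[j] <- ra / rgamma(1, sh)
          if (is.null(fixed_g)) {
            ra_g <- spec$scale^2 / 2 + qf / (2 * st$sigma2[j])
            st$g[j] <- ra_g / rgamma(1, (1 + P) / 2)
          }
        } else if (spec$type == "median_split") {
          sdj <- sqrt(s2)
          prec <- DtD + diag(1 / st$lambda[, j], P)
          st$delta[, j] <- rmvn_prec(prec, crossprod(D, (r - st$mu[j]) / sdj))
          st$lambda[, j] <- (spec$scale^2 + st$delta[, j]^2) / (2 * rgamma(P, 1))
          cvec <- drop(D %*% st$delta[, j])
          v <- 1 / (N / s2 + 1)
          st$mu[j] <- rnorm(1, v * sum(r - sdj * cvec) / s2, sqrt(v))
          # sigma2: Metropolis on log sigma2 (group means depend on sigma)
          u <- r - st$mu[j]
          logpost_s2 <- function(x) {
            sum(dnorm(u, sqrt(x) * cvec, sqrt(x), log = TRUE)) +
              ig_logpdf(x, 2, 0.5) + log(x)
          }
          prop <- exp(log(s2) + rnorm(1) * 0.3)
          if (log(runif(1)) < logpost_s2(prop) - logpost_s2(s2))
            st$sigma2[j] <- prop
        } else { # basic hierarchy, sigma ~ Uniform(0, 1.5)
          v <- 1 / (N / s2 + 1)
          st$mu[j] <- rnorm(1, v * sum(r) / s2, sqrt(v))
          sig <- sqrt(s2)
          prop <- sig + rnorm(1) * step_s2[j] * 0.2
          if (prop > 0 && prop < 1.5) {
            lr <- sum(dnorm(r, st$mu[j], prop, log = TRUE)) -
              sum(dnorm(r, st$mu[j], sig, log = TRUE))
            if (log(runif(1)) < lr) st$sigma2[j] <- prop^2
          }
        }
      }

      ## --- non-centered translation and scale moves -----------------------
      if (has_lik && !zp_fixed) {
        for (j in seq_len(J)) {
          ## joint translation move over the intercept and every coefficient,
          ## one likelihood evaluation per column
          eps <- rnorm(n_dir) * step_sh[, j]
          mu_new <- st$mu[j] + eps[1]
          lpdiff <- dnorm(mu_new, 0, 1, log = TRUE) -
            dnorm(st$mu[j], 0, 1, log = TRUE)
          shift <- rep(eps[1], N)
          if (spec$type == "regression") {
            dal <- drop(Lm %*% eps[-1])
            a_new <- st$alpha[, j] + dal
            shift <- shift + drop(X %*% dal)
            qf_old <- drop(crossprod(st$alpha[, j], M %*% st$alpha[, j]))
            qf_new <- drop(crossprod(a_new, M %*% a_new))
            lpdiff <- lpdiff - (qf_new - qf_old) /
              (2 * st$g[j] * st$sigma2[j])
          } else if (spec$type == "median_split") {
            dde <- drop(Lmd %*% eps[-1])
            d_new <- st$delta[, j] + dde
            shift <- shift + drop(D %*% dde) * sqrt(st$sigma2[j])
            lpdiff <- lpdiff +
              sum(dcauchy(d_new, 0, spec$scale, log = TRUE)) -
              sum(dcauchy(st$delta[, j], 0, spec$scale, log = TRUE))
          }
          prop_j <- zp[, j] + shift
          natj <- inverse_probit(prop_j, pvl_bounds[j])
          ll_prop <- lik_col(nat, j, natj)
          if (log(runif(1)) < sum(ll_prop - ll) + lpdiff) {
            zp[, j] <- prop_j; nat[, j] <- natj; ll <- ll_prop
            st$mu[j] <- mu_new
            if (spec$type == "regression") st$alpha[, j] <- a_new
            else if (spec$type == "median_split") st$delta[, j] <- d_new
            if (in_burn) b_tr[j] <- b_tr[j] + 1 else acc_tr[j] <- acc_tr[j] + 1
          }
          ## weighted translation: shift each participant in proportion to
          ## their learned posterior spread (plus the matching intercept
          ## shift), so participants whose likelihood pins them tightly do
          ## not veto movement of the group mean; the hierarchy residual
          ## terms are evaluated exactly since the shift is non-uniform
          {
            eps <- rnorm(1) * step_wt[j]
            sh_vec <- s_hat[, j]
            d_mu <- mean(sh_vec)
            prop_j <- zp[, j] + eps * sh_vec
            mu_new <- st$mu[j] + eps * d_mu
            sdj <- sqrt(st$sigma2[j])
            m_cur <- st$mu[j] + switch(spec$type,
              regression = drop(X %*% st$alpha[, j]),
              median_split = drop(D %*% st$delta[, j]) * sdj,
              basic = 0)
            r_old <- zp[, j] - m_cur
            resid_shift <- eps * (sh_vec - d_mu)
            lpdiff <- sum(dnorm(r_old + resid_shift, 0, sdj, log = TRUE) -
                            dnorm(r_old, 0, sdj, log = TRUE)) +
              dnorm(mu_new, 0, 1, log = TRUE) -
              dnorm(st$mu[j], 0, 1, log = TRUE)
            natj <- inverse_probit(prop_j, pvl_bounds[j])
            ll_prop <- lik_col(nat, j, natj)
            if (log(runif(1)) < sum(ll_prop - ll) + lpdiff) {
              zp[, j] <- prop_j; nat[, j] <- natj; ll <- ll_prop
              st$mu[j] <- mu_new
              if (in_burn) b_wt[j] <- b_wt[j] + 1
              else acc_wt[j] <- acc_wt[j] + 1
            }
          }
          ## scale move: expand residual spread and residuals together
          if (spec$type != "basic") {
            h <- rnorm(1) * step_s2[j] * 0.3
            s2_new <- st$sigma2[j] * exp(h)
            mu_j <- st$mu[j]
            if (spec$type == "regression") {
              base <- mu_j + drop(X %*% st$alpha[, j])
              prop_j <- base + (zp[, j] - base) * exp(h / 2)
              qf <- drop(crossprod(st$alpha[, j], M %*% st$alpha[, j]))
              lpdiff <- ig_logpdf(s2_new, 2, 0.5) - ig_logpdf(st$sigma2[j], 2, 0.5) +
                h - P * h / 2 - qf / (2 * st$g[j]) * (1 / s2_new - 1 / st$sigma2[j])
            } else {
              prop_j <- mu_j + (zp[, j] - mu_j) * exp(h / 2)
              lpdiff <- ig_logpdf(s2_new, 2, 0.5) -
                ig_logpdf(st$sigma2[j], 2, 0.5) + h
            }
            natj <- inverse_probit(prop_j, pvl_bounds[j])
            ll_prop <- lik_col(nat, j, natj)
            if (log(runif(1)) < sum(ll_prop - ll) + lpdiff) {
              zp[, j] <- prop_j; nat[, j] <- natj; ll <- ll_prop
              st$sigma2[j] <- s2_new
              if (in_burn) b_sc[j] <- b_sc[j] + 1 else acc_sc[j] <- acc_sc[j] + 1
            }
          }
        }
        if (in_burn) {
          b_n <- b_n + 1L
          if (b_n == 50L) {
            for (j in seq_len(J)) {
              step_sh[, j] <- adapt_step(step_sh[, j], b_tr[j] / 50)
              step_s2[j] <- adapt_step(step_s2[j], b_sc[j] / 50)
              step_wt[j] <- adapt_step(step_wt[j], b_wt[j] / 50)
            }
            b_tr[] <- 0; b_sc[] <- 0; b_wt[] <- 0; b_n <- 0L
          }
        }
      }

      ## --- record ---------------------------------------------------------
      if (!in_burn && (iter - cfg$n_burnin) %% cfg$thin == 0L) {
        k_out <- k_out + 1L
        draws$mu[k_out, chain, ] <- st$mu
        draws$sigma2[k_out, chain, ] <- st$sigma2
        if (spec$type == "regression") {
          draws$alpha[k_out, chain, , ] <- st$alpha
          draws$g[k_out, chain, ] <- st$g
        } else if (spec$type == "median_split") {
          draws$delta[k_out, chain, , ] <- st$delta
        }
        if (store_individual && !zp_fixed)
          draws$zp[k_out, chain, , ] <- zp
        zp_mean <- zp_mean + zp
        if (!is.null(rb0)) {
          for (j in seq_len(J)) {
            if (spec$type == "regression") {
              Q <- XtX * (1 + 1 / (N * st$g[j])) / st$sigma2[j]
              mm <- solve(Q, crossprod(X, zp[, j] - st$mu[j]) / st$sigma2[j])
              for (p in seq_len(P)) {
                cm <- mm[p] - if (P > 1)
                  sum(Q[p, -p] * (st$alpha[-p, j] - mm[-p])) / Q[p, p] else 0
                # density of alpha_p at 0, mapped to the beta scale
                rb0[p, j] <- rb0[p, j] +
                  dnorm(0, cm, sqrt(1 / Q[p, p])) *
                  sqrt(st$sigma2[j]) / des$sds[p]
              }
            } else {
              Pd <- DtD + diag(1 / st$lambda[, j], P)
              md <- solve(Pd, crossprod(D, (zp[, j] - st$mu[j]) /
                                          sqrt(st$sigma2[j])))
              for (p in seq_len(P)) {
                cm <- md[p] - if (P > 1)
                  sum(Pd[p, -p] * (st$delta[-p, j] - md[-p])) / Pd[p, p] else 0
                rb0[p, j] <- rb0[p, j] + dnorm(0, cm, sqrt(1 / Pd[p, p]))
              }
            }
          }
        }
      }
    }
    if (has_lik && keep_try > 0) {
      accept[chain] <- mean(acc_keep) / keep_try
      attr(accept, "moves") <- rbind(attr(accept, "moves"),
        c(translation = acc_tr / keep_try, scale = acc_sc / keep_try))
      attr(accept, "steps") <- rbind(attr(accept, "steps"),
        c(sh = colMeans(step_sh), s2 = step_s2, wt = step_wt,
          zp = mean(step_i)))
    }
  }

  zp_mean <- zp_mean / (n_kept * cfg$n_chains)
  if (!is.null(rb0)) {
    rb0 <- rb0 / (n_kept * cfg$n_chains)
    dimnames(rb0) <- list(cn, pn)
  }
  structure(list(draws = draws, accept = accept, spec = spec, config = cfg,
                 rb_post0 = rb0,
                 n_kept = n_kept, param_names = pn, covariate_names = cn,
                 design = if (spec$type == "regression")
                   list(sds = des$sds, n = des$n, p = des$p) else
                     list(p = P, n = N),
                 zp_mean = zp_mean),
            class = "pvl_posterior")
}

#' @export
print.pvl_posterior <- function(x, ...) {
  cat("Hierarchical posterior (", x$spec$type, " spec)\n", sep = "")
  cat(" retained draws:", x$n_kept, "x", x$config$n_chains, "chains\n")
  rh <- tryCatch(gelman_rubin(x), error = function(e) NULL)
  if (!is.null(rh)) cat(" max split R-hat:", round(max(rh), 4), "\n")
  invisible(x)
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Potential-scale-reduction statistic computed after splitting each chain in
#' half, so within-chain trends inflate the diagnostic as well. Values near 1
#' indicate convergence; fits are flagged unless all group-level statistics
#' are at or below the gate (1.01 by default).
#'
#' @param x Either a draws matrix (iterations x chains) or a `pvl_posterior`,
#'   in which case the statistic is reported for every group-level quantity.
#' @return A single R-hat value for a matrix, or a named vector.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "pvl_posterior")) {
    d <- x$draws; pn <- x$param_names
    out <- c()
    for (j in seq_along(pn)) {
      out[paste0("mu[", pn[j], "]")] <- gelman_rubin(d$mu[, , j, drop = FALSE][, , 1])
      out[paste0("sigma2[", pn[j], "]")] <-
        gelman_rubin(d$sigma2[, , j, drop = FALSE][, , 1])
      if (!is.null(d$alpha)) {
        for (p in seq_len(dim(d$alpha)[3]))
          out[paste0("alpha[", p, ",", pn[j], "]")] <-
            gelman_rubin(d$alpha[, , p, j])
        out[paste0("g[", pn[j], "]")] <- gelman_rubin(d$g[, , j, drop = FALSE][, , 1])
      }
      if (!is.null(d$delta)) {
        for (p in seq_len(dim(d$delta)[3]))
          out[paste0("delta[", p, ",", pn[j], "]")] <-
            gelman_rubin(d$delta[, , p, j])
      }
    }
    return(out)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 chains", call. = FALSE)
  n <- nrow(x)
  if (n < 20L) stop("need at least 10 retained draws per half-chain",
                    call. = FALSE)
  half <- n %/% 2L
  split <- do.call(cbind, lapply(seq_len(ncol(x)), function(k)
    cbind(x[seq_len(half), k], x[(n - half + 1):n, k])))
  mns <- colMeans(split)
  vrs <- apply(split, 2, var)
  W <- mean(vrs)
  B <- half * var(mns)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
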