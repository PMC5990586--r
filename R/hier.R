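#' @useDynLib pvlreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm dcauchy qnorm pnorm rnorm runif rgamma rexp
#'   median sd var density quantile rbinom
NULL

# Upper bounds of the four PVL-Delta parameters on the natural scale, in the
# canonical order (A, w, a, c).
pvl_bounds <- c(A = 1, w = 5, a = 1, c = 5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probit transform of a bounded parameter
#'
#' Maps a parameter with natural range (0, U) onto the real line via
#' `z' = qnorm(z / U)`; `inverse_probit` maps back via `z = U * pnorm(z')`.
#' The pair is a bijection between (0, U) and the reals, which is what lets
#' normal hierarchical (and regression) structure be placed on bounded model
#' parameters.
#'
#' @param z Natural-scale value(s), strictly inside (0, upper).
#' @param upper Upper bound of the parameter (1 for A and a, 5 for w and c).
#' @return Probit-scale value(s).
#' @export
probit_transform <- function(z, upper = 1) {
  if (any(z <= 0 | z >= upper))
    stop("`z` must lie strictly inside (0, ", upper, ")", call. = FALSE)
  qnorm(z / upper)
}

#' @rdname probit_transform
#' @param zp Probit-scale value(s).
#' @export
inverse_probit <- function(zp, upper = 1) upper * pnorm(zp)

#' Centered covariate design
#'
#' Centers each covariate column to mean zero and records its standard
#' deviation. The denominator-N standard deviation is used so that
#' `crossprod(X)/N` equals `diag(s^2)` exactly for uncorrelated columns,
#' matching the scaling of the mixture-of-g prior.
#'
#' @param x Numeric matrix or data.frame, participants in rows, covariates in
#'   columns.
#' @return An object of class `covariate_design`: list with `centered` (N x P
#'   matrix), `sds`, `means`, `n`, `p`.
#' @export
center_covariates <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("covariates must be numeric with no missing values", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 participants", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(colMeans(xc^2))
  if (any(s <= 0)) {
    j <- which(s <= 0)[1]
    stop("degenerate covariate (constant column): ",
         colnames(x)[j] %||% j, call. = FALSE)
  }
  if (is.null(colnames(xc))) colnames(xc) <- paste0("x", seq_len(ncol(xc)))
  structure(list(centered = xc, sds = s, means = mu,
                 n = nrow(xc), p = ncol(xc)),
            class = "covariate_design")
}

#' Effect-coded median-split design
#'
#' Dichotomizes each covariate at its median: +0.5 for scores strictly above
#' the median, -0.5 otherwise. This is the design matrix of the median-split
#' comparison model; the coefficient of a +/-0.5 coded column is the
#' standardized difference between the above- and below-median groups.
#'
#' @inheritParams center_covariates
#' @return N x P matrix of entries in \{-0.5, +0.5\}.
#' @export
effect_code <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("covariates must be numeric with no missing values", call. = FALSE)
  d <- apply(x, 2, function(col) ifelse(col > median(col), 0.5, -0.5))
  if (is.null(colnames(d))) colnames(d) <- paste0("x", seq_len(ncol(d)))
  d
}

# Inverse-gamma log-density with shape a and scale (rate on 1/x) b.
ig_logpdf <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}

#' Mixture-of-g prior log-densities
#'
#' `regression_logprior` evaluates the conditional multivariate-normal
#' log-density of the regression weights, `alpha | g ~ N(0, g * sigma2 *
#' solve(crossprod(X)/N))`; `g_logprior` evaluates the inverse-gamma(1/2,
#' s^2/2) log-density of the latent scale `g`. Marginally over `g` the weights
#' follow a multivariate Cauchy (Jeffreys-Zellner-Siow) prior with scale `s`.
#'
#' @param alpha Numeric P-vector of regression weights.
#' @param g Positive scalar latent mixing variable.
#' @param sigma2 Residual variance of the criterion (the probit-scale model
#'   parameter).
#' @param design A `covariate_design`.
#' @return Log-density (scalar).
#' @export
regression_logprior <- function(alpha, g, sigma2, design) {
  stopifnot(inherits(design, "covariate_design"))
  if (g <= 0 || sigma2 <= 0) return(-Inf)
  M <- crossprod(design$centered) / design$n
  P <- design$p
  ch <- tryCatch(chol(M), error = function(e)
    stop("singular design: covariates are collinear", call. = FALSE))
  qf <- sum((ch %*% alpha)^2) # alpha' M alpha
  -P / 2 * log(2 * pi * g * sigma2) + sum(log(diag(ch))) -
    qf / (2 * g * sigma2)
}

#' @rdname regression_logprior
#' @param s Cauchy scale of the implied prior on standardized effect sizes.
#' @export
g_logprior <- function(g, s = 1) {
  if (s <= 0) stop("`s` must be positive", call. = FALSE)
  ig_logpdf(g, 1 / 2, s^2 / 2)
}

#' Hierarchical model specifications
#'
#' Three variants of the hierarchical PVL-Delta model over probit-scale
#' parameters `z'` in \{A', w', a', c'\}:
#'
#' * `regression_spec()`: `z'_i ~ N(mu + x_i' alpha, sigma2)` with centered
#'   covariates, `mu ~ N(0,1)`, `sigma2 ~ InvGamma(2, 1/2)` and the
#'   Jeffreys-Zellner-Siow mixture-of-g prior on `alpha` (scale `s`).
#' * `median_split_spec()`: `z'_i ~ N(mu + delta' d_i * sigma, sigma2)` with
#'   effect-coded (+/-0.5) median-split designs `d_i` and independent
#'   Cauchy(0, s) priors on the standardized group differences `delta`.
#' * `basic_hier_spec()`: intercept-only hierarchy, `mu ~ N(0,1)`,
#'   `sigma ~ Uniform(0, 1.5)`.
#'
#' @param scale Cauchy prior scale `s` for the standardized effect sizes
#'   (default 1; use 1/3 when small effects are expected a priori).
#' @return A list of class `pvl_model_spec` with fields `type` and `scale`.
#' @export
regression_spec <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(type = "regression", scale = scale), class = "pvl_model_spec")
}

#' @rdname regression_spec
#' @export
median_split_spec <- function(scale = 1) {
  stopifnot(scale > 0)
  structure(list(type = "median_split", scale = scale),
            class = "pvl_model_spec")
}

#' @rdname regression_spec
#' @export
basic_hier_spec <- function() {
  structure(list(type = "basic", scale = NA_real_), class = "pvl_model_spec")
}

#' Joint log-density of a hierarchical model variant
#'
#' Sums (i) the PVL-Delta choice log-likelihood of every participant at the
#' natural-scale parameters `inverse_probit(z')`, (ii) the hierarchical normal
#' log-density of each probit-scale parameter given its group-level mean
#' structure, and (iii) all group-level log-priors. Used as the reference
#' density for the sampler and checked term-by-term against an independent
#' hand-coded oracle in the tests.
#'
#' @param spec A `pvl_model_spec`.
#' @param data An `igt_data` data.frame, or `NULL` for the prior-plus-hierarchy
#'   density with no behavioral likelihood.
#' @param covariates Raw N x P covariate matrix (centered or effect-coded
#'   internally as the model variant requires); ignored by the basic
#'   hierarchy.
#' @param state Named list of latent values: `zp` (N x 4 matrix, columns A',
#'   w', a', c'), `mu` (4), `sigma2` (4), and `alpha` (P x 4) plus `g` (4) for
#'   the regression spec or `delta` (P x 4) for the median-split spec.
#' @return Scalar log-density (finite at any interior point).
#' @export
joint_logdensity <- function(spec, data, covariates, state) {
  stopifnot(inherits(spec, "pvl_model_spec"))
  zp <- state$zp
  N <- nrow(zp)
  if (ncol(zp) != 4L) stop("`state$zp` must have 4 columns", call. = FALSE)
  lp <- 0
  # group-level mean structure per model parameter
  des <- NULL; D <- NULL
  if (spec$type == "regression") {
    des <- center_covariates(covariates)
    if (des$n != N) stop("covariate/participant dimension mismatch",
                         call. = FALSE)
    if (!is.matrix(state$alpha) || any(dim(state$alpha) != c(des$p, 4)))
      stop("`state$alpha` must be a P x 4 matrix", call. = FALSE)
  } else if (spec$type == "median_split") {
    D <- effect_code(covariates)
    if (nrow(D) != N) stop("covariate/participant dimension mismatch",
                           call. = FALSE)
    if (!is.matrix(state$delta) || any(dim(state$delta) != c(ncol(D), 4)))
      stop("`state$delta` must be a P x 4 matrix", call. = FALSE)
  }
  for (j in 1:4) {
    s2 <- state$sigma2[j]
    if (s2 <= 0) return(-Inf)
    m <- switch(spec$type,
      regression = state$mu[j] + drop(des$centered %*% state$alpha[, j]),
      median_split = state$mu[j] + drop(D %*% state$delta[, j]) * sqrt(s2),
      basic = rep(state$mu[j], N))
    lp <- lp + sum(dnorm(zp[, j], m, sqrt(s2), log = TRUE))
    lp <- lp + dnorm(state$mu[j], 0, 1, log = TRUE)
    lp <- lp + switch(spec$type,
      regression = ig_logpdf(s2, 2, 1 / 2) +
        regression_logprior(state$alpha[, j], state$g[j], s2, des) +
        g_logprior(state$g[j], spec$scale),
      median_split = ig_logpdf(s2, 2, 1 / 2) +
        sum(dcauchy(state$delta[, j], 0, spec$scale, log = TRUE)),
      # uniform prior on sigma, expressed as a density over sigma2
      basic = if (sqrt(s2) < 1.5) log(1 / 1.5) - log(2 * sqrt(s2)) else -Inf)
    if (!is.finite(lp)) return(lp)
  }
  if (!is.null(data)) {
    nat <- vapply(1:4, function(j) inverse_probit(zp[, j], pvl_bounds[j]),
                  numeric(N))
    lp <- lp + sum(pvl_loglik(matrix(nat, N, 4), data))
  }
  lp
}
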