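#' PVL-Delta parameter set
#'
#' Bundles and validates the four PVL-Delta parameters: outcome sensitivity
#' `A` in \[0,1\], loss aversion `w` in \[0,5\], updating rate `a` in \[0,1\]
#' and consistency `c` in \[0,5\]. The softmax sensitivity is the derived
#' quantity `theta = 3^c - 1`.
#'
#' @param A Outcome sensitivity: shape of the prospect utility function
#'   (1 = linear utility, 0 = step function of the outcome sign).
#' @param w Loss aversion: impact of negative relative to positive net
#'   outcomes (1 = symmetric).
#' @param a Updating rate of the delta learning rule (0 = no updating,
#'   1 = expectancy replaced by the latest utility).
#' @param c Consistency: exploitation vs exploration; `c = 0` gives uniform
#'   random choice.
#' @return A list of class `pvl_params` with fields `A`, `w`, `a`, `c` and
#'   `theta`.
#' @examples
#' p <- pvl_params(A = 0.5, w = 1.5, a = 0.3, c = 1)
#' p$theta # 2
#' @export
pvl_params <- function(A, w, a, c) {
  chk <- function(x, lo, hi, nm) {
    if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
      stop("`", nm, "` must be a single value in [", lo, ",", hi, "]",
           call. = FALSE)
    as.numeric(x)
  }
  out <- list(A = chk(A, 0, 1, "A"), w = chk(w, 0, 5, "w"),
              a = chk(a, 0, 1, "a"), c = chk(c, 0, 5, "c"))
  out$theta <- pvl_sensitivity(out$c)
  class(out) <- "pvl_params"
  out
}

#' Prospect utility of a net outcome
#'
#' `u(x) = x^A` for `x >= 0` and `-w * |x|^A` for `x < 0`. A net outcome of 0
#' has utility 0 for every `A` (continuity from below; this fixes the `0^0`
#' corner).
#'
#' @param x Net outcome(s), win + loss.
#' @param A Outcome sensitivity in \[0,1\].
#' @param w Loss aversion in \[0,5\].
#' @return Numeric vector of subjective utilities.
#' @export
pvl_utility <- function(x, A, w) {
  if (A < 0 || A > 1) stop("`A` must lie in [0,1]", call. = FALSE)
  if (w < 0 || w > 5) stop("`w` must lie in [0,5]", call. = FALSE)
  ifelse(x == 0, 0, ifelse(x > 0, x^A, -w * abs(x)^A))
}

#' Delta-rule expectancy update
#'
#' `Ev <- Ev + a * (u - Ev)` applied to the chosen deck only.
#'
#' @param ev_prev Previous expectancy (scalar or vector).
#' @param u Subjective utility of the current outcome.
#' @param a Updating rate in \[0,1\].
#' @export
pvl_update <- function(ev_prev, u, a) {
  if (a < 0 || a > 1) stop("`a` must lie in [0,1]", call. = FALSE)
  ev_prev + a * (u - ev_prev)
}

#' Softmax sensitivity from consistency
#'
#' `theta = 3^c - 1`; `theta = 0` (uniform random choice) iff `c = 0`.
#'
#' @param c Consistency in \[0,5\].
#' @export
pvl_sensitivity <- function(c) {
  if (any(c < 0 | c > 5)) stop("`c` must lie in [0,5]", call. = FALSE)
  3^c - 1
}

#' Softmax choice probabilities over deck expectancies
#'
#' `P_k = exp(theta * Ev_k) / sum_j exp(theta * Ev_j)`, computed with a
#' max-shift so large `theta * Ev` cannot overflow.
#'
#' @param ev Numeric 4-vector of expected utilities.
#' @param theta Sensitivity, `>= 0`.
#' @return Probability 4-vector summing to 1.
#' @export
pvl_choice_prob <- function(ev, theta) {
  if (theta < 0) stop("`theta` must be non-negative", call. = FALSE)
  z <- theta * ev
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Simulate one PVL-Delta agent on the IGT
#'
#' The first choice is uniform over the four decks; every later choice is
#' drawn from the softmax over current expectancies. Each choice consumes the
#' next scheduled position of its deck, expectancies start at zero and are
#' updated by the delta rule after every draw.
#'
#' @param params A `pvl_params` object.
#' @param schedule An `igt_schedule`; `n_trials` must not exceed its
#'   `max_draws`.
#' @param n_trials Number of trials to simulate.
#' @param participant Participant identifier stamped on the records.
#' @param seed Optional integer seed; when supplied the simulation is
#'   reproducible and the caller's RNG state is restored afterwards.
#' @return An `igt_data` data.frame with `n_trials` rows.
#' @export
simulate_pvl_agent <- function(params, schedule, n_trials,
                               participant = 1L, seed = NULL) {
  stopifnot(inherits(params, "pvl_params"), inherits(schedule, "igt_schedule"))
  if (n_trials > schedule$max_draws)
    stop("`n_trials` exceeds schedule max_draws", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  ev <- numeric(4)
  drawn <- integer(4)
  choice <- integer(n_trials); win <- numeric(n_trials); loss <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    p <- if (t == 1L) rep(0.25, 4) else pvl_choice_prob(ev, params$theta)
    k <- sample.int(4L, 1L, prob = p)
    drawn[k] <- drawn[k] + 1L
    out <- igt_deal(schedule, k, drawn[k])
    choice[t] <- k; win[t] <- out[["win"]]; loss[t] <- out[["loss"]]
    u <- pvl_utility(out[["net"]], params$A, params$w)
    ev[k] <- pvl_update(ev[k], u, params$a)
  }
  validate_igt_data(data.frame(participant = participant,
                               trial = seq_len(n_trials),
                               choice = choice, win = win, loss = loss))
}

#' PVL-Delta choice log-likelihood
#'
#' Log-probability of a participant's observed choice sequence given
#' parameters, with expectancies rebuilt from the observed outcomes. Trial 1
#' contributes the uniform constant `log(1/4)`. `backend = "R"` is a plain-R
#' reference implementation; `backend = "cpp"` (default) is the compiled path
#' used by the sampler — the two agree to machine precision.
#'
#' @param params A `pvl_params` object, or an N x 4 matrix of (A, w, a, c)
#'   rows for several participants.
#' @param data An `igt_data` data.frame (all participants must share the same
#'   trial count when `params` is a matrix).
#' @param backend `"cpp"` or `"R"`.
#' @return Named numeric vector of per-participant log-likelihoods.
#' @export
pvl_loglik <- function(params, data, backend = c("cpp", "R")) {
  backend <- match.arg(backend)
  m <- igt_matrices(data)
  par <- if (inherits(params, "pvl_params")) {
    matrix(rep(c(params$A, params$w, params$a, params$c), each = m$n_participants),
           m$n_participants, 4)
  } else {
    stopifnot(is.matrix(params), ncol(params) == 4,
              nrow(params) == m$n_participants)
    params
  }
  ll <- if (backend == "cpp") {
    pvl_loglik_cpp(par, m$choice, m$net)
  } else {
    vapply(seq_len(m$n_participants), function(i) {
      pvl_loglik_one_r(par[i, ], m$choice[, i], m$net[, i])
    }, numeric(1))
  }
  names(ll) <- m$ids
  ll
}

# Reference R implementation of the single-participant likelihood; kept
# independent of the compiled path so the two can be cross-checked.
pvl_loglik_one_r <- function(par, choice, net) {
  A <- par[1]; w <- par[2]; a <- par[3]; c <- par[4]
  theta <- pvl_sensitivity(c)
  ev <- numeric(4)
  ll <- log(1 / 4)
  for (t in seq_along(choice)) {
    k <- choice[t]
    if (t > 1L) ll <- ll + log(pvl_choice_prob(ev, theta)[k])
    u <- pvl_utility(net[t], A, w)
    ev[k] <- pvl_update(ev[k], u, a)
  }
  ll
}
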