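#' Sample stimuli from the zero-mean Normal stimulus model
#'
#' @param env an [env_params()] object.
#' @param n number of draws.
#' @return numeric vector of `n` stimuli.
#' @export
sample_stimulus <- function(env, n = 1L) {
  stopifnot(inherits(env, "env_params"))
  stats::rnorm(n, mean = 0, sd = env$sigma_s)
}

#' Component means of the action mixture at a stimulus
#'
#' Each mixture component's mean is an affine function of the stimulus:
#' `intercept_i + slope_i * s`.
#'
#' @param policy a [policy_params()] object.
#' @param s scalar stimulus.
#' @return numeric vector of length `n_components`.
#' @examples
#' component_means(policy_params(c(1.5, 0)), s = 0.7)  # 1.5
#' @export
component_means <- function(policy, s) {
  stopifnot(inherits(policy, "policy_params"))
  w <- policy$weights
  idx <- seq_len(policy$n_components)
  w[2L * idx - 1L] + w[2L * idx] * s
}

policy_collapse_error <- function() {
  stop(structure(
    class = c("policy_collapse", "error", "condition"),
    list(message = paste0(
      "policy collapse: mixture density underflows (or is non-finite) ",
      "at every action value"),
      call = NULL)
  ))
}

#' Probability mass function over the discrete actions
#'
#' The mixture density is evaluated at the integer action locations
#' `1:n_actions` and renormalized. When the density underflows at every
#' action (the component means all sit so far from the action grid that no
#' action retains positive density) a `policy_collapse` error is signalled
#' rather than returning 0/0. This underflow boundary matters dynamically:
#' the weight updates treat collapsed policies as maximally costly, which
#' caps how deterministic the policy can become over the remembered
#' stimuli.
#'
#' With `limit = TRUE` the pmf is instead evaluated in log space
#' (max-subtracted), which yields the well-defined limit of the
#' renormalized mixture as it degenerates: a point mass on the action
#' nearest the closest component mean. The simulator samples from this
#' limit so an agent whose policy has saturated still acts.
#'
#' @inheritParams component_means
#' @param limit evaluate the degenerate-policy limit instead of signalling
#'   policy collapse on underflow.
#' @return probability vector of length `n_actions` summing to 1.
#' @examples
#' action_pmf(policy_params(c(1.5, 0)), s = 0)  # c(0.5, 0.5)
#' @export
action_pmf <- function(policy, s, limit = FALSE) {
  stopifnot(inherits(policy, "policy_params"))
  m <- component_means(policy, s)
  if (!all(is.finite(m))) policy_collapse_error()
  a <- seq_len(policy$n_actions)
  q <- -(outer(a, m, "-"))^2 / (2 * policy$sigma_a^2)  # Na x Nw
  if (limit) {
    qmax <- apply(q, 1L, max)
    logd <- qmax + log(rowSums(exp(q - qmax)))
    p <- exp(logd - max(logd))
    return(p / sum(p))
  }
  dens <- rowSums(exp(q))
  norm <- sum(dens)
  if (norm == 0 || !is.finite(norm)) policy_collapse_error()
  dens / norm
}

#' Sample one action from the policy at a stimulus
#'
#' @inheritParams component_means
#' @param u optional uniform deviate in `[0, 1)`; when supplied the action is
#'   obtained by inverse-CDF lookup (used by the simulator's role-separated
#'   random streams), otherwise one uniform is drawn from the session RNG.
#' @param limit passed to [action_pmf()]; the simulator samples from the
#'   degenerate-policy limit.
#' @return integer action in `1:n_actions`.
#' @export
sample_action <- function(policy, s, u = NULL, limit = FALSE) {
  p <- action_pmf(policy, s, limit = limit)
  if (is.null(u)) u <- stats::runif(1L)
  cum <- cumsum(p)
  1L + findInterval(u, cum[-length(cum)])
}

#' Mean reward for an action-stimulus pair
#'
#' The default `"product"` form is `alpha * (a - beta) * s`; the
#' `"additive"` form is `alpha * a + beta * s`.
#'
#' @param env an [env_params()] object.
#' @param a integer action (vectorized).
#' @param s stimulus (vectorized).
#' @param form `"product"` (default) or `"additive"`.
#' @return numeric mean reward.
#' @examples
#' reward_mean(env_params(), a = 1, s = -1)  # +1
#' reward_mean(env_params(), a = 2, s = 1)   # +1
#' @export
reward_mean <- function(env, a, s, form = c("product", "additive")) {
  stopifnot(inherits(env, "env_params"))
  form <- match.arg(form)
  if (form == "product") env$alpha * (a - env$beta) * s
  else env$alpha * a + env$beta * s
}

#' Sample a reward for an action-stimulus pair
#'
#' @inheritParams reward_mean
#' @param n number of draws.
#' @return numeric vector of rewards drawn from
#'   `Normal(reward_mean(env, a, s), sigma_r^2)`.
#' @export
sample_reward <- function(env, a, s, n = 1L, form = c("product", "additive")) {
  form <- match.arg(form)
  stats::rnorm(n, mean = reward_mean(env, a, s, form), sd = env$sigma_r)
}
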