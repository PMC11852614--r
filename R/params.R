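#' Policy parameters for the Gaussian-mixture action model
#'
#' The agent maps a scalar stimulus to a distribution over `n_actions`
#' discrete actions located at the integers `1:n_actions`. The unnormalized
#' density at action `a` is a sum of `n_components` Gaussian bumps whose
#' means depend linearly on the stimulus: the i-th component has mean
#' `w[2i-1] + w[2i] * s`. Weights are stored interleaved as
#' `(intercept_1, slope_1, ..., intercept_Nw, slope_Nw)`.
#'
#' @param weights numeric vector of length `2 * n_components`
#'   (intercept, slope per mixture component).
#' @param n_actions integer number of discrete actions (>= 2).
#' @param sigma_a positive standard deviation of each mixture component.
#' @return an object of class `policy_params`.
#' @examples
#' policy_params(c(1.5, 0))                 # standard two-action policy
#' policy_params(c(1.25, 0, 1.75, 0))       # two mixture components
#' @export
policy_params <- function(weights, n_actions = 2L, sigma_a = 1) {
  weights <- as.numeric(weights)
  n_actions <- as.integer(n_actions)
  if (length(weights) == 0L || length(weights) %% 2L != 0L) {
    stop("`weights` must have even, positive length (intercept, slope pairs)",
         call. = FALSE)
  }
  if (!all(is.finite(weights))) {
    stop("`weights` must be finite", call. = FALSE)
  }
  if (is.na(n_actions) || n_actions < 2L) {
    stop("`n_actions` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sigma_a) || length(sigma_a) != 1L || !is.finite(sigma_a) ||
      sigma_a <= 0) {
    stop("`sigma_a` must be a positive number", call. = FALSE)
  }
  structure(
    list(weights = weights, n_components = length(weights) %/% 2L,
         n_actions = n_actions, sigma_a = as.numeric(sigma_a)),
    class = "policy_params"
  )
}

#' @export
print.policy_params <- function(x, ...) {
  cat("<policy_params> ", x$n_components, " component(s), ",
      x$n_actions, " actions, sigma_a = ", format(x$sigma_a), "\n", sep = "")
  cat("  weights:", paste(format(x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Environment parameters: stimulus and reward models
#'
#' Stimuli are drawn from `Normal(0, sigma_s^2)`. Rewards for taking action
#' `a` at stimulus `s` are drawn from `Normal(mu(a, s), sigma_r^2)` where,
#' under the default `"product"` form, `mu(a, s) = alpha * (a - beta) * s`.
#' With the standard `alpha = 2`, `beta = 3/2` this rewards action 1 for
#' negative stimuli and action 2 for positive ones, symmetrically. The
#' `"additive"` form `mu(a, s) = alpha * a + beta * s` is available through
#' [reward_mean()] and [sim_config()].
#'
#' @param sigma_s positive stimulus standard deviation.
#' @param alpha,beta reward-mean shape parameters.
#' @param sigma_r positive reward standard deviation.
#' @return an object of class `env_params`.
#' @examples
#' env_params()  # standard: sigma_s = 1, alpha = 2, beta = 1.5, sigma_r = 1
#' @export
env_params <- function(sigma_s = 1, alpha = 2, beta = 1.5, sigma_r = 1) {
  for (nm in c("sigma_s", "alpha", "beta", "sigma_r")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a finite number", call. = FALSE)
    }
  }
  if (sigma_s <= 0) stop("`sigma_s` must be > 0", call. = FALSE)
  if (sigma_r <= 0) stop("`sigma_r` must be > 0", call. = FALSE)
  structure(
    list(sigma_s = as.numeric(sigma_s), alpha = as.numeric(alpha),
         beta = as.numeric(beta), sigma_r = as.numeric(sigma_r)),
    class = "env_params"
  )
}

#' @export
print.env_params <- function(x, ...) {
  cat("<env_params> sigma_s = ", format(x$sigma_s), ", alpha = ",
      format(x$alpha), ", beta = ", format(x$beta), ", sigma_r = ",
      format(x$sigma_r), "\n", sep = "")
  invisible(x)
}

#' Options for the simplex weight update
#'
#' Controls the Nelder-Mead search (Lagarias et al. coefficient set) used to
#' re-estimate the policy weights each step. Termination requires both the
#' simplex function spread to fall below `f_tolerance` and the vertex
#' coordinate spread below `x_tolerance`.
#'
#' @param max_iterations iteration cap; `NULL` means `200 * n_weights`.
#' @param x_tolerance,f_tolerance positive convergence tolerances.
#' @param restart_count number of restarts from the incumbent optimum.
#' @param zero_delta absolute perturbation used for zero coordinates when
#'   building the initial simplex (nonzero coordinates are perturbed by
#'   5%). A non-degenerate value keeps the search from stalling along
#'   coordinates that start at zero, such as the slope weights.
#' @return an object of class `optimizer_options`.
#' @export
optimizer_options <- function(max_iterations = NULL, x_tolerance = 1e-6,
                              f_tolerance = 1e-6, restart_count = 0L,
                              zero_delta = 0.05) {
  if (!is.null(max_iterations)) {
    max_iterations <- as.integer(max_iterations)
    if (is.na(max_iterations) || max_iterations < 1L) {
      stop("`max_iterations` must be a positive integer or NULL",
           call. = FALSE)
    }
  }
  if (x_tolerance <= 0 || f_tolerance <= 0) {
    stop("tolerances must be > 0", call. = FALSE)
  }
  restart_count <- as.integer(restart_count)
  if (is.na(restart_count) || restart_count < 0L) {
    stop("`restart_count` must be a nonnegative integer", call. = FALSE)
  }
  if (!is.numeric(zero_delta) || length(zero_delta) != 1L || zero_delta <= 0) {
    stop("`zero_delta` must be a positive number", call. = FALSE)
  }
  structure(
    list(max_iterations = max_iterations,
         x_tolerance = as.numeric(x_tolerance),
         f_tolerance = as.numeric(f_tolerance),
         restart_count = restart_count,
         zero_delta = as.numeric(zero_delta)),
    class = "optimizer_options"
  )
}

match_reward_form <- function(form) {
  match.arg(form, c("product", "additive"))
}

reward_form_code <- function(form) {
  if (identical(form, "product")) 0L else 1L
}
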