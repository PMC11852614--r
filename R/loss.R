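# Floor on action probabilities before logs; keeps surprisal finite so the
# simplex search can retreat from near-degenerate policies.
PROB_FLOOR <- 1e-300
# Sentinel loss for non-finite evaluations (matches the compiled objective).
LOSS_SENTINEL <- 1e300

#' Choice-consistency loss: total surprisal of remembered actions
#'
#' The consistency loss of a candidate policy is the summed surprisal
#' (negative natural log probability) of every recorded action given its
#' recorded stimulus: `l_a(w) = -sum_j log p(a_j | s_j, w)`. Minimizing it
#' picks weights that make the remembered stimulus-action pairs as
#' unsurprising as possible. The sum (not the mean) over the memory window
#' is used, so the loss grows while the memory fills.
#'
#' @param policy a [policy_params()] object (the candidate weights).
#' @param history a non-empty [new_history()] buffer.
#' @return nonnegative scalar; a large sentinel (rather than an error) when
#'   the policy is degenerate at some remembered pair, so optimizers can
#'   retreat.
#' @examples
#' h <- as_history(s = rep(0, 20), a = rep(1L, 20))
#' consistency_loss(policy_params(c(1.5, 0)), h)  # 20 * log(2)
#' @export
consistency_loss <- function(policy, history) {
  stopifnot(inherits(policy, "policy_params"),
            inherits(history, "choice_history"))
  if (history_length(history) == 0L) {
    stop("`history` must be non-empty", call. = FALSE)
  }
  total <- 0
  for (j in seq_along(history$s)) {
    p <- tryCatch(action_pmf(policy, history$s[j]),
                  policy_collapse = function(e) NULL)
    if (is.null(p)) return(LOSS_SENTINEL)
    total <- total - log(max(p[history$a[j]], PROB_FLOOR))
  }
  total
}

#' Reward loss: negative expected mean reward over remembered stimuli
#'
#' The Bayesian expected reward loss of a candidate policy, evaluated on the
#' remembered stimuli: for each remembered stimulus the policy's expected
#' mean reward `sum_a p(a | s_j, w) * mu(a, s_j)` is computed analytically
#' from the Normal reward model, aggregated over the window, and negated.
#' The default aggregates by mean so that the reward and consistency terms
#' are of comparable magnitude in the lambda compromise; `aggregate = "sum"`
#' is available. `sampled = TRUE` replaces the analytic mean with the
#' recorded rewards, weighting each recorded reward by the candidate
#' policy's probability of the recorded action.
#'
#' @inheritParams consistency_loss
#' @param env an [env_params()] object.
#' @param form reward-mean form, `"product"` or `"additive"`.
#' @param aggregate `"mean"` (default) or `"sum"` over the window.
#' @param sampled use recorded rewards instead of the analytic expectation.
#' @return scalar reward loss (may be negative).
#' @examples
#' # deterministic "action 2 iff s > 0" policy on symmetric stimuli: lr = -1
#' h <- as_history(s = c(-1, 1), a = c(1L, 2L))
#' reward_loss(policy_params(c(1.5, 20), sigma_a = 0.1), h, env_params())
#' @export
reward_loss <- function(policy, history, env,
                        form = c("product", "additive"),
                        aggregate = c("mean", "sum"), sampled = FALSE) {
  stopifnot(inherits(policy, "policy_params"),
            inherits(history, "choice_history"),
            inherits(env, "env_params"))
  form <- match.arg(form)
  aggregate <- match.arg(aggregate)
  if (history_length(history) == 0L) {
    stop("`history` must be non-empty", call. = FALSE)
  }
  acc <- 0
  for (j in seq_along(history$s)) {
    p <- tryCatch(action_pmf(policy, history$s[j]),
                  policy_collapse = function(e) NULL)
    if (is.null(p)) return(LOSS_SENTINEL)
    if (sampled) {
      acc <- acc + p[history$a[j]] * history$r[j]
    } else {
      a <- seq_len(policy$n_actions)
      acc <- acc + sum(p * reward_mean(env, a, history$s[j], form))
    }
  }
  if (aggregate == "mean") -acc / history_length(history) else -acc
}

#' Lambda-weighted compromise between reward and consistency losses
#'
#' Scalarizes the two Bayesian expected losses as
#' `l_lambda = lambda * l_r + (1 - lambda) * l_a`. At `lambda = 0` only
#' choice consistency drives the weight updates; at `lambda = 1` only
#' expected reward does.
#'
#' @inheritParams reward_loss
#' @param lambda trade-off weight in `[0, 1]`.
#' @return an object of class `loss_breakdown`: list with elements `l_a`,
#'   `l_r`, `l_lambda`, `lambda`.
#' @export
compromise_loss <- function(policy, history, env, lambda,
                            form = c("product", "additive"),
                            aggregate = c("mean", "sum"), sampled = FALSE) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a number in [0, 1]", call. = FALSE)
  }
  l_a <- consistency_loss(policy, history)
  l_r <- reward_loss(policy, history, env, form = form,
                     aggregate = aggregate, sampled = sampled)
  structure(
    list(l_a = l_a, l_r = l_r,
         l_lambda = lambda * l_r + (1 - lambda) * l_a,
         lambda = as.numeric(lambda)),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss_breakdown> l_a = ", format(x$l_a), ", l_r = ", format(x$l_r),
      ", l_lambda = ", format(x$l_lambda), " (lambda = ", format(x$lambda),
      ")\n", sep = "")
  invisible(x)
}
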