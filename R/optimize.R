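#' Re-estimate policy weights by simplex minimization of the compromise loss
#'
#' Minimizes [compromise_loss()] over the weight vector with the Nelder-Mead
#' simplex search in the Lagarias et al. formulation (reflection 1,
#' expansion 2, contraction 0.5, shrink 0.5; initial simplex perturbs each
#' warm-start coordinate by 5%, or 0.00025 for zero entries; termination
#' when both the simplex f-spread and x-spread fall below their tolerances).
#' The search is warm-started at the current weights and is fully
#' deterministic given its inputs. Only the weights change; the policy
#' shape (`n_components`, `n_actions`, `sigma_a`) is fixed.
#'
#' @inheritParams compromise_loss
#' @param opts an [optimizer_options()] object.
#' @return a `policy_params` object with the optimized weights and
#'   attributes `loss` (a `loss_breakdown` at the optimum), `iterations`,
#'   and `converged`.
#' @export
minimize_compromise <- function(policy, history, env, lambda,
                                opts = optimizer_options(),
                                form = c("product", "additive"),
                                aggregate = c("mean", "sum"),
                                sampled = FALSE) {
  stopifnot(inherits(policy, "policy_params"),
            inherits(history, "choice_history"),
            inherits(env, "env_params"),
            inherits(opts, "optimizer_options"))
  form <- match.arg(form)
  aggregate <- match.arg(aggregate)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a number in [0, 1]", call. = FALSE)
  }
  if (!history_full(history)) {
    stop("minimization requires a full memory window (history length == ",
         history$capacity, ")", call. = FALSE)
  }
  n <- length(policy$weights)
  maxit <- if (is.null(opts$max_iterations)) 200L * n else opts$max_iterations
  res <- cpp_minimize(
    policy$weights, history$s, history$a, history$r,
    policy$n_actions, policy$sigma_a, env$alpha, env$beta, lambda,
    reward_form_code(form), if (aggregate == "mean") 0L else 1L,
    as.integer(isTRUE(sampled)),
    maxit, opts$x_tolerance, opts$f_tolerance,
    opts$restart_count, opts$zero_delta
  )
  if (isTRUE(res$failed)) {
    warning("compromise loss non-finite at the warm start; ",
            "weights left unchanged", call. = FALSE)
    return(policy)
  }
  out <- policy
  out$weights <- as.numeric(res$weights)
  if (max(abs(out$weights)) > 1e3) {
    warning("optimized weights exceed 1e3 in magnitude", call. = FALSE)
  }
  attr(out, "loss") <- structure(
    list(l_a = res$l_a, l_r = res$l_r, l_lambda = res$l_lambda,
         lambda = as.numeric(lambda)),
    class = "loss_breakdown"
  )
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  out
}
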