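#' Simulation configuration
#'
#' Bundles everything one run needs: the initial policy, the environment,
#' the compromise weight `lambda`, the memory length, the run length, the
#' seed, and the optimizer settings. Defaults are the standard parameter
#' set: initial weights `(1.5, 0)` (one mixture component whose mean sits
#' exactly midway between the two actions, so the initial choice is a coin
#' flip for every stimulus), two actions, `lambda = 0`, memory length 20,
#' `sigma_a = sigma_r = sigma_s = 1`, `(alpha, beta) = (2, 3/2)`.
#'
#' @param weights initial policy weights (length `2 * n_components`).
#' @param n_actions number of discrete actions.
#' @param sigma_a policy mixture component SD.
#' @param sigma_s stimulus SD.
#' @param alpha,beta reward-mean parameters.
#' @param sigma_r reward SD.
#' @param lambda compromise weight in `[0, 1]`.
#' @param memory_length memory window (number of remembered triples).
#' @param n_steps total simulation steps (`>= memory_length`).
#' @param seed integer seed for the run.
#' @param optimizer an [optimizer_options()] object.
#' @param reward_mean_form `"product"` (`alpha * (a - beta) * s`, default)
#'   or `"additive"` (`alpha * a + beta * s`).
#' @param reward_loss_form `"expected"` (analytic policy expectation,
#'   default) or `"sampled"` (recorded rewards).
#' @param reward_aggregate `"mean"` (default) or `"sum"` over the window.
#' @param update_start where each step's simplex minimization starts:
#'   `"initial"` (default) re-estimates the weights from the initial weight
#'   vector, so the fitted policy tracks the current memory window;
#'   `"previous"` warm-starts from the last estimate.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(weights = c(1.5, 0), n_actions = 2L, sigma_a = 1,
                       sigma_s = 1, alpha = 2, beta = 1.5, sigma_r = 1,
                       lambda = 0, memory_length = 20L, n_steps = 600L,
                       seed = 1L, optimizer = optimizer_options(),
                       reward_mean_form = c("product", "additive"),
                       reward_loss_form = c("expected", "sampled"),
                       reward_aggregate = c("mean", "sum"),
                       update_start = c("initial", "previous")) {
  policy <- policy_params(weights, n_actions = n_actions, sigma_a = sigma_a)
  env <- env_params(sigma_s = sigma_s, alpha = alpha, beta = beta,
                    sigma_r = sigma_r)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a number in [0, 1]", call. = FALSE)
  }
  memory_length <- as.integer(memory_length)
  n_steps <- as.integer(n_steps)
  if (is.na(memory_length) || memory_length < 1L) {
    stop("`memory_length` must be an integer >= 1", call. = FALSE)
  }
  if (is.na(n_steps) || n_steps < memory_length) {
    stop("`n_steps` must be an integer >= `memory_length`", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  stopifnot(inherits(optimizer, "optimizer_options"))
  structure(
    list(policy = policy, env = env, lambda = as.numeric(lambda),
         memory_length = memory_length, n_steps = n_steps, seed = seed,
         optimizer = optimizer,
         reward_mean_form = match.arg(reward_mean_form),
         reward_loss_form = match.arg(reward_loss_form),
         reward_aggregate = match.arg(reward_aggregate),
         update_start = match.arg(update_start)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_steps, " steps, memory ", x$memory_length,
      ", lambda = ", format(x$lambda), ", seed = ", x$seed, "\n", sep = "")
  print(x$policy)
  print(x$env)
  invisible(x)
}

# Three independent sub-seeds (one per sampling role) derived from the run
# seed, so that changing one sampling call never perturbs the other streams.
role_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Initialize simulator state
#'
#' Pre-generates the three role-separated random streams (stimuli, action
#' uniforms, reward noise) for the whole run and sets up the empty memory
#' and the trajectory record.
#'
#' @param config a [sim_config()] object.
#' @return an opaque state list consumed by [sim_step()].
#' @export
sim_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  T_ <- config$n_steps
  seeds <- role_seeds(config$seed)
  stimuli <- with_seed(seeds[1L],
                       stats::rnorm(T_, 0, config$env$sigma_s))
  unif <- with_seed(seeds[2L], stats::runif(T_))
  znoise <- with_seed(seeds[3L], stats::rnorm(T_))
  nw2 <- length(config$policy$weights)
  list(
    config = config, t = 0L,
    policy = config$policy,
    history = new_history(config$memory_length),
    stimuli = stimuli, unif = unif, znoise = znoise,
    rec_s = numeric(T_), rec_a = integer(T_), rec_r = numeric(T_),
    rec_w = matrix(NA_real_, nrow = T_, ncol = nw2),
    rec_la = numeric(T_), rec_lr = numeric(T_), rec_ll = numeric(T_),
    n_update_failures = 0L, n_weight_warnings = 0L
  )
}

#' Advance the simulation by one step
#'
#' Samples the stimulus, the action, and the reward; appends the triple to
#' the memory; once the memory is full, re-estimates the policy weights by
#' minimizing the compromise loss; records everything. During warmup
#' (memory not yet full) the weights stay at their initial values.
#'
#' @param state a state from [sim_state()] or a previous `sim_step()`.
#' @return the advanced state.
#' @export
sim_step <- function(state) {
  cfg <- state$config
  t <- state$t + 1L
  if (t > cfg$n_steps) stop("simulation already complete", call. = FALSE)
  s <- state$stimuli[t]
  a <- sample_action(state$policy, s, u = state$unif[t], limit = TRUE)
  r <- reward_mean(cfg$env, a, s, form = cfg$reward_mean_form) +
    cfg$env$sigma_r * state$znoise[t]
  state$history <- history_append(state$history, s, a, r)

  sampled <- identical(cfg$reward_loss_form, "sampled")
  if (history_full(state$history)) {
    init <- if (identical(cfg$update_start, "previous")) state$policy
            else cfg$policy
    res <- withCallingHandlers(
      minimize_compromise(init, state$history, cfg$env, cfg$lambda,
                          opts = cfg$optimizer, form = cfg$reward_mean_form,
                          aggregate = cfg$reward_aggregate,
                          sampled = sampled),
      warning = function(w) {
        state$n_weight_warnings <<- state$n_weight_warnings + 1L
        invokeRestart("muffleWarning")
      }
    )
    loss <- attr(res, "loss")
    if (is.null(loss)) {  # failed update: weights unchanged
      state$n_update_failures <- state$n_update_failures + 1L
      loss <- compromise_loss(state$policy, state$history, cfg$env,
                              cfg$lambda, form = cfg$reward_mean_form,
                              aggregate = cfg$reward_aggregate,
                              sampled = sampled)
    }
    state$policy <- policy_params(res$weights, cfg$policy$n_actions,
                                  cfg$policy$sigma_a)
  } else {
    loss <- compromise_loss(state$policy, state$history, cfg$env, cfg$lambda,
                            form = cfg$reward_mean_form,
                            aggregate = cfg$reward_aggregate,
                            sampled = sampled)
  }

  state$t <- t
  state$rec_s[t] <- s
  state$rec_a[t] <- a
  state$rec_r[t] <- r
  state$rec_w[t, ] <- state$policy$weights
  state$rec_la[t] <- loss$l_a
  state$rec_lr[t] <- loss$l_r
  state$rec_ll[t] <- loss$l_lambda
  state
}

#' Run a complete simulation
#'
#' Executes the sequential loop: sample stimulus, sample action, sample
#' reward, append to memory, and (once the memory holds a full window)
#' re-estimate the policy weights by simplex minimization of the compromise
#' loss — repeated for `n_steps` steps. The run is fully reproducible from
#' `(config, seed)`.
#'
#' @param config a [sim_config()] object.
#' @return a `choice_trajectory`: a data frame with one row per step and
#'   columns `t`, `s`, `a`, `r`, `w_0 ... w_{2Nw-1}`, `loss_a`, `loss_r`,
#'   `loss_lambda`; the configuration is attached as attribute `config`.
#' @examples
#' \donttest{
#' traj <- run_simulation(sim_config(n_steps = 60, seed = 7))
#' head(traj)
#' }
#' @export
run_simulation <- function(config) {
  state <- sim_state(config)
  for (t in seq_len(config$n_steps)) state <- sim_step(state)
  nw2 <- ncol(state$rec_w)
  traj <- data.frame(
    t = seq_len(config$n_steps), s = state$rec_s, a = state$rec_a,
    r = state$rec_r
  )
  w <- as.data.frame(state$rec_w)
  names(w) <- paste0("w_", seq_len(nw2) - 1L)
  traj <- cbind(traj, w)
  traj$loss_a <- state$rec_la
  traj$loss_r <- state$rec_lr
  traj$loss_lambda <- state$rec_ll
  attr(traj, "config") <- config
  attr(traj, "n_update_failures") <- state$n_update_failures
  attr(traj, "n_weight_warnings") <- state$n_weight_warnings
  class(traj) <- c("choice_trajectory", "data.frame")
  traj
}

#' @export
print.choice_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<choice_trajectory> ", nrow(x), " steps, ",
      cfg$policy$n_actions, " actions, lambda = ", format(cfg$lambda),
      ", seed = ", cfg$seed, "\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  invisible(x)
}

#' Write / read a trajectory as CSV with a JSON config sidecar
#'
#' @param traj a `choice_trajectory`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `choice_trajectory` (with config restored when the sidecar
#'   is present).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "choice_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  cfg <- attr(traj, "config")
  jsonlite::write_json(config_to_list(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(df, "config") <- config_from_list(
      jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  class(df) <- c("choice_trajectory", "data.frame")
  df
}
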