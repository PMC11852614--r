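#' Centered running average of an action series
#'
#' @param actions numeric or integer series.
#' @param window odd window width (>= 1); edges use the available points.
#' @return numeric series of the same length.
#' @examples
#' running_average(c(1, 2, 1, 2, 1), window = 5)
#' @export
running_average <- function(actions, window = 5L) {
  if (length(actions) == 0L) stop("`actions` must be non-empty", call. = FALSE)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  if (window == 1L) return(as.numeric(actions))
  half <- window %/% 2L
  n <- length(actions)
  cs <- cumsum(c(0, actions))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

traj_n_actions <- function(traj, n_actions = NULL) {
  if (!is.null(n_actions)) return(as.integer(n_actions))
  cfg <- attr(traj, "config")
  if (!is.null(cfg)) return(cfg$policy$n_actions)
  max(traj$a)
}

traj_memory_length <- function(traj, memory_length = NULL) {
  if (!is.null(memory_length)) return(as.integer(memory_length))
  cfg <- attr(traj, "config")
  if (!is.null(cfg)) return(cfg$memory_length)
  20L
}

#' Last-occurrence (stoppage) times of each action
#'
#' For each action, the last step at which it was sampled. Actions still
#' being sampled within the final `memory_length` steps are flagged as
#' censored (winners); the stoppage time of a losing action is its
#' last-occurrence index.
#'
#' @param traj a `choice_trajectory` (or any data frame with columns `t`
#'   and `a`).
#' @param n_actions,memory_length overrides; taken from the trajectory's
#'   config when available.
#' @return data frame with columns `action`, `last_step` (NA if never
#'   sampled), `sampled`, `censored`.
#' @export
stoppage_times <- function(traj, n_actions = NULL, memory_length = NULL) {
  na <- traj_n_actions(traj, n_actions)
  delta <- traj_memory_length(traj, memory_length)
  T_ <- max(traj$t)
  last <- vapply(seq_len(na), function(k) {
    idx <- traj$t[traj$a == k]
    if (length(idx) == 0L) NA_integer_ else as.integer(max(idx))
  }, integer(1))
  data.frame(
    action = seq_len(na),
    last_step = last,
    sampled = !is.na(last),
    censored = !is.na(last) & last > T_ - delta
  )
}

#' Classifier thresholds for the behavior taxonomy
#'
#' @param overlap_separated pairwise stimulus-set overlap below which two
#'   actions count as discriminated.
#' @param overlap_intermingled overlap at or above which two actions count
#'   as intermingled.
#' @param window assessment window length in steps.
#' @param band_gap_factor a gap between consecutive sorted stimuli larger
#'   than this multiple of the median gap splits an action's stimuli into
#'   separate bands.
#' @param dominance_freq single-action sampling frequency above which a
#'   block counts as non-discriminating.
#' @param min_points minimum stimuli an action needs inside a window to be
#'   assessed.
#' @param stride step between consecutive sliding assessment windows.
#' @param min_windows number of discriminated windows required to call a
#'   discrimination phase.
#' @return a list of class `classifier_options`.
#' @export
classifier_options <- function(overlap_separated = 0.15,
                               overlap_intermingled = 0.5,
                               window = 100L, band_gap_factor = 4,
                               dominance_freq = 0.95, min_points = 3L,
                               stride = 10L, min_windows = 2L) {
  structure(
    list(overlap_separated = overlap_separated,
         overlap_intermingled = overlap_intermingled,
         window = as.integer(window),
         band_gap_factor = band_gap_factor,
         dominance_freq = dominance_freq,
         min_points = as.integer(min_points),
         stride = as.integer(stride),
         min_windows = as.integer(min_windows)),
    class = "classifier_options"
  )
}

# fraction of x lying inside the occupied stimulus bands of y, taken
# symmetrically (max of the two directions). Band-based rather than
# span-based so that a sandwich geometry — where one action's band nests
# inside the other's overall span but not inside its occupied bands — can
# still register as separated.
pair_overlap <- function(x, y, opts = classifier_options()) {
  frac_in <- function(a, b) {
    bands <- stimulus_bands(b, opts$band_gap_factor)
    keep <- vapply(bands, function(bd) {
      sum(b >= bd[1] & b <= bd[2]) >= opts$min_points
    }, logical(1))
    bands <- bands[keep]
    if (length(bands) == 0L) bands <- list(range(b))
    inside <- rep(FALSE, length(a))
    for (bd in bands) inside <- inside | (a >= bd[1] & a <= bd[2])
    mean(inside)
  }
  max(frac_in(x, y), frac_in(y, x))
}

# split a sorted stimulus set into bands at gaps larger than
# band_gap_factor * median gap; returns a list of numeric ranges
stimulus_bands <- function(x, band_gap_factor = 4) {
  x <- sort(x)
  n <- length(x)
  if (n < 3L) return(list(range(x)))
  gaps <- diff(x)
  med <- stats::median(gaps)
  if (med <= 0) med <- mean(gaps)
  cuts <- which(gaps > band_gap_factor * med)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  mapply(function(i, j) c(x[i], x[j]), starts, ends, SIMPLIFY = FALSE)
}

window_rows <- function(traj, end, window) {
  start <- max(min(traj$t), end - window + 1L)
  traj[traj$t >= start & traj$t <= end, , drop = FALSE]
}

# stimuli per action inside a window, restricted to assessable actions
action_stimuli <- function(rows, na, min_points) {
  out <- lapply(seq_len(na), function(k) rows$s[rows$a == k])
  names(out) <- as.character(seq_len(na))
  out[vapply(out, length, integer(1)) >= min_points]
}

all_separated <- function(groups, thresh, opts = classifier_options()) {
  ks <- names(groups)
  if (length(ks) < 2L) return(FALSE)
  for (i in seq_along(ks)) {
    for (j in seq_along(ks)) {
      if (j <= i) next
      if (pair_overlap(groups[[i]], groups[[j]], opts) >= thresh) {
        return(FALSE)
      }
    }
  }
  TRUE
}

max_overlap <- function(groups, opts = classifier_options()) {
  ks <- names(groups)
  if (length(ks) < 2L) return(NA_real_)
  m <- 0
  for (i in seq_along(ks)) {
    for (j in seq_along(ks)) {
      if (j <= i) next
      m <- max(m, pair_overlap(groups[[i]], groups[[j]], opts))
    }
  }
  m
}

window_direction <- function(rows, min_points = 3L) {
  s1 <- rows$s[rows$a == 1L]
  s2 <- rows$s[rows$a == 2L]
  if (length(s1) < min_points || length(s2) < min_points) return(NA_character_)
  m1 <- stats::median(s1)
  m2 <- stats::median(s2)
  if (m2 > m1) "action2_positive" else if (m2 < m1) "action1_positive"
  else "none"
}

# Does the banded structure of a set of action-stimulus groups interleave
# (some action owns two bands with another action's band between them)?
bands_interleave <- function(groups, opts) {
  bands <- list()
  for (k in names(groups)) {
    bs <- stimulus_bands(groups[[k]], opts$band_gap_factor)
    # ignore tiny outlier bands
    for (b in bs) {
      npts <- sum(groups[[k]] >= b[1] & groups[[k]] <= b[2])
      if (npts >= opts$min_points) {
        bands[[length(bands) + 1L]] <- list(owner = k, center = mean(b))
      }
    }
  }
  if (length(bands) <= length(groups)) return(FALSE)
  owners <- vapply(bands, `[[`, character(1), "owner")
  centers <- vapply(bands, `[[`, numeric(1), "center")
  owners <- owners[order(centers)]
  owners <- owners[c(TRUE, owners[-1L] != owners[-length(owners)])]
  anyDuplicated(owners) > 0L
}

# Assess one window: are all actions present and pairwise separated, do the
# stimulus bands of one action interleave with another's (sandwich), and
# which action owns the positive side. The sandwich pattern must hold in
# both halves of the window as well as the whole, so that a drifting
# threshold boundary (whose time-aggregated points mimic interleaved
# bands) is not mistaken for a stationary sandwich map.
assess_window <- function(rows, na, opts) {
  groups <- action_stimuli(rows, na, opts$min_points)
  present <- length(groups) == na
  separated <- present && all_separated(groups, opts$overlap_separated, opts)
  sandwich <- FALSE
  if (separated && bands_interleave(groups, opts)) {
    half <- rows$t <= rows$t[1L] + (rows$t[nrow(rows)] - rows$t[1L]) / 2
    g1 <- action_stimuli(rows[half, , drop = FALSE], na, opts$min_points)
    g2 <- action_stimuli(rows[!half, , drop = FALSE], na, opts$min_points)
    sandwich <- length(g1) == na && length(g2) == na &&
      bands_interleave(g1, opts) && bands_interleave(g2, opts)
  }
  list(present = present, separated = separated, sandwich = sandwich,
       direction = window_direction(rows, opts$min_points),
       max_overlap = max_overlap(groups, opts))
}

# Sliding assessment windows over the post-warmup record, up to the
# earliest losing-action stoppage.
scan_windows <- function(traj, na, delta, opts) {
  T_ <- max(traj$t)
  st <- stoppage_times(traj, n_actions = na, memory_length = delta)
  losers <- st[st$sampled & !st$censored, , drop = FALSE]
  stop_t <- if (nrow(losers) > 0L) min(losers$last_step) else T_
  first_end <- delta + opts$window
  ends <- if (stop_t >= first_end) {
    unique(c(seq(first_end, stop_t, by = opts$stride), stop_t))
  } else {
    stop_t  # truncated window: fewer than `window` post-warmup steps
  }
  list(
    stoppage = st, stop_t = stop_t, truncated = stop_t < first_end,
    assessments = lapply(ends, function(e) {
      rows <- window_rows(traj, e, opts$window)
      c(assess_window(rows, na, opts), list(end = e))
    })
  )
}

#' Classify the behavior of one simulation run
#'
#' Assigns exactly one taxonomy label to a trajectory. The run's
#' stimulus-action record is scanned with sliding assessment windows
#' (length `window`, stride `stride`) covering the post-warmup record up to
#' the earliest losing action's stoppage; a window counts as discriminated
#' when every action is present and all pairs of actions occupy stimulus
#' sets that overlap by less than `overlap_separated`. A run's class is the
#' pattern its discriminated windows reveal: because the winning action
#' invades the loser's stimulus band during the final takeover, the
#' interesting structure lives in the phase before stoppage, not in the
#' last steps.
#'
#' Labels, in precedence order:
#' \describe{
#'   \item{non_discriminating}{one action is sampled more than
#'     `dominance_freq` of the time in every post-warmup block, with no
#'     discrimination phase.}
#'   \item{switching}{discriminated windows occur with both dominance
#'     directions (an action's stimulus band moves from one side of the
#'     axis to the other).}
#'   \item{sandwich}{in at least `min_windows` discriminated windows, one
#'     action's stimuli form two or more bands with another action's band
#'     between them (band owners interleave along the stimulus axis).}
#'   \item{full_discrimination}{at least `min_windows` discriminated
#'     windows with a consistent direction.}
#'   \item{intermingled}{no discrimination phase before one action takes
#'     over.}
#' }
#'
#' @param traj a `choice_trajectory`.
#' @param opts a [classifier_options()] list.
#' @param n_actions,memory_length overrides; taken from the config when
#'   available.
#' @return a list of class `behavior_label` with elements `label` and
#'   `detail`.
#' @export
classify_run <- function(traj, opts = classifier_options(),
                         n_actions = NULL, memory_length = NULL) {
  na <- traj_n_actions(traj, n_actions)
  delta <- traj_memory_length(traj, memory_length)
  detail <- character(0)

  scan <- scan_windows(traj, na, delta, opts)
  if (scan$truncated) detail <- c(detail, "short-run")
  post <- traj[traj$t > delta, , drop = FALSE]

  disc <- Filter(function(a) a$separated, scan$assessments)
  n_disc <- length(disc)
  n_sand <- sum(vapply(disc, `[[`, logical(1), "sandwich"))
  # direction sequence from non-sandwich windows only: a sandwich map has
  # no meaningful left/right dominance (its medians tie), and the jitter
  # would masquerade as direction switching
  plain <- Filter(function(a) !a$sandwich, disc)
  dirs <- vapply(plain, `[[`, character(1), "direction")
  dirs <- dirs[!is.na(dirs) & dirs != "none"]

  label <- NULL

  # non-discriminating: one action dominates every post-warmup block and
  # no discrimination phase ever forms
  if (nrow(post) >= opts$window && n_disc == 0L) {
    winner <- as.integer(names(which.max(table(post$a))))
    nblock <- nrow(post) %/% opts$window
    block_dom <- vapply(seq_len(nblock), function(b) {
      idx <- ((b - 1L) * opts$window + 1L):(b * opts$window)
      mean(post$a[idx] == winner) > opts$dominance_freq
    }, logical(1))
    if (length(block_dom) > 0L && all(block_dom)) {
      label <- "non_discriminating"
      detail <- c(detail, paste0("dominant action ", winner))
    }
  }

  if (is.null(label) && n_sand >= opts$min_windows) {
    label <- "sandwich"
    detail <- c(detail, paste0(n_sand, "/", n_disc,
                               " windows with interleaved bands"))
  }

  # switching: both dominance directions supported by enough windows
  if (is.null(label) && na == 2L && length(dirs) > 0L) {
    n_pos <- sum(dirs == "action2_positive")
    n_neg <- sum(dirs == "action1_positive")
    if (n_pos >= opts$min_windows && n_neg >= opts$min_windows &&
        dirs[1L] != dirs[length(dirs)]) {
      label <- "switching"
      detail <- c(detail, paste0(dirs[1L], " -> ", dirs[length(dirs)]))
    }
  }

  if (is.null(label) && n_disc >= opts$min_windows) {
    label <- "full_discrimination"
    if (length(dirs) > 0L) detail <- c(detail, dirs[length(dirs)])
  }

  if (is.null(label)) {
    label <- "intermingled"
    mo <- vapply(scan$assessments, `[[`, numeric(1), "max_overlap")
    mo <- mo[!is.na(mo)]
    detail <- c(detail,
                if (length(mo) == 0L) "actions missing from windows"
                else paste0("min overlap ",
                            formatC(min(mo), digits = 2, format = "f")))
  }

  structure(list(label = label, detail = paste(detail, collapse = "; ")),
            class = "behavior_label")
}

#' @export
print.behavior_label <- function(x, ...) {
  cat("<behavior_label> ", x$label,
      if (nzchar(x$detail)) paste0(" (", x$detail, ")"), "\n", sep = "")
  invisible(x)
}

#' Which action ends up on the positive side of the stimulus axis
#'
#' The direction of the last discriminated assessment window (the
#' converged stimulus-action map just before one action takes over, or at
#' the end of the run when none does). When no window is discriminated,
#' falls back to comparing the median stimulus eliciting each of actions 1
#' and 2 in the final window; an action absent there is judged from the
#' window ending at its own stoppage.
#'
#' @inheritParams classify_run
#' @return `"action2_positive"`, `"action1_positive"`, or `"none"`.
#' @export
dominance_direction <- function(traj, opts = classifier_options(),
                                n_actions = NULL, memory_length = NULL) {
  na <- traj_n_actions(traj, n_actions)
  delta <- traj_memory_length(traj, memory_length)
  scan <- scan_windows(traj, na, delta, opts)
  disc <- Filter(function(a) a$separated, scan$assessments)
  dirs <- vapply(disc, `[[`, character(1), "direction")
  dirs <- dirs[!is.na(dirs) & dirs != "none"]
  if (length(dirs) > 0L) return(dirs[length(dirs)])

  st <- scan$stoppage
  win <- window_rows(traj, scan$stop_t, opts$window)
  med <- function(k) {
    x <- win$s[win$a == k]
    if (length(x) >= 1L) return(stats::median(x))
    # action absent from the final window: judge from the phase preceding
    # its own stoppage
    row <- st[st$action == k, ]
    if (!row$sampled) return(NA_real_)
    w2 <- window_rows(traj, row$last_step, opts$window)
    x <- w2$s[w2$a == k]
    if (length(x) >= 1L) stats::median(x) else NA_real_
  }
  m1 <- med(1L)
  m2 <- med(2L)
  if (is.na(m1) || is.na(m2) || m1 == m2) return("none")
  if (m2 > m1) "action2_positive" else "action1_positive"
}

#' Summarize one run
#'
#' @inheritParams classify_run
#' @return a list of class `run_summary`: stoppage table, behavior label,
#'   dominance direction, `discrimination_achieved` flag, and the sorted
#'   losing-action stoppage times.
#' @export
run_summary <- function(traj, opts = classifier_options()) {
  st <- stoppage_times(traj)
  behavior <- classify_run(traj, opts)
  losers <- st[st$sampled & !st$censored, , drop = FALSE]
  structure(
    list(stoppage = st,
         behavior = behavior,
         dominance = dominance_direction(traj, opts),
         discrimination_achieved =
           behavior$label %in% c("full_discrimination", "sandwich"),
         losing_stoppages = sort(losers$last_step),
         n_censored_actions = sum(st$censored)),
    class = "run_summary"
  )
}

#' Run a batch of independent simulations and aggregate their statistics
#'
#' Runs `n_runs` simulations with seeds `seed_base, seed_base + 1, ...`,
#' summarizes each, and aggregates: losing-action stoppage means and SDs,
#' behavior-class frequencies with binomial standard errors, dominance
#' directions, and (for three or more actions) the correlation and
#' regression of the second losing stoppage on the first.
#'
#' @param config a [sim_config()] template; each run gets its own seed.
#' @param n_runs number of independent runs (>= 2).
#' @param seed_base seed of the first run.
#' @param opts a [classifier_options()] list.
#' @param keep_trajectories keep the full trajectories in the result.
#' @return an object of class `batch_summary`.
#' @export
batch_run <- function(config, n_runs = 40L, seed_base = 1L,
                      opts = classifier_options(),
                      keep_trajectories = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 2L) {
    stop("`n_runs` must be an integer >= 2", call. = FALSE)
  }
  summaries <- vector("list", n_runs)
  trajectories <- if (keep_trajectories) vector("list", n_runs) else NULL
  seeds <- seed_base + seq_len(n_runs) - 1L
  failed <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- seeds[i]
    traj <- tryCatch(run_simulation(cfg), error = function(e) e)
    if (inherits(traj, "error")) {
      failed[i] <- TRUE
      message("run with seed ", seeds[i], " failed and was excluded: ",
              conditionMessage(traj))
      next
    }
    summaries[[i]] <- run_summary(traj, opts)
    if (keep_trajectories) trajectories[[i]] <- traj
  }
  out <- aggregate_batch(summaries[!failed], config, seeds[!failed],
                         if (keep_trajectories) trajectories[!failed])
  out$n_failed_runs <- sum(failed)
  out
}

aggregate_batch <- function(summaries, config, seeds,
                            trajectories = NULL) {
  n_runs <- length(summaries)
  first_stop <- vapply(summaries, function(x) {
    if (length(x$losing_stoppages) >= 1L) x$losing_stoppages[1L] else NA_real_
  }, numeric(1))
  second_stop <- vapply(summaries, function(x) {
    if (length(x$losing_stoppages) >= 2L) x$losing_stoppages[2L] else NA_real_
  }, numeric(1))
  labels <- vapply(summaries, function(x) x$behavior$label, character(1))
  dominance <- vapply(summaries, function(x) x$dominance, character(1))

  all_labels <- c("full_discrimination", "intermingled", "sandwich",
                  "switching", "non_discriminating")
  counts <- table(factor(labels, levels = all_labels))
  freq <- as.numeric(counts) / n_runs
  behavior_freq <- data.frame(
    label = all_labels, count = as.integer(counts),
    pct = 100 * freq, se_pct = 100 * sqrt(freq * (1 - freq) / n_runs)
  )

  regression <- NULL
  pairs_ok <- !is.na(first_stop) & !is.na(second_stop)
  if (sum(pairs_ok) >= 3L) {
    regression <- stoppage_regression(first_stop[pairs_ok],
                                      second_stop[pairs_ok])
  }

  structure(
    list(n_runs = n_runs, seeds = seeds, config = config,
         summaries = summaries, trajectories = trajectories,
         labels = labels, dominance = dominance,
         first_stoppage = first_stop, second_stoppage = second_stop,
         n_censored_runs = sum(is.na(first_stop)),
         mean_stoppage = mean(first_stop, na.rm = TRUE),
         sd_stoppage = stats::sd(first_stop, na.rm = TRUE),
         behavior_freq = behavior_freq,
         pct_action2_positive = 100 * mean(dominance == "action2_positive"),
         regression = regression),
    class = "batch_summary"
  )
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("<batch_summary> ", x$n_runs, " runs (", x$n_censored_runs,
      " with no stoppage)\n", sep = "")
  cat("  losing-action stoppage: mean ", formatC(x$mean_stoppage, digits = 1,
                                                 format = "f"),
      " +/- ", formatC(x$sd_stoppage, digits = 1, format = "f"),
      " (SD)\n", sep = "")
  bf <- x$behavior_freq[x$behavior_freq$count > 0L, ]
  for (i in seq_len(nrow(bf))) {
    cat("  ", bf$label[i], ": ", formatC(bf$pct[i], digits = 1, format = "f"),
        "% +/- ", formatC(bf$se_pct[i], digits = 1, format = "f"),
        "% (SE)\n", sep = "")
  }
  if (!is.null(x$regression)) {
    cat("  second vs first stoppage: r = ",
        formatC(x$regression$r, digits = 3, format = "f"),
        ", slope = ", formatC(x$regression$slope, digits = 2, format = "f"),
        ", intercept = ",
        formatC(x$regression$intercept, digits = 1, format = "f"),
        " (n = ", x$regression$n, ")\n", sep = "")
  }
  invisible(x)
}

#' Correlation and regression of second vs first losing stoppage times
#'
#' @param x either a `batch_summary` (its valid stoppage pairs are used) or
#'   a numeric vector of first stoppage times.
#' @param y numeric vector of second stoppage times when `x` is numeric.
#' @return list with `r` (Pearson correlation), `slope`, `intercept`
#'   (ordinary least squares of second on first), and `n`.
#' @export
stoppage_regression <- function(x, y = NULL) {
  if (inherits(x, "batch_summary")) {
    ok <- !is.na(x$first_stoppage) & !is.na(x$second_stoppage)
    y <- x$second_stoppage[ok]
    x <- x$first_stoppage[ok]
  }
  if (length(x) < 3L) {
    stop("need at least 3 stoppage-time pairs", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(x))
}

#' Sweep the reward-consistency trade-off weight
#'
#' Runs a batch at each lambda on the grid and tabulates, per lambda, the
#' percentage of runs in which action 2 ends up on the positive stimulus
#' side, and the mean losing-action stoppage time with its censoring count.
#'
#' @param config a [sim_config()] template.
#' @param lambda_grid numeric vector of lambda values in `[0, 1]`.
#' @param n_runs runs per lambda.
#' @param seed_base first seed; lambda index `i` uses seeds
#'   `seed_base + (i - 1) * n_runs + 0:(n_runs - 1)`.
#' @param opts a [classifier_options()] list.
#' @return data frame with columns `lambda`, `pct_action2_positive`, `se`,
#'   `mean_stoppage`, `sd_stoppage`, `n_censored`; the per-lambda
#'   `batch_summary` objects are attached as attribute `batches`.
#' @export
lambda_sweep <- function(config, lambda_grid, n_runs = 40L, seed_base = 1L,
                         opts = classifier_options()) {
  stopifnot(all(lambda_grid >= 0 & lambda_grid <= 1))
  batches <- vector("list", length(lambda_grid))
  rows <- vector("list", length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    cfg <- config
    cfg$lambda <- lambda_grid[i]
    b <- batch_run(cfg, n_runs = n_runs,
                   seed_base = seed_base + (i - 1L) * n_runs, opts = opts)
    batches[[i]] <- b
    p <- b$pct_action2_positive / 100
    rows[[i]] <- data.frame(
      lambda = lambda_grid[i],
      pct_action2_positive = b$pct_action2_positive,
      se = 100 * sqrt(p * (1 - p) / n_runs),
      mean_stoppage = b$mean_stoppage,
      sd_stoppage = b$sd_stoppage,
      n_censored = b$n_censored_runs
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "batches") <- batches
  out
}
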