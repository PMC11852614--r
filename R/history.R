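#' Bounded choice memory
#'
#' A FIFO buffer holding the most recent `capacity` (stimulus, action,
#' reward) triples. Appending beyond capacity evicts the oldest entry. The
#' capacity is the memory length of the consistency loss: only these
#' remembered pairs enter the per-step weight re-estimation.
#'
#' @param capacity integer memory length (>= 1).
#' @return an object of class `choice_history`.
#' @examples
#' h <- new_history(3)
#' h <- history_append(h, s = 0.2, a = 1L, r = 0.5)
#' history_length(h)
#' @export
new_history <- function(capacity) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1L) {
    stop("`capacity` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(s = numeric(0), a = integer(0), r = numeric(0), capacity = capacity),
    class = "choice_history"
  )
}

#' @rdname new_history
#' @param history a `choice_history`.
#' @param s,a,r the stimulus, action and reward to append.
#' @export
history_append <- function(history, s, a, r) {
  stopifnot(inherits(history, "choice_history"))
  history$s <- c(history$s, as.numeric(s))
  history$a <- c(history$a, as.integer(a))
  history$r <- c(history$r, as.numeric(r))
  n <- length(history$s)
  if (n > history$capacity) {
    keep <- (n - history$capacity + 1L):n
    history$s <- history$s[keep]
    history$a <- history$a[keep]
    history$r <- history$r[keep]
  }
  history
}

#' @rdname new_history
#' @export
history_length <- function(history) {
  stopifnot(inherits(history, "choice_history"))
  length(history$s)
}

#' @rdname new_history
#' @export
history_full <- function(history) {
  history_length(history) == history$capacity
}

#' @export
print.choice_history <- function(x, ...) {
  cat("<choice_history> ", history_length(x), "/", x$capacity,
      " entries\n", sep = "")
  invisible(x)
}

# Build a choice_history directly from parallel vectors (keeps the last
# `capacity` entries). Used by tests and the analysis layer.
#' @rdname new_history
#' @export
as_history <- function(s, a, r = NULL, capacity = length(s)) {
  if (is.null(r)) r <- rep(0, length(s))
  stopifnot(length(s) == length(a), length(s) == length(r))
  h <- new_history(capacity)
  n <- length(s)
  keep <- if (n > capacity) (n - capacity + 1L):n else seq_len(n)
  h$s <- as.numeric(s[keep])
  h$a <- as.integer(a[keep])
  h$r <- as.numeric(r[keep])
  h
}
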