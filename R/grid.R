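# Grid-task selection logs and achieved-bitrate evaluation.

#' Grid-task selection log
#'
#' Sequence of target-selection events on the 6x6 grid task. Each event is
#' a timestamp (seconds from session start, strictly increasing) and an
#' outcome: `correct`, `incorrect`, or `timeout` (no selection within the
#' allowed time).
#'
#' @param time_s strictly increasing event times (seconds).
#' @param outcome per-event outcome in `{"correct","incorrect","timeout"}`.
#' @param duration session duration `T` in seconds (default: time of the
#'   last event).
#' @param n_targets number of selectable targets (default 36).
#' @return an object of class `selection_log`.
#' @export
selection_log <- function(time_s, outcome, duration = NULL, n_targets = 36L) {
  time_s <- as.numeric(time_s)
  outcome <- as.character(outcome)
  if (length(time_s) != length(outcome))
    stop("`time_s` and `outcome` must have the same length", call. = FALSE)
  if (length(time_s) && any(diff(time_s) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  bad <- setdiff(unique(outcome), c("correct", "incorrect", "timeout"))
  if (length(bad))
    stop("outcomes must be 'correct', 'incorrect' or 'timeout'", call. = FALSE)
  if (is.null(duration)) duration <- if (length(time_s)) max(time_s) else 0
  if (length(time_s) && duration < max(time_s))
    stop("`duration` must cover all events", call. = FALSE)
  structure(list(time_s = time_s, outcome = outcome,
                 duration = as.numeric(duration),
                 n_targets = as.integer(n_targets)),
            class = "selection_log")
}

#' @export
print.selection_log <- function(x, ...) {
  cat(sprintf("<selection_log> %d events over %.1f s (%d correct, %d incorrect, %d timeout)\n",
              length(x$time_s), x$duration,
              sum(x$outcome == "correct"), sum(x$outcome == "incorrect"),
              sum(x$outcome == "timeout")))
  invisible(x)
}

#' Achieved bitrate of a grid-task session
#'
#' With `c` correct and `l` incorrect selections in `T` seconds on an
#' `n_targets` grid, the achieved bitrate is
#' \deqn{B = \max(0, c - \ell)\,\log_2(n_{targets}) / T}
#' bits per second: every incorrect selection cancels one correct
#' selection, so a 50% success rate conveys zero information. Timeouts
#' contribute only to `T`.
#'
#' @param log a [selection_log()].
#' @return bitrate in bits per second.
#' @export
grid_bitrate <- function(log) {
  stopifnot(inherits(log, "selection_log"))
  if (log$duration <= 0) stop("session duration must be positive", call. = FALSE)
  cc <- sum(log$outcome == "correct")
  ll <- sum(log$outcome == "incorrect")
  max(0, cc - ll) * log2(log$n_targets) / log$duration
}

#' Selection success rate
#'
#' Fraction of events ending in a correct selection, counting timeouts as
#' failures: `c / (c + l + timeouts)`.
#'
#' @param log a [selection_log()].
#' @return fraction in `[0, 1]`.
#' @export
success_rate <- function(log) {
  stopifnot(inherits(log, "selection_log"))
  n <- length(log$time_s)
  if (n == 0L || all(log$outcome == "timeout"))
    stop("need at least one non-timeout event", call. = FALSE)
  sum(log$outcome == "correct") / n
}

#' Target acquisition time statistics
#'
#' Acquire times are the inter-event intervals (the first interval runs
#' from session start) minus the post-selection lockout; timeout events
#' are excluded from the summary.
#'
#' @param log a [selection_log()].
#' @param lockout lockout duration in seconds (default 0.200).
#' @return list with `times` (per-selection acquire times, seconds),
#'   `mean`, `median`, `sd`, `n`.
#' @export
acquire_time_stats <- function(log, lockout = 0.200) {
  stopifnot(inherits(log, "selection_log"))
  if (!length(log$time_s)) stop("empty log", call. = FALSE)
  iv <- diff(c(0, log$time_s))
  # the first event has no preceding lockout
  lk <- c(0, rep(lockout, length(iv) - 1))
  at <- iv - lk
  keep <- log$outcome != "timeout"
  at <- at[keep]
  if (!length(at)) stop("need at least one non-timeout event", call. = FALSE)
  list(times = at, mean = mean(at), median = stats::median(at),
       sd = stats::sd(at), n = length(at))
}
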