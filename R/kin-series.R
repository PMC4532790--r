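#' Per-bin cursor kinematics
#'
#' 2D position (cm) and 2D velocity (cm/s) on the same time base as a paired
#' [spike_counts()] object, with optional per-bin epoch, trial and condition
#' labels used for hold/reach analyses and condition averaging.
#'
#' @param pos 2 x K matrix of positions (cm).
#' @param vel 2 x K matrix of velocities (cm/s).
#' @param bin_width bin width in seconds.
#' @param epoch optional per-bin labels in `{"reach","hold","other"}`.
#' @param trial optional integer per-bin trial ids.
#' @param condition optional per-bin condition (target) labels.
#' @return an object of class `kin_series`.
#' @export
kin_series <- function(pos, vel, bin_width = 0.015, epoch = NULL,
                       trial = NULL, condition = NULL) {
  pos <- as.matrix(pos); vel <- as.matrix(vel)
  if (nrow(pos) != 2L || nrow(vel) != 2L)
    stop("`pos` and `vel` must be 2 x K matrices", call. = FALSE)
  K <- ncol(pos)
  if (ncol(vel) != K)
    stop("`pos` and `vel` must share the same number of bins", call. = FALSE)
  check_len <- function(v, what) {
    if (!is.null(v) && length(v) != K)
      stop(sprintf("`%s` must have one entry per bin", what), call. = FALSE)
    v
  }
  if (!is.null(epoch)) {
    epoch <- as.character(check_len(epoch, "epoch"))
    bad <- setdiff(unique(epoch), c("reach", "hold", "other"))
    if (length(bad))
      stop("`epoch` labels must be 'reach', 'hold' or 'other'", call. = FALSE)
  }
  structure(list(pos = pos, vel = vel, bin_width = bin_width,
                 epoch = epoch,
                 trial = check_len(trial, "trial"),
                 condition = check_len(condition, "condition")),
            class = "kin_series")
}

#' @export
print.kin_series <- function(x, ...) {
  cat(sprintf("<kin_series> %d bins @ %g ms%s\n", ncol(x$pos),
              1000 * x$bin_width,
              if (!is.null(x$epoch)) " (labelled)" else ""))
  invisible(x)
}

# Stack a kin_series into the 4 x K regression target [pos; vel].
kin_matrix <- function(X) {
  if (inherits(X, "kin_series")) rbind(X$pos, X$vel) else as.matrix(X)
}

#' Epoch mask for hold/reach analyses
#'
#' @param hold_bins,reach_bins disjoint integer vectors of bin indices.
#' @return an object of class `epoch_mask`.
#' @export
epoch_mask <- function(hold_bins, reach_bins) {
  hold_bins <- as.integer(hold_bins); reach_bins <- as.integer(reach_bins)
  if (length(intersect(hold_bins, reach_bins)))
    stop("hold and reach bin sets must be disjoint", call. = FALSE)
  structure(list(hold_bins = hold_bins, reach_bins = reach_bins),
            class = "epoch_mask")
}

#' Build the standard hold/reach epoch mask from labelled kinematics
#'
#' Hold bins are taken from 100 ms after hold initiation to 150 ms before
#' hold completion; reach bins are all bins labelled `"reach"`.
#'
#' @param X a labelled [kin_series()].
#' @return an [epoch_mask()].
#' @export
epoch_mask_from_labels <- function(X) {
  if (is.null(X$epoch)) stop("kin_series has no epoch labels", call. = FALSE)
  dt <- X$bin_width
  trim_lead <- ceiling(0.100 / dt)   # drop first 100 ms of each hold
  trim_tail <- ceiling(0.150 / dt)   # drop last 150 ms of each hold
  is_hold <- X$epoch == "hold"
  runs <- rle(is_hold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hold_bins <- integer(0)
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    a <- starts[i] + trim_lead
    b <- ends[i] - trim_tail
    if (a <= b) hold_bins <- c(hold_bins, a:b)
  }
  epoch_mask(hold_bins, which(X$epoch == "reach"))
}
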