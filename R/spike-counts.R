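#' Binned spike counts
#'
#' Container for a channels-by-bins matrix of binned threshold-crossing
#' counts on a contiguous time base. Bins are non-overlapping, of width
#' `bin_width` seconds, and indexed `k = 1..K` (bin `k` covers the half-open
#' interval `[(k-1)*bin_width, k*bin_width)`).
#'
#' Real recordings hold non-negative integer counts; the Gaussian
#' observation model, and the synthetic generator in its Gaussian-emission
#' mode, operate on real-valued observations in the same container. Strict
#' integer validation is therefore opt-in via `integer_counts`.
#'
#' @param counts numeric matrix, channels x bins.
#' @param bin_width bin width in seconds (default 0.015).
#' @param channel_ids optional character vector of channel labels.
#' @param integer_counts if `TRUE`, require non-negative integer entries.
#' @return an object of class `spike_counts`.
#' @export
spike_counts <- function(counts, bin_width = 0.015, channel_ids = NULL,
                         integer_counts = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number", call. = FALSE)
  if (anyNA(counts))
    stop("`counts` must not contain missing values (contiguous time base)",
         call. = FALSE)
  if (integer_counts) {
    if (any(counts < 0) || any(counts != round(counts)))
      stop("`counts` must be non-negative integers", call. = FALSE)
  }
  if (is.null(channel_ids)) {
    channel_ids <- if (!is.null(rownames(counts))) rownames(counts)
                   else sprintf("ch%03d", seq_len(nrow(counts)))
  }
  if (length(channel_ids) != nrow(counts))
    stop("`channel_ids` length must equal the number of channels",
         call. = FALSE)
  structure(list(counts = counts, bin_width = bin_width,
                 channel_ids = as.character(channel_ids)),
            class = "spike_counts")
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf("<spike_counts> %d channels x %d bins @ %g ms\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$bin_width))
  invisible(x)
}

#' @export
dim.spike_counts <- function(x) dim(x$counts)

# Coerce either a spike_counts object or a bare matrix to a numeric matrix.
as_count_matrix <- function(Y) {
  if (inherits(Y, "spike_counts")) Y$counts else as.matrix(Y)
}

n_channels <- function(Y) nrow(as_count_matrix(Y))
n_bins <- function(Y) ncol(as_count_matrix(Y))
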