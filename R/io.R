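# Delimited-text session files and JSON model serialization.

FORMAT_VERSION <- "1.0"

#' Write a session (spike counts + kinematics) as delimited text
#'
#' Writes `<prefix>.counts.tsv` (rows = channels, columns = bins, with
#' `#`-prefixed header lines declaring `bin_width` and `channel_ids`) and
#' `<prefix>.kin.tsv` (one row per bin: `bin`, `pos_x`, `pos_y`, `vel_x`,
#' `vel_y`, and label columns when present). Counts round-trip exactly;
#' kinematics are written with 17 significant digits (double precision).
#'
#' @param prefix path prefix for the two files.
#' @param Y a [spike_counts()].
#' @param X a [kin_series()] (optional).
#' @return (invisibly) the written file paths.
#' @export
write_session <- function(prefix, Y, X = NULL) {
  stopifnot(inherits(Y, "spike_counts"))
  cf <- paste0(prefix, ".counts.tsv")
  con <- file(cf, "w")
  writeLines(c(sprintf("#format_version\t%s", FORMAT_VERSION),
               sprintf("#bin_width\t%.17g", Y$bin_width),
               sprintf("#channel_ids\t%s", paste(Y$channel_ids, collapse = ","))),
             con)
  utils::write.table(format(Y$counts, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  paths <- cf
  if (!is.null(X)) {
    stopifnot(inherits(X, "kin_series"))
    kf <- paste0(prefix, ".kin.tsv")
    df <- data.frame(bin = seq_len(ncol(X$pos)),
                     pos_x = X$pos[1, ], pos_y = X$pos[2, ],
                     vel_x = X$vel[1, ], vel_y = X$vel[2, ])
    if (!is.null(X$epoch)) df$epoch <- X$epoch
    if (!is.null(X$trial)) df$trial <- X$trial
    if (!is.null(X$condition)) df$condition <- X$condition
    con <- file(kf, "w")
    writeLines(sprintf("#bin_width\t%.17g", X$bin_width), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, kf)
  }
  invisible(paths)
}

read_header <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- list()
  for (i in hdr_idx) {
    parts <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    hdr[[parts[1]]] <- if (length(parts) > 1) parts[2] else ""
  }
  list(header = hdr, body = lines[setdiff(seq_along(lines), hdr_idx)],
       body_lines = setdiff(seq_along(lines), hdr_idx))
}

#' Read a session written by [write_session()]
#'
#' @param prefix path prefix used when writing.
#' @param integer_counts require the counts file to hold non-negative
#'   integers (errors name the offending line).
#' @return list with `Y` ([spike_counts()]) and `X` ([kin_series()] or
#'   `NULL` when no kinematics file exists).
#' @export
read_session <- function(prefix, integer_counts = FALSE) {
  cf <- paste0(prefix, ".counts.tsv")
  if (!file.exists(cf)) stop(sprintf("no counts file at '%s'", cf),
                             call. = FALSE)
  h <- read_header(cf)
  if (is.null(h$header$bin_width))
    stop(sprintf("%s: missing bin_width header", cf), call. = FALSE)
  bw <- as.numeric(h$header$bin_width)
  rows <- strsplit(h$body, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) > 1L) {
    bad <- h$body_lines[which(widths != widths[1])[1]]
    stop(sprintf("%s: ragged row at line %d", cf, bad), call. = FALSE)
  }
  counts <- matrix(NA_real_, length(rows), widths[1])
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v))
      stop(sprintf("%s: non-numeric entry at line %d", cf, h$body_lines[i]),
           call. = FALSE)
    if (integer_counts && (any(v < 0) || any(v != round(v))))
      stop(sprintf("%s: non-integer counts at line %d", cf, h$body_lines[i]),
           call. = FALSE)
    counts[i, ] <- v
  }
  ids <- if (!is.null(h$header$channel_ids))
    strsplit(h$header$channel_ids, ",", fixed = TRUE)[[1]] else NULL
  Y <- spike_counts(counts, bin_width = bw, channel_ids = ids,
                    integer_counts = integer_counts)
  kf <- paste0(prefix, ".kin.tsv")
  X <- NULL
  if (file.exists(kf)) {
    hk <- read_header(kf)
    if (is.null(hk$header$bin_width))
      stop(sprintf("%s: missing bin_width header", kf), call. = FALSE)
    df <- utils::read.table(text = paste(hk$body, collapse = "\n"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    X <- kin_series(rbind(df$pos_x, df$pos_y), rbind(df$vel_x, df$vel_y),
                    bin_width = as.numeric(hk$header$bin_width),
                    epoch = df$epoch, trial = df$trial,
                    condition = df$condition)
    if (ncol(X$pos) != ncol(Y$counts))
      stop("counts and kinematics disagree on the number of bins",
           call. = FALSE)
  }
  list(Y = Y, X = X)
}

#' Write / read a selection log as delimited text
#'
#' Two-column TSV (`time_s`, `outcome`) with `#`-prefixed `duration` and
#' `n_targets` headers.
#'
#' @param log a [selection_log()].
#' @param path file path.
#' @return `write_selection_log`: invisibly, the path.
#' @export
write_selection_log <- function(log, path) {
  stopifnot(inherits(log, "selection_log"))
  con <- file(path, "w")
  writeLines(c(sprintf("#duration\t%.17g", log$duration),
               sprintf("#n_targets\t%d", log$n_targets)), con)
  utils::write.table(data.frame(time_s = sprintf("%.17g", log$time_s),
                                outcome = log$outcome),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_selection_log
#' @export
read_selection_log <- function(path) {
  h <- read_header(path)
  df <- utils::read.table(text = paste(h$body, collapse = "\n"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  selection_log(df$time_s, df$outcome,
                duration = as.numeric(h$header$duration),
                n_targets = as.integer(h$header$n_targets))
}

# ---- JSON model serialization ----

# Doubles are serialized as 17-significant-digit strings: that many
# digits uniquely identify an IEEE double, so round trips are bit-exact
# (jsonlite's numeric path can lose the last ulp).
num_ser <- function(x) sprintf("%.17g", as.numeric(x))
num_deser <- function(x) as.numeric(unlist(x))
mat_ser <- function(m) list(dim = dim(m), data = num_ser(m))
mat_deser <- function(x) matrix(num_deser(x$data), x$dim[1], x$dim[2])

lds_ser <- function(p) {
  list(M = mat_ser(p$M), P = mat_ser(p$P), Ncov = mat_ser(p$Ncov),
       R = mat_ser(p$R), pi1 = num_ser(p$pi1), S1 = mat_ser(p$S1),
       d = p$d, N = p$N, bin_width = num_ser(p$bin_width))
}
lds_deser <- function(x) {
  lds_params(mat_deser(x$M), mat_deser(x$P), mat_deser(x$Ncov),
             mat_deser(x$R), num_deser(x$pi1), mat_deser(x$S1),
             bin_width = num_deser(x$bin_width), check_diagonal = FALSE)
}

#' Save / load LDS parameters as JSON
#'
#' Structured-text serialization with explicit field names, shapes,
#' `bin_width` and a format-version string; full double precision.
#'
#' @param params an [lds_params()].
#' @param path file path.
#' @return `load_lds`: the restored [lds_params()].
#' @export
save_lds <- function(params, path) {
  stopifnot(inherits(params, "lds_params"))
  obj <- c(list(format_version = FORMAT_VERSION, object = "lds_params"),
           lds_ser(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lds
#' @export
load_lds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format_version) || !identical(x$object, "lds_params"))
    stop("not an lds_params file", call. = FALSE)
  lds_deser(x)
}

#' Save / load a fitted decoder as JSON
#'
#' Serializes any decoder model to structured text tagged with its
#' `decoder_type` and a format-version string; `load_model` dispatches on
#' the tag and restores the model to full precision.
#'
#' @param model a fitted decoder.
#' @param path file path.
#' @return `load_model`: the restored decoder.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  type <- model$decoder_type
  fields <- switch(type,
    ndf = list(lds = lds_ser(model$lds), L = mat_ser(model$L),
               bias = num_ser(model$bias),
               steady_gain = mat_ser(model$steady_gain)),
    ole = list(L = mat_ser(model$L), bias = num_ser(model$bias),
               kernel_sd = num_ser(model$kernel_sd)),
    wf = list(L_blocks = stats::setNames(lapply(model$L_blocks, mat_ser),
                                         paste0("lag", seq_along(model$L_blocks) - 1L)),
              bias = num_ser(model$bias), p = model$p,
              lam = num_ser(model$lam)),
    kkf = list(A = mat_ser(model$A), C = mat_ser(model$C),
               W = mat_ser(model$W), Q = mat_ser(model$Q),
               velocity_only = model$velocity_only),
    pcsmooth = list(components = mat_ser(model$components),
                    center = num_ser(model$center),
                    L = mat_ser(model$L), bias = num_ser(model$bias),
                    kernel_sd = num_ser(model$kernel_sd),
                    n_components = model$n_components),
    stop(sprintf("unknown decoder_type '%s'", type), call. = FALSE))
  obj <- c(list(format_version = FORMAT_VERSION, decoder_type = type), fields)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format_version))
    stop("missing format_version: not a decoder file", call. = FALSE)
  if (!identical(x$format_version, FORMAT_VERSION))
    stop(sprintf("unsupported format_version '%s'", x$format_version),
         call. = FALSE)
  type <- x$decoder_type
  need <- function(f) {
    if (is.null(x[[f]]))
      stop(sprintf("corrupted decoder file: missing field '%s'", f),
           call. = FALSE)
    x[[f]]
  }
  switch(type,
    ndf = new_decoder("ndf", list(
      lds = lds_deser(need("lds")), L = mat_deser(need("L")),
      bias = num_deser(need("bias")),
      steady_gain = mat_deser(need("steady_gain")), em_trace = NULL)),
    ole = new_decoder("ole", list(
      L = mat_deser(need("L")), bias = num_deser(need("bias")),
      kernel_sd = num_deser(need("kernel_sd")))),
    wf = new_decoder("wf", list(
      L_blocks = unname(lapply(need("L_blocks"), mat_deser)),
      bias = num_deser(need("bias")), p = as.integer(need("p")),
      lam = num_deser(need("lam")))),
    kkf = new_decoder("kkf", list(
      A = mat_deser(need("A")), C = mat_deser(need("C")),
      W = mat_deser(need("W")), Q = mat_deser(need("Q")),
      velocity_only = isTRUE(x$velocity_only))),
    pcsmooth = new_decoder("pcsmooth", list(
      components = mat_deser(need("components")),
      center = num_deser(need("center")), L = mat_deser(need("L")),
      bias = num_deser(need("bias")),
      kernel_sd = num_deser(need("kernel_sd")),
      n_components = as.integer(need("n_components")))),
    stop(sprintf("unknown decoder_type '%s'", type), call. = FALSE))
}
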