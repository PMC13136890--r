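# Per-read, per-position signal feature matrices (dwell time, current mean,
# current SD) as produced by signal-to-reference aligners, plus the
# preprocessing used before energy-distance calculation: log-transform of
# dwell and per-position robust (median/MAD) scaling pooled over both samples.

#' Construct a per-read signal matrix
#'
#' @param df A data.frame with columns `read_id`, `position` (1-based),
#'   `dwell` (> 0, unit-agnostic but uniform per file), `mean` (normalized
#'   current), `sd` (>= 0). At most one record per (read, position).
#' @param ref_length Reference length; defaults to the maximum observed
#'   position.
#' @return A data.frame of class `signal_matrix` with a `ref_length`
#'   attribute.
#' @export
signal_matrix <- function(df, ref_length = NULL) {
  need <- c("read_id", "position", "dwell", "mean", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("signal matrix missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[, need]
  df$read_id <- as.character(df$read_id)
  df$position <- as.integer(df$position)
  bad <- which(!is.finite(df$dwell) | df$dwell <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive dwell in rows: %s",
                 paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$sd) | df$sd < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-finite sd in rows: %s",
                 paste(utils::head(bad, 10), collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(df$read_id, df$position)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (read_id, position) records, e.g. row %d",
                 which(duplicated(key))[1]), call. = FALSE)
  }
  if (is.null(ref_length)) ref_length <- max(df$position, 0L)
  if (length(df$position) && max(df$position) > ref_length) {
    stop("positions exceed ref_length", call. = FALSE)
  }
  class(df) <- c("signal_matrix", "data.frame")
  attr(df, "ref_length") <- as.integer(ref_length)
  df
}

#' Read / write the signal TSV dialect
#'
#' Tab-separated with header `read_id, position, dwell, mean, sd`; one record
#' per row, positions 1-based. Malformed rows are rejected with their row
#' numbers.
#'
#' @param path File path.
#' @param ref_length Reference length attached to the matrix (default: max
#'   observed position).
#' @param sm A [signal_matrix()].
#' @return `read_signal_tsv()` a `signal_matrix`; `write_signal_tsv()` the
#'   path invisibly.
#' @export
read_signal_tsv <- function(path, ref_length = NULL) {
  .check_file(path, "signal TSV")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "position", "dwell", "mean", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("signal TSV missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  signal_matrix(df, ref_length = ref_length)
}

#' @rdname read_signal_tsv
#' @export
write_signal_tsv <- function(sm, path) {
  stopifnot(inherits(sm, "signal_matrix"))
  utils::write.table(as.data.frame(sm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Retain reads with near-full reference coverage
#'
#' Keeps reads whose covered-position fraction of the reference is at least
#' `min_frac` (default 0.9, mirroring the "coverage above 90%" filter used
#' before signal analysis).
#'
#' @param sm A [signal_matrix()].
#' @param min_frac Minimum covered fraction in (0, 1].
#' @return A filtered `signal_matrix`; the number of reads in/out is recorded
#'   in attributes `reads_in` / `reads_out`.
#' @export
coverage_filter <- function(sm, min_frac = 0.9) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1) {
    stop("`min_frac` must lie in (0, 1]", call. = FALSE)
  }
  L <- attr(sm, "ref_length")
  cov <- table(sm$read_id)
  keep_ids <- names(cov)[as.numeric(cov) / L >= min_frac]
  out <- sm[sm$read_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sm)
  attr(out, "ref_length") <- L
  attr(out, "reads_in") <- length(cov)
  attr(out, "reads_out") <- length(keep_ids)
  out
}

#' Log-transform dwell and robustly scale both samples per position
#'
#' Dwell times are replaced by their natural logarithm; then each channel
#' (log-dwell, current mean, current SD) is scaled per reference position as
#' `(x - median) / (1.4826 * MAD)`, with the median and MAD pooled over both
#' samples at that position so that between-sample location differences — the
#' very signal being detected — survive scaling. Channels with zero MAD fall
#' back to centering only; affected (position, channel) pairs are recorded in
#' the `mad_fallback` attribute of each returned matrix.
#'
#' @param modified,control Non-empty [signal_matrix()]s over the same
#'   reference.
#' @return A list with scaled `modified` and `control` signal matrices.
#' @export
preprocess_signals <- function(modified, control) {
  stopifnot(inherits(modified, "signal_matrix"),
            inherits(control, "signal_matrix"))
  if (!nrow(modified) || !nrow(control)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  modified$dwell <- log(modified$dwell)
  control$dwell <- log(control$dwell)

  pos_all <- sort(unique(c(modified$position, control$position)))
  fallback <- list()
  for (ch in c("dwell", "mean", "sd")) {
    pooled <- c(modified[[ch]], control[[ch]])
    pos <- c(modified$position, control$position)
    med <- tapply(pooled, factor(pos, levels = pos_all), stats::median)
    madv <- tapply(pooled, factor(pos, levels = pos_all), stats::mad)
    scale_one <- function(x, p) {
      m <- as.numeric(med[as.character(p)])
      s <- as.numeric(madv[as.character(p)])
      ifelse(s > 0, (x - m) / s, x - m)
    }
    modified[[ch]] <- scale_one(modified[[ch]], modified$position)
    control[[ch]] <- scale_one(control[[ch]], control$position)
    fb <- pos_all[!is.na(madv) & madv == 0]
    if (length(fb)) fallback[[ch]] <- fb
  }
  if (length(fallback)) {
    warning(sprintf(
      "MAD = 0 fallback (centering only) at %d (position, channel) pairs",
      sum(lengths(fallback))), call. = FALSE)
  }
  attr(modified, "mad_fallback") <- fallback
  attr(control, "mad_fallback") <- fallback
  attr(modified, "preprocessed") <- TRUE
  attr(control, "preprocessed") <- TRUE
  list(modified = modified, control = control)
}

#' Windowed 9-dimensional feature vectors at a center position
#'
#' For a 3-nt window centered at `center`, each read with records at all of
#' `center - 1`, `center`, `center + 1` contributes one 9-dimensional vector
#' ordered (log-dwell, mean, sd) at `center - 1`, then `center`, then
#' `center + 1`. Reads missing any window position (e.g. through a deletion)
#' are excluded from this window only. Edge centers have no 3-nt window and
#' return an undefined marker.
#'
#' @param sm A (preprocessed) [signal_matrix()].
#' @param center Center position, `2 <= center <= ref_length - 1`.
#' @return A list of class `sample_features` with elements `center`,
#'   `vectors` (n x 9 matrix; `NULL` when undefined), `read_ids` and
#'   `defined`.
#' @export
window_features <- function(sm, center) {
  stopifnot(inherits(sm, "signal_matrix"))
  L <- attr(sm, "ref_length")
  if (center < 2L || center > L - 1L) {
    return(structure(list(center = center, vectors = NULL,
                          read_ids = character(), defined = FALSE),
                     class = "sample_features"))
  }
  win <- sm[sm$position %in% (center - 1L):(center + 1L), , drop = FALSE]
  cnt <- table(win$read_id)
  ids <- names(cnt)[cnt == 3L]
  if (!length(ids)) {
    return(structure(list(center = center,
                          vectors = matrix(numeric(0), 0, 9),
                          read_ids = character(), defined = TRUE),
                     class = "sample_features"))
  }
  win <- win[win$read_id %in% ids, , drop = FALSE]
  win <- win[order(win$read_id, win$position), , drop = FALSE]
  # rows are (center-1, center, center+1) triples per read after ordering
  vec <- matrix(t(as.matrix(win[, c("dwell", "mean", "sd")])),
                ncol = 9, byrow = TRUE)
  colnames(vec) <- as.vector(outer(c("dwell", "mean", "sd"),
                                   c("m1", "c0", "p1"),
                                   function(a, b) paste(a, b, sep = "_")))
  structure(list(center = center, vectors = vec,
                 read_ids = sort(ids), defined = TRUE),
            class = "sample_features")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d records, %d reads, ref_length %d\n",
              nrow(x), length(unique(x$read_id)), attr(x, "ref_length")))
  NextMethod()
}
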