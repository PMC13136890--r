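# Modification-call pileups in a bedMethyl-like dialect and their
# summarization. The consequential convention: percent_modified uses the
# canonical-call denominator — only reads basecalled as the relevant canonical
# base count, so n_mod / (n_mod + n_canonical); deletions, miscalls and
# filtered reads (n_other) never enter the ratio.

#' Construct a modification-call pileup
#'
#' @param df A data.frame with columns `position` (1-based), `mod_code`,
#'   `n_mod`, `n_canonical`, `n_other`; an optional `ref_base` column is
#'   carried through.
#' @param sample Sample label.
#' @return A data.frame of class `mod_pileup` with added `n_valid`
#'   (`n_mod + n_canonical`) and `percent_modified` (`NA` where `n_valid`
#'   is 0).
#' @export
mod_pileup <- function(df, sample = "") {
  need <- c("position", "mod_code", "n_mod", "n_canonical", "n_other")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("mod pileup missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (k in c("n_mod", "n_canonical", "n_other")) {
    if (any(df[[k]] < 0)) {
      stop(sprintf("negative counts in `%s`", k), call. = FALSE)
    }
    df[[k]] <- as.integer(df[[k]])
  }
  df$position <- as.integer(df$position)
  key <- paste(df$position, df$mod_code)
  if (anyDuplicated(key)) {
    stop("duplicate (position, mod_code) rows", call. = FALSE)
  }
  df$n_valid <- df$n_mod + df$n_canonical
  df$percent_modified <- ifelse(df$n_valid > 0,
                                100 * df$n_mod / df$n_valid, NA_real_)
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mod_pileup", "data.frame")
  attr(df, "sample") <- sample
  df
}

#' Read / write the bedMethyl-like dialect
#'
#' Minimal 10-column tab-separated subset (no header): chrom, start, end
#' (0-based half-open, length-1 intervals), mod code, score (valid coverage
#' capped at 1000), strand (fixed `+` for single-stranded RNA references),
#' n_valid, n_mod, n_canonical, n_other. The reader converts coordinates to
#' 1-based.
#'
#' @param mp A [mod_pileup()].
#' @param path File path.
#' @param chrom Reference name used on output.
#' @param sample Sample label attached on input.
#' @return `write_bedmethyl()` the path invisibly; `read_bedmethyl()` a
#'   `mod_pileup`.
#' @export
write_bedmethyl <- function(mp, path, chrom = "synthetic_ref") {
  stopifnot(inherits(mp, "mod_pileup"))
  out <- data.frame(chrom = chrom,
                    start = mp$position - 1L,
                    end = mp$position,
                    code = mp$mod_code,
                    score = pmin(mp$n_valid, 1000L),
                    strand = "+",
                    n_valid = mp$n_valid,
                    n_mod = mp$n_mod,
                    n_canonical = mp$n_canonical,
                    n_other = mp$n_other)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedmethyl
#' @export
read_bedmethyl <- function(path, sample = "") {
  .check_file(path, "bedMethyl file")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 10L) {
    stop("bedMethyl subset requires 10 columns", call. = FALSE)
  }
  names(df)[1:10] <- c("chrom", "start", "end", "code", "score", "strand",
                       "n_valid", "n_mod", "n_canonical", "n_other")
  if (any(df$end - df$start != 1L)) {
    stop("bedMethyl intervals must have length 1", call. = FALSE)
  }
  if (any(df$n_mod < 0 | df$n_canonical < 0 | df$n_other < 0)) {
    stop("bedMethyl counts must be >= 0", call. = FALSE)
  }
  mod_pileup(data.frame(position = df$end,  # 0-based start + 1
                        mod_code = df$code,
                        n_mod = df$n_mod,
                        n_canonical = df$n_canonical,
                        n_other = df$n_other,
                        stringsAsFactors = FALSE),
             sample = sample)
}

#' Per-position modified fraction
#'
#' @param mp A [mod_pileup()].
#' @param positions Optional position restriction (e.g. ground-truth sites);
#'   an empty vector yields an empty table.
#' @return A data.frame with columns `position`, `mod_code`,
#'   `percent_modified`, `defined`.
#' @export
mod_fraction <- function(mp, positions = NULL) {
  stopifnot(inherits(mp, "mod_pileup"))
  out <- data.frame(position = mp$position, mod_code = mp$mod_code,
                    percent_modified = mp$percent_modified,
                    defined = !is.na(mp$percent_modified))
  if (!is.null(positions)) {
    out <- out[out$position %in% as.integer(positions), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Cumulative modification curve
#'
#' Running sum of `percent_modified` over ascending positions; undefined
#' positions contribute 0. Modified samples rise steadily while canonical
#' controls stay near flat, giving a transcript-level summary of
#' modification content.
#'
#' @param mp A [mod_pileup()].
#' @return A data.frame of class `cumulative_curve` with columns `position`
#'   and `cumulative_percent` (non-decreasing).
#' @export
cumulative_curve <- function(mp) {
  stopifnot(inherits(mp, "mod_pileup"))
  pct <- mp$percent_modified
  pct[is.na(pct)] <- 0
  out <- data.frame(position = mp$position,
                    cumulative_percent = cumsum(pct))
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' @export
print.mod_pileup <- function(x, ...) {
  cat(sprintf(
    "<mod_pileup> %d rows, sample '%s', mean percent_modified %.2f\n",
    nrow(x), attr(x, "sample"),
    mean(x$percent_modified, na.rm = TRUE)))
  NextMethod()
}
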