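# Per-position basecall pileups and the total variation percentage.
#
# Total variation at a position is the percentage of non-reference events:
#   100 * (mismatched base calls + deletion calls + insertion calls) /
#         (A + C + G + U calls + deletion calls + insertion calls)
# Depth (a+c+g+u+del) excludes insertion calls, which have no reference
# position of their own, but the denominator above includes them.

#' Construct a per-position pileup table
#'
#' @param df A data.frame with columns `position` (1-based, strictly
#'   increasing), `ref_base` (A/C/G/U; T is normalized to U), base-call counts
#'   `a`, `c`, `g`, `u`, and `del_calls`, `ins_calls`.
#' @param sample Sample label attached to the table.
#' @return A data.frame of class `pileup_table` with an added `depth` column
#'   (`a+c+g+u+del_calls`).
#' @export
pileup_table <- function(df, sample = "") {
  need <- c("position", "ref_base", "a", "c", "g", "u",
            "del_calls", "ins_calls")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("pileup table missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[, need]
  df$ref_base <- .to_rna(df$ref_base)
  if (!all(df$ref_base %in% RNA_BASES)) {
    stop("ref_base must be one of A, C, G, U", call. = FALSE)
  }
  cnt <- c("a", "c", "g", "u", "del_calls", "ins_calls")
  for (k in cnt) {
    if (any(df[[k]] < 0)) stop("pileup counts must be >= 0", call. = FALSE)
    df[[k]] <- as.integer(df[[k]])
  }
  if (is.unsorted(df$position, strictly = TRUE)) {
    stop("positions must be strictly increasing without duplicates",
         call. = FALSE)
  }
  df$depth <- df$a + df$c + df$g + df$u + df$del_calls
  class(df) <- c("pileup_table", "data.frame")
  attr(df, "sample") <- sample
  df
}

#' @noRd
.mismatch_counts <- function(pt) {
  base_cols <- c(A = "a", C = "c", G = "g", U = "u")
  calls <- as.matrix(pt[, base_cols])
  ref_idx <- match(pt$ref_base, names(base_cols))
  ref_calls <- calls[cbind(seq_len(nrow(pt)), ref_idx)]
  rowSums(calls) - ref_calls
}

#' Total variation percentage per position
#'
#' The fraction of non-reference events (mismatched base calls, deletions,
#' insertions) among all events at a position, as a percentage. Positions
#' whose denominator is zero (no coverage) are returned as `NA` — undefined,
#' not 0% — so coverage gaps never deflate downstream summaries.
#'
#' @param pt A [pileup_table()].
#' @return Numeric vector (percent, in `[0, 100]` or `NA`) aligned with the
#'   rows of `pt`.
#' @examples
#' pt <- pileup_table(data.frame(position = 1, ref_base = "A", a = 70, c = 0,
#'                               g = 10, u = 0, del_calls = 15, ins_calls = 5))
#' total_variation(pt)  # 30
#' @export
total_variation <- function(pt) {
  stopifnot(inherits(pt, "pileup_table"))
  denom <- pt$depth + pt$ins_calls
  num <- .mismatch_counts(pt) + pt$del_calls + pt$ins_calls
  ifelse(denom > 0, 100 * num / denom, NA_real_)
}

#' Per-type error breakdown
#'
#' Splits the total variation into mismatch-by-base, deletion and insertion
#' components sharing the total-variation denominator. Component fractions sum
#' to `total_variation_pct / 100` exactly (within numerical tolerance).
#'
#' @param pt A [pileup_table()].
#' @return A data.frame with columns `position`, `ref_base`, fractions
#'   `mismatch_a`, `mismatch_c`, `mismatch_g`, `mismatch_u` (the reference
#'   base's own column is 0), `deletion_frac`, `insertion_frac`, and
#'   `total_variation_pct`.
#' @export
error_breakdown <- function(pt) {
  stopifnot(inherits(pt, "pileup_table"))
  denom <- pt$depth + pt$ins_calls
  base_cols <- c(A = "a", C = "c", G = "g", U = "u")
  out <- data.frame(position = pt$position, ref_base = pt$ref_base)
  for (b in names(base_cols)) {
    f <- ifelse(denom > 0 & pt$ref_base != b,
                pt[[base_cols[[b]]]] / denom, 0)
    f[denom == 0] <- NA_real_
    out[[paste0("mismatch_", base_cols[[b]])]] <- f
  }
  out$deletion_frac <- ifelse(denom > 0, pt$del_calls / denom, NA_real_)
  out$insertion_frac <- ifelse(denom > 0, pt$ins_calls / denom, NA_real_)
  out$total_variation_pct <- total_variation(pt)
  out
}

#' Modified-minus-control total variation difference
#'
#' @param modified,control [pileup_table()]s with overlapping position ranges.
#' @return A data.frame with columns `position`, `tv_modified`, `tv_control`,
#'   `delta` (percentage points). A position undefined (zero denominator) in
#'   either table has `NA` delta.
#' @export
error_delta <- function(modified, control) {
  stopifnot(inherits(modified, "pileup_table"),
            inherits(control, "pileup_table"))
  shared <- intersect(modified$position, control$position)
  if (!length(shared)) {
    stop("pileup tables cover disjoint position ranges", call. = FALSE)
  }
  tv_m <- total_variation(modified)[match(shared, modified$position)]
  tv_c <- total_variation(control)[match(shared, control$position)]
  data.frame(position = shared, tv_modified = tv_m, tv_control = tv_c,
             delta = tv_m - tv_c)
}

#' Read / write the pileup CSV dialect
#'
#' Header columns: `position, ref_base, A, C, G, U, del, ins` (integers, one
#' row per position).
#'
#' @param pt A [pileup_table()].
#' @param path File path.
#' @param sample Sample label for the returned table.
#' @return `write_pileup_csv()` the path invisibly; `read_pileup_csv()` a
#'   `pileup_table`.
#' @export
write_pileup_csv <- function(pt, path) {
  stopifnot(inherits(pt, "pileup_table"))
  out <- data.frame(position = pt$position, ref_base = pt$ref_base,
                    A = pt$a, C = pt$c, G = pt$g, U = pt$u,
                    del = pt$del_calls, ins = pt$ins_calls)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pileup_csv
#' @export
read_pileup_csv <- function(path, sample = "") {
  .check_file(path, "pileup CSV")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "ref_base", "A", "C", "G", "U", "del", "ins")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("pileup CSV missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  pileup_table(data.frame(position = df$position, ref_base = df$ref_base,
                          a = df$A, c = df$C, g = df$G, u = df$U,
                          del_calls = df$del, ins_calls = df$ins,
                          stringsAsFactors = FALSE),
               sample = sample)
}

#' Write an error-annotated pileup CSV
#'
#' The pileup CSV dialect plus `total_variation_pct` and the per-type
#' breakdown columns.
#'
#' @param pt A [pileup_table()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_error_csv <- function(pt, path) {
  stopifnot(inherits(pt, "pileup_table"))
  bd <- error_breakdown(pt)
  out <- data.frame(position = pt$position, ref_base = pt$ref_base,
                    A = pt$a, C = pt$c, G = pt$g, U = pt$u,
                    del = pt$del_calls, ins = pt$ins_calls,
                    depth = pt$depth)
  out <- cbind(out, bd[, setdiff(names(bd), c("position", "ref_base"))])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a pileup table from a coordinate-sorted alignment file
#'
#' Adapter over `Rsamtools`/`GenomicAlignments`: counts base calls and
#' deletions per reference position and insertion events anchored at the
#' reference position they follow, after dropping unmapped and secondary
#' records and reads below `min_mapq`. Insertions of any length count as one
#' event. The alignment file must be indexed.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param reference Reference sequence (character, RNA or DNA alphabet) or a
#'   path to a FASTA file containing it.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param sample Sample label.
#' @return A [pileup_table()] covering positions 1..reference length.
#' @export
pileup_from_alignments <- function(bam_path, reference, min_mapq = 20,
                                   sample = "") {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop(sprintf("package '%s' is required for BAM ingestion", pkg),
           call. = FALSE)
    }
  }
  .check_file(bam_path, "alignment file")
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop(sprintf("missing index (.bai) for %s", bam_path), call. = FALSE)
  }
  if (length(reference) == 1L && file.exists(reference) &&
      grepl("\\.(fa|fasta)$", reference, ignore.case = TRUE)) {
    reference <- as.character(Biostrings::readBStringSet(reference)[[1]])
  }
  ref <- .to_rna(strsplit(reference, "")[[1]])
  L <- length(ref)

  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  sbp <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
  pp <- Rsamtools::PileupParam(max_depth = 1e6L, min_base_quality = 0L,
                               min_mapq = min_mapq,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = TRUE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam_path, scanBamParam = sbp, pileupParam = pp)
  pu$nucleotide <- .to_rna(as.character(pu$nucleotide))

  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c(RNA_BASES, "-")))
  keep <- pu$pos >= 1 & pu$pos <= L & pu$nucleotide %in% colnames(counts)
  pu <- pu[keep, , drop = FALSE]
  if (nrow(pu)) {
    idx <- cbind(pu$pos, match(pu$nucleotide, colnames(counts)))
    counts[idx] <- counts[idx] + pu$count
  }

  # Insertion events, anchored at the reference position they follow.
  ga <- GenomicAlignments::readGAlignments(bam_path, param = sbp)
  ins_calls <- integer(L)
  if (length(ga)) {
    ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(ga),
      pos = GenomicAlignments::start(ga), ops = "I")
    anchors <- unlist(lapply(ir, function(r) unique(methods::slot(r, "start") - 1L)))
    anchors <- anchors[anchors >= 1 & anchors <= L]
    if (length(anchors)) {
      tab <- table(factor(anchors, levels = seq_len(L)))
      ins_calls <- as.integer(tab)
    }
  }

  pileup_table(data.frame(
    position = seq_len(L), ref_base = ref,
    a = counts[, "A"], c = counts[, "C"], g = counts[, "G"],
    u = counts[, "U"],
    del_calls = counts[, "-"], ins_calls = ins_calls,
    stringsAsFactors = FALSE
  ), sample = sample)
}

#' @export
print.pileup_table <- function(x, ...) {
  cat(sprintf("<pileup_table> %d positions, sample '%s', mean depth %.1f\n",
              nrow(x), attr(x, "sample"), mean(x$depth)))
  NextMethod()
}
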