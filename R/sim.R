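# Synthetic paired canonical/modified direct-RNA datasets.
#
# The generator emulates the phenomenology observed when sequencing synthetic
# modified RNA standards: deletion-dominant basecall error elevation at and
# around modified sites over a low (<5%) background, a current-mean shift and
# current-SD inflation at modified sites, a dwell-time perturbation offset
# ~10 nt from the site (3'->5' translocation places the site near the motor
# protein while a downstream base sits in the pore), 5'-end coverage decay,
# and sub-stoichiometric modified-call fractions from a modification-aware
# basecaller.

#' Configuration for the synthetic dataset generator
#'
#' Builds and validates the parameter set that fully determines one paired
#' canonical/modified simulation. Every stochastic choice downstream is driven
#' by `seed`, so an identical configuration reproduces identical outputs.
#'
#' @param seed Integer seed; fully determines the generated dataset.
#' @param ref_length Reference length in nt (>= 3).
#' @param ref_sequence Optional explicit reference over `A,C,G,U`; when `NULL`
#'   a uniform random sequence of `ref_length` nt is drawn.
#' @param n_reads_control,n_reads_modified Number of simulated reads per
#'   sample.
#' @param modified_positions Integer vector of 1-based modified reference
#'   positions. Defaults to the three alternating-position clusters used by
#'   site-specifically modified 120-nt standards (33/35/37, 70/72/74,
#'   107/109/111).
#' @param baseline_error Named numeric `c(mismatch=, deletion=, insertion=)`
#'   per-position event rates away from modified sites; their sum must be < 1
#'   (the remainder is the correct-call rate).
#' @param modified_error Event rates at modified positions
#'   (deletion-dominant by default).
#' @param neighbor_halfwidth Error elevation decays linearly from
#'   `modified_error` at the site back to `baseline_error` over this many
#'   neighbouring nt (reaching baseline at distance `neighbor_halfwidth + 1`).
#' @param signal_base_levels Named numeric map base -> mean normalized current.
#' @param noise_sd Per-event current noise SD (also sets the scale of the
#'   within-event current SD draw).
#' @param dwell_logmean,dwell_logsd Log-normal dwell-time parameters (events).
#' @param mod_mean_shift Additive current-mean shift at modified positions in
#'   the modified sample.
#' @param mod_sd_inflation Multiplicative factor on the current SD at modified
#'   positions in the modified sample.
#' @param dwell_offset Integer nt; the dwell perturbation is applied at
#'   `site + dwell_offset` (clipped at the reference end), not at the site.
#' @param dwell_shift_logmean Additive shift on log dwell at offset positions.
#' @param five_prime_dropout Named numeric `c(frac=, mean_depth=)`: fraction of
#'   reads truncated at the 5' end and the mean truncation depth in nt.
#' @param mod_call_rate Probability that a modified position is called modified
#'   on a correctly basecalled read (modified sample only).
#' @param false_mod_rate Probability that an unmodified position is called
#'   modified on a correctly basecalled read.
#' @param mod_code Modification code label used in mod-call pileups and ground
#'   truth (e.g. `"2OMeA"`, `"m1Y"`, `"m5C"`).
#' @param canonical_base The canonical base the modification chemistry sits on
#'   (default `"A"`, as in adenosine-sharing modification clusters). Generated
#'   references carry this base at every modified position, and mod-call
#'   pileups cover exactly the reference positions of this base — a
#'   modification-aware basecaller only emits calls where its target base is
#'   expected.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_dataset()], [write_fixture()]
#' @export
sim_config <- function(seed = 1L,
                       ref_length = 120L,
                       ref_sequence = NULL,
                       n_reads_control = 200L,
                       n_reads_modified = 200L,
                       modified_positions = c(33L, 35L, 37L, 70L, 72L, 74L,
                                              107L, 109L, 111L),
                       baseline_error = c(mismatch = 0.02, deletion = 0.01,
                                          insertion = 0.005),
                       modified_error = c(mismatch = 0.05, deletion = 0.15,
                                          insertion = 0.01),
                       neighbor_halfwidth = 2L,
                       signal_base_levels = c(A = 0.6, C = -0.2, G = 0.9,
                                              U = -0.8),
                       noise_sd = 0.1,
                       dwell_logmean = 2.0,
                       dwell_logsd = 0.5,
                       mod_mean_shift = 0.3,
                       mod_sd_inflation = 1.5,
                       dwell_offset = 10L,
                       dwell_shift_logmean = 0.3,
                       five_prime_dropout = c(frac = 0.5, mean_depth = 15),
                       mod_call_rate = 0.8,
                       false_mod_rate = 0.01,
                       mod_code = "2OMeA",
                       canonical_base = "A") {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .cfg_stop("seed", "must be a single integer")
  }
  if (!is.numeric(ref_length) || length(ref_length) != 1L || ref_length < 3) {
    .cfg_stop("ref_length", "must be a single integer >= 3")
  }
  ref_length <- as.integer(ref_length)
  if (!is.null(ref_sequence)) {
    bases <- .to_rna(strsplit(ref_sequence, "")[[1]])
    if (!all(bases %in% RNA_BASES)) {
      .cfg_stop("ref_sequence", "must contain only A, C, G, U (or T)")
    }
    ref_sequence <- paste(bases, collapse = "")
    ref_length <- length(bases)
    if (ref_length < 3) .cfg_stop("ref_sequence", "must be >= 3 nt")
  }
  for (nm in c("n_reads_control", "n_reads_modified")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      .cfg_stop(nm, "must be a positive integer")
    }
  }
  modified_positions <- sort(unique(as.integer(modified_positions)))
  if (length(modified_positions) &&
      (min(modified_positions) < 1L || max(modified_positions) > ref_length)) {
    .cfg_stop("modified_positions",
              sprintf("must lie within [1, %d]", ref_length))
  }
  .check_rates <- function(r, field) {
    need <- c("mismatch", "deletion", "insertion")
    if (!is.numeric(r) || !all(need %in% names(r))) {
      .cfg_stop(field, "must be named rates c(mismatch=, deletion=, insertion=)")
    }
    r <- r[need]
    if (any(r < 0) || any(r > 1)) .cfg_stop(field, "rates must lie in [0, 1]")
    if (r[["mismatch"]] + r[["deletion"]] > 1) {
      .cfg_stop(field,
                "mismatch + deletion must be <= 1 (remainder is correct)")
    }
    r
  }
  baseline_error <- .check_rates(baseline_error, "baseline_error")
  modified_error <- .check_rates(modified_error, "modified_error")
  if (!is.numeric(neighbor_halfwidth) || neighbor_halfwidth < 0) {
    .cfg_stop("neighbor_halfwidth", "must be a non-negative integer")
  }
  if (!all(RNA_BASES %in% names(signal_base_levels))) {
    .cfg_stop("signal_base_levels", "must name all of A, C, G, U")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    .cfg_stop("noise_sd", "must be positive")
  }
  if (!is.numeric(dwell_logsd) || dwell_logsd <= 0) {
    .cfg_stop("dwell_logsd", "must be positive")
  }
  if (!is.numeric(mod_sd_inflation) || mod_sd_inflation <= 0) {
    .cfg_stop("mod_sd_inflation", "must be positive")
  }
  if (!all(c("frac", "mean_depth") %in% names(five_prime_dropout))) {
    .cfg_stop("five_prime_dropout", "must be c(frac=, mean_depth=)")
  }
  if (five_prime_dropout[["frac"]] < 0 || five_prime_dropout[["frac"]] > 1) {
    .cfg_stop("five_prime_dropout", "frac must lie in [0, 1]")
  }
  if (five_prime_dropout[["mean_depth"]] < 0) {
    .cfg_stop("five_prime_dropout", "mean_depth must be >= 0")
  }
  for (nm in c("mod_call_rate", "false_mod_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) .cfg_stop(nm, "must lie in [0, 1]")
  }
  canonical_base <- .to_rna(canonical_base)
  if (!canonical_base %in% RNA_BASES) {
    .cfg_stop("canonical_base", "must be one of A, C, G, U")
  }
  structure(list(
    seed = as.integer(seed), ref_length = ref_length,
    ref_sequence = ref_sequence,
    n_reads_control = as.integer(n_reads_control),
    n_reads_modified = as.integer(n_reads_modified),
    modified_positions = modified_positions,
    baseline_error = baseline_error, modified_error = modified_error,
    neighbor_halfwidth = as.integer(neighbor_halfwidth),
    signal_base_levels = signal_base_levels, noise_sd = noise_sd,
    dwell_logmean = dwell_logmean, dwell_logsd = dwell_logsd,
    mod_mean_shift = mod_mean_shift, mod_sd_inflation = mod_sd_inflation,
    dwell_offset = as.integer(dwell_offset),
    dwell_shift_logmean = dwell_shift_logmean,
    five_prime_dropout = five_prime_dropout,
    mod_call_rate = mod_call_rate, false_mod_rate = false_mod_rate,
    mod_code = mod_code, canonical_base = canonical_base
  ), class = "sim_config")
}

#' Ground-truth modified positions
#'
#' @param positions Integer vector of 1-based modified positions.
#' @param mod_code Character vector of modification codes, recycled to the
#'   length of `positions`.
#' @param ref_length Reference length used for bounds checking (optional).
#' @return A data.frame of class `ground_truth` with columns `position` and
#'   `mod_code`.
#' @export
ground_truth <- function(positions, mod_code = "mod", ref_length = NULL) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && min(positions) < 1L) {
    stop("ground-truth positions must be >= 1", call. = FALSE)
  }
  if (!is.null(ref_length) && length(positions) &&
      max(positions) > ref_length) {
    stop("ground-truth positions exceed reference length", call. = FALSE)
  }
  out <- data.frame(position = positions,
                    mod_code = rep_len(as.character(mod_code),
                                       length(positions)),
                    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth", "data.frame")
  out
}

# Per-position event rates for one sample. Elevation decays linearly from the
# modified-site rate to baseline, reaching baseline at halfwidth + 1 nt.
#' @noRd
.position_rates <- function(cfg, modified) {
  L <- cfg$ref_length
  out <- list(
    mismatch = rep(cfg$baseline_error[["mismatch"]], L),
    deletion = rep(cfg$baseline_error[["deletion"]], L),
    insertion = rep(cfg$baseline_error[["insertion"]], L)
  )
  if (modified && length(cfg$modified_positions)) {
    d <- vapply(seq_len(L),
                function(p) min(abs(p - cfg$modified_positions)), numeric(1))
    w <- pmax(0, 1 - d / (cfg$neighbor_halfwidth + 1))
    for (k in names(out)) {
      out[[k]] <- out[[k]] +
        w * (cfg$modified_error[[k]] - cfg$baseline_error[[k]])
    }
  }
  out
}

#' @noRd
.simulate_sample <- function(cfg, ref, n_reads, modified, label) {
  L <- cfg$ref_length
  rates <- .position_rates(cfg, modified)

  # 3'-anchored reads: a five_prime_dropout fraction starts downstream of 1.
  trunc <- stats::runif(n_reads) < cfg$five_prime_dropout[["frac"]]
  mean_depth <- cfg$five_prime_dropout[["mean_depth"]]
  extra <- if (mean_depth > 1) {
    stats::rgeom(n_reads, 1 / mean_depth)
  } else {
    integer(n_reads)
  }
  starts <- ifelse(trunc, pmin(1L + 1L + extra, L - 2L), 1L)

  pos <- unlist(lapply(starts, function(s) seq.int(s, L)), use.names = FALSE)
  rid <- rep.int(seq_len(n_reads), L - starts + 1L)

  u <- stats::runif(length(pos))
  p_del <- rates$deletion[pos]
  p_mm <- rates$mismatch[pos]
  outcome <- ifelse(u < p_del, "del", ifelse(u < p_del + p_mm, "mm", "ok"))
  ins <- stats::rbinom(length(pos), 1L, rates$insertion[pos]) == 1L

  called <- ref[pos]
  mm_idx <- which(outcome == "mm")
  if (length(mm_idx)) {
    # mismatches uniform over the three alternative bases
    alt_pick <- sample.int(3L, length(mm_idx), replace = TRUE)
    alts <- vapply(seq_along(mm_idx), function(i) {
      setdiff(RNA_BASES, ref[pos[mm_idx[i]]])[alt_pick[i]]
    }, character(1))
    called[mm_idx] <- alts
  }
  called[outcome == "del"] <- NA_character_

  pos_f <- factor(pos, levels = seq_len(L))
  base_counts <- table(pos_f, factor(called, levels = RNA_BASES))
  del_calls <- as.integer(table(pos_f[outcome == "del"]))
  ins_calls <- as.integer(table(pos_f[ins]))

  pt <- pileup_table(data.frame(
    position = seq_len(L),
    ref_base = ref,
    a = as.integer(base_counts[, "A"]),
    c = as.integer(base_counts[, "C"]),
    g = as.integer(base_counts[, "G"]),
    u = as.integer(base_counts[, "U"]),
    del_calls = del_calls,
    ins_calls = ins_calls,
    stringsAsFactors = FALSE
  ), sample = label)

  # Signal records exist wherever the base was not deleted; basecall errors do
  # not remove the underlying signal event.
  keep <- outcome != "del"
  sp <- pos[keep]
  is_mod_pos <- sp %in% cfg$modified_positions & modified
  offset_pos <- unique(pmin(cfg$modified_positions + cfg$dwell_offset, L))
  at_offset <- sp %in% offset_pos & modified

  meanlog <- cfg$dwell_logmean + ifelse(at_offset, cfg$dwell_shift_logmean, 0)
  dwell <- stats::rlnorm(length(sp), meanlog, cfg$dwell_logsd)
  cur_mean <- cfg$signal_base_levels[ref[sp]] +
    ifelse(is_mod_pos, cfg$mod_mean_shift, 0) +
    stats::rnorm(length(sp), 0, cfg$noise_sd)
  cur_sd <- cfg$noise_sd * abs(stats::rnorm(length(sp), 1, 0.3)) *
    ifelse(is_mod_pos, cfg$mod_sd_inflation, 1)

  sm <- signal_matrix(data.frame(
    read_id = sprintf("%s_read_%04d", label, rid[keep]),
    position = sp,
    dwell = dwell,
    mean = unname(cur_mean),
    sd = cur_sd,
    stringsAsFactors = FALSE
  ), ref_length = L)

  # Modified calls are drawn only among correctly basecalled reads; miscalled
  # or deleted reads never enter the modified/canonical denominator.
  ok_f <- pos_f[outcome == "ok"]
  n_correct <- as.integer(table(ok_f))
  depth <- pt$depth
  call_rate <- ifelse(seq_len(L) %in% cfg$modified_positions & modified,
                      cfg$mod_call_rate, cfg$false_mod_rate)
  n_mod <- stats::rbinom(L, n_correct, call_rate)
  # a modification-aware model emits calls only where its target canonical
  # base is expected
  at_base <- which(ref == cfg$canonical_base)
  mp <- mod_pileup(data.frame(
    position = at_base,
    ref_base = ref[at_base],
    mod_code = cfg$mod_code,
    n_mod = n_mod[at_base],
    n_canonical = n_correct[at_base] - n_mod[at_base],
    n_other = depth[at_base] - n_correct[at_base],
    stringsAsFactors = FALSE
  ), sample = label)

  list(pileup = pt, signal = sm, modcall = mp)
}

#' Simulate a paired canonical/modified dataset
#'
#' Generates a reference sequence plus two complete sample bundles. The
#' control sample has all modification effects disabled; the modified sample
#' applies elevated (deletion-dominant) error rates at and around
#' `modified_positions`, a current-mean shift and current-SD inflation at the
#' sites themselves, and a dwell-time perturbation at `site + dwell_offset`.
#' Reads are 3'-anchored with 5'-end truncation only, mirroring the coverage
#' decay of direct RNA sequencing.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `mod_sim` with elements `reference` (character),
#'   `pileup`, `signal`, `modcall` (each a list with `control` and `modified`
#'   entries), `truth` (a [ground_truth()]), and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7, n_reads_control = 50,
#'                                    n_reads_modified = 50))
#' sim$truth
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    stop("`cfg` must be created with sim_config()", call. = FALSE)
  }
  .with_seed(cfg$seed, {
    ref <- if (is.null(cfg$ref_sequence)) {
      r <- sample(RNA_BASES, cfg$ref_length, replace = TRUE)
      # generated references carry the modification chemistry's canonical
      # base at every modified site (site-specific standards are designed
      # this way); explicit sequences are taken as given
      r[cfg$modified_positions] <- cfg$canonical_base
      r
    } else {
      strsplit(cfg$ref_sequence, "")[[1]]
    }
    truth <- ground_truth(cfg$modified_positions, cfg$mod_code,
                          cfg$ref_length)
    control <- .simulate_sample(cfg, ref, cfg$n_reads_control,
                                modified = FALSE, label = "control")
    modified <- .simulate_sample(cfg, ref, cfg$n_reads_modified,
                                 modified = TRUE, label = "modified")
    structure(list(
      reference = paste(ref, collapse = ""),
      pileup = list(control = control$pileup, modified = modified$pileup),
      signal = list(control = control$signal, modified = modified$signal),
      modcall = list(control = control$modcall, modified = modified$modcall),
      truth = truth,
      config = cfg
    ), class = "mod_sim")
  })
}

#' Write a simulated bundle to disk as plain-text fixtures
#'
#' Emits a FASTA reference, two pileup CSVs, two signal TSVs, two
#' bedMethyl-like mod-call files, a truth BED (0-based half-open) and the
#' generator configuration as YAML. All files round-trip losslessly through
#' the package's readers.
#'
#' @param bundle A `mod_sim` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param chrom Reference name used in FASTA/BED/bedMethyl output.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(bundle, out_dir, chrom = "synthetic_ref") {
  if (!inherits(bundle, "mod_sim")) {
    stop("`bundle` must come from simulate_dataset()", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  paths <- c(
    reference = file.path(out_dir, "reference.fasta"),
    pileup_control = file.path(out_dir, "pileup_control.csv"),
    pileup_modified = file.path(out_dir, "pileup_modified.csv"),
    signal_control = file.path(out_dir, "signal_control.tsv"),
    signal_modified = file.path(out_dir, "signal_modified.tsv"),
    modcall_control = file.path(out_dir, "modcalls_control.bed"),
    modcall_modified = file.path(out_dir, "modcalls_modified.bed"),
    truth = file.path(out_dir, "truth.bed"),
    config = file.path(out_dir, "sim_config.yaml")
  )
  seqs <- Biostrings::RNAStringSet(bundle$reference)
  names(seqs) <- chrom
  Biostrings::writeXStringSet(seqs, paths[["reference"]])
  write_pileup_csv(bundle$pileup$control, paths[["pileup_control"]])
  write_pileup_csv(bundle$pileup$modified, paths[["pileup_modified"]])
  write_signal_tsv(bundle$signal$control, paths[["signal_control"]])
  write_signal_tsv(bundle$signal$modified, paths[["signal_modified"]])
  write_bedmethyl(bundle$modcall$control, paths[["modcall_control"]],
                  chrom = chrom)
  write_bedmethyl(bundle$modcall$modified, paths[["modcall_modified"]],
                  chrom = chrom)
  write_truth_bed(bundle$truth, paths[["truth"]], chrom = chrom)
  write_sim_config(bundle$config, paths[["config"]])
  invisible(paths)
}

#' Serialize / restore a generator configuration as YAML
#'
#' @param cfg A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns the path invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$baseline_error <- as.list(x$baseline_error)
  x$modified_error <- as.list(x$modified_error)
  x$signal_base_levels <- as.list(x$signal_base_levels)
  x$five_prime_dropout <- as.list(x$five_prime_dropout)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  .check_file(path, "config YAML")
  x <- yaml::read_yaml(path)
  for (nm in c("baseline_error", "modified_error", "signal_base_levels",
               "five_prime_dropout")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  x$modified_positions <- as.integer(unlist(x$modified_positions))
  do.call(sim_config, x)
}

#' Read / write ground truth as BED
#'
#' Truth positions are stored as 0-based half-open single-nt intervals with
#' the modification code in the name column; the reader converts back to
#' 1-based coordinates.
#'
#' @param truth A [ground_truth()].
#' @param path File path.
#' @param chrom Reference name.
#' @return `write_truth_bed()` the path invisibly; `read_truth_bed()` a
#'   `ground_truth`.
#' @export
write_truth_bed <- function(truth, path, chrom = "synthetic_ref") {
  stopifnot(inherits(truth, "ground_truth"))
  df <- data.frame(chrom = chrom,
                   start = truth$position - 1L,
                   end = truth$position,
                   name = truth$mod_code)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  .check_file(path, "truth BED")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("truth BED needs >= 4 columns", call. = FALSE)
  if (any(df[[3]] - df[[2]] != 1L)) {
    stop("truth BED intervals must have length 1", call. = FALSE)
  }
  ground_truth(df[[3]], df[[4]])
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed=%d ref_length=%d reads=%d/%d sites=%d code=%s\n",
    x$seed, x$ref_length, x$n_reads_control, x$n_reads_modified,
    length(x$modified_positions), x$mod_code))
  invisible(x)
}

#' @export
print.mod_sim <- function(x, ...) {
  cat(sprintf(
    "<mod_sim> %d-nt reference, %d modified sites, %d/%d reads (control/modified)\n",
    nchar(x$reference), nrow(x$truth),
    x$config$n_reads_control, x$config$n_reads_modified))
  invisible(x)
}
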