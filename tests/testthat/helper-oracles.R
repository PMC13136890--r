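# Shared helpers: an independent brute-force energy-distance oracle, small
# configuration factories, and fixture builders used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reduce any tabular object to a bare data.frame (drop classes and labels)
# so round-trip comparisons look only at the data.
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  keep <- attributes(x)[c("names", "row.names")]
  attributes(x) <- c(keep, list(class = "data.frame"))
  x
}

# Brute-force energy distance: explicit loop over the rows of each set, with
# Euclidean norms computed directly. Deliberately independent of the
# cross-product formulation used by the package.
energy_oracle <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  m <- nrow(y)
  s_xy <- 0
  for (i in seq_len(n)) {
    s_xy <- s_xy + sum(sqrt(colSums((t(y) - x[i, ])^2)))
  }
  s_xx <- 0
  for (i in seq_len(n)) {
    s_xx <- s_xx + sum(sqrt(colSums((t(x) - x[i, ])^2)))
  }
  s_yy <- 0
  for (j in seq_len(m)) {
    s_yy <- s_yy + sum(sqrt(colSums((t(y) - y[j, ])^2)))
  }
  2 * s_xy / (n * m) - s_xx / n^2 - s_yy / m^2
}

# Configuration with every modification effect switched off (error rates at
# baseline, no signal or dwell perturbation): the modified bundle is then a
# second draw from the control distribution.
null_sim_config <- function(seed, dwell_shift_logmean = 0, ...) {
  sim_config(seed = seed,
             modified_error = c(mismatch = 0.02, deletion = 0.01,
                                insertion = 0.005),
             mod_mean_shift = 0, mod_sd_inflation = 1,
             dwell_shift_logmean = dwell_shift_logmean, ...)
}

# Small-read-count configuration for cheap structural tests.
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_reads_control = 60, n_reads_modified = 60, ...)
}

# Restrict a signal matrix to a set of read ids, preserving ref_length.
subset_reads <- function(sm, ids) {
  signal_matrix(as.data.frame(sm[sm$read_id %in% ids, , drop = FALSE]),
                ref_length = attr(sm, "ref_length"))
}

# One-row pileup table for formula tests.
pileup_row <- function(ref_base, a = 0, c = 0, g = 0, u = 0,
                       del = 0, ins = 0, position = 1) {
  pileup_table(data.frame(position = position, ref_base = ref_base,
                          a = a, c = c, g = g, u = u,
                          del_calls = del, ins_calls = ins,
                          stringsAsFactors = FALSE))
}

# Standard full-pipeline score tracks (total variation and energy distance)
# for a simulated bundle, mirroring run_all()'s analysis path.
pipeline_scores <- function(sim, max_vectors = 1000) {
  tv <- total_variation(sim$pileup$modified)
  pre <- preprocess_signals(coverage_filter(sim$signal$modified),
                            coverage_filter(sim$signal$control))
  prof <- energy_profile(pre$modified, pre$control,
                         max_vectors = max_vectors)
  list(
    tv = scored_positions(sim$pileup$modified$position, tv, sim$truth),
    ed = scored_positions(prof$position, prof$energy_distance, sim$truth),
    profile = prof
  )
}
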