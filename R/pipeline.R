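# End-to-end orchestration: pileup errors -> signal features -> energy
# distance -> detection evaluation -> mod-call summarization, as available
# inputs permit. Numeric CSV/JSON outputs are the tested surface; plots are
# artifacts.

#' Pipeline run configuration
#'
#' Paths may be `NULL`; stages whose inputs are missing are skipped with a
#' logged notice. All provided paths are checked at validation time.
#'
#' @param out_dir Output directory.
#' @param reference Path to the reference FASTA.
#' @param pileup_control,pileup_modified Pileup CSV paths.
#' @param signal_control,signal_modified Signal TSV paths.
#' @param bedmethyl_control,bedmethyl_modified bedMethyl-like paths.
#' @param truth_bed Ground-truth BED path.
#' @param min_coverage_frac Read coverage filter fraction (default 0.9).
#' @param min_vectors,max_vectors,subsample_seed Energy-profile parameters.
#' @param tv_threshold Total-variation threshold (percent) for the confusion
#'   matrix (default 20).
#' @param proximity_window False-positive attribution window in nt (default
#'   7).
#' @param plots Emit per-position PDF plots (default `TRUE`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       reference = NULL,
                       pileup_control = NULL, pileup_modified = NULL,
                       signal_control = NULL, signal_modified = NULL,
                       bedmethyl_control = NULL, bedmethyl_modified = NULL,
                       truth_bed = NULL,
                       min_coverage_frac = 0.9,
                       min_vectors = 10, max_vectors = 1000,
                       subsample_seed = 1L,
                       tv_threshold = 20,
                       proximity_window = 7,
                       plots = TRUE) {
  if (missing(out_dir) || !is.character(out_dir) || length(out_dir) != 1L) {
    .cfg_stop("out_dir", "must be a single path")
  }
  paths <- list(reference = reference,
                pileup_control = pileup_control,
                pileup_modified = pileup_modified,
                signal_control = signal_control,
                signal_modified = signal_modified,
                bedmethyl_control = bedmethyl_control,
                bedmethyl_modified = bedmethyl_modified,
                truth_bed = truth_bed)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      .cfg_stop(nm, sprintf("file does not exist: %s", p))
    }
  }
  if (min_coverage_frac <= 0 || min_coverage_frac > 1) {
    .cfg_stop("min_coverage_frac", "must lie in (0, 1]")
  }
  if (min_vectors < 2) .cfg_stop("min_vectors", "must be >= 2")
  if (max_vectors < min_vectors) {
    .cfg_stop("max_vectors", "must be >= min_vectors")
  }
  structure(c(paths, list(
    out_dir = out_dir,
    min_coverage_frac = min_coverage_frac,
    min_vectors = min_vectors, max_vectors = max_vectors,
    subsample_seed = as.integer(subsample_seed),
    tv_threshold = tv_threshold,
    proximity_window = proximity_window,
    plots = isTRUE(plots)
  )), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  .check_file(path, "run config YAML")
  x <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  path_keys <- c("reference", "pileup_control", "pileup_modified",
                 "signal_control", "signal_modified",
                 "bedmethyl_control", "bedmethyl_modified", "truth_bed")
  for (nm in path_keys) {
    if (!is.null(x[[nm]]) && !grepl("^(/|[A-Za-z]:)", x[[nm]])) {
      x[[nm]] <- file.path(base, x[[nm]])
    }
  }
  do.call(run_config, x)
}

#' @noRd
.log_stage <- function(...) message(sprintf(...))

#' @noRd
.save_plot <- function(p, path) {
  suppressMessages(ggplot2::ggsave(path, p, width = 8, height = 3.2,
                                   device = "pdf"))
}

#' Run the full detection pipeline
#'
#' Executes every stage whose inputs are present, writes per-stage CSVs, a
#' metrics JSON and (optionally) per-position plots into the configured
#' output directory, and records a manifest (package version, seeds, input
#' MD5 digests). Re-running on identical inputs and seeds reproduces
#' identical numeric outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`errors`, `profile`, `metrics`, `modsummary`) and the written `paths`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  paths <- character()
  truth <- if (!is.null(cfg$truth_bed)) read_truth_bed(cfg$truth_bed)
  ref_length <- if (!is.null(cfg$reference)) {
    nchar(as.character(Biostrings::readBStringSet(cfg$reference)[[1]]))
  }

  ## --- pileup error stage -------------------------------------------------
  have_pileups <- !is.null(cfg$pileup_control) && !is.null(cfg$pileup_modified)
  if (have_pileups) {
    ctrl <- read_pileup_csv(cfg$pileup_control, sample = "control")
    mod <- read_pileup_csv(cfg$pileup_modified, sample = "modified")
    .log_stage("pileup stage: %d/%d positions (control/modified)",
               nrow(ctrl), nrow(mod))
    delta <- error_delta(mod, ctrl)
    p1 <- file.path(cfg$out_dir, "errors_control.csv")
    p2 <- file.path(cfg$out_dir, "errors_modified.csv")
    p3 <- file.path(cfg$out_dir, "error_delta.csv")
    write_error_csv(ctrl, p1)
    write_error_csv(mod, p2)
    utils::write.csv(delta, p3, row.names = FALSE, quote = FALSE)
    paths <- c(paths, errors_control = p1, errors_modified = p2,
               error_delta = p3)
    out$errors <- list(control = ctrl, modified = mod, delta = delta)
    if (cfg$plots) {
      depth_df <- rbind(
        data.frame(position = ctrl$position, depth = ctrl$depth,
                   sample = "control"),
        data.frame(position = mod$position, depth = mod$depth,
                   sample = "modified"))
      .save_plot(
        ggplot2::ggplot(depth_df,
                        ggplot2::aes(x = .data$position, y = .data$depth,
                                     colour = .data$sample)) +
          ggplot2::geom_line() +
          ggplot2::labs(y = "depth (reads)"),
        file.path(cfg$out_dir, "depth.pdf"))
      .save_plot(
        ggplot2::ggplot(delta,
                        ggplot2::aes(x = .data$position, y = .data$delta)) +
          ggplot2::geom_col() +
          ggplot2::labs(y = "total variation delta (pp)"),
        file.path(cfg$out_dir, "tv_delta.pdf"))
    }
  } else {
    .log_stage("pileup stage skipped: pileup CSVs not provided")
  }

  ## --- signal / energy stage ---------------------------------------------
  have_signal <- !is.null(cfg$signal_control) && !is.null(cfg$signal_modified)
  if (have_signal) {
    sc <- read_signal_tsv(cfg$signal_control, ref_length = ref_length)
    sm <- read_signal_tsv(cfg$signal_modified, ref_length = ref_length)
    sc_f <- coverage_filter(sc, cfg$min_coverage_frac)
    sm_f <- coverage_filter(sm, cfg$min_coverage_frac)
    .log_stage("coverage filter (>= %.0f%%): control %d -> %d reads, modified %d -> %d reads",
               100 * cfg$min_coverage_frac,
               attr(sc_f, "reads_in"), attr(sc_f, "reads_out"),
               attr(sm_f, "reads_in"), attr(sm_f, "reads_out"))
    if (cfg$plots) {
      sig_list <- list(control = sc_f, modified = sm_f)
      band_df <- do.call(rbind, lapply(names(sig_list), function(lbl) {
        s <- sig_list[[lbl]]
        agg <- function(v, f) tapply(v, s$position, f)
        pos <- sort(unique(s$position))
        df <- do.call(rbind, lapply(c("dwell", "mean", "sd"), function(ch) {
          data.frame(position = pos, channel = ch,
                     med = as.numeric(agg(s[[ch]], stats::median)),
                     q1 = as.numeric(agg(s[[ch]],
                                         function(x) stats::quantile(x, .25))),
                     q3 = as.numeric(agg(s[[ch]],
                                         function(x) stats::quantile(x, .75))))
        }))
        df$sample <- lbl
        df
      }))
      .save_plot(
        ggplot2::ggplot(band_df,
                        ggplot2::aes(x = .data$position, y = .data$med,
                                     colour = .data$sample,
                                     fill = .data$sample)) +
          ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1,
                                            ymax = .data$q3),
                               alpha = 0.25, colour = NA) +
          ggplot2::geom_line() +
          ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
          ggplot2::labs(y = "median (IQR band)"),
        file.path(cfg$out_dir, "signal_bands.pdf"))
    }
    pre <- preprocess_signals(sm_f, sc_f)
    prof <- energy_profile(pre$modified, pre$control,
                           min_vectors = cfg$min_vectors,
                           max_vectors = cfg$max_vectors,
                           subsample_seed = cfg$subsample_seed)
    p4 <- file.path(cfg$out_dir, "energy_profile.csv")
    write_profile_csv(prof, p4)
    paths <- c(paths, energy_profile = p4)
    out$profile <- prof
    if (cfg$plots) {
      .save_plot(
        ggplot2::ggplot(prof[prof$defined, ],
                        ggplot2::aes(x = .data$position,
                                     y = .data$energy_distance)) +
          ggplot2::geom_line() +
          ggplot2::labs(y = "energy distance"),
        file.path(cfg$out_dir, "energy_profile.pdf"))
    }
  } else {
    .log_stage("signal/energy stage skipped: signal TSVs not provided")
  }

  ## --- detection evaluation stage -----------------------------------------
  if (!is.null(truth) && (have_pileups || have_signal)) {
    metrics <- list()
    if (have_pileups) {
      sp_tv <- scored_positions(out$errors$modified$position,
                                total_variation(out$errors$modified), truth)
      metrics$total_variation <- evaluate_scores(
        sp_tv, threshold = cfg$tv_threshold, window = cfg$proximity_window)
    }
    if (have_signal) {
      sp_ed <- scored_positions(out$profile$position,
                                out$profile$energy_distance, truth)
      metrics$energy_distance <- evaluate_scores(sp_ed)
    }
    p5 <- file.path(cfg$out_dir, "metrics.json")
    jsonlite::write_json(metrics, p5, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, metrics = p5)
    out$metrics <- metrics
    .log_stage("evaluation stage: %s",
               paste(sprintf("%s AUROC %.3f", names(metrics),
                             vapply(metrics, `[[`, numeric(1), "auroc")),
                     collapse = ", "))
  } else {
    .log_stage("evaluation stage skipped: needs truth BED plus scores")
  }

  ## --- mod-call summarization stage ---------------------------------------
  have_bm <- !is.null(cfg$bedmethyl_control) && !is.null(cfg$bedmethyl_modified)
  if (have_bm) {
    mc <- read_bedmethyl(cfg$bedmethyl_control, sample = "control")
    mm <- read_bedmethyl(cfg$bedmethyl_modified, sample = "modified")
    frac <- mod_fraction(mm, positions = if (!is.null(truth)) truth$position)
    curves <- rbind(
      cbind(cumulative_curve(mc), sample = "control"),
      cbind(cumulative_curve(mm), sample = "modified"))
    p6 <- file.path(cfg$out_dir, "modsummary.csv")
    p7 <- file.path(cfg$out_dir, "cumulative_curves.csv")
    utils::write.csv(frac, p6, row.names = FALSE, quote = FALSE)
    utils::write.csv(curves, p7, row.names = FALSE, quote = FALSE)
    paths <- c(paths, modsummary = p6, cumulative_curves = p7)
    out$modsummary <- list(fraction = frac, curves = curves)
    if (cfg$plots) {
      .save_plot(
        ggplot2::ggplot(curves,
                        ggplot2::aes(x = .data$position,
                                     y = .data$cumulative_percent,
                                     colour = .data$sample)) +
          ggplot2::geom_line() +
          ggplot2::labs(y = "cumulative modification (%)"),
        file.path(cfg$out_dir, "cumulative_curves.pdf"))
    }
  } else {
    .log_stage("mod-call stage skipped: bedMethyl files not provided")
  }

  ## --- manifest ------------------------------------------------------------
  inputs <- Filter(Negate(is.null),
                   cfg[c("reference", "pileup_control", "pileup_modified",
                         "signal_control", "signal_modified",
                         "bedmethyl_control", "bedmethyl_modified",
                         "truth_bed")])
  manifest <- list(
    package = "poremod",
    version = as.character(utils::packageVersion("poremod")),
    parameters = cfg[c("min_coverage_frac", "min_vectors", "max_vectors",
                       "subsample_seed", "tv_threshold",
                       "proximity_window")],
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1)))
  )
  pm <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, manifest = pm)
  out$paths <- paths
  invisible(out)
}
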