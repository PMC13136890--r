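# Two-sample energy distance over sliding 3-nt windows.
#
# For feature sets X = {x_1..x_n} and Y = {y_1..y_m},
#   E(X, Y) = 2/(nm) sum_ij ||x_i - y_j||
#           - 1/n^2  sum_ij ||x_i - x_j||
#           - 1/m^2  sum_ij ||y_i - y_j||
# with ||.|| the Euclidean norm. E is symmetric, zero on identical multisets,
# non-negative in expectation, and scales linearly with the data.

#' @noRd
.as_feature_matrix <- function(x) {
  if (inherits(x, "sample_features")) {
    if (!isTRUE(x$defined)) return(NULL)
    x <- x$vectors
  }
  if (is.null(x)) return(NULL)
  as.matrix(x)
}

# All three terms are sliced from one pairwise distance matrix so that
# identical multisets cancel to exactly zero.
#' @noRd
.energy_terms <- function(x, y) {
  n <- nrow(x)
  m <- nrow(y)
  D <- as.matrix(stats::dist(rbind(x, y)))
  cross <- D[seq_len(n), n + seq_len(m), drop = FALSE]
  wx <- D[seq_len(n), seq_len(n), drop = FALSE]
  wy <- D[n + seq_len(m), n + seq_len(m), drop = FALSE]
  2 * sum(cross) / (n * m) - sum(wx) / n^2 - sum(wy) / m^2
}

#' Two-sample energy distance
#'
#' Computes the energy statistic between two sets of feature vectors of equal
#' dimension (rows = observations). Sets with fewer than `min_vectors` rows
#' yield `NA` (an undefined marker), not an error, so that low-coverage
#' windows drop out of profiles silently.
#'
#' @param x,y Numeric matrices (or [window_features()] results) with matching
#'   column count.
#' @param min_vectors Minimum rows required per set (default 2; profiles use
#'   a stricter default).
#' @return A single numeric value, or `NA` if either set is too small or
#'   undefined.
#' @examples
#' energy_distance(matrix(0), matrix(1), min_vectors = 1)      # 2
#' energy_distance(matrix(c(0, 0)), matrix(c(1, 3)))           # 3
#' @export
energy_distance <- function(x, y, min_vectors = 2) {
  x <- .as_feature_matrix(x)
  y <- .as_feature_matrix(y)
  if (is.null(x) || is.null(y)) return(NA_real_)
  if (nrow(x) < min_vectors || nrow(y) < min_vectors) return(NA_real_)
  if (ncol(x) != ncol(y)) {
    stop("feature sets must have the same dimension", call. = FALSE)
  }
  .energy_terms(x, y)
}

#' Per-position energy-distance profile
#'
#' Slides a 3-nt window along the reference; at each valid center both
#' samples are windowed into 9-dimensional vectors ([window_features()]),
#' optionally subsampled to at most `max_vectors` rows (seeded, uniform
#' without replacement), and compared with [energy_distance()]. Edge centers
#' and windows where either sample has fewer than `min_vectors` vectors are
#' reported as undefined (`NA` value, `defined = FALSE`).
#'
#' @param modified,control Preprocessed [signal_matrix()]s (see
#'   [preprocess_signals()]).
#' @param min_vectors Minimum vectors per sample per window (default 10).
#' @param max_vectors Cap on vectors per sample per window (default 1000);
#'   larger windows are subsampled.
#' @param subsample_seed Seed for the subsampling RNG; the caller's RNG state
#'   is untouched.
#' @return A data.frame of class `energy_profile` with columns `position`,
#'   `energy_distance`, `n`, `m`, `defined`.
#' @export
energy_profile <- function(modified, control, min_vectors = 10,
                           max_vectors = 1000, subsample_seed = 1L) {
  stopifnot(inherits(modified, "signal_matrix"),
            inherits(control, "signal_matrix"))
  L <- max(attr(modified, "ref_length"), attr(control, "ref_length"))
  if (!length(intersect(unique(modified$position),
                        unique(control$position)))) {
    stop("samples cover disjoint position ranges", call. = FALSE)
  }
  .with_seed(subsample_seed, {
    res <- lapply(seq_len(L), function(center) {
      if (center < 2L || center > L - 1L) {
        return(list(value = NA_real_, n = 0L, m = 0L, defined = FALSE))
      }
      fx <- window_features(modified, center)
      fy <- window_features(control, center)
      X <- .as_feature_matrix(fx)
      Y <- .as_feature_matrix(fy)
      n <- if (is.null(X)) 0L else nrow(X)
      m <- if (is.null(Y)) 0L else nrow(Y)
      if (n < min_vectors || m < min_vectors) {
        return(list(value = NA_real_, n = n, m = m, defined = FALSE))
      }
      if (n > max_vectors) {
        X <- X[sample.int(n, max_vectors), , drop = FALSE]
        n <- as.integer(max_vectors)
      }
      if (m > max_vectors) {
        Y <- Y[sample.int(m, max_vectors), , drop = FALSE]
        m <- as.integer(max_vectors)
      }
      list(value = energy_distance(X, Y, min_vectors = min_vectors),
           n = n, m = m, defined = TRUE)
    })
    out <- data.frame(
      position = seq_len(L),
      energy_distance = vapply(res, `[[`, numeric(1), "value"),
      n = vapply(res, `[[`, integer(1), "n"),
      m = vapply(res, `[[`, integer(1), "m"),
      defined = vapply(res, `[[`, logical(1), "defined")
    )
    class(out) <- c("energy_profile", "data.frame")
    out
  })
}

#' Read / write the energy-profile CSV dialect
#'
#' Columns: `position, energy_distance, n, m, defined`.
#'
#' @param ep An [energy_profile()] result.
#' @param path File path.
#' @return `write_profile_csv()` the path invisibly; `read_profile_csv()` an
#'   `energy_profile`.
#' @export
write_profile_csv <- function(ep, path) {
  stopifnot(inherits(ep, "energy_profile"))
  utils::write.csv(as.data.frame(ep), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  .check_file(path, "profile CSV")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "energy_distance", "n", "m", "defined")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("profile CSV missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("energy_profile", "data.frame")
  df
}

#' @export
print.energy_profile <- function(x, ...) {
  def <- x$defined
  cat(sprintf(
    "<energy_profile> %d positions (%d defined), max E = %.4g at position %s\n",
    nrow(x), sum(def),
    if (any(def)) max(x$energy_distance[def]) else NA,
    if (any(def)) x$position[def][which.max(x$energy_distance[def])] else "NA"))
  NextMethod()
}
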