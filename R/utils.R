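# Internal helpers shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

#' @noRd
.cfg_stop <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normalize a base vector to the RNA alphabet (DNA T -> U, upper case).
#' @noRd
.to_rna <- function(x) {
  x <- toupper(x)
  x[x == "T"] <- "U"
  x
}

#' @noRd
.check_file <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("%s not found: %s", what, as.character(path)[1]), call. = FALSE)
  }
  invisible(path)
}
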