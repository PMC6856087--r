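#' Derive a child seed from a master seed
#'
#' Child seeds for partitions, models and traits are derived from a single
#' master seed by a stable string hash, so that every source of randomness in
#' a run is reproducible from one integer without seed collisions between
#' stages.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the consumer
#'   (e.g. `"partition"`, `3`, `"MTDL"`).
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
#' @examples
#' deriveSeed(1, "partition", 2, "GBLUP")
deriveSeed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483563
  as.integer(h) + 1L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Zero-padded label makers used throughout the generator.
lineLabels <- function(n) sprintf("L%0*d", max(3L, nchar(n)), seq_len(n))
markerLabels <- function(n) sprintf("M%0*d", max(4L, nchar(n)), seq_len(n))
envLabels <- function(n) paste0("E", seq_len(n))

# Check a square matrix is symmetric PSD up to numerical jitter.
assertPSD <- function(g, tol = 1e-6, what = "matrix") {
  if (!isSymmetric(unname(g), tol = 1e-8))
    stop(what, " must be symmetric", call. = FALSE)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop(what, " is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}
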