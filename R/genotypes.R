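#' Construct a MarkerMatrix from a dosage matrix
#'
#' @param values Numeric lines x markers matrix of allele dosages in
#'   \{0, 1, 2\} (NA = missing). Row/column names are used as line/marker
#'   IDs; defaults are generated when absent.
#' @param imputed Logical; set `TRUE` when entries are post-imputation
#'   continuous dosages.
#' @return A [MarkerMatrix-class].
#' @export
#' @examples
#' m <- markerMatrix(matrix(c(0, 1, 2, NA), 2, 2))
markerMatrix <- function(values, imputed = FALSE) {
  values <- as.matrix(values)
  if (is.logical(values)) storage.mode(values) <- "double"  # all-NA columns
  if (is.null(rownames(values))) rownames(values) <- lineLabels(nrow(values))
  if (is.null(colnames(values))) colnames(values) <- markerLabels(ncol(values))
  new("MarkerMatrix", values = values, imputed = imputed)
}

#' Marker quality control
#'
#' Retains exactly the markers with a missing fraction at most `max_missing`
#' and minor allele frequency at least `min_maf`. MAF is computed on
#' non-missing calls as `min(f, 1 - f)` where `f` is half the mean dosage.
#' The order of surviving markers is preserved.
#'
#' @param m A [MarkerMatrix-class].
#' @param max_missing Maximum tolerated missing fraction (default 0.10:
#'   markers with more than 10\% missing calls are excluded).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return A filtered [MarkerMatrix-class].
#' @export
qcMarkers <- function(m, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(is(m, "MarkerMatrix"))
  v <- m@values
  if (ncol(v) == 0) stop("empty marker matrix")
  miss <- colMeans(is.na(v))
  f <- colMeans(v, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- miss <= max_missing & !is.nan(maf) & maf >= min_maf
  if (!any(keep))
    stop("quality control removed every marker (", ncol(v), " tested)")
  new("MarkerMatrix", values = v[, keep, drop = FALSE], imputed = m@imputed)
}

#' Mean imputation of missing genotype calls
#'
#' Missing entries are replaced by the marker's mean dosage over non-missing
#' calls; non-missing entries are unchanged. Column means are therefore
#' invariant under imputation.
#'
#' @param m A [MarkerMatrix-class]; every marker must have at least one
#'   non-missing call (run [qcMarkers()] first).
#' @return A [MarkerMatrix-class] with `imputed = TRUE`.
#' @export
imputeMissing <- function(m) {
  stopifnot(is(m, "MarkerMatrix"))
  v <- m@values
  nm <- colSums(!is.na(v))
  if (any(nm == 0))
    stop("marker(s) with all calls missing: ",
         paste(head(colnames(v)[nm == 0], 5), collapse = ", "),
         " - remove them with qcMarkers() first")
  if (anyNA(v)) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2]]
  }
  new("MarkerMatrix", values = v, imputed = TRUE)
}

#' Genomic relationship matrix G = W W^T / p
#'
#' With `center = TRUE` (default) `W` is the column-centered dosage matrix,
#' the VanRaden-style realized kinship; with `center = FALSE` the raw
#' dosages are used. Scaling is by the number of markers `p`.
#'
#' @param m An imputed (no missing values) [MarkerMatrix-class].
#' @param center Center marker columns before forming the cross-product.
#' @return A [GRM-class].
#' @export
computeGRM <- function(m, center = TRUE) {
  stopifnot(is(m, "MarkerMatrix"))
  v <- m@values
  if (ncol(v) == 0) stop("cannot compute a GRM from zero markers")
  if (anyNA(v)) stop("marker matrix contains missing values; impute first")
  if (center) v <- sweep(v, 2, colMeans(v))
  g <- tcrossprod(v) / ncol(v)
  g <- (g + t(g)) / 2                   # enforce exact symmetry
  new("GRM", matrix = g)
}

#' GRM constructor from a plain matrix
#' @param g Symmetric numeric matrix with line IDs as dimnames (generated
#'   when absent).
#' @return A [GRM-class].
#' @export
grmMatrix <- function(g) {
  g <- as.matrix(g)
  if (is.null(rownames(g))) dimnames(g) <- list(lineLabels(nrow(g)),
                                                lineLabels(ncol(g)))
  colnames(g) <- rownames(g)
  new("GRM", matrix = (g + t(g)) / 2)
}

#' Cholesky factor of a (jittered) GRM
#'
#' Returns the upper-triangular `U` with `crossprod(U) = G + eps * I`, where
#' `eps` is the smallest value in the geometric ladder \{0, jitter_start,
#' 10 jitter_start, ..., 1e-2 trace(G)/J\} for which the factorization
#' succeeds. A rank-deficient GRM (e.g. duplicated lines) therefore factors
#' with a small reported ridge. The feature encoding for the networks uses
#' `t(U)`, the transpose of this upper factor.
#'
#' @param g A [GRM-class] (or symmetric matrix).
#' @param jitter_start First non-zero ridge to try (default 1e-8).
#' @return A [CholeskyFactor-class]; slot `jitter` holds the ridge used.
#' @export
choleskyFactor <- function(g, jitter_start = 1e-8) {
  gm <- if (is(g, "GRM")) g@matrix else as.matrix(grmMatrix(g))
  J <- nrow(gm)
  cap <- 1e-2 * max(sum(diag(gm)), J * jitter_start) / J
  eps <- 0
  repeat {
    u <- tryCatch(chol(gm + diag(eps, J)), error = function(e) NULL)
    if (!is.null(u)) {
      dimnames(u) <- dimnames(gm)
      return(new("CholeskyFactor", upper = u, jitter = eps))
    }
    if (eps >= cap)
      stop("Cholesky factorization failed even at ridge ", format(eps),
           "; the GRM is not a valid relationship matrix")
    eps <- if (eps == 0) jitter_start else 10 * eps
    eps <- min(eps, cap)
  }
}

# ---- text I/O ---------------------------------------------------------------

#' Read/write genotype, GRM and phenotype tables as CSV
#'
#' `writeGenotypesCSV()`/`readGenotypesCSV()` store lines in rows with a
#' leading `line` column and marker IDs as header, missing calls as `NA`.
#' `readGenotypesRaw()` reads PLINK `.raw`-style whitespace-delimited dosage
#' text (FID IID PAT MAT SEX PHENOTYPE then one column per marker).
#' `writeGRMCSV()`/`readGRMCSV()` store the square matrix with line-ID
#' header and leading column. Phenotypes travel as long CSV with columns
#' `line,environment,trait,value`.
#'
#' @param m,g Objects to write.
#' @param pheno Long phenotype data frame.
#' @param path File path.
#' @return Readers return the corresponding object; writers return the path
#'   invisibly.
#' @name gpMET-io
NULL

#' @rdname gpMET-io
#' @export
writeGenotypesCSV <- function(m, path) {
  stopifnot(is(m, "MarkerMatrix"))
  df <- data.frame(line = rownames(m@values), m@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname gpMET-io
#' @export
readGenotypesCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  storage.mode(v) <- "double"
  markerMatrix(v, imputed = anyNA(v) == FALSE && any(v %% 1 != 0))
}

#' @rdname gpMET-io
#' @export
readGenotypesRaw <- function(path) {
  df <- read.table(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    colnames(df))
  ids <- if ("IID" %in% colnames(df)) as.character(df$IID) else
    lineLabels(nrow(df))
  v <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  markerMatrix(v)
}

#' @rdname gpMET-io
#' @export
writeGRMCSV <- function(g, path) {
  gm <- if (is(g, "GRM")) g@matrix else as.matrix(g)
  df <- data.frame(line = rownames(gm), gm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname gpMET-io
#' @export
readGRMCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df[[1]]
  grmMatrix(g)
}

#' @rdname gpMET-io
#' @export
writePhenotypesCSV <- function(pheno, path) {
  stopifnot(all(c("line", "environment", "trait", "value") %in% names(pheno)))
  write.csv(pheno[, c("line", "environment", "trait", "value")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname gpMET-io
#' @export
readPhenotypesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("line", "environment", "trait", "value") %in% names(df)))
  df$line <- as.character(df$line)
  df$environment <- as.character(df$environment)
  df$trait <- as.character(df$trait)
  df
}
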