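#' @import methods
#' @importFrom stats rnorm runif rbinom rchisq median var sd setNames predict
#' @importFrom utils read.csv write.csv read.table packageVersion head
NULL

#' MarkerMatrix: biallelic SNP dosages for a panel of lines
#'
#' Lines in rows, markers in columns. Raw calls are allele dosages in
#' \{0, 1, 2\} with `NA` for missing; after mean imputation
#' (`imputeMissing()`) entries may be continuous, flagged by the `imputed`
#' slot.
#'
#' @slot values Numeric lines x markers matrix (dimnames = line/marker IDs).
#' @slot imputed Logical; `TRUE` once missing calls have been imputed.
#' @export
setClass("MarkerMatrix",
  representation(values = "matrix", imputed = "logical"),
  prototype(imputed = FALSE))

setValidity("MarkerMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry line (row) and marker (column) names")
  if (anyDuplicated(rownames(v))) return("duplicate line IDs")
  if (anyDuplicated(colnames(v))) return("duplicate marker IDs")
  if (!is.numeric(v)) return("values must be numeric")
  if (!object@imputed) {
    ok <- is.na(v) | v == 0 | v == 1 | v == 2
    if (!all(ok)) return("non-missing raw calls must be in {0, 1, 2}")
  } else if (anyNA(v)) return("imputed matrix must not contain NA")
  TRUE
})

#' GRM: genomic relationship matrix
#'
#' Symmetric, positive semi-definite (up to numerical jitter) realized-kinship
#' matrix over lines, typically \eqn{G = WW^T/p} from (centered) marker
#' dosages.
#'
#' @slot matrix Numeric J x J symmetric matrix with line IDs as dimnames.
#' @export
setClass("GRM", representation(matrix = "matrix"))

setValidity("GRM", function(object) {
  g <- object@matrix
  if (nrow(g) != ncol(g)) return("GRM must be square")
  if (is.null(rownames(g)) || !identical(rownames(g), colnames(g)))
    return("GRM must have identical row and column line IDs")
  if (anyDuplicated(rownames(g))) return("duplicate line IDs")
  if (!isSymmetric(unname(g), tol = 1e-8)) return("GRM must be symmetric")
  TRUE
})

#' CholeskyFactor: upper-triangular factor of a (jittered) GRM
#'
#' Holds the upper-triangular `U` with `crossprod(U) = G + jitter * I`; the
#' neural-network feature encoding post-multiplies design matrices by `t(U)`.
#'
#' @slot upper Numeric upper-triangular J x J matrix.
#' @slot jitter Numeric ridge added to the diagonal before factorization.
#' @export
setClass("CholeskyFactor",
  representation(upper = "matrix", jitter = "numeric"))

setValidity("CholeskyFactor", function(object) {
  u <- object@upper
  if (nrow(u) != ncol(u)) return("factor must be square")
  if (is.null(rownames(u)) || !identical(rownames(u), colnames(u)))
    return("factor must carry line IDs on both dimensions")
  if (any(u[lower.tri(u)] != 0)) return("factor must be upper triangular")
  if (length(object@jitter) != 1 || object@jitter < 0)
    return("jitter must be a single non-negative number")
  TRUE
})

#' GBLUPFit: a fitted multi-environment GBLUP model
#'
#' @slot envEffects Named numeric vector of environment fixed effects.
#' @slot genomicBlups Named numeric vector of line genomic BLUPs.
#' @slot interactionBlups Environments x lines matrix of G x E BLUPs
#'   (0 x 0 when the model excludes the interaction).
#' @slot varianceEstimates List with components `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, each `c(mean, sd)` (sd is `NA` for the exact solver;
#'   `sigma2_ge` is `NULL` without interaction).
#' @slot includeInteraction Logical.
#' @slot estimator Character, `"gibbs"` or `"fixed_variances"`.
#' @slot diagnostics List of chain summaries (n kept samples, thinning,
#'   posterior draws of the variances).
#' @export
setClass("GBLUPFit",
  representation(envEffects = "numeric", genomicBlups = "numeric",
                 interactionBlups = "matrix", varianceEstimates = "list",
                 includeInteraction = "logical", estimator = "character",
                 diagnostics = "list"))

#' EncodedInputs: feature matrix for the deep-learning models
#'
#' Concatenation `X = [Z_E, Z_G U^T, Z_GE (I (x) U^T)]` (interaction block
#' optional), with labeled column spans per block.
#'
#' @slot X Numeric feature matrix, one row per phenotype record.
#' @slot blocks Named list of integer column index vectors
#'   (`environment`, `genotype`, optionally `interaction`).
#' @export
setClass("EncodedInputs",
  representation(X = "matrix", blocks = "list"))

#' TrainedNetwork: a fitted feedforward network
#'
#' @slot weights List of weight matrices (input -> hidden ... -> output).
#' @slot biases List of bias vectors, one per non-input layer.
#' @slot spec List of hyperparameters used for training.
#' @slot center,scale Numeric vectors standardizing features at prediction.
#' @slot history Data frame of per-epoch training (and validation) loss.
#' @slot bestEpoch Integer epoch with minimal validation loss (final epoch
#'   when no validation set was supplied).
#' @export
setClass("TrainedNetwork",
  representation(weights = "list", biases = "list", spec = "list",
                 center = "numeric", scale = "numeric",
                 history = "data.frame", bestEpoch = "integer"))

#' CVPartition: one CV1 train/test split over observed cells
#'
#' @slot id Integer partition index.
#' @slot testCells,trainCells Data frames with columns `line`,
#'   `environment`; disjoint, union = all observed cells.
#' @export
setClass("CVPartition",
  representation(id = "integer", testCells = "data.frame",
                 trainCells = "data.frame"))

setValidity("CVPartition", function(object) {
  key <- function(d) paste(d$line, d$environment, sep = "\r")
  if (anyDuplicated(key(object@testCells))) return("duplicate test cells")
  if (any(key(object@testCells) %in% key(object@trainCells)))
    return("test and training cells overlap")
  TRUE
})

#' PredictionReport: observed vs. predicted values with MAAPE summaries
#'
#' @slot records Data frame with one row per predicted (cell, trait):
#'   partition, model, interaction, trait, line, environment, observed,
#'   predicted.
#' @slot perEnv Per (model, interaction, trait, environment) MAAPE averaged
#'   over partitions.
#' @slot summaries Cross-environment min/max/mean/median MAAPE per
#'   (model, interaction, trait).
#' @slot winners Count per (interaction, trait, model) of environments where
#'   that model achieved the lowest MAAPE.
#' @export
setClass("PredictionReport",
  representation(records = "data.frame", perEnv = "data.frame",
                 summaries = "data.frame", winners = "data.frame"))

# ---- generics & accessors ---------------------------------------------------

#' Line identifiers of a gpMET object
#' @param x A `MarkerMatrix`, `GRM` or `CholeskyFactor`.
#' @return Character vector of line IDs.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname lineIds
#' @export
setMethod("lineIds", "MarkerMatrix", function(x) rownames(x@values))
#' @rdname lineIds
#' @export
setMethod("lineIds", "GRM", function(x) rownames(x@matrix))
#' @rdname lineIds
#' @export
setMethod("lineIds", "CholeskyFactor", function(x) rownames(x@upper))

#' Marker identifiers of a MarkerMatrix
#' @param x A `MarkerMatrix`.
#' @return Character vector of marker IDs.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname markerIds
#' @export
setMethod("markerIds", "MarkerMatrix", function(x) colnames(x@values))

#' @export
#' @describeIn MarkerMatrix-class extract the dosage matrix.
#' @param x A `MarkerMatrix`.
#' @param ... Unused.
setMethod("as.matrix", "MarkerMatrix", function(x, ...) x@values)

#' @export
#' @describeIn GRM-class extract the relationship matrix.
#' @param x A `GRM`.
#' @param ... Unused.
setMethod("as.matrix", "GRM", function(x, ...) x@matrix)

#' @export
#' @describeIn CholeskyFactor-class extract the upper-triangular factor.
#' @param x A `CholeskyFactor`.
#' @param ... Unused.
setMethod("as.matrix", "CholeskyFactor", function(x, ...) x@upper)

setMethod("show", "MarkerMatrix", function(object) {
  v <- object@values
  cat("MarkerMatrix:", nrow(v), "lines x", ncol(v), "markers;",
      sprintf("%.2f%%", 100 * mean(is.na(v))), "missing",
      if (object@imputed) "(imputed)" else "", "\n")
})

setMethod("show", "GRM", function(object) {
  cat("GRM over", nrow(object@matrix), "lines; mean diagonal",
      sprintf("%.3f", mean(diag(object@matrix))), "\n")
})

setMethod("show", "CholeskyFactor", function(object) {
  cat("CholeskyFactor over", nrow(object@upper), "lines; jitter",
      format(object@jitter), "\n")
})

setMethod("show", "GBLUPFit", function(object) {
  cat("GBLUPFit (", object@estimator, ", ",
      if (object@includeInteraction) "with" else "without",
      " G x E interaction)\n", sep = "")
  cat("  environments:", length(object@envEffects),
      " lines:", length(object@genomicBlups), "\n")
  ve <- object@varianceEstimates
  cat("  variances: sigma2_g =", sprintf("%.4g", ve$sigma2_g[1]),
      if (object@includeInteraction)
        paste(" sigma2_ge =", sprintf("%.4g", ve$sigma2_ge[1])) else "",
      " sigma2_e =", sprintf("%.4g", ve$sigma2_e[1]), "\n")
})

setMethod("show", "TrainedNetwork", function(object) {
  s <- object@spec
  cat("TrainedNetwork:", s$n_hidden_layers, "hidden layer(s) x",
      s$units_per_layer, "units ->", s$n_outputs, "output(s);",
      nrow(object@history), "epochs trained\n")
})

setMethod("show", "CVPartition", function(object) {
  cat("CVPartition", object@id, ":", nrow(object@testCells), "test /",
      nrow(object@trainCells), "training cells\n")
})

setMethod("show", "PredictionReport", function(object) {
  cat("PredictionReport:", nrow(object@records), "predicted records\n")
  if (nrow(object@summaries)) print(object@summaries, row.names = FALSE)
})

#' Components of a prediction report
#' @param x A `PredictionReport`.
#' @return The corresponding data frame.
#' @export
reportRecords <- function(x) x@records
#' @rdname reportRecords
#' @export
perEnvMAAPE <- function(x) x@perEnv
#' @rdname reportRecords
#' @export
reportSummaries <- function(x) x@summaries
#' @rdname reportRecords
#' @export
reportWinners <- function(x) x@winners
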