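#' Configuration of an end-to-end prediction experiment
#'
#' Either `genotypes_csv`/`phenotypes_csv` point at input tables, or data
#' are simulated from `simulation`. The experiment crosses the selected
#' models with the selected interaction modes over CV1 partitions. All
#' randomness derives from `seed` through [deriveSeed()].
#'
#' @param simulation A [simulationConfig()] (used when no input paths are
#'   given).
#' @param genotypes_csv,phenotypes_csv Optional input paths (as written by
#'   [writeGenotypesCSV()]/[writePhenotypesCSV()]).
#' @param models Subset of `c("GBLUP", "UDL", "MTDL")`.
#' @param interaction_modes Subset of `c("I", "WI")` (with / without the
#'   genotype-by-environment term).
#' @param p_testing,n_partitions CV1 controls.
#' @param gblup A [gblupSpec()].
#' @param network A [networkSpec()] template for both DL models.
#' @param grid A [hyperGrid()]; the default is the desk-scale grid (units
#'   20/60/100, epochs up to 50, layers 1--2). Set `paper_grid = TRUE` for
#'   the full 6,000-combination grid.
#' @param paper_grid Use the full grid (units 20--200 step 20, epochs
#'   1--200, layers 1--3); intended for cluster-scale runs.
#' @param qc_max_missing,qc_min_maf Marker QC thresholds.
#' @param center_grm Center marker columns when computing the GRM.
#' @param outdir Optional output directory for CSV/JSON artifacts.
#' @param seed Master seed.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      genotypes_csv = NULL, phenotypes_csv = NULL,
                      models = c("GBLUP", "UDL", "MTDL"),
                      interaction_modes = c("I", "WI"),
                      p_testing = 0.20, n_partitions = 5,
                      gblup = gblupSpec(),
                      network = networkSpec(),
                      grid = NULL, paper_grid = FALSE,
                      qc_max_missing = 0.10, qc_min_maf = 0.05,
                      center_grm = TRUE, outdir = NULL, seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  interaction_modes <- match.arg(interaction_modes, c("I", "WI"),
                                 several.ok = TRUE)
  if (length(models) == 0 || length(interaction_modes) == 0)
    stop("select at least one model and one interaction mode")
  if (is.null(grid))
    grid <- if (paper_grid) hyperGrid()
            else hyperGrid(units_values = c(20L, 60L, 100L),
                           epoch_values = 1:50, layer_values = 1:2)
  structure(list(simulation = simulation, genotypes_csv = genotypes_csv,
                 phenotypes_csv = phenotypes_csv, models = models,
                 interaction_modes = interaction_modes,
                 p_testing = p_testing,
                 n_partitions = as.integer(n_partitions),
                 gblup = gblup, network = network, grid = grid,
                 qc_max_missing = qc_max_missing, qc_min_maf = qc_min_maf,
                 center_grm = center_grm, outdir = outdir,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [runConfig()]; the nested
#' `simulation`, `gblup`, `network` and `grid` blocks mirror
#' [simulationConfig()], [gblupSpec()], [networkSpec()] and [hyperGrid()].
#'
#' @param path YAML file path.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$trait_genetic_correlation))
      sim$trait_genetic_correlation <-
        do.call(rbind, sim$trait_genetic_correlation)
    args$simulation <- do.call(simulationConfig, sim)
  }
  if (!is.null(raw$gblup)) args$gblup <- do.call(gblupSpec, raw$gblup)
  if (!is.null(raw$network)) args$network <- do.call(networkSpec, raw$network)
  if (!is.null(raw$grid)) args$grid <- do.call(hyperGrid, raw$grid)
  do.call(runConfig, args)
}

# One partition x one DL model x one interaction mode -> prediction records.
runDeepModel <- function(model, mode, part, enc_all, cellsAll, wide, traits,
                         config, child_seed) {
  inter <- mode == "I"
  keyAll <- paste(cellsAll$line, cellsAll$environment, sep = "\r")
  trnKey <- paste(part@trainCells$line, part@trainCells$environment, sep = "\r")
  tstKey <- paste(part@testCells$line, part@testCells$environment, sep = "\r")
  tr <- match(trnKey, keyAll); te <- match(tstKey, keyAll)
  X <- enc_all@X
  tmpl <- config$network
  tmpl$seed <- child_seed
  class(tmpl) <- "NetworkSpec"
  fitOne <- function(targets) {
    gs <- gridSearch(X[tr, , drop = FALSE], targets[tr, , drop = FALSE],
                     grid = config$grid, spec_template = tmpl)
    sp <- gs$best_spec
    fit <- trainNetwork(X[tr, , drop = FALSE], targets[tr, , drop = FALSE], sp)
    predictNetwork(fit, X[te, , drop = FALSE])
  }
  recs <- list()
  if (model == "MTDL") {
    targets <- as.matrix(wide[, traits, drop = FALSE])
    pred <- fitOne(targets)
    for (t in seq_along(traits)) {
      recs[[t]] <- data.frame(
        partition = part@id, model = model, interaction = mode,
        trait = traits[t], line = part@testCells$line,
        environment = part@testCells$environment,
        observed = wide[te, traits[t]], predicted = pred[, t],
        stringsAsFactors = FALSE)
    }
  } else {
    for (t in seq_along(traits)) {
      tmpl$seed <- deriveSeed(child_seed, traits[t])
      targets <- as.matrix(wide[, traits[t], drop = FALSE])
      pred <- fitOne(targets)
      recs[[t]] <- data.frame(
        partition = part@id, model = model, interaction = mode,
        trait = traits[t], line = part@testCells$line,
        environment = part@testCells$environment,
        observed = wide[te, traits[t]], predicted = pred[, 1],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Run the full prediction experiment
#'
#' Executes marker QC, imputation, GRM and Cholesky factorization, CV1
#' partitioning, and — per partition — fits every selected model in every
#' selected interaction mode on the training cells and predicts the test
#' cells, then summarizes per-environment MAAPE. A failure in one model is
#' recorded and does not abort the others. With `outdir` set, tidy CSV
#' tables and a JSON manifest (configuration digest, seeds, package
#' version) are written.
#'
#' @param config A [runConfig()].
#' @return A [PredictionReport-class]; attribute `"manifest"` carries the
#'   run metadata, attribute `"failures"` any per-model errors.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  seed <- config$seed

  if (!is.null(config$genotypes_csv)) {
    geno <- readGenotypesCSV(config$genotypes_csv)
    pheno <- readPhenotypesCSV(config$phenotypes_csv)
  } else {
    sim <- config$simulation
    sim$seed <- deriveSeed(seed, "simulation")
    class(sim) <- "SimulationConfig"
    geno <- simulateMarkers(sim)
  }
  geno <- qcMarkers(geno, config$qc_max_missing, config$qc_min_maf)
  geno <- imputeMissing(geno)
  grm <- computeGRM(geno, center = config$center_grm)
  cf <- choleskyFactor(grm)
  if (is.null(config$genotypes_csv)) {
    design <- makeIncompleteDesign(sim)
    pheno <- simulatePhenotypes(design, grm, sim)$phenotypes
  }

  traits <- unique(pheno$trait)
  cellsAll <- unique(pheno[, c("line", "environment")])
  rownames(cellsAll) <- NULL
  keyAll <- paste(cellsAll$line, cellsAll$environment, sep = "\r")
  wide <- cellsAll
  for (t in traits) {
    sub <- pheno[pheno$trait == t, ]
    wide[[t]] <- sub$value[match(keyAll,
                                 paste(sub$line, sub$environment, sep = "\r"))]
  }

  env_ids <- unique(cellsAll$environment)
  line_ids <- lineIds(grm)
  Z <- buildDesignMatrices(cellsAll, env_ids, line_ids)
  needI <- "I" %in% config$interaction_modes &&
    any(c("UDL", "MTDL") %in% config$models)
  enc <- list(
    I = if (needI) encodeFeatures(Z$Z_E, Z$Z_G, Z$Z_GE, cf,
                                  include_interaction = TRUE),
    WI = if (any(c("UDL", "MTDL") %in% config$models))
      encodeFeatures(Z$Z_E, Z$Z_G, NULL, cf, include_interaction = FALSE))

  parts <- cv1Partition(pheno, config$p_testing, config$n_partitions,
                        seed = deriveSeed(seed, "cv1"))

  records <- list(); failures <- list()
  for (part in parts) {
    trnKey <- paste(part@trainCells$line, part@trainCells$environment,
                    sep = "\r")
    tstKey <- paste(part@testCells$line, part@testCells$environment,
                    sep = "\r")
    for (mode in config$interaction_modes) {
      for (model in config$models) {
        child <- deriveSeed(seed, "partition", part@id, model, mode)
        res <- tryCatch({
          if (model == "GBLUP") {
            recs <- list()
            for (t in traits) {
              sub <- pheno[pheno$trait == t, ]
              subKey <- paste(sub$line, sub$environment, sep = "\r")
              trn <- sub[subKey %in% trnKey, ]
              spec <- config$gblup
              spec$include_interaction <- mode == "I"
              spec$seed <- deriveSeed(child, t)
              class(spec) <- "GBLUPSpec"
              fit <- fitGBLUP(trn, grm, spec, env_ids = env_ids)
              obs <- sub$value[match(tstKey, subKey)]
              recs[[t]] <- data.frame(
                partition = part@id, model = model, interaction = mode,
                trait = t, line = part@testCells$line,
                environment = part@testCells$environment,
                observed = obs,
                predicted = predictGBLUP(fit, part@testCells),
                stringsAsFactors = FALSE)
            }
            do.call(rbind, recs)
          } else {
            runDeepModel(model, mode, part, enc[[mode]], cellsAll, wide,
                         traits, config, child)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[paste(part@id, model, mode, sep = "/")]] <-
            conditionMessage(res)
        } else {
          records[[length(records) + 1L]] <- res
        }
      }
    }
  }
  if (length(records) == 0)
    stop("every model failed: ",
         paste(unlist(failures), collapse = " | "))
  records <- do.call(rbind, records)
  report <- summarizePredictions(records)
  manifest <- list(
    package = "gpMET", version = as.character(packageVersion("gpMET")),
    seed = seed, models = config$models,
    interaction_modes = config$interaction_modes,
    n_partitions = config$n_partitions, p_testing = config$p_testing,
    n_markers_post_qc = length(markerIds(geno)),
    n_lines = length(line_ids), n_envs = length(env_ids),
    traits = traits, failures = failures)
  attr(report, "manifest") <- manifest
  attr(report, "failures") <- failures
  if (!is.null(config$outdir)) writeReport(report, config$outdir, manifest)
  report
}

#' Write a prediction report to tidy CSV plus a JSON manifest
#'
#' @param report A [PredictionReport-class].
#' @param outdir Output directory (created if needed).
#' @param manifest Optional manifest list (defaults to the report's
#'   attribute).
#' @return `outdir`, invisibly.
#' @export
writeReport <- function(report, outdir, manifest = attr(report, "manifest")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report@records, file.path(outdir, "records.csv"),
            row.names = FALSE)
  write.csv(report@perEnv, file.path(outdir, "per_env_maape.csv"),
            row.names = FALSE)
  write.csv(report@summaries, file.path(outdir, "summaries.csv"),
            row.names = FALSE)
  write.csv(report@winners, file.path(outdir, "winners.csv"),
            row.names = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
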