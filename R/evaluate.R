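#' CV1 random cross-validation over observed cells
#'
#' Emulates prediction in incomplete trials: each partition hides
#' `round(p_testing * N)` distinct observed (line, environment) cells, where
#' N is the number of observed cells. Cells are drawn by sampling a line —
#' without replacement if the number of distinct lines J is at least the
#' target count, with replacement otherwise — then one environment uniformly
#' among that line's observed environments; duplicate draws are redrawn
#' until the target count of distinct cells is reached. Partitions are drawn
#' independently, so a cell may appear in the test set of more than one
#' partition. Every environment keeps at least one training record
#' (offending cells are redrawn, with a message).
#'
#' @param pheno Long phenotype data frame (`line`, `environment`, ...); the
#'   observed cells are the distinct (line, environment) pairs.
#' @param p_testing Fraction of cells assigned to testing, in (0, 1)
#'   (default 0.20).
#' @param n_partitions Number of independent partitions (default 5).
#' @param seed Integer seed; partitions are reproducible given it.
#' @return List of [CVPartition-class] objects.
#' @export
cv1Partition <- function(pheno, p_testing = 0.20, n_partitions = 5, seed = 1) {
  if (p_testing <= 0 || p_testing >= 1) stop("p_testing must be in (0, 1)")
  cells <- unique(pheno[, c("line", "environment")])
  rownames(cells) <- NULL
  N <- nrow(cells)
  target <- round(p_testing * N)
  lines <- unique(cells$line)
  J <- length(lines)
  env_of <- split(cells$environment, cells$line)[lines]
  if (any(lengths(env_of) == 0)) stop("every line must be observed somewhere")
  cellKey <- paste(cells$line, cells$environment, sep = "\r")
  env_sizes <- table(cells$environment)
  if (target > N) stop("unreachable test-set size")

  lapply(seq_len(n_partitions), function(k) {
    withSeed(deriveSeed(seed, "cv1", k), {
      test <- character(0)
      drawCell <- function() {
        ln <- lines[sample.int(J, 1)]
        ev <- env_of[[ln]]
        ev <- ev[sample.int(length(ev), 1)]
        paste(ln, ev, sep = "\r")
      }
      if (J >= target) {
        # distinct lines guarantee distinct cells
        ln <- lines[sample.int(J, target)]
        test <- vapply(ln, function(l) {
          ev <- env_of[[l]]
          paste(l, ev[sample.int(length(ev), 1)], sep = "\r")
        }, "", USE.NAMES = FALSE)
      } else {
        while (length(test) < target) {
          cand <- drawCell()
          if (!cand %in% test) test <- c(test, cand)
        }
      }
      # every environment must retain >= 1 training record
      testEnv <- function(t) sub("^.*\r", "", t)
      for (guard in seq_len(1000L)) {
        tallies <- table(factor(testEnv(test), names(env_sizes)))
        bad <- names(tallies)[tallies == env_sizes[names(tallies)]]
        if (length(bad) == 0) break
        message("cv1Partition: redrawing test cell(s) to keep environment(s) ",
                paste(bad, collapse = ", "), " represented in training")
        drop <- vapply(bad, function(e) {
          inEnv <- which(testEnv(test) == e)
          inEnv[sample.int(length(inEnv), 1)]
        }, 1L)
        test <- test[-drop]
        attempts <- 0L
        while (length(test) < target) {
          attempts <- attempts + 1L
          if (attempts > 10000L)
            stop("unreachable test-set target under the environment-coverage ",
                 "constraint")
          cand <- drawCell()
          if (cand %in% test) next
          e <- sub("^.*\r", "", cand)
          if (sum(testEnv(test) == e) + 1 >= env_sizes[[e]]) next
          test <- c(test, cand)
        }
      }
      in_test <- cellKey %in% test
      new("CVPartition", id = as.integer(k),
          testCells = cells[in_test, , drop = FALSE],
          trainCells = cells[!in_test, , drop = FALSE])
    })
  })
}

#' Mean arctangent absolute percentage error
#'
#' `mean(atan(|(y - yhat) / y|))`, a scale-free prediction-error metric
#' bounded in `[0, pi/2]`. When the observed value is zero the term is
#' `pi/2` if the prediction is non-zero (the division-by-zero limit) and 0
#' if both are zero. Smaller is better.
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @param na.rm Drop pairs with a missing member.
#' @return A value in `[0, pi/2]`.
#' @export
#' @examples
#' maape(c(1, 2), c(2, 2))  # mean(atan(1), atan(0)) = pi/8
maape <- function(observed, predicted, na.rm = FALSE) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) == 0) stop("empty vectors")
  if (na.rm) {
    ok <- !(is.na(observed) | is.na(predicted))
    observed <- observed[ok]; predicted <- predicted[ok]
    if (length(observed) == 0) stop("no complete pairs")
  }
  terms <- ifelse(observed == 0,
                  ifelse(predicted == 0, 0, pi / 2),
                  atan(abs((observed - predicted) / observed)))
  mean(terms)
}

#' Summarize prediction records into a per-environment MAAPE report
#'
#' For every (model, interaction, trait, environment), MAAPE is computed
#' over that environment's test cells within each partition and then
#' averaged (unweighted) over the partitions in which the environment was
#' tested. Cross-environment range/mean/median per (model, interaction,
#' trait) and per-environment winner tallies are also reported.
#' Environments with no test cells in any partition are excluded with a
#' message.
#'
#' @param records Data frame with columns `partition`, `model`,
#'   `interaction`, `trait`, `line`, `environment`, `observed`,
#'   `predicted`.
#' @return A [PredictionReport-class].
#' @export
summarizePredictions <- function(records) {
  needed <- c("partition", "model", "interaction", "trait", "line",
              "environment", "observed", "predicted")
  if (!all(needed %in% names(records)))
    stop("records must contain columns: ", paste(needed, collapse = ", "))
  if (nrow(records) == 0) stop("no records")
  rec <- records[!(is.na(records$observed) | is.na(records$predicted)), ,
                 drop = FALSE]

  # per (model, interaction, trait, environment, partition) MAAPE
  grp <- interaction(rec$model, rec$interaction, rec$trait, rec$environment,
                     rec$partition, drop = TRUE, sep = "\r")
  pieces <- split(rec, grp)
  perPart <- do.call(rbind, lapply(pieces, function(d) data.frame(
    model = d$model[1], interaction = d$interaction[1], trait = d$trait[1],
    environment = d$environment[1], partition = d$partition[1],
    maape = maape(d$observed, d$predicted), stringsAsFactors = FALSE)))
  rownames(perPart) <- NULL

  allEnvs <- unique(records$environment)
  testedEnvs <- unique(perPart$environment)
  skipped <- setdiff(allEnvs, testedEnvs)
  if (length(skipped))
    message("summarizePredictions: environment(s) with no test cells in any ",
            "partition excluded: ", paste(skipped, collapse = ", "))

  grp2 <- interaction(perPart$model, perPart$interaction, perPart$trait,
                      perPart$environment, drop = TRUE, sep = "\r")
  perEnv <- do.call(rbind, lapply(split(perPart, grp2), function(d) data.frame(
    model = d$model[1], interaction = d$interaction[1], trait = d$trait[1],
    environment = d$environment[1], maape = mean(d$maape),
    n_partitions = nrow(d), stringsAsFactors = FALSE)))
  perEnv <- perEnv[order(perEnv$model, perEnv$interaction, perEnv$trait,
                         perEnv$environment), ]
  rownames(perEnv) <- NULL

  grp3 <- interaction(perEnv$model, perEnv$interaction, perEnv$trait,
                      drop = TRUE, sep = "\r")
  summaries <- do.call(rbind, lapply(split(perEnv, grp3), function(d)
    data.frame(model = d$model[1], interaction = d$interaction[1],
               trait = d$trait[1], n_envs = nrow(d),
               min = min(d$maape), max = max(d$maape),
               mean = mean(d$maape), median = median(d$maape),
               stringsAsFactors = FALSE)))
  summaries <- summaries[order(summaries$trait, summaries$interaction,
                               summaries$model), ]
  rownames(summaries) <- NULL

  # winner tallies: per (interaction, trait, environment), the model with
  # the lowest averaged MAAPE
  grp4 <- interaction(perEnv$interaction, perEnv$trait, perEnv$environment,
                      drop = TRUE, sep = "\r")
  winRows <- lapply(split(perEnv, grp4), function(d)
    d[which.min(d$maape), c("model", "interaction", "trait", "environment")])
  wins <- do.call(rbind, winRows)
  grp5 <- interaction(wins$interaction, wins$trait, drop = TRUE, sep = "\r")
  winners <- do.call(rbind, lapply(split(wins, grp5), function(d) {
    models <- sort(unique(perEnv$model))
    data.frame(interaction = d$interaction[1], trait = d$trait[1],
               model = models,
               wins = as.integer(table(factor(d$model, models))),
               n_envs = length(unique(d$environment)),
               stringsAsFactors = FALSE)
  }))
  rownames(winners) <- NULL

  new("PredictionReport", records = records, perEnv = perEnv,
      summaries = summaries, winners = winners)
}
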