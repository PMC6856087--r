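#' Configuration for the synthetic multi-environment trial generator
#'
#' Bundles every knob of the generative model
#' \deqn{y_{ij} = \mu_t + E_i + g_j + gE_{ij} + e_{ij}}
#' with \eqn{g \sim N(0, \sigma_1^2 G)}, \eqn{gE \sim N(0, \sigma_2^2 I_I
#' \otimes G)} and \eqn{e \sim N(0, \sigma^2)}. The desk-scale defaults (100
#' lines, 1,000 markers, 8 environments) keep every downstream stage fast;
#' `scale = "full"` switches to the trial-scale design of 270 lines, 14,163
#' markers and 43 environments with 57--193 lines observed per environment.
#'
#' Traits default to three positively-valued, genetically correlated traits
#' emulating days to heading, grain yield and plant height; baselines are
#' large relative to the noise so that MAAPE (which divides by the observed
#' value) is well behaved.
#'
#' @param n_lines,n_markers,n_envs Design dimensions.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-marker allele
#'   frequencies are drawn uniformly in this range.
#' @param marker_missing_rate Proportion of genotype calls set missing,
#'   independently of the genotype.
#' @param lines_per_env_range Length-2 integer range; each environment
#'   observes a uniform number of distinct lines in this range.
#' @param env_effect_spread Standard deviation of environment means, per
#'   trait (recycled).
#' @param trait_baselines Positive trait means, one per trait; their length
#'   sets the number of traits.
#' @param sigma2_g,sigma2_ge,sigma2_e Genomic, interaction and residual
#'   variances per trait (recycled). Zero is allowed for degenerate,
#'   noise-free checks.
#' @param trait_genetic_correlation Symmetric positive-definite correlation
#'   matrix of the genomic effects across traits.
#' @param seed Integer master seed for the generator.
#' @param scale `"desk"` (default) or `"full"`.
#' @return A validated list of class `SimulationConfig`.
#' @export
#' @examples
#' cfg <- simulationConfig(n_lines = 20, n_markers = 50, n_envs = 3,
#'                         lines_per_env_range = c(10, 20), seed = 11)
simulationConfig <- function(n_lines = 100, n_markers = 1000, n_envs = 8,
                             maf_range = c(0.05, 0.5),
                             marker_missing_rate = 0.05,
                             lines_per_env_range = c(21, 71),
                             env_effect_spread = c(8, 1, 10),
                             trait_baselines = c(90, 6, 95),
                             sigma2_g = c(16, 0.5, 25),
                             sigma2_ge = c(4, 0.3, 9),
                             sigma2_e = c(4, 0.2, 9),
                             trait_genetic_correlation = NULL,
                             seed = 1,
                             scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    if (missing(n_lines)) n_lines <- 270
    if (missing(n_markers)) n_markers <- 14163
    if (missing(n_envs)) n_envs <- 43
    if (missing(lines_per_env_range)) lines_per_env_range <- c(57, 193)
  }
  n_traits <- length(trait_baselines)
  if (n_traits < 1 || any(trait_baselines <= 0))
    stop("trait_baselines must be positive (MAAPE divides by the observed value)")
  if (is.null(trait_genetic_correlation)) {
    trait_genetic_correlation <- matrix(0.5, n_traits, n_traits)
    diag(trait_genetic_correlation) <- 1
  }
  cfg <- list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    n_envs = as.integer(n_envs), maf_range = as.numeric(maf_range),
    marker_missing_rate = marker_missing_rate,
    lines_per_env_range = as.integer(lines_per_env_range),
    env_effect_spread = rep_len(env_effect_spread, n_traits),
    trait_baselines = as.numeric(trait_baselines),
    sigma2_g = rep_len(sigma2_g, n_traits),
    sigma2_ge = rep_len(sigma2_ge, n_traits),
    sigma2_e = rep_len(sigma2_e, n_traits),
    trait_genetic_correlation = trait_genetic_correlation,
    n_traits = n_traits, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  if (cfg$n_lines < 2 || cfg$n_markers < 1 || cfg$n_envs < 1)
    stop("need n_lines >= 2, n_markers >= 1, n_envs >= 1")
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stop("maf_range must lie within (0, 0.5] with min <= max")
  if (cfg$marker_missing_rate < 0 || cfg$marker_missing_rate >= 1)
    stop("marker_missing_rate must be in [0, 1)")
  rng <- cfg$lines_per_env_range
  if (length(rng) != 2 || rng[1] < 1 || rng[2] > cfg$n_lines || rng[1] > rng[2])
    stop("lines_per_env_range must lie within [1, n_lines]")
  if (any(c(cfg$sigma2_g, cfg$sigma2_ge, cfg$sigma2_e) < 0))
    stop("variance components must be non-negative")
  if (any(cfg$env_effect_spread < 0))
    stop("env_effect_spread must be non-negative")
  C <- cfg$trait_genetic_correlation
  if (nrow(C) != cfg$n_traits || any(abs(diag(C) - 1) > 1e-12))
    stop("trait_genetic_correlation must be n_traits x n_traits with unit diagonal")
  if (!isSymmetric(unname(C), tol = 1e-10))
    stop("trait_genetic_correlation must be symmetric")
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("trait_genetic_correlation must be positive definite")
  invisible(cfg)
}

#' Simulate a biallelic marker matrix
#'
#' Per-marker allele frequencies are drawn uniformly in `maf_range`; dosages
#' are Binomial(2, p) per line (markers independent, no LD or population
#' structure); missingness is Bernoulli(`marker_missing_rate`) independent of
#' genotype. Reproducible from `config$seed`.
#'
#' @param config A [simulationConfig()].
#' @return A [MarkerMatrix-class] with raw \{0,1,2\}/NA calls.
#' @export
simulateMarkers <- function(config) {
  validateSimulationConfig(config)
  withSeed(deriveSeed(config$seed, "markers"), {
    p <- runif(config$n_markers, config$maf_range[1], config$maf_range[2])
    v <- vapply(p, function(pm) rbinom(config$n_lines, 2L, pm),
                numeric(config$n_lines))
    if (config$marker_missing_rate > 0) {
      miss <- matrix(runif(length(v)) < config$marker_missing_rate,
                     nrow(v), ncol(v))
      v[miss] <- NA_real_
    }
    dimnames(v) <- list(lineLabels(config$n_lines),
                        markerLabels(config$n_markers))
    new("MarkerMatrix", values = v, imputed = FALSE)
  })
}

#' Draw the observed (line, environment) cells of an incomplete trial
#'
#' Each environment observes a uniformly drawn number of distinct lines
#' within `lines_per_env_range` (sampled without replacement: a line occurs
#' at most once per environment). The whole design is redrawn until every
#' line appears in at least one environment.
#'
#' @param config A [simulationConfig()].
#' @return Data frame with columns `line`, `environment`; no duplicate cells.
#' @export
makeIncompleteDesign <- function(config) {
  validateSimulationConfig(config)
  if (config$n_envs * config$lines_per_env_range[2] < config$n_lines)
    stop("infeasible design: even maximal environments cannot cover every line")
  lines <- lineLabels(config$n_lines)
  envs <- envLabels(config$n_envs)
  withSeed(deriveSeed(config$seed, "design"), {
    for (try in seq_len(1000L)) {
      lo <- config$lines_per_env_range[1]
      hi <- config$lines_per_env_range[2]
      sizes <- lo + sample.int(hi - lo + 1L, config$n_envs,
                               replace = TRUE) - 1L
      per_env <- lapply(sizes, function(k) sort(sample.int(config$n_lines, k)))
      if (length(unique(unlist(per_env))) == config$n_lines) {
        return(data.frame(
          line = lines[unlist(per_env)],
          environment = rep(envs, lengths(per_env)),
          stringsAsFactors = FALSE))
      }
    }
    stop("could not cover every line in 1000 design draws; widen lines_per_env_range")
  })
}

#' Simulate multi-trait phenotypes on an incomplete design
#'
#' For each trait t and observed cell (i, j):
#' `y = baseline_t + E_i + g_j + gE_ij + e_ij`, with genomic effects drawn
#' with between-line covariance `sigma2_g[t] * G` and the configured genetic
#' correlation across traits, interaction effects drawn independently per
#' environment with covariance `sigma2_ge[t] * G` (the `I_I (x) G`
#' structure), and iid residuals. Interaction and residual terms are
#' independent across traits.
#'
#' @param design Data frame of observed cells, as from
#'   [makeIncompleteDesign()].
#' @param grm A [GRM-class] covering the design's lines (positive
#'   semi-definite).
#' @param config A [simulationConfig()].
#' @return List with `phenotypes` (long data frame: line, environment,
#'   trait, value) and `effects` (list of the true `env_effects`
#'   (envs x traits), `genomic_effects` (lines x traits) and
#'   `interaction_effects` (envs x lines x traits array)) for recovery
#'   tests.
#' @export
simulatePhenotypes <- function(design, grm, config) {
  validateSimulationConfig(config)
  stopifnot(is(grm, "GRM"))
  g_lines <- lineIds(grm)
  if (!all(design$line %in% g_lines))
    stop("design contains lines absent from the GRM")
  assertPSD(as.matrix(grm), what = "GRM")
  J <- length(g_lines)
  envs <- unique(design$environment)
  I <- length(envs)
  Tt <- config$n_traits
  traits <- paste0("T", seq_len(Tt))
  L <- t(as.matrix(choleskyFactor(grm)))        # G + eps*I = L %*% t(L)

  withSeed(deriveSeed(config$seed, "phenotypes"), {
    # genomic effects: vec(g) ~ N(0, Sigma_T (x) G), Sigma_T = D C D
    Dsd <- sqrt(config$sigma2_g)
    C <- config$trait_genetic_correlation
    CT <- chol(C)                               # C = t(CT) %*% CT
    Zg <- matrix(rnorm(J * Tt), J, Tt)
    g <- (L %*% Zg) %*% CT                      # cov over lines = G per trait
    g <- sweep(g, 2, Dsd, `*`)
    dimnames(g) <- list(g_lines, traits)

    Emat <- matrix(0, I, Tt, dimnames = list(envs, traits))
    for (t in seq_len(Tt))
      Emat[, t] <- rnorm(I, 0, config$env_effect_spread[t])

    gE <- array(0, dim = c(I, J, Tt), dimnames = list(envs, g_lines, traits))
    for (t in seq_len(Tt)) {
      s <- sqrt(config$sigma2_ge[t])
      if (s > 0)
        for (i in seq_len(I)) gE[i, , t] <- s * as.numeric(L %*% rnorm(J))
    }

    li <- match(design$line, g_lines)
    ei <- match(design$environment, envs)
    out <- vector("list", Tt)
    for (t in seq_len(Tt)) {
      e <- rnorm(nrow(design), 0, sqrt(config$sigma2_e[t]))
      out[[t]] <- data.frame(
        line = design$line, environment = design$environment,
        trait = traits[t],
        value = config$trait_baselines[t] + Emat[cbind(ei, t)] +
          g[cbind(li, t)] + gE[cbind(ei, li, rep(t, length(li)))] + e,
        stringsAsFactors = FALSE)
    }
    list(phenotypes = do.call(rbind, out),
         effects = list(env_effects = Emat, genomic_effects = g,
                        interaction_effects = gE))
  })
}
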