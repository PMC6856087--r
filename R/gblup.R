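#' Design matrices for the multi-environment model
#'
#' Builds the one-hot incidence matrices of environments (`Z_E`, n x I),
#' lines (`Z_G`, n x J) and environment-line cells (`Z_GE`, n x I*J).
#' `Z_GE` columns are ordered in environment-major blocks of J lines,
#' consistent with the `I_I (x) G` interaction covariance: record r observed
#' on environment i and line j has its 1 at column `(i - 1) * J + j`. Every
#' row of each matrix sums to 1.
#'
#' @param records Data frame with columns `line` and `environment` (one row
#'   per phenotype record).
#' @param env_ids,line_ids Ordered label sets fixing column order; default
#'   to order of first appearance in `records`. Labels in `records` that are
#'   not in these sets are an error.
#' @return List with sparse matrices `Z_E`, `Z_G`, `Z_GE` (column names:
#'   environment, line, and `env:line` labels).
#' @export
buildDesignMatrices <- function(records, env_ids = NULL, line_ids = NULL) {
  if (nrow(records) == 0) stop("no records")
  if (is.null(env_ids)) env_ids <- unique(records$environment)
  if (is.null(line_ids)) line_ids <- unique(records$line)
  ei <- match(records$environment, env_ids)
  li <- match(records$line, line_ids)
  if (anyNA(ei)) stop("unknown environment label(s) in records")
  if (anyNA(li)) stop("unknown line label(s) in records")
  n <- nrow(records); I <- length(env_ids); J <- length(line_ids)
  Z_E <- Matrix::sparseMatrix(i = seq_len(n), j = ei, x = 1, dims = c(n, I),
                              dimnames = list(NULL, env_ids))
  Z_G <- Matrix::sparseMatrix(i = seq_len(n), j = li, x = 1, dims = c(n, J),
                              dimnames = list(NULL, line_ids))
  Z_GE <- Matrix::sparseMatrix(i = seq_len(n), j = (ei - 1L) * J + li, x = 1,
                               dims = c(n, I * J),
                               dimnames = list(NULL, paste(rep(env_ids, each = J),
                                                           rep(line_ids, I),
                                                           sep = ":")))
  list(Z_E = Z_E, Z_G = Z_G, Z_GE = Z_GE)
}

#' Specification of a GBLUP fit
#'
#' @param include_interaction Include the genotype-by-environment term
#'   (`I`) or not (`WI`).
#' @param estimator `"gibbs"` (Bayesian sampler, the default) or
#'   `"fixed_variances"` (exact Henderson mixed-model-equation solve at the
#'   supplied variances).
#' @param n_iterations,burn_in,thin Gibbs chain controls.
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-square
#'   variance priors.
#' @param prior_split Proportions of the training phenotypic variance used
#'   as prior scales for (genomic, interaction, residual); must sum to 1.
#' @param fixed_variances Numeric `c(sigma2_g, sigma2_ge, sigma2_e)`;
#'   required by `"fixed_variances"` and by `update_variances = FALSE`.
#' @param update_variances Logical; when `FALSE` the Gibbs sampler keeps the
#'   variances fixed at `fixed_variances` (used for oracle comparisons).
#' @param seed Integer seed for the sampler.
#' @return A validated list of class `GBLUPSpec`.
#' @export
gblupSpec <- function(include_interaction = TRUE,
                      estimator = c("gibbs", "fixed_variances"),
                      n_iterations = 6000, burn_in = 1000, thin = 5,
                      prior_df = 5, prior_split = c(0.25, 0.25, 0.5),
                      fixed_variances = NULL, update_variances = TRUE,
                      seed = 1) {
  estimator <- match.arg(estimator)
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (abs(sum(prior_split) - 1) > 1e-8 || any(prior_split <= 0))
    stop("prior_split must be positive and sum to 1")
  if (thin < 1) stop("thin must be >= 1")
  needs_fixed <- estimator == "fixed_variances" || !update_variances
  if (needs_fixed && (is.null(fixed_variances) || length(fixed_variances) != 3))
    stop("fixed_variances = c(sigma2_g, sigma2_ge, sigma2_e) required")
  if (!is.null(fixed_variances) &&
      (fixed_variances[1] <= 0 || fixed_variances[3] <= 0 ||
       fixed_variances[2] < 0))
    stop("fixed variances must be positive (sigma2_ge may be 0)")
  structure(list(include_interaction = include_interaction,
                 estimator = estimator,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_df = prior_df, prior_split = prior_split,
                 fixed_variances = fixed_variances,
                 update_variances = update_variances,
                 seed = as.integer(seed)),
            class = "GBLUPSpec")
}

# Internal: shared indexing/validation for both estimators.
gblupProblem <- function(pheno, grm, env_ids = NULL) {
  stopifnot(is(grm, "GRM"))
  if (!("value" %in% names(pheno)))
    stop("pheno must contain a 'value' column (one trait at a time)")
  if ("trait" %in% names(pheno) && length(unique(pheno$trait)) > 1)
    stop("pheno contains several traits; fit one trait at a time")
  pheno <- pheno[!is.na(pheno$value), , drop = FALSE]
  if (nrow(pheno) == 0) stop("no non-missing records")
  lines <- lineIds(grm)
  if (!all(pheno$line %in% lines))
    stop("training lines absent from the GRM: ",
         paste(head(setdiff(pheno$line, lines), 5), collapse = ", "))
  if (is.null(env_ids)) env_ids <- unique(pheno$environment)
  ei <- match(pheno$environment, env_ids)
  if (anyNA(ei)) stop("unknown environment label(s)")
  n_per_env <- tabulate(ei, length(env_ids))
  if (any(n_per_env == 0))
    stop("singular fixed-effect system: environment(s) without training ",
         "records: ", paste(env_ids[n_per_env == 0], collapse = ", "))
  list(pheno = pheno, env_ids = env_ids, line_ids = lines,
       ei = ei, li = match(pheno$line, lines), y = pheno$value,
       n_per_env = n_per_env)
}

#' Fit the multi-environment GBLUP model
#'
#' Fits `y_ij = E_i + g_j + gE_ij + e_ij` with `g ~ N(0, sigma2_g G)`,
#' `gE ~ N(0, sigma2_ge I_I (x) G)` (dropped when
#' `include_interaction = FALSE`) and iid residuals; environments are fixed
#' effects.
#'
#' Under `estimator = "gibbs"` a Gibbs sampler is run with flat priors on
#' the environment effects, multivariate-normal full conditionals for `g`
#' and `gE` — reparameterized through the eigenfactor of `G`, so each update
#' is an iid-scale draw — and scaled-inverse-chi-square full conditionals
#' for the three variances (prior scales = `prior_split` times the training
#' phenotypic variance, df = `prior_df`). Posterior means are reported; the
#' chain is deterministic under `spec$seed`.
#'
#' Under `estimator = "fixed_variances"` Henderson's mixed-model equations
#' are solved exactly at the supplied variances, which provides a
#' deterministic oracle path.
#'
#' @param pheno Training records: data frame with `line`, `environment`,
#'   `value` (single trait; `NA` values are dropped).
#' @param grm A [GRM-class] containing every training line (lines present in
#'   the GRM but unobserved still receive BLUPs).
#' @param spec A [gblupSpec()].
#' @param env_ids Optional ordered environment labels; every environment
#'   must have at least one training record.
#' @return A [GBLUPFit-class].
#' @export
fitGBLUP <- function(pheno, grm, spec = gblupSpec(), env_ids = NULL) {
  pr <- gblupProblem(pheno, grm, env_ids)
  if (spec$estimator == "fixed_variances") gblupMME(pr, grm, spec)
  else gblupGibbs(pr, grm, spec)
}

# Exact Henderson mixed-model-equation solve at fixed variances.
gblupMME <- function(pr, grm, spec) {
  v <- spec$fixed_variances
  s2g <- v[1]; s2ge <- v[2]; s2e <- v[3]
  inter <- spec$include_interaction
  # sigma2_ge = 0 collapses the interaction model onto the WI fit exactly:
  # solve the WI system and report zero interaction BLUPs.
  solve_inter <- inter && s2ge > 0
  I <- length(pr$env_ids); J <- length(pr$line_ids); n <- length(pr$y)
  Z <- buildDesignMatrices(pr$pheno, pr$env_ids, pr$line_ids)
  X <- Z$Z_E
  cf <- choleskyFactor(grm)
  Ginv <- chol2inv(cf@upper)
  Zu <- if (solve_inter) cbind(Z$Z_G, Z$Z_GE) else Z$Z_G
  C11 <- as.matrix(Matrix::crossprod(X))
  C12 <- as.matrix(Matrix::crossprod(X, Zu))
  C22 <- as.matrix(Matrix::crossprod(Zu))
  ridge_g <- (s2e / s2g) * Ginv
  if (solve_inter) {
    C22[seq_len(J), seq_len(J)] <- C22[seq_len(J), seq_len(J)] + ridge_g
    for (i in seq_len(I)) {
      b <- J + (i - 1L) * J + seq_len(J)
      C22[b, b] <- C22[b, b] + (s2e / s2ge) * Ginv
    }
  } else {
    C22 <- C22 + ridge_g
  }
  C <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  rhs <- c(as.numeric(Matrix::crossprod(X, pr$y)),
           as.numeric(Matrix::crossprod(Zu, pr$y)))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("singular mixed-model equations: ", conditionMessage(e)))
  beta <- setNames(sol[seq_len(I)], pr$env_ids)
  gvec <- setNames(sol[I + seq_len(J)], pr$line_ids)
  geMat <- matrix(0, 0, 0)
  if (inter) {
    geMat <- if (solve_inter)
      matrix(sol[I + J + seq_len(I * J)], nrow = I, byrow = TRUE,
             dimnames = list(pr$env_ids, pr$line_ids))
    else matrix(0, I, J, dimnames = list(pr$env_ids, pr$line_ids))
  }
  new("GBLUPFit", envEffects = beta, genomicBlups = gvec,
      interactionBlups = geMat,
      varianceEstimates = list(
        sigma2_g = c(s2g, NA), sigma2_ge = if (inter) c(s2ge, NA),
        sigma2_e = c(s2e, NA)),
      includeInteraction = inter, estimator = "fixed_variances",
      diagnostics = list(n = n, solver = "henderson-mme",
                         grm_jitter = cf@jitter))
}

# Gibbs sampler; g and gE are updated through K = V diag(sqrt(lambda)) from
# the eigendecomposition of G, so their full conditionals are iid-scale.
gblupGibbs <- function(pr, grm, spec) {
  inter <- spec$include_interaction
  I <- length(pr$env_ids); J <- length(pr$line_ids); n <- length(pr$y)
  y <- pr$y; ei <- pr$ei; li <- pr$li
  eg <- eigen(as.matrix(grm), symmetric = TRUE)
  lam <- pmax(eg$values, max(eg$values) * 1e-10)
  K <- eg$vectors %*% diag(sqrt(lam), J)

  # Sum a length-n vector into J line bins.
  lineSums <- function(x, rows = NULL) {
    if (is.null(rows)) {
      s <- numeric(J); t <- rowsum(x, li)
    } else {
      s <- numeric(J); t <- rowsum(x[rows], li[rows])
    }
    s[as.integer(rownames(t))] <- t
    s
  }

  counts <- tabulate(li, J)
  eigM <- function(cnt) {
    M <- crossprod(K * sqrt(cnt))          # K^T diag(cnt) K
    e <- eigen(M, symmetric = TRUE)
    list(V = e$vectors, psi = pmax(e$values, 0))
  }
  Eg <- eigM(counts)
  rec_by_env <- split(seq_len(n), ei)
  if (inter) {
    Ei_list <- lapply(seq_len(I), function(i) {
      cnt <- tabulate(li[rec_by_env[[i]]], J)
      eigM(cnt)
    })
  }

  vy <- var(y)
  nu <- spec$prior_df
  Sc <- spec$prior_split * vy
  upd <- spec$update_variances
  if (!upd || !is.null(spec$fixed_variances)) {
    fv <- spec$fixed_variances
  } else fv <- NULL
  s2g <- if (!upd) fv[1] else Sc[1]
  s2ge <- if (!upd) fv[2] else Sc[2]
  s2e <- if (!upd) fv[3] else Sc[3]

  beta <- setNames(as.numeric(rowsum(y, ei)) / pr$n_per_env, pr$env_ids)
  a <- numeric(J); gvec <- numeric(J)
  aEnv <- matrix(0, I, J); geMat <- matrix(0, I, J)
  gerec <- numeric(n)

  keep <- seq(spec$burn_in + 1L, spec$n_iterations)
  keep <- keep[(seq_along(keep) - 1L) %% spec$thin == 0]
  nk <- length(keep)
  sum_beta <- numeric(I); sum_g <- numeric(J); sumsq_g <- numeric(J)
  sum_ge <- matrix(0, I, J); sumsq_ge <- matrix(0, I, J)
  sumsq_beta <- numeric(I)
  vdraws <- matrix(NA_real_, nk, 3,
                   dimnames = list(NULL, c("sigma2_g", "sigma2_ge", "sigma2_e")))
  ki <- 0L

  withSeed(spec$seed, {
    for (it in seq_len(spec$n_iterations)) {
      grec <- gvec[li]
      # environment fixed effects: flat prior
      resid_env <- y - grec - gerec
      mb <- as.numeric(rowsum(resid_env, ei)) / pr$n_per_env
      beta <- mb + rnorm(I, 0, sqrt(s2e / pr$n_per_env))
      brec <- beta[ei]

      # genomic effects through K
      s <- lineSums(y - brec - gerec)
      rhs <- crossprod(K, s) / s2e
      d <- Eg$psi / s2e + 1 / s2g
      m <- Eg$V %*% (crossprod(Eg$V, rhs) / d)
      a <- as.numeric(m + Eg$V %*% (rnorm(J) / sqrt(d)))
      gvec <- as.numeric(K %*% a)
      grec <- gvec[li]

      # interaction effects, one block per environment
      if (inter) {
        part <- y - brec - grec
        for (i in seq_len(I)) {
          rows <- rec_by_env[[i]]
          si <- lineSums(part, rows)
          rhs_i <- crossprod(K, si) / s2e
          E_i <- Ei_list[[i]]
          d_i <- E_i$psi / s2e + 1 / s2ge
          m_i <- E_i$V %*% (crossprod(E_i$V, rhs_i) / d_i)
          aEnv[i, ] <- as.numeric(m_i + E_i$V %*% (rnorm(J) / sqrt(d_i)))
          geMat[i, ] <- as.numeric(K %*% aEnv[i, ])
        }
        gerec <- geMat[cbind(ei, li)]
      }

      # variance components: scaled-inverse-chi-square full conditionals
      if (upd) {
        s2g <- (nu * Sc[1] + sum(a^2)) / rchisq(1, nu + J)
        if (inter)
          s2ge <- (nu * Sc[2] + sum(aEnv^2)) / rchisq(1, nu + I * J)
        sse <- sum((y - brec - grec - gerec)^2)
        s2e <- (nu * Sc[3] + sse) / rchisq(1, nu + n)
      }

      if (ki < nk && it == keep[ki + 1L]) {
        ki <- ki + 1L
        sum_beta <- sum_beta + beta; sumsq_beta <- sumsq_beta + beta^2
        sum_g <- sum_g + gvec; sumsq_g <- sumsq_g + gvec^2
        if (inter) { sum_ge <- sum_ge + geMat; sumsq_ge <- sumsq_ge + geMat^2 }
        vdraws[ki, ] <- c(s2g, if (inter) s2ge else NA, s2e)
      }
    }
  })

  postSD <- function(s, sq) sqrt(pmax(sq / nk - (s / nk)^2, 0))
  beta_hat <- setNames(sum_beta / nk, pr$env_ids)
  g_hat <- setNames(sum_g / nk, pr$line_ids)
  ge_hat <- matrix(0, 0, 0)
  if (inter) {
    ge_hat <- sum_ge / nk
    dimnames(ge_hat) <- list(pr$env_ids, pr$line_ids)
  }
  vstat <- function(col) c(mean(vdraws[, col]), sd(vdraws[, col]))
  new("GBLUPFit", envEffects = beta_hat, genomicBlups = g_hat,
      interactionBlups = ge_hat,
      varianceEstimates = list(
        sigma2_g = vstat("sigma2_g"),
        sigma2_ge = if (inter) vstat("sigma2_ge"),
        sigma2_e = vstat("sigma2_e")),
      includeInteraction = inter, estimator = "gibbs",
      diagnostics = list(
        n = n, n_samples = nk, thin = spec$thin,
        variance_draws = vdraws,
        beta_sd = setNames(postSD(sum_beta, sumsq_beta), pr$env_ids),
        g_sd = setNames(postSD(sum_g, sumsq_g), pr$line_ids),
        ge_sd = if (inter) postSD(sum_ge, sumsq_ge)))
}

#' Predict phenotypes for (line, environment) cells from a GBLUP fit
#'
#' `yhat_ij = E_i + g_j (+ gE_ij)`. Interaction BLUPs for cells unobserved
#' in training come from the same joint solve/posterior, borrowing
#' information through `G` within each environment.
#'
#' @param fit A [GBLUPFit-class].
#' @param cells Data frame with columns `line`, `environment`; all labels
#'   must be known to the fit.
#' @param include_interaction Use the interaction term; defaults to the
#'   fitted model's setting. Requesting it from a fit without the term is an
#'   error.
#' @return Numeric vector of predictions, one per row of `cells`.
#' @export
predictGBLUP <- function(fit, cells, include_interaction = NULL) {
  if (is.null(include_interaction))
    include_interaction <- fit@includeInteraction
  if (include_interaction && !fit@includeInteraction)
    stop("fit has no interaction term; refit with include_interaction = TRUE")
  ei <- match(cells$environment, names(fit@envEffects))
  li <- match(cells$line, names(fit@genomicBlups))
  if (anyNA(ei)) stop("environment(s) unknown to the fit")
  if (anyNA(li)) stop("line(s) unknown to the fit")
  pred <- fit@envEffects[ei] + fit@genomicBlups[li]
  if (include_interaction) pred <- pred + fit@interactionBlups[cbind(ei, li)]
  unname(pred)
}

#' @describeIn predictGBLUP `predict` method for `GBLUPFit`.
#' @param object A [GBLUPFit-class].
#' @param ... Passed on to `predictGBLUP()`.
#' @export
setMethod("predict", "GBLUPFit", function(object, cells, ...)
  predictGBLUP(object, cells, ...))
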