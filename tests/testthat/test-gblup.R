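test_that("design matrices are environment-major one-hot encodings", {
  one <- data.frame(line = "L001", environment = "E1")
  Z1 <- buildDesignMatrices(one)
  expect_equal(dim(Z1$Z_E), c(1, 1))
  expect_equal(dim(Z1$Z_GE), c(1, 1))
  expect_equal(as.numeric(Z1$Z_GE), 1)

  cells <- completeCells(3, 2)
  Z <- buildDesignMatrices(cells, paste0("E", 1:2), sprintf("L%03d", 1:3))
  expect_equal(dim(Z$Z_GE), c(6, 6))
  expect_true(all(Matrix::rowSums(Z$Z_E) == 1))
  expect_true(all(Matrix::rowSums(Z$Z_G) == 1))
  expect_true(all(Matrix::rowSums(Z$Z_GE) == 1))
  # row r has its 1 at column (env_index - 1) * J + line_index
  li <- match(cells$line, sprintf("L%03d", 1:3))
  ei <- match(cells$environment, paste0("E", 1:2))
  expect_equal(apply(as.matrix(Z$Z_GE), 1, which.max),
               (ei - 1) * 3 + li, ignore_attr = TRUE)

  expect_error(buildDesignMatrices(cells, env_ids = "E9"), "unknown environment")
})

test_that("fixed-variance solver matches the dense GLS oracle", {
  for (s in 1:3) {
    set.seed(100 + s)
    J <- 3 + s; I <- 2 + s %% 2
    G <- toyGRM(J, seed = s)
    cells <- completeCells(J, I, lines = lineIds(G))
    cells <- cells[sample(nrow(cells), nrow(cells) - 2), ]
    ph <- data.frame(cells, value = rnorm(nrow(cells), 10, 2))
    vv <- c(0.8, 0.4, 0.3)
    fit <- fitGBLUP(ph, G,
                    gblupSpec(include_interaction = TRUE,
                              estimator = "fixed_variances",
                              fixed_variances = vv),
                    env_ids = paste0("E", seq_len(I)))
    or <- glsOracle(ph, as.matrix(G), vv[1], vv[2], vv[3],
                    paste0("E", seq_len(I)))
    expect_lt(max(abs(fit@envEffects - or$beta)), 1e-8)
    expect_lt(max(abs(fit@genomicBlups - or$g)), 1e-8)
    expect_lt(max(abs(fit@interactionBlups - or$ge)), 1e-8)
  }
})

test_that("vanishing genomic variance shrinks BLUPs to environment means", {
  G <- toyGRM(6, seed = 2)
  cells <- completeCells(6, 2, lines = lineIds(G))
  set.seed(3)
  ph <- data.frame(cells, value = rnorm(12, 50, 5))
  fit <- fitGBLUP(ph, G, gblupSpec(include_interaction = FALSE,
                                   estimator = "fixed_variances",
                                   fixed_variances = c(1e-8, 0, 1)))
  expect_lt(max(abs(fit@genomicBlups)), 1e-5)
  env_means <- tapply(ph$value, ph$environment, mean)
  expect_equal(unname(fit@envEffects),
               as.numeric(env_means[names(fit@envEffects)]),
               tolerance = 1e-6)
})

test_that("held-out cell predictions equal the oracle conditional mean", {
  G <- toyGRM(5, seed = 7)
  cells <- completeCells(5, 3, lines = lineIds(G))
  held <- cells[8, , drop = FALSE]
  train <- cells[-8, ]
  set.seed(11)
  ph <- data.frame(train, value = rnorm(nrow(train), 30, 3))
  vv <- c(0.9, 0.5, 0.2)
  fit <- fitGBLUP(ph, G, gblupSpec(include_interaction = TRUE,
                                   estimator = "fixed_variances",
                                   fixed_variances = vv),
                  env_ids = paste0("E", 1:3))
  or <- glsOracle(ph, as.matrix(G), vv[1], vv[2], vv[3], paste0("E", 1:3))
  oracle_pred <- or$beta[held$environment] + or$g[held$line] +
    or$ge[held$environment, held$line]
  expect_lt(abs(predictGBLUP(fit, held) - oracle_pred), 1e-8)

  # WI prediction is exactly E_i + g_j, and asking it for interaction errors
  fwi <- fitGBLUP(ph, G, gblupSpec(include_interaction = FALSE,
                                   estimator = "fixed_variances",
                                   fixed_variances = vv))
  expect_equal(predictGBLUP(fwi, held),
               unname(fwi@envEffects[held$environment] +
                      fwi@genomicBlups[held$line]))
  expect_error(predictGBLUP(fwi, held, include_interaction = TRUE),
               "no interaction")
  expect_error(predictGBLUP(fit, data.frame(line = "L001",
                                            environment = "E99")),
               "unknown")
})

test_that("zero interaction variance reproduces the WI fit exactly", {
  G <- toyGRM(6, seed = 4)
  cells <- completeCells(6, 2, lines = lineIds(G))
  set.seed(5)
  ph <- data.frame(cells, value = rnorm(12, 8))
  fi <- fitGBLUP(ph, G, gblupSpec(include_interaction = TRUE,
                                  estimator = "fixed_variances",
                                  fixed_variances = c(0.5, 0, 0.3)))
  fw <- fitGBLUP(ph, G, gblupSpec(include_interaction = FALSE,
                                  estimator = "fixed_variances",
                                  fixed_variances = c(0.5, 0, 0.3)))
  expect_equal(fi@envEffects, fw@envEffects, tolerance = 1e-10)
  expect_equal(fi@genomicBlups, fw@genomicBlups, tolerance = 1e-10)
  expect_true(all(fi@interactionBlups == 0))
})

test_that("GBLUP with uncentered G equals ridge regression on markers", {
  # single environment; penalty lambda = p * s2e / s2g
  set.seed(9)
  J <- 12; p <- 30
  W <- matrix(sample(0:2, J * p, TRUE), J)
  m <- markerMatrix(W, imputed = TRUE)
  G <- computeGRM(m, center = FALSE)
  s2g <- 0.6; s2e <- 0.4
  y <- rnorm(J, 5)
  ph <- data.frame(line = lineIds(G), environment = "E1", value = y)
  fit <- fitGBLUP(ph, G, gblupSpec(include_interaction = FALSE,
                                   estimator = "fixed_variances",
                                   fixed_variances = c(s2g, 0, s2e)))
  lambda <- p * s2e / s2g
  # ridge with unpenalized intercept, solved by its normal equations
  A <- rbind(cbind(J, t(colSums(W))),
             cbind(colSums(W), crossprod(W) + diag(lambda, p)))
  sol <- solve(A, c(sum(y), as.numeric(crossprod(W, y))))
  ghat_ridge <- as.numeric(W %*% sol[-1])
  expect_lt(max(abs(fit@genomicBlups - ghat_ridge)), 1e-6)
})

test_that("the Gibbs sampler agrees with the exact solver and is seeded", {
  G <- toyGRM(7, seed = 6)
  cells <- completeCells(7, 3, lines = lineIds(G))
  set.seed(13)
  ph <- data.frame(cells, value = rnorm(nrow(cells), 20, 2))
  vv <- c(0.7, 0.4, 0.3)
  mme <- fitGBLUP(ph, G, gblupSpec(include_interaction = TRUE,
                                   estimator = "fixed_variances",
                                   fixed_variances = vv))
  spec <- gblupSpec(include_interaction = TRUE, estimator = "gibbs",
                    n_iterations = 6000, burn_in = 1000, thin = 5,
                    fixed_variances = vv, update_variances = FALSE, seed = 17)
  gib <- fitGBLUP(ph, G, spec)
  expect_lt(max(abs(gib@genomicBlups - mme@genomicBlups)), 0.1)
  expect_lt(max(abs(gib@envEffects - mme@envEffects)), 0.15)
  # seeded determinism
  gib2 <- fitGBLUP(ph, G, spec)
  expect_identical(gib@genomicBlups, gib2@genomicBlups)
})

test_that("an environment without training records is reported", {
  G <- toyGRM(4, seed = 1)
  ph <- data.frame(line = lineIds(G), environment = "E1",
                   value = rnorm(4, 10))
  expect_error(fitGBLUP(ph, G, gblupSpec(estimator = "fixed_variances",
                                         fixed_variances = c(1, 1, 1)),
                        env_ids = c("E1", "E2")),
               "singular fixed-effect")
})
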