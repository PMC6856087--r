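test_that("feature encoding satisfies the covariance identities", {
  # identity kinship leaves the genotype design unchanged
  gI <- grmMatrix(diag(4))
  cells <- completeCells(4, 2, lines = lineIds(gI))
  Z <- buildDesignMatrices(cells, paste0("E", 1:2), lineIds(gI))
  encI <- encodeFeatures(Z$Z_E, Z$Z_G, NULL, choleskyFactor(gI))
  expect_equal(unname(encI@X[, encI@blocks$genotype]),
               unname(as.matrix(Z$Z_G)))

  # random PSD G: X_G X_G' = Z_G G Z_G', X_GE X_GE' = Z_GE (I (x) G) Z_GE'
  for (s in 1:4) {
    J <- sample(3:8, 1); I <- sample(2:4, 1)
    G <- toyGRM(J, seed = 40 + s)
    cells <- completeCells(J, I, lines = lineIds(G))
    cells <- cells[sample(nrow(cells), nrow(cells) - 1), ]
    Z <- buildDesignMatrices(cells, paste0("E", seq_len(I)), lineIds(G))
    cf <- choleskyFactor(G)
    enc <- encodeFeatures(Z$Z_E, Z$Z_G, Z$Z_GE, cf, include_interaction = TRUE)
    Gm <- as.matrix(G) + diag(cf@jitter, J)
    XG <- enc@X[, enc@blocks$genotype]
    XGE <- enc@X[, enc@blocks$interaction]
    expect_lt(max(abs(tcrossprod(XG) -
                      as.matrix(Z$Z_G %*% Gm %*% Matrix::t(Z$Z_G)))), 1e-8)
    K <- kronecker(diag(I), Gm)
    expect_lt(max(abs(tcrossprod(XGE) -
                      as.matrix(Z$Z_GE %*% K %*% Matrix::t(Z$Z_GE)))), 1e-8)
  }

  # ordering mismatch is rejected
  Zbad <- Z
  colnames(Zbad$Z_G) <- rev(colnames(Zbad$Z_G))
  expect_error(encodeFeatures(Zbad$Z_E, Zbad$Z_G, NULL, cf), "ordering")
})

test_that("depth, size and width follow the bias-augmented accounting", {
  expect_equal(networkDepth(c(8, 4, 4, 4, 3)), 4)
  expect_equal(networkSize(c(8, 4, 4, 4, 3)), 27)
  expect_equal(networkWidth(c(8, 4, 4, 4, 3)), 9)
  expect_equal(networkDepth(c(5, 1)), 1)
  expect_equal(networkSize(c(1, 1)), 3)
  expect_equal(networkWidth(c(1, 1)), 2)
  expect_equal(networkDepth(c(5, 3, 2)), 2)
  expect_equal(networkSize(c(5, 3, 2)), 12)
  expect_equal(networkWidth(c(3, 10, 2)), 11)
  expect_error(networkDepth(5))
})

test_that("grid cardinality is the product of the three dimensions", {
  expect_equal(countGrid(hyperGrid()), 6000)
  expect_equal(countGrid(hyperGrid(1, 1, 1)), 1)
  expect_equal(countGrid(hyperGrid(c(10, 20), c(1, 2, 3), c(1, 2))), 12)
  expect_error(hyperGrid(units_values = c(0, 10)), "positive")
})

test_that("training is seeded-deterministic and fits realizable functions", {
  set.seed(2)
  n <- 150; d <- 6
  X <- matrix(runif(n * d), n)
  w <- runif(d)
  y <- 4 + X %*% w    # positive linear map: realizable with RELU output
  sp <- networkSpec(n_hidden_layers = 1, units_per_layer = 40,
                    dropout_rate = 0, max_epochs = 2000,
                    learning_rate = 0.02, seed = 5)
  fit <- trainNetwork(X, y, sp)
  fit2 <- trainNetwork(X, y, sp)
  expect_identical(fit@weights, fit2@weights)
  expect_lt(utils::tail(fit@history$train_loss, 1), 1e-3 * var(as.numeric(y)))

  # constant positive target is matched through the bias path
  yc <- rep(3, n)
  fitc <- trainNetwork(X, yc, networkSpec(n_hidden_layers = 1,
                                          units_per_layer = 8,
                                          dropout_rate = 0, max_epochs = 200,
                                          learning_rate = 0.01, seed = 1))
  expect_lt(max(abs(predictNetwork(fitc, X) - 3)), 0.2)
})

test_that("inference is deterministic, non-negative under RELU, and matches
           a pencil-and-paper forward pass", {
  set.seed(3)
  X <- matrix(rnorm(60), 20)
  fit <- trainNetwork(X, abs(rnorm(20)) + 1,
                      networkSpec(units_per_layer = 5, max_epochs = 10,
                                  seed = 2))
  expect_identical(predictNetwork(fit, X), predictNetwork(fit, X))
  expect_true(all(predictNetwork(fit, X) >= 0))

  # hand-set 1-hidden-unit network: x = 1 standardized off (center 0 scale 1)
  hand <- new("TrainedNetwork",
              weights = list(matrix(2), matrix(-3)),
              biases = list(0.5, 10),
              spec = unclass(networkSpec(n_hidden_layers = 1,
                                         units_per_layer = 1)),
              center = 0, scale = 1,
              history = data.frame(), bestEpoch = 1L)
  # relu(1*2 + 0.5) = 2.5 ; relu(2.5 * -3 + 10) = 2.5
  expect_equal(as.numeric(predictNetwork(hand, matrix(1))), 2.5)

  zero <- new("TrainedNetwork",
              weights = list(matrix(0), matrix(0)),
              biases = list(0, 0),
              spec = unclass(networkSpec(n_hidden_layers = 1,
                                         units_per_layer = 1)),
              center = 0, scale = 1,
              history = data.frame(), bestEpoch = 1L)
  expect_true(all(predictNetwork(zero, matrix(rnorm(5))) == 0))

  expect_error(predictNetwork(fit, matrix(0, 2, 9)), "feature dimension")
})

test_that("grid search scores every combination and breaks ties lexicographically", {
  set.seed(4)
  X <- matrix(runif(200), 50)
  y <- 2 + X %*% runif(4)
  grid <- hyperGrid(units_values = c(4, 8), epoch_values = c(3, 6),
                    layer_values = 1:2)
  gs <- gridSearch(X, y, grid, spec_template = networkSpec(dropout_rate = 0,
                                                           seed = 6))
  expect_equal(nrow(gs$table), countGrid(grid))
  expect_equal(gs$table[order(gs$table$val_loss,
                              gs$table$layers,
                              gs$table$units,
                              gs$table$epochs)[1], "val_loss"],
               gs$best$val_loss)

  # single combination comes straight back
  gs1 <- gridSearch(X, y, hyperGrid(7, 4, 2),
                    spec_template = networkSpec(dropout_rate = 0, seed = 1))
  expect_equal(gs1$best_spec$units_per_layer, 7L)
  expect_equal(gs1$best_spec$max_epochs, 4L)
  expect_equal(gs1$best_spec$n_hidden_layers, 2L)

  # all-zero inputs and targets tie every combination at zero loss:
  # the smallest (layers, units, epochs) must win
  X0 <- matrix(0, 30, 3)
  y0 <- rep(0, 30)
  gst <- gridSearch(X0, y0, grid,
                    spec_template = networkSpec(dropout_rate = 0,
                                                learning_rate = 0, seed = 2))
  expect_true(all(gst$table$val_loss == gst$table$val_loss[1]))
  expect_equal(gst$best$layers, 1L)
  expect_equal(gst$best$units, 4L)
  expect_equal(gst$best$epochs, 3L)

  expect_error(gridSearch(X[1:3, ], y[1:3], grid, validation_fraction = 0.01),
               "validation split")
})

test_that("a single-output multi-trait network reduces to the univariate model", {
  set.seed(8)
  X <- matrix(runif(120), 40)
  y <- matrix(3 + X %*% runif(3), ncol = 1)
  sp <- networkSpec(n_hidden_layers = 2, units_per_layer = 10,
                    n_outputs = 1, dropout_rate = 0.2, max_epochs = 25,
                    seed = 9)
  f1 <- trainNetwork(X, y, sp)
  f2 <- trainNetwork(X, as.numeric(y), sp)
  expect_identical(f1@history$train_loss, f2@history$train_loss)
  expect_identical(f1@weights, f2@weights)
})

test_that("multi-trait training is on average no worse than univariate on
           strongly correlated traits", {
  n_rep <- 10
  mt <- ud <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # small panel, noisy traits, near-unit genetic correlation: the regime
    # where sharing information across traits effectively enlarges the
    # training set
    cfg <- simulationConfig(
      n_lines = 30, n_markers = 120, n_envs = 3,
      lines_per_env_range = c(23, 30), marker_missing_rate = 0,
      trait_baselines = c(50, 60), env_effect_spread = c(4, 4),
      sigma2_g = c(25, 25), sigma2_ge = c(0, 0), sigma2_e = c(8, 8),
      trait_genetic_correlation = matrix(c(1, .95, .95, 1), 2),
      seed = 700 + r)
    m <- imputeMissing(qcMarkers(simulateMarkers(cfg)))
    g <- computeGRM(m)
    d <- makeIncompleteDesign(cfg)
    sim <- simulatePhenotypes(d, g, cfg)
    ph <- sim$phenotypes
    parts <- cv1Partition(ph, 0.2, 1, seed = r)
    p <- parts[[1]]
    cellsAll <- unique(ph[, c("line", "environment")])
    Z <- buildDesignMatrices(cellsAll, unique(cellsAll$environment), lineIds(g))
    enc <- encodeFeatures(Z$Z_E, Z$Z_G, NULL, choleskyFactor(g))
    key <- cellKey(cellsAll)
    tr <- match(cellKey(p@trainCells), key)
    te <- match(cellKey(p@testCells), key)
    wide <- sapply(c("T1", "T2"), function(t) {
      sub <- ph[ph$trait == t, ]
      sub$value[match(key, cellKey(sub))]
    })
    spm <- networkSpec(n_hidden_layers = 1, units_per_layer = 30,
                       n_outputs = 2, dropout_rate = 0.1, max_epochs = 80,
                       learning_rate = 0.003, seed = r)
    fm <- trainNetwork(enc@X[tr, ], wide[tr, ], spm)
    pm <- predictNetwork(fm, enc@X[te, ])
    spu <- spm; spu$n_outputs <- 1L; class(spu) <- "NetworkSpec"
    pu <- sapply(1:2, function(t) {
      fu <- trainNetwork(enc@X[tr, ], wide[tr, t], spu)
      predictNetwork(fu, enc@X[te, ])[, 1]
    })
    mt[r] <- mean(sapply(1:2, function(t) maape(wide[te, t], pm[, t])))
    ud[r] <- mean(sapply(1:2, function(t) maape(wide[te, t], pu[, t])))
  }
  expect_lte(mean(mt), mean(ud))
})
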