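#' Cholesky-encoded feature matrix for the networks
#'
#' Builds `X = [Z_E, Z_G U^T, Z_GE (I_I (x) U^T)]` (interaction block only
#' when requested), where `U` is the upper Cholesky factor of the GRM, so
#' the genotype block satisfies the covariance identity
#' `X_G X_G^T = Z_G G Z_G^T` (and the interaction block the analogous
#' Kronecker identity). The Kronecker product is applied blockwise per
#' environment; it is never materialized as an `I*J x I*J` matrix.
#'
#' @param Z_E,Z_G,Z_GE Design matrices from [buildDesignMatrices()]
#'   (`Z_GE` may be `NULL` when `include_interaction = FALSE`).
#' @param factor A [CholeskyFactor-class]; its line ordering must match the
#'   columns of `Z_G`.
#' @param include_interaction Append the encoded interaction block.
#' @return An [EncodedInputs-class].
#' @export
encodeFeatures <- function(Z_E, Z_G, Z_GE = NULL, factor,
                           include_interaction = FALSE) {
  stopifnot(is(factor, "CholeskyFactor"))
  lines <- lineIds(factor)
  if (!identical(colnames(Z_G), lines))
    stop("line ordering of Z_G does not match the Cholesky factor")
  Ut <- t(factor@upper)
  n <- nrow(Z_G); I <- ncol(Z_E); J <- ncol(Z_G)
  X_G <- as.matrix(Z_G %*% Ut)
  colnames(X_G) <- paste0("g_", lines)
  blocks <- list(environment = seq_len(I), genotype = I + seq_len(J))
  X <- cbind(as.matrix(Z_E), X_G)
  if (include_interaction) {
    if (is.null(Z_GE)) stop("Z_GE required when include_interaction = TRUE")
    if (ncol(Z_GE) != I * J)
      stop("Z_GE must have I * J environment-major columns")
    # row r, observed in environment i on line j, has block i equal to
    # row j of U^T; recover (i, j) from the position of the 1 in Z_GE
    col1 <- as(Z_GE, "TsparseMatrix")
    ord <- order(col1@i)
    cells <- col1@j[ord] + 1L
    ei <- (cells - 1L) %/% J + 1L
    li <- (cells - 1L) %% J + 1L
    X_GE <- matrix(0, n, I * J)
    for (i in seq_len(I)) {
      rows <- which(ei == i)
      if (length(rows))
        X_GE[rows, (i - 1L) * J + seq_len(J)] <- Ut[li[rows], , drop = FALSE]
    }
    colnames(X_GE) <- paste0("ge_", colnames(Z_GE))
    blocks$interaction <- I + J + seq_len(I * J)
    X <- cbind(X, X_GE)
  }
  new("EncodedInputs", X = X, blocks = blocks)
}

#' Network accounting: depth, size and width
#'
#' For a feedforward network described by its layer widths (input first,
#' output last): the depth is the number of layers excluding the input
#' layer; the size is the total neuron count where the input and each
#' hidden layer carry one extra bias unit (the output layer does not); the
#' width is the maximum bias-augmented layer width. For layer widths
#' `(8, 4, 4, 4, 3)` these are 4, |9+5+5+5+3| = 27 and 9.
#'
#' @param layer_sizes Integer vector of layer widths, length >= 2.
#' @return An integer count.
#' @export
#' @examples
#' networkDepth(c(8, 4, 4, 4, 3))  # 4
#' networkSize(c(8, 4, 4, 4, 3))   # 27
#' networkWidth(c(8, 4, 4, 4, 3))  # 9
networkDepth <- function(layer_sizes) {
  stopifnot(length(layer_sizes) >= 2)
  length(layer_sizes) - 1L
}

#' @rdname networkDepth
#' @export
networkSize <- function(layer_sizes) {
  stopifnot(length(layer_sizes) >= 2)
  k <- length(layer_sizes)
  as.integer(sum(layer_sizes[-k] + 1L) + layer_sizes[k])
}

#' @rdname networkDepth
#' @export
networkWidth <- function(layer_sizes) {
  stopifnot(length(layer_sizes) >= 2)
  k <- length(layer_sizes)
  as.integer(max(c(layer_sizes[-k] + 1L, layer_sizes[k])))
}

#' Hyperparameters of a feedforward network
#'
#' @param n_hidden_layers Number of hidden layers (1--3).
#' @param units_per_layer Units in each hidden layer (same for all).
#' @param n_outputs 1 for the univariate model, the number of traits for
#'   the multi-trait model.
#' @param dropout_rate Inverted-dropout rate on each hidden layer
#'   (default 0.30).
#' @param max_epochs Training epochs (default 200).
#' @param activation,output_activation `"relu"` (default, suits strictly
#'   positive traits) or `"linear"`.
#' @param learning_rate,momentum,batch_size Mini-batch gradient-descent
#'   controls.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A validated list of class `NetworkSpec`.
#' @export
networkSpec <- function(n_hidden_layers = 1, units_per_layer = 50,
                        n_outputs = 1, dropout_rate = 0.30,
                        max_epochs = 200, activation = "relu",
                        output_activation = "relu",
                        learning_rate = 0.005, momentum = 0.9,
                        batch_size = 64, seed = 1) {
  if (n_hidden_layers < 1 || n_hidden_layers > 3)
    stop("n_hidden_layers must be 1, 2 or 3")
  if (units_per_layer < 1) stop("units_per_layer must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (!activation %in% c("relu", "linear") ||
      !output_activation %in% c("relu", "linear"))
    stop("supported activations: relu, linear")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units_per_layer = as.integer(units_per_layer),
                 n_outputs = as.integer(n_outputs),
                 dropout_rate = dropout_rate,
                 max_epochs = as.integer(max_epochs),
                 activation = activation,
                 output_activation = output_activation,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "NetworkSpec")
}

#' Hyperparameter grid for units, epochs and layers
#'
#' Defaults follow the study design: units 20 to 200 in steps of 20, epochs
#' 1 to 200, layers 1 to 3 — 6,000 combinations in total.
#'
#' @param units_values,epoch_values,layer_values Positive integer vectors.
#' @return A list of class `HyperGrid`.
#' @export
hyperGrid <- function(units_values = seq(20L, 200L, by = 20L),
                      epoch_values = 1:200, layer_values = 1:3) {
  for (v in list(units_values, epoch_values, layer_values))
    if (length(v) == 0 || any(v < 1) || any(v %% 1 != 0))
      stop("grid values must be positive integers")
  structure(list(units_values = as.integer(units_values),
                 epoch_values = as.integer(epoch_values),
                 layer_values = as.integer(layer_values)),
            class = "HyperGrid")
}

#' Number of hyperparameter combinations in a grid
#' @param grid A [hyperGrid()].
#' @return Product of the three list lengths.
#' @export
#' @examples
#' countGrid(hyperGrid())  # 6000
countGrid <- function(grid) {
  length(grid$units_values) * length(grid$epoch_values) *
    length(grid$layer_values)
}

actFun <- function(name) switch(name, relu = function(x) pmax(x, 0),
                                linear = identity)
actGrad <- function(name) switch(name,
                                 relu = function(pre) (pre > 0) * 1,
                                 linear = function(pre) 1)

asFeatureMatrix <- function(inputs) {
  if (is(inputs, "EncodedInputs")) inputs@X else as.matrix(inputs)
}

#' Train a feedforward network by mini-batch gradient descent
#'
#' Forward pass through 1--3 fully connected hidden layers with bias terms
#' and the configured activation; mean-squared-error loss, summed equally
#' over outputs for multi-trait targets; inverted dropout on each hidden
#' layer during training; fixed learning rate with momentum. Features are
#' standardized on the training set (the stored center/scale are re-applied
#' at prediction); targets stay on their original positive scale so a RELU
#' output is feasible. Rows with any missing target are dropped (listwise).
#' Deterministic under `spec$seed`.
#'
#' @param inputs [EncodedInputs-class] or numeric feature matrix.
#' @param targets Numeric vector or n x n_outputs matrix.
#' @param spec A [networkSpec()].
#' @param validation Optional `list(inputs =, targets =)` on which loss is
#'   evaluated (dropout disabled) after every epoch; the epoch with minimal
#'   validation loss is recorded as `bestEpoch` and its weights retained.
#' @return A [TrainedNetwork-class] with a per-epoch loss `history`.
#' @export
trainNetwork <- function(inputs, targets, spec = networkSpec(),
                         validation = NULL) {
  X <- asFeatureMatrix(inputs)
  Y <- as.matrix(targets)
  if (nrow(X) != nrow(Y)) stop("inputs and targets disagree in rows")
  if (ncol(Y) != spec$n_outputs)
    stop("targets have ", ncol(Y), " column(s) but spec$n_outputs = ",
         spec$n_outputs)
  ok <- rowSums(is.na(Y)) == 0
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  n <- nrow(X)
  if (n < 2) stop("need at least 2 complete training rows")

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  L <- spec$n_hidden_layers
  M <- spec$units_per_layer
  O <- spec$n_outputs
  sizes <- c(ncol(X), rep(M, L), O)
  act <- actFun(spec$activation); dact <- actGrad(spec$activation)
  oact <- actFun(spec$output_activation)
  doact <- actGrad(spec$output_activation)
  keep <- 1 - spec$dropout_rate

  hasVal <- !is.null(validation)
  if (hasVal) {
    Xv <- asFeatureMatrix(validation$inputs)
    Yv <- as.matrix(validation$targets)
    okv <- rowSums(is.na(Yv)) == 0
    Xv <- Xv[okv, , drop = FALSE]; Yv <- Yv[okv, , drop = FALSE]
    if (nrow(Xv) < 1) stop("validation set has no complete rows")
    Xvs <- sweep(sweep(Xv, 2, ctr), 2, scl, `/`)
  }

  withSeed(spec$seed, {
    W <- vector("list", L + 1); B <- vector("list", L + 1)
    for (l in seq_len(L + 1)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                       fan_in, sizes[l + 1])
      B[[l]] <- numeric(sizes[l + 1])
    }
    B[[L + 1]] <- colMeans(Y)          # start the output at the target mean
    vW <- lapply(W, function(w) w * 0); vB <- lapply(B, function(b) b * 0)

    forward <- function(Xin) {
      H <- Xin
      for (l in seq_len(L)) H <- act(sweep(H %*% W[[l]], 2, B[[l]], `+`))
      oact(sweep(H %*% W[[L + 1]], 2, B[[L + 1]], `+`))
    }
    valLoss <- function() mean((forward(Xvs) - Yv)^2)

    nb <- max(1L, ceiling(n / spec$batch_size))
    history <- data.frame(epoch = seq_len(spec$max_epochs),
                          train_loss = NA_real_, val_loss = NA_real_)
    best <- list(epoch = spec$max_epochs, loss = Inf, W = W, B = B)

    for (ep in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        rows <- ord[seq.int((bi - 1L) * spec$batch_size + 1L,
                            min(bi * spec$batch_size, n))]
        Xb <- Xs[rows, , drop = FALSE]; Yb <- Y[rows, , drop = FALSE]
        m <- length(rows)
        Hs <- vector("list", L + 1); Pre <- vector("list", L + 1)
        Msk <- vector("list", L)
        Hs[[1]] <- Xb
        for (l in seq_len(L)) {
          Pre[[l]] <- sweep(Hs[[l]] %*% W[[l]], 2, B[[l]], `+`)
          Hl <- act(Pre[[l]])
          if (spec$dropout_rate > 0) {
            Msk[[l]] <- matrix((runif(m * sizes[l + 1]) < keep) / keep,
                               m, sizes[l + 1])
            Hl <- Hl * Msk[[l]]
          }
          Hs[[l + 1]] <- Hl
        }
        Pre[[L + 1]] <- sweep(Hs[[L + 1]] %*% W[[L + 1]], 2, B[[L + 1]], `+`)
        P <- oact(Pre[[L + 1]])
        err <- P - Yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep,
               "; lower the learning rate")
        ep_loss <- ep_loss + loss * m
        delta <- (2 / (m * O)) * err * doact(Pre[[L + 1]])
        for (l in rev(seq_len(L + 1))) {
          gW <- crossprod(Hs[[l]], delta)
          gB <- colSums(delta)
          if (l > 1) {
            delta <- tcrossprod(delta, W[[l]]) * dact(Pre[[l - 1]])
            if (spec$dropout_rate > 0) delta <- delta * Msk[[l - 1]]
          }
          vW[[l]] <- spec$momentum * vW[[l]] - spec$learning_rate * gW
          vB[[l]] <- spec$momentum * vB[[l]] - spec$learning_rate * gB
          W[[l]] <- W[[l]] + vW[[l]]
          B[[l]] <- B[[l]] + vB[[l]]
        }
      }
      history$train_loss[ep] <- ep_loss / n
      if (hasVal) {
        vl <- valLoss()
        history$val_loss[ep] <- vl
        if (vl < best$loss) best <- list(epoch = ep, loss = vl, W = W, B = B)
      }
    }
    if (!hasVal) best <- list(epoch = spec$max_epochs, loss = NA, W = W, B = B)
    new("TrainedNetwork", weights = best$W, biases = best$B,
        spec = unclass(spec), center = ctr, scale = scl,
        history = history, bestEpoch = as.integer(best$epoch))
  })
}

#' Predict from a trained network
#'
#' Deterministic forward pass with dropout disabled (inverted dropout during
#' training keeps train/test expectations consistent). With the default RELU
#' output all predictions are non-negative.
#'
#' @param model A [TrainedNetwork-class].
#' @param inputs [EncodedInputs-class] or feature matrix with the training
#'   feature dimension.
#' @return n x n_outputs matrix of predictions.
#' @export
predictNetwork <- function(model, inputs) {
  X <- asFeatureMatrix(inputs)
  if (ncol(X) != length(model@center))
    stop("feature dimension (", ncol(X), ") does not match training (",
         length(model@center), ")")
  H <- sweep(sweep(X, 2, model@center), 2, model@scale, `/`)
  s <- model@spec
  act <- actFun(s$activation); oact <- actFun(s$output_activation)
  L <- s$n_hidden_layers
  for (l in seq_len(L))
    H <- act(sweep(H %*% model@weights[[l]], 2, model@biases[[l]], `+`))
  P <- oact(sweep(H %*% model@weights[[L + 1]], 2, model@biases[[L + 1]], `+`))
  dimnames(P) <- NULL
  P
}

#' @describeIn predictNetwork `predict` method for `TrainedNetwork`.
#' @param object A [TrainedNetwork-class].
#' @param ... Unused.
#' @export
setMethod("predict", "TrainedNetwork", function(object, inputs, ...)
  predictNetwork(object, inputs))

#' Grid search over units, epochs and layers
#'
#' For each (units, layers) pair one network is trained on an inner 80/20
#' split of the supplied rows, and the inner-validation loss is recorded at
#' every epoch in `grid$epoch_values` — equivalent to evaluating every
#' (units, epochs, layers) combination, at a fraction of the cost. The
#' combination with minimal inner-validation loss wins; ties break to fewer
#' layers, then fewer units, then fewer epochs.
#'
#' @param inputs [EncodedInputs-class] or feature matrix.
#' @param targets Numeric vector/matrix of training targets.
#' @param grid A [hyperGrid()].
#' @param validation_fraction Fraction of rows held out as the inner
#'   validation set (drawn once, seeded).
#' @param spec_template A [networkSpec()] providing all non-grid
#'   hyperparameters and the seed.
#' @return List with `best_spec` (a [networkSpec()] whose `max_epochs` is
#'   the selected epoch), `best` (one-row data frame) and `table` (the full
#'   score table, one row per grid combination).
#' @export
gridSearch <- function(inputs, targets, grid = hyperGrid(),
                       validation_fraction = 0.2,
                       spec_template = networkSpec()) {
  X <- asFeatureMatrix(inputs)
  Y <- as.matrix(targets)
  n <- nrow(X)
  n_val <- floor(validation_fraction * n)
  if (n_val < 1) stop("validation split smaller than 1 record")
  val_rows <- withSeed(deriveSeed(spec_template$seed, "grid-val"),
                       sample.int(n, n_val))
  tr_rows <- setdiff(seq_len(n), val_rows)
  max_ep <- max(grid$epoch_values)
  tabs <- list()
  for (layers in sort(grid$layer_values)) {
    for (units in sort(grid$units_values)) {
      sp <- spec_template
      sp$n_hidden_layers <- layers
      sp$units_per_layer <- as.integer(units)
      sp$max_epochs <- max_ep
      sp$n_outputs <- ncol(Y)
      class(sp) <- "NetworkSpec"
      fit <- trainNetwork(X[tr_rows, , drop = FALSE],
                          Y[tr_rows, , drop = FALSE], sp,
                          validation = list(inputs = X[val_rows, , drop = FALSE],
                                            targets = Y[val_rows, , drop = FALSE]))
      tabs[[length(tabs) + 1L]] <- data.frame(
        layers = layers, units = as.integer(units),
        epochs = grid$epoch_values,
        val_loss = fit@history$val_loss[grid$epoch_values])
    }
  }
  tab <- do.call(rbind, tabs)
  ord <- order(tab$val_loss, tab$layers, tab$units, tab$epochs)
  best <- tab[ord[1], ]
  best_spec <- spec_template
  best_spec$n_hidden_layers <- best$layers
  best_spec$units_per_layer <- best$units
  best_spec$max_epochs <- best$epochs
  best_spec$n_outputs <- ncol(Y)
  class(best_spec) <- "NetworkSpec"
  list(best_spec = best_spec, best = best, table = tab)
}
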