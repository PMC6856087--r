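# Shared fixture builders: everything is generated in code, no stored data.

# A small positive-definite GRM with line labels.
toyGRM <- function(J, seed = 1, p = 2 * J) {
  set.seed(seed)
  W <- matrix(rnorm(J * p), J)
  g <- tcrossprod(W) / p
  dimnames(g) <- list(sprintf("L%03d", seq_len(J)), sprintf("L%03d", seq_len(J)))
  grmMatrix(g)
}

# A complete (line x environment) cell table.
completeCells <- function(J, I, lines = sprintf("L%03d", seq_len(J)),
                          envs = paste0("E", seq_len(I))) {
  expand.grid(line = lines, environment = envs,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

# Dense generalized-least-squares oracle for the multi-environment model:
# V = s2g Zg G Zg' + s2ge Zge (I (x) G) Zge' + s2e I, beta by GLS, BLUPs by
# the conditional-mean formula. Independent of the package's MME solver.
glsOracle <- function(pheno, G, s2g, s2ge, s2e, env_ids, interaction = TRUE) {
  line_ids <- rownames(G)
  Z <- buildDesignMatrices(pheno, env_ids, line_ids)
  X <- as.matrix(Z$Z_E); Zg <- as.matrix(Z$Z_G); Zge <- as.matrix(Z$Z_GE)
  I <- length(env_ids)
  y <- pheno$value
  V <- s2g * Zg %*% G %*% t(Zg) + s2e * diag(length(y))
  if (interaction && s2ge > 0)
    V <- V + s2ge * Zge %*% kronecker(diag(I), G) %*% t(Zge)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  g <- as.numeric(s2g * G %*% t(Zg) %*% Vi %*% r)
  ge <- if (interaction && s2ge > 0)
    as.numeric(s2ge * kronecker(diag(I), G) %*% t(Zge) %*% Vi %*% r)
  else rep(0, I * nrow(G))
  list(beta = setNames(as.numeric(beta), env_ids),
       g = setNames(g, line_ids),
       ge = matrix(ge, nrow = I, byrow = TRUE,
                   dimnames = list(env_ids, line_ids)))
}

cellKey <- function(d) paste(d$line, d$environment, sep = "\r")
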