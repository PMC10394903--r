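# fixtures are built in code at test time

# genes x columns matrix with ids
toyMatrix <- function(values, genes = NULL, cols = NULL, unitTag = "counts") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(cols)) cols <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cols)
  ExpressionMatrix(values, unitTag = unitTag)
}

# reference with unit cell counts from a profile matrix
toyReference <- function(profiles, unitTag = "counts") {
  em <- if (is(profiles, "ExpressionMatrix")) profiles else toyMatrix(profiles,
    cols = paste0("ct", seq_len(ncol(as.matrix(profiles)))), unitTag = unitTag)
  ClusterReference(em, setNames(rep(1, ncol(em@values)), colnames(em@values)))
}

# reduced-scale synthetic concurrent dataset for fast module tests
smallConcurrent <- function(seed = 1, tau = 0.5, nGenes = 400,
                            cellsPerSample = 1500, ...) {
  design <- sampleDesign(seed, nGenes = nGenes)
  generateConcurrent(design, PlatformBiasModel(tau = tau, ...),
                     cellsPerSample = cellsPerSample, seed = seed)
}

# vectors with an exact target correlation structure (via Cholesky), then
# shifted positive so they can serve as expression profiles
correlatedProfiles <- function(corMat, n = 200, seed = 42) {
  k <- ncol(corMat)
  set.seed(seed)
  raw <- matrix(rnorm(n * k), n, k)
  base <- qr.Q(qr(scale(raw, scale = FALSE)))[, seq_len(k)] * sqrt(n - 1)
  out <- base %*% chol(corMat)
  out <- sweep(out, 2, apply(out, 2, min), "-") + 1
  colnames(out) <- LETTERS[seq_len(k)]
  rownames(out) <- paste0("g", seq_len(n))
  out
}

# exhaustive simplex grid minimum of the (optionally weighted) least-squares
# deconvolution objective, for 3 cell types at the given step
simplexGridMin <- function(X, z, w = NULL, step = 1e-3) {
  stopifnot(ncol(X) == 3)
  if (is.null(w)) w <- rep(1, nrow(X))
  G <- crossprod(X, X * w)
  q <- crossprod(X * w, z)
  c0 <- sum(w * z^2)
  R <- chol(G)
  s <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = s, p2 = s)
  grid <- grid[grid$p1 + grid$p2 <= 1 + 1e-12, ]
  P <- cbind(grid$p1, grid$p2, pmax(1 - grid$p1 - grid$p2, 0))
  obj <- c0 - 2 * as.numeric(P %*% q) + rowSums((P %*% t(R))^2)
  min(obj)
}
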