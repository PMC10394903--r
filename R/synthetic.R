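# Synthetic concurrent bulk + single-cell datasets with known ground truth.
# The default design emulates a six-mixture experiment over six cell types:
# three variable tumor lines, two immune types jointly fixed at 15% of every
# mixture, and one rare stem-cell type cycling through 0.5%, 1% and 2%.
# The platform-bias model injects a per-gene multiplicative capture factor on
# the single-cell side — the exactly-linear distortion the per-gene transform
# is designed to absorb — plus optional dropout and bulk noise.

.designTypes <- c("tumorA", "tumorB", "tumorC", "immune1", "immune2", "stem")

#' Draw a ground-truth mixture design
#'
#' Six mixtures over six cell types. The two immune types jointly account for
#' 15\% of every mixture; the stem type cycles through 0.5\%, 1\% and 2\%
#' (mixtures 1 and 4 at 0.5\%, 3 and 6 at 2\%); the three tumor types share
#' the remaining mass, with mixture 1 dominated by one tumor type (>= 66\% of
#' the whole mixture) and mixture 4 balanced. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param nGenes number of genes the downstream generator will simulate
#'   (default 2000).
#' @return a \linkS4class{MixtureDesign}.
#' @export
sampleDesign <- function(seed = 1, nGenes = 2000) {
  p <- withLocalSeed(seed, {
    stem <- c(0.005, 0.01, 0.02, 0.005, 0.01, 0.02)
    imm1 <- 0.15 * runif(6, 0.3, 0.7)
    out <- matrix(0, 6, 6, dimnames = list(paste0("M", 1:6), .designTypes))
    out[, "stem"] <- stem
    out[, "immune1"] <- imm1
    out[, "immune2"] <- 0.15 - imm1
    for (i in 1:6) {
      mass <- 1 - 0.15 - stem[i]
      tum <- if (i == 1) {
        a <- runif(1, 0.66, min(0.72, mass - 0.02))
        rest <- runif(1, 0.3, 0.7) * (mass - a)
        c(a, rest, mass - a - rest)
      } else if (i == 4) {
        j <- runif(2, -0.02, 0.02)
        c(mass / 3 + j[1], mass / 3 + j[2], mass / 3 - sum(j))
      } else {
        # every line visibly present: Dirichlet on the mass above a 5% floor
        g <- rgamma(3, 1)
        g / sum(g) * (mass - 3 * 0.05) + 0.05
      }
      out[i, 1:3] <- tum
    }
    out
  })
  new("MixtureDesign", proportions = p, nGenes = nGenes, seed = seed)
}

# per-cell-type mean expression: log-normal(0, 1) per (gene, type), with a
# disjoint 5% block of type-specific marker genes boosted 8-fold per type
trueTypeProfiles <- function(nGenes, types) {
  K <- length(types)
  mu <- matrix(rlnorm(nGenes * K, 0, 1), nGenes, K,
               dimnames = list(sprintf("gene_%04d", seq_len(nGenes)), types))
  block <- max(1, floor(0.05 * nGenes))
  for (j in seq_len(K)) {
    lo <- (j - 1) * block + 1
    hi <- min(j * block, nGenes)
    if (lo <= hi) mu[lo:hi, j] <- mu[lo:hi, j] * 8
  }
  mu
}

# per-cell-type capture/content scalars on the single-cell side: explicit
# values when supplied, otherwise drawn log-normal(0, tau) (so tau = 0 gives
# an unbiased platform). Must be called inside the generator's seeded block.
resolveContent <- function(bias, types) {
  cont <- setNames(rlnorm(length(types), 0, bias@tau), types)
  if (length(bias@contentScalars)) {
    if (is.null(names(bias@contentScalars)) &&
        length(bias@contentScalars) == length(types))
      names(bias@contentScalars) <- types
    cont[] <- 1
    cont[names(bias@contentScalars)] <- bias@contentScalars
  }
  cont
}

#' Generate a synthetic concurrent dataset
#'
#' Simulates aligned bulk and single-cell profiles for a mixture design under
#' a platform-bias model. Bulk counts are Poisson around depth-scaled
#' content-weighted mixtures of the true type profiles, then multiplied by
#' log-normal noise. Cells are assigned to types multinomially per sample;
#' per-cell counts are negative binomial (dispersion 0.5) around the
#' capture-biased (and, if enabled, dropout-thinned) type means. The realized
#' per-sample cell fractions are returned as the gold standard, and the true
#' type profiles for oracle deconvolution.
#'
#' @param design a \linkS4class{MixtureDesign}.
#' @param bias a \linkS4class{PlatformBiasModel}.
#' @param cellsPerSample cells simulated per sample (default 2000).
#' @param bulkDepth expected total bulk counts per sample (default 1e6).
#' @param seed seed for the generator's randomness (default the design seed).
#' @param sparse store single-cell counts as a sparse Matrix (default TRUE).
#' @return list with \code{dataset} (\linkS4class{ConcurrentDataset}),
#'   \code{gold} (realized cell fractions, \linkS4class{CompositionMatrix}),
#'   \code{trueProfiles} (genes x types \linkS4class{ExpressionMatrix}),
#'   \code{design}, and \code{captureFactors} (the injected per-gene bias).
#' @export
generateConcurrent <- function(design, bias = PlatformBiasModel(),
                               cellsPerSample = 2000, bulkDepth = 1e6,
                               seed = design@seed, sparse = TRUE) {
  P <- design@proportions
  types <- colnames(P)
  G <- as.integer(design@nGenes)
  S <- nrow(P)
  withLocalSeed(seed + 104729, {
    mu <- trueTypeProfiles(G, types)
    cont <- resolveContent(bias, types)
    capture <- if (bias@typeDependentBias)
      matrix(rlnorm(G * length(types), 0, bias@tau), G, length(types))
    else matrix(rlnorm(G, 0, bias@tau), G, length(types))
    scMean <- sweep(mu * capture, 2, cont[types], "*")
    if (bias@dropout > 0) {
      keepProb <- 1 - bias@dropout * exp(-rowMeans(mu))
      scMean <- scMean * keepProb
    }
    # bulk: Poisson around the depth-scaled, unbiased mixture expectation
    mix <- mu %*% t(P)  # genes x samples
    lam <- sweep(mix, 2, colSums(mix), "/") * bulkDepth
    bulkv <- matrix(rpois(G * S, lam), G, S,
                    dimnames = list(rownames(mu), rownames(P)))
    if (bias@bulkNoiseSdlog > 0)
      bulkv <- bulkv * matrix(rlnorm(G * S, 0, bias@bulkNoiseSdlog), G, S)
    # single cell: multinomial type assignment, NB counts per cell
    cellMats <- list()
    cellSample <- character(0)
    cellType <- character(0)
    goldv <- matrix(0, S, length(types), dimnames = list(rownames(P), types))
    for (i in seq_len(S)) {
      n <- drop(rmultinom(1, cellsPerSample, P[i, ]))
      if (any(n == 0)) {
        n <- drop(rmultinom(1, cellsPerSample, P[i, ]))
        if (any(n == 0))
          stopf("sample %s: cell type(s) received 0 cells twice; increase cellsPerSample",
                rownames(P)[i])
      }
      goldv[i, ] <- n / sum(n)
      for (j in seq_along(types)) {
        counts <- matrix(rnbinom(G * n[j], mu = scMean[, j], size = 2), G, n[j])
        cellMats[[length(cellMats) + 1L]] <- counts
      }
      cellSample <- c(cellSample, rep(rownames(P)[i], sum(n)))
      cellType <- c(cellType, rep(types, n))
    }
    sc <- do.call(cbind, cellMats)
    dimnames(sc) <- list(rownames(mu),
                         sprintf("cell_%06d", seq_len(ncol(sc))))
    if (sparse) sc <- methods::as(Matrix::Matrix(sc, sparse = TRUE), "CsparseMatrix")
    mito <- prefixFraction(ExpressionMatrix(sc), "gene_000[1-9]$")
    labels <- CellLabelTable(colnames(sc), cellSample, cellType,
                             mitoFraction = mito, riboFraction = mito)
    scm <- ExpressionMatrix(sc, "counts")
    bulkm <- ExpressionMatrix(bulkv, "counts")
    list(dataset = ConcurrentDataset(bulkm, scm, labels),
         gold = CompositionMatrix(goldv, kind = "gold_standard"),
         trueProfiles = ExpressionMatrix(mu, "arbitrary"),
         design = design,
         captureFactors = capture,
         typeScalars = cont)
  })
}

#' Expected-value (noise-free) concurrent dataset
#'
#' Emits exact expectations instead of sampled counts: bulk columns are the
#' content-weighted mixtures of the true type profiles (no depth scaling, no
#' Poisson or log-normal noise), the pseudobulk slot is the exact
#' capture-biased mixture expectation, and the single-cell side holds one
#' deterministic cell block per (sample, type) — every cell exactly equal to
#' the capture-biased type mean — so cluster profiles are exact. The gold
#' standard equals the design proportions. Used for exact solver tests.
#'
#' @param design a \linkS4class{MixtureDesign}.
#' @param bias a \linkS4class{PlatformBiasModel}; its \code{bulkNoiseSdlog}
#'   and \code{dropout} are ignored here unless dropout > 0, in which case
#'   the deterministic per-gene thinning factor is applied.
#' @param cellsPerType deterministic cells per (sample, type) block
#'   (default 10).
#' @param seed seed for the capture-factor draw (default the design seed).
#' @return list as in \code{\link{generateConcurrent}}.
#' @export
expectedValueMode <- function(design, bias = PlatformBiasModel(),
                              cellsPerType = 10, seed = design@seed) {
  P <- design@proportions
  types <- colnames(P)
  G <- as.integer(design@nGenes)
  S <- nrow(P)
  withLocalSeed(seed + 104729, {
    mu <- trueTypeProfiles(G, types)
    cont <- resolveContent(bias, types)
    capture <- if (bias@typeDependentBias)
      matrix(rlnorm(G * length(types), 0, bias@tau), G, length(types))
    else matrix(rlnorm(G, 0, bias@tau), G, length(types))
    scMean <- sweep(mu * capture, 2, cont[types], "*")
    if (bias@dropout > 0)
      scMean <- scMean * (1 - bias@dropout * exp(-rowMeans(mu)))
    bulkv <- mu %*% t(P)
    dimnames(bulkv) <- list(rownames(mu), rownames(P))
    pbv <- scMean %*% t(P)  # exact expectation of the per-sample cell mean
    dimnames(pbv) <- dimnames(bulkv)
    nc <- S * length(types) * cellsPerType
    sc <- matrix(0, G, nc, dimnames = list(rownames(mu),
                                           sprintf("cell_%06d", seq_len(nc))))
    cellSample <- rep(rownames(P), each = length(types) * cellsPerType)
    cellType <- rep(rep(types, each = cellsPerType), S)
    for (j in seq_along(types)) sc[, cellType == types[j]] <- scMean[, j]
    labels <- CellLabelTable(colnames(sc), cellSample, cellType,
                             mitoFraction = rep(0, nc), riboFraction = rep(0, nc))
    ds <- new("ConcurrentDataset",
              bulk = ExpressionMatrix(bulkv, "arbitrary"),
              scCounts = ExpressionMatrix(sc, "arbitrary"),
              scLabels = labels,
              pseudobulk = ExpressionMatrix(pbv, "arbitrary"))
    list(dataset = ds,
         gold = CompositionMatrix(P, kind = "gold_standard"),
         trueProfiles = ExpressionMatrix(mu, "arbitrary"),
         design = design,
         captureFactors = capture,
         typeScalars = cont)
  })
}

#' Write a generated dataset to disk
#'
#' Writes the MTX triplet, bulk TSV, label TSV, gold TSV and true-profile TSV
#' of a \code{\link{generateConcurrent}} result into a directory.
#'
#' @param gen list returned by \code{\link{generateConcurrent}} or
#'   \code{\link{expectedValueMode}}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeConcurrent <- function(gen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMtxTriplet(gen$dataset@scCounts, file.path(dir, "sc"))
  writeDenseMatrix(gen$dataset@bulk, file.path(dir, "bulk.tsv"))
  writeCellLabels(gen$dataset@scLabels, file.path(dir, "labels.tsv"))
  writeComposition(gen$gold, file.path(dir, "gold.tsv"))
  writeDenseMatrix(gen$trueProfiles, file.path(dir, "true_profiles.tsv"))
  invisible(dir)
}
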