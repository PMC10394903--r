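test_that("pseudobulk is the per-sample mean across cells", {
  m <- toyMatrix(matrix(c(0, 1, 4, 3, 5, 7), 2, 3), cols = paste0("c", 1:3))
  lab <- CellLabelTable(paste0("c", 1:3), c("s1", "s1", "s2"), rep("A", 3))
  pb <- makePseudobulk(m, lab)
  expect_equal(exprValues(pb)[, "s1"], c(g1 = 2, g2 = 2))
  expect_equal(exprValues(pb)[, "s2"], c(g1 = 5, g2 = 7))  # one-cell sample

  set.seed(31)
  v <- matrix(rpois(40 * 60, 3), 40, 60,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:60)))
  ss <- sample(paste0("s", 1:3), 60, replace = TRUE)
  pb2 <- makePseudobulk(ExpressionMatrix(v), CellLabelTable(colnames(v), ss, ss))
  for (s in paste0("s", 1:3))
    expect_lt(max(abs(exprValues(pb2)[, s] - rowMeans(v[, ss == s]))), 1e-12)
})

# a minimal concurrent dataset built by hand: 2 genes never make the
# transform-fit universe checks trip, so use 30 genes, 4 samples
makeHandDataset <- function(bulkv, pbv) {
  S <- ncol(bulkv)
  cells <- paste0("c", seq_len(S))
  sc <- matrix(1, nrow(bulkv), S, dimnames = list(rownames(bulkv), cells))
  lab <- CellLabelTable(cells, colnames(bulkv), rep("A", S))
  new("ConcurrentDataset",
      bulk = ExpressionMatrix(bulkv, "arbitrary"),
      scCounts = ExpressionMatrix(sc, "arbitrary"),
      scLabels = lab,
      pseudobulk = ExpressionMatrix(pbv, "arbitrary"))
}

test_that("per-gene transform fit matches the closed form", {
  # two samples, one informative gene: bulk (1,3), pseudobulk (2,8) => a=3, b=-1
  bulkv <- matrix(c(1, 1, 3, 1), 2, 2,
                  dimnames = list(c("gA", "gB"), c("s1", "s2")))
  pbv <- matrix(c(2, 1, 8, 1), 2, 2, dimnames = dimnames(bulkv))
  ds <- makeHandDataset(bulkv, pbv)
  m <- fitGeneTransform(ds, "eq2")
  expect_equal(m@coefficients["gA", "a"], 3)
  expect_equal(m@coefficients["gA", "b"], -1)
  # zero-bulk-variance gene falls back to the pseudobulk mean
  expect_equal(m@coefficients["gB", "a"], 0)
  expect_equal(m@coefficients["gB", "b"], 1)

  # identity when pseudobulk equals bulk
  set.seed(33)
  bv <- matrix(rlnorm(120), 30, 4,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  dsI <- makeHandDataset(bv, bv)
  mI <- fitGeneTransform(dsI, "eq2")
  expect_equal(unname(mI@coefficients$a), rep(1, 30), tolerance = 1e-12)
  expect_equal(unname(mI@coefficients$b), rep(0, 30), tolerance = 1e-12)
})

test_that("eq2 fit matches an independent least-squares oracle on random data", {
  set.seed(35)
  G <- 500; S <- 10
  bv <- matrix(rlnorm(G * S), G, S,
               dimnames = list(paste0("g", 1:G), paste0("s", 1:S)))
  pv <- matrix(rlnorm(G * S), G, S, dimnames = dimnames(bv))
  m <- fitGeneTransform(makeHandDataset(bv, pv), "eq2")
  idx <- c(1, 50, 123, 250, 499)
  for (g in idx) {
    fit <- lm(pv[g, ] ~ bv[g, ])  # independent oracle
    expect_equal(m@coefficients[g, "a"], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(m@coefficients[g, "b"], unname(coef(fit)[1]), tolerance = 1e-10)
  }
  # the fit minimizes the per-gene residual sum of squares
  g <- 7
  rss <- function(a, b) sum((pv[g, ] - (a * bv[g, ] + b))^2)
  a0 <- m@coefficients[g, "a"]; b0 <- m@coefficients[g, "b"]
  for (da in c(-1e-3, 1e-3)) for (db in c(-1e-3, 0, 1e-3))
    expect_gte(rss(a0 + da, b0 + db), rss(a0, b0))
})

test_that("transform application follows the fitted map and drops out-of-scope genes", {
  bulkv <- matrix(c(1, 1, 3, 1), 2, 2,
                  dimnames = list(c("gA", "gB"), c("s1", "s2")))
  pbv <- matrix(c(2, 1, 8, 1), 2, 2, dimnames = dimnames(bulkv))
  m <- fitGeneTransform(makeHandDataset(bulkv, pbv), "eq2")
  newBulk <- toyMatrix(matrix(c(2, 9), 2, 1), genes = c("gA", "gB"), cols = "sX")
  tx <- transformBulk(m, newBulk)
  expect_equal(exprValues(tx)["gA", "sX"], 3 * 2 - 1)  # = 5

  # eq3 is the identity when the two spaces share means and sds
  set.seed(37)
  bv <- matrix(rlnorm(120), 30, 4,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  m3 <- fitGeneTransform(makeHandDataset(bv, bv), "eq3")
  tx3 <- transformBulk(m3, ExpressionMatrix(bv, "arbitrary"))
  expect_equal(exprValues(tx3), bv[rownames(exprValues(tx3)), ], tolerance = 1e-12)
})

test_that("squid deconvolution returns unit vectors for pure reference columns", {
  set.seed(39)
  X <- matrix(rlnorm(240), 60, 4,
              dimnames = list(paste0("g", 1:60), paste0("ct", 1:4)))
  ref <- toyReference(X)
  r <- squidDeconvolve(X[, 3], ref)
  expect_equal(unname(r$proportions), c(0, 0, 1, 0), tolerance = 1e-9)
})

test_that("without platform bias and noise, the transform collapses and SQUID = DWLS", {
  gen <- expectedValueMode(sampleDesign(2, nGenes = 500),
                           PlatformBiasModel(tau = 0))
  spec <- SolverSpec(seed = 2)
  ests <- squidDeconvolveMatrix(gen$dataset, spec)
  ref <- clusterProfiles(gen$dataset@scCounts, gen$dataset@scLabels)
  estd <- deconvolveMatrix(gen$dataset@bulk, ref, spec)
  expect_lt(max(abs(compValues(ests) -
                    compValues(estd)[, colnames(compValues(ests))])), 1e-6)
})

test_that("with per-gene platform bias, SQUID beats DWLS on untransformed bulk", {
  gen <- smallConcurrent(seed = 1, tau = 0.5)
  spec <- SolverSpec(seed = 1)
  ref <- clusterProfiles(gen$dataset@scCounts, gen$dataset@scLabels)
  rmse <- function(est) evaluateComposition(est, gen$gold)@rmse
  rSquid <- rmse(looCrossValidate(gen$dataset, spec))
  rDwls <- rmse(deconvolveMatrix(gen$dataset@bulk, ref, spec))
  expect_lt(rSquid, rDwls)
})

test_that("eq2 and eq3 transform paths perform equivalently", {
  gen <- smallConcurrent(seed = 3, tau = 0.5)
  spec <- SolverSpec(seed = 3)
  r2 <- evaluateComposition(looCrossValidate(gen$dataset, spec, mode = "eq2"),
                            gen$gold)@rmse
  r3 <- evaluateComposition(looCrossValidate(gen$dataset, spec, mode = "eq3"),
                            gen$gold)@rmse
  expect_lt(abs(r2 - r3), 0.02)
})

test_that("leave-one-out never reads the held-out sample's single-cell data", {
  gen <- smallConcurrent(seed = 5, tau = 0.3, nGenes = 300)
  ds <- gen$dataset
  spec <- SolverSpec(seed = 5)

  # sentinel: a gene expressed only in M1's cells is absent from M1's fold model
  v <- as.matrix(exprValues(ds@scCounts))
  sentinel <- "gene_0300"
  v[sentinel, ] <- 0
  v[sentinel, ds@scLabels@sampleId == "M1"] <- 50
  dsSent <- new("ConcurrentDataset", bulk = ds@bulk,
                scCounts = ExpressionMatrix(v, "counts"),
                scLabels = ds@scLabels,
                pseudobulk = makePseudobulk(ExpressionMatrix(v, "counts"), ds@scLabels))
  train <- setdiff(colnames(exprValues(ds@bulk)), "M1")
  keep <- dsSent@scLabels@sampleId %in% train
  foldDs <- ConcurrentDataset(
    ExpressionMatrix(exprValues(dsSent@bulk)[, train], "counts"),
    ExpressionMatrix(exprValues(dsSent@scCounts)[, keep], "counts"),
    dsSent@scLabels[keep])
  foldModel <- fitGeneTransform(foldDs, "eq2")
  expect_false(sentinel %in% rownames(foldModel@coefficients))

  # corrupting the held-out sample's cells leaves its own fold row unchanged
  base <- looCrossValidate(ds, spec)
  v2 <- as.matrix(exprValues(ds@scCounts))
  m1cells <- ds@scLabels@sampleId == "M1"
  v2[, m1cells] <- v2[, m1cells] * 1000 + 7
  dsCorrupt <- new("ConcurrentDataset", bulk = ds@bulk,
                   scCounts = ExpressionMatrix(v2, "counts"),
                   scLabels = ds@scLabels,
                   pseudobulk = makePseudobulk(ExpressionMatrix(v2, "counts"),
                                               ds@scLabels))
  corrupt <- suppressWarnings(looCrossValidate(dsCorrupt, spec))
  expect_equal(compValues(corrupt)["M1", ], compValues(base)["M1", ],
               tolerance = 1e-12)
})

test_that("leave-one-out folds of identical samples give identical rows", {
  set.seed(41)
  G <- 50
  genes <- paste0("g", 1:G)
  X <- matrix(rlnorm(G * 3), G, 3, dimnames = list(genes, c("A", "B", "C")))
  zcol <- as.numeric(X %*% c(0.5, 0.3, 0.2))
  bulkv <- matrix(zcol, G, 3, dimnames = list(genes, paste0("s", 1:3)))
  # bulk must vary a little across samples for the per-gene fit to be defined
  bulkv <- bulkv * matrix(rep(c(1, 1.1, 0.9), each = G), G, 3)
  cells <- paste0("c", 1:9)
  scv <- X[, rep(1:3, 3)]
  colnames(scv) <- cells
  lab <- CellLabelTable(cells, rep(paste0("s", 1:3), each = 3),
                        rep(c("A", "B", "C"), 3))
  ds <- ConcurrentDataset(ExpressionMatrix(bulkv, "arbitrary"),
                          ExpressionMatrix(scv, "arbitrary"), lab)
  est <- looCrossValidate(ds, SolverSpec(seed = 7))
  # exchangeable folds: the three rows agree up to the bulk scale factor,
  # which reported proportions are invariant to
  expect_equal(compValues(est)["s1", ], compValues(est)["s2", ], tolerance = 1e-6)
  expect_equal(compValues(est)["s1", ], compValues(est)["s3", ], tolerance = 1e-6)
})
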