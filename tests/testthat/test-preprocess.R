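# cell QC ------------------------------------------------------------------

test_that("qc filter removes the strict tails of each covariate, as a union", {
  n <- 1000
  counts <- toyMatrix(matrix(1, 2, n), cols = paste0("c", 1:n))
  mito <- (1:n) / (n + 1)
  # ribo ranking shifted by half the cells: tails are disjoint from mito's
  ribo <- (((1:n + 499) %% n) + 1) / (n + 1)
  lab <- CellLabelTable(paste0("c", 1:n), rep("s1", n), rep("A", n),
                        mitoFraction = mito, riboFraction = ribo)
  res <- qcFilterCells(counts, lab, tail = 0.005)
  # 5 strictly below and 5 strictly above the type-7 quantiles per covariate
  removedByMito <- c(1:5, 996:1000)
  removedByRibo <- which(ribo < quantile(ribo, 0.005) | ribo > quantile(ribo, 0.995))
  expect_length(intersect(removedByMito, removedByRibo), 0)
  expect_setequal(cellIds(res$labels),
                  paste0("c", setdiff(1:n, union(removedByMito, removedByRibo))))
  expect_equal(length(res$labels), 980L)

  # coincident rankings: the two covariates flag the same cells
  lab2 <- CellLabelTable(paste0("c", 1:n), rep("s1", n), rep("A", n),
                         mitoFraction = mito, riboFraction = mito)
  res2 <- qcFilterCells(counts, lab2, tail = 0.005)
  expect_equal(length(res2$labels), 990L)
  expect_setequal(cellIds(res2$labels), paste0("c", 6:995))
})

test_that("qc filter: constant covariates remove nothing; tail = 0 is identity", {
  n <- 50
  counts <- toyMatrix(matrix(1, 2, n), cols = paste0("c", 1:n))
  lab <- CellLabelTable(paste0("c", 1:n), rep("s1", n), rep("A", n),
                        mitoFraction = rep(0.05, n), riboFraction = rep(0.05, n))
  expect_equal(length(qcFilterCells(counts, lab)$labels), n)
  lab2 <- CellLabelTable(paste0("c", 1:n), rep("s1", n), rep("A", n),
                         mitoFraction = (1:n) / (n + 1), riboFraction = (1:n) / (n + 1))
  expect_equal(length(qcFilterCells(counts, lab2, tail = 0)$labels), n)
})

test_that("qc filter derives fractions from gene-name prefixes when absent", {
  v <- rbind("MT-CO1" = c(rep(0, 99), 90), "RPS1" = rep(1, 100),
             "ACTB" = rep(9, 100))
  counts <- toyMatrix(v, genes = rownames(v), cols = paste0("c", 1:100))
  lab <- CellLabelTable(paste0("c", 1:100), rep("s1", 100), rep("A", 100))
  res <- qcFilterCells(counts, lab, tail = 0.005)
  expect_false("c100" %in% cellIds(res$labels))  # extreme mito cell dropped
})

# detectable genes ----------------------------------------------------------

test_that("detectable-gene rule: >=10 cells OR >=1% of a cluster's cells", {
  nBig <- 5000; nSmall <- 200
  expr <- matrix(0, 3, nBig + nSmall,
                 dimnames = list(c("tenCells", "threeOfSmall", "fiveOfBig"),
                                 paste0("c", 1:(nBig + nSmall))))
  expr["tenCells", 1:10] <- 1              # 10 cells of the 5000-cell cluster
  expr["threeOfSmall", nBig + (1:3)] <- 1  # 3 >= 1% of 200
  expr["fiveOfBig", 1:5] <- 1              # 5 < 10 and 5 < 50
  lab <- CellLabelTable(colnames(expr), rep("s1", ncol(expr)),
                        rep(c("big", "small"), c(nBig, nSmall)))
  kept <- geneIds(filterDetectableGenes(ExpressionMatrix(expr), lab))
  expect_setequal(kept, c("tenCells", "threeOfSmall"))
})

test_that("detectable-gene filter is monotone in added expressing cells", {
  set.seed(3)
  n <- 400
  expr <- matrix(rbinom(20 * n, 1, 0.02), 20, n,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:n)))
  lab <- CellLabelTable(paste0("c", 1:n), rep("s1", n),
                        rep(c("A", "B"), each = n / 2))
  kept1 <- geneIds(filterDetectableGenes(ExpressionMatrix(expr), lab))
  expr2 <- expr
  expr2[, 1:50] <- 1  # add expressing cells to cluster A
  kept2 <- geneIds(filterDetectableGenes(ExpressionMatrix(expr2), lab))
  expect_true(all(kept1 %in% kept2))
})

# normalization -------------------------------------------------------------

test_that("normalization methods match their definitions", {
  m <- toyMatrix(matrix(c(10, 10), 2, 1))
  tpm <- normalizeExpression(m, "TPM", geneLengths = c(g1 = 1000, g2 = 2000))
  expect_equal(exprValues(tpm)[, 1], c(g1 = 666666.67, g2 = 333333.33),
               tolerance = 1e-2 / 666666)
  expect_equal(unitTag(tpm), "TPM")

  # TPM columns sum to 1e6 within 1e-6 relative
  set.seed(5)
  big <- toyMatrix(matrix(rpois(300, 20), 30, 10))
  lens <- setNames(runif(30, 200, 5000), paste0("g", 1:30))
  expect_equal(colSums(exprValues(normalizeExpression(big, "TPM", lens))),
               setNames(rep(1e6, 10), paste0("s", 1:10)), tolerance = 1e-6)

  # TMM of identical columns = CPM
  two <- toyMatrix(matrix(c(5, 20, 75, 5, 20, 75), 3, 2))
  tmm <- normalizeExpression(two, "TMM")
  cpm <- exprValues(two) / 100 * 1e6
  expect_equal(exprValues(tmm), cpm)

  # LogNormalize of 0 is exactly 0; natural log of 1 + 1e4 * fraction
  ln <- normalizeExpression(toyMatrix(matrix(c(0, 100), 2, 1)), "LogNormalize")
  expect_identical(exprValues(ln)["g1", 1], 0)
  expect_equal(exprValues(ln)["g2", 1], log(1 + 1e4))

  # none is the identity
  expect_identical(exprValues(normalizeExpression(two, "none")), exprValues(two))
  expect_error(normalizeExpression(toyMatrix(matrix(c(0, 0, 1, 1), 2)), "TMM"),
               "s1")
})

# cluster profiles and gold standard ----------------------------------------

test_that("cluster profiles are per-cluster means", {
  m <- toyMatrix(matrix(c(2, 0, 4, 0, 1, 1), 2, 3), cols = paste0("c", 1:3))
  lab <- CellLabelTable(paste0("c", 1:3), rep("s1", 3), c("A", "A", "B"))
  ref <- clusterProfiles(m, lab)
  expect_equal(exprValues(profiles(ref))[, "A"], c(g1 = 3, g2 = 0))
  expect_equal(exprValues(profiles(ref))[, "B"], c(g1 = 1, g2 = 1))
  expect_equal(cellCounts(ref), c(A = 2, B = 1))

  # random case against a brute-force group-by mean
  set.seed(9)
  v <- matrix(rpois(50 * 30, 4), 50, 30,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:30)))
  cl <- sample(c("A", "B", "C"), 30, replace = TRUE)
  lab2 <- CellLabelTable(colnames(v), rep("s1", 30), cl)
  ref2 <- clusterProfiles(ExpressionMatrix(v), lab2)
  for (k in c("A", "B", "C"))
    expect_lt(max(abs(exprValues(profiles(ref2))[, k] -
                      rowMeans(v[, cl == k, drop = FALSE]))), 1e-12)
})

test_that("gold standard counts cluster fractions per sample", {
  lab <- CellLabelTable(paste0("c", 1:6), rep("s1", 6),
                        c("A", "A", "B", "B", "B", "B"))
  gs <- goldStandardFromClusters(lab)
  expect_equal(compValues(gs)["s1", ], c(A = 1 / 3, B = 2 / 3))
  expect_equal(sum(compValues(gs)), 1)

  one <- goldStandardFromClusters(CellLabelTable("c1", "s1", "A"))
  expect_equal(compValues(one)["s1", "A"], 1)

  # multinomial concentration: 10,000 cells, 6 types
  set.seed(21)
  p <- c(0.3, 0.25, 0.2, 0.13, 0.10, 0.02)
  cl <- sample(paste0("t", 1:6), 1e4, replace = TRUE, prob = p)
  big <- goldStandardFromClusters(CellLabelTable(paste0("c", 1:1e4),
                                                 rep("s1", 1e4), cl))
  expect_lt(max(abs(compValues(big)[1, paste0("t", 1:6)] - p)), 0.02)
  expect_equal(rowSums(compValues(big)), c(s1 = 1))
})

# markers -------------------------------------------------------------------

test_that("marker calling combines fold-change and rank-sum evidence", {
  n <- 200
  v <- matrix(1, 3, n, dimnames = list(c("mk", "flat", "weak"), paste0("c", 1:n)))
  inA <- 1:50
  v["mk", inA] <- 8                 # lfc = log2(9/2) ~ 2.17 with pc = 1
  v["weak", inA] <- 1.2             # lfc below log2(1.5)
  lab <- CellLabelTable(paste0("c", 1:n), rep("s1", n),
                        rep(c("A", "B"), c(50, 150)))
  mk <- findMarkers(ExpressionMatrix(v, unitTag = "TMM"), lab)
  expect_equal(mk$A, "mk")
  expect_false("flat" %in% unlist(mk))     # identical distribution, not a marker
  empty <- findMarkers(ExpressionMatrix(v, unitTag = "TMM"), lab,
                       lfcThreshold = Inf)
  expect_true(all(lengths(empty) == 0))
  expect_error(findMarkers(ExpressionMatrix(v, unitTag = "counts"), lab), "TMM")
})

# cluster merging ------------------------------------------------------------

test_that("cluster merging respects the correlation threshold", {
  set.seed(2)
  a <- rlnorm(100)
  profIdent <- cbind(A = a, B = a)
  rownames(profIdent) <- paste0("g", 1:100)
  refI <- ClusterReference(ExpressionMatrix(profIdent, "lognorm"),
                           c(A = 10, B = 30))
  resI <- mergeSimilarClusters(refI)
  expect_equal(ncol(exprValues(profiles(resI$reference))), 1L)
  expect_equal(sum(cellCounts(resI$reference)), 40)
  expect_equal(nrow(resI$mergeLog), 1L)

  prof90 <- correlatedProfiles(matrix(c(1, 0.90, 0.90, 1), 2), seed = 3)
  expect_equal(cor(prof90)[1, 2], 0.90, tolerance = 1e-12)
  ref90 <- ClusterReference(ExpressionMatrix(prof90, "lognorm"),
                            c(A = 5, B = 5))
  res90 <- mergeSimilarClusters(ref90)
  expect_equal(ncol(exprValues(profiles(res90$reference))), 2L)
  expect_equal(nrow(res90$mergeLog), 0L)
})

test_that("greedy merging follows descending correlation and recomputes", {
  cm <- matrix(c(1, 0.99, 0.92, 0.99, 1, 0.96, 0.92, 0.96, 1), 3)
  prof <- correlatedProfiles(cm, seed = 8)
  ref <- ClusterReference(ExpressionMatrix(prof, "lognorm"),
                          c(A = 10, B = 10, C = 10))
  res <- mergeSimilarClusters(ref)
  lg <- res$mergeLog
  # first merge is the highest pair {A, B}
  expect_equal(sort(c(lg$cluster_a[1], lg$cluster_b[1])), c("A", "B"))
  expect_equal(lg$r[1], 0.99, tolerance = 1e-9)
  # C joins only if its recomputed correlation with the merged profile >= 0.95
  mergedAB <- (prof[, "A"] * 10 + prof[, "B"] * 10) / 20
  shouldMergeC <- cor(mergedAB, prof[, "C"]) >= 0.95
  expect_equal(ncol(exprValues(profiles(res$reference))),
               if (shouldMergeC) 1L else 2L)
  # total cell count conserved; iterations bounded by initial clusters - 1
  expect_equal(sum(cellCounts(res$reference)), 30)
  expect_lte(max(lg$iteration), 2L)
})
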