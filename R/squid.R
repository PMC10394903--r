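# SQUID: per-gene linear transformation of bulk RNA-seq profiles into
# single-cell measurement space, fitted on concurrent pseudobulk profiles,
# followed by dampened weighted least-squares deconvolution over all genes
# with nonzero expression in both spaces.

#' Per-sample pseudobulk profiles from single-cell counts
#'
#' For each sample, the arithmetic mean expression across that sample's
#' cells, giving one pseudobulk column per sample.
#'
#' @param scCounts genes x cells \linkS4class{ExpressionMatrix}.
#' @param labels \linkS4class{CellLabelTable} aligned with the columns.
#' @return genes x samples \linkS4class{ExpressionMatrix}.
#' @export
makePseudobulk <- function(scCounts, labels) {
  stopifnot(identical(labels@cellId, colnames(scCounts@values)))
  ss <- labels@sampleId
  ids <- unique(ss)
  n <- table(ss)[ids]
  if (any(n == 0)) stopf("sample(s) with no cells: %s",
                         paste(ids[n == 0], collapse = ", "))
  pb <- vapply(ids, function(s)
    Matrix::rowSums(scCounts@values[, ss == s, drop = FALSE]) / sum(ss == s),
    numeric(nrow(scCounts@values)))
  pb <- matrix(pb, nrow(scCounts@values), length(ids),
               dimnames = list(rownames(scCounts@values), ids))
  ExpressionMatrix(pb, unitTag = "arbitrary")
}

# genes with nonzero total expression in both the bulk matrix and the
# single-cell counts (dataset-wide rule used for transform fitting)
transformGeneUniverse <- function(bulk, pseudobulk) {
  genes <- sharedGenes(rownames(bulk@values), rownames(pseudobulk@values))
  bt <- rowSums(asDense(bulk@values)[genes, , drop = FALSE])
  pt <- rowSums(asDense(pseudobulk@values)[genes, , drop = FALSE])
  genes[bt != 0 & pt != 0]
}

#' Fit the per-gene bulk-to-single-cell transform
#'
#' For every gene with nonzero expression in both the bulk and single-cell
#' profiles, fits the linear map from bulk to pseudobulk across the aligned
#' samples. Mode \code{"eq2"} is a per-gene simple linear regression of
#' pseudobulk on bulk: a_g = cov(z_g, zhat_g) / var(z_g), b_g = mean(zhat_g)
#' - a_g * mean(z_g); genes with zero bulk variance fall back to a_g = 0,
#' b_g = mean(zhat_g). Mode \code{"eq3"} stores the per-gene means and
#' standard deviations of both spaces for the standardized mapping
#' z -> mean(zhat_g) + (sd(zhat_g)/sd(z_g)) (z - mean(z_g)), which does not
#' require concurrent profiling; genes with zero bulk sd are excluded.
#'
#' @param ds a \linkS4class{ConcurrentDataset} with >= 2 aligned samples.
#' @param mode \code{"eq2"} (default) or \code{"eq3"}.
#' @return a \linkS4class{TransformModel}.
#' @export
fitGeneTransform <- function(ds, mode = c("eq2", "eq3")) {
  mode <- match.arg(mode)
  if (ncol(ds@bulk@values) < 2)
    stopf("the transform fit needs >= 2 aligned samples")
  genes <- transformGeneUniverse(ds@bulk, ds@pseudobulk)
  if (!length(genes)) stopf("no genes with nonzero expression in both spaces")
  Z <- asDense(ds@bulk@values)[genes, , drop = FALSE]
  Zh <- asDense(ds@pseudobulk@values)[genes, , drop = FALSE]
  mz <- rowMeans(Z); mzh <- rowMeans(Zh)
  if (mode == "eq2") {
    vz <- rowSums((Z - mz)^2)
    cv <- rowSums((Z - mz) * (Zh - mzh))
    a <- ifelse(vz > 0, cv / vz, 0)
    b <- mzh - a * mz
    cf <- data.frame(a = a, b = b, row.names = genes)
  } else {
    n <- ncol(Z)
    sz <- sqrt(rowSums((Z - mz)^2) / (n - 1))
    szh <- sqrt(rowSums((Zh - mzh)^2) / (n - 1))
    ok <- sz > 0
    cf <- data.frame(meanPseudobulk = mzh[ok], meanBulk = mz[ok],
                     sdPseudobulk = szh[ok], sdBulk = sz[ok],
                     row.names = genes[ok])
    if (!nrow(cf)) stopf("no genes with positive bulk sd for the eq3 transform")
  }
  new("TransformModel", mode = mode, coefficients = cf)
}

#' Transform bulk profiles into single-cell space
#'
#' Applies a fitted \linkS4class{TransformModel} gene-wise to a bulk matrix.
#' Genes outside the model's gene universe are dropped; the output carries
#' unit tag "arbitrary" because transformed values may be negative.
#'
#' @param model a \linkS4class{TransformModel}.
#' @param bulk genes x samples \linkS4class{ExpressionMatrix}; must contain
#'   every modeled gene.
#' @return transformed \linkS4class{ExpressionMatrix} on the model's gene
#'   universe.
#' @export
transformBulk <- function(model, bulk) {
  genes <- rownames(model@coefficients)
  missing <- setdiff(genes, rownames(bulk@values))
  if (length(missing))
    stopf("bulk matrix lacks %d modeled gene(s), e.g. %s", length(missing),
          missing[1])
  Z <- asDense(bulk@values)[genes, , drop = FALSE]
  cf <- model@coefficients
  out <- if (model@mode == "eq2") {
    Z * cf$a + cf$b
  } else {
    if (any(cf$sdBulk == 0)) stopf("eq3 transform with zero bulk sd")
    cf$meanPseudobulk + (cf$sdPseudobulk / cf$sdBulk) * (Z - cf$meanBulk)
  }
  dimnames(out) <- dimnames(Z)
  ExpressionMatrix(out, unitTag = "arbitrary")
}

#' Deconvolve one transformed bulk profile
#'
#' Restricts to genes with nonzero values in both the transformed column and
#' the reference (row sums), then runs dampened weighted least squares on
#' that universe. No signature gene selection is performed: all shared
#' nonzero genes are used.
#'
#' @param transformedCol named numeric vector: one transformed bulk column.
#' @param ref \linkS4class{ClusterReference} on the raw single-cell scale.
#' @param spec \linkS4class{SolverSpec} for the dampened solver.
#' @return list as returned by \code{\link{solveDWLS}}.
#' @export
squidDeconvolve <- function(transformedCol, ref, spec = SolverSpec()) {
  prof <- asDense(ref@profiles@values)
  genes <- sharedGenes(rownames(prof), names(transformedCol))
  rs <- rowSums(prof[genes, , drop = FALSE])
  genes <- genes[transformedCol[genes] != 0 & rs != 0]
  if (length(genes) < ncol(prof))
    stopf("shared nonzero gene universe (%d genes) smaller than the number of cell types (%d)",
          length(genes), ncol(prof))
  subref <- ClusterReference(
    ExpressionMatrix(prof[genes, , drop = FALSE], ref@profiles@unitTag),
    cellCounts = ref@cellCounts)
  solveDWLS(transformedCol[genes], subref, spec)
}

# cluster reference on the raw single-cell scale from a subset of samples
referenceFromSamples <- function(scCounts, labels, samples) {
  keep <- labels@sampleId %in% samples
  clusterProfiles(
    ExpressionMatrix(scCounts@values[, keep, drop = FALSE], scCounts@unitTag),
    labels[keep])
}

#' SQUID with leave-one-out cross-validation
#'
#' For each held-out sample: the transform model is fitted on the concurrent
#' profiles of all other samples, the cluster reference and pseudobulk are
#' rebuilt from those samples' single-cell data only, the held-out sample's
#' bulk column is transformed, and its composition estimated with dampened
#' weighted least squares. The held-out sample's single-cell data are never
#' read by its own fold.
#'
#' @param ds a \linkS4class{ConcurrentDataset} with >= 3 aligned samples.
#' @param spec \linkS4class{SolverSpec}.
#' @param mode transform mode, \code{"eq2"} (default) or \code{"eq3"}.
#' @return a \linkS4class{CompositionMatrix} (kind "estimate"), rows in input
#'   sample order; metadata holds per-fold iteration counts and the fold log.
#' @export
looCrossValidate <- function(ds, spec = SolverSpec(), mode = c("eq2", "eq3")) {
  mode <- match.arg(mode)
  samples <- colnames(ds@bulk@values)
  if (length(samples) < 3) stopf("leave-one-out needs >= 3 aligned samples")
  rows <- list()
  iters <- setNames(rep(NA_real_, length(samples)), samples)
  foldLog <- data.frame(sample = samples, n_train = NA_integer_,
                        n_genes_model = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    s <- samples[i]
    train <- setdiff(samples, s)
    if (length(train) < 2) stopf("fold %s has < 2 training samples", s)
    keep <- ds@scLabels@sampleId %in% train
    scTrain <- ExpressionMatrix(ds@scCounts@values[, keep, drop = FALSE],
                                ds@scCounts@unitTag)
    labTrain <- ds@scLabels[keep]
    bulkTrain <- ExpressionMatrix(
      ds@bulk@values[, train, drop = FALSE], ds@bulk@unitTag)
    foldDs <- ConcurrentDataset(bulkTrain, scTrain, labTrain)
    model <- fitGeneTransform(foldDs, mode = mode)
    ref <- clusterProfiles(scTrain, labTrain)
    heldBulk <- ExpressionMatrix(ds@bulk@values[, s, drop = FALSE],
                                 ds@bulk@unitTag)
    tx <- transformBulk(model, heldBulk)
    col <- setNames(asDense(tx@values)[, 1], rownames(tx@values))
    res <- squidDeconvolve(col, ref, spec)
    rows[[s]] <- res$proportions
    iters[s] <- res$iterations
    foldLog$n_train[i] <- length(train)
    foldLog$n_genes_model[i] <- nrow(model@coefficients)
  }
  types <- sort(unique(unlist(lapply(rows, names))))
  est <- t(vapply(rows, function(r) r[types], numeric(length(types))))
  dimnames(est) <- list(samples, types)
  CompositionMatrix(est, kind = "estimate",
    metadata = list(method = "SQUID", mode = mode, iterations = iters,
                    foldLog = foldLog))
}

#' SQUID without cross-validation
#'
#' Fits the transform on all concurrent samples, transforms every bulk
#' column, and deconvolves each against the full-data cluster reference.
#'
#' @inheritParams looCrossValidate
#' @return a \linkS4class{CompositionMatrix} (kind "estimate").
#' @export
squidDeconvolveMatrix <- function(ds, spec = SolverSpec(), mode = c("eq2", "eq3")) {
  mode <- match.arg(mode)
  model <- fitGeneTransform(ds, mode = mode)
  ref <- clusterProfiles(ds@scCounts, ds@scLabels)
  tx <- transformBulk(model, ds@bulk)
  v <- asDense(tx@values)
  rows <- lapply(seq_len(ncol(v)), function(i)
    squidDeconvolve(setNames(v[, i], rownames(v)), ref, spec))
  types <- names(rows[[1]]$proportions)
  est <- t(vapply(rows, function(r) r$proportions[types], numeric(length(types))))
  dimnames(est) <- list(colnames(v), types)
  CompositionMatrix(est, kind = "estimate",
    metadata = list(method = "SQUID", mode = mode,
                    iterations = vapply(rows, `[[`, numeric(1), "iterations")))
}
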