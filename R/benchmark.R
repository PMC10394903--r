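#' Evaluate a composition estimate against a gold standard
#'
#' Aligns the two matrices on their shared samples and cell types (by id,
#' order-independent; unmatched cell types are dropped with a message),
#' flattens the aligned entries into paired vectors, and reports the Pearson
#' correlation and the root mean squared error over all pairs, plus a
#' per-cell-type breakdown. If either flattened vector has zero variance the
#' correlation is reported as NA with a reason; the RMSE is still computed.
#'
#' @param est \linkS4class{CompositionMatrix} of estimates.
#' @param gold gold-standard \linkS4class{CompositionMatrix}.
#' @param method,bulkNormalization,referenceNormalization labels recorded on
#'   the result.
#' @return a \linkS4class{BenchmarkResult}.
#' @export
evaluateComposition <- function(est, gold, method = "",
                                bulkNormalization = "none",
                                referenceNormalization = "none") {
  ss <- intersect(rownames(est@values), rownames(gold@values))
  tt <- intersect(colnames(est@values), colnames(gold@values))
  if (!length(ss) || !length(tt))
    stopf("no shared samples or cell types between estimate and gold standard")
  dropped <- length(union(colnames(est@values), colnames(gold@values))) - length(tt)
  if (dropped > 0)
    message(sprintf("evaluate: dropped %d cell type(s) absent from one side", dropped))
  e <- est@values[ss, tt, drop = FALSE]
  g <- gold@values[ss, tt, drop = FALSE]
  ok <- is.finite(e) & is.finite(g)
  if (mean(ok) < 0.95)
    warnf("more than 5%% of points are missing and excluded pairwise")
  ev <- e[ok]; gv <- g[ok]
  reason <- ""
  if (var(ev) == 0 || var(gv) == 0) {
    r <- NA_real_
    reason <- "zero variance in flattened estimates or gold standard"
  } else r <- cor(ev, gv)
  rmse <- sqrt(mean((ev - gv)^2))
  per <- do.call(rbind, lapply(tt, function(ct) {
    oki <- ok[, ct]
    ei <- e[oki, ct]; gi <- g[oki, ct]
    data.frame(celltype = ct,
               pearson_r = if (length(ei) > 1 && var(ei) > 0 && var(gi) > 0)
                 cor(ei, gi) else NA_real_,
               rmse = sqrt(mean((ei - gi)^2)), n = sum(oki),
               stringsAsFactors = FALSE)
  }))
  new("BenchmarkResult", method = method,
      bulkNormalization = bulkNormalization,
      referenceNormalization = referenceNormalization,
      pearsonR = r, rmse = rmse, nPoints = sum(ok), perCelltype = per,
      reason = reason)
}

#' Coerce a BenchmarkResult (or list of them) to a data.frame row
#'
#' @param x a \linkS4class{BenchmarkResult}.
#' @param row.names,optional,... ignored.
#' @return one-row data.frame: method, bulk_norm, ref_norm, pearson_r, rmse,
#'   n_points.
#' @export
as.data.frame.BenchmarkResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(method = x@method, bulk_norm = x@bulkNormalization,
             ref_norm = x@referenceNormalization, pearson_r = x@pearsonR,
             rmse = x@rmse, n_points = x@nPoints, stringsAsFactors = FALSE)
}

#' Run the method-by-normalization benchmark grid
#'
#' Evaluates the Cartesian product of deconvolution methods, bulk
#' normalizations and reference normalizations on a concurrent dataset
#' against a gold standard. SQUID rows use leave-one-out cross-validation;
#' all other methods deconvolve each bulk column against the (optionally
#' normalized) cluster reference. Individual cell failures are recorded and
#' the grid continues. Externally produced composition tables (read with
#' \code{\link{readComposition}}) can be appended via \code{external}.
#'
#' @param ds a \linkS4class{ConcurrentDataset}.
#' @param gold gold-standard \linkS4class{CompositionMatrix}.
#' @param methods character vector from \{"OLS","NNLS","RLR","DWLS","SQUID"\}.
#' @param bulkNorms,refNorms normalization names accepted by
#'   \code{\link{normalizeExpression}}.
#' @param spec \linkS4class{SolverSpec} used for DWLS/SQUID.
#' @param geneLengths named vector, required when "TPM" appears in a grid.
#' @param external optional named list of \linkS4class{CompositionMatrix}
#'   estimates from external tools; each is evaluated as one extra row.
#' @return long-format data.frame: method, bulk_norm, ref_norm, pearson_r,
#'   rmse, n_points, error (NA on success).
#' @export
runGrid <- function(ds, gold, methods = c("OLS", "NNLS", "RLR", "DWLS", "SQUID"),
                    bulkNorms = "none", refNorms = "none",
                    spec = SolverSpec(), geneLengths = NULL,
                    external = list()) {
  rows <- list()
  rawRef <- clusterProfiles(ds@scCounts, ds@scLabels)
  for (m in methods) for (bn in bulkNorms) for (rn in refNorms) {
    row <- tryCatch({
      bulk <- normalizeExpression(ds@bulk, bn, geneLengths = geneLengths)
      if (m == "SQUID") {
        dsn <- new("ConcurrentDataset", bulk = bulk, scCounts = ds@scCounts,
                   scLabels = ds@scLabels, pseudobulk = ds@pseudobulk)
        est <- looCrossValidate(dsn, spec)
      } else {
        prof <- normalizeExpression(rawRef@profiles, rn, geneLengths = geneLengths)
        ref <- ClusterReference(prof, cellCounts = rawRef@cellCounts)
        est <- deconvolveMatrix(bulk, ref, SolverSpec(method = m,
          epsilon = spec@epsilon, maxIterations = spec@maxIterations,
          dampingGrid = spec@dampingGrid, nSubsamples = spec@nSubsamples,
          seed = spec@seed))
      }
      res <- evaluateComposition(est, gold, method = m,
                                 bulkNormalization = bn,
                                 referenceNormalization = rn)
      cbind(as.data.frame(res), error = NA_character_)
    }, error = function(e)
      data.frame(method = m, bulk_norm = bn, ref_norm = rn,
                 pearson_r = NA_real_, rmse = NA_real_, n_points = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- row
  }
  for (nm in names(external)) {
    row <- tryCatch(
      cbind(as.data.frame(evaluateComposition(external[[nm]], gold, method = nm,
        bulkNormalization = "external", referenceNormalization = "external")),
        error = NA_character_),
      error = function(e)
        data.frame(method = nm, bulk_norm = "external", ref_norm = "external",
                   pearson_r = NA_real_, rmse = NA_real_, n_points = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
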