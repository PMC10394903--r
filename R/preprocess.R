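#' Quality-control filter on cells by mitochondrial/ribosomal content
#'
#' Removes cells whose mitochondrial or ribosomal content fraction is extreme:
#' the union of cells strictly below the \code{tail} quantile or strictly
#' above the \code{1 - tail} quantile of either covariate, with quantiles
#' computed jointly over all cells. The strict inequality means a constant
#' covariate removes nothing. Missing fractions are derived from gene-name
#' prefixes ("MT-"/"mt-" for mitochondrial, "RPS"/"RPL" for ribosomal genes,
#' configurable).
#'
#' @param sc genes x cells \linkS4class{ExpressionMatrix} of counts.
#' @param labels \linkS4class{CellLabelTable} aligned with \code{sc} columns.
#' @param tail tail mass removed on each side of each covariate
#'   (default 0.005, i.e. top 0.5\% and bottom 0.5\%).
#' @param mitoPrefixes,riboPrefixes gene-name prefixes used when fractions
#'   are absent from \code{labels}.
#' @return list with elements \code{counts} (filtered ExpressionMatrix) and
#'   \code{labels} (filtered CellLabelTable).
#' @export
qcFilterCells <- function(sc, labels, tail = 0.005,
                          mitoPrefixes = c("MT-", "mt-"),
                          riboPrefixes = c("RPS", "RPL", "Rps", "Rpl")) {
  stopifnot(is(sc, "ExpressionMatrix"), is(labels, "CellLabelTable"))
  if (!identical(labels@cellId, colnames(sc@values)))
    stopf("label table cells must align with matrix columns")
  mito <- labels@mitoFraction
  ribo <- labels@riboFraction
  if (anyNA(mito)) mito <- prefixFraction(sc, mitoPrefixes)
  if (anyNA(ribo)) ribo <- prefixFraction(sc, riboPrefixes)
  keep <- rep(TRUE, length(labels))
  if (tail > 0) {
    for (f in list(mito, ribo)) {
      lo <- quantile(f, tail, names = FALSE)
      hi <- quantile(f, 1 - tail, names = FALSE)
      keep <- keep & f >= lo & f <= hi
    }
  }
  if (sum(keep) < 10)
    stopf("fewer than 10 cells remain after QC (%d)", sum(keep))
  list(counts = ExpressionMatrix(sc@values[, keep, drop = FALSE], sc@unitTag),
       labels = labels[keep])
}

# fraction of each cell's counts carried by genes whose name starts with one
# of the given prefixes
prefixFraction <- function(sc, prefixes) {
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")")
  hit <- grepl(pat, rownames(sc@values))
  tot <- Matrix::colSums(sc@values)
  sub <- if (any(hit)) Matrix::colSums(sc@values[hit, , drop = FALSE]) else 0
  ifelse(tot > 0, sub / tot, 0)
}

#' Keep detectable genes
#'
#' A gene is retained iff, in at least one cluster, it has nonzero counts in
#' at least 10 cells or at least 1\% of that cluster's cells (logical OR).
#'
#' @param sc genes x cells \linkS4class{ExpressionMatrix}.
#' @param labels \linkS4class{CellLabelTable} with cluster assignments.
#' @param minCells the absolute arm of the rule (default 10).
#' @param minFraction the relative arm of the rule (default 0.01).
#' @return filtered \linkS4class{ExpressionMatrix}.
#' @export
filterDetectableGenes <- function(sc, labels, minCells = 10, minFraction = 0.01) {
  stopifnot(identical(labels@cellId, colnames(sc@values)))
  cl <- labels@clusterId
  keep <- rep(FALSE, nrow(sc@values))
  for (k in unique(cl)) {
    idx <- which(cl == k)
    nExpr <- Matrix::rowSums(sc@values[, idx, drop = FALSE] > 0)
    keep <- keep | (nExpr >= minCells) | (nExpr >= minFraction * length(idx))
  }
  if (!any(keep)) stopf("no detectable genes remain after filtering")
  ExpressionMatrix(sc@values[keep, , drop = FALSE], sc@unitTag)
}

#' Normalize an expression matrix
#'
#' @param mat \linkS4class{ExpressionMatrix} of counts (for TPM/TMM) or any
#'   non-negative values.
#' @param method \code{"none"} (identity), \code{"TPM"} (gene-length rate,
#'   columns rescaled to sum 1e6), \code{"TMM"} (trimmed mean of M-values
#'   scaling factors; output is counts-per-million divided by the factor), or
#'   \code{"LogNormalize"} (natural log of 1 + scaleFactor * count / column
#'   sum).
#' @param geneLengths named vector covering all genes; required for TPM.
#' @param scaleFactor LogNormalize scale factor (default 1e4).
#' @return normalized \linkS4class{ExpressionMatrix} with the matching unit
#'   tag.
#' @export
normalizeExpression <- function(mat, method = c("none", "TPM", "TMM", "LogNormalize"),
                                geneLengths = NULL, scaleFactor = 1e4) {
  method <- match.arg(method)
  v <- mat@values
  if (method == "none") return(mat)
  cs <- Matrix::colSums(v)
  if (any(cs == 0))
    stopf("zero column sum for column(s): %s",
          paste(colnames(v)[cs == 0], collapse = ", "))
  if (method == "TPM") {
    if (is.null(geneLengths)) stopf("TPM requires gene lengths")
    len <- geneLengths[rownames(v)]
    if (anyNA(len)) stopf("gene lengths missing for some genes")
    rate <- asDense(v) / len
    out <- sweep(rate, 2, colSums(rate), "/") * 1e6
    return(ExpressionMatrix(out, "TPM"))
  }
  if (method == "TMM") {
    f <- edgeR::calcNormFactors(asDense(v), method = "TMM")
    out <- sweep(asDense(v), 2, cs * f / 1e6, "/")
    return(ExpressionMatrix(out, "TMM"))
  }
  # LogNormalize
  out <- log1p(asDense(sweep(v, 2, cs, "/")) * scaleFactor)
  ExpressionMatrix(out, "lognorm")
}

#' Cluster-mean expression profiles
#'
#' Averages gene expression across all cells of each cluster (arithmetic
#' mean, on whatever scale the input is on — raw counts by default), giving
#' the genes x clusters reference used for deconvolution.
#'
#' @param sc genes x cells \linkS4class{ExpressionMatrix}.
#' @param labels \linkS4class{CellLabelTable}.
#' @return a \linkS4class{ClusterReference}.
#' @export
clusterProfiles <- function(sc, labels) {
  stopifnot(identical(labels@cellId, colnames(sc@values)))
  cl <- labels@clusterId
  ids <- unique(cl)
  n <- table(cl)[ids]
  empty <- ids[n == 0]
  if (length(empty)) {
    warnf("dropping empty cluster(s): %s", paste(empty, collapse = ", "))
    ids <- setdiff(ids, empty)
  }
  prof <- vapply(ids, function(k)
    Matrix::rowSums(sc@values[, cl == k, drop = FALSE]) / sum(cl == k),
    numeric(nrow(sc@values)))
  prof <- matrix(prof, nrow(sc@values), length(ids),
                 dimnames = list(rownames(sc@values), ids))
  ClusterReference(ExpressionMatrix(prof, sc@unitTag),
                   cellCounts = setNames(as.numeric(table(cl)[ids]), ids))
}

#' Gold-standard composition from cluster cell counts
#'
#' For each sample, the fraction of its cells assigned to each cluster.
#' Counts are integers, so rows sum to one exactly.
#'
#' @param labels \linkS4class{CellLabelTable}.
#' @return a gold-standard \linkS4class{CompositionMatrix}.
#' @export
goldStandardFromClusters <- function(labels) {
  tab <- table(labels@sampleId, labels@clusterId)
  ns <- rowSums(tab)
  if (any(ns == 0)) {
    warnf("dropping sample(s) with no cells: %s",
          paste(rownames(tab)[ns == 0], collapse = ", "))
    tab <- tab[ns > 0, , drop = FALSE]
    ns <- ns[ns > 0]
  }
  v <- sweep(unclass(tab), 1, ns, "/")
  CompositionMatrix(v, kind = "gold_standard")
}

#' One-vs-rest marker genes by Wilcoxon rank-sum test
#'
#' For each cluster, tests every gene against all other cells with a
#' two-sided Wilcoxon rank-sum test on TMM-normalized expression. A gene is a
#' marker iff log2((mean_in + pc) / (mean_out + pc)) >= lfcThreshold and its
#' Benjamini-Hochberg adjusted p-value is <= alpha. Markers are ordered by
#' descending fold-change.
#'
#' @param sc TMM-normalized \linkS4class{ExpressionMatrix} (asserted via the
#'   unit tag).
#' @param labels \linkS4class{CellLabelTable}.
#' @param lfcThreshold log2 fold-change threshold (default log2(1.5)).
#' @param alpha BH-adjusted p-value cutoff (default 0.05).
#' @param pseudocount added to both means before the ratio (default 1).
#' @return named list: cluster id -> character vector of marker genes.
#' @export
findMarkers <- function(sc, labels, lfcThreshold = log2(1.5), alpha = 0.05,
                        pseudocount = 1) {
  if (sc@unitTag != "TMM")
    stopf("findMarkers expects TMM-normalized input (unit tag is '%s')", sc@unitTag)
  stopifnot(identical(labels@cellId, colnames(sc@values)))
  v <- asDense(sc@values)
  cl <- labels@clusterId
  out <- list()
  for (k in unique(cl)) {
    inK <- cl == k
    if (sum(inK) < 3) {
      warnf("cluster %s has < 3 cells; excluded from marker calling", k)
      next
    }
    mIn <- rowMeans(v[, inK, drop = FALSE])
    mOut <- rowMeans(v[, !inK, drop = FALSE])
    lfc <- log2((mIn + pseudocount) / (mOut + pseudocount))
    cand <- which(lfc >= lfcThreshold)
    if (is.infinite(lfcThreshold)) cand <- integer(0)
    if (!length(cand)) { out[[k]] <- character(0); next }
    p <- vapply(cand, function(g)
      suppressWarnings(wilcox.test(v[g, inK], v[g, !inK], exact = FALSE)$p.value),
      numeric(1))
    padj <- p.adjust(p, method = "BH")
    sel <- cand[!is.na(padj) & padj <= alpha]
    out[[k]] <- rownames(v)[sel][order(lfc[sel], decreasing = TRUE)]
  }
  out
}

#' Merge highly correlated clusters
#'
#' Iteratively merges clusters whose mean profiles are nearly identical:
#' at each pass, all pairwise Pearson correlations between cluster profiles
#' are computed, a maximal set of non-overlapping pairs with r >= rMin is
#' selected greedily in descending correlation order (exact ties broken by
#' lexicographic cluster-id order), each selected pair is merged into a
#' cell-count-weighted mean profile with summed counts, and the procedure
#' repeats until no pair qualifies. Intended for profiles computed on
#' log-transformed, library-size-normalized data.
#'
#' @param ref a \linkS4class{ClusterReference} with >= 2 clusters.
#' @param rMin Pearson correlation threshold for merging (default 0.95).
#' @return list with \code{reference} (merged \linkS4class{ClusterReference})
#'   and \code{mergeLog} (data.frame: iteration, cluster_a, cluster_b, r,
#'   new_id).
#' @export
mergeSimilarClusters <- function(ref, rMin = 0.95) {
  prof <- asDense(ref@profiles@values)
  counts <- ref@cellCounts[colnames(prof)]
  log <- data.frame(iteration = integer(0), cluster_a = character(0),
                    cluster_b = character(0), r = numeric(0),
                    new_id = character(0), stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    if (ncol(prof) < 2) break
    iter <- iter + 1L
    cc <- suppressWarnings(cor(prof))
    diag(cc) <- -Inf
    cc[is.na(cc)] <- -Inf
    pairs <- which(upper.tri(cc) & cc >= rMin, arr.ind = TRUE)
    if (!nrow(pairs)) break
    r <- cc[pairs]
    nm <- colnames(prof)
    ord <- order(-r, nm[pairs[, 1]], nm[pairs[, 2]])
    pairs <- pairs[ord, , drop = FALSE]
    r <- r[ord]
    # greedy maximal set of non-overlapping pairs, descending r
    used <- rep(FALSE, ncol(prof))
    sel <- integer(0)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      sel <- c(sel, i)
    }
    drop <- integer(0)
    for (i in sel) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      newId <- paste(nm[a], nm[b], sep = "+")
      w <- counts[c(a, b)]
      prof[, a] <- (prof[, a] * w[1] + prof[, b] * w[2]) / sum(w)
      colnames(prof)[a] <- newId
      counts[a] <- sum(w)
      names(counts)[a] <- newId
      drop <- c(drop, b)
      log <- rbind(log, data.frame(iteration = iter, cluster_a = nm[a],
                                   cluster_b = nm[b], r = r[match(i, seq_along(r))],
                                   new_id = newId, stringsAsFactors = FALSE))
    }
    prof <- prof[, -drop, drop = FALSE]
    counts <- counts[-drop]
  }
  list(reference = ClusterReference(
         ExpressionMatrix(prof, ref@profiles@unitTag), cellCounts = counts),
       mergeLog = log)
}
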