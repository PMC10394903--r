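#' @import methods
#' @importFrom stats cor var sd quantile rlnorm rpois rnbinom rbinom rgamma
#'   runif rmultinom wilcox.test p.adjust setNames coef
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix readMM writeMM rowSums colSums
NULL

setClassUnion("matrixOrSparse", c("matrix", "Matrix"))

#' ExpressionMatrix: genes-by-columns expression values
#'
#' The central expression container: a numeric genes x columns matrix (columns
#' are bulk samples or single cells) with unique gene and column identifiers
#' carried as dimnames, plus a unit tag recording what the values are.
#' Internally everything in the package is genes x columns; readers reorient
#' at the boundary.
#'
#' @slot values numeric matrix or sparse Matrix, genes in rows.
#' @slot unitTag one of \code{"counts"}, \code{"TPM"}, \code{"TMM"},
#'   \code{"lognorm"}, \code{"arbitrary"}. Values must be non-negative unless
#'   the tag is \code{"lognorm"} or \code{"arbitrary"} (transformed bulk
#'   profiles may contain negatives).
#' @name ExpressionMatrix-class
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrixOrSparse", unitTag = "character"),
  prototype(unitTag = "counts")
)

.validExpressionMatrix <- function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene ids (rownames) and column ids (colnames)")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, paste0("duplicate gene ids: ",
        paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, paste0("duplicate column ids: ",
        paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  }
  if (length(object@unitTag) != 1L ||
      !object@unitTag %in% c("counts", "TPM", "TMM", "lognorm", "arbitrary"))
    msg <- c(msg, "unitTag must be one of counts, TPM, TMM, lognorm, arbitrary")
  vmin <- suppressWarnings(min(v))
  if (length(v) && !all(is.finite(range(if (is(v, "Matrix")) v@x else v, 0))))
    msg <- c(msg, "values must be finite")
  if (length(v) && !object@unitTag %in% c("lognorm", "arbitrary") &&
      is.finite(vmin) && vmin < 0)
    msg <- c(msg, "negative values not allowed for this unit tag")
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionMatrix", .validExpressionMatrix)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (or sparse Matrix) with genes in rows; must
#'   have unique rownames and colnames.
#' @param unitTag unit of the values; see \linkS4class{ExpressionMatrix}.
#' @return an \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(1:6, 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, unitTag = "counts") {
  if (is.data.frame(values)) values <- as.matrix(values)
  new("ExpressionMatrix", values = values, unitTag = unitTag)
}

#' CellLabelTable: per-cell metadata
#'
#' Carries the per-cell sample and cluster assignments plus the QC covariates
#' (mitochondrial and ribosomal content fractions) used by cell filtering.
#'
#' @slot cellId unique cell identifiers.
#' @slot sampleId sample of origin per cell.
#' @slot clusterId cluster label per cell (may be "unassigned").
#' @slot mitoFraction,riboFraction per-cell content fractions in [0, 1]; may
#'   be NA, in which case QC derives them from gene-name prefixes.
#' @name CellLabelTable-class
#' @aliases CellLabelTable-class
#' @exportClass CellLabelTable
setClass("CellLabelTable",
  representation(cellId = "character", sampleId = "character",
                 clusterId = "character", mitoFraction = "numeric",
                 riboFraction = "numeric"))

setValidity("CellLabelTable", function(object) {
  n <- length(object@cellId)
  msg <- character()
  if (anyDuplicated(object@cellId))
    msg <- c(msg, "cell ids must be unique")
  if (length(object@sampleId) != n || length(object@clusterId) != n ||
      length(object@mitoFraction) != n || length(object@riboFraction) != n)
    msg <- c(msg, "all per-cell vectors must have equal length")
  if (any(is.na(object@sampleId)) || any(is.na(object@clusterId)))
    msg <- c(msg, "every cell needs a sample_id and cluster_id")
  for (nm in c("mitoFraction", "riboFraction")) {
    f <- slot(object, nm)
    if (any(!is.na(f) & (f < 0 | f > 1)))
      msg <- c(msg, paste(nm, "must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellLabelTable
#'
#' @param cellId,sampleId,clusterId character vectors of equal length.
#' @param mitoFraction,riboFraction optional per-cell fractions in [0, 1].
#' @return a \linkS4class{CellLabelTable}.
#' @export
CellLabelTable <- function(cellId, sampleId, clusterId = rep("unassigned", length(cellId)),
                           mitoFraction = rep(NA_real_, length(cellId)),
                           riboFraction = rep(NA_real_, length(cellId))) {
  new("CellLabelTable", cellId = as.character(cellId),
      sampleId = as.character(sampleId), clusterId = as.character(clusterId),
      mitoFraction = as.numeric(mitoFraction), riboFraction = as.numeric(riboFraction))
}

#' CompositionMatrix: samples-by-cell-types proportions
#'
#' Holds either a gold-standard composition (rows sum to one) or solver
#' estimates. Raw (pre-renormalization) solver output, iteration counts and
#' other solver metadata travel in the \code{metadata} list.
#'
#' @slot values numeric samples x cell-types matrix with dimnames.
#' @slot kind \code{"gold_standard"} or \code{"estimate"}.
#' @slot metadata free-form list (raw estimates, solver info, logs).
#' @name CompositionMatrix-class
#' @aliases CompositionMatrix-class
#' @exportClass CompositionMatrix
setClass("CompositionMatrix",
  representation(values = "matrix", kind = "character", metadata = "list"),
  prototype(kind = "estimate", metadata = list()))

setValidity("CompositionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) > 0 && (is.null(rownames(v)) || is.null(colnames(v))))
    msg <- c(msg, "values must carry sample ids (rownames) and cell-type ids (colnames)")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate cell-type ids")
  if (length(v) && !all(is.finite(v))) msg <- c(msg, "values must be finite")
  if (!object@kind %in% c("gold_standard", "estimate"))
    msg <- c(msg, "kind must be gold_standard or estimate")
  if (object@kind == "gold_standard" && nrow(v) > 0) {
    if (any(v < 0)) msg <- c(msg, "gold standard proportions must be >= 0")
    if (any(abs(rowSums(v) - 1) > 1e-6))
      msg <- c(msg, "gold standard rows must sum to 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CompositionMatrix
#'
#' @param values numeric samples x cell-types matrix with dimnames.
#' @param kind \code{"gold_standard"} or \code{"estimate"}.
#' @param metadata optional list of solver metadata.
#' @return a \linkS4class{CompositionMatrix}.
#' @export
CompositionMatrix <- function(values, kind = "estimate", metadata = list()) {
  new("CompositionMatrix", values = as.matrix(values), kind = kind,
      metadata = metadata)
}

#' ClusterReference: cluster-mean expression profiles
#'
#' The deconvolution reference (signature) matrix: per-cluster mean expression
#' profiles together with the number of cells behind each cluster and,
#' optionally, ranked marker gene lists.
#'
#' @slot profiles \linkS4class{ExpressionMatrix}, genes x clusters.
#' @slot cellCounts named integer-valued vector, cells per cluster (>= 1).
#' @slot markers named list: cluster id -> character vector of marker genes
#'   ordered by descending fold-change.
#' @name ClusterReference-class
#' @aliases ClusterReference-class
#' @exportClass ClusterReference
setClass("ClusterReference",
  representation(profiles = "ExpressionMatrix", cellCounts = "numeric",
                 markers = "list"),
  prototype(markers = list()))

setValidity("ClusterReference", function(object) {
  msg <- character()
  ids <- colnames(object@profiles@values)
  if (!identical(sort(names(object@cellCounts)), sort(ids)))
    msg <- c(msg, "cellCounts names must match cluster ids")
  if (any(object@cellCounts < 1)) msg <- c(msg, "each retained cluster needs >= 1 cell")
  if (length(object@markers) && !all(names(object@markers) %in% ids))
    msg <- c(msg, "marker list names must be cluster ids")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterReference
#'
#' @param profiles \linkS4class{ExpressionMatrix} of cluster-mean expression,
#'   genes x clusters.
#' @param cellCounts named vector of per-cluster cell counts.
#' @param markers optional named list of ranked marker genes per cluster.
#' @return a \linkS4class{ClusterReference}.
#' @export
ClusterReference <- function(profiles, cellCounts, markers = list()) {
  new("ClusterReference", profiles = profiles, cellCounts = cellCounts,
      markers = markers)
}

#' TransformModel: per-gene bulk-to-single-cell linear map
#'
#' In mode \code{"eq2"} each in-scope gene carries a slope/intercept pair
#' (a, b) fitted by regressing the concurrent pseudobulk on the bulk profile
#' across samples. In mode \code{"eq3"} each gene carries the pseudobulk and
#' bulk means and standard deviations of the standardized mapping, which does
#' not require concurrent profiling.
#'
#' @slot mode \code{"eq2"} or \code{"eq3"}.
#' @slot coefficients data.frame with rownames = the modeled gene universe
#'   (genes with nonzero expression in both spaces); columns \code{a},
#'   \code{b} for eq2, or \code{meanPseudobulk}, \code{meanBulk},
#'   \code{sdPseudobulk}, \code{sdBulk} for eq3.
#' @name TransformModel-class
#' @aliases TransformModel-class
#' @exportClass TransformModel
setClass("TransformModel",
  representation(mode = "character", coefficients = "data.frame"))

setValidity("TransformModel", function(object) {
  msg <- character()
  cf <- object@coefficients
  if (!object@mode %in% c("eq2", "eq3")) msg <- c(msg, "mode must be eq2 or eq3")
  need <- if (object@mode == "eq2") c("a", "b") else
    c("meanPseudobulk", "meanBulk", "sdPseudobulk", "sdBulk")
  if (!all(need %in% colnames(cf)))
    msg <- c(msg, paste("coefficients must have columns:", paste(need, collapse = ", ")))
  else if (!all(vapply(cf[need], function(x) all(is.finite(x)), logical(1))))
    msg <- c(msg, "coefficients must be finite")
  if (object@mode == "eq3" && "sdBulk" %in% colnames(cf) && any(cf$sdBulk <= 0))
    msg <- c(msg, "eq3 requires a positive bulk sd for every modeled gene")
  if (length(msg)) msg else TRUE
})

#' ConcurrentDataset: aligned bulk + single-cell profiles
#'
#' A set of samples assayed by both bulk RNA-seq and scnRNA-seq. Bulk and
#' pseudobulk columns align one-to-one by sample id; the single-cell counts
#' and label table provide the per-fold references and pseudobulk profiles
#' for leave-one-out cross-validation.
#'
#' @slot bulk \linkS4class{ExpressionMatrix}, genes x samples.
#' @slot scCounts \linkS4class{ExpressionMatrix}, genes x cells.
#' @slot scLabels \linkS4class{CellLabelTable} for the cells of scCounts.
#' @slot pseudobulk \linkS4class{ExpressionMatrix}, genes x samples: per
#'   sample, mean expression across that sample's cells.
#' @name ConcurrentDataset-class
#' @aliases ConcurrentDataset-class
#' @exportClass ConcurrentDataset
setClass("ConcurrentDataset",
  representation(bulk = "ExpressionMatrix", scCounts = "ExpressionMatrix",
                 scLabels = "CellLabelTable", pseudobulk = "ExpressionMatrix"))

setValidity("ConcurrentDataset", function(object) {
  msg <- character()
  bs <- colnames(object@bulk@values)
  if (!identical(bs, colnames(object@pseudobulk@values)))
    msg <- c(msg, "bulk and pseudobulk sample ids must align one-to-one")
  if (!setequal(unique(object@scLabels@sampleId), bs))
    msg <- c(msg, "single-cell sample ids must match bulk sample ids")
  if (!identical(object@scLabels@cellId, colnames(object@scCounts@values)))
    msg <- c(msg, "label table rows must align with single-cell columns")
  if (length(msg)) msg else TRUE
})

#' Construct a ConcurrentDataset
#'
#' @param bulk genes x samples \linkS4class{ExpressionMatrix}.
#' @param scCounts genes x cells \linkS4class{ExpressionMatrix}.
#' @param scLabels \linkS4class{CellLabelTable}; sample ids must match the
#'   bulk columns.
#' @param pseudobulk optional precomputed pseudobulk; computed with
#'   \code{\link{makePseudobulk}} when missing.
#' @return a \linkS4class{ConcurrentDataset}.
#' @export
ConcurrentDataset <- function(bulk, scCounts, scLabels, pseudobulk = NULL) {
  if (is.null(pseudobulk)) {
    pseudobulk <- makePseudobulk(scCounts, scLabels)
    pb <- pseudobulk@values[, colnames(bulk@values), drop = FALSE]
    pseudobulk <- ExpressionMatrix(pb, unitTag = pseudobulk@unitTag)
  }
  new("ConcurrentDataset", bulk = bulk, scCounts = scCounts,
      scLabels = scLabels, pseudobulk = pseudobulk)
}

#' SolverSpec: deconvolution solver configuration
#'
#' @slot method one of \code{"OLS"}, \code{"NNLS"}, \code{"RLR"},
#'   \code{"DWLS"}.
#' @slot epsilon convergence bound on the Euclidean norm of successive
#'   proportion iterates (default 0.01, absolute).
#' @slot maxIterations iteration cap for DWLS / RLR (default 1000).
#' @slot dampingGrid candidate damping constants for the DWLS weight cap
#'   (default 2^(0:14)).
#' @slot nSubsamples number of half-gene subsamples in the damping-constant
#'   search (default 20).
#' @slot seed integer seed for the damping search subsampling stream.
#' @name SolverSpec-class
#' @aliases SolverSpec-class
#' @exportClass SolverSpec
setClass("SolverSpec",
  representation(method = "character", epsilon = "numeric",
                 maxIterations = "numeric", dampingGrid = "numeric",
                 nSubsamples = "numeric", seed = "numeric"),
  prototype(method = "DWLS", epsilon = 0.01, maxIterations = 1000,
            dampingGrid = 2^(0:14), nSubsamples = 20, seed = 1))

setValidity("SolverSpec", function(object) {
  msg <- character()
  if (!object@method %in% c("OLS", "NNLS", "RLR", "DWLS"))
    msg <- c(msg, "method must be one of OLS, NNLS, RLR, DWLS")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (!length(object@dampingGrid)) msg <- c(msg, "damping grid must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Construct a SolverSpec
#'
#' @param method solver name: OLS, NNLS, RLR or DWLS.
#' @param epsilon DWLS convergence bound (Euclidean norm of the change in the
#'   proportion vector between iterations).
#' @param maxIterations iteration cap.
#' @param dampingGrid candidate damping constants (powers of two).
#' @param nSubsamples subsamples in the damping-constant search.
#' @param seed seed for the damping search subsampling.
#' @return a \linkS4class{SolverSpec}.
#' @export
SolverSpec <- function(method = "DWLS", epsilon = 0.01, maxIterations = 1000,
                       dampingGrid = 2^(0:14), nSubsamples = 20, seed = 1) {
  new("SolverSpec", method = method, epsilon = epsilon,
      maxIterations = maxIterations, dampingGrid = dampingGrid,
      nSubsamples = nSubsamples, seed = seed)
}

#' BenchmarkResult: accuracy of one estimate against a gold standard
#'
#' @slot method solver name evaluated.
#' @slot bulkNormalization,referenceNormalization normalization labels.
#' @slot pearsonR Pearson correlation over all aligned (sample, cell type)
#'   pairs; NA (with \code{reason}) when either flattened vector has zero
#'   variance.
#' @slot rmse root mean squared error over the same pairs.
#' @slot nPoints number of aligned pairs (samples x cell types).
#' @slot perCelltype data.frame of per-cell-type Pearson r and RMSE.
#' @slot reason character: why pearsonR is NA, or "".
#' @name BenchmarkResult-class
#' @aliases BenchmarkResult-class
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
  representation(method = "character", bulkNormalization = "character",
                 referenceNormalization = "character", pearsonR = "numeric",
                 rmse = "numeric", nPoints = "numeric",
                 perCelltype = "data.frame", reason = "character"),
  prototype(method = "", bulkNormalization = "none",
            referenceNormalization = "none", reason = ""))

setValidity("BenchmarkResult", function(object) {
  if (length(object@rmse) == 1 && !is.na(object@rmse) &&
      (!is.finite(object@rmse) || object@rmse < 0))
    "rmse must be finite and >= 0" else TRUE
})

#' MixtureDesign: ground-truth mixture proportions
#'
#' Emulates a six-mixture design over six cell types: three variable tumor
#' lines, two immune types jointly fixed at 15% of each mixture, and one
#' stem-cell type cycling through 0.5%, 1% and 2%.
#'
#' @slot proportions samples x cell-types matrix of true proportions; rows
#'   sum to one.
#' @slot nGenes number of genes to simulate.
#' @slot seed seed the design was drawn with.
#' @name MixtureDesign-class
#' @aliases MixtureDesign-class
#' @exportClass MixtureDesign
setClass("MixtureDesign",
  representation(proportions = "matrix", nGenes = "numeric", seed = "numeric"))

setValidity("MixtureDesign", function(object) {
  p <- object@proportions
  msg <- character()
  if (any(p < 0)) msg <- c(msg, "proportions must be >= 0")
  if (any(abs(rowSums(p) - 1) > 1e-12)) msg <- c(msg, "each sample must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PlatformBiasModel: cross-platform measurement bias
#'
#' Models the systematic differences between bulk RNA-seq and single-cell
#' measurements of the same sample, applied to the single-cell counts only:
#' a per-gene multiplicative log-normal capture factor (the exactly-linear
#' component a per-gene transform can correct), a per-cell-type RNA-content /
#' capture scalar (cell-size and UMI-depth differences between types, which
#' rescale whole reference columns and therefore distort proportion estimates
#' from untransformed bulk), optional mean-dependent dropout thinning, and
#' multiplicative log-normal bulk noise. Both capture components are governed
#' by the single dial tau, so tau = 0 is an exactly unbiased platform. All
#' distributional choices are synthetic-data assumptions of this package,
#' not measured platform properties.
#'
#' @slot tau sdlog of the per-gene log-normal capture factor and of the
#'   per-cell-type capture scalar; 0 means an unbiased platform.
#' @slot contentScalars named per-cell-type RNA-content/capture multipliers
#'   on the single-cell side. Empty (default) means: drawn log-normal(0, tau)
#'   at generation time. Supply an explicit vector (e.g. all 1) to fix them.
#' @slot dropout dropout intensity in [0, 1]: per-gene thinning probability
#'   \code{dropout * exp(-gene mean)}; 0 disables (default).
#' @slot bulkNoiseSdlog sdlog of multiplicative log-normal bulk noise
#'   (default 0.1).
#' @slot typeDependentBias if TRUE, draw an independent capture factor per
#'   (gene, cell type) — violates the per-gene linearity the transform
#'   assumes; off by default.
#' @name PlatformBiasModel-class
#' @aliases PlatformBiasModel-class
#' @exportClass PlatformBiasModel
setClass("PlatformBiasModel",
  representation(tau = "numeric", contentScalars = "numeric",
                 dropout = "numeric", bulkNoiseSdlog = "numeric",
                 typeDependentBias = "logical"),
  prototype(tau = 0.5, contentScalars = numeric(), dropout = 0,
            bulkNoiseSdlog = 0.1, typeDependentBias = FALSE))

setValidity("PlatformBiasModel", function(object) {
  msg <- character()
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (length(object@contentScalars) && any(object@contentScalars <= 0))
    msg <- c(msg, "content scalars must be > 0")
  if (object@dropout < 0 || object@dropout > 1)
    msg <- c(msg, "dropout must lie in [0, 1]")
  if (object@bulkNoiseSdlog < 0) msg <- c(msg, "bulkNoiseSdlog must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PlatformBiasModel
#'
#' @param tau sdlog of the per-gene capture factor (default 0.5).
#' @param contentScalars optional named per-cell-type RNA-content multipliers.
#' @param dropout dropout intensity in [0, 1] (default 0, disabled).
#' @param bulkNoiseSdlog sdlog of multiplicative bulk noise (default 0.1).
#' @param typeDependentBias draw capture factors per (gene, type) instead of
#'   per gene (default FALSE).
#' @return a \linkS4class{PlatformBiasModel}.
#' @export
PlatformBiasModel <- function(tau = 0.5, contentScalars = numeric(),
                              dropout = 0, bulkNoiseSdlog = 0.1,
                              typeDependentBias = FALSE) {
  new("PlatformBiasModel", tau = tau, contentScalars = contentScalars,
      dropout = dropout, bulkNoiseSdlog = bulkNoiseSdlog,
      typeDependentBias = typeDependentBias)
}
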