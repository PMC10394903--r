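# Constrained least-squares solvers mapping one bulk profile plus a
# cell-type reference onto proportion estimates. All solvers return both the
# raw solution (on the original scale, possibly negative for OLS/RLR) and the
# reported proportions under convention C1: negatives clamped to zero, then
# renormalized to sum one.

# clamp + renormalize (convention C1)
reportProportions <- function(raw) {
  p <- pmax(raw, 0)
  s <- sum(p)
  if (s <= 0) stopf("all coefficients non-positive; cannot report proportions")
  p / s
}

# align a bulk column and reference to their shared gene universe and check
# the solver preconditions
alignSolverInputs <- function(bulkCol, ref) {
  X <- asDense(ref@profiles@values)
  genes <- sharedGenes(rownames(X), names(bulkCol))
  if (length(genes) < ncol(X))
    stopf("shared gene universe (%d genes) smaller than the number of cell types (%d)",
          length(genes), ncol(X))
  X <- X[genes, , drop = FALSE]
  z <- bulkCol[genes]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cc <- suppressWarnings(cor(X))
    diag(cc) <- 0
    cc[is.na(cc)] <- 1  # constant columns are degenerate too
    bad <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stopf("reference is rank-deficient; most collinear cluster pair: %s, %s",
          colnames(X)[bad[1]], colnames(X)[bad[2]])
  }
  list(X = X, z = z, qrX = qrX)
}

#' Ordinary least-squares deconvolution of one bulk profile
#'
#' Minimizes sum_g (z_g - sum_j p_j x_gj)^2 exactly via the QR decomposition.
#' The raw solution may contain negative coefficients; reported proportions
#' clamp negatives to zero and renormalize to sum one, with the raw solution
#' returned alongside so either convention can be evaluated.
#'
#' @param bulkCol named numeric vector: one bulk sample's expression.
#' @param ref \linkS4class{ClusterReference} (genes x cell types).
#' @return list with \code{proportions} (sums to 1), \code{raw} (unconstrained
#'   coefficients) and \code{objective}.
#' @export
solveOLS <- function(bulkCol, ref) {
  a <- alignSolverInputs(bulkCol, ref)
  raw <- qr.coef(a$qrX, a$z)
  fit <- as.numeric(a$X %*% raw)
  list(proportions = reportProportions(raw), raw = raw,
       objective = sum((a$z - fit)^2))
}

# weighted non-negative least squares via normal-equation reduction:
# ||W^(1/2)(z - Xp)||^2 = ||R p - d||^2 + const with R'R = X'WX and
# R'd = X'Wz, so an m x k problem reduces to a k x k Lawson-Hanson solve.
wnnls <- function(X, z, w = NULL) {
  if (is.null(w)) {
    G <- crossprod(X)
    q <- crossprod(X, z)
  } else {
    Xw <- X * w
    G <- crossprod(X, Xw)
    q <- crossprod(Xw, z)
  }
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R)) {
    # near-singular normal equations: fall back to the full-size solve
    sw <- if (is.null(w)) 1 else sqrt(w)
    return(pracma::lsqnonneg(asDense(X) * sw, as.numeric(z * sw))$x)
  }
  d <- backsolve(R, q, transpose = TRUE)
  pracma::lsqnonneg(R, as.numeric(d))$x
}

#' Non-negative least-squares deconvolution of one bulk profile
#'
#' Minimizes the least-squares objective subject to p >= 0 (Lawson-Hanson
#' active set on the reduced normal equations; deterministic). Reported
#' proportions renormalize the raw non-negative solution to sum one.
#'
#' @inheritParams solveOLS
#' @return list with \code{proportions}, \code{raw}, \code{objective}.
#' @export
solveNNLS <- function(bulkCol, ref) {
  a <- alignSolverInputs(bulkCol, ref)
  raw <- setNames(wnnls(a$X, a$z), colnames(a$X))
  fit <- as.numeric(a$X %*% raw)
  list(proportions = reportProportions(raw), raw = raw,
       objective = sum((a$z - fit)^2))
}

#' Robust linear-regression deconvolution of one bulk profile
#'
#' Huber-loss M-estimation (tuning constant 1.345) by iteratively reweighted
#' least squares, then convention C1 reporting. When the ordinary
#' least-squares fit is already (numerically) exact — zero residual scale,
#' where the Huber estimate coincides with least squares — the OLS solution
#' is returned directly. A zero bulk vector returns a zero raw solution.
#'
#' @inheritParams solveOLS
#' @param maxIterations IRLS iteration cap (default 1000).
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @return list with \code{proportions} (NA for an all-zero bulk vector),
#'   \code{raw}, \code{objective} (residual sum of squares of the raw fit).
#' @export
solveRLR <- function(bulkCol, ref, maxIterations = 1000, tol = 1e-8) {
  a <- alignSolverInputs(bulkCol, ref)
  if (all(a$z == 0)) {
    raw <- setNames(rep(0, ncol(a$X)), colnames(a$X))
    return(list(proportions = rep(NA_real_, ncol(a$X)), raw = raw, objective = 0))
  }
  ols <- qr.coef(a$qrX, a$z)
  res <- a$z - as.numeric(a$X %*% ols)
  if (max(abs(res)) <= 1e-10 * max(abs(a$z))) {
    raw <- ols
  } else {
    fit <- tryCatch(
      MASS::rlm(a$X, a$z, psi = MASS::psi.huber, k = 1.345,
                maxit = maxIterations, acc = tol),
      error = function(e) NULL)
    if (is.null(fit)) {
      warnf("robust fit failed; returning the least-squares solution")
      raw <- ols
    } else {
      if (!fit$converged)
        warnf("robust fit did not converge in %d iterations; returning last iterate",
              maxIterations)
      raw <- coef(fit)
    }
  }
  names(raw) <- colnames(a$X)
  fitv <- as.numeric(a$X %*% raw)
  list(proportions = reportProportions(raw), raw = raw,
       objective = sum((a$z - fitv)^2))
}

# choose the damping constant: cap weights at d * min positive weight and
# pick the d whose normalized weighted solution varies least across fixed
# half-gene subsamples (cross-validation variance criterion). Computed once,
# from the initial solution's weights.
chooseDampingConstant <- function(X, z, w, spec) {
  wpos <- w[w > 0]
  if (!length(wpos)) return(spec@dampingGrid[1])
  wmin <- min(wpos)
  m <- nrow(X)
  half <- ceiling(m / 2)
  subsets <- withLocalSeed(spec@seed, lapply(seq_len(spec@nSubsamples),
    function(i) sample.int(m, half)))
  best <- spec@dampingGrid[1]
  bestCrit <- Inf
  for (d in spec@dampingGrid) {
    wd <- pmin(w, d * wmin)
    sols <- vapply(subsets, function(idx) {
      p <- wnnls(X[idx, , drop = FALSE], z[idx], wd[idx])
      s <- sum(p)
      if (s > 0) p / s else p
    }, numeric(ncol(X)))
    crit <- sum(apply(sols, 1, var))
    if (is.finite(crit) && crit < bestCrit - 1e-15) {
      bestCrit <- crit
      best <- d
    }
    if (d * wmin >= max(w)) break  # larger d's no longer change the cap
  }
  best
}

#' Dampened weighted least-squares deconvolution of one bulk profile
#'
#' Iteratively reweighted non-negative least squares with dampened weights.
#' Starting from the NNLS solution, iteration l computes per-gene weights
#' w_g = 1 / max((X p^(l-1))_g^2, delta), caps them at d times the smallest
#' positive weight (the damping constant d, chosen once from a powers-of-two
#' grid by a cross-validation variance criterion on fixed seeded half-gene
#' subsamples), solves the weighted NNLS problem, renormalizes to sum one,
#' and stops when the Euclidean norm of the change in the proportion vector
#' is at most \code{spec@epsilon} (default 0.01, absolute) or after
#' \code{spec@maxIterations}.
#'
#' @inheritParams solveOLS
#' @param spec a \linkS4class{SolverSpec} (epsilon, damping grid, iteration
#'   cap, subsampling seed).
#' @return list with \code{proportions}, \code{raw} (last weighted NNLS
#'   solution), \code{objective} (weighted objective at the final weights),
#'   \code{iterations}, \code{converged}, \code{dampingConstant},
#'   \code{weights} (final dampened weights, named by gene) and
#'   \code{stepNorms} (per-iteration change norms).
#' @export
solveDWLS <- function(bulkCol, ref, spec = SolverSpec()) {
  a <- alignSolverInputs(bulkCol, ref)
  X <- a$X; z <- a$z
  p <- wnnls(X, z)
  s <- sum(p)
  if (s <= 0) stopf("initial NNLS solution is identically zero")
  p <- p / s
  pred <- as.numeric(X %*% p)
  delta <- 1e-12 * max(pred^2)
  if (delta == 0) stopf("all predicted expression is zero")
  w0 <- 1 / pmax(pred^2, delta)
  d <- chooseDampingConstant(X, z, w0, spec)
  stepNorms <- numeric(0)
  converged <- FALSE
  iter <- 0L
  raw <- p
  while (iter < spec@maxIterations) {
    iter <- iter + 1L
    pred <- as.numeric(X %*% p)
    delta <- 1e-12 * max(pred^2)
    w <- 1 / pmax(pred^2, delta)
    wpos <- w[w > 0]
    w <- pmin(w, d * min(wpos))
    raw <- wnnls(X, z, w)
    s <- sum(raw)
    pNew <- if (s > 0) raw / s else p
    stepNorms <- c(stepNorms, l2norm(pNew - p))
    if (l2norm(pNew - p) <= spec@epsilon) {
      p <- pNew
      converged <- TRUE
      break
    }
    p <- pNew
  }
  if (!converged)
    warnf("DWLS did not reach the %.3g convergence bound in %d iterations",
          spec@epsilon, spec@maxIterations)
  fitRes <- z - as.numeric(X %*% raw)
  list(proportions = setNames(p, colnames(X)), raw = setNames(raw, colnames(X)),
       objective = sum(w * fitRes^2), iterations = iter, converged = converged,
       dampingConstant = d, weights = setNames(w, rownames(X)),
       stepNorms = stepNorms)
}

#' Deconvolve every sample of a bulk matrix
#'
#' Vectorizes any solver over the columns of a bulk matrix; one composition
#' row per sample. Deterministic given inputs and spec.
#'
#' @param bulk genes x samples \linkS4class{ExpressionMatrix}.
#' @param ref \linkS4class{ClusterReference}.
#' @param spec \linkS4class{SolverSpec}; \code{spec@method} picks the solver.
#' @return a \linkS4class{CompositionMatrix} (kind "estimate") whose metadata
#'   holds the raw solutions and, for DWLS, iteration counts and damping
#'   constants.
#' @export
deconvolveMatrix <- function(bulk, ref, spec = SolverSpec()) {
  v <- asDense(bulk@values)
  if (ncol(v) < 1) stopf("need at least one bulk sample")
  solver <- switch(spec@method,
    OLS = function(z) solveOLS(z, ref),
    NNLS = function(z) solveNNLS(z, ref),
    RLR = function(z) solveRLR(z, ref, maxIterations = spec@maxIterations),
    DWLS = function(z) solveDWLS(z, ref, spec))
  types <- colnames(ref@profiles@values)
  est <- matrix(NA_real_, ncol(v), length(types),
                dimnames = list(colnames(v), types))
  raw <- est
  iters <- setNames(rep(NA_real_, ncol(v)), colnames(v))
  for (i in seq_len(ncol(v))) {
    res <- tryCatch(solver(setNames(v[, i], rownames(v))),
      error = function(e) stopf("sample %s: %s", colnames(v)[i], conditionMessage(e)))
    est[i, ] <- res$proportions
    raw[i, ] <- res$raw
    if (!is.null(res$iterations)) iters[i] <- res$iterations
  }
  CompositionMatrix(est, kind = "estimate",
    metadata = list(method = spec@method, raw = raw, iterations = iters))
}
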