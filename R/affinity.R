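# Pairwise distances, kNN masks and sparse fusion-weight graphs.

#' Construct a fusion graph from an explicit edge list
#'
#' @param n sample count.
#' @param edges two-column matrix of sample index pairs (l1 < l2).
#' @param weights positive weight per edge.
#' @return a \linkS4class{FusionGraph}; its \code{D} slot is the sparse signed
#'   incidence matrix with +1 at l1 and -1 at l2 in each row.
#' @export
fusionGraph <- function(n, edges, weights) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  m <- nrow(edges)
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(m), 2L),
    j = c(edges[, 1L], edges[, 2L]),
    x = rep(c(1, -1), each = m),
    dims = c(m, n))
  g <- new("FusionGraph", n = as.integer(n), edges = edges,
           weights = as.numeric(weights), D = D)
  validObject(g)
  g
}

.as_view_list <- function(views) {
  if (is(views, "DataView")) views <- list(views)
  if (!length(views) || !all(vapply(views, is, TRUE, "DataView")))
    .stop("icclust_contract", "views must be DataView objects")
  n <- vapply(views, function(v) nrow(v@X), 1L)
  if (length(unique(n)) != 1L)
    .stop("icclust_contract", "all views must share the same samples (rows)")
  views
}

#' Gower distance across data views
#'
#' Mixed-type dissimilarity: the average over all features (pooled across
#' views) of the range-normalized absolute difference
#' \code{|x_ij - x_i'j| / R_j}. Entries lie in [0, 1]; features with zero
#' range are dropped from both numerator and denominator.
#'
#' @param views a \linkS4class{DataView} or list of views sharing rows.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
gowerDistance <- function(views) {
  views <- .as_view_list(views)
  n <- nrow(views[[1L]]@X)
  acc <- matrix(0, n, n)
  p_used <- 0L
  for (v in views) {
    for (j in seq_len(ncol(v@X))) {
      x <- v@X[, j]
      R <- max(x) - min(x)
      if (R <= 0) next
      acc <- acc + abs(outer(x, x, "-")) / R
      p_used <- p_used + 1L
    }
  }
  if (p_used == 0L) return(acc)
  acc / p_used
}

# Pairwise distance matrix induced by a view's own loss; used for
# single-view (Gecco) fusion weights. Distance losses evaluate the loss
# between the two rows directly; likelihood/deviance losses are symmetrized
# as l(x_i, c(x_j)) + l(x_j, c(x_i)) with c the data-to-parameter map.
#' Loss-induced pairwise distances for one view
#'
#' @param view a \linkS4class{DataView}.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
lossDistance <- function(view) {
  X <- view@X
  n <- nrow(X)
  f <- view@loss@family
  D <- matrix(0, n, n)
  if (.is_distance(f)) {
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      d <- evalLoss(view@loss, X[i, , drop = FALSE], X[k, , drop = FALSE])
      D[i, k] <- D[k, i] <- d
    }
  } else {
    # parameter-scale image of each row
    P <- switch(f,
      poisson_ll   = log(pmax(X, .center_eps)),
      negbin_ll    = log(pmax(X, .center_eps)),
      bernoulli_ll = {
        Xc <- pmin(pmax(X, .center_eps), 1 - .center_eps)
        log(Xc / (1 - Xc))
      },
      binomial_dev = pmin(pmax(X, .center_eps), 1 - .center_eps),
      pmax(X, .center_eps))  # mean-scale deviances
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      d <- evalLoss(view@loss, X[i, , drop = FALSE], P[k, , drop = FALSE]) +
           evalLoss(view@loss, X[k, , drop = FALSE], P[i, , drop = FALSE])
      D[i, k] <- D[k, i] <- d
    }
  }
  D
}

#' Symmetric k-nearest-neighbor mask
#'
#' \code{mask[i, j]} is TRUE iff j is among i's \code{kappa} nearest
#' neighbors or vice versa (self excluded). Ties are broken towards the
#' lowest sample index for determinism.
#'
#' @param Dmat symmetric distance matrix with zero diagonal.
#' @param kappa neighborhood size, between 1 and n - 1.
#' @return symmetric logical matrix with FALSE diagonal.
#' @export
knnMask <- function(Dmat, kappa) {
  n <- nrow(Dmat)
  if (kappa < 1 || kappa > n - 1)
    .stop("icclust_contract", "kappa must lie in [1, n - 1]")
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- Dmat[i, ]
    d[i] <- Inf
    nn <- order(d, seq_len(n))[seq_len(kappa)]
    mask[i, nn] <- TRUE
  }
  mask <- mask | t(mask)
  diag(mask) <- FALSE
  mask
}

#' Default kernel bandwidth
#'
#' Chosen so that \code{phi * median(off-diagonal distances) = 1}.
#'
#' @param Dmat symmetric distance matrix.
#' @return positive scalar.
#' @export
defaultPhi <- function(Dmat) {
  med <- stats::median(Dmat[upper.tri(Dmat)])
  if (!is.finite(med) || med <= 0) 1 else 1 / med
}

#' kNN kernel fusion weights
#'
#' Builds the sparse fusion-weight graph over the k-nearest-neighbor mask.
#' \code{scheme = "gaussian"} uses \code{w = exp(-phi * d)}; \code{"sne"}
#' uses symmetrized stochastic-neighbor-embedding conditional probabilities
#' \code{p_ij = (p_j|i + p_i|j) / (2n)} with
#' \code{p_j|i = exp(-phi d_ij) / sum_k exp(-phi d_ik)}.
#'
#' @param Dmat symmetric distance matrix with zero diagonal.
#' @param kappa neighborhood size (default 5).
#' @param phi kernel bandwidth (>= 0); default \code{\link{defaultPhi}}.
#' @param scheme \code{"gaussian"} or \code{"sne"}.
#' @return a \linkS4class{FusionGraph}. A warning of class
#'   \code{icclust_disconnected} is raised if the retained edges do not
#'   connect all samples (full fusion to the loss-specific center then cannot
#'   occur).
#' @export
kernelWeights <- function(Dmat, kappa = 5, phi = NULL,
                          scheme = c("gaussian", "sne")) {
  scheme <- match.arg(scheme)
  n <- nrow(Dmat)
  if (is.null(phi)) phi <- defaultPhi(Dmat)
  if (phi < 0) .stop("icclust_contract", "phi must be >= 0")
  mask <- knnMask(Dmat, kappa)
  W <- if (scheme == "gaussian") {
    exp(-phi * Dmat)
  } else {
    E <- exp(-phi * Dmat)
    diag(E) <- 0
    Pc <- E / rowSums(E)          # p_{j|i} in row i
    (Pc + t(Pc)) / (2 * n)
  }
  W[!mask] <- 0
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  g <- fusionGraph(n, idx, W[idx])
  comp <- igraph::components(igraph::graph_from_edgelist(g@edges,
                                                         directed = FALSE))
  if (comp$no > 1L || nrow(g@edges) == 0L || max(g@edges) < n)
    warning(warningCondition(
      "fusion graph is not fully connected; full fusion is unattainable",
      class = c("icclust_disconnected", "icclust_warning")))
  g
}

#' Feature-importance weighted Gower distance
#'
#' Recomputes the Gower distance after an initial fit, scaling each feature's
#' contribution by its estimated importance
#' \code{||U_.j - center_j|| / max_j ||U_.j - center_j||} (within-view
#' normalized) and each view by the inverse loss weight \code{1 / pi_k}.
#' Views whose features are all fully shrunk contribute zero (with a
#' warning).
#'
#' @param views list of \linkS4class{DataView}.
#' @param U_hat list of fitted centroid matrices, parallel to \code{views}.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
weightedGowerUpdate <- function(views, U_hat) {
  views <- .as_view_list(views)
  if (length(U_hat) != length(views))
    .stop("icclust_contract", "one U_hat matrix per view required")
  n <- nrow(views[[1L]]@X)
  acc <- matrix(0, n, n)
  for (k in seq_along(views)) {
    v <- views[[k]]
    imp <- sqrt(colSums((U_hat[[k]] -
                         matrix(v@center, nrow(v@X), ncol(v@X),
                                byrow = TRUE))^2))
    if (max(imp) <= 0) {
      warning(warningCondition(
        sprintf("view %d: all features shrunk; view dropped from distances", k),
        class = c("icclust_allshrunk", "icclust_warning")))
      next
    }
    imp <- imp / max(imp)
    for (j in seq_len(ncol(v@X))) {
      if (imp[j] <= 0) next
      x <- v@X[, j]
      R <- max(x) - min(x)
      if (R <= 0) next
      acc <- acc + (imp[j] / v@weight) * abs(outer(x, x, "-")) / R
    }
  }
  acc
}
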