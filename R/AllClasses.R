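#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t
NULL

#' LossSpec: a convex loss family
#'
#' Describes one convex loss from the generalized convex clustering framework:
#' a distance (euclidean, manhattan, minkowski, chebychev, mahalanobis), an
#' exponential-family negative log-likelihood on the natural-parameter scale
#' (poisson_ll, bernoulli_ll, negbin_ll), or a deviance on the mean scale
#' (poisson_dev, binomial_dev, negbin_dev).
#'
#' @slot family character; the loss family identifier.
#' @slot smooth logical; TRUE iff the gradient exists everywhere on the
#'   admissible domain (FALSE exactly for manhattan, minkowski with q = 1 and
#'   chebychev).
#' @slot params named list of family-specific parameters: \code{q} (Minkowski
#'   exponent, >= 1), \code{C} (Mahalanobis positive-definite matrix),
#'   \code{theta} (negative-binomial dispersion, > 0).
#' @export
setClass("LossSpec",
  representation(family = "character", smooth = "logical", params = "list"),
  prototype(family = "euclidean", smooth = TRUE, params = list()))

#' DataView: one data view with its loss
#'
#' A sample-by-feature matrix together with the convex loss used to model it,
#' the per-feature loss-specific centers and the view-level loss weight
#' (by default the reciprocal null deviance, so heterogeneous views contribute
#' on a common scale).
#'
#' @slot X numeric matrix, n samples by p features.
#' @slot loss a \linkS4class{LossSpec}.
#' @slot center numeric vector of length p; columnwise loss-specific centers.
#' @slot weight positive scalar; the loss weight pi_k.
#' @export
setClass("DataView",
  representation(X = "matrix", loss = "LossSpec", center = "numeric",
                 weight = "numeric"))

#' FusionGraph: sparse fusion-weight graph over samples
#'
#' Edges are sample pairs with strictly positive fusion weight; \code{D} is
#' the signed incidence (directed difference) matrix so that the l-th row of
#' \code{D \%*\% U} equals \code{U[l1, ] - U[l2, ]}.
#'
#' @slot n integer sample count.
#' @slot edges integer matrix with two columns (l1 < l2), one row per edge.
#' @slot weights numeric vector of positive edge weights.
#' @slot D sparse incidence matrix, |edges| x n.
#' @export
setClass("FusionGraph",
  representation(n = "integer", edges = "matrix", weights = "numeric",
                 D = "Matrix"))

#' GeccoFit: a fitted convex clustering model
#'
#' @slot U list of per-view centroid matrices (n x p_k).
#' @slot V stacked fusion variable, |edges| x sum(p_k).
#' @slot labels integer cluster assignment per sample (shared across views).
#' @slot selected list of per-view logical feature masks.
#' @slot objective attained objective value.
#' @slot gamma,alpha penalty levels used.
#' @slot nClusters,nFeatures integer summaries.
#' @slot converged logical; FALSE if the iteration cap was reached.
#' @slot iter iterations used.
#' @slot residuals named numeric: final relative primal and dual residuals.
#' @slot state internal solver state for warm starts.
#' @export
setClass("GeccoFit",
  representation(U = "list", V = "matrix", labels = "integer",
                 selected = "list", objective = "numeric", gamma = "numeric",
                 alpha = "numeric", nClusters = "integer",
                 nFeatures = "integer", converged = "logical",
                 iter = "integer", residuals = "numeric", state = "list"))

#' GeccoPath: fits over a (gamma, alpha) grid
#'
#' @slot grid data.frame with one row per grid point: gamma, alpha, nClusters,
#'   nFeatures, objective, converged, iter.
#' @slot fits list of \linkS4class{GeccoFit}, parallel to \code{grid}.
#' @export
setClass("GeccoPath",
  representation(grid = "data.frame", fits = "list"))

setValidity("LossSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L || !object@family %in% lossFamilies())
    msg <- c(msg, sprintf("unknown loss family '%s'",
                          paste(object@family, collapse = ",")))
  else {
    p <- object@params
    if (object@family == "minkowski" &&
        (is.null(p$q) || !is.numeric(p$q) || p$q < 1))
      msg <- c(msg, "minkowski requires exponent q >= 1")
    if (object@family == "mahalanobis") {
      C <- p$C
      if (is.null(C) || !is.matrix(C) || nrow(C) != ncol(C) ||
          any(abs(C - t(C)) > 1e-8) ||
          inherits(try(chol(C), silent = TRUE), "try-error"))
        msg <- c(msg, "mahalanobis requires a symmetric positive-definite C")
    }
    if (object@family %in% c("negbin_ll", "negbin_dev") &&
        (is.null(p$theta) || !is.numeric(p$theta) || p$theta <= 0))
      msg <- c(msg, "negative binomial requires dispersion theta > 0")
    expect_smooth <- !(object@family %in% c("manhattan", "chebychev") ||
                       (object@family == "minkowski" &&
                        isTRUE(object@params$q == 1)))
    if (!identical(object@smooth, expect_smooth))
      msg <- c(msg, "smooth flag inconsistent with family")
  }
  if (length(msg)) msg else TRUE
})

setValidity("DataView", function(object) {
  msg <- character()
  if (!is.numeric(object@X)) msg <- c(msg, "X must be numeric")
  if (length(object@center) != ncol(object@X))
    msg <- c(msg, "center length must equal ncol(X)")
  if (length(object@weight) != 1L || !is.finite(object@weight) ||
      object@weight <= 0)
    msg <- c(msg, "weight must be a positive scalar")
  if (length(msg)) msg else TRUE
})

setValidity("FusionGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  else if (nrow(e)) {
    if (any(e[, 1] >= e[, 2])) msg <- c(msg, "edges must satisfy l1 < l2")
    if (any(e < 1L) || any(e > object@n)) msg <- c(msg, "edge index out of range")
    if (anyDuplicated(e)) msg <- c(msg, "duplicate edges")
    if (length(object@weights) != nrow(e))
      msg <- c(msg, "one weight per edge required")
    else if (any(object@weights <= 0))
      msg <- c(msg, "weights must be strictly positive")
  }
  if (!all(dim(object@D) == c(nrow(e), object@n)))
    msg <- c(msg, "D has wrong dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LossSpec", function(object) {
  cat("LossSpec:", object@family,
      if (object@smooth) "(smooth)" else "(non-smooth)", "\n")
  if (length(object@params)) {
    for (nm in names(object@params)) {
      v <- object@params[[nm]]
      if (is.matrix(v)) cat("  ", nm, ": ", nrow(v), "x", ncol(v),
                            " matrix\n", sep = "")
      else cat("  ", nm, ": ", format(v), "\n", sep = "")
    }
  }
  invisible(object)
})

setMethod("show", "DataView", function(object) {
  cat("DataView: ", nrow(object@X), " samples x ", ncol(object@X),
      " features, loss ", object@loss@family,
      ", weight ", signif(object@weight, 4), "\n", sep = "")
  invisible(object)
})

setMethod("show", "FusionGraph", function(object) {
  cat("FusionGraph: ", object@n, " samples, ", nrow(object@edges),
      " weighted edges\n", sep = "")
  invisible(object)
})

setMethod("show", "GeccoFit", function(object) {
  cat("GeccoFit: gamma = ", signif(object@gamma, 4),
      ", alpha = ", signif(object@alpha, 4),
      "\n  clusters: ", object@nClusters,
      "   selected features: ", object@nFeatures,
      "\n  objective: ", format(object@objective),
      "   converged: ", object@converged,
      " (", object@iter, " iterations)\n", sep = "")
  invisible(object)
})

setMethod("show", "GeccoPath", function(object) {
  cat("GeccoPath with", nrow(object@grid), "grid points\n")
  print(utils::head(object@grid, 10))
  if (nrow(object@grid) > 10) cat("...\n")
  invisible(object)
})

# ---- accessors ----

#' @rdname accessors
#' @param object a fitted object.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures",
           function(object) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' Accessors for fitted convex clustering models
#'
#' \code{clusterLabels} returns the integer cluster assignment (shared across
#' views); \code{selectedFeatures} the per-view logical masks of features not
#' shrunk to their loss-specific centers; \code{centroids} the list of fitted
#' centroid matrices; \code{nClusters} the number of clusters.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("clusterLabels", "GeccoFit", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "GeccoFit", function(object) object@selected)

#' @rdname accessors
#' @export
setMethod("centroids", "GeccoFit", function(object) object@U)

#' @rdname accessors
#' @export
setMethod("nClusters", "GeccoFit", function(object) object@nClusters)
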