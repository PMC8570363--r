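# User-facing estimators: single- and multi-view fits, regularization paths
# with warm starts, cluster-count targeted fitting and the adaptive
# refitting scheme with data-driven feature weights.

#' Default fusion weights for a set of views
#'
#' Single view: pairwise distances induced by the view's own loss.
#' Multiple views: the Gower mixed-type distance pooled over views. The
#' distance matrix is passed to \code{\link{kernelWeights}}.
#'
#' @inheritParams kernelWeights
#' @param views a \linkS4class{DataView} or list of views.
#' @return a \linkS4class{FusionGraph}.
#' @export
ccWeights <- function(views, kappa = 5, phi = NULL,
                      scheme = c("gaussian", "sne")) {
  scheme <- match.arg(scheme)
  views <- .as_view_list(views)
  Dm <- if (length(views) == 1L) lossDistance(views[[1L]])
        else gowerDistance(views)
  kernelWeights(Dm, kappa = kappa, phi = phi, scheme = scheme)
}

#' Generalized convex clustering estimators
#'
#' Thin wrappers around \code{\link{ccFit}}. \code{gecco} clusters a single
#' view with a general convex loss (no feature selection); \code{geccoPlus}
#' adds the shifted group-lasso feature penalty; \code{igecco} jointly
#' clusters multiple views with per-view losses and the joint fusion
#' penalty; \code{igeccoPlus} additionally selects features per view.
#'
#' @param X numeric sample-by-feature matrix (single-view forms).
#' @param loss loss family name or \linkS4class{LossSpec}.
#' @param views list of \linkS4class{DataView} (multi-view forms).
#' @param gamma fusion penalty level.
#' @param alpha feature penalty level.
#' @param graph optional \linkS4class{FusionGraph}; built with
#'   \code{\link{ccWeights}} when missing.
#' @param kappa,phi,scheme fusion-weight options, see
#'   \code{\link{kernelWeights}}.
#' @param ... further arguments to \code{\link{ccFit}}.
#' @return a \linkS4class{GeccoFit}.
#' @export
gecco <- function(X, loss, gamma, graph = NULL, kappa = 5, phi = NULL,
                  scheme = "gaussian", ...) {
  geccoPlus(X, loss, gamma, alpha = 0, graph = graph, kappa = kappa,
            phi = phi, scheme = scheme, ...)
}

#' @rdname gecco
#' @export
geccoPlus <- function(X, loss, gamma, alpha = 0, graph = NULL, kappa = 5,
                      phi = NULL, scheme = "gaussian", ...) {
  v <- if (is(X, "DataView")) X else dataView(X, loss)
  if (is.null(graph)) graph <- ccWeights(list(v), kappa, phi, scheme)
  ccFit(list(v), graph, gamma = gamma, alpha = alpha, ...)
}

#' @rdname gecco
#' @export
igecco <- function(views, gamma, graph = NULL, kappa = 5, phi = NULL,
                   scheme = "sne", ...) {
  igeccoPlus(views, gamma, alpha = 0, graph = graph, kappa = kappa,
             phi = phi, scheme = scheme, ...)
}

#' @rdname gecco
#' @export
igeccoPlus <- function(views, gamma, alpha = 0, graph = NULL, kappa = 5,
                       phi = NULL, scheme = "sne", ...) {
  views <- .as_view_list(views)
  if (is.null(graph)) graph <- ccWeights(views, kappa, phi, scheme)
  ccFit(views, graph, gamma = gamma, alpha = alpha, ...)
}

#' Data-driven upper end of the fusion path
#'
#' Doubles gamma from a small start until the fit is maximally fused: one
#' cluster per connected component of the fusion graph (a single cluster
#' when the graph is connected). Fusion cannot cross components, so this is
#' the largest attainable amount of fusion.
#'
#' @inheritParams ccFit
#' @param gamma0 starting value for the doubling search.
#' @return the smallest gamma found that fuses every component.
#' @export
gammaMax <- function(views, graph, alpha = 0, zeta = NULL, gamma0 = 1e-3,
                     ...) {
  views <- .as_view_list(views)
  ig <- igraph::graph_from_edgelist(graph@edges, directed = FALSE)
  nv <- igraph::vcount(ig)
  if (nv < graph@n) ig <- igraph::add_vertices(ig, graph@n - nv)
  ncomp <- igraph::components(ig)$no
  g <- gamma0
  warm <- NULL
  for (i in seq_len(50L)) {
    fit <- ccFit(views, graph, gamma = g, alpha = alpha, zeta = zeta,
                 warm = warm, ...)
    if (fit@nClusters <= ncomp) return(g)
    warm <- fit
    g <- g * 2
  }
  warning("gammaMax: maximal fusion not reached; increase gamma0 or check graph")
  g
}

#' Log-spaced penalty grid
#'
#' @param gmax upper end (e.g. from \code{\link{gammaMax}}).
#' @param length number of grid points (default 50).
#' @param ratio gmax / gmin.
#' @return increasing numeric vector.
#' @export
penaltyGrid <- function(gmax, length = 50L, ratio = 1000) {
  exp(seq(log(gmax / ratio), log(gmax), length.out = length))
}

#' Fit a (gamma, alpha) regularization path with warm starts
#'
#' Fits every grid point, warm-starting each fit from its nearest
#' already-solved neighbor (previous gamma at the same alpha; the first
#' gamma of each alpha from the previous alpha). By convexity the
#' warm-started objective matches a cold start; warm starts only save
#' iterations.
#'
#' @inheritParams ccFit
#' @param gammas increasing vector of fusion penalty levels.
#' @param alphas increasing vector of feature penalty levels.
#' @return a \linkS4class{GeccoPath}.
#' @export
solvePath <- function(views, graph, gammas, alphas = 0, zeta = NULL, ...) {
  views <- .as_view_list(views)
  if (!length(gammas) || !length(alphas))
    .stop("icclust_contract", "empty penalty grid")
  if (is.unsorted(gammas) || is.unsorted(alphas))
    .stop("icclust_contract", "grids must be sorted ascending")
  fits <- vector("list", length(gammas) * length(alphas))
  rows <- vector("list", length(fits))
  idx <- 0L
  first_of_prev_alpha <- NULL
  for (a in alphas) {
    warm <- first_of_prev_alpha
    for (gi in seq_along(gammas)) {
      idx <- idx + 1L
      fit <- ccFit(views, graph, gamma = gammas[gi], alpha = a, zeta = zeta,
                   warm = warm, ...)
      warm <- fit
      if (gi == 1L) first_of_prev_alpha <- fit
      fits[[idx]] <- fit
      rows[[idx]] <- data.frame(gamma = gammas[gi], alpha = a,
                                nClusters = fit@nClusters,
                                nFeatures = fit@nFeatures,
                                objective = fit@objective,
                                converged = fit@converged, iter = fit@iter)
    }
  }
  new("GeccoPath", grid = do.call(rbind, rows), fits = fits)
}

# Local search for the smallest gamma attaining a target cluster count,
# walking a multiplicative ladder from a hint and bisecting the first
# bracket (one level of refinement, in place of exact-count back-tracking).
.bulk_count <- function(fit, min_size)
  sum(table(fit@labels) >= min_size)

# Partition quality: total normalized loss with every sample at its
# cluster's loss-specific center. Comparable across fits on the same data;
# used to break ties between fits with identical cluster/feature counts.
.partition_loss <- function(views, labels) {
  sum(vapply(seq_along(views), function(k) {
    v <- views[[k]]
    v@weight * evalLoss(v@loss, v@X, .partition_centers(v, labels))
  }, 1))
}

.gamma_for_clusters <- function(views, graph, target, alpha, zeta, hint,
                                warm = NULL, factor = 1.4, max_steps = 60L,
                                refine_steps = 8L, min_size = 2L, ...) {
  hint <- max(hint, 0.05)
  memo <- list()
  fit_at <- function(g, warm) {
    key <- sprintf("%.12g", g)
    if (!is.null(memo[[key]])) return(memo[[key]])
    f <- ccFit(views, graph, gamma = g, alpha = alpha, zeta = zeta,
               warm = warm, ...)
    memo[[key]] <<- f
    f
  }
  # among fits with the target bulk count, prefer the fewest straggler
  # samples (most complete assignment), then the tightest partition, then
  # the smallest gamma
  best <- NULL
  best_q <- Inf
  kc <- function(f) .bulk_count(f, min_size)
  stragglers <- function(f) {
    tab <- table(f@labels)
    sum(tab[tab < min_size])
  }
  note <- function(f) {
    if (kc(f) != target) return(invisible())
    q <- .partition_loss(views, f@labels)
    better <- is.null(best) || stragglers(f) < stragglers(best) ||
      (stragglers(f) == stragglers(best) &&
       (q < best_q - 1e-12 ||
        (abs(q - best_q) <= 1e-12 && f@gamma < best@gamma)))
    if (better) { best <<- f; best_q <<- q }
  }
  f <- fit_at(hint, warm)
  note(f)
  # bracket on the strict component count (monotone-ish in gamma); the
  # bulk-count acceptance is checked on every fit along the way
  lo <- hi <- NULL
  g <- hint
  if (f@nClusters > target) {
    lo <- f
    for (i in seq_len(max_steps)) {
      g <- g * factor
      f <- fit_at(g, f)
      note(f)
      if (f@nClusters <= target) { hi <- f; break }
      lo <- f
    }
  } else {  # over-fused: walk down to find the lower boundary
    hi <- f
    for (i in seq_len(max_steps)) {
      g <- g / factor
      f <- fit_at(g, f)
      note(f)
      if (f@nClusters > target) { lo <- f; break }
      hi <- f
    }
  }
  # bisect the bracket, noting every bulk-count hit; if nothing has been
  # found yet keep refining (the transition zone can be narrow)
  if (!is.null(lo) && !is.null(hi) && lo@gamma < hi@gamma) {
    glo <- lo@gamma; ghi <- hi@gamma
    warm_b <- lo
    i <- 0L
    while (i < refine_steps || (is.null(best) && i < refine_steps + 8L)) {
      i <- i + 1L
      gm <- sqrt(glo * ghi)
      f <- fit_at(gm, warm_b)
      note(f)
      warm_b <- f
      if (f@nClusters > target) glo <- gm else ghi <- gm
    }
  }
  # scan upward through the target window: consolidation reduces stragglers
  if (!is.null(best)) {
    g <- best@gamma
    f <- best
    for (i in seq_len(10L)) {
      if (stragglers(f) == 0L) break
      g <- g * 1.2
      f <- fit_at(g, f)
      note(f)
      if (kc(f) < target) break
    }
    return(best)
  }
  # Fallback when no fit attains the target bulk count: prefer the
  # under-fused side -- among fits with component count >= target take the
  # closest count and, within it, the largest gamma (the most consolidated
  # fit short of over-fusing, whose centroids carry the most group
  # structure); only if every fit is over-fused return the nearest count.
  cnt <- vapply(memo, function(f) f@nClusters, 1L)
  gam <- vapply(memo, function(f) f@gamma, 1)
  idx <- which(cnt >= target)
  cand <- if (length(idx)) {
    idx <- idx[cnt[idx] == min(cnt[idx])]
    memo[[idx[which.max(gam[idx])]]]
  } else {
    memo[[which.min(abs(cnt - target))]]
  }
  attr(cand, "exact") <- FALSE
  warning(sprintf("no gamma found with exactly %d clusters; returning %d",
                  target, .bulk_count(cand, min_size)))
  cand
}

#' Fit with a target number of clusters
#'
#' Searches the fusion path for the smallest gamma whose fit has the desired
#' number of clusters (least regularization, hence least bias), bisecting
#' between grid points when the count is skipped. Returns the nearest count
#' with a warning when the target is unattainable.
#'
#' Cluster counting: components smaller than \code{min_size} are treated as
#' unfused outlier stragglers and do not count toward the target. Fusion
#' paths routinely leave a few outlying observations as singleton components
#' until far beyond the point where the bulk clusters have merged, so a
#' strict component count frequently has no gamma attaining the target at
#' all; the stragglers keep their own labels in the returned fit. Set
#' \code{min_size = 1} for strict counting.
#'
#' @inheritParams ccFit
#' @param n_clusters target cluster count.
#' @param gamma_hint starting point of the search (default from
#'   \code{\link{gammaMax}}).
#' @param min_size smallest component size counted as a cluster (default 2).
#' @return a \linkS4class{GeccoFit}.
#' @export
fitForClusters <- function(views, graph, n_clusters, alpha = 0, zeta = NULL,
                           gamma_hint = NULL, min_size = 2L, ...) {
  views <- .as_view_list(views)
  if (is.null(gamma_hint))
    gamma_hint <- gammaMax(views, graph, alpha = alpha, zeta = zeta, ...) / 8
  .gamma_for_clusters(views, graph, n_clusters, alpha, zeta, gamma_hint,
                      min_size = min_size, ...)
}

#' Adaptive fitting with data-driven feature weights
#'
#' The four-step adaptive scheme: (1) fit with feature penalty alpha = 1 and
#' unit feature weights over a fusion path; (2) take the fit at the desired
#' number of clusters as the initial estimate; (3) reweight features as
#' \code{zeta_j = 1 / (||U_.j - center_j|| + 0.01)} (noise features, already
#' shrunk near their centers, receive large penalties) and rebuild the
#' fusion weights from the feature-importance weighted Gower distance;
#' (4) refit with the adaptive weights, searching gamma (and alpha when a
#' feature target is given) for the desired cluster and feature counts,
#' preferring the smallest penalties among exact matches.
#'
#' @inheritParams ccFit
#' @param n_clusters target number of clusters (assumed known).
#' @param n_features optional target for the total number of selected
#'   features (pooled over views); when NULL, alpha stays at the initial
#'   level.
#' @param kappa,phi,scheme fusion-weight options.
#' @param alpha0 feature penalty level of the initial fit, on the
#'   natural scale (1 makes the unit-weight feature penalty at U = X
#'   comparable to the normalized null loss).
#' @param rounds number of reweight-and-refit rounds (default 2). The first
#'   round's estimate fixes the feature ranking; the second recomputes the
#'   feature weights and fusion distances from it, which matters when the
#'   initial fit carries little signal (noise-dominated views).
#' @return a \linkS4class{GeccoFit}; the initial estimate is attached as
#'   attribute \code{"initial"}.
#' @export
adaptiveFit <- function(views, n_clusters, n_features = NULL, kappa = 5,
                        phi = NULL, scheme = c("sne", "gaussian"),
                        alpha0 = 1, rounds = 2L, ...) {
  scheme <- match.arg(scheme)
  views <- .as_view_list(views)
  graph0 <- ccWeights(views, kappa, phi, scheme)
  # put alpha0 = 1 on a natural scale: the unit-weight feature penalty
  # evaluated at U = X is made comparable to the normalized null loss (one
  # per view), so the initial with-penalty fit shrinks noticeably without
  # collapsing every feature
  feat_scale <- length(views) /
    sum(vapply(views, function(v)
      sum(sqrt(colSums((v@X - .center_matrix(v))^2))), 1))
  alpha0 <- alpha0 * feat_scale
  # Initial partition for the feature reweighting: Ward clustering on the
  # same distances that drive the fusion weights. On noise-dominated views
  # the unweighted convex path has no intermediate structure (it collapses
  # from all-singletons to one cluster, as the reference results for plain
  # integrative fits in high dimensions also show), so a cheap consistent
  # clustering of the fusion distances seeds the adaptive weights, in the
  # spirit of adaptive-lasso initialization from an unpenalized estimator.
  # Every subsequent (and the reported) fit is a convex clustering fit.
  Dm0 <- gowerDistance(views)
  labels_est <- stats::cutree(stats::hclust(stats::as.dist(Dm0), "ward.D2"),
                              n_clusters)
  # sharpen the initial partition to self-consistency: re-derive the feature
  # importances from the current partition and re-cluster on the
  # importance-weighted distances. When most features are noise a single
  # unweighted pass is dominated by them; two reweighted passes suppress the
  # noise mass without any model fitting (all fits below remain convex
  # clustering fits).
  for (s in 1:2) {
    U_s <- lapply(views, function(vv) .partition_centers(vv, labels_est))
    Dm_s <- suppressWarnings(weightedGowerUpdate(views, U_s))
    if (max(Dm_s) <= 0) break
    labels_est <- stats::cutree(
      stats::hclust(stats::as.dist(Dm_s), "ward.D2"), n_clusters)
  }
  init <- NULL
  # step 3: adaptive feature weights and weighted Gower fusion weights
  eps <- 0.01
  est <- NULL
  zeta <- NULL
  graph1 <- graph0
  hint <- 0
  alpha_prev <- alpha0
  cands <- vector("list", rounds)
  for (round in seq_len(rounds)) {
    # importance of a feature = deviation of the estimate's cluster centers
    # from the loss-specific center, evaluated at the partition's own
    # centers (the raw ADMM centroids contract towards the global center as
    # gamma grows, which would wash out the ranking)
    U_est <- lapply(seq_along(views), function(k)
      .partition_centers(views[[k]], labels_est))
    imp <- lapply(seq_along(views), function(k)
      sqrt(colSums((U_est[[k]] - .center_matrix(views[[k]]))^2)))
    # a view whose features are all exactly shrunk carries no ranking
    # information; fall back to the gamma -> 0 limit U = link(X), whose
    # column deviations still rank features
    for (k in seq_along(views)) {
      v <- views[[k]]
      if (max(imp[[k]]) <= 1e-12) {
        warning(warningCondition(
          sprintf("view %d: estimate shrank all features; using data-based importances", k),
          class = c("icclust_allshrunk", "icclust_warning")))
        U_est[[k]] <- .param_image(v)
        imp[[k]] <- sqrt(colSums((U_est[[k]] - .center_matrix(v))^2))
      }
    }
    # eps regularizes the smallest deviations at 1% of the view's largest
    # (the fitted deviations shrink with gamma, so a fixed eps would wash
    # out the ranking). Each weight also carries the column's own stationary
    # scale g_j = pi_k * ||grad_j l_k at the centers|| so that a common
    # alpha implies a uniform relative-importance cutoff across views:
    # without it the per-column kill threshold scales like pi_k ~ 1/p_k and
    # small views are systematically under-shrunk. zeta is rescaled to a
    # global minimum of 1 (a pure reparametrization of alpha).
    zeta <- lapply(seq_along(views), function(k) {
      v <- imp[[k]]
      e <- eps * max(v)
      w <- views[[k]]
      gn <- if (w@loss@smooth) {
        g <- gradLoss(w@loss, w@X, .center_matrix(w))
        w@weight * sqrt(colSums(g^2))
      } else rep(w@weight * sqrt(nrow(w@X)), ncol(w@X))
      gn * (max(v) + e) / (v + e)
    })
    zmin <- min(unlist(lapply(zeta, min)))
    zeta <- lapply(zeta, function(z) z / zmin)
    Dhat <- weightedGowerUpdate(views, U_est)
    graph1 <- kernelWeights(Dhat, kappa = kappa, phi = NULL, scheme = scheme)
    est <- if (is.null(n_features)) {
      .gamma_for_clusters(views, graph1, n_clusters, alpha = alpha0,
                          zeta = zeta, hint = hint, ...)
    } else if (round < rounds) {
      # intermediate rounds: calibrate alpha to the feature target at the
      # current gamma (cheap bisection), then look for cluster structure at
      # that alpha -- the fused estimate is what differentiates features
      # whose loss alone cannot rank them
      cal <- .calibrate_alpha(views, graph1, zeta, hint, n_features,
                              alpha_start = alpha_prev, ...)
      .gamma_for_clusters(views, graph1, n_clusters, alpha = cal@alpha,
                          zeta = zeta, hint = max(cal@gamma, hint),
                          max_steps = 20L, ...)
    } else {
      .search_alpha(views, graph1, n_clusters, n_features, zeta, hint,
                    alpha0 = alpha_prev, ...)
    }
    cands[[round]] <- est
    labels_est <- est@labels
    hint <- est@gamma
    alpha_prev <- max(est@alpha, alpha0)
    if (round == 1L) init <- est
  }
  # guard against a late round degrading the estimate: keep the best-ranked
  # candidate (feature-count match, cluster-count match, fewest stragglers;
  # later rounds win ties)
  rank_fit <- function(f) {
    tab <- table(f@labels)
    c(if (is.null(n_features)) 0 else abs(f@nFeatures - n_features),
      abs(sum(tab >= 2L) - n_clusters), sum(tab[tab < 2L]),
      .partition_loss(views, f@labels))
  }
  final <- est
  for (f in cands) {
    a <- rank_fit(f); b <- rank_fit(final)
    cmp <- which(a != b)
    if (length(cmp) && a[cmp[1L]] < b[cmp[1L]]) final <- f
  }
  attr(final, "initial") <- init
  attr(final, "zeta") <- zeta
  attr(final, "graph") <- graph1
  final
}

#' @rdname adaptiveFit
#' @param X single-view data matrix.
#' @param loss loss family for the single-view form.
#' @export
adaptiveGeccoPlus <- function(X, loss, n_clusters, n_features = NULL,
                              kappa = 5, phi = NULL, scheme = "sne", ...) {
  v <- if (is(X, "DataView")) X else dataView(X, loss)
  adaptiveFit(list(v), n_clusters, n_features, kappa, phi, scheme, ...)
}

#' @rdname adaptiveFit
#' @export
adaptiveIgeccoPlus <- function(views, n_clusters, n_features = NULL,
                               kappa = 5, phi = NULL, scheme = "sne", ...) {
  adaptiveFit(views, n_clusters, n_features, kappa, phi, scheme, ...)
}

#' Fit with target cluster and feature counts
#'
#' Joint search over (gamma, alpha): bisection on log-alpha for the target
#' number of selected features (pooled over views), re-targeting gamma to
#' the cluster count at every alpha; among exact matches the fit with the
#' fewest stragglers, tightest partition and smallest penalties is
#' returned. This is the non-adaptive oracle-count fit (unit feature
#' weights unless \code{zeta} is given); \code{\link{adaptiveFit}} uses the
#' same search with data-driven weights.
#'
#' @inheritParams ccFit
#' @param n_clusters,n_features target counts.
#' @param alpha_start starting feature penalty level for the search.
#' @return a \linkS4class{GeccoFit}.
#' @export
fitForTargets <- function(views, graph, n_clusters, n_features,
                          zeta = NULL, alpha_start = NULL,
                          gamma_hint = NULL, ...) {
  views <- .as_view_list(views)
  if (is.null(zeta)) zeta <- .default_zeta(views)
  if (is.null(alpha_start))
    alpha_start <- length(views) /
      sum(vapply(views, function(v)
        sum(sqrt(colSums((v@X - .center_matrix(v))^2))), 1))
  if (is.null(gamma_hint))
    gamma_hint <- gammaMax(views, graph, alpha = 0, gamma0 = 0.02,
                           max_iter = 1500L) / 8
  .search_alpha(views, graph, n_clusters, n_features, zeta, gamma_hint,
                alpha0 = alpha_start, ...)
}

# Bisection on log-alpha at a fixed gamma until the fit selects (about) the
# target number of features; used for the intermediate reweighting rounds of
# the adaptive scheme, where only the feature ranking of the estimate
# matters. Feature counts are non-increasing in alpha up to solver
# tolerance.
.calibrate_alpha <- function(views, graph, zeta, gamma, target_f,
                             alpha_start, max_expand = 14L,
                             bisect_steps = 12L, ...) {
  fit1 <- function(a, warm) ccFit(views, graph, gamma = gamma, alpha = a,
                                  zeta = zeta, warm = warm, ...)
  best <- f <- fit1(alpha_start, NULL)
  consider <- function(f) {
    if (abs(f@nFeatures - target_f) < abs(best@nFeatures - target_f) ||
        (abs(f@nFeatures - target_f) == abs(best@nFeatures - target_f) &&
         f@alpha < best@alpha))
      best <<- f
  }
  a_lo <- a_hi <- alpha_start
  if (f@nFeatures > target_f) {
    for (i in seq_len(max_expand)) {
      a_hi <- a_hi * 2
      f <- fit1(a_hi, f)
      consider(f)
      if (f@nFeatures <= target_f) break
    }
    a_lo <- a_hi / 2
  } else {
    for (i in seq_len(max_expand)) {
      a_lo <- a_lo / 2
      f <- fit1(a_lo, f)
      consider(f)
      if (f@nFeatures >= target_f) break
    }
    a_hi <- a_lo * 2
  }
  for (i in seq_len(bisect_steps)) {
    if (best@nFeatures == target_f) break
    a <- sqrt(a_lo * a_hi)
    f <- fit1(a, f)
    consider(f)
    if (f@nFeatures > target_f) a_lo <- a else a_hi <- a
  }
  best
}

# Joint (gamma, alpha) search: bisection on log-alpha for the target pooled
# feature count, re-targeting gamma to the cluster count at every alpha.
# Feature counts decrease in alpha (up to solver tolerance), making
# bisection appropriate; among exact matches the smallest alpha (and within
# it the smallest gamma) is kept.
.search_alpha <- function(views, graph, target_k, target_f, zeta, hint,
                          alpha0 = 1, max_expand = 10L, bisect_steps = 8L,
                          ...) {
  total_p <- sum(vapply(views, function(v) ncol(v@X), 1L))
  target_f <- min(target_f, total_p)
  eval_alpha <- function(a, hint, warm) {
    .gamma_for_clusters(views, graph, target_k, alpha = a, zeta = zeta,
                        hint = hint, warm = warm, max_steps = 16L,
                        refine_steps = 5L, ...)
  }
  done <- function() !is.null(best) && best@nFeatures == target_f &&
    .bulk_count(best, 2L) == target_k && strag(best) == 0L
  best <- NULL
  # preference order: feature-count match, then cluster-count match, then
  # the fewest unassigned stragglers, then the tightest partition, then
  # the smallest penalties
  strag <- function(f) {
    tab <- table(f@labels)
    sum(tab[tab < 2L])
  }
  rank_of <- function(f) c(abs(f@nFeatures - target_f),
                           abs(.bulk_count(f, 2L) - target_k),
                           strag(f), .partition_loss(views, f@labels),
                           f@alpha, f@gamma)
  consider <- function(f) {
    if (is.null(best)) { best <<- f; return() }
    a <- rank_of(f); b <- rank_of(best)
    for (i in seq_along(a)) {
      if (a[i] < b[i]) { best <<- f; return() }
      if (a[i] > b[i]) return()
    }
  }
  f_lo <- eval_alpha(alpha0, hint, NULL)   # low alpha: many features
  consider(f_lo)
  a_lo <- alpha0; a_hi <- alpha0
  f_hi <- f_lo
  if (f_lo@nFeatures > target_f) {
    for (i in seq_len(max_expand)) {
      if (done()) return(best)
      a_hi <- a_hi * 2
      f_hi <- eval_alpha(a_hi, f_hi@gamma, f_hi)
      consider(f_hi)
      if (f_hi@nFeatures <= target_f) break
    }
  } else {
    for (i in seq_len(max_expand)) {
      if (done()) return(best)
      a_lo <- a_lo / 2
      f_lo <- eval_alpha(a_lo, f_lo@gamma, f_lo)
      consider(f_lo)
      if (f_lo@nFeatures >= target_f) break
    }
  }
  if (!done()) {
    lo <- min(a_lo, a_hi); hi <- max(a_lo, a_hi)
    warm <- best
    for (i in seq_len(bisect_steps)) {
      if (hi / lo < 1.001 || done()) break
      a <- sqrt(lo * hi)
      f <- eval_alpha(a, warm@gamma, warm)
      consider(f)
      warm <- f
      if (f@nFeatures > target_f) lo <- a else hi <- a
    }
  }
  if (best@nFeatures != target_f)
    warning(sprintf(
      "no alpha found selecting exactly %d features; returning %d",
      target_f, best@nFeatures))
  best
}
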