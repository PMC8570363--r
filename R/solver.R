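# Solver layer: the production one-step inexact multi-block ADMM (compiled),
# a pure-R engine covering every loss family (used as the reference and for
# families without a compiled kernel), and cluster / feature extraction.

.fam_codes <- c(euclidean = 0L, poisson_ll = 1L, poisson_dev = 2L,
                bernoulli_ll = 3L, binomial_dev = 4L, negbin_ll = 5L,
                negbin_dev = 6L, manhattan = 10L, chebychev = 11L)

.cpp_supported <- function(views) {
  all(vapply(views, function(v) {
    f <- v@loss@family
    f %in% names(.fam_codes) ||
      (f == "minkowski" && isTRUE(v@loss@params$q == 1))
  }, TRUE))
}

.fam_code_of <- function(loss) {
  f <- loss@family
  if (f == "minkowski" && isTRUE(loss@params$q == 1)) f <- "manhattan"
  .fam_codes[[f]]
}

.default_zeta <- function(views)
  lapply(views, function(v) rep(1, ncol(v@X)))

#' Fit the convex clustering problem at one (gamma, alpha)
#'
#' Runs the multi-block ADMM with inexact one-step sub-problem updates:
#' per outer iteration each smooth view takes a single backtracked
#' proximal-gradient step per column, each non-differentiable distance view a
#' single sweep of the four-variable splitting with
#' \code{M = (D'D + 2I)^(-1)}, followed by the joint fusion-variable
#' block soft-threshold and dual ascent. Being convex, the attained objective
#' is initialization-independent (warm starts change speed, not the answer).
#'
#' @param views a \linkS4class{DataView} or list of views sharing rows.
#' @param graph a \linkS4class{FusionGraph} over the samples.
#' @param gamma nonnegative fusion penalty level.
#' @param alpha nonnegative feature penalty level.
#' @param zeta optional list of per-view nonnegative feature weights
#'   (default all 1).
#' @param rho augmented-Lagrangian parameter (> 0).
#' @param tol relative primal/dual residual tolerance.
#' @param max_iter iteration cap; reaching it flags \code{converged = FALSE}.
#' @param warm optional \linkS4class{GeccoFit} (or its \code{state} list) to
#'   warm-start from.
#' @param engine \code{"auto"} (compiled kernel when the loss families allow,
#'   else the R engine), \code{"cpp"} or \code{"r"}.
#' @param cluster_tol relative tolerance for declaring centroid rows fused
#'   and feature columns shrunk.
#' @return a \linkS4class{GeccoFit}.
#' @export
ccFit <- function(views, graph, gamma, alpha = 0, zeta = NULL, rho = 1,
                  tol = 1e-5, max_iter = 10000L, warm = NULL,
                  engine = c("auto", "cpp", "r"), cluster_tol = 1e-6) {
  engine <- match.arg(engine)
  views <- .as_view_list(views)
  if (is.null(zeta)) zeta <- .default_zeta(views)
  if (nrow(graph@edges) == 0L && gamma > 0)
    .stop("icclust_contract", "empty fusion graph requires gamma = 0")
  st <- .run_admm(views, graph, gamma, alpha, zeta, rho, tol, max_iter,
                  warm = .warm_state(warm), inner_steps = 1L,
                  inner_tol = 1e-9, engine = engine)
  .make_fit(st, views, graph, gamma, alpha, cluster_tol)
}

#' Reference full multi-block ADMM
#'
#' Baseline solver in which each per-view sub-problem is iterated to an inner
#' tolerance at every outer step (iterated proximal-gradient for smooth
#' losses, iterated four-variable splitting for non-differentiable distance
#' losses). Slower than \code{\link{ccFit}} but reaches the same objective;
#' used to verify the one-step updates.
#'
#' @inheritParams ccFit
#' @param inner_steps cap on inner iterations per outer step.
#' @param inner_tol inner relative-change tolerance.
#' @return a \linkS4class{GeccoFit}.
#' @export
fitFullADMM <- function(views, graph, gamma, alpha = 0, zeta = NULL,
                        rho = 1, tol = 1e-5, max_iter = 2000L,
                        inner_steps = 100L, inner_tol = 1e-9,
                        engine = c("auto", "cpp", "r"), cluster_tol = 1e-6) {
  engine <- match.arg(engine)
  views <- .as_view_list(views)
  if (is.null(zeta)) zeta <- .default_zeta(views)
  st <- .run_admm(views, graph, gamma, alpha, zeta, rho, tol, max_iter,
                  warm = NULL, inner_steps = as.integer(inner_steps),
                  inner_tol = inner_tol, engine = engine)
  .make_fit(st, views, graph, gamma, alpha, cluster_tol)
}

.warm_state <- function(warm) {
  if (is.null(warm)) return(NULL)
  if (is(warm, "GeccoFit")) warm@state else warm
}

.run_admm <- function(views, graph, gamma, alpha, zeta, rho, tol, max_iter,
                      warm, inner_steps, inner_tol, engine) {
  use_cpp <- switch(engine,
    cpp = TRUE, r = FALSE, auto = .cpp_supported(views))
  if (use_cpp && !.cpp_supported(views))
    .stop("icclust_unsupported",
          "compiled engine does not support these loss families")
  if (use_cpp) {
    fams <- vapply(views, function(v) .fam_code_of(v@loss), 1L)
    thetas <- vapply(views, function(v) {
      th <- v@loss@params$theta
      if (is.null(th)) 0 else th
    }, 1)
    init <- if (is.null(warm)) list() else warm
    res <- .cc_admm_cpp(lapply(views, function(v) v@X), fams, thetas,
                        vapply(views, function(v) v@weight, 1),
                        lapply(views, function(v) v@center), zeta,
                        graph@edges - 1L, graph@weights, gamma, alpha, rho,
                        as.integer(max_iter), tol, inner_steps, inner_tol,
                        init)
  } else {
    res <- .r_admm(views, graph, gamma, alpha, zeta, rho, tol,
                   as.integer(max_iter), warm, inner_steps, inner_tol)
  }
  # single source of truth for the reported objective (the compiled kernel
  # does not evaluate rowwise non-smooth losses)
  res$objective <- .cc_objective(views, res$U, graph, gamma, alpha, zeta)
  res$gamma <- gamma; res$alpha <- alpha
  if (is.null(res$rho)) res$rho <- rho
  res
}

.make_fit <- function(st, views, graph, gamma, alpha, cluster_tol) {
  labels <- extractClusters(st, graph, tol = cluster_tol)
  selected <- extractFeatures(st, views, tol = cluster_tol)
  new("GeccoFit",
      U = st$U, V = as.matrix(st$V), labels = labels, selected = selected,
      objective = st$objective, gamma = gamma, alpha = alpha,
      nClusters = length(unique(labels)),
      nFeatures = sum(vapply(selected, sum, 1L)),
      converged = isTRUE(st$converged), iter = as.integer(st$iter),
      residuals = c(primal = st$primal, dual = st$dual),
      state = st[c("U", "V", "Lambda", "Z", "R", "Psi", "N", "rho")])
}

# ---- pure-R engine (all loss families, incl. minkowski / mahalanobis) ----

.r_admm <- function(views, graph, gamma, alpha, zeta, rho, tol, max_iter,
                    warm, inner_steps, inner_tol) {
  K <- length(views)
  n <- nrow(views[[1L]]@X)
  pk <- vapply(views, function(v) ncol(v@X), 1L)
  E <- graph@edges; m <- nrow(E); w <- graph@weights
  Dmul <- function(U) if (m) U[E[, 1], , drop = FALSE] -
                              U[E[, 2], , drop = FALSE]
                      else matrix(0, 0, ncol(U))
  Dtmul <- function(A) {
    R <- matrix(0, n, ncol(A))
    if (m) {
      for (l in seq_len(m)) {
        R[E[l, 1], ] <- R[E[l, 1], ] + A[l, ]
        R[E[l, 2], ] <- R[E[l, 2], ] - A[l, ]
      }
    }
    R
  }
  smooth_k <- vapply(views, function(v) v@loss@smooth, TRUE)
  # (D'D + 2I) Cholesky for non-smooth views
  if (any(!smooth_k)) {
    DtD <- matrix(0, n, n)
    for (l in seq_len(m)) {
      i <- E[l, 1]; j <- E[l, 2]
      DtD[i, i] <- DtD[i, i] + 1; DtD[j, j] <- DtD[j, j] + 1
      DtD[i, j] <- DtD[i, j] - 1; DtD[j, i] <- DtD[j, i] - 1
    }
    Mch <- chol(DtD + 2 * diag(n))
  }
  off <- cumsum(c(0L, pk))
  U <- Lam <- Z <- Rv <- Psi <- N <- vector("list", K)
  V <- matrix(0, m, sum(pk))
  if (!is.null(warm)) {
    U <- warm$U; Lam <- warm$Lambda; V <- as.matrix(warm$V)
    Z <- warm$Z; Rv <- warm$R; Psi <- warm$Psi; N <- warm$N
    if (!is.null(warm$rho) && warm$rho > 1e-6 && warm$rho < 1e8)
      rho <- warm$rho
  }
  for (k in seq_len(K)) {
    v <- views[[k]]
    if (is.null(U[[k]])) {
      U[[k]] <- v@X
      if (v@loss@family %in% c("poisson_dev", "negbin_dev"))
        U[[k]] <- pmax(U[[k]], 1e-3)
      if (v@loss@family == "binomial_dev")
        U[[k]] <- pmin(pmax(U[[k]], 1e-3), 1 - 1e-3)
      Lam[[k]] <- matrix(0, m, pk[k])
    }
    if (!smooth_k[k] && is.null(Z[[k]])) {
      Z[[k]] <- matrix(0, n, pk[k])
      Rv[[k]] <- U[[k]] - .center_matrix(v)
      Psi[[k]] <- matrix(0, n, pk[k])
      N[[k]] <- matrix(0, n, pk[k])
    }
  }
  steps <- rep(1, K)
  rel_p <- rel_d <- Inf; it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    Vold <- V; Zold <- Z; Rold <- Rv
    for (k in seq_len(K)) {
      v <- views[[k]]
      cols <- (off[k] + 1L):off[k + 1L]
      Vk <- V[, cols, drop = FALSE]
      Ctr <- .center_matrix(v)
      if (smooth_k[k]) {
        for (s_i in seq_len(inner_steps)) {
          A <- Dmul(U[[k]]) - Vk + Lam[[k]]
          G <- v@weight * gradLoss(v@loss, v@X, U[[k]]) + rho * Dtmul(A)
          g0 <- v@weight * evalLoss(v@loss, v@X, U[[k]]) +
                rho / 2 * sum(A^2)
          s <- steps[k]
          repeat {
            cand <- proxShiftedCols(U[[k]] - s * G, v@center,
                                    s * alpha * zeta[[k]])
            d <- cand - U[[k]]
            dn <- sum(d^2)
            if (dn == 0) break
            Ac <- Dmul(cand) - Vk + Lam[[k]]
            lc <- tryCatch(v@weight * evalLoss(v@loss, v@X, cand) +
                           rho / 2 * sum(Ac^2), error = function(e) Inf)
            if (is.finite(lc) && lc <= g0 + sum(G * d) + dn / (2 * s) + 1e-12)
              break
            s <- s / 2
            if (s < 1e-13)
              .stop("icclust_step_collapse", "backtracking step collapse")
          }
          steps[k] <- min(s * 1.25, 1)
          rel <- sqrt(sum((cand - U[[k]])^2)) /
                 (1 + sqrt(sum(U[[k]]^2)))
          U[[k]] <- cand
          if (inner_steps > 1L && rel < inner_tol) break
        }
      } else {
        for (s_i in seq_len(inner_steps)) {
          B <- Dtmul(Vk - Lam[[k]]) + Ctr + Rv[[k]] - N[[k]] +
               v@X - Z[[k]] + Psi[[k]]
          Uprev <- U[[k]]
          U[[k]] <- backsolve(Mch, forwardsolve(t(Mch), B))
          Z[[k]] <- proxLoss(v@loss, v@X - U[[k]] + Psi[[k]],
                             v@weight / rho)
          RA <- U[[k]] - Ctr + N[[k]]
          Rv[[k]] <- proxShiftedCols(RA, rep(0, pk[k]),
                                     alpha * zeta[[k]] / rho)
          Psi[[k]] <- Psi[[k]] + v@X - U[[k]] - Z[[k]]
          N[[k]] <- N[[k]] + U[[k]] - Ctr - Rv[[k]]
          if (inner_steps > 1L &&
              sqrt(sum((U[[k]] - Uprev)^2)) /
                (1 + sqrt(sum(Uprev^2))) < inner_tol) break
        }
      }
    }
    DUs <- lapply(U, Dmul)
    if (m) {
      A <- do.call(cbind, DUs) +
           do.call(cbind, Lam)
      V <- proxRowGroups(A, gamma * w / rho)
    }
    pr2 <- du2 <- du_sc2 <- 0
    sc_p <- 0.01 * sqrt(sum(vapply(views, function(v) sum(v@X^2), 1))) +
            1e-12
    for (k in seq_len(K)) {
      cols <- (off[k] + 1L):off[k + 1L]
      Vk <- V[, cols, drop = FALSE]
      rk <- DUs[[k]] - Vk
      Lam[[k]] <- Lam[[k]] + rk
      pr2 <- pr2 + sum(rk^2)
      sc_p <- max(sc_p, sqrt(sum(DUs[[k]]^2)), sqrt(sum(Vk^2)))
      du2 <- du2 + sum((rho * Dtmul(Vk - Vold[, cols, drop = FALSE]))^2)
      du_sc2 <- du_sc2 + sum((rho * Dtmul(Lam[[k]]))^2)
      if (!smooth_k[k]) {
        v <- views[[k]]; Ctr <- .center_matrix(v)
        pr2 <- pr2 + sum((v@X - U[[k]] - Z[[k]])^2) +
               sum((U[[k]] - Ctr - Rv[[k]])^2)
        du2 <- du2 + sum((rho * (Z[[k]] - Zold[[k]]))^2) +
               sum((rho * (Rv[[k]] - Rold[[k]]))^2)
        du_sc2 <- du_sc2 + sum((rho * Psi[[k]])^2) + sum((rho * N[[k]])^2)
        sc_p <- max(sc_p, sqrt(sum(v@X^2)))
      }
    }
    rel_p <- sqrt(pr2) / sc_p
    du_floor <- 0.01 * sqrt(sum(vapply(views, function(v)
      (v@weight^2) * sum(v@X^2), 1))) + 1e-12
    rel_d <- sqrt(du2) / max(du_floor, sqrt(du_sc2))
    if (rel_p < tol && rel_d < tol) { converged <- TRUE; break }
    # residual balancing, mirroring the compiled kernel
    if (it %% 10L == 0L) {
      tau <- if (rel_p > 10 * rel_d) 2 else if (rel_d > 10 * rel_p) 0.5
             else 0
      if (tau != 0 && rho * tau > 1e-6 && rho * tau < 1e8) {
        rho <- rho * tau
        Lam <- lapply(Lam, function(M) M / tau)
        for (k in seq_len(K)) if (!smooth_k[k]) {
          Psi[[k]] <- Psi[[k]] / tau; N[[k]] <- N[[k]] / tau
        }
      }
    }
  }
  obj <- .cc_objective(views, U, graph, gamma, alpha, zeta)
  list(U = U, V = V, Lambda = Lam, Z = Z, R = Rv, Psi = Psi, N = N,
       objective = obj, iter = it, converged = converged,
       primal = rel_p, dual = rel_d)
}

# objective of the penalized problem at centroids U
.cc_objective <- function(views, U, graph, gamma, alpha, zeta = NULL) {
  if (is.null(zeta)) zeta <- .default_zeta(views)
  obj <- 0
  for (k in seq_along(views)) {
    v <- views[[k]]
    obj <- obj + v@weight * evalLoss(v@loss, v@X, U[[k]])
    if (alpha > 0) {
      dev <- U[[k]] - .center_matrix(v)
      obj <- obj + alpha * sum(zeta[[k]] * sqrt(colSums(dev^2)))
    }
  }
  if (gamma > 0 && nrow(graph@edges)) {
    DU <- do.call(cbind, lapply(U, function(Uk)
      Uk[graph@edges[, 1], , drop = FALSE] -
      Uk[graph@edges[, 2], , drop = FALSE]))
    obj <- obj + gamma * sum(graph@weights * sqrt(rowSums(DU^2)))
  }
  obj
}

#' Extract cluster labels from a fitted state
#'
#' Samples i and i' share a cluster when their centroid rows coincide across
#' all views; operationally, every fusion edge whose stacked difference
#' variable has (numerically) zero norm is contracted, and clusters are the
#' connected components. Labels are deterministic: components are numbered by
#' their smallest member index.
#'
#' @param state a \linkS4class{GeccoFit} or solver state list with \code{V}.
#' @param graph the \linkS4class{FusionGraph} used in the fit.
#' @param tol relative fusion tolerance.
#' @return integer vector of labels in 1..nClusters.
#' @export
extractClusters <- function(state, graph, tol = 1e-6) {
  V <- if (is(state, "GeccoFit")) state@V else as.matrix(state$V)
  U <- if (is(state, "GeccoFit")) state@U else state$U
  n <- graph@n
  if (nrow(graph@edges) == 0L) return(seq_len(n))
  rn <- sqrt(rowSums(V^2))
  # threshold relative to both the largest difference and the centroid row
  # scale, so that numerically-zero V patterns in fully fused regimes do
  # not fragment into spurious clusters
  u_scale <- sqrt(mean(rowSums(do.call(cbind, U)^2)))
  fused <- rn <= tol * max(1, max(rn), u_scale)
  g <- igraph::graph_from_edgelist(graph@edges[fused, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - length(igraph::V(g))))
  memb <- igraph::components(g)$membership
  first <- vapply(split(seq_len(n), memb), min, 1L)
  as.integer(match(memb, names(sort(first))))
}

#' Extract selected-feature masks
#'
#' A feature is selected when its centroid column is not shrunk to the
#' loss-specific center. Smooth views read this off \code{U} (whose prox
#' update collapses columns exactly); non-smooth views read the splitting
#' variable \code{R} which carries the exact zeros.
#'
#' @param state a \linkS4class{GeccoFit} or solver state list.
#' @param views the list of \linkS4class{DataView} used in the fit.
#' @param tol relative shrinkage tolerance.
#' @return list of logical masks, one per view.
#' @export
extractFeatures <- function(state, views, tol = 1e-6) {
  views <- .as_view_list(views)
  U <- if (is(state, "GeccoFit")) state@U else state$U
  Rv <- if (is(state, "GeccoFit")) state@state$R else state$R
  lapply(seq_along(views), function(k) {
    v <- views[[k]]
    dev <- if (!is.null(Rv) && length(Rv) >= k && !is.null(Rv[[k]]))
      Rv[[k]] else U[[k]] - .center_matrix(v)
    nrm <- sqrt(colSums(dev^2))
    x_scale <- max(sqrt(colSums((v@X - .center_matrix(v))^2)), 1)
    nrm > tol * max(1, max(nrm), x_scale)
  })
}
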