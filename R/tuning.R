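# Data-driven selection of (gamma, alpha) over a solved path.

#' BIC-style tuning over a regularization path
#'
#' Scores every grid point of a solved path with the information criterion
#' \code{2 * sum_k pi_k l_k(X^(k), U^(k)) + log(n) * df}, where the
#' effective degrees of freedom are the number of distinct cluster centroids
#' times the number of selected features (summed over views) - the standard
#' accounting for fused centroids and group-sparse columns. This is a
#' documented variant of an information criterion, not a reproduction of any
#' particular published formula.
#'
#' @param path a \linkS4class{GeccoPath}.
#' @param views the views the path was fitted on.
#' @return list with \code{gamma}, \code{alpha}, \code{fit} (the chosen
#'   \linkS4class{GeccoFit}), and \code{table} (a data.frame with the
#'   criterion and df per grid point).
#' @export
bicSelect <- function(path, views) {
  views <- .as_view_list(views)
  if (!length(path@fits))
    .stop("icclust_contract", "empty path")
  n <- nrow(views[[1L]]@X)
  score_one <- function(fit) {
    dev <- 2 * sum(vapply(seq_along(views), function(k)
      views[[k]]@weight * evalLoss(views[[k]]@loss, views[[k]]@X,
                                   fit@U[[k]]), 1))
    df <- fit@nClusters * fit@nFeatures
    c(dev = dev, df = df, bic = dev + log(n) * df)
  }
  sc <- t(vapply(path@fits, score_one, c(dev = 1, df = 1, bic = 1)))
  tab <- cbind(path@grid[, c("gamma", "alpha", "nClusters", "nFeatures")],
               as.data.frame(sc))
  i <- which.min(tab$bic)
  list(gamma = tab$gamma[i], alpha = tab$alpha[i], fit = path@fits[[i]],
       table = tab)
}

#' Subsampling co-clustering stability scaffold
#'
#' Repeatedly fits on random half-samples at fixed (gamma, alpha) and counts
#' how often each sample pair is co-clustered. Intended as a building block
#' for stability-based tuning; off by default in all pipelines because of
#' its cost.
#'
#' @inheritParams ccFit
#' @param B number of subsamples.
#' @param frac row fraction per subsample.
#' @return symmetric matrix of co-clustering frequencies (NA for pairs never
#'   subsampled together).
#' @export
stabilityCoCluster <- function(views, graph, gamma, alpha = 0, B = 20L,
                               frac = 0.5, ...) {
  views <- .as_view_list(views)
  n <- nrow(views[[1L]]@X)
  co <- tog <- matrix(0, n, n)
  for (b in seq_len(B)) {
    idx <- sort(sample.int(n, floor(frac * n)))
    sub <- lapply(views, function(v)
      dataView(v@X[idx, , drop = FALSE], v@loss))
    gsub <- ccWeights(sub, kappa = min(5L, length(idx) - 1L))
    fit <- ccFit(sub, gsub, gamma = gamma, alpha = alpha, ...)
    lab <- fit@labels
    same <- outer(lab, lab, "==")
    co[idx, idx] <- co[idx, idx] + same
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  out <- co / tog
  out[tog == 0] <- NA
  diag(out) <- 1
  out
}
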