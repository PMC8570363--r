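# Proximal operators of the two structured penalties: the row-group fusion
# penalty on stacked centroid differences and the shifted column group lasso.

#' Rowwise block soft-thresholding
#'
#' Proximal operator of the weighted group penalty \code{sum_l t_l ||A_l.||_2}:
#' each row is scaled by \code{max(0, 1 - t_l / ||A_l.||_2)}, giving exact
#' zero rows when the norm falls below the threshold. This is the fusion
#' variable update of the ADMM.
#'
#' @param A numeric matrix.
#' @param t nonnegative threshold, scalar or one per row.
#' @return matrix of the same shape.
#' @examples
#' proxRowGroups(matrix(c(3, 4), 1), 2.5)  # (1.5, 2)
#' @export
proxRowGroups <- function(A, t) {
  A <- as.matrix(A)
  if (any(t < 0)) .stop("icclust_contract", "thresholds must be >= 0")
  nrm <- sqrt(rowSums(A^2))
  scl <- pmax(0, 1 - t / pmax(nrm, .Machine$double.eps))
  scl[nrm == 0] <- 0
  A * scl
}

#' Shifted columnwise block soft-thresholding
#'
#' Proximal operator of the shifted group-lasso feature penalty
#' \code{sum_j t_j ||U_.j - center_j 1||_2}: each column is shrunk towards its
#' loss-specific center, collapsing exactly onto it when
#' \code{||U_.j - center_j 1||_2 <= t_j} (the feature is then unselected).
#'
#' @param U numeric matrix.
#' @param centers numeric vector of length \code{ncol(U)}.
#' @param t nonnegative threshold, scalar or one per column.
#' @return matrix of the same shape.
#' @export
proxShiftedCols <- function(U, centers, t) {
  U <- as.matrix(U)
  if (length(centers) != ncol(U))
    .stop("icclust_contract", "one center per column required")
  if (any(t < 0)) .stop("icclust_contract", "thresholds must be >= 0")
  Ctr <- matrix(centers, nrow(U), ncol(U), byrow = TRUE)
  Z <- U - Ctr
  nrm <- sqrt(colSums(Z^2))
  scl <- pmax(0, 1 - t / pmax(nrm, .Machine$double.eps))
  scl[nrm == 0] <- 0
  Ctr + sweep(Z, 2L, scl, "*")
}
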