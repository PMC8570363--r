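# Clustering and feature-selection accuracy metrics.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie form,
#' computed from the contingency table): 1 for identical partitions up to
#' relabeling, around 0 for random agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar in (-1, 1].
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    .stop("icclust_contract", "labels must have equal length >= 2")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  nC2 <- choose2(length(a))
  expected <- sum_a * sum_b / nC2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

#' Feature-selection F1 score
#'
#' F1 = 2PR / (P + R) of a selected-feature mask against the true
#' informative mask; defined as 0 when nothing is selected. Lists of masks
#' (one per view) are pooled across views before computing precision and
#' recall ("overall" multi-view F1).
#'
#' @param selected logical mask or list of per-view masks.
#' @param truth logical mask or list matching \code{selected}.
#' @return scalar in [0, 1].
#' @examples
#' featureF1(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE)) # 0.5
#' @export
featureF1 <- function(selected, truth) {
  selected <- as.logical(unlist(selected))
  truth <- as.logical(unlist(truth))
  if (length(selected) != length(truth))
    .stop("icclust_contract", "masks must have equal length")
  if (!any(truth))
    .stop("icclust_undefined_metric", "truth mask has no positives")
  tp <- sum(selected & truth)
  if (sum(selected) == 0L || tp == 0L) return(0)
  P <- tp / sum(selected)
  R <- tp / sum(truth)
  2 * P * R / (P + R)
}

#' Clustering and feature-selection report
#'
#' @param fit a \linkS4class{GeccoFit}.
#' @param labels true cluster labels.
#' @param informative optional list of true informative-feature masks.
#' @return list with \code{ari} and, when \code{informative} is given,
#'   overall and per-view \code{f1}, \code{precision} and \code{recall}.
#' @export
metricReport <- function(fit, labels, informative = NULL) {
  out <- list(ari = adjustedRandIndex(fit@labels, labels))
  if (!is.null(informative)) {
    sel <- fit@selected
    pr <- function(s, t) {
      tp <- sum(s & t)
      c(precision = if (sum(s)) tp / sum(s) else 0,
        recall = tp / sum(t))
    }
    out$f1 <- featureF1(sel, informative)
    out$per_view <- lapply(seq_along(sel), function(k) {
      c(f1 = featureF1(sel[[k]], informative[[k]]),
        pr(sel[[k]], informative[[k]]))
    })
  }
  out
}
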