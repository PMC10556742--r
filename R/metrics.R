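#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted half; equals the area under the ROC curve and is invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) outcome labels; both classes required.
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(.9, .8, .3, .2), c(1, 1, 0, 0))
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-sum `AP = sum_k (R_k - R_{k-1}) P_k` over descending-score
#' thresholds, with tied scores collapsed into one threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AP in (0, 1].
#' @export
averagePrecision <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1L)
  if (np == 0L) stop("AP undefined without positives")
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]; s <- scores[o]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  rec <- tp / np
  keep <- c(s[-1] != s[-length(s)], TRUE)   # distinct thresholds only
  sum(diff(c(0, rec[keep])) * prec[keep])
}
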