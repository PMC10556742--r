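## canonical "lo\rhi" keys for unordered pairs
pairKeys <- function(m) {
  if (!nrow(m)) return(character())
  paste0(pmin(m[, 1], m[, 2]), "\r", pmax(m[, 1], m[, 2]))
}

## coerce data.frame/matrix of two id columns to a sorted character matrix
asPairMatrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (!is.matrix(x)) stop("pairs must be a two-column matrix or data.frame")
  storage.mode(x) <- "character"
  m <- cbind(pmin(x[, 1], x[, 2]), pmax(x[, 1], x[, 2]))
  dimnames(m) <- NULL
  m[!duplicated(pairKeys(m)), , drop = FALSE]
}

#' Construct a positive/negative disease pair set
#'
#' @param positives,negatives two-column matrices or data.frames of
#'   disease ids (unordered pairs; deduplicated and endpoint-sorted).
#' @param graph optional [HetGraph-class]; if supplied, all ids must be
#'   DISEASE nodes.
#' @return a [PairSet-class].
#' @export
pairSet <- function(positives, negatives = NULL, graph = NULL) {
  pos <- asPairMatrix(positives)
  neg <- if (is.null(negatives) || !NROW(negatives))
    matrix(character(), 0, 2) else asPairMatrix(negatives)
  if (!is.null(graph)) {
    ids <- unique(c(pos, neg))
    bad <- setdiff(ids, diseaseIds(graph))
    if (length(bad))
      stop("pair ids are not DISEASE nodes in the graph: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  new("PairSet", positives = pos, negatives = neg)
}

setMethod("show", "PairSet", function(object) {
  cat(sprintf("PairSet: %d positive, %d negative disease pair(s)\n",
              nrow(object@positives), nrow(object@negatives)))
})

#' @describeIn PairSet positive pair matrix
#' @param x a `PairSet`
#' @export
positivePairs <- function(x) x@positives

#' @describeIn PairSet negative pair matrix
#' @export
negativePairs <- function(x) x@negatives

#' Score a disease pair
#'
#' Logistic sigmoid of the embedding dot product; symmetric in its
#' arguments and strictly increasing in the dot product.
#'
#' @param h1,h2 embedding vectors of equal dimension.
#' @return association probability in (0, 1).
#' @examples
#' scorePair(rep(1, 4) / 2, rep(1, 4) / 2)  # sigmoid(1)
#' @export
scorePair <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("embedding dimension mismatch")
  sigmoid(sum(h1 * h2))
}

#' Negative-sampling log-sigmoid loss
#'
#' `L = -sum(log sigmoid(h1.h2))` over positives minus
#' `sum(log sigmoid(-h1.h2))` over negatives, computed in a numerically
#' stable form; additive over pairs and non-negative.
#'
#' @param pairs a [PairSet-class] (positives must be non-empty).
#' @param embeddings matrix with one row per disease, rownames = ids.
#' @return scalar loss.
#' @export
computeLoss <- function(pairs, embeddings) {
  pos <- pairs@positives
  neg <- pairs@negatives
  if (!nrow(pos)) stop("empty positive set")
  miss <- setdiff(unique(c(pos, neg)), rownames(embeddings))
  if (length(miss))
    stop("pair members without embeddings: ",
         paste(utils::head(miss, 5), collapse = ", "))
  zp <- rowSums(embeddings[pos[, 1], , drop = FALSE] *
                  embeddings[pos[, 2], , drop = FALSE])
  L <- -sum(logSigmoid(zp))
  if (nrow(neg)) {
    zn <- rowSums(embeddings[neg[, 1], , drop = FALSE] *
                    embeddings[neg[, 2], , drop = FALSE])
    L <- L - sum(logSigmoid(-zn))
  }
  L
}

#' Sample negative disease pairs
#'
#' Uniform seeded sample (without replacement) of unordered disease pairs
#' outside the positive set and outside `exclude`.  If the requested size
#' exceeds the available complement, the whole complement is returned with
#' a warning.
#'
#' @param graph a [HetGraph-class].
#' @param positives positive pairs (matrix/data.frame of ids).
#' @param ratio negatives per positive.
#' @param seed RNG seed; same seed, same sample.
#' @param exclude optional additional pairs to avoid (e.g. held-out test
#'   negatives).
#' @param size optional explicit sample size overriding `ratio`.
#' @return character matrix of sampled pairs (n x 2).
#' @export
sampleNegatives <- function(graph, positives, ratio = 1, seed = 1L,
                            exclude = NULL, size = NULL) {
  ds <- sort(diseaseIds(graph))
  pos <- asPairMatrix(positives)
  want <- if (is.null(size)) ceiling(ratio * nrow(pos)) else size
  banned <- pairKeys(pos)
  if (!is.null(exclude) && NROW(exclude))
    banned <- union(banned, pairKeys(asPairMatrix(exclude)))
  nAll <- choose(length(ds), 2)
  nAvail <- nAll - length(banned)
  if (nAvail <= 0) {
    warning("no disease pairs left outside the excluded sets")
    return(matrix(character(), 0, 2))
  }
  if (want > nAvail)
    warning(sprintf(
      "requested %d negatives but only %d pairs available; returning all",
      want, nAvail))
  withSeed(derivedSeed(seed, 2L), {
    if (nAll <= 2e5) {
      allp <- t(utils::combn(ds, 2))
      free <- allp[!pairKeys(allp) %in% banned, , drop = FALSE]
      take <- min(want, nrow(free))
      free[sort(sample.int(nrow(free), take)), , drop = FALSE]
    } else {
      ## rejection sampling for large disease sets
      got <- character(0)
      out <- NULL
      while (length(got) < min(want, nAvail)) {
        i <- sample.int(length(ds), 4L * want, replace = TRUE)
        j <- sample.int(length(ds), 4L * want, replace = TRUE)
        ok <- i != j
        cand <- cbind(pmin(ds[i[ok]], ds[j[ok]]),
                      pmax(ds[i[ok]], ds[j[ok]]))
        k <- pairKeys(cand)
        new <- !duplicated(k) & !k %in% banned & !k %in% got
        cand <- cand[new, , drop = FALSE]
        got <- c(got, pairKeys(cand))
        out <- rbind(out, cand)
      }
      out[seq_len(min(want, nAvail)), , drop = FALSE]
    }
  })
}
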