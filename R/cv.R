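#' Repeated k-fold cross-validation of the link predictor
#'
#' The known positive pairs are split into `folds` seeded folds.  For each
#' fold the model is trained on the other folds' positives (training
#' negatives resampled each epoch from the non-positive complement,
#' excluding the held-out evaluation pairs) and evaluated on the held-out
#' positives against an equal-sized seeded sample of held-out negatives
#' disjoint from the training negatives.  The whole procedure is repeated
#' `repeats` times with distinct derived seeds; identical master seeds
#' reproduce the report exactly.
#'
#' Note the positive pair list links diseases, not disease-gene edges, so
#' held-out positives never have to be removed from the graph: the graph
#' layers and the supervision signal are disjoint by construction.
#'
#' @param graph a [HetGraph-class].
#' @param positives known disease-association pairs.
#' @param config from [embedConfig()].
#' @param train from [trainConfig()]; its seed is overridden per fold.
#' @param folds number of folds (positives must be at least this many).
#' @param repeats independent repetitions averaged in the report.
#' @param seed master seed.
#' @param schemaIds meta-path schemas for the embedding.
#' @return a [CVReport-class].
#' @export
crossValidate <- function(graph, positives, config = embedConfig(),
                          train = trainConfig(), folds = 10L, repeats = 10L,
                          seed = 1L,
                          schemaIds = c("M1", "M2", "M3", "M4")) {
  pos <- asPairMatrix(positives)
  n <- nrow(pos)
  if (n < folds) stop("need at least as many positives as folds")
  res <- list()
  for (r in seq_len(repeats)) {
    repSeed <- derivedSeed(seed, 100L * r)
    fa <- withSeed(repSeed, sample(rep(seq_len(folds), length.out = n)))
    for (f in seq_len(folds)) {
      testPos <- pos[fa == f, , drop = FALSE]
      trainPos <- pos[fa != f, , drop = FALSE]
      if (!nrow(testPos)) stop("fold with zero positives")
      testNeg <- sampleNegatives(graph, pos, size = nrow(testPos),
                                 seed = derivedSeed(repSeed, 10L + f))
      tcf <- train
      tcf$seed <- derivedSeed(repSeed, 500L + f)
      model <- trainModel(graph, trainPos, config = config, train = tcf,
                          schemaIds = schemaIds,
                          excludePairs = rbind(testNeg, testPos))
      emb <- diseaseEmbeddings(model)
      sc <- c(pairScores(emb, testPos), pairScores(emb, testNeg))
      lab <- rep(c(1L, 0L), c(nrow(testPos), nrow(testNeg)))
      res[[length(res) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        auc = aucScore(sc, lab), ap = averagePrecision(sc, lab))
    }
  }
  new("CVReport", results = do.call(rbind, res), folds = folds,
      repeats = repeats, seed = as.numeric(seed))
}

## sigmoid dot-product scores for a matrix of id pairs
pairScores <- function(embeddings, pairs) {
  if (!nrow(pairs)) return(numeric())
  sigmoid(rowSums(embeddings[pairs[, 1], , drop = FALSE] *
                    embeddings[pairs[, 2], , drop = FALSE]))
}

#' @describeIn CVReport per-repeat, per-fold results data.frame
#' @param x,object a `CVReport`
#' @export
cvResults <- function(x) x@results

#' @describeIn CVReport list with mean `auc`, mean `ap` (on [0,1]) and the
#'   per-repeat means
#' @export
cvSummary <- function(x) {
  perRepeat <- do.call(rbind, lapply(split(x@results, x@results$repeat_),
                                     function(d) data.frame(
                                       repeat_ = d$repeat_[1],
                                       auc = mean(d$auc), ap = mean(d$ap))))
  rownames(perRepeat) <- NULL
  list(auc = mean(x@results$auc), ap = mean(x@results$ap),
       perRepeat = perRepeat)
}

setMethod("show", "CVReport", function(object) {
  s <- cvSummary(object)
  cat(sprintf("CVReport: %d-fold x %d repeat(s), seed %g\n",
              object@folds, object@repeats, object@seed))
  cat(sprintf("  mean AUC %.2f%%  mean AP %.2f%%\n",
              100 * s$auc, 100 * s$ap))
})

#' Rank candidate disease pairs by predicted association
#'
#' Scores every unordered disease pair not in the known positive set with
#' the sigmoid dot-product predictor and returns them sorted by
#' descending score, ties broken lexicographically by pair id.
#'
#' @param embeddings matrix with rownames = disease ids (e.g.
#'   [diseaseEmbeddings()]).
#' @param knownPositives pairs to exclude from ranking.
#' @param topK optional truncation (e.g. 15 for a shortlist).
#' @return data.frame with columns rank, disease1, disease2, score.
#' @export
rankPredictions <- function(embeddings, knownPositives = NULL,
                            topK = NULL) {
  ds <- sort(rownames(embeddings))
  if (length(ds) < 2L) stop("need at least 2 embedded diseases")
  cand <- t(utils::combn(ds, 2))
  if (!is.null(knownPositives) && NROW(knownPositives)) {
    known <- pairKeys(asPairMatrix(knownPositives))
    cand <- cand[!pairKeys(cand) %in% known, , drop = FALSE]
  }
  sc <- pairScores(embeddings, cand)
  o <- order(-sc, cand[, 1], cand[, 2])
  out <- data.frame(rank = seq_along(o), disease1 = cand[o, 1],
                    disease2 = cand[o, 2], score = sc[o],
                    stringsAsFactors = FALSE)
  if (!is.null(topK)) out <- utils::head(out, topK)
  rownames(out) <- NULL
  out
}
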