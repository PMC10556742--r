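#' Train the embedding model end-to-end
#'
#' Full-batch Adam minimization of the negative-sampling log-sigmoid loss
#' over disease pairs.  Negatives are resampled every epoch (seeded), so
#' the positive pairs anchor the geometry while the sampled complement
#' pushes unrelated diseases apart.  With `valFraction > 0` a slice of the
#' positives is held out and training stops early when its AUC has not
#' improved for `patience` epochs (the best parameters are kept).
#'
#' @param graph a [HetGraph-class] with at least 2 disease nodes.
#' @param positives known disease-association pairs (matrix/data.frame of
#'   ids, or a [PairSet-class] whose positives are used).
#' @param config from [embedConfig()].
#' @param train from [trainConfig()].
#' @param schemaIds meta-path schemas to aggregate over.
#' @param excludePairs pairs that must never be sampled as training
#'   negatives (e.g. a held-out evaluation set).
#' @param quiet suppress progress messages.
#' @return an [EmbedModel-class] with the trained parameters and the
#'   per-epoch loss trace.
#' @export
trainModel <- function(graph, positives, config = embedConfig(),
                       train = trainConfig(),
                       schemaIds = c("M1", "M2", "M3", "M4"),
                       excludePairs = NULL, quiet = TRUE) {
  if (is(positives, "PairSet")) positives <- positives@positives
  pos <- asPairMatrix(positives)
  if (!nrow(pos)) stop("empty positive set")
  if (length(diseaseIds(graph)) < 2L) stop("need at least 2 disease nodes")
  cfg <- unclass(config)
  cfg$capSeed <- train$seed
  state <- prepareModel(graph, cfg, schemaIds, seed = train$seed,
                        quiet = quiet)
  dNames <- state$nodes$id[state$dIdx]
  toIdx <- function(m) {
    ix <- cbind(match(m[, 1], dNames), match(m[, 2], dNames))
    if (anyNA(ix)) stop("pair ids are not DISEASE nodes in the graph")
    ix
  }
  valPos <- NULL
  if (train$valFraction > 0 && nrow(pos) >= 4L) {
    nv <- max(1L, floor(train$valFraction * nrow(pos)))
    vix <- withSeed(derivedSeed(train$seed, 3L),
                    sample.int(nrow(pos), nv))
    valPos <- pos[vix, , drop = FALSE]
    pos <- pos[-vix, , drop = FALSE]
  }
  posIdx <- toIdx(pos)

  params <- initParamsFromState(state, train$seed)
  skeleton <- params
  theta <- flattenParams(params)
  opt <- adamInit(length(theta))
  lossTrace <- numeric(0)
  bestVal <- -Inf; bestTheta <- theta; sinceBest <- 0L

  for (epoch in seq_len(train$epochs)) {
    fullComp <- !is.finite(train$negRatio)   # whole complement, tiny graphs
    neg <- if (fullComp) {
      suppressWarnings(sampleNegatives(
        graph, rbind(pos, valPos), seed = derivedSeed(train$seed, 1000L),
        exclude = excludePairs, size = .Machine$integer.max))
    } else {
      sampleNegatives(graph, rbind(pos, valPos), ratio = train$negRatio,
                      seed = derivedSeed(train$seed, 1000L + epoch),
                      exclude = excludePairs)
    }
    negIdx <- if (nrow(neg)) toIdx(neg) else matrix(integer(), 0, 2)
    params <- unflattenParams(theta, skeleton)
    lg <- withSeed(derivedSeed(train$seed, 2000L + epoch),
                   lossAndGrad(state, params, posIdx, negIdx,
                               train = cfg$dropout > 0))
    if (!is.finite(lg$loss))
      stop(sprintf(
        "non-finite loss at epoch %d (loss=%g, lr=%g); aborting",
        epoch, lg$loss, train$lr))
    lossTrace <- c(lossTrace, lg$loss)
    st <- adamStep(opt, theta, flattenParams(lg$grads), train$lr)
    opt <- st$opt; theta <- st$par

    if (!is.null(valPos)) {
      params <- unflattenParams(theta, skeleton)
      emb <- forwardCore(state, params, train = FALSE)$emb
      vIdx <- toIdx(valPos)
      vNeg <- sampleNegatives(graph, rbind(pos, valPos), seed =
                                derivedSeed(train$seed, 4L),
                              size = nrow(valPos))
      zs <- c(rowSums(emb[vIdx[, 1], , drop = FALSE] *
                        emb[vIdx[, 2], , drop = FALSE]),
              rowSums(emb[match(vNeg[, 1], dNames), , drop = FALSE] *
                        emb[match(vNeg[, 2], dNames), , drop = FALSE]))
      lab <- rep(c(1L, 0L), c(nrow(vIdx), nrow(vNeg)))
      vauc <- aucScore(zs, lab)
      if (vauc > bestVal + 1e-9) {
        bestVal <- vauc; bestTheta <- theta; sinceBest <- 0L
      } else sinceBest <- sinceBest + 1L
      if (sinceBest >= train$patience) {
        if (!quiet) message("early stop at epoch ", epoch)
        theta <- bestTheta
        break
      }
    }
    if (!quiet && epoch %% 10L == 0L)
      message(sprintf("epoch %d: loss %.4f", epoch, lg$loss))
  }
  new("EmbedModel", graph = graph,
      params = unflattenParams(theta, skeleton), config = cfg,
      schemaIds = schemaIds, lossTrace = lossTrace)
}

setMethod("show", "EmbedModel", function(object) {
  cat("EmbedModel: meta-path attention disease embedding\n")
  cat(sprintf("  schemas: %s | hidden %d, heads %d, out %d\n",
              paste(object@schemaIds, collapse = ","),
              object@config$hidden, object@config$heads,
              object@config$outDim))
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epoch(s), final loss %.4f\n",
                length(object@lossTrace),
                object@lossTrace[length(object@lossTrace)]))
})

#' Disease embeddings of a trained model
#'
#' Evaluation-mode forward pass (dropout off); deterministic for a fixed
#' model.
#'
#' @param model an [EmbedModel-class].
#' @return matrix (diseases x outDim), rownames = disease ids.
#' @export
diseaseEmbeddings <- function(model) {
  state <- prepareModel(model@graph, model@config, model@schemaIds,
                        seed = model@config$capSeed %||% 1L)
  forwardCore(state, model@params, train = FALSE)$emb
}

#' Per-epoch training loss
#' @param model an [EmbedModel-class]
#' @return numeric vector of losses
#' @export
lossTrace <- function(model) model@lossTrace

#' Write embeddings as TSV
#'
#' @param embeddings matrix with rownames (e.g. [diseaseEmbeddings()]).
#' @param path output file.
#' @export
writeEmbeddings <- function(embeddings, path) {
  df <- data.frame(id = rownames(embeddings), embeddings,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
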