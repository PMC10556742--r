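#' Embedding configuration
#'
#' Hyperparameters of the meta-path attention embedding.  Defaults follow
#' the model's reference setting: 8 attention heads, inter-path attention
#' dimension 128, output embedding dimension 64, dropout 0.5.  `hidden`
#' must be even (vectors are read as hidden/2 complex components by the
#' rotation encoder) and divisible by `heads`.
#'
#' @param hidden projected latent dimension d' shared by all node types.
#' @param outDim output embedding dimension.
#' @param heads number of intra-path attention heads.
#' @param attnDim dimension of the inter-path attention space.
#' @param dropout dropout rate applied to attention coefficients and
#'   projected features during training (never at inference).
#' @param slope negative slope of the LeakyReLU in attention logits.
#' @param cap maximum meta-path instances kept per (target, schema);
#'   NULL for no cap.
#' @param featureMode initial node features: "learnable" free embeddings
#'   (default; no node attributes ship with the association tables),
#'   "onehot", or "provided".
#' @param features named list of per-type feature matrices when
#'   `featureMode = "provided"`.
#' @return a validated configuration list.
#' @export
embedConfig <- function(hidden = 64L, outDim = 64L, heads = 8L,
                        attnDim = 128L, dropout = 0.5, slope = 0.01,
                        cap = 128L, featureMode = c("learnable", "onehot",
                                                    "provided"),
                        features = NULL) {
  featureMode <- match.arg(featureMode)
  stopifnot(hidden > 0, outDim > 0, heads > 0, attnDim > 0,
            dropout >= 0, dropout < 1, slope > 0)
  if (hidden %% 2L != 0L) stop("hidden must be even (complex pairs)")
  if (hidden %% heads != 0L) stop("heads must divide hidden")
  if (featureMode == "provided" && is.null(features))
    stop("featureMode 'provided' requires a features list")
  structure(list(hidden = as.integer(hidden), outDim = as.integer(outDim),
                 heads = as.integer(heads), attnDim = as.integer(attnDim),
                 dropout = dropout, slope = slope,
                 cap = if (is.null(cap)) NULL else as.integer(cap),
                 featureMode = featureMode, features = features),
            class = "embed_config")
}

#' Training configuration
#'
#' @param epochs number of full-batch epochs.
#' @param lr Adam learning rate.
#' @param negRatio negatives sampled per positive each epoch (>= 1).
#' @param valFraction fraction of training positives held out for
#'   early-stopping validation AUC (0 disables early stopping).
#' @param patience early-stop patience in epochs.
#' @param seed master seed for initialization, negative sampling and
#'   dropout.
#' @return a validated configuration list.
#' @export
trainConfig <- function(epochs = 100L, lr = 5e-3, negRatio = 1,
                        valFraction = 0, patience = 10L, seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, negRatio >= 1, valFraction >= 0,
            valFraction < 1, patience >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, negRatio = negRatio,
                 valFraction = valFraction, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

## ---- model state: everything fixed during training --------------------

## enumerate instances for all schemas, convert to integer index matrices,
## and precompute the per-target grouping used by intra-path attention
prepareModel <- function(graph, config, schemaIds = c("M1", "M2", "M3", "M4"),
                         seed = 1L, quiet = TRUE) {
  nodes <- graph@nodes
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  typeRows <- lapply(stats::setNames(NODE_TYPES, NODE_TYPES),
                     function(t) which(nodes$type == t))
  dIdx <- typeRows$DISEASE
  if (length(dIdx) < 1L) stop("graph has no DISEASE nodes")
  sch <- list()
  for (sid in schemaIds) {
    iset <- enumerateInstances(graph, sid, target = NULL,
                               cap = config$cap %||% Inf, seed = seed)
    im <- iset@instances
    I <- matrix(unname(idx[im]), nrow = nrow(im), ncol = ncol(im))
    ord <- order(I[, 1])
    I <- I[ord, , drop = FALSE]
    present <- unique(I[, 1])                # sorted (rows sorted by target)
    g2 <- match(I[, 1], present)             # consecutive group index
    starved <- setdiff(dIdx, present)
    if (!quiet && length(starved))
      message(sprintf("schema %s: %d disease node(s) with no instances: %s",
                      sid, length(starved),
                      paste(nodes$id[utils::head(starved, 5)],
                            collapse = ", ")))
    sch[[sid]] <- list(
      schema = iset@schema, I = I, n = nrow(I),
      g2 = g2, present = present,
      grpRow = match(present, dIdx),         # disease-row of each group
      splitIdx = split(seq_len(nrow(I)), g2))
  }
  list(graph = graph, nodes = nodes, idx = idx, typeRows = typeRows,
       dIdx = dIdx, nD = length(dIdx), config = config,
       schemaIds = schemaIds, sch = sch)
}

## feature dimension per node type under the configured mode
featureDims <- function(state) {
  cfg <- state$config
  vapply(NODE_TYPES, function(t) {
    nT <- length(state$typeRows[[t]])
    switch(cfg$featureMode,
           learnable = cfg$hidden,
           onehot = max(nT, 1L),
           provided = ncol(cfg$features[[t]]))
  }, integer(1))
}

#' Initialize embedding parameters
#'
#' Creates all learnable tensors: per-type node features (in "learnable"
#' mode), per-type projection matrices, per-edge-type relation phase
#' vectors (unit-modulus by construction: stored as angles), per-schema
#' multi-head attention vectors, the inter-path summary transform, query
#' vector, and the output projection.
#'
#' @param graph a [HetGraph-class].
#' @param config from [embedConfig()].
#' @param schemaIds meta-path schemas to parameterize.
#' @param seed RNG seed.
#' @return named list of parameter arrays.
#' @export
initEmbedParams <- function(graph, config, schemaIds = c("M1", "M2", "M3",
                                                         "M4"),
                            seed = 1L) {
  state <- prepareModel(graph, config, schemaIds, seed = seed)
  initParamsFromState(state, seed)
}

initParamsFromState <- function(state, seed) {
  cfg <- state$config
  H <- cfg$hidden; K <- cfg$heads; Hk <- H %/% K
  dA <- featureDims(state)
  withSeed(derivedSeed(seed, 1L), {
    rmat <- function(r, c, sd = 0.1) matrix(stats::rnorm(r * c, 0, sd), r, c)
    params <- list()
    if (cfg$featureMode == "learnable") {
      params$X <- lapply(stats::setNames(NODE_TYPES, NODE_TYPES), function(t)
        rmat(max(length(state$typeRows[[t]]), 0L), dA[t], sd = 0.5))
    }
    params$W <- lapply(stats::setNames(NODE_TYPES, NODE_TYPES), function(t)
      rmat(H, dA[t], sd = 1 / sqrt(dA[t])))
    params$theta <- lapply(stats::setNames(EDGE_TYPES, EDGE_TYPES),
                           function(e) stats::rnorm(H / 2, 0, 0.5))
    params$attn <- lapply(stats::setNames(state$schemaIds, state$schemaIds),
                          function(s) list(a1 = rmat(K, Hk), a2 = rmat(K, Hk)))
    params$Msum <- rmat(cfg$attnDim, H, sd = 1 / sqrt(H))
    params$bsum <- numeric(cfg$attnDim)
    params$q <- stats::rnorm(cfg$attnDim, 0, 0.1)
    params$Wo <- rmat(cfg$outDim, H, sd = 1 / sqrt(H))
    params
  })
}

## fixed (non-learnable) feature matrices, if any
fixedFeatures <- function(state) {
  cfg <- state$config
  if (cfg$featureMode == "learnable") return(NULL)
  lapply(stats::setNames(NODE_TYPES, NODE_TYPES), function(t) {
    nT <- length(state$typeRows[[t]])
    if (cfg$featureMode == "onehot") diag(max(nT, 1L))[seq_len(nT), ,
                                                       drop = FALSE]
    else cfg$features[[t]]
  })
}

## ---- vectorized forward pass ------------------------------------------

## Full forward pass over all schemas; returns embeddings and, when
## keepCache, every intermediate needed by the analytic backward pass.
forwardCore <- function(state, params, train = FALSE, keepCache = FALSE) {
  cfg <- state$config
  H <- cfg$hidden; K <- cfg$heads; Hk <- H %/% K; H2 <- H %/% 2L
  N <- nrow(state$nodes); nD <- state$nD
  Xfix <- fixedFeatures(state)

  Hp <- matrix(0, N, H)
  for (t in NODE_TYPES) {
    rows <- state$typeRows[[t]]
    if (!length(rows)) next
    X <- if (is.null(Xfix)) params$X[[t]] else Xfix[[t]]
    Hp[rows, ] <- X %*% t(params$W[[t]])
  }
  maskHp <- NULL
  if (train && cfg$dropout > 0) {
    maskHp <- matrix(stats::rbinom(N * H, 1L, 1 - cfg$dropout) /
                       (1 - cfg$dropout), N, H)
    Hp <- Hp * maskHp
  }

  scache <- list()
  HPs <- list()
  for (sid in state$schemaIds) {
    ss <- state$sch[[sid]]
    if (ss$n == 0L) {
      HPs[[sid]] <- matrix(0, nD, H)
      scache[[sid]] <- list(empty = TRUE)
      next
    }
    sc <- list(empty = FALSE)
    L <- ncol(ss$I); E <- L - 1L
    oList <- vector("list", L)
    o <- Hp[ss$I[, 1], , drop = FALSE]
    oList[[1]] <- o
    for (i in seq_len(E)) {
      phi <- ss$schema@edgeSigns[i] * params$theta[[ss$schema@edgeTypes[i]]]
      o <- Hp[ss$I[, i + 1L], , drop = FALSE] +
        rotateHalves(o, cos(phi), sin(phi))
      oList[[i + 1L]] <- o
    }
    hInst <- o / L
    hT <- Hp[ss$I[, 1], , drop = FALSE]

    a1 <- params$attn[[sid]]$a1; a2 <- params$attn[[sid]]$a2
    l <- matrix(0, ss$n, K)
    for (k in seq_len(K)) {
      ck <- (k - 1L) * Hk + seq_len(Hk)
      l[, k] <- hT[, ck, drop = FALSE] %*% a1[k, ] +
        hInst[, ck, drop = FALSE] %*% a2[k, ]
    }
    e <- leakyRelu(l, cfg$slope)
    G <- length(ss$splitIdx)
    mx <- t(vapply(ss$splitIdx, function(ix)
      apply(e[ix, , drop = FALSE], 2, max), numeric(K)))
    if (K == 1L) mx <- matrix(mx, G, 1L)
    w <- exp(e - mx[ss$g2, , drop = FALSE])
    Ssum <- rowsum(w, ss$g2)
    alphaS <- w / Ssum[ss$g2, , drop = FALSE]
    maskA <- NULL
    alphaM <- alphaS
    if (train && cfg$dropout > 0) {
      maskA <- matrix(stats::rbinom(ss$n * K, 1L, 1 - cfg$dropout) /
                        (1 - cfg$dropout), ss$n, K)
      alphaM <- alphaS * maskA
    }
    Cg <- matrix(0, G, H)
    for (k in seq_len(K)) {
      ck <- (k - 1L) * Hk + seq_len(Hk)
      Cg[, ck] <- rowsum(alphaM[, k] * hInst[, ck, drop = FALSE], ss$g2)
    }
    HP <- matrix(0, nD, H)
    HP[ss$grpRow, ] <- elu(Cg)
    HPs[[sid]] <- HP
    if (keepCache)
      scache[[sid]] <- list(empty = FALSE, oList = oList, hInst = hInst,
                            l = l, alphaS = alphaS, alphaM = alphaM,
                            maskA = maskA, Cg = Cg)
  }

  M <- length(state$schemaIds)
  Zs <- vector("list", M); svecs <- matrix(0, cfg$attnDim, M)
  for (m in seq_len(M)) {
    Z <- tanh(HPs[[m]] %*% t(params$Msum) +
                rep(params$bsum, each = nD))
    Zs[[m]] <- Z
    svecs[, m] <- colMeans(Z)
  }
  eS <- as.numeric(params$q %*% svecs)
  beta <- exp(eS - max(eS)); beta <- beta / sum(beta)
  fused <- matrix(0, nD, H)
  for (m in seq_len(M)) fused <- fused + beta[m] * HPs[[m]]
  U <- fused %*% t(params$Wo)
  emb <- elu(U)
  rownames(emb) <- state$nodes$id[state$dIdx]

  out <- list(emb = emb, beta = stats::setNames(beta, state$schemaIds))
  if (keepCache)
    out$cache <- list(Hp = Hp, maskHp = maskHp, scache = scache, HPs = HPs,
                      Zs = Zs, svecs = svecs, beta = beta, fused = fused,
                      U = U)
  out
}

#' Compute disease embeddings with a trained or given parameter set
#'
#' Runs the full embedding pipeline in evaluation mode (no dropout):
#' node-content projection, relational-rotation instance encoding,
#' intra-meta-path multi-head attention, inter-meta-path attention and
#' output projection.  Deterministic for fixed parameters.
#'
#' @param graph a [HetGraph-class].
#' @param params parameter list from [initEmbedParams()] or a trained
#'   model.
#' @param config from [embedConfig()].
#' @param schemaIds schemas to aggregate over.
#' @param seed seed controlling the instance-cap subsample.
#' @return matrix of disease embeddings (rows named by disease id), with
#'   the inter-path attention weights in attribute `"beta"`.
#' @export
forwardEmbed <- function(graph, params, config,
                         schemaIds = c("M1", "M2", "M3", "M4"), seed = 1L) {
  state <- prepareModel(graph, config, schemaIds, seed = seed)
  fw <- forwardCore(state, params, train = FALSE)
  structure(fw$emb, beta = fw$beta)
}

## ---- public single-instance / single-target operation surface ---------

#' Project node features into the shared latent space
#'
#' @param x feature matrix (nodes x dA) or a single feature vector.
#' @param W projection matrix (hidden x dA).
#' @return projected matrix (nodes x hidden) or vector.
#' @export
projectNodeFeatures <- function(x, W) {
  if (is.null(dim(x))) {
    if (length(x) != ncol(W)) stop("shape mismatch: length(x) != ncol(W)")
    return(as.numeric(W %*% x))
  }
  if (ncol(x) != ncol(W)) stop("shape mismatch: ncol(x) != ncol(W)")
  x %*% t(W)
}

#' Encode one meta-path instance with the relational rotation encoder
#'
#' Starting from the projected vector of the node at position 0, each step
#' adds the next node's vector to the accumulator rotated by the step's
#' relation phases (element-wise complex product with a unit-modulus
#' relation vector; the first half of a vector holds real parts, the
#' second half imaginary parts), and the result is divided by the number
#' of nodes.  With all phases zero this reduces to the arithmetic mean of
#' the node vectors.
#'
#' @param nodeVecs matrix (L x hidden) of projected node vectors along the
#'   instance.
#' @param relPhases matrix ((L-1) x hidden/2) of relation phase angles,
#'   sign already reflecting traversal direction (reverse traversal uses
#'   the complex conjugate, i.e. negated phases).
#' @return encoded instance vector of length hidden.
#' @export
encodeInstance <- function(nodeVecs, relPhases) {
  L <- nrow(nodeVecs)
  if (L < 2L) stop("an instance needs at least 2 nodes")
  relPhases <- matrix(relPhases, nrow = L - 1L)
  if (ncol(relPhases) != ncol(nodeVecs) / 2L)
    stop("relation vector dimension must be hidden/2")
  o <- nodeVecs[1, , drop = FALSE]
  for (i in seq_len(L - 1L)) {
    phi <- relPhases[i, ]
    o <- nodeVecs[i + 1L, , drop = FALSE] +
      rotateHalves(o, cos(phi), sin(phi))
  }
  as.numeric(o) / L
}

#' Intra-meta-path multi-head attention for one target node
#'
#' Scores every instance of the target by a LeakyReLU attention logit on
#' the concatenation of the target's projected vector and the instance
#' encoding (per head on the head's slice), softmax-normalizes the scores
#' over the target's instances, and returns the activated
#' attention-weighted sum with heads concatenated.
#'
#' @param hTarget projected vector of the target (length hidden).
#' @param hInst matrix (n x hidden) of instance encodings.
#' @param a1,a2 per-head attention vectors (heads x hidden/heads), applied
#'   to the target and instance slices respectively.
#' @param slope LeakyReLU negative slope.
#' @return list with `h` (aggregated vector, length hidden) and `alpha`
#'   (n x heads attention weights, each column summing to 1).
#' @export
intraMetapathAggregate <- function(hTarget, hInst, a1, a2, slope = 0.01) {
  if (nrow(hInst) == 0L)
    return(list(h = elu(numeric(length(hTarget))),
                alpha = matrix(numeric(), 0, nrow(a1))))
  K <- nrow(a1); H <- length(hTarget); Hk <- H %/% K
  h <- numeric(H); alpha <- matrix(0, nrow(hInst), K)
  for (k in seq_len(K)) {
    ck <- (k - 1L) * Hk + seq_len(Hk)
    l <- as.numeric(hInst[, ck, drop = FALSE] %*% a2[k, ]) +
      sum(hTarget[ck] * a1[k, ])
    e <- leakyRelu(l, slope)
    w <- exp(e - max(e))
    alpha[, k] <- w / sum(w)
    h[ck] <- elu(colSums(alpha[, k] * hInst[, ck, drop = FALSE]))
  }
  list(h = h, alpha = alpha)
}

#' Summarize one meta-path over all disease nodes
#'
#' Mean over nodes of `tanh(M h + b)`: the schema-level summary entering
#' inter-meta-path attention.
#'
#' @param HP matrix (nodes x hidden) of per-node meta-path vectors.
#' @param M transform matrix (attnDim x hidden).
#' @param b bias vector (attnDim).
#' @return summary vector of length attnDim.
#' @export
summarizeMetapath <- function(HP, M, b) {
  if (ncol(HP) != ncol(M)) stop("shape mismatch: ncol(HP) != ncol(M)")
  colMeans(tanh(HP %*% t(M) + rep(b, each = nrow(HP))))
}

#' Inter-meta-path attention aggregation
#'
#' Computes one global softmax weight per schema from the query vector and
#' the schema summaries, shared by all disease nodes, and returns the
#' weighted sum of per-schema node vectors.
#'
#' @param HPs list of per-schema matrices (nodes x hidden).
#' @param svecs matrix (attnDim x schemas) of schema summaries, or list.
#' @param q query vector (attnDim).
#' @return list with `h` (nodes x hidden fused matrix) and `beta` (schema
#'   weights summing to 1).
#' @export
interMetapathAggregate <- function(HPs, svecs, q) {
  if (is.list(svecs)) svecs <- do.call(cbind, svecs)
  eS <- as.numeric(q %*% svecs)
  beta <- exp(eS - max(eS)); beta <- beta / sum(beta)
  h <- matrix(0, nrow(HPs[[1]]), ncol(HPs[[1]]))
  for (m in seq_along(HPs)) h <- h + beta[m] * HPs[[m]]
  list(h = h, beta = beta)
}

#' Output projection of fused vectors
#'
#' @param h fused matrix (nodes x hidden) or a vector.
#' @param Wo output projection (outDim x hidden).
#' @return activated embeddings (nodes x outDim).
#' @export
projectOutput <- function(h, Wo) {
  if (is.null(dim(h))) {
    if (length(h) != ncol(Wo)) stop("shape mismatch")
    return(elu(as.numeric(Wo %*% h)))
  }
  if (ncol(h) != ncol(Wo)) stop("shape mismatch")
  elu(h %*% t(Wo))
}
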