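## Analytic gradients of the full forward pass.  Mirrors forwardCore
## step by step in reverse; every cached intermediate is consumed once.

## scatter-add rows of m into acc at integer indices idx (with repeats)
addAtRows <- function(acc, idx, m) {
  rs <- rowsum(m, idx)
  at <- as.integer(rownames(rs))
  acc[at, ] <- acc[at, , drop = FALSE] + rs
  acc
}

## zero-filled gradient skeleton matching the parameter list
zeroLike <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

backwardCore <- function(state, params, cache, dEmb) {
  cfg <- state$config
  H <- cfg$hidden; K <- cfg$heads; Hk <- H %/% K; H2 <- H %/% 2L
  N <- nrow(state$nodes); nD <- state$nD
  M <- length(state$schemaIds)
  g <- zeroLike(params)

  ## output projection
  dU <- dEmb * eluGrad(cache$U)
  g$Wo <- t(dU) %*% cache$fused
  dFused <- dU %*% params$Wo

  ## inter-path attention
  beta <- cache$beta
  dBeta <- vapply(seq_len(M), function(m) sum(dFused * cache$HPs[[m]]),
                  numeric(1))
  dHPs <- lapply(seq_len(M), function(m) beta[m] * dFused)
  deS <- beta * (dBeta - sum(beta * dBeta))
  g$q <- as.numeric(cache$svecs %*% deS)
  for (m in seq_len(M)) {
    dZ <- (deS[m] / nD) * rep(params$q, each = nD) *
      (1 - cache$Zs[[m]]^2)
    g$Msum <- g$Msum + t(dZ) %*% cache$HPs[[m]]
    g$bsum <- g$bsum + colSums(dZ)
    dHPs[[m]] <- dHPs[[m]] + dZ %*% params$Msum
  }

  ## intra-path attention + rotation encoder, per schema
  dHp <- matrix(0, N, H)
  for (m in seq_len(M)) {
    sid <- state$schemaIds[m]
    sc <- cache$scache[[sid]]
    if (isTRUE(sc$empty)) next
    ss <- state$sch[[sid]]
    L <- ncol(ss$I); E <- L - 1L
    a1 <- params$attn[[sid]]$a1; a2 <- params$attn[[sid]]$a2

    dCg <- dHPs[[m]][ss$grpRow, , drop = FALSE] * eluGrad(sc$Cg)
    dCgExp <- dCg[ss$g2, , drop = FALSE]
    dAlphaM <- matrix(0, ss$n, K)
    dhInst <- matrix(0, ss$n, H)
    dl <- matrix(0, ss$n, K)
    for (k in seq_len(K)) {
      ck <- (k - 1L) * Hk + seq_len(Hk)
      dAlphaM[, k] <- rowSums(dCgExp[, ck, drop = FALSE] *
                                sc$hInst[, ck, drop = FALSE])
      dhInst[, ck] <- sc$alphaM[, k] * dCgExp[, ck, drop = FALSE]
    }
    dAlphaS <- if (is.null(sc$maskA)) dAlphaM else dAlphaM * sc$maskA
    inner <- rowsum(sc$alphaS * dAlphaS, ss$g2)
    de <- sc$alphaS * (dAlphaS - inner[ss$g2, , drop = FALSE])
    dlAll <- de * leakyReluGrad(sc$l, cfg$slope)
    hT <- cache$Hp[ss$I[, 1], , drop = FALSE]
    for (k in seq_len(K)) {
      ck <- (k - 1L) * Hk + seq_len(Hk)
      g$attn[[sid]]$a1[k, ] <- g$attn[[sid]]$a1[k, ] +
        as.numeric(t(hT[, ck, drop = FALSE]) %*% dlAll[, k])
      g$attn[[sid]]$a2[k, ] <- g$attn[[sid]]$a2[k, ] +
        as.numeric(t(sc$hInst[, ck, drop = FALSE]) %*% dlAll[, k])
    }
    ## gradient into the target's projected vector from the a1 logit term,
    ## and into instance encodings from the a2 term
    dhT <- matrix(0, ss$n, H)
    for (k in seq_len(K)) {
      ck <- (k - 1L) * Hk + seq_len(Hk)
      dhT[, ck] <- outer(dlAll[, k], a1[k, ])
      dhInst[, ck] <- dhInst[, ck, drop = FALSE] + outer(dlAll[, k], a2[k, ])
    }

    ## rotation encoder backward
    do <- dhInst / L
    for (i in rev(seq_len(E))) {
      dHp <- addAtRows(dHp, ss$I[, i + 1L], do)
      rho <- sc$oList[[i + 1L]] - cache$Hp[ss$I[, i + 1L], , drop = FALSE]
      et <- ss$schema@edgeTypes[i]
      sgn <- ss$schema@edgeSigns[i]
      dA_ <- do[, seq_len(H2), drop = FALSE]
      dB_ <- do[, H2 + seq_len(H2), drop = FALSE]
      rA <- rho[, seq_len(H2), drop = FALSE]
      rB <- rho[, H2 + seq_len(H2), drop = FALSE]
      dphi <- colSums(dB_ * rA - dA_ * rB)
      g$theta[[et]] <- g$theta[[et]] + sgn * dphi
      phi <- sgn * params$theta[[et]]
      do <- rotateHalves(do, cos(phi), -sin(phi))
    }
    dHp <- addAtRows(dHp, ss$I[, 1], do + dhT)
  }

  ## dropout on projected features
  if (!is.null(cache$maskHp)) dHp <- dHp * cache$maskHp

  ## node content projection
  Xfix <- fixedFeatures(state)
  for (t in NODE_TYPES) {
    rows <- state$typeRows[[t]]
    if (!length(rows)) next
    X <- if (is.null(Xfix)) params$X[[t]] else Xfix[[t]]
    dHpT <- dHp[rows, , drop = FALSE]
    g$W[[t]] <- t(dHpT) %*% X
    if (is.null(Xfix)) g$X[[t]] <- dHpT %*% params$W[[t]]
  }
  g
}

## loss of Eq.-7 form plus gradient wrt all parameters
lossAndGrad <- function(state, params, posIdx, negIdx, train = FALSE) {
  fw <- forwardCore(state, params, train = train, keepCache = TRUE)
  emb <- fw$emb
  zPos <- rowSums(emb[posIdx[, 1], , drop = FALSE] *
                    emb[posIdx[, 2], , drop = FALSE])
  loss <- -sum(logSigmoid(zPos))
  dEmb <- matrix(0, nrow(emb), ncol(emb))
  gPos <- -sigmoid(-zPos)                    # dL/dz for positives
  dEmb <- addAtRows(dEmb, posIdx[, 1],
                    gPos * emb[posIdx[, 2], , drop = FALSE])
  dEmb <- addAtRows(dEmb, posIdx[, 2],
                    gPos * emb[posIdx[, 1], , drop = FALSE])
  if (nrow(negIdx)) {
    zNeg <- rowSums(emb[negIdx[, 1], , drop = FALSE] *
                      emb[negIdx[, 2], , drop = FALSE])
    loss <- loss - sum(logSigmoid(-zNeg))
    gNeg <- sigmoid(zNeg)                    # dL/dz for negatives
    dEmb <- addAtRows(dEmb, negIdx[, 1],
                      gNeg * emb[negIdx[, 2], , drop = FALSE])
    dEmb <- addAtRows(dEmb, negIdx[, 2],
                      gNeg * emb[negIdx[, 1], , drop = FALSE])
  }
  grads <- backwardCore(state, params, fw$cache, dEmb)
  list(loss = loss, grads = grads)
}

## ---- parameter flattening and Adam ------------------------------------

flattenParams <- function(p) {
  unlist(p, use.names = FALSE)
}

unflattenParams <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  assign_ <- function(x) {
    n <- length(x)
    v <- vec[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(v, nrow(x), ncol(x)) else v
  }
  rapply(out, assign_, how = "replace")
}

adamInit <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamStep <- function(opt, par, grad, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, par = par - lr * mhat / (sqrt(vhat) + eps))
}
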