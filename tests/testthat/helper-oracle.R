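# independent oracles: join-based typed-walk enumeration and a
# straight-line complex-arithmetic reimplementation of the forward pass

# enumerate all typed walks matching a schema by iterated data.frame joins
oracleEnumerate <- function(graph, schema, target) {
  if (is.character(schema)) schema <- metaPathSchema(schema)
  nd <- nodeTable(graph)
  ed <- edgeTable(graph)
  typeOf <- stats::setNames(nd$type, nd$id)
  nt <- schema@nodeTypes
  et <- schema@edgeTypes
  walks <- data.frame(p1 = target, stringsAsFactors = FALSE)
  for (i in seq_along(et)) {
    rows <- ed[ed$type == et[i], , drop = FALSE]
    # both traversal orientations, then keep those typed correctly
    cand <- rbind(data.frame(a = rows$src, b = rows$dst),
                  data.frame(a = rows$dst, b = rows$src))
    cand <- cand[typeOf[cand$a] == nt[i] & typeOf[cand$b] == nt[i + 1], ,
                 drop = FALSE]
    names(cand) <- c(paste0("p", i), paste0("p", i + 1))
    walks <- merge(walks, cand, by = paste0("p", i))
    if (!nrow(walks)) break
  }
  if (!nrow(walks))
    return(matrix(character(), 0, length(nt)))
  as.matrix(walks[, paste0("p", seq_along(nt)), drop = FALSE])
}

walkKeys <- function(m) {
  if (!nrow(m)) return(character())
  sort(apply(m, 1, paste, collapse = ">"))
}

# complex-number reimplementation of the rotation encoder for one instance
oracleEncode <- function(nodeVecs, relPhases) {
  H <- ncol(nodeVecs); H2 <- H / 2
  toC <- function(v) complex(real = v[1:H2], imaginary = v[(H2 + 1):H])
  o <- toC(nodeVecs[1, ])
  for (i in seq_len(nrow(nodeVecs) - 1)) {
    o <- toC(nodeVecs[i + 1, ]) + o * exp(1i * relPhases[i, ])
  }
  o <- o / nrow(nodeVecs)
  c(Re(o), Im(o))
}

oracleElu <- function(x) ifelse(x > 0, x, exp(x) - 1)

# scalar, loop-everything forward pass over all schemas for every disease
oracleForward <- function(graph, params, config,
                          schemaIds = c("M1", "M2", "M3", "M4")) {
  nd <- nodeTable(graph)
  H <- config$hidden; K <- config$heads; Hk <- H / K
  types <- unique(nd$type)
  # projected vectors, node by node
  hp <- list()
  for (t in types) {
    ids <- nd$id[nd$type == t]
    for (j in seq_along(ids))
      hp[[ids[j]]] <- as.numeric(params$W[[t]] %*% params$X[[t]][j, ])
  }
  ds <- nd$id[nd$type == "DISEASE"]
  HPs <- list()
  for (sid in schemaIds) {
    schema <- metaPathSchema(sid)
    L <- length(schema@nodeTypes)
    HP <- matrix(0, length(ds), H)
    for (di in seq_along(ds)) {
      inst <- oracleEnumerate(graph, schema, ds[di])
      if (!nrow(inst)) { HP[di, ] <- oracleElu(rep(0, H)); next }
      enc <- matrix(0, nrow(inst), H)
      for (r in seq_len(nrow(inst))) {
        nv <- t(vapply(inst[r, ], function(id) hp[[id]], numeric(H)))
        ph <- t(vapply(seq_len(L - 1), function(i)
          schema@edgeSigns[i] * params$theta[[schema@edgeTypes[i]]],
          numeric(H / 2)))
        enc[r, ] <- oracleEncode(nv, ph)
      }
      hT <- hp[[ds[di]]]
      for (k in seq_len(K)) {
        ck <- (k - 1) * Hk + seq_len(Hk)
        e <- numeric(nrow(inst))
        for (r in seq_len(nrow(inst))) {
          l <- sum(params$attn[[sid]]$a1[k, ] * hT[ck]) +
            sum(params$attn[[sid]]$a2[k, ] * enc[r, ck])
          e[r] <- if (l > 0) l else config$slope * l
        }
        al <- exp(e - max(e)); al <- al / sum(al)
        acc <- rep(0, Hk)
        for (r in seq_len(nrow(inst))) acc <- acc + al[r] * enc[r, ck]
        HP[di, ck] <- oracleElu(acc)
      }
    }
    HPs[[sid]] <- HP
  }
  svec <- sapply(schemaIds, function(sid) {
    z <- rep(0, config$attnDim)
    for (di in seq_along(ds))
      z <- z + tanh(as.numeric(params$Msum %*% HPs[[sid]][di, ]) +
                      params$bsum)
    z / length(ds)
  })
  eS <- as.numeric(params$q %*% svec)
  beta <- exp(eS - max(eS)); beta <- beta / sum(beta)
  emb <- matrix(0, length(ds), config$outDim)
  for (di in seq_along(ds)) {
    fused <- rep(0, H)
    for (m in seq_along(schemaIds))
      fused <- fused + beta[m] * HPs[[schemaIds[m]]][di, ]
    emb[di, ] <- oracleElu(as.numeric(params$Wo %*% fused))
  }
  rownames(emb) <- ds
  emb
}

# central-difference gradient of f at theta
numericGradient <- function(f, theta, eps = 1e-5) {
  vapply(seq_along(theta), function(i) {
    u <- theta; u[i] <- theta[i] + eps; fp <- f(u)
    u[i] <- theta[i] - eps; fm <- f(u)
    (fp - fm) / (2 * eps)
  }, numeric(1))
}
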