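# internal numerical and RNG helpers

sigmoid <- function(z) 1 / (1 + exp(-z))

# log(sigmoid(z)) without overflow for large |z|; NaN propagates
logSigmoid <- function(z) {
  out <- rep(NaN, length(z))
  pos <- which(z >= 0)
  neg <- which(z < 0)
  out[pos] <- -log1p(exp(-z[pos]))
  out[neg] <- z[neg] - log1p(exp(z[neg]))
  out
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
eluGrad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

leakyRelu <- function(x, slope) ifelse(x > 0, x, slope * x)
leakyReluGrad <- function(x, slope) ifelse(x > 0, 1, slope)

# evaluate `expr` under a temporary RNG state; global stream untouched
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic integer sub-stream seeds, kept inside 32-bit range
derivedSeed <- function(seed, k = 0L) {
  s <- (abs(as.double(seed)) * 48271 + as.double(k) * 7919 + 1) %% 2147483646
  as.integer(s) + 1L
}

# multiply every row of m by vector v (length ncol(m))
rowScale <- function(m, v) m * rep(v, each = nrow(m))

# rotate complex-pair columns: first half real parts, second half imaginary
rotateHalves <- function(m, co, si) {
  h2 <- ncol(m) %/% 2L
  a <- m[, seq_len(h2), drop = FALSE]
  b <- m[, h2 + seq_len(h2), drop = FALSE]
  cbind(rowScale(a, co) - rowScale(b, si),
        rowScale(a, si) + rowScale(b, co))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
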