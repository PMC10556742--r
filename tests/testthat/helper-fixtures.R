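# shared fixtures, built in code at test time

# small graph touching all four layers; hand-checkable
toyGraph <- function() {
  buildGraph(
    dg = data.frame(from = c("d1", "d1", "d2", "d3"),
                    to = c("g1", "g2", "g2", "g3")),
    gg = data.frame(from = "g1", to = "g2"),
    gm = data.frame(from = c("g2", "g3"), to = c("m1", "m2")),
    mp = data.frame(from = c("m1", "m2"), to = c("p1", "p1")),
    quiet = TRUE)
}

# small embedding config used throughout the unit tests
toyConfig <- function(dropout = 0, hidden = 4L, heads = 2L)
  embedConfig(hidden = hidden, outDim = 3L, heads = heads, attnDim = 3L,
              dropout = dropout, cap = NULL)

# desk-scale config for synthetic cross-validation runs
cvEmbedConfig <- function()
  embedConfig(hidden = 16L, outDim = 16L, heads = 4L, attnDim = 32L,
              dropout = 0.1, cap = 128L)

cvTrainConfig <- function()
  trainConfig(epochs = 100L, lr = 0.01, negRatio = 2,
              valFraction = 0.15, patience = 12L)

# random typed graph with all four layers, <= 50 nodes
randomTypedGraph <- function(seed) {
  set.seed(seed)
  nd <- sample(2:5, 1); ng <- sample(2:8, 1)
  nm <- sample(1:6, 1); np <- sample(1:4, 1)
  ds <- paste0("d", seq_len(nd)); gs <- paste0("g", seq_len(ng))
  ms <- paste0("m", seq_len(nm)); ps <- paste0("p", seq_len(np))
  pick <- function(a, b, p) {
    gr <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
    gr[runif(nrow(gr)) < p, , drop = FALSE]
  }
  dg <- pick(ds, gs, 0.4)
  if (!nrow(dg)) dg <- data.frame(from = ds[1], to = gs[1])
  gg <- if (ng >= 2) {
    pr <- t(combn(gs, 2))
    as.data.frame(pr[runif(nrow(pr)) < 0.3, , drop = FALSE],
                  stringsAsFactors = FALSE) |>
      stats::setNames(c("from", "to"))
  } else NULL
  gm <- pick(gs, ms, 0.3)
  mp <- pick(ms, ps, 0.4)
  buildGraph(dg = dg, gg = if (!is.null(gg) && nrow(gg)) gg else NULL,
             gm = if (nrow(gm)) gm else NULL,
             mp = if (nrow(mp)) mp else NULL, quiet = TRUE)
}

writeTsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
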