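twoComponentGraph <- function() {
  # two disjoint isomorphic components, ids prefixed a/b
  lay <- function(p) list(
    dg = data.frame(from = paste0(p, c("d1", "d1", "d2")),
                    to = paste0(p, c("g1", "g2", "g2"))),
    gg = data.frame(from = paste0(p, "g1"), to = paste0(p, "g2")),
    gm = data.frame(from = paste0(p, "g2"), to = paste0(p, "m1")),
    mp = data.frame(from = paste0(p, "m1"), to = paste0(p, "p1")))
  a <- lay("a_"); b <- lay("b_")
  buildGraph(dg = rbind(a$dg, b$dg), gg = rbind(a$gg, b$gg),
             gm = rbind(a$gm, b$gm), mp = rbind(a$mp, b$mp), quiet = TRUE)
}

test_that("isomorphic components with tied features embed identically", {
  g <- twoComponentGraph()
  cfg <- toyConfig()
  params <- initEmbedParams(g, cfg, seed = 5)
  # tie component b's free features to component a's: within each type the
  # node ids sort as a_* then b_*, in the same within-component order
  for (t in names(params$X)) {
    n <- nrow(params$X[[t]])
    if (n >= 2)
      params$X[[t]][(n / 2 + 1):n, ] <- params$X[[t]][1:(n / 2), ]
  }
  emb <- forwardEmbed(g, params, cfg)
  expect_equal(emb["a_d1", ], emb["b_d1", ], tolerance = 1e-10)
  expect_equal(emb["a_d2", ], emb["b_d2", ], tolerance = 1e-10)
})

test_that("evaluation-mode forward passes are bitwise reproducible", {
  g <- toyGraph()
  cfg <- toyConfig(dropout = 0.5)   # dropout must be inert in eval mode
  params <- initEmbedParams(g, cfg, seed = 2)
  e1 <- forwardEmbed(g, params, cfg)
  e2 <- forwardEmbed(g, params, cfg)
  expect_identical(e1, e2)
})

test_that("the vectorized forward pass matches the scalar oracle", {
  for (seed in c(3, 11)) {
    g <- randomTypedGraph(seed + 200)
    expect_lte(nrow(nodeTable(g)), 50)
    cfg <- toyConfig()
    params <- initEmbedParams(g, cfg, seed = seed)
    emb <- forwardEmbed(g, params, cfg)
    ref <- oracleForward(g, params, unclass(cfg))
    expect_equal(emb[rownames(ref), , drop = FALSE], ref,
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("intra- and inter-path attention weights are normalized", {
  fix <- generateFixture(syntheticSpec(), seed = 2)
  g <- fixtureGraph(fix)
  cfg <- embedConfig(hidden = 8, outDim = 4, heads = 4, attnDim = 6,
                     dropout = 0, cap = 32)
  state <- MetaPathDD:::prepareModel(g, unclass(cfg), seed = 1)
  for (ps in 1:3) {
    params <- MetaPathDD:::initParamsFromState(state, ps)
    fw <- MetaPathDD:::forwardCore(state, params, keepCache = TRUE)
    expect_equal(sum(fw$beta), 1, tolerance = 1e-6)
    for (sid in names(fw$cache$scache)) {
      sc <- fw$cache$scache[[sid]]
      if (isTRUE(sc$empty)) next
      sums <- rowsum(sc$alphaS, state$sch[[sid]]$g2)
      expect_true(all(abs(sums - 1) < 1e-6))
    }
  }
})

test_that("relation vectors stay unit-modulus under parameter updates", {
  # phases are the learned parameters, so the relation vector r = exp(i*theta)
  # has unit modulus after any update by construction
  g <- toyGraph()
  fixpos <- matrix(c("d1", "d2"), 1)
  m <- trainModel(g, fixpos, toyConfig(), trainConfig(epochs = 3, lr = 0.05),
                  quiet = TRUE)
  for (et in names(m@params$theta)) {
    r <- exp(1i * m@params$theta[[et]])
    expect_true(all(abs(Mod(r) - 1) < 1e-6))
  }
})
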