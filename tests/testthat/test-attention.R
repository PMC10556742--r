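test_that("a single instance receives attention weight one", {
  hT <- rnorm(4); hI <- matrix(rnorm(4), 1, 4)
  a1 <- matrix(rnorm(4), 2, 2); a2 <- matrix(rnorm(4), 2, 2)
  out <- intraMetapathAggregate(hT, hI, a1, a2)
  expect_equal(as.numeric(out$alpha), c(1, 1))
  expect_equal(out$h, as.numeric(ifelse(hI > 0, hI, exp(hI) - 1)),
               tolerance = 1e-12)
})

test_that("identical encoder outputs share attention equally", {
  hT <- rnorm(4); v <- rnorm(4)
  hI <- rbind(v, v)
  a1 <- matrix(rnorm(4), 2, 2); a2 <- matrix(rnorm(4), 2, 2)
  out <- intraMetapathAggregate(hT, hI, a1, a2)
  expect_equal(as.numeric(out$alpha), rep(0.5, 4), tolerance = 1e-12)
})

test_that("attention weights match a hand exp-normalize (single head)", {
  hT <- c(0.2, -0.1)
  hI <- rbind(c(1, 0), c(0, 1), c(1, 1))
  a1 <- matrix(c(0.3, -0.2), 1, 2)
  a2 <- matrix(c(0.5, 0.4), 1, 2)
  slope <- 0.01
  l <- as.numeric(hI %*% a2[1, ]) + sum(hT * a1[1, ])
  e <- ifelse(l > 0, l, slope * l)
  alpha <- exp(e) / sum(exp(e))
  out <- intraMetapathAggregate(hT, hI, a1, a2, slope = slope)
  expect_equal(as.numeric(out$alpha), alpha, tolerance = 1e-10)
  expect_equal(sum(out$alpha), 1, tolerance = 1e-6)
})

test_that("aggregation is invariant to the order of a target's instances", {
  set.seed(4)
  for (rep in 1:5) {
    hT <- rnorm(6)
    hI <- matrix(rnorm(8 * 6), 8, 6)
    a1 <- matrix(rnorm(6), 2, 3); a2 <- matrix(rnorm(6), 2, 3)
    ref <- intraMetapathAggregate(hT, hI, a1, a2)$h
    perm <- sample(8)
    got <- intraMetapathAggregate(hT, hI[perm, ], a1, a2)$h
    expect_lt(max(abs(got - ref)), 1e-6)
  }
})

test_that("zero instances produce the activated zero vector", {
  out <- intraMetapathAggregate(rnorm(4), matrix(0, 0, 4),
                                matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(out$h, rep(0, 4))
})

test_that("meta-path summaries are means of tanh transforms", {
  expect_equal(summarizeMetapath(matrix(0, 1, 3), diag(3), rep(0, 3)),
               rep(0, 3))
  h <- c(0.5, -1, 2)
  HP <- rbind(h, h, h)
  M <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
  expect_equal(summarizeMetapath(HP, M, b),
               as.numeric(tanh(M %*% h + b)), tolerance = 1e-12)
  HP2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(summarizeMetapath(HP2, M, b),
               (tanh(as.numeric(M %*% HP2[1, ]) + b) +
                  tanh(as.numeric(M %*% HP2[2, ]) + b)) / 2,
               tolerance = 1e-12)
})

test_that("inter-path attention degenerates and normalizes correctly", {
  HPs <- list(matrix(rnorm(6), 2, 3))
  out <- interMetapathAggregate(HPs, list(rnorm(4)), rnorm(4))
  expect_equal(out$beta, 1)
  expect_equal(out$h, HPs[[1]])

  # zero query -> uniform weights over schemas
  HPs4 <- lapply(1:4, function(i) matrix(rnorm(6), 2, 3))
  out4 <- interMetapathAggregate(HPs4, lapply(1:4, function(i) rnorm(5)),
                                 rep(0, 5))
  expect_equal(out4$beta, rep(0.25, 4))

  # hand logits
  sv <- cbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 0))
  q <- c(0.7, -0.3)
  eS <- as.numeric(q %*% sv)
  beta <- exp(eS - max(eS)); beta <- beta / sum(beta)
  outh <- interMetapathAggregate(lapply(1:4, function(i) matrix(0, 1, 2)),
                                 sv, q)
  expect_equal(outh$beta, beta, tolerance = 1e-10)
  expect_equal(sum(outh$beta), 1, tolerance = 1e-6)
})

test_that("output projection applies the activation after the linear map", {
  expect_equal(projectOutput(rep(0, 3), diag(3)), rep(0, 3))
  Wo <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  h <- c(0.5, -0.25)
  u <- as.numeric(Wo %*% h)
  expect_equal(projectOutput(h, Wo), ifelse(u > 0, u, exp(u) - 1),
               tolerance = 1e-12)
  expect_error(projectOutput(c(1, 2, 3), Wo), "shape mismatch")
})

test_that("default configuration produces 64-dimensional embeddings", {
  cfg <- embedConfig()
  expect_equal(cfg$outDim, 64L)
  expect_equal(cfg$heads, 8L)
  expect_equal(cfg$attnDim, 128L)
  expect_equal(cfg$dropout, 0.5)
  g <- toyGraph()
  params <- initEmbedParams(g, cfg, seed = 1)
  emb <- forwardEmbed(g, params, cfg)
  expect_equal(dim(emb), c(3L, 64L))
})
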