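test_that("pair scores are sigmoid dot products, symmetric and monotone", {
  expect_equal(scorePair(rep(0, 4), rnorm(4)), 0.5)
  expect_equal(scorePair(c(1, 0), c(0, 1)), 0.5)
  d <- 16
  v <- rep(1, d) / sqrt(d)
  expect_equal(scorePair(v, v), 1 / (1 + exp(-1)), tolerance = 1e-6)
  a <- rnorm(8); b <- rnorm(8)
  expect_identical(scorePair(a, b), scorePair(b, a))
  expect_error(scorePair(rnorm(3), rnorm(4)), "dimension mismatch")
  # strictly increasing in the dot product
  s <- vapply(c(-2, -1, 0, 1, 2), function(z) scorePair(c(z, 0), c(1, 0)),
              numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("the loss matches hand-computed log-sigmoid sums", {
  emb <- rbind(d1 = c(1, 0), d2 = c(0, 1), d3 = c(-1, 0))
  # one positive at dot 0 -> log 2
  ps <- pairSet(matrix(c("d1", "d2"), 1))
  expect_equal(computeLoss(ps, emb), log(2), tolerance = 1e-12)
  # one positive and one negative both at dot 0 -> 2 log 2
  ps2 <- pairSet(matrix(c("d1", "d2"), 1), matrix(c("d2", "d3"), 1))
  expect_equal(computeLoss(ps2, emb), 2 * log(2), tolerance = 1e-12)
  # mixed set against a scalar evaluation
  set.seed(1)
  emb2 <- matrix(rnorm(10 * 4), 10, 4,
                 dimnames = list(paste0("d", 1:10), NULL))
  pos <- rbind(c("d1", "d2"), c("d3", "d4"), c("d5", "d6"))
  neg <- rbind(c("d7", "d8"), c("d9", "d10"))
  hand <- 0
  for (i in 1:3) hand <- hand -
    log(1 / (1 + exp(-sum(emb2[pos[i, 1], ] * emb2[pos[i, 2], ]))))
  for (i in 1:2) hand <- hand -
    log(1 / (1 + exp(sum(emb2[neg[i, 1], ] * emb2[neg[i, 2], ]))))
  expect_equal(computeLoss(pairSet(pos, neg), emb2), hand,
               tolerance = 1e-10)
  expect_error(computeLoss(pairSet(pos[0, , drop = FALSE]), emb2),
               "empty positive set")
})

test_that("the loss is additive over pairs and finite for huge dots", {
  emb <- rbind(d1 = c(50, 0), d2 = c(50, 0), d3 = c(-50, 0), d4 = c(50, 0))
  ps <- pairSet(rbind(c("d1", "d2"), c("d1", "d3")),
                rbind(c("d2", "d4")))
  parts <- computeLoss(pairSet(rbind(c("d1", "d2"))), emb) +
    computeLoss(pairSet(rbind(c("d1", "d3"))), emb) +
    computeLoss(pairSet(rbind(c("d1", "d2")), rbind(c("d2", "d4"))), emb) -
    computeLoss(pairSet(rbind(c("d1", "d2"))), emb)
  expect_equal(computeLoss(ps, emb), parts, tolerance = 1e-10)
  expect_true(is.finite(computeLoss(ps, emb)))
  expect_gte(computeLoss(ps, emb), 0)
})

test_that("pair sets reject overlap, self-pairs and duplicates", {
  expect_error(pairSet(rbind(c("d1", "d1"))), "self-pair")
  expect_error(pairSet(rbind(c("d1", "d2")), rbind(c("d2", "d1"))),
               "disjoint")
  # duplicates collapse silently in the constructor
  ps <- pairSet(rbind(c("d1", "d2"), c("d2", "d1")))
  expect_equal(nrow(positivePairs(ps)), 1L)
})

test_that("negative sampling is seeded, sized and complement-restricted", {
  g <- buildGraph(dg = data.frame(from = paste0("d", 1:8), to = "g1"),
                  quiet = TRUE)
  pos <- rbind(c("d1", "d2"), c("d3", "d4"))
  n1 <- sampleNegatives(g, pos, ratio = 5, seed = 3)
  n2 <- sampleNegatives(g, pos, ratio = 5, seed = 3)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), 10L)
  expect_false(any(MetaPathDD:::pairKeys(n1) %in%
                     MetaPathDD:::pairKeys(pos)))
  # exclusion honored
  n3 <- sampleNegatives(g, pos, ratio = 2, seed = 3, exclude = n1[1:3, ])
  expect_false(any(MetaPathDD:::pairKeys(n3) %in%
                     MetaPathDD:::pairKeys(n1[1:3, , drop = FALSE])))
})

test_that("an exhausted complement returns all pairs with a warning", {
  g <- buildGraph(dg = data.frame(from = c("d1", "d2", "d3"), to = "g1"),
                  quiet = TRUE)
  allp <- t(combn(c("d1", "d2", "d3"), 2))
  expect_warning(n0 <- sampleNegatives(g, allp, ratio = 1, seed = 1),
                 "no disease pairs left")
  expect_equal(nrow(n0), 0L)
  expect_warning(n1 <- sampleNegatives(g, allp[1:2, ], ratio = 5, seed = 1),
                 "returning all")
  expect_equal(nrow(n1), 1L)
})
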