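test_that("schemas have disease ends and consistent type sequences", {
  sch <- metaPathSchemas()
  expect_named(sch, c("M1", "M2", "M3", "M4"))
  for (s in sch) {
    expect_equal(length(s@nodeTypes), length(s@edgeTypes) + 1L)
    expect_equal(s@nodeTypes[1], "DISEASE")
    expect_equal(s@nodeTypes[length(s@nodeTypes)], "DISEASE")
  }
  # the homolog-bridged path is the 5-node reading
  expect_equal(sch$M3@nodeTypes,
               c("DISEASE", "HGENE", "MGENE", "HGENE", "DISEASE"))
  expect_error(metaPathSchema("M9"), "unknown")
})

test_that("M1 instances from a shared gene include the degenerate walk", {
  g <- buildGraph(dg = data.frame(from = c("d1", "d2"), to = "g1"),
                  quiet = TRUE)
  im <- instanceMatrix(enumerateInstances(g, "M1", target = "d1"))
  expect_equal(walkKeys(im), sort(c("d1>g1>d1", "d1>g1>d2")))
  # neighborhood includes the target itself and d2
  expect_setequal(unique(im[, 3]), c("d1", "d2"))
})

test_that("no disease-gene edge means no instances", {
  g <- buildGraph(dg = data.frame(from = "d2", to = "g1"),
                  gg = data.frame(from = "g1", to = "g2"), quiet = TRUE)
  # d1 unknown -> fatal; d2 with M2 but no second disease -> palindromes only
  expect_error(enumerateInstances(g, "M1", target = "dX"), "unknown target")
  im <- instanceMatrix(enumerateInstances(g, "M1", target = "d2"))
  expect_equal(walkKeys(im), "d2>g1>d2")
})

test_that("M2 chains traverse PPI edges between disease genes", {
  g <- buildGraph(dg = data.frame(from = c("d1", "d2"), to = c("g1", "g2")),
                  gg = data.frame(from = "g1", to = "g2"), quiet = TRUE)
  im <- instanceMatrix(enumerateInstances(g, "M2", target = "d1"))
  expect_equal(walkKeys(im), walkKeys(oracleEnumerate(g, "M2", "d1")))
  expect_true("d1>g1>g2>d2" %in% walkKeys(im))
})

test_that("enumeration equals the join-based oracle on random graphs", {
  for (seed in 1:12) {
    g <- randomTypedGraph(seed)
    for (sid in c("M1", "M2", "M3", "M4")) {
      for (d in diseaseIds(g)) {
        got <- instanceMatrix(enumerateInstances(g, sid, target = d,
                                                 cap = NULL))
        expect_equal(walkKeys(got), walkKeys(oracleEnumerate(g, sid, d)),
                     info = sprintf("seed %d schema %s target %s",
                                    seed, sid, d))
      }
    }
  }
})

test_that("palindromic instance counts are symmetric between endpoints", {
  for (seed in 1:6) {
    g <- randomTypedGraph(seed + 100)
    ds <- diseaseIds(g)
    for (sid in c("M1", "M3")) {
      im <- instanceMatrix(enumerateInstances(g, sid, cap = NULL))
      if (!nrow(im)) next
      ends <- paste(im[, 1], im[, ncol(im)])
      rev <- paste(im[, ncol(im)], im[, 1])
      cnt <- table(ends)
      expect_equal(unname(cnt[names(cnt)]),
                   unname(table(rev)[names(cnt)]))
    }
  }
})

test_that("the instance cap subsamples deterministically per seed", {
  fix <- generateFixture(syntheticSpec(), seed = 3)
  g <- fixtureGraph(fix)
  a <- enumerateInstances(g, "M4", cap = 16, seed = 9)
  b <- enumerateInstances(g, "M4", cap = 16, seed = 9)
  c <- enumerateInstances(g, "M4", cap = 16, seed = 10)
  expect_identical(instanceMatrix(a), instanceMatrix(b))
  expect_false(identical(instanceMatrix(a), instanceMatrix(c)))
  # cap bounds the per-target count
  expect_true(max(table(instanceMatrix(a)[, 1])) <= 16)
  # capped rows are a subset of the full enumeration
  full <- walkKeys(instanceMatrix(enumerateInstances(g, "M4", cap = NULL)))
  expect_true(all(walkKeys(instanceMatrix(a)) %in% full))
})
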