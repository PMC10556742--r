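test_that("a saturated one-community spec yields complete structures", {
  sp <- syntheticSpec(nCommunities = 1, diseasesPerComm = 2,
                      hgenesPerComm = 2, phenosPerComm = 1,
                      dgWithin = 1, dgNoise = 0, ppiWithin = 1,
                      ppiBetween = 0, homologCoverage = 1, mpAttach = 1,
                      phenoOnlyFrac = 0, posRate = 1)
  fix <- generateFixture(sp, seed = 1)
  expect_equal(nrow(fix$tables$dg), 4L)        # complete bipartite 2x2
  expect_equal(nrow(fix$positives), 1L)
  expect_equal(nrow(fix$tables$homolog), 2L)
  g <- fixtureGraph(fix)
  expect_equal(sort(unique(nodeTable(g)$type)),
               c("DISEASE", "HGENE", "MGENE", "PHENO"))
})

test_that("zero noise probabilities imply zero cross-community edges", {
  sp <- syntheticSpec(dgNoise = 0, ppiBetween = 0, phenoOnlyFrac = 0)
  fix <- generateFixture(sp, seed = 2)
  comm <- function(id) sub("^p?[A-Z](\\d+)_.*$", "\\1", id)
  expect_true(all(comm(fix$tables$dg$from) == comm(fix$tables$dg$to)))
  expect_true(all(comm(fix$tables$ppi$a) == comm(fix$tables$ppi$b)))
})

test_that("the generator is a pure function of spec and seed", {
  f1 <- generateFixture(syntheticSpec(), seed = 5)
  f2 <- generateFixture(syntheticSpec(), seed = 5)
  f3 <- generateFixture(syntheticSpec(), seed = 6)
  expect_identical(f1, f2)
  expect_false(identical(f1$tables$dg, f3$tables$dg))
})

test_that("marginal edge counts are stable across seeds", {
  sp <- syntheticSpec()
  counts <- t(vapply(1:20, function(s) {
    f <- generateFixture(sp, seed = s)
    c(dg = nrow(f$tables$dg), ppi = nrow(f$tables$ppi),
      gp = nrow(f$tables$gp), hom = nrow(f$tables$homolog))
  }, numeric(4)))
  # expected within-community DG edges: 3 normal communities at p=0.25 on
  # an 8x20 grid, plus 20 forced private-gene edges in the phenotype-only
  # community, plus a small noise term; a loose 3-sigma style band
  expect_gt(mean(counts[, "dg"]), 110)
  expect_lt(mean(counts[, "dg"]), 190)
  # homologs: 80 genes at 60% coverage
  expect_gt(mean(counts[, "hom"]), 38)
  expect_lt(mean(counts[, "hom"]), 58)
  # dispersion sanity: seeds differ but not wildly
  expect_true(all(apply(counts, 2, sd) > 0))
  expect_lt(max(apply(counts, 2, sd) / colMeans(counts)), 0.35)
})

test_that("phenotype-only communities share no genes across diseases", {
  sp <- syntheticSpec(phenoOnlyFrac = 1, dgNoise = 0, ppiBetween = 0)
  fix <- generateFixture(sp, seed = 3)
  # each gene is owned by exactly one disease
  expect_true(all(table(fix$tables$dg$to) == 1))
  # PPI links stay inside one disease's private gene set
  owner <- stats::setNames(fix$tables$dg$from, fix$tables$dg$to)
  gene <- function(p) sub("^p", "", p)
  expect_true(all(owner[gene(fix$tables$ppi$a)] ==
                    owner[gene(fix$tables$ppi$b)]))
})

test_that("the shuffled null permutes positives deterministically", {
  fix <- generateFixture(syntheticSpec(), seed = 7)
  n1 <- shuffleNull(fix, seed = 1)
  n2 <- shuffleNull(fix, seed = 1)
  expect_identical(n1$positives, n2$positives)
  k0 <- MetaPathDD:::pairKeys(MetaPathDD:::asPairMatrix(fix$positives))
  k1 <- MetaPathDD:::pairKeys(MetaPathDD:::asPairMatrix(n1$positives))
  expect_lt(length(intersect(k0, k1)), length(k0))
  # graph tables untouched; pair degrees preserved under the relabeling
  expect_identical(n1$tables, fix$tables)
  expect_equal(sort(as.numeric(table(unlist(n1$positives)))),
               sort(as.numeric(table(unlist(fix$positives)))))
})

test_that("fixtures round-trip through the TSV writer and parsers", {
  fix <- generateFixture(syntheticSpec(nCommunities = 2, diseasesPerComm = 4,
                                       hgenesPerComm = 6, phenosPerComm = 2),
                         seed = 8)
  d <- tempfile()
  writeFixture(fix, d)
  expect_true(all(file.exists(file.path(d, c(
    "disease_gene.tsv", "gene_pheno.tsv", "homolog.tsv", "ppi_links.tsv",
    "protein_gene.tsv", "positives.tsv", "truth.json")))))
  dg <- parseAssociationTable(file.path(d, "disease_gene.tsv"))
  gp <- parseAssociationTable(file.path(d, "gene_pheno.tsv"))
  hom <- parseAssociationTable(file.path(d, "homolog.tsv"))
  map <- utils::read.delim(file.path(d, "protein_gene.tsv"), header = FALSE)
  gg <- parsePpiTable(file.path(d, "ppi_links.tsv"), mapping = map)
  g1 <- buildGraph(dg = dg, gg = gg, gm = hom, mp = gp, quiet = TRUE)
  g2 <- fixtureGraph(fix)
  expect_identical(nodeTable(g1), nodeTable(g2))
  expect_equal(edgeTable(g1)[, c("src", "dst", "type")],
               edgeTable(g2)[, c("src", "dst", "type")])
})
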