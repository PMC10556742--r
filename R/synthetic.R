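#' Synthetic fixture specification
#'
#' Parameters of the planted-community generator that emulates the five
#' input tables of the cross-species pipeline: disease-gene, mouse
#' gene-phenotype, human-mouse homolog, scored PPI links and the
#' protein-to-gene mapping, plus a positive disease-pair list.  Diseases
#' and genes are organized in communities; positive pairs live within
#' communities, so community structure is the recoverable signal.  In a
#' \emph{phenotype-only} community each disease owns a private gene set
#' (no shared genes, no cross-disease PPI), and its diseases are linked
#' only through mouse orthologs sharing phenotypes -- the meta-paths that
#' traverse the mouse layers are then the only informative ones.
#'
#' PPI confidence scores are drawn uniformly from 600-999 within
#' communities and 1-399 between, so the standard >= 400 confidence filter
#' retains exactly the within-community interactions.
#'
#' @param nCommunities number of planted communities.
#' @param diseasesPerComm,hgenesPerComm,phenosPerComm nodes per community.
#' @param dgWithin within-community disease-gene edge probability.
#' @param dgNoise cross-community disease-gene noise probability.
#' @param ppiWithin,ppiBetween PPI edge probabilities (within / between).
#' @param homologCoverage share of human genes with a mouse ortholog.
#' @param mpAttach mouse gene-phenotype attachment probability.
#' @param phenoOnlyFrac fraction of communities that are phenotype-only.
#' @param posRate sampling rate of within-community disease pairs into the
#'   positive list.
#' @return validated spec list.
#' @export
syntheticSpec <- function(nCommunities = 4L, diseasesPerComm = 8L,
                          hgenesPerComm = 20L, phenosPerComm = 5L,
                          dgWithin = 0.25, dgNoise = 0.01,
                          ppiWithin = 0.15, ppiBetween = 0.005,
                          homologCoverage = 0.6, mpAttach = 0.5,
                          phenoOnlyFrac = 0.25, posRate = 0.5) {
  probs <- c(dgWithin, dgNoise, ppiWithin, ppiBetween, homologCoverage,
             mpAttach, phenoOnlyFrac, posRate)
  stopifnot(all(probs >= 0), all(probs <= 1), nCommunities >= 1,
            diseasesPerComm >= 1, hgenesPerComm >= 1, phenosPerComm >= 1)
  structure(list(nCommunities = as.integer(nCommunities),
                 diseasesPerComm = as.integer(diseasesPerComm),
                 hgenesPerComm = as.integer(hgenesPerComm),
                 phenosPerComm = as.integer(phenosPerComm),
                 dgWithin = dgWithin, dgNoise = dgNoise,
                 ppiWithin = ppiWithin, ppiBetween = ppiBetween,
                 homologCoverage = homologCoverage, mpAttach = mpAttach,
                 phenoOnlyFrac = phenoOnlyFrac, posRate = posRate),
            class = "synthetic_spec")
}

## all unordered pairs of a character vector (0-row safe)
allPairsOf <- function(v) {
  if (length(v) < 2L) return(matrix(character(), 0, 2))
  t(utils::combn(v, 2))
}

#' Generate a synthetic five-table fixture
#'
#' Pure function of (spec, seed): emits the five association tables, the
#' positive disease-pair list and the ground-truth community map.
#'
#' @param spec from [syntheticSpec()].
#' @param seed RNG seed.
#' @return list with elements `tables` (data.frames `dg`, `gp`, `homolog`,
#'   `ppi`, `mapping`), `positives` (data.frame from/to) and `truth`
#'   (community assignment and phenotype-only flags).
#' @export
generateFixture <- function(spec = syntheticSpec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withSeed(derivedSeed(seed, 7L), {
    nC <- spec$nCommunities
    phenoOnly <- seq_len(nC) <= round(spec$phenoOnlyFrac * nC)
    dg <- gp <- hom <- ppi <- list()
    posL <- list()
    communities <- list()
    fmt <- function(p, c, i) sprintf("%s%02d_%02d", p, c, i)
    for (c in seq_len(nC)) {
      ds <- fmt("D", c, seq_len(spec$diseasesPerComm))
      gs <- fmt("G", c, seq_len(spec$hgenesPerComm))
      ph <- fmt("P", c, seq_len(spec$phenosPerComm))
      communities[[c]] <- list(diseases = ds, genes = gs, phenos = ph,
                               phenoOnly = phenoOnly[c])
      if (phenoOnly[c]) {
        ## private gene sets: community signal flows only through the
        ## mouse phenotype layer
        owner <- rep_len(seq_along(ds), length(gs))
        dg[[c]] <- data.frame(from = ds[owner], to = gs,
                              stringsAsFactors = FALSE)
        pp <- allPairsOf(gs)
        same <- owner[match(pp[, 1], gs)] == owner[match(pp[, 2], gs)]
        pp <- pp[same, , drop = FALSE]
        keep <- stats::runif(nrow(pp)) < spec$ppiWithin
        pp <- pp[keep, , drop = FALSE]
      } else {
        grid <- expand.grid(from = ds, to = gs, stringsAsFactors = FALSE)
        sel <- stats::runif(nrow(grid)) < spec$dgWithin
        dgc <- grid[sel, , drop = FALSE]
        lonely <- setdiff(ds, dgc$from)    # every disease keeps >= 1 gene
        if (length(lonely))
          dgc <- rbind(dgc, data.frame(
            from = lonely, to = sample(gs, length(lonely), replace = TRUE),
            stringsAsFactors = FALSE))
        dg[[c]] <- dgc
        pp <- allPairsOf(gs)
        pp <- pp[stats::runif(nrow(pp)) < spec$ppiWithin, , drop = FALSE]
      }
      if (nrow(pp))
        ppi[[length(ppi) + 1L]] <- data.frame(
          a = pp[, 1], b = pp[, 2],
          score = sample(600:999, nrow(pp), replace = TRUE),
          stringsAsFactors = FALSE)
      ## 1-1 mouse orthologs for a covered share of the community genes
      cov <- gs[stats::runif(length(gs)) < spec$homologCoverage]
      if (length(cov)) {
        mg <- sub("^G", "M", cov)
        hom[[c]] <- data.frame(from = cov, to = mg,
                               stringsAsFactors = FALSE)
        att <- expand.grid(from = mg, to = ph, stringsAsFactors = FALSE)
        att <- att[stats::runif(nrow(att)) < spec$mpAttach, , drop = FALSE]
        if (nrow(att)) gp[[c]] <- att
      }
      wp <- allPairsOf(ds)
      wp <- wp[stats::runif(nrow(wp)) < spec$posRate, , drop = FALSE]
      if (nrow(wp))
        posL[[c]] <- data.frame(from = wp[, 1], to = wp[, 2],
                                stringsAsFactors = FALSE)
    }
    ## cross-community noise layers
    allD <- unlist(lapply(communities, `[[`, "diseases"))
    allG <- unlist(lapply(communities, `[[`, "genes"))
    commOfD <- rep(seq_len(nC), each = spec$diseasesPerComm)
    commOfG <- rep(seq_len(nC), each = spec$hgenesPerComm)
    if (spec$dgNoise > 0 && nC > 1L) {
      grid <- expand.grid(di = seq_along(allD), gi = seq_along(allG))
      grid <- grid[commOfD[grid$di] != commOfG[grid$gi], , drop = FALSE]
      sel <- stats::runif(nrow(grid)) < spec$dgNoise
      if (any(sel))
        dg[[length(dg) + 1L]] <- data.frame(
          from = allD[grid$di[sel]], to = allG[grid$gi[sel]],
          stringsAsFactors = FALSE)
    }
    if (spec$ppiBetween > 0 && nC > 1L) {
      pp <- allPairsOf(allG)
      cross <- commOfG[match(pp[, 1], allG)] != commOfG[match(pp[, 2], allG)]
      pp <- pp[cross & stats::runif(nrow(pp)) < spec$ppiBetween, ,
               drop = FALSE]
      if (nrow(pp))
        ppi[[length(ppi) + 1L]] <- data.frame(
          a = pp[, 1], b = pp[, 2],
          score = sample(1:399, nrow(pp), replace = TRUE),
          stringsAsFactors = FALSE)
    }
    positives <- if (length(posL)) do.call(rbind, posL) else
      data.frame(from = character(), to = character())
    if (!nrow(positives))
      stop("spec implies zero positive disease pairs")
    ppiAll <- do.call(rbind, ppi)
    mapping <- data.frame(protein = paste0("p", allG), gene = allG,
                          stringsAsFactors = FALSE)
    tables <- list(
      dg = do.call(rbind, dg),
      gp = do.call(rbind, gp),
      homolog = do.call(rbind, hom),
      ppi = data.frame(a = paste0("p", ppiAll$a), b = paste0("p", ppiAll$b),
                       score = ppiAll$score, stringsAsFactors = FALSE),
      mapping = mapping)
    truth <- list(
      community = stats::setNames(
        as.list(commOfD), allD),
      phenoOnly = phenoOnly)
    list(tables = tables, positives = positives, truth = truth)
  })
}

#' Write a fixture to disk as five TSVs plus truth.json
#'
#' @param fixture from [generateFixture()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  wt(fixture$tables$dg, "disease_gene.tsv")
  wt(fixture$tables$gp, "gene_pheno.tsv")
  wt(fixture$tables$homolog, "homolog.tsv")
  wt(fixture$tables$ppi, "ppi_links.tsv")
  wt(fixture$tables$mapping, "protein_gene.tsv")
  wt(fixture$positives, "positives.tsv")
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Build the heterogeneous graph of a fixture
#'
#' Applies the same pipeline as the file-based path: PPI links filtered at
#' the confidence threshold and mapped to genes with unit weights, then
#' the four layers assembled into a [HetGraph-class].
#'
#' @param fixture from [generateFixture()].
#' @param minConfidence PPI confidence threshold.
#' @return a [HetGraph-class].
#' @export
fixtureGraph <- function(fixture, minConfidence = 400L) {
  tb <- fixture$tables
  keep <- tb$ppi$score >= minConfidence
  pmap <- stats::setNames(tb$mapping$gene, tb$mapping$protein)
  gg <- data.frame(from = unname(pmap[tb$ppi$a[keep]]),
                   to = unname(pmap[tb$ppi$b[keep]]),
                   stringsAsFactors = FALSE)
  buildGraph(dg = tb$dg, gg = gg, gm = tb$homolog, mp = tb$gp,
             quiet = TRUE)
}

#' Shuffled-null control fixture
#'
#' Relabels the diseases inside the positive pair list through a seeded
#' random permutation of all disease ids.  The graph tables are untouched
#' and each disease keeps its pair degree, but the alignment between
#' positives and planted communities is destroyed -- the no-signal
#' control for structure-recovery tests.
#'
#' @param fixture from [generateFixture()].
#' @param seed RNG seed.
#' @return fixture with permuted positives (truth marked `shuffled`).
#' @export
shuffleNull <- function(fixture, seed = 1L) {
  ds <- sort(unique(names(fixture$truth$community)))
  perm <- withSeed(derivedSeed(seed, 11L),
                   stats::setNames(sample(ds), ds))
  out <- fixture
  out$positives <- data.frame(from = unname(perm[fixture$positives$from]),
                              to = unname(perm[fixture$positives$to]),
                              stringsAsFactors = FALSE)
  out$truth$shuffled <- TRUE
  out
}
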