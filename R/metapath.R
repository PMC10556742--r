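SCHEMA_DEFS <- list(
  M1 = list(nodeTypes = c("DISEASE", "HGENE", "DISEASE"),
            edgeTypes = c("DG", "DG"),
            edgeSigns = c(1, -1)),
  M2 = list(nodeTypes = c("DISEASE", "HGENE", "HGENE", "DISEASE"),
            edgeTypes = c("DG", "GG", "DG"),
            edgeSigns = c(1, 1, -1)),
  M3 = list(nodeTypes = c("DISEASE", "HGENE", "MGENE", "HGENE", "DISEASE"),
            edgeTypes = c("DG", "GM", "GM", "DG"),
            edgeSigns = c(1, 1, -1, -1)),
  M4 = list(nodeTypes = c("DISEASE", "HGENE", "MGENE", "PHENO",
                          "MGENE", "HGENE", "DISEASE"),
            edgeTypes = c("DG", "GM", "MP", "MP", "GM", "DG"),
            edgeSigns = c(1, 1, 1, -1, -1, -1))
)

#' Meta-path schemas of the disease network
#'
#' The four disease-anchored meta-paths: M1 disease-gene-disease (two
#' diseases share a gene), M2 disease-gene-gene-disease (their genes'
#' proteins interact), M3 disease-gene-mouse gene-gene-disease (their
#' genes share a mouse ortholog) and M4
#' disease-gene-mouse gene-phenotype-mouse gene-gene-disease (their
#' orthologs share a mouse phenotype).
#'
#' @param id one of "M1", "M2", "M3", "M4".
#' @param ids character vector of schema ids.
#' @return `metaPathSchema` a [MetaPathSchema-class]; `metaPathSchemas` a
#'   named list of them.
#' @examples
#' metaPathSchema("M3")
#' @export
metaPathSchema <- function(id) {
  if (!id %in% names(SCHEMA_DEFS)) stop("unknown meta-path schema: ", id)
  d <- SCHEMA_DEFS[[id]]
  new("MetaPathSchema", id = id, nodeTypes = d$nodeTypes,
      edgeTypes = d$edgeTypes, edgeSigns = d$edgeSigns)
}

#' @rdname metaPathSchema
#' @export
metaPathSchemas <- function(ids = c("M1", "M2", "M3", "M4")) {
  stats::setNames(lapply(ids, metaPathSchema), ids)
}

setMethod("show", "MetaPathSchema", function(object) {
  abbr <- c(DISEASE = "D", HGENE = "G", MGENE = "M", PHENO = "P")
  cat(sprintf("MetaPathSchema %s: %s\n", object@id,
              paste(abbr[object@nodeTypes], collapse = "-")))
})

#' Enumerate meta-path instances
#'
#' Walks the typed graph from each target disease following the schema's
#' node/edge-type template and returns every conforming walk.  Nodes may
#' repeat across positions (the degenerate d-g-d walk back to the target
#' itself is a valid instance, keeping every connected disease in its own
#' neighborhood).  If a target has more than `cap` instances for the
#' schema, a seeded uniform subsample of size `cap` is kept; enumeration
#' is deterministic for a fixed seed.
#'
#' @param graph a [HetGraph-class].
#' @param schema a [MetaPathSchema-class] or schema id string.
#' @param target a disease id, or NULL for all disease nodes.
#' @param cap maximum instances per target (NULL/Inf for no cap).
#' @param seed RNG seed for the subsample.
#' @return a [MetaPathInstanceSet-class]; rows are walks, column 1 the
#'   target disease.
#' @examples
#' g <- buildGraph(dg = data.frame(from = c("d1", "d2"), to = "g1"),
#'                 quiet = TRUE)
#' instanceMatrix(enumerateInstances(g, "M1", target = "d1"))
#' @export
enumerateInstances <- function(graph, schema, target = NULL, cap = 128L,
                               seed = 1L) {
  if (is.character(schema)) schema <- metaPathSchema(schema)
  stopifnot(is(schema, "MetaPathSchema"))
  if (is.null(cap) || !is.finite(cap)) cap <- Inf
  ad <- typedAdjacency(graph)
  if (is.null(target)) {
    targets <- which(graph@nodes$type == "DISEASE")
  } else {
    if (!target %in% graph@nodes$id)
      stop("unknown target node: ", target)
    targets <- unname(ad$idx[target])
    if (graph@nodes$type[targets] != "DISEASE")
      stop("target is not a DISEASE node: ", target)
  }
  L <- length(schema@nodeTypes)
  out <- withSeed(derivedSeed(seed), {
    res <- vector("list", length(targets))
    for (k in seq_along(targets)) {
      w <- walkFrom(ad, schema, targets[k])
      if (nrow(w) > cap)
        w <- w[sort(sample.int(nrow(w), cap)), , drop = FALSE]
      res[[k]] <- w
    }
    do.call(rbind, res)
  })
  if (is.null(out)) out <- matrix(integer(), 0, L)
  inst <- matrix(graph@nodes$id[out], nrow = nrow(out), ncol = L)
  new("MetaPathInstanceSet", schema = schema, instances = inst)
}

## breadth-wise typed walk expansion from one start node (integer index)
walkFrom <- function(ad, schema, start) {
  walks <- matrix(start, nrow = 1L)
  for (i in seq_along(schema@edgeTypes)) {
    et <- schema@edgeTypes[i]
    sym <- EDGE_ENDPOINTS[[et]][1] == EDGE_ENDPOINTS[[et]][2]
    a <- ad$adj[[et]]
    last <- walks[, ncol(walks)]
    nbr <- if (sym) {
      mapply(function(f, r) c(f, r), a$fwd[last], a$rev[last],
             SIMPLIFY = FALSE)
    } else if (schema@edgeSigns[i] > 0) a$fwd[last] else a$rev[last]
    cnt <- lengths(nbr)
    if (!sum(cnt)) return(matrix(integer(), 0, length(schema@nodeTypes)))
    walks <- cbind(walks[rep.int(seq_along(cnt), cnt), , drop = FALSE],
                   unlist(nbr, use.names = FALSE))
  }
  walks
}

#' @describeIn MetaPathInstanceSet the walk matrix (character node ids)
#' @param x,object a `MetaPathInstanceSet`
#' @export
instanceMatrix <- function(x) x@instances

#' @describeIn MetaPathInstanceSet number of instances
#' @export
numInstances <- function(x) nrow(x@instances)

setMethod("show", "MetaPathInstanceSet", function(object) {
  cat(sprintf("MetaPathInstanceSet: %d instance(s) of schema %s (%d targets)\n",
              nrow(object@instances), object@schema@id,
              length(unique(object@instances[, 1]))))
})
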