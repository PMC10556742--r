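#' Assemble the cross-species heterogeneous network
#'
#' Combines the four association layers into one typed graph: human
#' disease-gene (\code{dg}), gene-gene links from the filtered PPI network
#' (\code{gg}), human-mouse homologs (\code{gm}) and mouse gene-phenotype
#' (\code{mp}).  Node sets are the unions over the layers; an identifier
#' claimed by two different node types is a fatal type collision.  Edges
#' are undirected, deduplicated, self-loop free and weighted 1.0.
#'
#' @param dg,gg,gm,mp data.frames with columns `from`, `to` (e.g. from
#'   [parseAssociationTable()] / [parsePpiTable()]).  Column orientation
#'   fixes node types: `dg` is disease-gene, `gm` is human gene-mouse
#'   gene, `mp` is mouse gene-phenotype; `gg` joins human genes.
#' @param quiet suppress the per-layer summary message.
#' @return a [HetGraph-class] object.
#' @examples
#' g <- buildGraph(dg = data.frame(from = "d1", to = "g1"))
#' nodeTable(g)
#' @export
buildGraph <- function(dg = NULL, gg = NULL, gm = NULL, mp = NULL,
                       quiet = FALSE) {
  layers <- list(DG = dg, GG = gg, GM = gm, MP = mp)
  nodeType <- character()
  edges <- list()
  claim <- function(types, ids, ty) {
    prev <- types[ids]
    bad <- !is.na(prev) & prev != ty
    if (any(bad))
      stop("node type collision: ", paste(unique(ids[bad]), collapse = ", "),
           " claimed as both ", ty, " and ",
           paste(unique(prev[bad]), collapse = ","))
    types[ids] <- ty
    types
  }
  for (et in names(layers)) {
    lay <- layers[[et]]
    if (is.null(lay) || !nrow(lay)) next
    a <- as.character(lay$from)
    b <- as.character(lay$to)
    if (et == "GG") {        # symmetric layer: canonical order src < dst
      lo <- pmin(a, b); hi <- pmax(a, b)
      a <- lo; b <- hi
    }
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    key <- paste0(a, "\r", b)
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
    want <- EDGE_ENDPOINTS[[et]]
    nodeType <- claim(nodeType, a, want[1])
    nodeType <- claim(nodeType, b, want[2])
    edges[[et]] <- data.frame(src = a, dst = b, type = et,
                              weight = 1.0, stringsAsFactors = FALSE)
  }
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(src = character(), dst = character(), type = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  ids <- sort(names(nodeType))
  nd <- data.frame(id = ids, type = unname(nodeType[ids]),
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$type, ed$src, ed$dst), , drop = FALSE]
  rownames(ed) <- NULL
  g <- new("HetGraph", nodes = nd, edges = ed)
  if (!quiet) {
    for (et in names(layers))
      if (!is.null(edges[[et]]))
        message(sprintf("%s layer: %d edges", et, nrow(edges[[et]])))
    message(sprintf("graph: %d nodes (%s), %d edges", nrow(nd),
                    paste(names(table(nd$type)), table(nd$type),
                          sep = "=", collapse = ", "), nrow(ed)))
  }
  g
}

#' @describeIn HetGraph node table (id, type)
#' @param x,object a `HetGraph`
#' @export
nodeTable <- function(x) x@nodes

#' @describeIn HetGraph edge table (src, dst, type, weight)
#' @export
edgeTable <- function(x) x@edges

#' @describeIn HetGraph ids of a given node type (default: all ids)
#' @param type optional node type filter
#' @export
nodeIds <- function(x, type = NULL) {
  if (is.null(type)) x@nodes$id else x@nodes$id[x@nodes$type == type]
}

#' @describeIn HetGraph disease node ids
#' @export
diseaseIds <- function(x) nodeIds(x, "DISEASE")

setMethod("show", "HetGraph", function(object) {
  nt <- table(factor(object@nodes$type, levels = NODE_TYPES))
  et <- table(factor(object@edges$type, levels = EDGE_TYPES))
  cat("HetGraph: cross-species heterogeneous biological network\n")
  cat(sprintf("  nodes: %d  (DISEASE %d | HGENE %d | MGENE %d | PHENO %d)\n",
              nrow(object@nodes), nt["DISEASE"], nt["HGENE"], nt["MGENE"],
              nt["PHENO"]))
  cat(sprintf("  edges: %d  (DG %d | GG %d | GM %d | MP %d)\n",
              nrow(object@edges), et["DG"], et["GG"], et["GM"], et["MP"]))
})

#' Serialize / restore a heterogeneous graph as TSV
#'
#' Writes `nodes.tsv` (id, type) and `edges.tsv` (src, dst, type, weight)
#' into `dir`; `readGraphDir` restores the object and revalidates it.
#'
#' @param graph a [HetGraph-class]
#' @param dir output directory (created if needed)
#' @return `writeGraphDir` returns `dir` invisibly; `readGraphDir` a
#'   [HetGraph-class].
#' @export
writeGraphDir <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(graph@nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(graph@edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeGraphDir
#' @export
readGraphDir <- function(dir) {
  nd <- utils::read.delim(file.path(dir, "nodes.tsv"),
                          colClasses = "character")
  ed <- utils::read.delim(file.path(dir, "edges.tsv"),
                          colClasses = c(src = "character",
                                         dst = "character",
                                         type = "character",
                                         weight = "numeric"))
  new("HetGraph", nodes = nd, edges = ed)
}

## typed adjacency: for each edge type, neighbor index lists in both
## directions, over integer node indices 1..N in nodeTable order
typedAdjacency <- function(graph) {
  idx <- stats::setNames(seq_len(nrow(graph@nodes)), graph@nodes$id)
  n <- length(idx)
  adj <- list()
  for (et in EDGE_TYPES) {
    sel <- graph@edges$type == et
    s <- unname(idx[graph@edges$src[sel]])
    d <- unname(idx[graph@edges$dst[sel]])
    fwd <- split(d, factor(s, levels = seq_len(n)))
    rev <- split(s, factor(d, levels = seq_len(n)))
    adj[[et]] <- list(fwd = fwd, rev = rev)
  }
  list(idx = idx, adj = adj, n = n)
}
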