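#' @import methods
NULL

## node and edge type vocabulary of the cross-species network
NODE_TYPES <- c("DISEASE", "HGENE", "MGENE", "PHENO")
EDGE_TYPES <- c("DG", "GG", "GM", "MP")

## endpoint node types demanded by each edge type (canonical orientation:
## src carries the first type, dst the second; GG is ordered src < dst)
EDGE_ENDPOINTS <- list(
  DG = c("DISEASE", "HGENE"),
  GG = c("HGENE",  "HGENE"),
  GM = c("HGENE",  "MGENE"),
  MP = c("MGENE",  "PHENO")
)

#' Typed heterogeneous biological network
#'
#' Container for the four-layer cross-species network: human disease-gene
#' associations (\code{DG}), protein-protein interactions between the
#' coding genes (\code{GG}), human-mouse homologous gene links (\code{GM})
#' and mouse gene-phenotype associations (\code{MP}).  Edges are
#' undirected, stored once in a canonical orientation, carry weight 1.0,
#' and every endpoint is typed as one of \code{DISEASE}, \code{HGENE},
#' \code{MGENE} or \code{PHENO}.
#'
#' @slot nodes data.frame with columns \code{id} (character) and
#'   \code{type} (character, one of the four node types).
#' @slot edges data.frame with columns \code{src}, \code{dst},
#'   \code{type} and \code{weight}.
#'
#' @seealso [buildGraph()], [nodeTable()], [edgeTable()]
#' @export
setClass("HetGraph",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("HetGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (!all(c("id", "type") %in% names(nd)))
    return("nodes must have columns id, type")
  if (!all(c("src", "dst", "type", "weight") %in% names(ed)))
    return("edges must have columns src, dst, type, weight")
  if (anyDuplicated(nd$id))
    msgs <- c(msgs, "duplicated node ids")
  if (!all(nd$type %in% NODE_TYPES))
    msgs <- c(msgs, "unknown node type")
  if (nrow(ed)) {
    if (!all(ed$type %in% EDGE_TYPES))
      msgs <- c(msgs, "unknown edge type")
    typeOf <- stats::setNames(nd$type, nd$id)
    for (et in unique(ed$type)) {
      sel <- ed$type == et
      want <- EDGE_ENDPOINTS[[et]]
      if (!all(typeOf[ed$src[sel]] == want[1], na.rm = FALSE) ||
          !all(typeOf[ed$dst[sel]] == want[2]))
        msgs <- c(msgs, sprintf("edge type %s joins wrong node types", et))
    }
    if (any(ed$src == ed$dst))
      msgs <- c(msgs, "self-loop present")
    key <- paste(ed$type, ed$src, ed$dst)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate edges")
    if (any(ed$weight[ed$type == "GG"] != 1))
      msgs <- c(msgs, "GG edge weights must all equal 1.0")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Meta-path schema over the heterogeneous network
#'
#' An ordered node-type / edge-type template both of whose ends are
#' \code{DISEASE}.  Four schemas are predefined: M1 (D-G-D), M2 (D-G-G-D),
#' M3 (D-G-M-G-D) and M4 (D-G-M-P-M-G-D).  \code{edgeSigns} records the
#' traversal direction of each edge relative to its canonical orientation;
#' the relational rotation encoder conjugates the relation vector on
#' reverse traversal.
#'
#' @slot id character schema label.
#' @slot nodeTypes character vector of node types along the path.
#' @slot edgeTypes character vector of edge types (one shorter).
#' @slot edgeSigns numeric vector of +1/-1 traversal directions.
#' @export
setClass("MetaPathSchema",
  representation(id = "character", nodeTypes = "character",
                 edgeTypes = "character", edgeSigns = "numeric"))

setValidity("MetaPathSchema", function(object) {
  if (length(object@nodeTypes) != length(object@edgeTypes) + 1L)
    return("node-type sequence must be one longer than edge-type sequence")
  if (object@nodeTypes[1] != "DISEASE" ||
      object@nodeTypes[length(object@nodeTypes)] != "DISEASE")
    return("both ends of a schema must be DISEASE")
  if (length(object@edgeSigns) != length(object@edgeTypes))
    return("edgeSigns must match edgeTypes in length")
  for (i in seq_along(object@edgeTypes)) {
    want <- EDGE_ENDPOINTS[[object@edgeTypes[i]]]
    if (object@edgeSigns[i] < 0) want <- rev(want)
    if (object@nodeTypes[i] != want[1] || object@nodeTypes[i + 1] != want[2])
      return(sprintf("edge %d inconsistent with node types", i))
  }
  TRUE
})

#' Set of meta-path instances sharing one schema
#'
#' Each row of \code{instances} is a concrete typed walk whose node types
#' match the schema positionally and whose consecutive nodes are joined by
#' an edge of the schema's edge type.  Column 1 holds the target disease.
#'
#' @slot schema the [MetaPathSchema-class] the walks conform to.
#' @slot instances character matrix, one walk per row.
#' @export
setClass("MetaPathInstanceSet",
  representation(schema = "MetaPathSchema", instances = "matrix"))

setValidity("MetaPathInstanceSet", function(object) {
  if (nrow(object@instances) &&
      ncol(object@instances) != length(object@schema@nodeTypes))
    return("instance width must match schema length")
  TRUE
})

#' Positive and sampled negative disease pairs
#'
#' Unordered disease-id pairs: the known-association positives and a
#' disjoint sampled negative set used by the negative-sampling loss.
#'
#' @slot positives character matrix (n x 2), each row sorted.
#' @slot negatives character matrix (m x 2), each row sorted.
#' @export
setClass("PairSet",
  representation(positives = "matrix", negatives = "matrix"))

setValidity("PairSet", function(object) {
  pk <- pairKeys(object@positives)
  nk <- pairKeys(object@negatives)
  if (any(object@positives[, 1] == object@positives[, 2]) ||
      any(object@negatives[, 1] == object@negatives[, 2]))
    return("self-pair (d,d) not allowed")
  if (anyDuplicated(pk) || anyDuplicated(nk))
    return("duplicate pairs")
  if (length(intersect(pk, nk)))
    return("positives and negatives must be disjoint")
  TRUE
})

#' Trained meta-path attention embedding model
#'
#' Holds the learnable tensors of the embedding network (node features,
#' per-type projections, relation phase vectors, intra- and inter-path
#' attention parameters, output projection), the configuration they were
#' trained under, and the per-epoch loss trace.
#'
#' @slot graph the [HetGraph-class] the model was trained on.
#' @slot params named list of parameter arrays.
#' @slot config embedding configuration list (see [embedConfig()]).
#' @slot schemaIds character vector of meta-path schema ids used.
#' @slot lossTrace numeric per-epoch training loss.
#' @export
setClass("EmbedModel",
  representation(graph = "HetGraph", params = "list", config = "ANY",
                 schemaIds = "character", lossTrace = "numeric"))

#' Cross-validation report
#'
#' Per-repeat, per-fold AUC and average precision of the link predictor,
#' plus their means.  Values are stored on the [0,1] scale; \code{show}
#' prints percentages with two decimals.
#'
#' @slot results data.frame with columns repeat_, fold, auc, ap.
#' @slot folds number of folds.
#' @slot repeats number of repeats.
#' @slot seed master seed of the run.
#' @export
setClass("CVReport",
  representation(results = "data.frame", folds = "numeric",
                 repeats = "numeric", seed = "numeric"))
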