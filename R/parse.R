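#' Parse a two-column association table
#'
#' Reads a tab-separated association report (MGI-report style: disease-gene,
#' gene-phenotype or homolog tables), extracts two identifier columns,
#' drops blank or malformed rows with a diagnostic count, and returns
#' deduplicated undirected edges (each pair stored once, sorted).
#'
#' @param path path to a TSV file; lines starting with `#` are ignored.
#' @param columns integer vector of length 2 giving the (1-based) indices
#'   of the two identifier columns; report layouts vary by release, so the
#'   mapping is declared rather than guessed.
#' @return data.frame with columns `from`, `to`; one row per unique
#'   undirected pair.
#' @examples
#' tf <- tempfile()
#' writeLines(c("d1\tg1", "d2\tg1", "d1\tg1"), tf)
#' parseAssociationTable(tf)
#' @export
parseAssociationTable <- function(path, columns = c(1L, 2L)) {
  raw <- readAssocTsv(path)
  if (max(columns) > ncol(raw))
    stop("zero valid rows in ", path, ": fewer columns than requested (",
         ncol(raw), " < ", max(columns), ")")
  a <- trimws(as.character(raw[[columns[1]]]))
  b <- trimws(as.character(raw[[columns[2]]]))
  ok <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & a != b
  nbad <- sum(!ok)
  if (nbad > 0)
    message(nbad, " blank/malformed/self-pair row(s) skipped in ", path)
  if (!any(ok))
    stop("zero valid rows in ", path, " (", nbad, " rows skipped)")
  dedupPairs(a[ok], b[ok])
}

#' Parse a STRING-style scored protein link table
#'
#' Retains interactions whose combined confidence score is at least
#' `minConfidence` (default 400, the threshold used to prune low-confidence
#' links), maps each protein to its coding gene through `mapping`, drops
#' unmapped rows with a diagnostic count, and returns deduplicated
#' undirected gene-gene edges, every edge weighted 1.0.
#'
#' @param path TSV/whitespace-separated file with columns protein-a,
#'   protein-b, combined-score (indices configurable via `columns`).
#' @param mapping data.frame whose first two columns are protein id and
#'   gene id, or NULL to use protein ids directly.
#' @param minConfidence integer score threshold; rows with score >=
#'   `minConfidence` are kept.
#' @param columns integer vector of length 3: protein-a, protein-b, score.
#' @return data.frame with columns `from`, `to`, `weight` (all 1.0).
#' @export
parsePpiTable <- function(path, mapping = NULL, minConfidence = 400L,
                          columns = c(1L, 2L, 3L)) {
  raw <- readAssocTsv(path)
  if (max(columns) > ncol(raw))
    stop("zero valid rows in ", path, ": fewer columns than requested")
  a <- trimws(as.character(raw[[columns[1]]]))
  b <- trimws(as.character(raw[[columns[2]]]))
  sc <- suppressWarnings(as.numeric(as.character(raw[[columns[3]]])))
  badScore <- is.na(sc) & nzchar(trimws(as.character(raw[[columns[3]]])))
  if (any(badScore))
    warning(sum(badScore), " row(s) with non-numeric score skipped in ", path)
  ok <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & !is.na(sc)
  keep <- ok & sc >= minConfidence
  a <- a[keep]; b <- b[keep]
  if (!is.null(mapping)) {
    pmap <- stats::setNames(as.character(mapping[[2]]),
                            as.character(mapping[[1]]))
    ga <- unname(pmap[a]); gb <- unname(pmap[b])
    unmapped <- is.na(ga) | is.na(gb)
    if (any(unmapped))
      message(sum(unmapped), " PPI row(s) dropped: protein without gene mapping")
    a <- ga[!unmapped]; b <- gb[!unmapped]
  }
  nonself <- a != b
  ed <- dedupPairs(a[nonself], b[nonself])
  ed$weight <- rep(1.0, nrow(ed))
  ed
}

## read a TSV skipping '#' comment lines; missing file is fatal
readAssocTsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    stop("zero valid rows in ", path, " (empty or comments only)")
  dt <- tryCatch(
    data.table::fread(text = lines, sep = "\t", header = FALSE,
                      data.table = FALSE, colClasses = "character",
                      fill = TRUE, quote = ""),
    error = function(e) stop("zero valid rows in ", path, ": ",
                             conditionMessage(e)))
  if (!nrow(dt) || !ncol(dt)) stop("zero valid rows in ", path)
  dt
}

## store each undirected pair once (first-seen orientation kept, so
## bipartite layers preserve their column typing), duplicates removed
dedupPairs <- function(a, b) {
  key <- paste0(pmin(a, b), "\r", pmax(a, b))
  keep <- !duplicated(key)
  data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
}
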