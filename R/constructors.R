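#' Construct an OntologyGraph
#'
#' @param terms `data.frame` with columns `accession`, `name`, `definition`,
#'   `namespace`, `is_obsolete` (missing text columns default to `""`,
#'   `is_obsolete` to `FALSE`).
#' @param edges `data.frame` with columns `child`, `parent` (is-a pairs).
#' @param aliases named character vector mapping alt_id accessions to
#'   canonical ones.
#' @param namespaces the declared namespace set; defaults to the namespaces
#'   occurring in `terms` union `c("BP","CC","MF")`.
#' @return An [OntologyGraph-class] object.
#' @export
OntologyGraph <- function(terms, edges = NULL, aliases = character(),
                          namespaces = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (is.null(terms$name)) terms$name <- ""
  if (is.null(terms$definition)) terms$definition <- ""
  if (is.null(terms$is_obsolete)) terms$is_obsolete <- FALSE
  terms <- terms[, c("accession", "name", "definition", "namespace",
                     "is_obsolete")]
  rownames(terms) <- NULL
  if (is.null(edges) || !nrow(as.data.frame(edges)))
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)[, c("child",
                                                              "parent")]
  rownames(edges) <- NULL
  if (is.null(namespaces))
    namespaces <- union(c("BP", "CC", "MF"), unique(terms$namespace))
  new("OntologyGraph", terms = terms, edges = edges,
      aliases = aliases, namespaces = namespaces)
}

#' @describeIn OntologyGraph Accessions of all terms in the graph.
#' @param x,object an `OntologyGraph`.
#' @export
accessions <- function(x) x@terms$accession

#' @describeIn OntologyGraph The term record table.
#' @export
termData <- function(x) x@terms

#' @describeIn OntologyGraph The is-a edge table (columns `child`, `parent`).
#' @export
isaEdges <- function(x) x@edges

#' @describeIn OntologyGraph Named vector accession -> namespace.
#' @export
termNamespaces <- function(x) setNames(x@terms$namespace, x@terms$accession)

#' Resolve accessions through alt_id aliases
#'
#' Secondary accessions (recorded as `alt_id` in OBO, typically the result
#' of term merges between ontology versions) are mapped to their canonical
#' accession; canonical accessions pass through unchanged.
#'
#' @param graph an [OntologyGraph-class].
#' @param ids character vector of accessions.
#' @return character vector of canonical accessions.
#' @export
resolveAccessions <- function(graph, ids) {
  hit <- ids %in% names(graph@aliases)
  ids[hit] <- unname(graph@aliases[ids[hit]])
  ids
}

#' Construct a LabelTable
#'
#' @param labels named character vector with values `POS`, `NEG` or
#'   `UNKNOWN` (or a data.frame with columns `accession`, `label` and
#'   optionally `provenance`).
#' @param provenance named character vector (or single value recycled);
#'   one of `gold`, `curated`, `propagated_desc`, `propagated_anc`.
#' @return A [LabelTable-class] object.
#' @export
LabelTable <- function(labels = character(), provenance = "gold") {
  if (is.data.frame(labels)) {
    prov <- if (!is.null(labels$provenance)) labels$provenance else provenance
    provenance <- prov
    labels <- setNames(labels$label, labels$accession)
  }
  if (length(provenance) == 1L)
    provenance <- rep(provenance, length(labels))
  names(provenance) <- names(labels)
  new("LabelTable", labels = labels, provenance = provenance)
}

#' Query and update label tables
#'
#' `labelOf` returns the label of each requested accession (`UNKNOWN` for
#' accessions absent from the table).  `setLabels` returns a new table with
#' the given accessions (re)labelled.  `positiveTerms` / `negativeTerms` /
#' `labelledTerms` return the accessions carrying a POS / NEG / either
#' label.
#'
#' @param x a [LabelTable-class].
#' @param ids character vector of accessions.
#' @param label single label value to assign.
#' @param provenance provenance recorded for the assignment.
#' @return `labelOf`: character vector parallel to `ids`; `setLabels`: a new
#'   `LabelTable`; the others: character vectors of accessions.
#' @export
labelOf <- function(x, ids) {
  out <- x@labels[ids]
  out[is.na(out)] <- "UNKNOWN"
  setNames(out, ids)
}

#' @rdname labelOf
#' @export
setLabels <- function(x, ids, label, provenance = "curated") {
  if (!length(ids)) return(x)
  lab <- x@labels
  prov <- x@provenance
  lab[ids] <- label
  prov[ids] <- provenance
  new("LabelTable", labels = lab, provenance = prov)
}

#' @rdname labelOf
#' @export
positiveTerms <- function(x) names(x@labels)[x@labels == "POS"]

#' @rdname labelOf
#' @export
negativeTerms <- function(x) names(x@labels)[x@labels == "NEG"]

#' @rdname labelOf
#' @export
labelledTerms <- function(x) names(x@labels)[x@labels != "UNKNOWN"]

#' @rdname labelOf
#' @export
labelProvenance <- function(x) x@provenance

setMethod("as.data.frame", "LabelTable", function(x, ...) {
  data.frame(accession = names(x@labels), label = unname(x@labels),
             provenance = unname(x@provenance), stringsAsFactors = FALSE)
})

#' Read / write a label table as TSV
#'
#' Three tab-separated columns with a header: `accession`, `label` in
#' `{+,-,?}`, `provenance`.  `+` maps to POS, `-` to NEG, `?` to UNKNOWN.
#'
#' @param path file path.
#' @param graph optional [OntologyGraph-class]; when given, accessions are
#'   resolved through its alt_id aliases.
#' @return [LabelTable-class] for the reader; invisibly `path` for the
#'   writer.
#' @export
readLabelTable <- function(path, graph = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          quote = "", comment.char = "")
  if (!all(c("accession", "label") %in% names(df)))
    stop("label TSV must have columns 'accession' and 'label'")
  map <- c("+" = "POS", "-" = "NEG", "?" = "UNKNOWN")
  bad <- setdiff(unique(df$label), names(map))
  if (length(bad))
    stop("unknown label symbol(s): ", paste(bad, collapse = ", "))
  acc <- df$accession
  if (!is.null(graph)) acc <- resolveAccessions(graph, acc)
  prov <- if (!is.null(df$provenance)) df$provenance else "gold"
  LabelTable(setNames(unname(map[df$label]), acc), provenance = prov)
}

#' @rdname readLabelTable
#' @param x a [LabelTable-class] to write.
#' @export
writeLabelTable <- function(x, path) {
  map <- c(POS = "+", NEG = "-", UNKNOWN = "?")
  df <- data.frame(accession = names(x@labels),
                   label = unname(map[x@labels]),
                   provenance = unname(x@provenance),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an AssociationTable
#'
#' Collapses duplicate (gene, term) pairs and builds both lookup indexes.
#'
#' @param assoc `data.frame` with columns `gene`, `term`.
#' @return An [AssociationTable-class].
#' @export
AssociationTable <- function(assoc) {
  assoc <- as.data.frame(assoc, stringsAsFactors = FALSE)[, c("gene", "term")]
  assoc <- unique(assoc)
  rownames(assoc) <- NULL
  g2t <- split(assoc$term, assoc$gene)
  t2g <- split(assoc$gene, assoc$term)
  new("AssociationTable", assoc = assoc, gene2terms = g2t, term2genes = t2g)
}

#' @describeIn AssociationTable The unique (gene, term) association rows.
#' @param x an `AssociationTable`.
#' @export
associations <- function(x) x@assoc

#' @describeIn AssociationTable All gene-product identifiers in the table.
#' @export
geneProducts <- function(x) names(x@gene2terms)
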