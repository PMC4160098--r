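#' Read a GAF 2.1/2.2 gene association file
#'
#' Applies the standard filtering for property-class discovery: rows whose
#' qualifier field contains a negation component (`NOT`, possibly combined
#' as `NOT|...`) are removed; every evidence code is retained, including
#' IEA (uncurated electronic annotations); duplicate (gene, term) rows are
#' collapsed.  Gene identity is `DB:DB_Object_ID` (columns 1 and 2), since
#' annotations from all organisms are pooled and symbols collide.
#'
#' @param path path to a GAF file; comment lines start with `!`.
#' @param graph optional [OntologyGraph-class]; when supplied, term
#'   accessions are resolved through alt_id aliases and associations to
#'   unknown terms are dropped.
#' @return An [AssociationTable-class].
#' @export
readGaf <- function(path, graph = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lineNo <- which(!startsWith(lines, "!") & nzchar(lines))
  lines <- lines[lineNo]
  if (!length(lines))
    return(AssociationTable(data.frame(gene = character(),
                                       term = character(),
                                       stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 15L)
  if (length(bad))
    stop(sprintf("GAF parse error: line %d has %d columns (>= 15 required)",
                 lineNo[bad[1]], nf[bad[1]]))
  db <- vapply(fields, `[[`, "", 1L)
  objid <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  negated <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                    function(q) any(q == "NOT"), logical(1))
  gene <- paste0(db, ":", objid)
  keep <- !negated
  gene <- gene[keep]; term <- term[keep]
  if (!is.null(graph)) {
    term <- resolveAccessions(graph, term)
    known <- term %in% graph@terms$accession
    gene <- gene[known]; term <- term[known]
  }
  AssociationTable(data.frame(gene = gene, term = term,
                              stringsAsFactors = FALSE))
}

#' Write associations as GAF 2.2
#'
#' Emits one minimally populated 17-column GAF row per association, enough
#' to round-trip through [readGaf()].
#'
#' @param x an [AssociationTable-class].
#' @param path output file path.
#' @param taxon taxon column value.
#' @return Invisibly, `path`.
#' @export
writeGaf <- function(x, path, taxon = "taxon:32644") {
  a <- x@assoc
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("!gaf-version: 2.2", "!generated-by: ontoloop"), con)
  if (nrow(a)) {
    sp <- regexpr(":", a$gene, fixed = TRUE)
    db <- substr(a$gene, 1L, sp - 1L)
    oid <- substr(a$gene, sp + 1L, nchar(a$gene))
    rows <- paste(db, oid, oid, "involved_in", a$term, "REF:0000001",
                  "IEA", "", "P", "", "", "protein", taxon, "20130408",
                  "ontoloop", "", "", sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Annotation queries
#'
#' `explicitTerms` returns the distinct terms directly annotated to a gene
#' product, with no propagation to ancestors (the form used for
#' lipid-relatedness gene weights).  `annotatedGenesInclusive` returns the
#' distinct gene products annotated to a term or any of its descendants
#' (the true-path direction used for term co-annotation scores).
#'
#' @param gene a gene-product identifier.
#' @param table an [AssociationTable-class].
#' @param term a term accession.
#' @param closure a [ClosureTable-class].
#' @return Character vector of accessions / gene identifiers.
#' @export
explicitTerms <- function(gene, table) {
  out <- table@gene2terms[[gene]]
  if (is.null(out)) character(0) else unique(out)
}

#' @rdname explicitTerms
#' @export
annotatedGenesInclusive <- function(term, table, closure) {
  .checkKnown(closure, term)
  members <- termDescendantsInclusive(term, closure)
  out <- unique(unlist(table@term2genes[members], use.names = FALSE))
  if (is.null(out)) character(0) else out
}
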