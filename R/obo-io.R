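## OBO 1.2/1.4 flat-file reader and writer.
##
## Only the tags the method needs are interpreted: id, name, namespace, def,
## is_a, relationship, is_obsolete, alt_id.  Everything else is ignored.
## part_of / regulates edges are dropped unless explicitly requested, because
## only the is-a relationship transmits a term property from parent to child.

# Long GO namespace names are abbreviated to the conventional two-letter
# codes; any other namespace string passes through unchanged.
.NS_ABBREV <- c(biological_process = "BP",
                cellular_component = "CC",
                molecular_function = "MF")

.abbrevNamespace <- function(ns) {
  hit <- ns %in% names(.NS_ABBREV)
  ns[hit] <- unname(.NS_ABBREV[ns[hit]])
  ns
}

# Strip an OBO def line: quoted string plus trailing dbxref bracket.
# 'def: "some text." [GOC:xyz]' -> 'some text.'
.parseDef <- function(x) {
  m <- regmatches(x, regexpr('^"(\\\\.|[^"\\\\])*"', x))
  if (!length(m)) return(trimws(sub("\\[[^]]*\\]\\s*$", "", x)))
  inner <- substr(m, 2L, nchar(m) - 1L)
  gsub('\\\\(.)', "\\1", inner)
}

#' Read an OBO 1.2/1.4 ontology file
#'
#' Parses `[Term]` stanzas into an [OntologyGraph-class].  By default only
#' `is_a` edges are kept; `relationship:` edges (part_of, regulates, ...)
#' are retained only when named in `keep_relationships`.  Obsolete terms are
#' kept as records but stripped of edges; `alt_id` lines are recorded as
#' aliases resolving to the canonical accession.
#'
#' @param path path to an OBO file.
#' @param keep_relationships character vector of relationship type names to
#'   keep as edges; default `"is_a"` only.
#' @return An [OntologyGraph-class].
#' @export
readObo <- function(path, keep_relationships = "is_a") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("(^|[^\\\\])!.*$", "\\1", lines)  # trailing comments
  n <- length(lines)
  acc <- nam <- def <- ns <- character(0)
  obs <- logical(0)
  childv <- parentv <- character(0)
  alias_from <- alias_to <- character(0)

  cur <- NULL
  inTerm <- FALSE
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    acc <<- c(acc, cur$id)
    nam <<- c(nam, cur$name %||% "")
    def <<- c(def, cur$def %||% "")
    ns <<- c(ns, cur$namespace %||% "")
    obs <<- c(obs, isTRUE(cur$obsolete))
    if (!isTRUE(cur$obsolete) && length(cur$parents)) {
      childv <<- c(childv, rep(cur$id, length(cur$parents)))
      parentv <<- c(parentv, cur$parents)
    }
    if (length(cur$alt)) {
      alias_from <<- c(alias_from, cur$alt)
      alias_to <<- c(alias_to, rep(cur$id, length(cur$alt)))
    }
  }

  for (i in seq_len(n)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (grepl("^\\[", line)) {
      if (inTerm) flush()
      inTerm <- identical(line, "[Term]")
      cur <- list(parents = character(0), alt = character(0))
      next
    }
    if (!inTerm) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1L)
      stop(sprintf("malformed OBO stanza line %d: '%s'", i, line))
    tag <- substr(line, 1L, colon - 1L)
    val <- trimws(substr(line, colon + 1L, nchar(line)))
    if (tag == "id") {
      if (val == "") stop(sprintf("empty id at OBO line %d", i))
      cur$id <- val
    } else if (tag == "name") cur$name <- val
    else if (tag == "namespace") cur$namespace <- .abbrevNamespace(val)
    else if (tag == "def") cur$def <- .parseDef(val)
    else if (tag == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (tag == "alt_id") cur$alt <- c(cur$alt, val)
    else if (tag == "is_a" && "is_a" %in% keep_relationships) {
      if (val == "") stop(sprintf("malformed is_a at OBO line %d", i))
      cur$parents <- c(cur$parents, val)
    } else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L)
        stop(sprintf("malformed relationship at OBO line %d: '%s'", i, line))
      if (parts[1] %in% setdiff(keep_relationships, "is_a"))
        cur$parents <- c(cur$parents, parts[2])
    }
  }
  if (inTerm) flush()

  terms <- data.frame(accession = acc, name = nam, definition = def,
                      namespace = ns, is_obsolete = obs,
                      stringsAsFactors = FALSE)
  edges <- unique(data.frame(child = childv, parent = parentv,
                             stringsAsFactors = FALSE))
  # edges pointing at obsolete parents are dropped with their record kept
  if (nrow(edges)) {
    obsAcc <- terms$accession[terms$is_obsolete]
    edges <- edges[!(edges$parent %in% obsAcc), , drop = FALSE]
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- .findCycle(edges)
      stop("cyclic is_a relationship: ", paste(cyc, collapse = " -> "))
    }
  }
  aliases <- setNames(alias_to, alias_from)
  OntologyGraph(terms, edges, aliases = aliases)
}

# one representative cycle, for the error message
.findCycle <- function(edges) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1)[1]
  nodes <- names(comp$membership)[comp$membership == big]
  sub <- igraph::induced_subgraph(g, nodes)
  # walk until repetition
  cur <- nodes[1]; seen <- character(0)
  repeat {
    seen <- c(seen, cur)
    nxt <- names(igraph::neighbors(sub, cur, mode = "out"))[1]
    if (nxt %in% seen)
      return(c(seen[which(seen == nxt):length(seen)], nxt))
    cur <- nxt
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an OntologyGraph as an OBO file
#'
#' Emits a minimal OBO 1.2 document (header plus one `[Term]` stanza per
#' term) that round-trips through [readObo()].
#'
#' @param graph an [OntologyGraph-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeObo <- function(graph, path) {
  tm <- graph@terms
  ed <- graph@edges
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("date: ", format(Sys.Date(), "%d:%m:%Y")),
               "saved-by: ontoloop", ""), con)
  longNs <- setNames(names(.NS_ABBREV), unname(.NS_ABBREV))
  byChild <- split(ed$parent, ed$child)
  rev_alias <- if (length(graph@aliases))
    split(names(graph@aliases), unname(graph@aliases)) else list()
  for (i in seq_len(nrow(tm))) {
    a <- tm$accession[i]
    out <- c("[Term]", paste0("id: ", a), paste0("name: ", tm$name[i]))
    nsl <- tm$namespace[i]
    if (nsl %in% names(longNs)) nsl <- longNs[[nsl]]
    out <- c(out, paste0("namespace: ", nsl))
    for (al in rev_alias[[a]]) out <- c(out, paste0("alt_id: ", al))
    if (nzchar(tm$definition[i]))
      out <- c(out, sprintf('def: "%s" []',
                            gsub('"', '\\\\"', tm$definition[i])))
    for (p in byChild[[a]]) out <- c(out, paste0("is_a: ", p))
    if (tm$is_obsolete[i]) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
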