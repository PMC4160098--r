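#' Strict transitive closure of the is-a DAG
#'
#' Computes every (descendant, ancestor) pair reachable through one or more
#' is-a edges, by dynamic programming over a topological order (each term's
#' ancestor set is the union of its parents and their ancestor sets).  The
#' closure is strict: reflexive pairs are never included, so ancestor and
#' descendant queries are unambiguous; aggregation that needs the term
#' itself uses the explicit inclusive variants.
#'
#' @param graph an [OntologyGraph-class] (must be acyclic, which the class
#'   validity already enforces).
#' @return A [ClosureTable-class].
#' @export
transitiveClosure <- function(graph) {
  ed <- graph@edges
  allAcc <- graph@terms$accession
  if (!nrow(ed)) {
    anc <- desc <- setNames(vector("list", length(allAcc)), allAcc)
    anc[] <- list(character(0)); desc[] <- list(character(0))
    return(new("ClosureTable",
               pairs = data.frame(descendant = character(),
                                  ancestor = character(),
                                  stringsAsFactors = FALSE),
               ancIndex = anc, descIndex = desc))
  }
  g <- igraph::graph_from_edgelist(as.matrix(ed), directed = TRUE)
  if (!igraph::is_dag(g))
    stop("cycle detected: ", paste(.findCycle(ed), collapse = " -> "))
  nodes <- igraph::V(g)$name
  idx <- setNames(seq_along(nodes), nodes)
  parents <- lapply(igraph::adjacent_vertices(g, nodes, mode = "out"),
                    as.integer)
  # reverse topological order of the child -> parent graph: parents first
  ord <- rev(as.integer(igraph::topo_sort(g, mode = "out")))
  ancSets <- vector("list", length(nodes))
  for (v in ord) {
    ps <- parents[[v]]
    if (!length(ps)) { ancSets[[v]] <- integer(0); next }
    ancSets[[v]] <- unique(c(ps, unlist(ancSets[ps], use.names = FALSE)))
  }
  descN <- unlist(lapply(seq_along(nodes),
                         function(v) rep.int(v, length(ancSets[[v]]))),
                  use.names = FALSE)
  ancN <- unlist(ancSets, use.names = FALSE)
  pairs <- data.frame(descendant = nodes[descN], ancestor = nodes[ancN],
                      stringsAsFactors = FALSE)
  ancIndex <- setNames(vector("list", length(allAcc)), allAcc)
  ancIndex[] <- list(character(0))
  descIndex <- ancIndex
  ancIndex[nodes] <- lapply(ancSets, function(s) nodes[s])
  sp <- split(pairs$descendant, pairs$ancestor)
  descIndex[names(sp)] <- sp
  new("ClosureTable", pairs = pairs, ancIndex = ancIndex,
      descIndex = descIndex)
}

#' @describeIn ClosureTable The (descendant, ancestor) pair table.
#' @param x a `ClosureTable`.
#' @export
closurePairs <- function(x) x@pairs

.checkKnown <- function(closure, term) {
  bad <- setdiff(term, names(closure@ancIndex))
  if (length(bad))
    stop("unknown accession(s): ", paste(bad, collapse = ", "))
}

#' Ancestor / descendant queries on a closure table
#'
#' Strict queries exclude the term itself; `termDescendantsInclusive` adds
#' it back, which is the variant used when aggregating annotations over a
#' term's subtree (the true-path direction).
#'
#' @param term character vector of accessions.
#' @param closure a [ClosureTable-class].
#' @return Character vector of accessions (union over `term`).
#' @export
termAncestors <- function(term, closure) {
  .checkKnown(closure, term)
  unique(unlist(closure@ancIndex[term], use.names = FALSE))
}

#' @rdname termAncestors
#' @export
termDescendants <- function(term, closure) {
  .checkKnown(closure, term)
  unique(unlist(closure@descIndex[term], use.names = FALSE))
}

#' @rdname termAncestors
#' @export
termDescendantsInclusive <- function(term, closure) {
  unique(c(term, termDescendants(term, closure)))
}
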