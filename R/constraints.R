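## Inheritance-constraint machinery.
##
## The constraint: if an ancestor term has the target property (POS), every
## descendant necessarily has it too.  Contrapositive: no NEG term may have
## a POS ancestor.  Checking uses the strict closure; propagation amplifies
## curation decisions (descendants of a curated positive become positive,
## ancestors of a curated negative become negative).

.emptyViolations <- function() {
  data.frame(ancestor = character(), descendant = character(),
             descendant_label = character(), stringsAsFactors = FALSE)
}

#' Check the inheritance constraint
#'
#' Reports every labelled-POS term with a descendant that is not POS
#' (NEG or UNKNOWN/unlabelled).  By default each offending descendant is
#' reported once, paired with its nearest (lowest) POS ancestor, to keep
#' reports small; `full = TRUE` returns every offending (POS ancestor,
#' descendant) pair.  An empty result is equivalent to consistency.  Each
#' violation admits two manual resolutions: relabel the descendant POS, or
#' relabel the ancestor NEG — the choice is a curator's, never automated
#' here.
#'
#' @param labels a [LabelTable-class].
#' @param closure a [ClosureTable-class] over the same graph.
#' @param full report all offending pairs instead of nearest-ancestor ones.
#' @return `data.frame` with columns `ancestor`, `descendant`,
#'   `descendant_label`; zero rows iff the labels are consistent.
#' @export
checkInheritance <- function(labels, closure, full = FALSE) {
  pos <- intersect(positiveTerms(labels), names(closure@descIndex))
  if (!length(pos)) return(.emptyViolations())
  descs <- closure@descIndex[pos]
  nd <- lengths(descs)
  anc <- rep.int(pos, nd)
  dsc <- unlist(descs, use.names = FALSE)
  lab <- labelOf(labels, dsc)
  bad <- lab != "POS"
  if (!any(bad)) return(.emptyViolations())
  out <- data.frame(ancestor = anc[bad], descendant = dsc[bad],
                    descendant_label = unname(lab[bad]),
                    stringsAsFactors = FALSE)
  if (full) {
    rownames(out) <- NULL
    return(out[order(out$descendant, out$ancestor), , drop = FALSE])
  }
  # nearest POS ancestor per offending descendant: a POS ancestor that is
  # not itself an ancestor of another POS ancestor of the same descendant
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$descendant),
    function(rows) {
      a <- out$ancestor[rows]
      if (length(a) == 1L) return(rows)
      isAbove <- vapply(a, function(ai)
        any(vapply(setdiff(a, ai),
                   function(aj) ai %in% closure@ancIndex[[aj]],
                   logical(1))), logical(1))
      cand <- rows[!isAbove]
      cand[order(out$ancestor[cand])][1]
    }), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$descendant), , drop = FALSE]
}

#' Propagate labels through the DAG
#'
#' `propagatePositiveDown` sets every strict descendant of the POS seed
#' terms to POS (provenance `propagated_desc`); `propagateNegativeUp` sets
#' every strict ancestor of the NEG seeds to NEG (provenance
#' `propagated_anc`).  Both are idempotent and return the set of terms that
#' actually changed (the desc+ / ance- bonus of a curation batch).  A
#' propagation that would flip an explicit opposite label is a genuine
#' constraint conflict and raises an error carrying the offending pairs —
#' such cases require a curator's decision and are never resolved silently.
#'
#' @param labels a [LabelTable-class].
#' @param seeds character vector of seed accessions (must already carry the
#'   label being propagated).
#' @param closure a [ClosureTable-class].
#' @return A list with elements `labels` (the updated [LabelTable-class])
#'   and `descPlus` (resp. `ancMinus`): accessions newly labelled.
#' @export
propagatePositiveDown <- function(labels, seeds, closure) {
  if (!length(seeds))
    return(list(labels = labels, descPlus = character(0)))
  sl <- labelOf(labels, seeds)
  if (any(sl != "POS"))
    stop("seeds not labelled POS: ",
         paste(seeds[sl != "POS"], collapse = ", "))
  desc <- termDescendants(seeds, closure)
  lab <- labelOf(labels, desc)
  conflict <- desc[lab == "NEG"]
  if (length(conflict))
    stop("propagation conflict: descendant(s) already NEG under a POS ",
         "ancestor (curator decision required): ",
         paste(conflict, collapse = ", "))
  newly <- desc[lab != "POS"]
  list(labels = setLabels(labels, newly, "POS", "propagated_desc"),
       descPlus = newly)
}

#' @rdname propagatePositiveDown
#' @export
propagateNegativeUp <- function(labels, seeds, closure) {
  if (!length(seeds))
    return(list(labels = labels, ancMinus = character(0)))
  sl <- labelOf(labels, seeds)
  if (any(sl != "NEG"))
    stop("seeds not labelled NEG: ",
         paste(seeds[sl != "NEG"], collapse = ", "))
  anc <- termAncestors(seeds, closure)
  lab <- labelOf(labels, anc)
  conflict <- anc[lab == "POS"]
  if (length(conflict))
    stop("propagation conflict: ancestor(s) already POS above a NEG ",
         "descendant (curator decision required): ",
         paste(conflict, collapse = ", "))
  newly <- anc[lab != "NEG"]
  list(labels = setLabels(labels, newly, "NEG", "propagated_anc"),
       ancMinus = newly)
}

#' Map curated labels onto a newer ontology version
#'
#' Ontologies evolve: terms become obsolete, merge (alt_id), get renamed or
#' redefined, and structural changes can break the inheritance constraint
#' (a previously positive parent may gain a negative or unexamined child).
#' This carries a label table from one graph version to another and reports
#' everything a curator must re-examine; it never auto-resolves violations.
#'
#' @param old_labels a [LabelTable-class] keyed by old-version accessions.
#' @param old_graph the [OntologyGraph-class] the labels were curated on.
#' @param new_graph the target [OntologyGraph-class].
#' @return A list with `labels` (the carried [LabelTable-class]) and
#'   `report`, itself a list: `dropped_obsolete` (accessions whose term is
#'   gone or obsolete in the new version), `changed_text` (carried terms
#'   whose name or definition changed, flagged for re-curation),
#'   `violations` (from [checkInheritance()] on the carried labels) and
#'   `carried` (count transferred unchanged).
#' @export
mapLabelsBetweenVersions <- function(old_labels, old_graph, new_graph) {
  oldAcc <- names(old_labels@labels)
  canon <- resolveAccessions(new_graph, oldAcc)
  newTerms <- new_graph@terms
  status <- setNames(rep("missing", length(canon)), oldAcc)
  inNew <- canon %in% newTerms$accession
  obsNew <- setNames(newTerms$is_obsolete, newTerms$accession)
  status[inNew] <- ifelse(obsNew[canon[inNew]], "obsolete", "carried")
  keep <- status == "carried"
  dropped <- oldAcc[!keep]

  carriedLabels <- setNames(unname(old_labels@labels[oldAcc[keep]]),
                            canon[keep])
  carriedProv <- setNames(unname(old_labels@provenance[oldAcc[keep]]),
                          canon[keep])
  # collapse alt_id merges deterministically (first occurrence wins; a
  # merge that disagrees on the label is surfaced as changed-text territory
  # for the curator via the violation/report path)
  dup <- duplicated(names(carriedLabels))
  newLabels <- new("LabelTable", labels = carriedLabels[!dup],
                   provenance = carriedProv[!dup])

  oldTm <- old_graph@terms
  oldName <- setNames(oldTm$name, oldTm$accession)
  oldDef <- setNames(oldTm$definition, oldTm$accession)
  newName <- setNames(newTerms$name, newTerms$accession)
  newDef <- setNames(newTerms$definition, newTerms$accession)
  carriedOld <- oldAcc[keep][!dup]
  carriedNew <- canon[keep][!dup]
  known <- carriedOld %in% names(oldName)
  changed <- carriedNew[known &
    (oldName[carriedOld] != newName[carriedNew] |
     oldDef[carriedOld] != newDef[carriedNew])]

  violations <- checkInheritance(newLabels, transitiveClosure(new_graph))
  list(labels = newLabels,
       report = list(dropped_obsolete = dropped,
                     changed_text = unname(changed),
                     violations = violations,
                     carried = length(carriedNew) - length(changed)))
}
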