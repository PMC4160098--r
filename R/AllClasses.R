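#' @import methods
#' @importFrom data.table data.table as.data.table setkey setkeyv := .N .SD
#' @importFrom stats setNames
NULL

# data.table NSE variable names used throughout
utils::globalVariables(c(
  "accession", "ancestor", "descendant", "child", "parent", "gene", "term",
  "label", "namespace", "weight", "member", "score", "nPos", "nNeg", "J"
))

#' Ontology graph of is-a relationships
#'
#' Holds the term records of an ontology (across one or more namespaces,
#' typically the three Gene Ontology sub-ontologies BP, CC and MF) together
#' with its is-a edge set.  Only is-a edges are stored because only the is-a
#' relationship lets a child term inherit a property (such as
#' lipid-relatedness) from its parent; part-of and regulates edges are
#' discarded at load time.
#'
#' @slot terms `data.frame` with columns `accession`, `name`, `definition`,
#'   `namespace`, `is_obsolete`.
#' @slot edges `data.frame` with columns `child`, `parent`; each row is one
#'   is-a edge (child is-a parent).
#' @slot aliases named `character`; maps secondary (alt_id) accessions to
#'   their canonical accession.
#' @slot namespaces `character`; the declared namespace set.
#'
#' @export
setClass("OntologyGraph",
  representation(
    terms = "data.frame",
    edges = "data.frame",
    aliases = "character",
    namespaces = "character"
  ),
  prototype(
    terms = data.frame(accession = character(), name = character(),
                       definition = character(), namespace = character(),
                       is_obsolete = logical(), stringsAsFactors = FALSE),
    edges = data.frame(child = character(), parent = character(),
                       stringsAsFactors = FALSE),
    aliases = character(),
    namespaces = c("BP", "CC", "MF")
  )
)

setValidity("OntologyGraph", function(object) {
  tm <- object@terms
  ed <- object@edges
  msgs <- character()
  if (anyDuplicated(tm$accession))
    msgs <- c(msgs, "duplicated term accessions")
  if (length(object@namespaces) &&
      !all(tm$namespace %in% object@namespaces))
    msgs <- c(msgs, "term namespace outside the declared namespace set")
  if (nrow(ed)) {
    known <- tm$accession
    if (!all(ed$child %in% known) || !all(ed$parent %in% known))
      msgs <- c(msgs, "edge endpoint not present in terms")
    else {
      ns <- setNames(tm$namespace, tm$accession)
      if (!all(ns[ed$child] == ns[ed$parent]))
        msgs <- c(msgs, "edge connects terms of different namespaces")
      obs <- tm$accession[tm$is_obsolete]
      if (any(ed$child %in% obs) || any(ed$parent %in% obs))
        msgs <- c(msgs, "obsolete term carries edges")
      g <- igraph::graph_from_edgelist(as.matrix(ed[, c("child", "parent")]),
                                       directed = TRUE)
      if (!igraph::is_dag(g))
        msgs <- c(msgs, "is-a edges contain a cycle")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Strict transitive closure of an ontology graph
#'
#' The set of all (descendant, ancestor) accession pairs reachable through
#' one or more is-a edges.  The closure is strict (irreflexive): no term is
#' its own ancestor.  Per-term ancestor and descendant indexes are built at
#' construction for O(1) lookup.
#'
#' @slot pairs `data.frame` with columns `descendant`, `ancestor`.
#' @slot ancIndex named `list`; accession -> character vector of strict
#'   ancestors.
#' @slot descIndex named `list`; accession -> character vector of strict
#'   descendants.
#'
#' @export
setClass("ClosureTable",
  representation(pairs = "data.frame", ancIndex = "list", descIndex = "list"),
  prototype(pairs = data.frame(descendant = character(),
                               ancestor = character(),
                               stringsAsFactors = FALSE),
            ancIndex = list(), descIndex = list())
)

setValidity("ClosureTable", function(object) {
  p <- object@pairs
  if (nrow(p) && any(p$descendant == p$ancestor))
    return("closure must be irreflexive")
  TRUE
})

#' Per-term class labels with provenance
#'
#' Maps term accessions to a class label in `POS` / `NEG` / `UNKNOWN`
#' (the GO+/GO-/GO? notation of curated lipid-relatedness generalises to any
#' binary term property).  Each labelled entry records where the label came
#' from: `gold` (initial gold standard), `curated` (a curator decision),
#' `propagated_desc` (descendant of a positive term, forced positive by the
#' inheritance constraint) or `propagated_anc` (ancestor of a negative term,
#' forced negative by its contrapositive).
#'
#' @slot labels named `character` in `c("POS","NEG","UNKNOWN")`.
#' @slot provenance named `character`, same names as `labels`.
#'
#' @export
setClass("LabelTable",
  representation(labels = "character", provenance = "character"),
  prototype(labels = character(), provenance = character())
)

.LABELS <- c("POS", "NEG", "UNKNOWN")
.PROVENANCE <- c("gold", "curated", "propagated_desc", "propagated_anc")

setValidity("LabelTable", function(object) {
  msgs <- character()
  if (!all(object@labels %in% .LABELS))
    msgs <- c(msgs, "labels must be POS, NEG or UNKNOWN")
  if (length(object@labels) != length(object@provenance) ||
      !identical(names(object@labels), names(object@provenance)))
    msgs <- c(msgs, "labels and provenance must be parallel named vectors")
  if (!all(object@provenance %in% .PROVENANCE))
    msgs <- c(msgs, "unknown provenance value")
  if (anyDuplicated(names(object@labels)))
    msgs <- c(msgs, "duplicated accessions in label table")
  if (length(msgs)) msgs else TRUE
})

#' Filtered gene-product association table
#'
#' Direct (explicit) gene-product-to-term associations after the standard
#' filtering: rows with a negative qualifier removed, all evidence codes
#' retained (including IEA), duplicate (gene, term) rows collapsed.  Gene
#' identity is the database-qualified id (`DB:DB_Object_ID`), never the
#' symbol, because symbols collide across the pooled organisms.
#'
#' @slot assoc `data.frame` with columns `gene`, `term`; unique rows.
#' @slot gene2terms named `list`; gene -> character vector of terms.
#' @slot term2genes named `list`; term -> character vector of genes.
#'
#' @export
setClass("AssociationTable",
  representation(assoc = "data.frame", gene2terms = "list",
                 term2genes = "list"),
  prototype(assoc = data.frame(gene = character(), term = character(),
                               stringsAsFactors = FALSE),
            gene2terms = list(), term2genes = list())
)

setValidity("AssociationTable", function(object) {
  if (anyDuplicated(object@assoc[, c("gene", "term")]))
    return("duplicate (gene, term) associations must be collapsed")
  TRUE
})

#' Result of an iterative or non-iterative predict-curate run
#'
#' @slot iterations `list` of per-iteration records.  Each record is a list
#'   with elements `iteration`, `batch` (data.frame accession/score), `tp`,
#'   `fp`, `ignored`, `descPlus`, `ancMinus` (character vectors),
#'   `trainSize` (integer) and `snapshot` (named numeric: prediction scores
#'   of the whole test set as it stood at the start of the iteration).
#' @slot finalLabels `LabelTable` after the last iteration (all curated and
#'   propagated labels applied).
#' @slot finalSnapshot named `numeric`; prediction scores of the surviving
#'   test set under the final model (after the last iteration's labels).
#' @slot iterative `logical`; `FALSE` for the single-training baseline.
#' @slot mode `character`; `"efficiency"` (negative-score batch entries
#'   discarded) or `"pr"` (kept).
#' @slot featureSet `character`; `"all"` or `"keywords"`.
#' @slot testPositives `character`; reference positives present in the
#'   initial test set (known in simulated runs), used by evaluation.
#' @slot initialTest `character`; the initial test set.
#'
#' @export
setClass("LoopResult",
  representation(iterations = "list", finalLabels = "LabelTable",
                 finalSnapshot = "numeric", iterative = "logical",
                 mode = "character", featureSet = "character",
                 testPositives = "character", initialTest = "character"),
  prototype(iterations = list(), finalSnapshot = numeric(),
            iterative = TRUE, mode = "efficiency", featureSet = "all",
            testPositives = character(), initialTest = character())
)

#' Self-contained synthetic ontology + annotation dataset
#'
#' Ground-truth labels satisfy the inheritance constraint by construction
#' (positives are planted as whole subtrees).  `withheld` lists the terms a
#' ground-truth curation oracle will answer `UNKNOWN` for, emulating GO?
#' terms that a real curator never examined.
#'
#' @slot graph `OntologyGraph`.
#' @slot labels `LabelTable`; complete POS/NEG ground truth.
#' @slot assoc `AssociationTable`.
#' @slot withheld `character`.
#' @slot config `list`; the generator configuration, including the seed.
#'
#' @export
setClass("SyntheticDataset",
  representation(graph = "OntologyGraph", labels = "LabelTable",
                 assoc = "AssociationTable", withheld = "character",
                 config = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "OntologyGraph", function(object) {
  tm <- object@terms
  cat("OntologyGraph with", nrow(tm), "terms and", nrow(object@edges),
      "is-a edges\n")
  if (nrow(tm)) {
    tab <- table(tm$namespace)
    cat("  namespaces:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    cat("  obsolete terms:", sum(tm$is_obsolete), "\n")
  }
  if (length(object@aliases))
    cat("  alt_id aliases:", length(object@aliases), "\n")
  invisible(object)
})

setMethod("show", "ClosureTable", function(object) {
  cat("ClosureTable:", nrow(object@pairs),
      "strict (descendant, ancestor) pairs over",
      length(object@ancIndex), "terms\n")
  invisible(object)
})

setMethod("show", "LabelTable", function(object) {
  tab <- table(factor(object@labels, levels = .LABELS))
  cat("LabelTable:", length(object@labels), "terms (",
      paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  invisible(object)
})

setMethod("show", "AssociationTable", function(object) {
  cat("AssociationTable:", nrow(object@assoc), "associations,",
      length(object@gene2terms), "gene products,",
      length(object@term2genes), "terms\n")
  invisible(object)
})

setMethod("show", "LoopResult", function(object) {
  cat(sprintf("LoopResult (%s, %s mode, %s features): %d iterations\n",
              if (object@iterative) "iterative" else "non-iterative",
              object@mode, object@featureSet, length(object@iterations)))
  if (length(object@iterations)) {
    eff <- sum(vapply(object@iterations,
                      function(r) length(r$tp) + length(r$fp), integer(1)))
    hit <- sum(vapply(object@iterations,
                      function(r) length(r$tp) + length(r$descPlus),
                      integer(1)))
    cat("  cumulative curation effort:", eff, " hit:", hit, "\n")
  }
  invisible(object)
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (seed", object@config$seed, ")\n")
  show(object@graph)
  show(object@labels)
  show(object@assoc)
  cat("  withheld (oracle UNKNOWN):", length(object@withheld), "\n")
  invisible(object)
})
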