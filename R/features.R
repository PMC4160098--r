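#' The default lipid keyword list
#'
#' The 36 lowercase keywords describing common lipid-related compounds
#' (LIPID MAPS-informed) used as binary text features.  Their exact forms
#' were chosen for precision and coverage without any natural-language
#' processing: e.g. `fats` rather than `fat` (so "fate" never matches) and
#' both the noun `sterol` and the adjective `steryl`; `bile acid` is the
#' single multi-token entry and matches as a literal substring including
#' the space.  The order is fixed — it defines the feature indices.
#'
#' @param path optional path to a one-keyword-per-line UTF-8 file; defaults
#'   to the list shipped with the package.
#' @return Character vector of keywords.
#' @export
lipidKeywords <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lipid_keywords.txt",
                        package = "ontoloop", mustWork = TRUE)
  kws <- readLines(path, warn = FALSE, encoding = "UTF-8")
  kws <- trimws(kws[nzchar(trimws(kws))])
  if (anyDuplicated(kws)) stop("duplicate keywords in ", path)
  if (!length(kws)) stop("empty keyword list: ", path)
  tolower(kws)
}

#' Binary keyword features of term text
#'
#' Bit i is 1 iff keyword i occurs as a case-insensitive substring of the
#' term name or definition — whether standing alone or inside a composite
#' word (so `lipo` matches "lipoprotein").  Keyword hits are deliberately
#' never propagated to ancestors: doing so trades a little sensitivity for
#' a large loss of specificity.
#'
#' @param terms an [OntologyGraph-class], or a `data.frame` with columns
#'   `accession`, `name`, `definition`.
#' @param keywords keyword list (see [lipidKeywords()]).
#' @return Integer 0/1 matrix, one row per term (rownames = accessions),
#'   one column per keyword.
#' @export
keywordFeatures <- function(terms, keywords = lipidKeywords()) {
  if (is(terms, "OntologyGraph")) terms <- terms@terms
  text <- tolower(paste(terms$name, terms$definition))
  bits <- vapply(keywords,
                 function(kw) as.integer(grepl(kw, text, fixed = TRUE)),
                 integer(length(text)))
  bits <- matrix(bits, nrow = length(text),
                 dimnames = list(terms$accession, keywords))
  bits
}

.weightTable <- function(labels, table, graph) {
  a <- as.data.table(table@assoc)
  if (!nrow(a))
    return(data.table(gene = character(), namespace = character(),
                      weight = numeric()))
  nsMap <- termNamespaces(graph)
  a[, namespace := nsMap[term]]
  a[, label := labelOf(labels, term)]
  lab <- a[label %in% c("POS", "NEG")]
  if (!nrow(lab))
    return(data.table(gene = character(), namespace = character(),
                      weight = numeric()))
  w <- lab[, .(nPos = sum(label == "POS"), nNeg = sum(label == "NEG")),
           by = .(gene, namespace)]
  w[, weight := nPos / (nPos + nNeg)]
  w[, .(gene, namespace, weight)]
}

#' Per-gene lipid-relatedness weights
#'
#' For each gene product and namespace, the weight is the number of its
#' POS explicit annotations divided by the number of its POS-or-NEG
#' explicit annotations in that namespace (distinct terms; annotations are
#' never propagated to ancestors here).  When the gene has no labelled
#' explicit annotation in a namespace the weight does not exist and `NA`
#' is returned — absence is distinct from a weight of zero.
#'
#' @param gene a gene-product identifier.
#' @param labels a [LabelTable-class].
#' @param table an [AssociationTable-class].
#' @param graph an [OntologyGraph-class] (supplies term namespaces).
#' @param namespace namespace code, e.g. `"BP"`.
#' @return `geneWeight`: a single numeric in \[0,1\] or `NA`;
#'   `geneWeights`: a `data.frame` (gene, namespace, weight) of the weights
#'   that exist.
#' @export
geneWeight <- function(gene, labels, table, graph, namespace) {
  terms <- explicitTerms(gene, table)
  ns <- termNamespaces(graph)[terms]
  terms <- terms[!is.na(ns) & ns == namespace]
  lab <- labelOf(labels, terms)
  nPos <- sum(lab == "POS"); nNeg <- sum(lab == "NEG")
  if (nPos + nNeg == 0L) return(NA_real_)
  nPos / (nPos + nNeg)
}

#' @rdname geneWeight
#' @export
geneWeights <- function(labels, table, graph) {
  as.data.frame(.weightTable(labels, table, graph))
}

#' Co-annotation sub-ontology score of a term
#'
#' Over the distinct gene products annotated to the term or any of its
#' descendants, the score is the mean of the genes' weights in the given
#' namespace, averaging only genes whose weight exists.  When the term has
#' no associated gene product, or none of them has a weight in that
#' namespace, the score is 0.  Scores therefore always lie in \[0,1\].
#'
#' @inheritParams geneWeight
#' @param term a term accession.
#' @param closure a [ClosureTable-class].
#' @param weights optional precomputed `geneWeights()` table.
#' @return Numeric score in \[0,1\].
#' @export
termSubontologyScore <- function(term, namespace, labels, table, graph,
                                 closure, weights = NULL) {
  if (is.null(weights)) weights <- geneWeights(labels, table, graph)
  genes <- annotatedGenesInclusive(term, table, closure)
  if (!length(genes)) return(0)
  w <- weights$weight[weights$namespace == namespace &
                        weights$gene %in% genes]
  if (!length(w)) return(0)
  mean(w)
}

#' Assemble the full feature matrix
#'
#' One row per non-obsolete term: the binary keyword bits followed by one
#' co-annotation score per namespace (for the default BP/CC/MF set this is
#' the 36 + 3 = 39-feature representation).  All namespace scores are
#' computed for every term regardless of the term's own namespace.  Scores
#' depend on the current labels through the gene weights and are always
#' recomputed from scratch; keyword bits depend only on term text and may
#' be precomputed once and passed in via `kwBits`.
#'
#' @inheritParams geneWeight
#' @param closure a [ClosureTable-class].
#' @param keywords keyword list.
#' @param kwBits optional precomputed [keywordFeatures()] matrix.
#' @return Numeric matrix, rownames = accessions, with
#'   `length(keywords) + length(namespaces)` columns; score columns are
#'   named `<ns>_score` in lower case.
#' @export
featurizeAll <- function(graph, labels, table, closure,
                         keywords = lipidKeywords(), kwBits = NULL) {
  tm <- graph@terms[!graph@terms$is_obsolete, , drop = FALSE]
  if (is.null(kwBits)) kwBits <- keywordFeatures(tm, keywords)
  kwBits <- kwBits[tm$accession, , drop = FALSE]
  nss <- graph@namespaces
  scores <- matrix(0, nrow = nrow(tm), ncol = length(nss),
                   dimnames = list(tm$accession,
                                   paste0(tolower(nss), "_score")))
  w <- .weightTable(labels, table, graph)
  a <- as.data.table(table@assoc)
  if (nrow(w) && nrow(a)) {
    # inclusive (term, member) membership: self plus strict descendants
    cp <- as.data.table(closure@pairs)
    members <- rbind(data.table(term = tm$accession, member = tm$accession),
                     cp[, .(term = ancestor, member = descendant)])
    setkey(a, term)
    tg <- a[members, on = c(term = "member"), nomatch = NULL,
            .(term = i.term, gene = x.gene), allow.cartesian = TRUE]
    tg <- unique(tg)
    setkey(w, gene)
    tw <- w[tg, on = "gene", nomatch = NULL, allow.cartesian = TRUE]
    sc <- tw[, .(score = mean(weight)), by = .(term, namespace)]
    sc <- sc[term %in% tm$accession]
    if (nrow(sc)) {
      col <- match(paste0(tolower(sc$namespace), "_score"),
                   colnames(scores))
      scores[cbind(match(sc$term, tm$accession), col)] <- sc$score
    }
  }
  cbind(kwBits, scores)
}
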