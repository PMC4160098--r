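## Synthetic ontology + annotation generator.
##
## Emulates the structure the method exploits: a multi-rooted is-a DAG over
## three namespaces, property-positive labels planted as whole subtrees (so
## the inheritance constraint holds by construction), term text with tunable
## keyword insertion (the rest of the positives are "implicit" — recognisable
## only through co-annotation), and gene-product annotations whose
## co-annotation structure correlates with the labels at a configurable
## fidelity.  Layered construction keeps the DAG acyclic without rejection
## sampling, and all randomness flows from the single config seed.

# filler vocabulary for term names/definitions; none of these words contains
# any default keyword as a substring, so keyword bits are fully controlled
.FILLER <- c("alpha", "beta", "gamma", "delta", "process", "activity",
             "component", "assembly", "binding", "regulation", "transport",
             "signal", "response", "complex", "pathway", "organelle",
             "nuclear", "division", "cycle", "protein", "matrix", "import",
             "export", "localization", "maintenance")

#' Synthetic dataset configuration
#'
#' Defaults describe the standard simulation conditions used throughout the
#' package's own experiments: three namespaces of 600 terms in 6 layers,
#' six planted positive subtrees per namespace sized so that roughly an
#' eighth of all terms are property-positive (the class balance typical of
#' a curated GO-scale property project), 60% of positives carrying
#' an explicit keyword (the rest implicit), 300 gene products averaging 8
#' annotations whose class matches the gene's leaning with probability 0.9
#' (the co-annotation fidelity), a 2% keyword noise rate on negatives, and
#' 10% of terms withheld from the oracle to emulate never-examined (GO?)
#' terms.
#'
#' @param termsPerNamespace terms per namespace.
#' @param namespaces namespace codes.
#' @param layers number of DAG layers (layer 1 is the namespace root).
#' @param edgeProb probability of an is-a edge to each candidate parent in
#'   the previous layer (at least one parent is always assigned).
#' @param multiParentRate probability a term gains one extra parent from
#'   any earlier layer.
#' @param posSeeds planted positive subtree roots per namespace.
#' @param seedLayer layer the subtree roots are drawn from.
#' @param keywordFraction fraction of positive terms given an explicit
#'   keyword in name or definition.
#' @param negKeywordRate keyword noise rate on negative terms.
#' @param genes number of gene products.
#' @param meanAnnotations mean annotations per gene (min 1, Poisson tail).
#' @param fidelity probability an annotation lands in the term class
#'   matching the gene's leaning.
#' @param posGeneFraction fraction of genes leaning positive.
#' @param withholdRate fraction of terms the oracle answers UNKNOWN for.
#' @param seed integer seed; the single source of randomness.
#' @return A named list of configuration values.
#' @export
syntheticConfig <- function(termsPerNamespace = 600L,
                            namespaces = c("BP", "CC", "MF"),
                            layers = 6L, edgeProb = 0.01,
                            multiParentRate = 0.1,
                            posSeeds = 6L, seedLayer = 4L,
                            keywordFraction = 0.6, negKeywordRate = 0.02,
                            genes = 300L, meanAnnotations = 8,
                            fidelity = 0.9, posGeneFraction = 0.35,
                            withholdRate = 0.1, seed = 1L) {
  cfg <- list(termsPerNamespace = as.integer(termsPerNamespace),
              namespaces = namespaces, layers = as.integer(layers),
              edgeProb = edgeProb, multiParentRate = multiParentRate,
              posSeeds = as.integer(posSeeds),
              seedLayer = as.integer(seedLayer),
              keywordFraction = keywordFraction,
              negKeywordRate = negKeywordRate, genes = as.integer(genes),
              meanAnnotations = meanAnnotations, fidelity = fidelity,
              posGeneFraction = posGeneFraction,
              withholdRate = withholdRate, seed = as.integer(seed))
  probs <- c(cfg$edgeProb, cfg$multiParentRate, cfg$keywordFraction,
             cfg$negKeywordRate, cfg$fidelity, cfg$posGeneFraction,
             cfg$withholdRate)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]")
  if (cfg$termsPerNamespace < cfg$layers || cfg$genes < 1L ||
      cfg$layers < 2L)
    stop("config error: counts too small")
  if (cfg$seedLayer >= cfg$layers || cfg$seedLayer < 2L)
    stop("config error: seedLayer must lie strictly between 1 and layers")
  cfg
}

# layered random DAG for one namespace; returns list(terms=..., edges=...)
.generateNamespaceDag <- function(ns, cfg) {
  n <- cfg$termsPerNamespace
  L <- cfg$layers
  w <- 2^(seq_len(L - 1) - 1)
  rest <- pmax(1L, round((n - 1L) * w / sum(w)))
  while (sum(rest) > n - 1L) rest[which.max(rest)] <- rest[which.max(rest)] - 1L
  while (sum(rest) < n - 1L) rest[which.max(rest)] <- rest[which.max(rest)] + 1L
  sizes <- c(1L, rest)
  layer <- rep(seq_len(L), times = sizes)
  acc <- sprintf("%s:%06d", ns, seq_len(n))
  childv <- parentv <- character(0)
  for (k in 2:L) {
    kids <- acc[layer == k]
    prev <- acc[layer == k - 1L]
    earlier <- acc[layer < k]
    for (kid in kids) {
      sel <- prev[stats::runif(length(prev)) < cfg$edgeProb]
      if (!length(sel)) sel <- sample(prev, 1L)
      if (stats::runif(1) < cfg$multiParentRate) {
        extra <- setdiff(earlier, sel)
        if (length(extra)) sel <- c(sel, sample(extra, 1L))
      }
      childv <- c(childv, rep(kid, length(sel)))
      parentv <- c(parentv, sel)
    }
  }
  list(terms = data.frame(accession = acc, namespace = ns, layer = layer,
                          stringsAsFactors = FALSE),
       edges = data.frame(child = childv, parent = parentv,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic dataset
#'
#' See [syntheticConfig()] for what is emulated.  Ground-truth labels are
#' planted as whole subtrees, so they satisfy the inheritance constraint by
#' construction; two calls with the same config (including seed) return
#' identical datasets.
#'
#' @param config a [syntheticConfig()] list.
#' @param keywords keyword list to draw inserted keywords from.
#' @return A [SyntheticDataset-class].
#' @export
generateSynthetic <- function(config = syntheticConfig(),
                              keywords = lipidKeywords()) {
  withr::with_seed(config$seed, {
    parts <- lapply(config$namespaces, .generateNamespaceDag, cfg = config)
    terms <- do.call(rbind, lapply(parts, `[[`, "terms"))
    edges <- do.call(rbind, lapply(parts, `[[`, "edges"))

    # plant positive subtrees
    graph0 <- OntologyGraph(
      data.frame(accession = terms$accession, name = "", definition = "",
                 namespace = terms$namespace, is_obsolete = FALSE,
                 stringsAsFactors = FALSE),
      edges, namespaces = config$namespaces)
    closure <- transitiveClosure(graph0)
    seeds <- unlist(lapply(config$namespaces, function(ns) {
      pool <- terms$accession[terms$namespace == ns &
                                terms$layer == config$seedLayer]
      if (length(pool) < config$posSeeds)
        stop("config error: more positive subtree seeds than layer-",
             config$seedLayer, " terms in namespace ", ns)
      sample(pool, config$posSeeds)
    }), use.names = FALSE)
    posTerms <- termDescendantsInclusive(seeds, closure)
    lab <- setNames(ifelse(terms$accession %in% posTerms, "POS", "NEG"),
                    terms$accession)
    labels <- LabelTable(lab, provenance = "gold")

    # term text with controlled keyword insertion
    nTot <- nrow(terms)
    nameWords <- matrix(sample(.FILLER, 2L * nTot, replace = TRUE), ncol = 2)
    defWords <- matrix(sample(.FILLER, 3L * nTot, replace = TRUE), ncol = 3)
    nm <- paste(nameWords[, 1], nameWords[, 2])
    df <- sprintf("A %s %s involving %s.", defWords[, 1], defWords[, 2],
                  defWords[, 3])
    isPos <- lab[terms$accession] == "POS"
    giveKw <- (isPos & stats::runif(nTot) < config$keywordFraction) |
      (!isPos & stats::runif(nTot) < config$negKeywordRate)
    kwPick <- sample(keywords, nTot, replace = TRUE)
    inName <- stats::runif(nTot) < 0.5
    hitN <- giveKw & inName
    hitD <- giveKw & !inName
    nm[hitN] <- paste(nm[hitN], kwPick[hitN])
    df[hitD] <- sprintf("A %s %s involving %s %s.", defWords[hitD, 1],
                        defWords[hitD, 2], kwPick[hitD], defWords[hitD, 3])

    graph <- OntologyGraph(
      data.frame(accession = terms$accession, name = nm, definition = df,
                 namespace = terms$namespace, is_obsolete = FALSE,
                 stringsAsFactors = FALSE),
      edges, namespaces = config$namespaces)

    # gene-product annotations with co-annotation signal
    genes <- sprintf("SDB:G%05d", seq_len(config$genes))
    leanPos <- stats::runif(config$genes) < config$posGeneFraction
    nAnn <- 1L + stats::rpois(config$genes,
                              max(config$meanAnnotations - 1, 0))
    posPool <- terms$accession[isPos]
    negPool <- terms$accession[!isPos]
    gv <- rep(genes, nAnn)
    lean <- rep(leanPos, nAnn)
    hitClass <- ifelse(stats::runif(length(gv)) < config$fidelity,
                       lean, !lean)
    tv <- character(length(gv))
    tv[hitClass] <- sample(posPool, sum(hitClass), replace = TRUE)
    tv[!hitClass] <- sample(negPool, sum(!hitClass), replace = TRUE)
    assoc <- AssociationTable(data.frame(gene = gv, term = tv,
                                         stringsAsFactors = FALSE))

    withheld <- sort(sample(terms$accession,
                            round(config$withholdRate * nTot)))
    new("SyntheticDataset", graph = graph, labels = labels, assoc = assoc,
        withheld = withheld, config = config)
  })
}

#' Curated reference labels of a synthetic dataset
#'
#' The ground truth as a finished curation project would record it: the
#' withheld terms (never examined, GO?-like) are UNKNOWN, everything else
#' keeps its planted label.  This is the table simulated experiments sample
#' starting conditions from and evaluate against.
#'
#' @param dataset a [SyntheticDataset-class].
#' @return A [LabelTable-class].
#' @export
curatedLabels <- function(dataset) {
  setLabels(dataset@labels, dataset@withheld, "UNKNOWN", "gold")
}

#' Ground-truth curation oracle
#'
#' Answers batch queries from the planted labels, except for the withheld
#' terms, which are consistently answered UNKNOWN (emulating terms a real
#' curator never examined).
#'
#' @param dataset a [SyntheticDataset-class].
#' @return A `curationOracle`.
#' @export
groundTruthOracle <- function(dataset) {
  oracleFromLabels(curatedLabels(dataset))
}

#' Write a synthetic dataset as plain-text fixtures
#'
#' Emits `ontology.obo`, `annotations.gaf` (GAF 2.2), `labels.tsv` (the
#' curated reference labels, `?` for withheld terms) and `manifest.json`
#' (the config, including the seed).  The files round-trip through
#' [readObo()] / [readGaf()] / [readLabelTable()].
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeFixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(obo = file.path(dir, "ontology.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             labels = file.path(dir, "labels.tsv"),
             manifest = file.path(dir, "manifest.json"))
  writeObo(dataset@graph, paths[["obo"]])
  writeGaf(dataset@assoc, paths[["gaf"]])
  writeLabelTable(curatedLabels(dataset), paths[["labels"]])
  jsonlite::write_json(dataset@config, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
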