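# Shared fixtures, built in code.

# Diamond-plus-tails DAG (single namespace):
#        T1
#       /  \
#      T2    T3
#       \   /  \
#        T4     T6
#        |
#        T5
# descendants(T1) = {T2..T6}; descendants(T2) = {T4, T5};
# ancestors(T5) = {T4, T2, T3, T1}.
diamondGraph <- function(namespace = "BP") {
  acc <- paste0("T", 1:6)
  OntologyGraph(
    data.frame(accession = acc, name = paste("term", acc),
               definition = "", namespace = namespace,
               is_obsolete = FALSE, stringsAsFactors = FALSE),
    data.frame(child = c("T2", "T3", "T4", "T4", "T5", "T6"),
               parent = c("T1", "T1", "T2", "T3", "T4", "T3"),
               stringsAsFactors = FALSE))
}

diamondClosure <- function(graph = diamondGraph()) transitiveClosure(graph)

# random DAG: edges only from higher- to lower-numbered nodes, so acyclic
randomDagGraph <- function(n, pEdge = 2 / n, namespace = "BP") {
  acc <- sprintf("N%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < pEdge
  edges <- data.frame(child = acc[pairs[keep, 2]],
                      parent = acc[pairs[keep, 1]],
                      stringsAsFactors = FALSE)
  OntologyGraph(
    data.frame(accession = acc, name = "", definition = "",
               namespace = namespace, is_obsolete = FALSE,
               stringsAsFactors = FALSE),
    edges)
}

# independent reachability oracle: plain per-node DFS over adjacency lists
bruteForceReachability <- function(graph) {
  acc <- accessions(graph)
  adj <- split(graph@edges$parent, graph@edges$child)
  reach <- function(v) {
    seen <- character(0)
    stack <- adj[[v]]
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (u %in% seen) next
      seen <- c(seen, u)
      stack <- c(stack, adj[[u]])
    }
    seen
  }
  out <- lapply(setNames(acc, acc), reach)
  d <- rep(acc, lengths(out))
  a <- unlist(out, use.names = FALSE)
  if (!length(a))
    return(data.frame(descendant = character(), ancestor = character(),
                      stringsAsFactors = FALSE))
  data.frame(descendant = d, ancestor = a, stringsAsFactors = FALSE)
}

sortPairs <- function(p) {
  p <- p[order(p$descendant, p$ancestor), c("descendant", "ancestor")]
  rownames(p) <- NULL
  p
}

# small synthetic dataset for fast loop tests
tinySyntheticConfig <- function(seed = 1L, ...) {
  syntheticConfig(termsPerNamespace = 100L, layers = 4L, seedLayer = 2L,
                  posSeeds = 2L, genes = 80L, meanAnnotations = 6,
                  seed = seed, ...)
}

tinyLoopSetup <- function(seed = 1L, posFrac = 0.1, negFrac = 0.1, ...) {
  ds <- generateSynthetic(tinySyntheticConfig(seed = seed, ...))
  closure <- transitiveClosure(ds@graph)
  final <- curatedLabels(ds)
  start <- makeStartingCondition(final, posFrac, negFrac, closure,
                                 seed = seed)
  list(ds = ds, graph = ds@graph, closure = closure, assoc = ds@assoc,
       final = final, start = start, oracle = groundTruthOracle(ds))
}

tinySchedule <- function() batchSchedule(c(10L, 15L), c(3L, 3L))

# hand-built LoopResult for the bookkeeping formulas
handLoopResult <- function() {
  snap <- c(a = 1, b = 0.5, c = 0.2, d = -0.1, e = -0.4)
  rec <- list(iteration = 1L,
              batch = data.frame(accession = c("a", "b", "c", "d"),
                                 score = c(1, 0.5, 0.2, -0.1),
                                 stringsAsFactors = FALSE),
              tp = c("a", "b"), fp = "c", ignored = "d",
              descPlus = c("x", "y", "z"), descUnknown = character(0),
              ancMinus = "w", trainSize = 10L, snapshot = snap)
  new("LoopResult", iterations = list(rec),
      finalLabels = LabelTable(c(a = "POS", b = "POS", c = "NEG")),
      finalSnapshot = c(e = -0.4), iterative = TRUE, mode = "efficiency",
      featureSet = "all",
      testPositives = c("a", "b", "x", "y", "z", letters[6:10]),
      initialTest = c(letters[1:5], "x", "y", "z", "w"))
}

# graph + annotations reproducing the documented gene-weight and
# term-score worked examples
weightExampleFixture <- function() {
  bp <- c(paste0("P", 1:7), paste0("N", 1:7), "U1", "U2")
  cc <- c("X", "X2", "CEMPTY", paste0("CN", 1:4), paste0("CU", 1:2))
  mf <- "MU1"
  tm <- data.frame(
    accession = c(bp, cc, mf),
    name = "", definition = "",
    namespace = c(rep("BP", length(bp)), rep("CC", length(cc)), "MF"),
    is_obsolete = FALSE, stringsAsFactors = FALSE)
  graph <- OntologyGraph(tm, data.frame(child = "X2", parent = "X"))
  labels <- LabelTable(setNames(
    c(rep("POS", 7), rep("NEG", 7), "UNKNOWN", "UNKNOWN",
      rep("UNKNOWN", 3), rep("NEG", 4), rep("UNKNOWN", 2), "UNKNOWN"),
    c(bp, cc, mf)))
  # gA: 1 BP+/4 BP- -> 0.2; gB: 3 BP+/7 BP- -> 0.3; gC: 7 BP+/3 BP- -> 0.7
  # gD: only an unlabelled BP term -> no BP weight
  # g:  3 BP+/2 BP-/2 BP?, 0 CC+/4 CC-/2 CC?, 1 MF? (the headline example)
  assoc <- AssociationTable(data.frame(rbind(
    cbind("DB:gA", c("P1", paste0("N", 1:4))),
    cbind("DB:gB", c(paste0("P", 1:3), paste0("N", 1:7))),
    cbind("DB:gC", c(paste0("P", 1:7), paste0("N", 1:3))),
    cbind("DB:gD", "U1"),
    cbind("DB:g", c(paste0("P", 1:3), "N1", "N2", "U1", "U2",
                    paste0("CN", 1:4), paste0("CU", 1:2), "MU1")),
    # the four distinct gene products annotated to X or its descendant X2
    cbind("DB:gA", "X"), cbind("DB:gB", "X"),
    cbind("DB:gC", "X2"), cbind("DB:gD", "X2")),
    stringsAsFactors = FALSE) |> setNames(c("gene", "term")))
  list(graph = graph, labels = labels, assoc = assoc,
       closure = transitiveClosure(graph))
}
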