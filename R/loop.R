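## The iterative predict-curate engine and its non-iterative baseline.

#' Batch-size schedule
#'
#' Batches are small at first (when every curated term still shifts the
#' classifier appreciably) and grow later.  The default expands to the
#' 25-iteration schedule: 100 terms per batch for iterations 1-5, 200 for
#' 6-10, 300 for 11-15 and 500 for 16-25.
#'
#' @param sizes batch sizes per block.
#' @param reps number of iterations per block.
#' @return Integer vector of per-iteration batch sizes.
#' @export
batchSchedule <- function(sizes = c(100L, 200L, 300L, 500L),
                          reps = c(5L, 5L, 5L, 10L)) {
  if (length(sizes) != length(reps) || any(sizes <= 0L) || any(reps <= 0L))
    stop("schedule blocks need positive sizes and repetition counts")
  rep(as.integer(sizes), as.integer(reps))
}

#' Loop configuration
#'
#' @param schedule per-iteration batch sizes (see [batchSchedule()]).
#' @param mode `"efficiency"` (batch entries with a negative prediction
#'   score are discarded before curation — used for the curation
#'   effort/hit measure) or `"pr"` (kept — used for recall/precision).
#' @param featureSet `"all"` (36 keyword bits + sub-ontology scores) or
#'   `"keywords"` (keyword bits only, the ablation).
#' @param cost SVM soft-margin cost.
#' @param seed integer seed for every stochastic step of a run.
#' @param maxIterations cap on iterations; defaults to the schedule length.
#' @param stopOnZeroTP stop once an iteration yields no true positive
#'   (operationalises "until no further property-positive terms are
#'   found").
#' @param keywords keyword list used for featurization.
#' @return A list of configuration values.
#' @export
loopConfig <- function(schedule = batchSchedule(),
                       mode = c("efficiency", "pr"),
                       featureSet = c("all", "keywords"),
                       cost = 1, seed = 1L,
                       maxIterations = length(schedule),
                       stopOnZeroTP = TRUE,
                       keywords = lipidKeywords()) {
  list(schedule = schedule, mode = match.arg(mode),
       featureSet = match.arg(featureSet), cost = cost,
       seed = as.integer(seed), maxIterations = maxIterations,
       stopOnZeroTP = stopOnZeroTP, keywords = keywords)
}

#' Curation oracles
#'
#' An oracle stands in for the human curator: given an accession it answers
#' `POS`, `NEG` or `UNKNOWN`, and answers are stable within a run.
#' `oracleFromLabels` replays a finished curated list (used by the
#' simulated experiments, where the final list is taken as correct);
#' `interactiveOracle` prompts on the console and caches each answer.
#'
#' @param labels a [LabelTable-class] of reference labels.
#' @return A `curationOracle` object: list with elements `label`
#'   (the query function) and `truth` (the reference [LabelTable-class],
#'   or `NULL` when there is none).
#' @export
oracleFromLabels <- function(labels) {
  structure(list(label = function(acc) unname(labelOf(labels, acc)),
                 truth = labels),
            class = "curationOracle")
}

#' @rdname oracleFromLabels
#' @export
interactiveOracle <- function() {
  cache <- new.env(parent = emptyenv())
  ask <- function(acc) {
    if (!is.null(cache[[acc]])) return(cache[[acc]])
    repeat {
      ans <- trimws(readline(sprintf("label for %s [+/-/?]: ", acc)))
      if (ans %in% c("+", "-", "?")) break
      cat("please answer +, - or ?\n")
    }
    cache[[acc]] <- c("+" = "POS", "-" = "NEG", "?" = "UNKNOWN")[[ans]]
    cache[[acc]]
  }
  structure(list(label = ask, truth = NULL), class = "curationOracle")
}

#' @export
print.curationOracle <- function(x, ...) {
  cat("curationOracle",
      if (is.null(x$truth)) "(interactive)" else "(replay)", "\n")
  invisible(x)
}

#' Build a simulated starting condition
#'
#' Samples a fraction of the final curated positives and negatives as the
#' initial training labels, then applies the inheritance constraint
#' (descendants of sampled positives join as POS, ancestors of sampled
#' negatives join as NEG), so the effective labelled proportion exceeds the
#' nominal one.  Everything else — remaining labelled terms and all
#' unlabelled ones — forms the test set.
#'
#' @param final_labels the reference [LabelTable-class] (the completed
#'   curated list in a simulation).
#' @param pos_frac,neg_frac fractions in \[0,1\] of the positive / negative
#'   list to sample.
#' @param closure a [ClosureTable-class].
#' @param seed integer seed for the sampling.
#' @param universe accessions eligible as training/test terms; defaults to
#'   every term in the closure index.
#' @return List with `training` ([LabelTable-class]), `test` (character)
#'   and `report` (nominal and effective proportions, in the
#'   nominal/effective slash convention).
#' @export
makeStartingCondition <- function(final_labels, pos_frac, neg_frac, closure,
                                  seed = 1L,
                                  universe = names(closure@ancIndex)) {
  if (pos_frac < 0 || pos_frac > 1 || neg_frac < 0 || neg_frac > 1)
    stop("pos_frac and neg_frac must lie in [0, 1]")
  posPool <- intersect(positiveTerms(final_labels), universe)
  negPool <- intersect(negativeTerms(final_labels), universe)
  picked <- withr::with_seed(seed, {
    list(pos = sort(sample(posPool, round(pos_frac * length(posPool)))),
         neg = sort(sample(negPool, round(neg_frac * length(negPool)))))
  })
  training <- LabelTable(setNames(
    c(rep("POS", length(picked$pos)), rep("NEG", length(picked$neg))),
    c(picked$pos, picked$neg)), provenance = "gold")
  if (length(picked$pos))
    training <- propagatePositiveDown(training, picked$pos, closure)$labels
  if (length(picked$neg))
    training <- propagateNegativeUp(training, picked$neg, closure)$labels
  test <- setdiff(universe, names(training@labels))
  report <- list(
    pos_nominal = pos_frac,
    pos_effective = if (length(posPool))
      length(intersect(positiveTerms(training), posPool)) /
        length(posPool) else 0,
    neg_nominal = neg_frac,
    neg_effective = if (length(negPool))
      length(intersect(negativeTerms(training), negPool)) /
        length(negPool) else 0,
    training_size = length(training@labels),
    test_size = length(test))
  list(training = training, test = test, report = report)
}

#' Select a curation batch from a ranked list
#'
#' Takes the top `size` entries (all of them when fewer remain).  In
#' efficiency mode, entries with a negative prediction score are then
#' discarded — a curator should not examine terms the classifier itself
#' rejects; in pr mode they are kept so recall can keep growing.
#'
#' @param ranked `data.frame` from [scoreAndRank()].
#' @param size batch size (> 0).
#' @param mode `"efficiency"` or `"pr"`.
#' @return `data.frame` with columns `accession`, `score`.
#' @export
selectBatch <- function(ranked, size, mode = c("efficiency", "pr")) {
  mode <- match.arg(mode)
  if (size <= 0) stop("batch size must be positive")
  batch <- utils::head(ranked, size)
  if (mode == "efficiency")
    batch <- batch[batch$score >= 0, , drop = FALSE]
  rownames(batch) <- NULL
  batch
}

#' Submit a batch to the curation oracle
#'
#' Partitions the batch by the oracle's answers: POS terms are true
#' positives, NEG terms false positives, UNKNOWN terms are ignored — they
#' cost no curation effort, contribute nothing to training, but are removed
#' from future test sets.
#'
#' @param batch character vector of accessions.
#' @param oracle a `curationOracle`.
#' @return List with character vectors `tp`, `fp`, `ignored`.
#' @export
curateBatch <- function(batch, oracle) {
  if (!length(batch))
    return(list(tp = character(0), fp = character(0),
                ignored = character(0)))
  ans <- vapply(batch, function(acc) {
    tryCatch(oracle$label(acc),
             error = function(e)
               stop("oracle failed on term ", acc, ": ",
                    conditionMessage(e), call. = FALSE))
  }, character(1))
  list(tp = unname(batch[ans == "POS"]),
       fp = unname(batch[ans == "NEG"]),
       ignored = unname(batch[ans == "UNKNOWN"]))
}

# In simulated runs some propagated descendants have no reference class
# (never-examined, GO?-like).  They are still labelled POS by the
# constraint and leave the test set, but the evaluation formulas must not
# count them as hits, so records keep them apart as descUnknown.
.splitByTruth <- function(descPlus, oracle) {
  if (is.null(oracle$truth) || !length(descPlus))
    return(list(known = descPlus, unknown = character(0)))
  lab <- labelOf(oracle$truth, descPlus)
  list(known = descPlus[lab != "UNKNOWN"],
       unknown = descPlus[lab == "UNKNOWN"])
}

.featuresFor <- function(graph, labels, table, closure, config, kwBits) {
  feats <- featurizeAll(graph, labels, table, closure,
                        keywords = config$keywords, kwBits = kwBits)
  if (config$featureSet == "keywords")
    feats <- feats[, seq_along(config$keywords), drop = FALSE]
  feats
}

.loopResult <- function(records, labels, finalSnapshot, iterative, config,
                        oracle, test0) {
  truthPos <- if (!is.null(oracle$truth))
    intersect(test0, positiveTerms(oracle$truth)) else character(0)
  new("LoopResult", iterations = records, finalLabels = labels,
      finalSnapshot = finalSnapshot, iterative = iterative,
      mode = config$mode, featureSet = config$featureSet,
      testPositives = truthPos, initialTest = test0)
}

#' Run the iterative predict-curate loop
#'
#' Each iteration: recompute features under the current labels (gene
#' weights change as labels accumulate), train the classifier on every
#' labelled term (curated and propagated alike), rank the test set, select
#' a batch per the schedule, query the oracle, then enforce the inheritance
#' constraint — descendants of new true positives become POS (desc+),
#' ancestors of new false positives become NEG (ance-) — and remove the
#' batch and everything propagated or ignored from the test set.  The loop
#' stops at the end of the schedule, on an empty batch, or (optionally) on
#' an iteration with zero true positives.
#'
#' @param graph an [OntologyGraph-class].
#' @param closure its [ClosureTable-class].
#' @param table an [AssociationTable-class].
#' @param training initial [LabelTable-class].
#' @param test character vector: the initial test set.
#' @param oracle a `curationOracle`.
#' @param config a [loopConfig()] list.
#' @return A [LoopResult-class].
#' @export
runIterative <- function(graph, closure, table, training, test, oracle,
                         config = loopConfig()) {
  labels <- training
  kwBits <- keywordFeatures(graph, config$keywords)
  records <- list()
  test0 <- test
  nIter <- min(config$maxIterations, length(config$schedule))
  feats <- NULL
  for (i in seq_len(nIter)) {
    if (!length(test)) break
    feats <- .featuresFor(graph, labels, table, closure, config, kwBits)
    model <- trainClassifier(feats, labels, cost = config$cost,
                             seed = config$seed)
    ranked <- scoreAndRank(model, feats, test)
    snapshot <- setNames(ranked$score, ranked$accession)
    batch <- selectBatch(ranked, config$schedule[i], config$mode)
    if (!nrow(batch)) break
    trainSize <- length(labelledTerms(labels))
    cur <- curateBatch(batch$accession, oracle)
    labels <- setLabels(labels, cur$tp, "POS", "curated")
    labels <- setLabels(labels, cur$fp, "NEG", "curated")
    down <- propagatePositiveDown(labels, cur$tp, closure)
    up <- propagateNegativeUp(down$labels, cur$fp, closure)
    labels <- up$labels
    dp <- .splitByTruth(down$descPlus, oracle)
    test <- setdiff(test, c(cur$tp, cur$fp, cur$ignored,
                            down$descPlus, up$ancMinus))
    records[[length(records) + 1L]] <- list(
      iteration = i, batch = batch, tp = cur$tp, fp = cur$fp,
      ignored = cur$ignored, descPlus = dp$known,
      descUnknown = dp$unknown, ancMinus = up$ancMinus,
      trainSize = trainSize, snapshot = snapshot)
    if (config$stopOnZeroTP && !length(cur$tp)) break
  }
  finalSnapshot <- setNames(numeric(0), character(0))
  if (length(test)) {
    feats <- .featuresFor(graph, labels, table, closure, config, kwBits)
    finalSnapshot <- tryCatch({
      model <- trainClassifier(feats, labels, cost = config$cost,
                               seed = config$seed)
      classifierScores(model, feats, test)
    }, error = function(e) setNames(rep(NA_real_, length(test)), test))
  }
  .loopResult(records, labels, finalSnapshot, TRUE, config, oracle, test0)
}

#' Run the non-iterative baseline
#'
#' The classifier is trained once on the starting labels and the test set
#' is ranked once.  Then, for up to `rounds` rounds, the top `batchSize`
#' terms of the (shrinking) list are curated, the inheritance constraint is
#' applied, and the batch plus everything propagated or ignored is removed
#' from the list — with no retraining in between.
#'
#' @inheritParams runIterative
#' @param batchSize terms taken from the top of the list per round.
#' @param rounds number of rounds.
#' @return A [LoopResult-class] with `iterative = FALSE`.
#' @export
runNonIterative <- function(graph, closure, table, training, test, oracle,
                            config = loopConfig(), batchSize = 300L,
                            rounds = 20L) {
  labels <- training
  kwBits <- keywordFeatures(graph, config$keywords)
  feats <- .featuresFor(graph, labels, table, closure, config, kwBits)
  model <- trainClassifier(feats, labels, cost = config$cost,
                           seed = config$seed)
  ranked <- scoreAndRank(model, feats, test)
  records <- list()
  test0 <- test
  for (r in seq_len(rounds)) {
    if (!nrow(ranked)) break
    snapshot <- setNames(ranked$score, ranked$accession)
    batch <- selectBatch(ranked, batchSize, config$mode)
    if (!nrow(batch)) break
    cur <- curateBatch(batch$accession, oracle)
    labels <- setLabels(labels, cur$tp, "POS", "curated")
    labels <- setLabels(labels, cur$fp, "NEG", "curated")
    down <- propagatePositiveDown(labels, cur$tp, closure)
    up <- propagateNegativeUp(down$labels, cur$fp, closure)
    labels <- up$labels
    dp <- .splitByTruth(down$descPlus, oracle)
    gone <- c(cur$tp, cur$fp, cur$ignored, down$descPlus, up$ancMinus)
    ranked <- ranked[!(ranked$accession %in% gone), , drop = FALSE]
    records[[length(records) + 1L]] <- list(
      iteration = r, batch = batch, tp = cur$tp, fp = cur$fp,
      ignored = cur$ignored, descPlus = dp$known,
      descUnknown = dp$unknown, ancMinus = up$ancMinus,
      trainSize = length(labelledTerms(training)), snapshot = snapshot)
  }
  finalSnapshot <- setNames(ranked$score, ranked$accession)
  .loopResult(records, labels, finalSnapshot, FALSE, config, oracle, test0)
}

#' Keyword-only ablation run
#'
#' The identical iterative loop with the co-annotation scores masked, i.e.
#' feature vectors truncated to the keyword bits.  On data containing
#' implicitly property-positive terms (no keyword, co-annotation signal
#' only) this plateaus below the all-feature run.
#'
#' @inheritParams runIterative
#' @return A [LoopResult-class] with `featureSet = "keywords"`.
#' @export
runKeywordOnly <- function(graph, closure, table, training, test, oracle,
                           config = loopConfig()) {
  config$featureSet <- "keywords"
  runIterative(graph, closure, table, training, test, oracle, config)
}
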