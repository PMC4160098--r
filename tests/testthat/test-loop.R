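test_that("starting-condition fractions bound the training set", {
  setup <- tinyLoopSetup(seed = 11L)
  cl <- setup$closure
  final <- setup$final
  universe <- accessions(setup$graph)
  none <- makeStartingCondition(final, 0, 0, cl, seed = 1L)
  expect_equal(length(none$training@labels), 0L)
  expect_setequal(none$test, names(cl@ancIndex))
  all <- makeStartingCondition(final, 1, 1, cl, seed = 1L)
  expect_true(all(labelOf(final, all$test) == "UNKNOWN"))
  expect_error(makeStartingCondition(final, -0.1, 0.5, cl), "\\[0, 1\\]")
})

test_that("the inheritance constraint inflates the starting condition", {
  cl <- diamondClosure()
  final <- LabelTable(c(T2 = "POS", T4 = "POS", T5 = "POS",
                        T1 = "NEG", T3 = "NEG", T6 = "NEG"))
  # force the sample to be exactly {T2}: pos pool of one after masking
  onlyT2 <- LabelTable(c(T2 = "POS", T1 = "NEG"))
  start <- makeStartingCondition(onlyT2, 1, 0, cl, seed = 1L)
  expect_setequal(positiveTerms(start$training), c("T2", "T4", "T5"))
  expect_gt(start$report$pos_effective, 0)
  # the nominal/effective proportions are reported for the pools
  full <- makeStartingCondition(final, 1 / 3, 0, cl, seed = 2L)
  expect_gte(full$report$pos_effective, full$report$pos_nominal - 1e-9)
})

test_that("selectBatch applies the negative-score rule per mode", {
  ranked <- data.frame(accession = c("a", "b", "c"),
                       score = c(2.0, -0.1, -0.5))
  expect_equal(nrow(selectBatch(ranked, 3, "efficiency")), 1L)
  expect_equal(nrow(selectBatch(ranked, 3, "pr")), 3L)
  allNeg <- data.frame(accession = c("a", "b"), score = c(-1, -2))
  expect_equal(nrow(selectBatch(allNeg, 2, "efficiency")), 0L)
  expect_equal(nrow(selectBatch(ranked, 2, "pr")), 2L)
  expect_error(selectBatch(ranked, 0, "pr"), "positive")
})

test_that("curateBatch partitions by the oracle's answers", {
  oracle <- oracleFromLabels(LabelTable(c(a = "POS", b = "NEG")))
  out <- curateBatch(c("a", "b", "c"), oracle)
  expect_equal(out$tp, "a")
  expect_equal(out$fp, "b")
  expect_equal(out$ignored, "c")
  empty <- curateBatch(character(0), oracle)
  expect_equal(lengths(empty), c(tp = 0L, fp = 0L, ignored = 0L))
  allPos <- curateBatch(c("a"), oracleFromLabels(LabelTable(c(a = "POS"))))
  expect_equal(allPos$fp, character(0))
})

test_that("an empty test set yields a zero-iteration result", {
  setup <- tinyLoopSetup(seed = 3L)
  run <- runIterative(setup$graph, setup$closure, setup$assoc,
                      setup$start$training, character(0), setup$oracle,
                      loopConfig(schedule = tinySchedule()))
  expect_equal(length(run@iterations), 0L)
})

test_that("the iterative loop terminates consistently and shrinks the test set", {
  setup <- tinyLoopSetup(seed = 5L)
  cfg <- loopConfig(schedule = tinySchedule(), seed = 5L,
                    stopOnZeroTP = FALSE)
  run <- runIterative(setup$graph, setup$closure, setup$assoc,
                      setup$start$training, setup$start$test, setup$oracle,
                      cfg)
  expect_gt(length(run@iterations), 0L)
  # final labels satisfy the inheritance constraint
  expect_equal(nrow(checkInheritance(run@finalLabels, setup$closure)), 0L)
  # test set shrinks by exactly the removed sets each iteration
  remaining <- setup$start$test
  for (r in run@iterations) {
    gone <- c(r$tp, r$fp, r$ignored, r$descPlus, r$descUnknown, r$ancMinus)
    expect_setequal(names(r$snapshot), remaining)
    # curated terms always come from the live test set
    expect_true(all(c(r$tp, r$fp, r$ignored) %in% remaining))
    remaining <- setdiff(remaining, gone)
    # batch sizes follow the schedule (pr mode keeps the full slot count)
    expect_lte(nrow(r$batch), cfg$schedule[r$iteration])
    # TP/FP/ignored partition the curated batch
    expect_setequal(c(r$tp, r$fp, r$ignored), r$batch$accession)
    # propagated positives never overlap the curated TPs
    expect_equal(intersect(r$descPlus, r$tp), character(0))
  }
  expect_setequal(names(run@finalSnapshot), remaining)
  # curated and evaluable propagated sets are disjoint across iterations
  allSets <- unlist(lapply(run@iterations, function(r)
    c(r$tp, r$fp, r$descPlus)))
  expect_equal(anyDuplicated(allSets), 0L)
})

test_that("fixed seeds reproduce identical runs", {
  setup <- tinyLoopSetup(seed = 12L)
  cfg <- loopConfig(schedule = tinySchedule(), seed = 12L)
  r1 <- runIterative(setup$graph, setup$closure, setup$assoc,
                     setup$start$training, setup$start$test, setup$oracle,
                     cfg)
  r2 <- runIterative(setup$graph, setup$closure, setup$assoc,
                     setup$start$training, setup$start$test, setup$oracle,
                     cfg)
  expect_equal(length(r1@iterations), length(r2@iterations))
  for (i in seq_along(r1@iterations)) {
    expect_equal(r1@iterations[[i]]$batch$accession,
                 r2@iterations[[i]]$batch$accession)
    expect_setequal(r1@iterations[[i]]$tp, r2@iterations[[i]]$tp)
    expect_setequal(r1@iterations[[i]]$descPlus,
                    r2@iterations[[i]]$descPlus)
  }
  expect_equal(as.data.frame(r1@finalLabels), as.data.frame(r2@finalLabels))
})

test_that("the non-iterative baseline shares iteration-1 behaviour", {
  setup <- tinyLoopSetup(seed = 21L)
  cfg <- loopConfig(schedule = batchSchedule(12L, 6L), seed = 21L,
                    mode = "pr", stopOnZeroTP = FALSE)
  it <- runIterative(setup$graph, setup$closure, setup$assoc,
                     setup$start$training, setup$start$test, setup$oracle,
                     cfg)
  ni <- runNonIterative(setup$graph, setup$closure, setup$assoc,
                        setup$start$training, setup$start$test,
                        setup$oracle, cfg, batchSize = 12L, rounds = 6L)
  # same starting state, same size: the first batches coincide
  expect_equal(ni@iterations[[1]]$batch$accession,
               it@iterations[[1]]$batch$accession)
  expect_false(ni@iterative)
  expect_true(it@iterative)
  # rounds are recorded like iterations
  expect_equal(vapply(ni@iterations, `[[`, integer(1), "iteration"),
               seq_along(ni@iterations))
})

test_that("a list shorter than the batch is consumed in one round", {
  setup <- tinyLoopSetup(seed = 22L)
  smallTest <- withr::with_seed(22, sample(setup$start$test, 8))
  ni <- runNonIterative(setup$graph, setup$closure, setup$assoc,
                        setup$start$training, smallTest, setup$oracle,
                        loopConfig(mode = "pr", seed = 22L),
                        batchSize = 300L, rounds = 20L)
  expect_equal(length(ni@iterations), 1L)
  expect_equal(nrow(ni@iterations[[1]]$batch), 8L)
})

test_that("keyword-only runs mask the co-annotation scores", {
  setup <- tinyLoopSetup(seed = 23L)
  cfg <- loopConfig(schedule = tinySchedule(), seed = 23L, mode = "pr",
                    stopOnZeroTP = FALSE)
  kw <- runKeywordOnly(setup$graph, setup$closure, setup$assoc,
                       setup$start$training, setup$start$test,
                       setup$oracle, cfg)
  expect_equal(kw@featureSet, "keywords")
  full <- runIterative(setup$graph, setup$closure, setup$assoc,
                       setup$start$training, setup$start$test,
                       setup$oracle, cfg)
  expect_equal(full@featureSet, "all")
})

test_that("keyword-free ontologies surface a degenerate-training error", {
  setup <- tinyLoopSetup(seed = 24L, keywordFraction = 0,
                         negKeywordRate = 0)
  cfg <- loopConfig(schedule = tinySchedule(), seed = 24L)
  expect_error(
    runKeywordOnly(setup$graph, setup$closure, setup$assoc,
                   setup$start$training, setup$start$test, setup$oracle,
                   cfg),
    "degenerate")
})
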