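test_that("efficiency curve applies effort = TP+FP, hit = TP+desc+", {
  res <- handLoopResult()
  curve <- efficiencyCurve(res)
  # 2 TP + 1 FP curated; 2 TP + 3 desc+ gained; 1 ignored contributes nothing
  expect_equal(curve$effort, 3L)
  expect_equal(curve$hit, 5L)
  expect_equal(curve$break_even, curve$effort)
  empty <- new("LoopResult", finalLabels = LabelTable())
  expect_equal(nrow(efficiencyCurve(empty)), 0L)
})

test_that("pr curve applies the cumulative recall/precision formulas", {
  res <- handLoopResult()
  curve <- prCurve(res, P = 10)
  expect_equal(curve$recall, 0.5)          # (2 + 3) / 10
  expect_equal(curve$precision, 5 / 6)     # (2 + 3) / (2 + 3 + 1)
  expect_error(prCurve(res, P = 0), "undefined")
  empty <- new("LoopResult", finalLabels = LabelTable())
  expect_equal(nrow(prCurve(empty, P = 5)), 0L)
})

test_that("recall reaches 1 with perfect curation and no false positives", {
  rec <- list(iteration = 1L,
              batch = data.frame(accession = c("a", "b"), score = c(1, 2)),
              tp = c("a", "b"), fp = character(0), ignored = character(0),
              descPlus = "c", descUnknown = character(0),
              ancMinus = character(0), trainSize = 2L,
              snapshot = c(a = 1, b = 2, c = 0.5))
  res <- new("LoopResult", iterations = list(rec),
             finalLabels = LabelTable(), finalSnapshot = numeric(),
             testPositives = c("a", "b", "c"))
  curve <- prCurve(res)
  expect_equal(curve$recall, 1)
  expect_equal(curve$precision, 1)
})

test_that("cumulative curves equal incremental accumulation of records", {
  setup <- tinyLoopSetup(seed = 14L)
  run <- runIterative(setup$graph, setup$closure, setup$assoc,
                      setup$start$training, setup$start$test, setup$oracle,
                      loopConfig(schedule = tinySchedule(), seed = 14L,
                                 stopOnZeroTP = FALSE))
  curve <- efficiencyCurve(run)
  eff <- 0L; hit <- 0L
  for (i in seq_along(run@iterations)) {
    r <- run@iterations[[i]]
    eff <- eff + length(r$tp) + length(r$fp)
    hit <- hit + length(r$tp) + length(r$descPlus)
    expect_equal(curve$effort[i], eff)
    expect_equal(curve$hit[i], hit)
  }
  expect_true(all(diff(curve$effort) >= 0) && all(diff(curve$hit) >= 0))
  pc <- prCurve(run)
  expect_true(all(diff(pc$recall) >= -1e-12))
  expect_true(all(pc$precision <= 1 + 1e-12, na.rm = TRUE))
})

test_that("keyword confusion counts ancestors only in with-ancestors mode", {
  g <- diamondGraph()
  tm <- termData(g)
  tm$name[tm$accession == "T1"] <- "lipid storage"   # keyword at the top
  g <- OntologyGraph(tm, isaEdges(g))
  cl <- transitiveClosure(g)
  labels <- LabelTable(c(T1 = "POS", T4 = "NEG", T5 = "POS", T6 = "NEG"))
  self <- keywordConfusion(labels, g, cl, mode = "self")
  anc <- keywordConfusion(labels, g, cl, mode = "with-ancestors")
  expect_equal(sum(self), 4L)
  expect_equal(sum(anc), 4L)
  expect_equal(self["POS", "keyword"], 1L)     # only T1 itself
  expect_equal(self["NEG", "keyword"], 0L)
  # every descendant of T1 inherits the hit in with-ancestors mode
  expect_equal(anc["POS", "keyword"], 2L)
  expect_equal(anc["NEG", "keyword"], 2L)
  expect_gte(anc["POS", "keyword"], self["POS", "keyword"])
  expect_gte(anc["NEG", "keyword"], self["NEG", "keyword"])
  # keyword-free ontology: hit column is all zero
  none <- keywordConfusion(labels, diamondGraph(), cl, mode = "self")
  expect_equal(unname(none[, "keyword"]), c(0L, 0L))
})

test_that("rank shift recovers the hand-computed exact signed-rank p", {
  # 5 persistent terms; the two reference positives move from ranks {4,5}
  # to ranks {1,2} between the two checkpoints
  snap0 <- c(t1 = 5, t2 = 4, t3 = 3, p1 = 2, p2 = 1)
  snap1 <- c(t1 = 1, t2 = 0.5, t3 = 0.4, p1 = 3, p2 = 2)
  rec <- list(iteration = 1L,
              batch = data.frame(accession = character(),
                                 score = numeric()),
              tp = character(0), fp = character(0), ignored = character(0),
              descPlus = character(0), descUnknown = character(0),
              ancMinus = character(0), trainSize = 2L, snapshot = snap0)
  res <- new("LoopResult", iterations = list(rec),
             finalLabels = LabelTable(), finalSnapshot = snap1,
             testPositives = c("p1", "p2"),
             initialTest = names(snap0))
  rs <- rankShift(res, checkpoints = c(0, 1))
  expect_setequal(rs$leftover, c("p1", "p2"))
  expect_equal(unname(rs$average_rank), c(4.5, 1.5))
  # exact enumeration over sign flips of two tied differences: p = 1/4
  expect_equal(rs$p_values["after_0", "after_1"], 0.25)
})

test_that("identical snapshots give equal ranks and a degenerate test", {
  snap <- c(a = 3, b = 2, p1 = 1)
  rec <- list(iteration = 1L, batch = data.frame(), tp = character(0),
              fp = character(0), ignored = character(0),
              descPlus = character(0), descUnknown = character(0),
              ancMinus = character(0), trainSize = 1L, snapshot = snap)
  res <- new("LoopResult", iterations = list(rec),
             finalLabels = LabelTable(), finalSnapshot = snap,
             testPositives = "p1", initialTest = names(snap))
  rs <- rankShift(res, checkpoints = c(0, 1))
  expect_equal(unname(rs$average_rank[1]), unname(rs$average_rank[2]))
  expect_true(rs$degenerate["after_0", "after_1"])
  expect_true(is.na(rs$p_values["after_0", "after_1"]))
  expect_error(rankShift(res, checkpoints = c(0, 5)), "checkpoints")
})

test_that("midranks are used for tied absolute differences", {
  # |d| = (3, 3, 1): midranks (2.5, 2.5, 1); all positive -> W = 6,
  # one-sided exact p = P(W >= 6) = 1/8
  p <- ontoloop:::.exactSignedRankP(c(3, 3, 1))$p
  expect_equal(p, 1 / 8)
  # mixed signs: d = (3, -3): W = 1.5, p = P(W >= 1.5) = 3/4
  expect_equal(ontoloop:::.exactSignedRankP(c(3, -3))$p, 3 / 4)
  # zero differences are dropped; all-zero is degenerate
  expect_true(ontoloop:::.exactSignedRankP(c(0, 0))$degenerate)
})
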