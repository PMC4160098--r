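test_that("all-UNKNOWN labels have no violations", {
  cl <- diamondClosure()
  lt <- LabelTable(setNames(rep("UNKNOWN", 6), paste0("T", 1:6)))
  expect_equal(nrow(checkInheritance(lt, cl)), 0L)
})

test_that("a non-positive descendant of a POS term is a violation", {
  cl <- diamondClosure()
  lt <- LabelTable(c(T2 = "POS", T4 = "UNKNOWN", T5 = "POS"))
  v <- checkInheritance(lt, cl)
  expect_equal(v$ancestor, "T2")
  expect_equal(v$descendant, "T4")
  expect_equal(v$descendant_label, "UNKNOWN")
})

test_that("violations report the nearest POS ancestor; full mode all pairs", {
  cl <- diamondClosure()
  # both T1 and T2 are POS ancestors of the offending T4; T2 is nearer
  lt <- LabelTable(c(T1 = "POS", T2 = "POS", T4 = "NEG"))
  v <- checkInheritance(lt, cl)
  byDesc <- v[v$descendant == "T4", ]
  expect_equal(byDesc$ancestor, "T2")
  vf <- checkInheritance(lt, cl, full = TRUE)
  expect_true(all(c("T1", "T2") %in% vf$ancestor[vf$descendant == "T4"]))
})

test_that("an unlabelled new child under a POS parent is flagged", {
  # a new version of a graph adds an unexamined child below a positive term
  g <- diamondGraph()
  tm <- rbind(termData(g),
              data.frame(accession = "T7", name = "new child",
                         definition = "", namespace = "BP",
                         is_obsolete = FALSE))
  g2 <- OntologyGraph(tm, rbind(isaEdges(g),
                                data.frame(child = "T7", parent = "T5")))
  lt <- LabelTable(c(T5 = "POS"))
  v <- checkInheritance(lt, transitiveClosure(g2))
  expect_equal(v$descendant, "T7")
  expect_equal(v$ancestor, "T5")
  # the curator's fix in such cases: relabel the child positive
  lt2 <- setLabels(lt, "T7", "POS")
  expect_equal(nrow(checkInheritance(lt2, transitiveClosure(g2))), 0L)
})

test_that("positive-down propagation labels descendants and is idempotent", {
  cl <- diamondClosure()
  lt <- LabelTable(c(T2 = "POS", T4 = "UNKNOWN", T5 = "UNKNOWN"))
  res <- propagatePositiveDown(lt, "T2", cl)
  expect_setequal(res$descPlus, c("T4", "T5"))
  expect_equal(unname(labelOf(res$labels, c("T4", "T5"))), c("POS", "POS"))
  expect_equal(unname(labelProvenance(res$labels)[c("T4", "T5")]),
               rep("propagated_desc", 2))
  again <- propagatePositiveDown(res$labels, "T2", cl)
  expect_equal(again$descPlus, character(0))
  # leaf seed: nothing to do
  leaf <- propagatePositiveDown(LabelTable(c(T5 = "POS")), "T5", cl)
  expect_equal(leaf$descPlus, character(0))
})

test_that("negative-up propagation labels ancestors and is idempotent", {
  cl <- diamondClosure()
  lt <- LabelTable(c(T5 = "NEG"))
  res <- propagateNegativeUp(lt, "T5", cl)
  expect_setequal(res$ancMinus, c("T4", "T2", "T3", "T1"))
  again <- propagateNegativeUp(res$labels, "T5", cl)
  expect_equal(again$ancMinus, character(0))
  root <- propagateNegativeUp(LabelTable(c(T1 = "NEG")), "T1", cl)
  expect_equal(root$ancMinus, character(0))
})

test_that("conflicting propagation raises instead of flipping labels", {
  cl <- diamondClosure()
  expect_error(
    propagatePositiveDown(LabelTable(c(T2 = "POS", T5 = "NEG")), "T2", cl),
    "conflict")
  expect_error(
    propagateNegativeUp(LabelTable(c(T5 = "NEG", T1 = "POS")), "T5", cl),
    "conflict")
  # seeds must already carry the propagated label
  expect_error(propagatePositiveDown(LabelTable(c(T2 = "NEG")), "T2", cl),
               "not labelled POS")
})

test_that("propagation is order-insensitive across disjoint seed sets", {
  cl <- diamondClosure()
  lt <- LabelTable(c(T2 = "POS", T6 = "POS"))
  ab <- propagatePositiveDown(
    propagatePositiveDown(lt, "T2", cl)$labels, "T6", cl)$labels
  ba <- propagatePositiveDown(
    propagatePositiveDown(lt, "T6", cl)$labels, "T2", cl)$labels
  expect_equal(sort(positiveTerms(ab)), sort(positiveTerms(ba)))
})

test_that("empty violations are equivalent to pairwise label consistency", {
  withr::with_seed(55, {
    cl <- diamondClosure()
    for (i in 1:30) {
      lab <- sample(c("POS", "NEG", "UNKNOWN"), 6, replace = TRUE)
      lt <- LabelTable(setNames(lab, paste0("T", 1:6)))
      p <- closurePairs(cl)
      consistent <- all(labelOf(lt, p$ancestor) != "POS" |
                          labelOf(lt, p$descendant) == "POS")
      expect_equal(nrow(checkInheritance(lt, cl)) == 0L, consistent)
    }
  })
})

test_that("label TSV round-trips with +/-/? symbols", {
  f <- withr::local_tempfile(fileext = ".tsv")
  lt <- LabelTable(c(T1 = "POS", T2 = "NEG", T3 = "UNKNOWN"),
                   provenance = c("gold", "curated", "gold"))
  writeLabelTable(lt, f)
  lt2 <- readLabelTable(f)
  expect_equal(as.data.frame(lt2), as.data.frame(lt))
})

test_that("version mapping: identity graphs carry everything untouched", {
  g <- diamondGraph()
  lt <- LabelTable(c(T4 = "POS", T5 = "POS", T3 = "NEG"))
  res <- mapLabelsBetweenVersions(lt, g, g)
  expect_equal(res$report$carried, 3L)
  expect_equal(res$report$dropped_obsolete, character(0))
  expect_equal(res$report$changed_text, character(0))
  expect_equal(nrow(res$report$violations), 0L)
  expect_equal(sort(positiveTerms(res$labels)), c("T4", "T5"))
})

test_that("version mapping reports obsolete drops, text changes, violations", {
  old <- diamondGraph()
  tm <- termData(old)
  # new version: T6 obsolete, T5 renamed, new unlabelled child T7 under T4
  tm$is_obsolete[tm$accession == "T6"] <- TRUE
  tm$name[tm$accession == "T5"] <- "renamed term"
  tm <- rbind(tm, data.frame(accession = "T7", name = "fresh",
                             definition = "", namespace = "BP",
                             is_obsolete = FALSE))
  ed <- isaEdges(old)
  ed <- ed[ed$child != "T6", ]
  ed <- rbind(ed, data.frame(child = "T7", parent = "T4"))
  newg <- OntologyGraph(tm, ed)
  lt <- LabelTable(c(T4 = "POS", T5 = "POS", T6 = "NEG"))
  res <- mapLabelsBetweenVersions(lt, old, newg)
  expect_equal(res$report$dropped_obsolete, "T6")
  expect_equal(res$report$changed_text, "T5")
  expect_equal(res$report$violations$descendant, "T7")
  expect_equal(res$report$violations$ancestor, "T4")
  expect_equal(res$report$carried, 1L)   # only T4 carried untouched
  expect_false("T6" %in% names(res$labels@labels))
})

test_that("version mapping resolves alt_id merges before joining", {
  old <- diamondGraph()
  tm <- termData(old)
  tm <- tm[tm$accession != "T6", ]
  ed <- isaEdges(old)[isaEdges(old)$child != "T6", ]
  newg <- OntologyGraph(tm, ed, aliases = c(T6 = "T3"))
  lt <- LabelTable(c(T6 = "NEG"))
  res <- mapLabelsBetweenVersions(lt, old, newg)
  expect_equal(unname(labelOf(res$labels, "T3")), "NEG")
})
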