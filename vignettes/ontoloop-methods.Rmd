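---
title: "Finding all ontology terms with a shared property: the ontoloop methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding all ontology terms with a shared property}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoloop)
```

## The problem

Given an ontology such as the Gene Ontology (GO) — three namespaces (BP,
CC, MF), each a rooted DAG of terms connected by is-a edges — we want the
complete set of terms that share some target property, for instance
lipid-relatedness.  A few of those terms are *explicit*: a lipid keyword
sits right in the term name or definition.  Many are *implicit*: nothing
in the text gives them away, and recognising them requires either expert
knowledge or indirect evidence.  Manually curating tens of thousands of
terms is prohibitive, so ontoloop implements a semi-automated strategy:
a classifier proposes the terms most likely to carry the property, a
(human or simulated) curator confirms or rejects them in batches, and the
ontology's own structure multiplies every decision.

Two structural facts carry the method:

* **The inheritance constraint.** Only is-a edges are used, because only
  is-a transmits a property from parent to child.  If an ancestor term
  carries the property, every descendant necessarily does; contrapositively,
  no property-negative term may have a property-positive ancestor.  Each
  confirmed positive therefore labels its whole descendant subtree for
  free (`desc+`), and each rejected prediction labels all its ancestors
  negative (`ance-`).
* **Co-annotation.** Terms annotated to the same gene products tend to
  describe related biology.  Gene products bridge labelled and unlabelled
  terms across all three namespaces, which pairwise semantic-similarity
  measures (confined to a neighbourhood of the DAG) cannot do.

## Features

Each non-obsolete term is represented by 39 features.

**36 keyword bits.** Bit $i$ is 1 iff keyword $i$ occurs as a
case-insensitive substring of the term name or definition, standing alone
or inside a longer word ("lipo" matches *lipoprotein*).  The shipped
default list holds 36 lipid keywords whose forms were chosen to avoid any
natural-language processing: "fats" rather than "fat" (so *fate* cannot
fire), both "sterol" and "steryl", and one multi-token entry,
"bile acid", matched literally including the space.  Keyword hits are
deliberately **not** propagated to ancestors: `keywordConfusion()` shows
that doing so buys a little sensitivity at a large cost in specificity.

**3 co-annotation scores.**  First every gene product $g$ gets a
per-namespace *property-relatedness weight*

$$ w_{ns}(g) = \frac{\#\text{POS explicit annotations of } g \text{ in } ns}
                    {\#\text{POS} + \#\text{NEG explicit annotations of } g \text{ in } ns}, $$

computed over *distinct explicitly annotated terms* (no propagation to
ancestors).  A gene explicitly annotated with 3 BP+, 2 BP− and 2 BP?
terms has BP weight $3/5 = 0.6$; with 0 CC+ and 4 CC−, CC weight $0$;
with only one MF? annotation, its MF weight *does not exist* — absence
and zero are distinct.  Then each term $t$ receives one score per
namespace: the mean weight of the distinct gene products annotated to $t$
*or any of its descendants* (the true-path direction), averaging only
genes whose weight exists, and 0 when no weight exists at all.  A term
with four inclusive gene products of which three have BP weights 0.2,
0.3, 0.7 scores $(0.2+0.3+0.7)/3 = 0.4$.  Scores always lie in $[0,1]$.

Counting *distinct terms* rather than annotation records in the weights
is a deliberate choice (duplicate records with different evidence codes
collapse); the annotation filtering keeps every evidence code including
IEA, removes rows with a `NOT` qualifier component, pools all organisms,
and identifies genes by `DB:DB_Object_ID`, never by symbol.

## The iterative predict-curate loop

Starting from labels with a known class (a gold standard, or a sampled
starting condition), each iteration of `runIterative()`:

1. recomputes all features under the current labels — gene weights change
   every time labels accumulate, so scores are always rebuilt from
   scratch (keyword bits depend only on text and are cached);
2. trains a linear-kernel soft-margin SVM (cost 1, no class weighting, no
   feature rescaling — the features are already in $[0,1]$) on every
   labelled term, curated and propagated alike;
3. ranks the test set by the signed linear decision value (positive means
   predicted property-positive; ties broken by accession so runs are
   deterministic);
4. selects a batch of top-ranked terms per the schedule — by default 100
   per batch for iterations 1–5, then 200, 300, and 500 for 16–25.  In
   *efficiency* mode, entries with a negative prediction score are
   discarded (a curator should not examine terms the classifier itself
   rejects); in *pr* mode they are kept so recall can keep growing;
5. queries the curation oracle.  Confirmed positives are `TP`, rejected
   ones `FP`, never-examined (GO?-like) answers are ignored: they cost no
   effort, add nothing to training, but leave the test set;
6. enforces the inheritance constraint: descendants of the new TPs become
   positive (`desc+`), ancestors of the new FPs become negative
   (`ance-`), and everything curated or propagated leaves the test set.
   A propagation that would flip an explicit opposite label raises an
   error — that situation is a genuine constraint conflict that only a
   curator may resolve, and it is never resolved silently.

The loop stops at the end of the schedule, on an empty batch, or
(optionally) on an iteration that finds no true positive.  The
non-iterative baseline `runNonIterative()` trains once, ranks once, and
repeatedly takes the top 300 of the shrinking list for 20 rounds with no
retraining.  `runKeywordOnly()` is the ablation: the identical loop on
feature vectors truncated to the 36 keyword bits.

Curation oracles are pluggable: `oracleFromLabels()` replays a finished
curated list (simulated experiments treat that list as correct),
`groundTruthOracle()` answers from a synthetic dataset's planted labels
with a configurable withheld fraction answered UNKNOWN, and
`interactiveOracle()` prompts a human on the console.

## Evaluation

* **Curation efficiency** (`efficiencyCurve()`): cumulative effort
  $= \sum(|TP| + |FP|)$ against cumulative hit $= \sum(|TP| + |desc+|)$.
  On or above the break-even diagonal, each examined term yields at least
  one positive on average.
* **Recall / precision** (`prCurve()`): recall
  $= (TP + desc+)/P$ with $P$ the reference positives in the test set;
  precision $= (TP + desc+)/(TP + desc+ + FP)$; cumulative over
  iterations.
* **Keyword confusion** (`keywordConfusion()`): labelled terms
  cross-tabulated by keyword presence, on the term itself or including
  its ancestors.
* **Rank shift** (`rankShift()`): the reference positives that survive
  every iteration uncurated should drift toward the top of the
  score-sorted persistent test list as the classifier improves.  Average
  ranks (rank 1 = best, ties share the midrank) are compared between
  checkpoints with a one-sided Wilcoxon signed-rank test.  For small
  samples the exact p is computed by enumerating all sign flips of the
  midranked absolute differences — the standard exact routine declines
  tied differences, which arise routinely here; larger samples use the
  normal approximation with tie correction.  An all-zero difference
  vector is reported as a degenerate test with no p-value.

In simulated runs, propagated descendants whose reference class was never
examined are tracked separately (`descUnknown`) and excluded from the
effort/hit/recall formulas; otherwise recall could exceed 1.

## The synthetic data generator

`generateSynthetic()` builds fully self-contained datasets so the whole
pipeline is testable offline.  What it emulates, and how:

* **Topology.** Per namespace, a layered random DAG (default 600 terms in
  6 layers, sizes doubling by layer): each term takes each previous-layer
  term as a parent with probability 0.01 (at least one parent always),
  plus an extra parent from any earlier layer with probability 0.1 —
  multiple inheritance without rejection sampling, acyclic by
  construction.
* **Labels.** Positives are planted as whole subtrees: 6 subtree roots
  per namespace drawn from layer 4, everything below them positive.  The
  inheritance constraint therefore holds by construction, and roughly an
  eighth of all terms end up positive — the class balance of a curated
  GO-scale property project.
* **Text.** 60% of positives receive one of the 36 keywords in their
  name or definition; the remaining positives are *implicit* — mandatory,
  because they are the reason co-annotation features exist at all.
  Negatives receive keyword noise at rate 0.02.  The filler vocabulary
  contains no keyword as a substring, so keyword bits are fully
  controlled.
* **Annotations.** 300 gene products, $1 + \mathrm{Pois}(7)$ annotations
  each; 35% of genes lean positive, and each annotation lands on a term
  of the gene's leaning class with probability 0.9 (the *co-annotation
  fidelity*), otherwise on the opposite class.
* **GO?-like terms.** 10% of terms are withheld: the ground-truth oracle
  answers UNKNOWN for them, consistently.  Withholding is uniform, far
  below the ~50% unexamined share of a real project, because real
  unexamined terms concentrate among low-scoring terms; uniform
  withholding at that rate would unrealistically waste half of every top
  batch.

All randomness flows from the single config seed; two calls with equal
configs return identical datasets.  What the generator does **not**
emulate: realistic GO topology statistics (term fan-out, depth
distribution), species structure, evidence-code composition, and textual
negation or disjunction ("not bounded by a lipid bilayer…") — a known
false-positive source in real definitions.  Passing tests on synthetic
data therefore demonstrate the machinery and the direction of the
methodological effects, not performance figures transferable to GO.

## Simulated experiment conventions

The package's own experiments (test suite) use 600-term namespaces, ten
seeds, fidelity 0.9, and starting conditions sampling 5% of the reference
positives and 10% of the negatives — the small-start regime where
iteration helps most.  The batch schedule is scaled 1:10 from the
GO-scale default (10/20/30/50 per block; baseline 30 × 20 rounds),
matching the ~1:10 ratio of synthetic to GO-scale test-set size.

Comparing the iterative and non-iterative efficiency curves needs a
convention, because effort is spent in discrete batches and the two
versions' cumulative curves jump at different places: ontoloop compares
cumulative hits at matched effort levels placed at multiples of the
baseline batch size beyond the first batch, interpolating both curves
linearly between recorded batch ends.  Comparing at one curve's own jump
points instead systematically favours whichever curve jumped last.

## Numerical and degenerate-input choices

* The transitive closure is strict (irreflexive); subtree aggregation
  uses the explicit `termDescendantsInclusive()` variant.  Closure
  construction is dynamic programming over a topological order and is
  cross-checked against brute-force DFS reachability in the tests.
* Constraint violations are reported once per offending descendant with
  its nearest positive ancestor (ties broken by accession); `full = TRUE`
  lists every pair.
* A training set with a single class, or with all-identical feature
  vectors (e.g. keyword-only features on keyword-free text), raises a
  degenerate-training error rather than fitting a meaningless model.
* Version mapping (`mapLabelsBetweenVersions()`) drops labels of obsolete
  terms, resolves alt_id merges first (first label wins on a merge),
  flags carried terms whose name or definition changed, and reports — but
  never auto-resolves — inheritance violations introduced by structural
  change.
* Obsolete terms are retained as records but stripped of edges, and are
  never featurized.

## Limitations

The classifier is intentionally simple (one linear SVM, fixed cost); the
paper-gap choices — hyperparameters, stopping rule, whether ignored terms
occupy batch slots (they do) — are all exposed in `loopConfig()`.
Multi-functional gene products can inflate co-annotation scores of
property-negative terms, and keyword negation in definitions is not
detected; both are inherent false-positive sources of the method, left to
the curator by design.
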