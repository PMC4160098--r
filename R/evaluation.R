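#' Curation-efficiency curve
#'
#' Per iteration, the cumulative curation effort (terms a curator actually
#' examined: TP + FP) against the cumulative curation hit (positives
#' gained: TP + desc+).  Ignored (UNKNOWN) terms contribute to neither
#' coordinate.  When hit/effort is at least 1 — i.e. the curve lies on or
#' above the break-even diagonal — every curated term yields on average at
#' least one positive.
#'
#' @param result a [LoopResult-class].
#' @return `data.frame` with columns `iteration`, `effort`, `hit`,
#'   `break_even` (the reference hit equal to the effort).
#' @export
efficiencyCurve <- function(result) {
  its <- result@iterations
  if (!length(its))
    return(data.frame(iteration = integer(), effort = integer(),
                      hit = integer(), break_even = integer()))
  eff <- cumsum(vapply(its, function(r) length(r$tp) + length(r$fp),
                       integer(1)))
  hit <- cumsum(vapply(its, function(r) length(r$tp) + length(r$descPlus),
                       integer(1)))
  data.frame(iteration = vapply(its, `[[`, integer(1), "iteration"),
             effort = eff, hit = hit, break_even = eff)
}

#' Recall / precision curve
#'
#' Cumulative over iterations: recall = (TP + desc+) / P where P is the
#' number of reference positives in the initial test set, and precision =
#' (TP + desc+) / (TP + desc+ + FP).  desc+ counts as found positives
#' because the inheritance constraint derives them from TP at no curation
#' cost.
#'
#' @param result a [LoopResult-class].
#' @param P total number of reference positives in the test set; defaults
#'   to the reference positives recorded in the result.
#' @return `data.frame` with columns `iteration`, `recall`, `precision`.
#' @export
prCurve <- function(result, P = length(result@testPositives)) {
  if (P <= 0) stop("recall undefined: P must be positive")
  its <- result@iterations
  if (!length(its))
    return(data.frame(iteration = integer(), recall = numeric(),
                      precision = numeric()))
  tpd <- cumsum(vapply(its, function(r) length(r$tp) + length(r$descPlus),
                       integer(1)))
  fp <- cumsum(vapply(its, function(r) length(r$fp), integer(1)))
  data.frame(iteration = vapply(its, `[[`, integer(1), "iteration"),
             recall = tpd / P,
             precision = ifelse(tpd + fp > 0, tpd / (tpd + fp), NA_real_))
}

#' Keyword/label confusion table
#'
#' Cross-tabulates the labelled (POS/NEG) terms by whether they carry at
#' least one keyword.  In `self` mode only the term's own name/definition
#' counts; in `with-ancestors` mode a term also counts as a hit when any of
#' its ancestors carries a keyword — which raises sensitivity at a heavy
#' cost in specificity, the reason keyword features are not propagated
#' upward in the classifier itself.
#'
#' @param labels a [LabelTable-class].
#' @param graph an [OntologyGraph-class].
#' @param closure a [ClosureTable-class].
#' @param keywords keyword list.
#' @param mode `"self"` or `"with-ancestors"`.
#' @return 2x2 integer matrix, rows `POS`/`NEG`, columns `no_keyword`/
#'   `keyword`.
#' @export
keywordConfusion <- function(labels, graph, closure,
                             keywords = lipidKeywords(),
                             mode = c("self", "with-ancestors")) {
  mode <- match.arg(mode)
  bits <- keywordFeatures(graph, keywords)
  selfHit <- rowSums(bits) > 0
  hit <- selfHit
  if (mode == "with-ancestors") {
    hitTerms <- names(selfHit)[selfHit]
    below <- termDescendants(intersect(hitTerms, names(closure@descIndex)),
                             closure)
    hit[intersect(below, names(hit))] <- TRUE
  }
  lab <- labels@labels[labels@labels != "UNKNOWN"]
  lab <- lab[names(lab) %in% names(hit)]
  out <- matrix(0L, 2, 2,
                dimnames = list(c("POS", "NEG"),
                                c("no_keyword", "keyword")))
  for (l in c("POS", "NEG")) {
    h <- hit[names(lab)[lab == l]]
    out[l, ] <- c(sum(!h), sum(h))
  }
  out
}

# Exact one-sided p of the Wilcoxon signed-rank statistic by sign-flip
# enumeration with midranks for tied absolute differences; the alternative
# is that the first series is larger (positive differences).  Zero
# differences are dropped beforehand (the standard convention).
.exactSignedRankP <- function(d, maxExact = 16L) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(p = NA_real_, degenerate = TRUE, n = 0L))
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  if (n <= maxExact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    stats <- as.vector(signs %*% r)
    p <- mean(stats >= obs - 1e-9)
  } else {
    # normal approximation with tie correction for larger samples
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p <- stats::pnorm((obs - mu) / sigma, lower.tail = FALSE)
  }
  list(p = p, degenerate = FALSE, n = n)
}

#' Rank-shift analysis of never-curated positives
#'
#' The terms that survive every iteration of a run without ever entering a
#' batch (the persistent leftover test set) are scored by the model at
#' every iteration.  If the classifier genuinely improves as labels
#' accumulate, the reference positives among the leftovers should drift
#' toward the top of the score-sorted persistent list.  For each requested
#' checkpoint ("after k iterations"; 0 means before the first) the average
#' rank of those leftover positives within the persistent list is computed
#' (rank 1 = highest score; ties share the midrank), and each checkpoint
#' pair is compared with a one-sided Wilcoxon signed-rank test
#' (alternative: the later checkpoint has smaller ranks).  Small samples
#' use the exact sign-flip enumeration; an all-zero difference vector is a
#' degenerate test and its p is omitted.
#'
#' @param result a [LoopResult-class] whose records retain score snapshots.
#' @param checkpoints integer vector of iteration counts; each must be
#'   between 0 and the number of recorded iterations.
#' @param positives reference positive accessions; defaults to the
#'   reference positives recorded in the result.
#' @return List with `leftover` (the leftover positive accessions),
#'   `average_rank` (named numeric per checkpoint), `ranks` (matrix
#'   leftover x checkpoint) and `p_values` (upper-triangle matrix of
#'   one-sided p-values, rows = earlier checkpoint).
#' @export
rankShift <- function(result, checkpoints,
                      positives = result@testPositives) {
  its <- result@iterations
  nIter <- length(its)
  if (any(checkpoints < 0 | checkpoints > nIter))
    stop("checkpoints must lie in [0, ", nIter, "]")
  persistent <- names(result@finalSnapshot)
  if (!length(persistent)) stop("no persistent test set in this result")
  leftover <- intersect(persistent, positives)
  if (!length(leftover)) stop("no leftover positives to rank")
  snapFor <- function(k) {
    s <- if (k < nIter) its[[k + 1L]]$snapshot else result@finalSnapshot
    s[persistent]
  }
  ranks <- vapply(checkpoints, function(k) {
    s <- snapFor(k)
    rk <- rank(-s, ties.method = "average")
    rk[leftover]
  }, numeric(length(leftover)))
  ranks <- matrix(ranks, nrow = length(leftover),
                  dimnames = list(leftover, paste0("after_", checkpoints)))
  avg <- colMeans(ranks)
  nc <- length(checkpoints)
  p <- matrix(NA_real_, nc, nc,
              dimnames = list(colnames(ranks), colnames(ranks)))
  degenerate <- matrix(FALSE, nc, nc, dimnames = dimnames(p))
  for (i in seq_len(nc)) for (j in seq_len(nc)) if (i < j) {
    d <- ranks[, i] - ranks[, j]   # positive when ranks improved
    res <- .exactSignedRankP(d)
    p[i, j] <- res$p
    degenerate[i, j] <- res$degenerate
  }
  list(leftover = leftover, average_rank = avg, ranks = ranks,
       p_values = p, degenerate = degenerate)
}
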