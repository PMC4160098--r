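#' Train the linear-margin term classifier
#'
#' A support vector machine with linear kernel (libsvm via \pkg{e1071}),
#' fitted on the feature vectors of the currently labelled terms.  The
#' returned model scores a term with the signed decision value of the
#' linear decision function: positive means predicted property-positive,
#' and the magnitude orders confidence.  Features are already bounded in
#' \[0,1\], so no rescaling is applied; no class weighting is used and the
#' soft-margin cost defaults to 1.
#'
#' @param features numeric feature matrix with accession rownames.
#' @param labels named character vector (or [LabelTable-class]) giving POS /
#'   NEG labels of the training terms; rows of `features` not named here
#'   are ignored.
#' @param cost soft-margin cost parameter C.
#' @param seed integer seed (libsvm training of an SVM with these inputs is
#'   deterministic; the seed guards the few RNG-dependent code paths).
#' @return A `termClassifier` object (list with the fitted svm, the sign
#'   orientation and the feature names).
#' @export
trainClassifier <- function(features, labels, cost = 1, seed = 1L) {
  if (is(labels, "LabelTable"))
    labels <- labels@labels[labels@labels != "UNKNOWN"]
  train <- intersect(rownames(features), names(labels))
  y <- factor(labels[train], levels = c("NEG", "POS"))
  if (length(unique(y)) < 2L || !length(train))
    stop("degenerate training set: need at least one POS and one NEG term")
  x <- features[train, , drop = FALSE]
  if (nrow(unique(x)) == 1L)
    stop("degenerate training set: all training vectors are identical, ",
         "no margin can separate the classes")
  model <- withr::with_seed(seed,
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
               probability = FALSE))
  # libsvm's decision value is positive for the first class it encountered;
  # orient so positive score always means predicted POS
  dv <- attr(stats::predict(model, x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (startsWith(colnames(dv)[1], "POS")) 1 else -1
  structure(list(svm = model, flip = flip, featureNames = colnames(x)),
            class = "termClassifier")
}

#' @export
print.termClassifier <- function(x, ...) {
  cat("termClassifier: linear-kernel SVM over", length(x$featureNames),
      "features,", x$svm$tot.nSV, "support vectors\n")
  invisible(x)
}

#' Score terms with a fitted classifier
#'
#' @param model a `termClassifier` from [trainClassifier()].
#' @param features feature matrix (must contain the model's features).
#' @param accessions rows to score; defaults to all rows.
#' @return Named numeric vector of decision scores (positive = predicted
#'   property-positive).
#' @export
classifierScores <- function(model, features, accessions = NULL) {
  if (is.null(accessions)) accessions <- rownames(features)
  if (!length(accessions))
    return(setNames(numeric(0), character(0)))
  x <- features[accessions, model$featureNames, drop = FALSE]
  pred <- stats::predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")[, 1]
  setNames(model$flip * as.numeric(dv), accessions)
}

#' Rank test-set terms by prediction score
#'
#' Sorts descending by score; ties are broken by ascending accession so
#' rankings are deterministic.
#'
#' @inheritParams classifierScores
#' @return `data.frame` with columns `accession`, `score`, sorted.
#' @export
scoreAndRank <- function(model, features, accessions = NULL) {
  s <- classifierScores(model, features, accessions)
  ord <- order(-s, names(s), method = "radix")
  data.frame(accession = names(s)[ord], score = unname(s)[ord],
             stringsAsFactors = FALSE)
}
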