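## Metrics (AUROC / AUPRC / F1 / Brier), macro aggregation over the three
## exam-level labels, seed-paired significance testing, and the test-time
## robustness perturbations.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted one half (midrank convention).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1) with at least one of each class.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("auroc: scores and labels must have equal length")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("auroc: undefined, labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' `sum_k (R_k - R_{k-1}) P_k` over descending-score thresholds, with tied
#' scores processed as one group.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("auprc: scores and labels must have equal length")
  npos <- sum(labels == 1)
  if (npos == 0L) stop("auprc: undefined, no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  n <- seq_along(y)
  last <- which(grp != c(grp[-1L], -1))          # last index of each tie group
  tpg <- tp[last]; ng <- n[last]
  prec <- tpg / ng
  rec <- tpg / npos
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a fixed probability threshold
#'
#' Predictions are `score >= threshold`; F1 = 2PR/(P+R), defined as 0 when
#' precision + recall is 0.
#'
#' @inheritParams auroc
#' @param threshold decision threshold (default 0.5 for all labels).
#' @return F1 in [0, 1].
#' @export
f1AtThreshold <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Brier score
#'
#' Mean squared error between predicted probabilities and binary labels;
#' lower is better calibrated.
#'
#' @inheritParams auroc
#' @return mean of (p - y)^2.
#' @export
brier <- function(scores, labels) {
  if (any(scores < 0 | scores > 1)) stop("brier: scores must lie in [0, 1]")
  mean((scores - labels)^2)
}

#' Per-label and macro metric report
#'
#' Computes AUROC, AUPRC, F1 (at the fixed threshold) and Brier independently
#' for each of the three labels and macro-averages them (unweighted mean).
#'
#' @param scores n x 3 probability matrix (columns abnormal, acl, meniscus).
#' @param labels n x 3 binary label matrix.
#' @param threshold F1 decision threshold.
#' @param naOnDegenerate when `TRUE`, a label column with a single class
#'   yields `NA` for its ranking metrics instead of an error.
#' @return a [MetricReport-class].
#' @export
metricReport <- function(scores, labels, threshold = 0.5,
                         naOnDegenerate = FALSE) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(ncol(scores) == 3L, all(dim(scores) == dim(labels)))
  per <- matrix(NA_real_, 4L, 3L,
                dimnames = list(c("auroc", "auprc", "f1", "brier"), LABEL_NAMES))
  for (j in seq_len(3L)) {
    s <- scores[, j]; y <- labels[, j]
    single <- length(unique(y)) < 2L
    if (single && !naOnDegenerate)
      stop("metricReport: label '", LABEL_NAMES[j], "' has a single class")
    per["auroc", j] <- if (single) NA_real_ else auroc(s, y)
    per["auprc", j] <- if (sum(y) == 0) NA_real_ else auprc(s, y)
    per["f1", j] <- f1AtThreshold(s, y, threshold)
    per["brier", j] <- brier(s, y)
  }
  methods::new("MetricReport", perLabel = per, macro = rowMeans(per),
               threshold = threshold, nExams = nrow(scores))
}

#' Seed-paired two-sided t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample standard deviation and
#' `n - 1` degrees of freedom. Degenerate cases are flagged: all differences
#' zero gives `t = 0, p = 1`; zero variance with nonzero mean gives `p = 0`.
#'
#' @param a,b equal-length numeric vectors of per-run metric values, paired
#'   by seed.
#' @return list of class `PairedTestResult`: `meanDiff`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b))
    stop("pairedTTest: inputs must have equal length")
  n <- length(a)
  if (n < 2L) stop("pairedTTest: need at least two paired values")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  ## differences equal up to floating-point representation count as
  ## zero-variance (the degenerate case), not as an astronomical t statistic
  if (s <= 1e-12 * max(1, abs(m))) {
    res <- list(meanDiff = m, t = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1L, p = if (m == 0) 1 else 0, degenerate = TRUE)
  } else {
    tstat <- m / (s / sqrt(n))
    res <- list(meanDiff = m, t = tstat, df = n - 1L,
                p = 2 * stats::pt(-abs(tstat), n - 1L), degenerate = FALSE)
  }
  class(res) <- "PairedTestResult"
  res
}

#' Test-time intensity-shift perturbation
#'
#' Adds a constant (in post-normalization intensity units) to every pixel of
#' every view; labels unchanged.
#'
#' @param exam an [ExamTensor-class].
#' @param shift additive constant (default 0.5).
#' @return perturbed `ExamTensor`.
#' @export
perturbIntensity <- function(exam, shift = 0.5) {
  methods::initialize(exam, views = lapply(exam@views, function(v) v + shift))
}

#' Test-time view-dropout perturbation
#'
#' Replaces exactly one uniformly chosen view (drawn from the current RNG
#' stream) with zeros; labels unchanged.
#'
#' @param exam an [ExamTensor-class].
#' @return perturbed `ExamTensor` with attribute `"droppedView"`.
#' @export
perturbViewDropout <- function(exam) {
  v <- sample.int(3L, 1L)
  views <- exam@views
  views[[v]] <- array(0, dim(views[[v]]))
  out <- methods::initialize(exam, views = views)
  attr(out, "droppedView") <- VIEW_NAMES[v]
  out
}

## apply a named perturbation to a list of exams (seeded)
applyPerturbation <- function(exams, perturbation = c("none", "intensity_shift",
                                                      "view_dropout"),
                              shift = 0.5, seed = 1L) {
  perturbation <- match.arg(perturbation)
  switch(perturbation,
    none = exams,
    intensity_shift = lapply(exams, perturbIntensity, shift = shift),
    view_dropout = {
      set.seed(as.integer(seed))
      lapply(exams, perturbViewDropout)
    })
}

#' Evaluate a model on exams, optionally under a perturbation
#'
#' @param model a [MILModel-class].
#' @param exams list of labeled [ExamTensor-class].
#' @param perturbation `"none"`, `"intensity_shift"` or `"view_dropout"`.
#' @param shift intensity-shift magnitude.
#' @param seed seed for the view-dropout draw.
#' @param threshold F1 threshold.
#' @param naOnDegenerate passed through to [metricReport()].
#' @return a [MetricReport-class].
#' @export
evaluateModel <- function(model, exams, perturbation = "none", shift = 0.5,
                          seed = 1L, threshold = 0.5, naOnDegenerate = FALSE) {
  exams <- applyPerturbation(exams, perturbation, shift = shift, seed = seed)
  pred <- predictExams(model, exams)
  labels <- t(vapply(exams, function(e) e@labels, integer(3L)))
  metricReport(pred$probs, labels, threshold = threshold,
               naOnDegenerate = naOnDegenerate)
}
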