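# Linear soft-margin SVM over the 13 posterior z-scores (the SVMP1
# biomarker). Solved by dual coordinate descent on the L1-loss dual with
# the bias handled as an augmented constant feature (the liblinear
# formulation):
#   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x~_i),  x~ = (x, 1).
# The problem is strictly convex in w, so any correct solver yields the
# same weights; tests verify against an independent box-constrained QP
# solution of the same dual.

# core solver: X (n x p, WITHOUT bias column), y in {-1, +1};
# compiled dual coordinate descent (see src/svm_dcd.cpp)
svm_dcd <- function(X, y, cost, tol = 1e-8, max_pass = 100000) {
  svm_dcd_cpp(X, as.numeric(y), cost, tol, max_pass)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the SVMP1 linear biomarker
#'
#' Fits a linear soft-margin SVM classifying CC against the rest on the
#' posterior z-score matrix. The cost hyperparameter is chosen from a grid
#' by stratified cross-validated accuracy (ties go to the smallest cost).
#' Scores are oriented so that LOWER scores are more CC-like (consistent
#' with the reduced posterior P1 in CC), by sign-flipping the decision
#' function if needed so that `mean(score | CC) < mean(score | non-CC)`.
#'
#' @param X numeric matrix, participants x 13 posterior electrodes
#'   (z-scores; columns named by electrode).
#' @param is_cc logical vector: `TRUE` for CC participants.
#' @param cost_grid candidate cost values (default `2^(-5:5)`).
#' @param nfolds cross-validation folds (default 5, reduced if a class is
#'   smaller).
#' @param seed seed controlling the fold assignment.
#' @return A `linear_biomarker_model`: list with `w` (named weights), `b`
#'   (bias), `cost`, `cv_accuracy`, `orientation` (`"lower"`), and
#'   `training_n`.
#' @export
train_linear_svm <- function(X, is_cc, cost_grid = 2^(-5:5), nfolds = 5,
                             seed = 1) {
  X <- as.matrix(X)
  if (!length(cost_grid)) stop("empty cost grid")
  y <- ifelse(is_cc, 1, -1)
  if (length(unique(y)) < 2) stop("both classes required for training")
  if (min(table(y)) < 2) stop("need >= 2 participants per class")
  k <- min(nfolds, min(table(y)))
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(cost_grid, function(cost) {
    hits <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- svm_dcd(X[tr, , drop = FALSE], y[tr], cost, tol = 1e-5)
      pred <- sign(X[!tr, , drop = FALSE] %*% m$w + m$b)
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  best <- which(acc >= max(acc) - 1e-12)[1]   # ties -> smallest cost
  fit <- svm_dcd(X, y, cost_grid[best])
  w <- fit$w; b <- fit$b
  score <- drop(X %*% w + b)
  if (mean(score[is_cc]) > mean(score[!is_cc])) { w <- -w; b <- -b }
  names(w) <- colnames(X)
  structure(list(w = w, b = b, cost = cost_grid[best],
                 cv_accuracy = stats::setNames(acc, cost_grid),
                 orientation = "lower", training_n = length(y)),
            class = "linear_biomarker_model")
}

#' @export
print.linear_biomarker_model <- function(x, ...) {
  cat("<linear_biomarker_model> SVMP1,", length(x$w), "electrodes, cost",
      format(x$cost), "\n")
  invisible(x)
}

#' SVMP1 score
#'
#' `score = w . z + b` for one participant or a matrix of participants.
#'
#' @param model a `linear_biomarker_model`.
#' @param z named posterior z-score vector, or a matrix with matching
#'   columns.
#' @return numeric score(s); lower = more CC-like.
#' @export
svmp1_score <- function(model, z) {
  if (is.matrix(z)) {
    if (ncol(z) != length(model$w)) stop("dimension mismatch")
    drop(z[, names(model$w), drop = FALSE] %*% model$w + model$b)
  } else {
    if (length(z) < length(model$w)) stop("dimension mismatch")
    sum(model$w * z[names(model$w)]) + model$b
  }
}

#' Threshold rule for a biomarker
#'
#' @param biomarker `"MPP1"` or `"SVMP1"`.
#' @param threshold cutoff value (z or weighted-z units).
#' @param direction side of the threshold labelled CC; `"le"` means scores
#'   at or below the threshold are CC (boundary counts as CC).
#' @param source identifier of the development cohort.
#' @return a `threshold_rule`.
#' @export
threshold_rule <- function(biomarker, threshold, direction = "le",
                           source = NA_character_) {
  direction <- match.arg(direction, c("le", "ge"))
  stopifnot(is.finite(threshold))
  structure(list(biomarker = biomarker, threshold = threshold,
                 direction = direction, source = source),
            class = "threshold_rule")
}

#' Apply a threshold rule
#'
#' @param score numeric biomarker score(s).
#' @param rule a [threshold_rule()].
#' @return character vector `"CC"` / `"non-CC"`; scores exactly at the
#'   threshold classify as CC.
#' @export
classify_scores <- function(score, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  cc <- if (rule$direction == "le") score <= rule$threshold
        else score >= rule$threshold
  ifelse(cc, "CC", "non-CC")
}
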