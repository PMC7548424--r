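# ROC analysis: empirical curves, AUC (Mann-Whitney), Youden-J threshold
# selection, DeLong confidence intervals, and the paired stratified
# bootstrap comparison of two correlated AUCs.

# orient scores so that HIGHER = more case-like
orient_scores <- function(score, direction) {
  direction <- match.arg(direction, c("le", "ge"))
  if (direction == "le") -score else score
}

#' Empirical ROC curve
#'
#' Computes the empirical ROC of a biomarker score for identifying CC
#' (the positive class). With `direction = "le"` (the package convention)
#' lower scores are more CC-like and each observed score value `t` defines
#' the rule "score <= t is CC". The AUC is the Mann-Whitney statistic
#' (ties counted 1/2), identical to the trapezoidal area.
#'
#' @param score numeric biomarker scores.
#' @param is_cc logical: `TRUE` for CC.
#' @param direction `"le"` (low = CC, default) or `"ge"`.
#' @return A `roc_result`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `direction`, `n_case`, `n_control`.
#' @export
roc_curve <- function(score, is_cc, direction = "le") {
  is_cc <- as.logical(is_cc)
  stopifnot(length(score) == length(is_cc), !anyNA(score), !anyNA(is_cc))
  if (!any(is_cc) || all(is_cc)) stop("both classes must be present")
  direction <- match.arg(direction, c("le", "ge"))
  thr <- sort(unique(score))
  if (direction == "le") {
    sens <- vapply(thr, function(t) mean(score[is_cc] <= t), numeric(1))
    spec <- vapply(thr, function(t) mean(score[!is_cc] > t), numeric(1))
  } else {
    thr <- rev(thr)
    sens <- vapply(thr, function(t) mean(score[is_cc] >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(score[!is_cc] < t), numeric(1))
  }
  s <- orient_scores(score, direction)
  r <- rank(s)                         # midranks handle ties
  n1 <- sum(is_cc); n0 <- sum(!is_cc)
  auc <- (sum(r[is_cc]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, direction = direction,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", round(x$auc, 3),
      sprintf("(%d cases / %d controls)\n", x$n_case, x$n_control))
  invisible(x)
}

#' Youden-J optimal threshold
#'
#' Selects the threshold maximizing `J = sensitivity + specificity - 1`
#' (the vertical distance of the ROC point from the chance diagonal).
#' Ties are broken in favour of the threshold with the higher specificity.
#'
#' @param roc a `roc_result`.
#' @param biomarker name recorded on the returned rule.
#' @param source development-cohort identifier recorded on the rule.
#' @return a [threshold_rule()] with attribute `"youden_j"`.
#' @export
youden_threshold <- function(roc, biomarker = "MPP1", source = NA_character_) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  cand <- which(j >= max(j) - 1e-12)
  best <- cand[order(-roc$specificity[cand])][1]
  rule <- threshold_rule(biomarker, roc$thresholds[best],
                         direction = roc$direction, source = source)
  attr(rule, "youden_j") <- j[best]
  attr(rule, "sensitivity") <- roc$sensitivity[best]
  attr(rule, "specificity") <- roc$specificity[best]
  rule
}

#' DeLong confidence interval for an AUC
#'
#' Nonparametric AUC variance from DeLong's placement values (midranks for
#' ties); the CI is `AUC +/- z * SE`, truncated to `[0, 1]`. Perfect
#' separation gives a degenerate zero-width interval with a warning.
#'
#' @param score,is_cc,direction as in [roc_curve()].
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `se`, `lower`, `upper`, `level`,
#'   `method = "delong"`.
#' @export
delong_ci <- function(score, is_cc, level = 0.95, direction = "le") {
  is_cc <- as.logical(is_cc)
  if (sum(is_cc) < 2 || sum(!is_cc) < 2) stop("need >= 2 per class")
  s <- orient_scores(score, direction)
  x <- s[is_cc]; y <- s[!is_cc]
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  v10 <- rowMeans(cmp)                 # placements of cases
  v01 <- colMeans(cmp)                 # placements of controls
  auc <- mean(v10)
  v <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
  se <- sqrt(v)
  if (se == 0)
    warning("degenerate AUC variance (perfect separation); zero-width CI")
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       level = level, method = "delong")
}

#' Paired stratified bootstrap comparison of two AUCs
#'
#' Compares two biomarkers scored on the same participants. Cases and
#' non-cases are resampled separately with replacement; both AUCs are
#' recomputed on each resample and
#' `D = (AUC_A - AUC_B) / SD_boot(delta AUC)` is referred to the standard
#' normal (two-sided).
#'
#' @param score_a,score_b paired score vectors.
#' @param is_cc logical case indicator.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @param direction score orientation, see [roc_curve()].
#' @return list with `D`, `p`, `auc_a`, `auc_b`, `n_boot`, `seed`.
#' @export
bootstrap_auc_test <- function(score_a, score_b, is_cc, n_boot = 2000,
                               seed = 1, direction = "le") {
  if (n_boot < 2) stop("n_boot must be >= 2")
  is_cc <- as.logical(is_cc)
  stopifnot(length(score_a) == length(score_b),
            length(score_a) == length(is_cc))
  a <- orient_scores(score_a, direction)
  b <- orient_scores(score_b, direction)
  idx1 <- which(is_cc); idx0 <- which(!is_cc)
  auc_fast <- function(s, i1, i0) {
    r <- rank(c(s[i1], s[i0]))
    n1 <- length(i1)
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(i0))
  }
  auc_a <- auc_fast(a, idx1, idx0)
  auc_b <- auc_fast(b, idx1, idx0)
  set.seed(seed)
  delta <- vapply(seq_len(n_boot), function(k) {
    i1 <- sample(idx1, replace = TRUE)
    i0 <- sample(idx0, replace = TRUE)
    auc_fast(a, i1, i0) - auc_fast(b, i1, i0)
  }, numeric(1))
  sd_d <- stats::sd(delta)
  d_stat <- if (sd_d == 0) 0 else (auc_a - auc_b) / sd_d
  list(D = d_stat, p = 2 * stats::pnorm(-abs(d_stat)),
       auc_a = auc_a, auc_b = auc_b, n_boot = n_boot, seed = seed)
}
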