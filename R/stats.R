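# Classification performance summaries and the regression models used to
# characterize the biomarkers: confusion metrics with likelihood ratios,
# Cohen's kappa, the OLS group model on MPP1, and the logistic confound
# models (age at surgery / time since surgery).

#' Confusion metrics and likelihood ratios
#'
#' `confusion_metrics()` cross-tabulates true labels against predictions;
#' `confusion_from_counts()` starts from the four counts, and
#' `confusion_from_rates()` from a printed sensitivity/specificity pair
#' (counts then unavailable). All report sensitivity, specificity,
#' accuracy, and the positive/negative likelihood ratios
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`.
#'
#' @param truth,prediction aligned vectors; the positive class is `"CC"`.
#' @return a `confusion_report` list with `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity`, `specificity`, `accuracy`, `lr_pos`, `lr_neg`.
#' @export
confusion_metrics <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction), length(truth) > 0)
  pos <- truth == "CC"
  pred_pos <- prediction == "CC"
  confusion_from_counts(tp = sum(pos & pred_pos), fn = sum(pos & !pred_pos),
                        tn = sum(!pos & !pred_pos), fp = sum(!pos & pred_pos))
}

#' @rdname confusion_metrics
#' @param tp,fn,tn,fp cell counts.
#' @export
confusion_from_counts <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion table")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / total,
                 lr_pos = sens / (1 - spec),
                 lr_neg = (1 - sens) / spec),
            class = "confusion_report")
}

#' @rdname confusion_metrics
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @export
confusion_from_rates <- function(sensitivity, specificity) {
  structure(list(tp = NA, fn = NA, tn = NA, fp = NA,
                 sensitivity = sensitivity, specificity = specificity,
                 accuracy = NA_real_,
                 lr_pos = sensitivity / (1 - specificity),
                 lr_neg = (1 - sensitivity) / specificity),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report>\n")
  if (!is.na(x$tp))
    cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.3f  specificity %.3f", x$sensitivity,
              x$specificity))
  if (!is.na(x$accuracy)) cat(sprintf("  accuracy %.3f", x$accuracy))
  cat(sprintf("\n  LR+ %.2f  LR- %.2f\n", x$lr_pos, x$lr_neg))
  invisible(x)
}

#' Cohen's kappa for two binary classifications
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement from the marginal products. When both ratings are
#' constant and identical, `p_e = 1` and kappa is defined as 1 with a
#' warning.
#'
#' @param rating_1,rating_2 aligned vectors (any two-level coding).
#' @return scalar kappa.
#' @export
cohens_kappa <- function(rating_1, rating_2) {
  stopifnot(length(rating_1) == length(rating_2), length(rating_1) > 0)
  n <- length(rating_1)
  lev <- union(unique(rating_1), unique(rating_2))
  t1 <- table(factor(rating_1, lev)) / n
  t2 <- table(factor(rating_2, lev)) / n
  p_o <- mean(rating_1 == rating_2)
  p_e <- sum(t1 * t2)
  if (1 - p_e < .Machine$double.eps) {
    warning("both ratings constant and equal; kappa defined as 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' OLS group model for MPP1
#'
#' Fits `MPP1 ~ Group` by ordinary least squares with the Control group as
#' the reference level, returning raw and standardized coefficients for the
#' CC and DC offsets. Standardized coefficients divide the raw coefficient
#' by the standard deviation of the outcome (the convention that reproduces
#' the published raw/standardized ratio; documented as an assumption).
#'
#' @param mpp1 numeric MPP1 values.
#' @param group factor/character with levels CC, DC, Control.
#' @return list with `coef` (data.frame: term, beta, std_beta, se, t, p),
#'   `adj_r2`, `f`, `df`, and the underlying `lm` fit.
#' @export
ols_group_model <- function(mpp1, group) {
  g <- factor(group, levels = c("Control", "DC", "CC"))
  if (any(is.na(g))) stop("unknown group label")
  if (nlevels(droplevels(g)) < 2) stop("need >= 2 groups")
  fit <- stats::lm(mpp1 ~ g)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- sub("^g", "", rownames(co))
  out <- data.frame(term = terms, beta = co[, 1],
                    std_beta = co[, 1] / stats::sd(mpp1),
                    se = co[, 2], t = co[, 3], p = co[, 4],
                    row.names = NULL)
  list(coef = out, adj_r2 = sm$adj.r.squared,
       f = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[2:3]), fit = fit)
}

#' Logistic confound model for classification accuracy
#'
#' Regresses per-participant classification success (CC and DC participants
#' only) on standardized age at surgery and time since surgery (months).
#' After standardization the intercept is the log-odds of a correct
#' classification at the mean age at surgery and mean recovery time.
#' Perfect separation (or a degenerate all-correct outcome) is flagged; the
#' reported fit is then the maximum-penalized-likelihood ridge fallback
#' obtained by adding a weak L2 penalty through data augmentation.
#'
#' @param correct logical/0-1 vector of classification success.
#' @param age_at_surgery,time_since_surgery months (unscaled; standardized
#'   internally).
#' @return list with `coef` (data.frame: term, beta, se, z, p),
#'   `separation` flag, and the `glm` fit.
#' @export
logistic_confound_model <- function(correct, age_at_surgery,
                                    time_since_surgery) {
  correct <- as.integer(correct)
  stopifnot(length(correct) == length(age_at_surgery),
            length(correct) == length(time_since_surgery))
  z1 <- as.numeric(scale(age_at_surgery))
  z2 <- as.numeric(scale(time_since_surgery))
  dat <- data.frame(correct = correct, aas = z1, tss = z2)
  fit <- suppressWarnings(
    stats::glm(correct ~ aas + tss, family = stats::binomial(), data = dat))
  mu <- fit$fitted.values
  sep <- !fit$converged || all(correct == correct[1]) ||
    any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  if (sep) {
    # weak ridge via prior pseudo-observations at the predictor origin
    aug <- data.frame(correct = c(correct, 0L, 1L),
                      aas = c(z1, 0, 0), tss = c(z2, 0, 0))
    w <- c(rep(1, length(correct)), 0.5, 0.5)
    fit <- suppressWarnings(
      stats::glm(correct ~ aas + tss, family = stats::binomial(),
                 data = aug, weights = w))
  }
  co <- summary(fit)$coefficients
  out <- data.frame(term = c("intercept", "age_at_surgery",
                             "time_since_surgery"),
                    beta = co[, 1], se = co[, 2], z = co[, 3], p = co[, 4],
                    row.names = NULL)
  list(coef = out, separation = sep, fit = fit)
}
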