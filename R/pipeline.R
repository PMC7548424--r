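# Two-experiment orchestration: develop biomarkers and thresholds on one
# cohort, freeze them, validate on a second cohort without refitting.

# deterministic checksum of an R object (artifact integrity, not crypto)
object_checksum <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

frozen_artifacts <- function(model, rules, montage) {
  art <- list(model = model, rules = rules,
              montage_labels = montage$labels)
  art$checksum <- object_checksum(art[c("model", "rules", "montage_labels")])
  class(art) <- "verp_artifacts"
  art
}

check_artifacts <- function(art) {
  stopifnot(inherits(art, "verp_artifacts"))
  ok <- identical(art$checksum,
                  object_checksum(art[c("model", "rules", "montage_labels")]))
  if (!ok) stop("frozen artifacts fail their checksum; development output ",
                "was modified after freezing")
  invisible(TRUE)
}

#' Develop biomarkers on a cohort (experiment 1 role)
#'
#' Runs the full development pipeline on a simulated (or otherwise
#' assembled) cohort: preprocessing, P1 feature extraction, the MPP1
#' biomarker, SVM training (SVMP1), ROC analyses with Youden-J thresholds
#' and DeLong CIs, the stratified bootstrap AUC comparison, the OLS group
#' model, and the logistic confound models. Returns an evaluation report
#' together with frozen artifacts (SVM weights + threshold rules) for
#' validation.
#'
#' @param cohort a `verp_cohort` from [simulate_cohort()], or a
#'   precomputed feature table from [cohort_features()].
#' @param group_mode `"all"` (CC vs DC + Control) or `"ccdc"`
#'   (CC vs DC only).
#' @param seed seed for SVM cross-validation folds and the bootstrap test.
#' @param cost_grid SVM cost grid.
#' @param n_boot bootstrap replicates for the AUC comparison.
#' @param montage montage.
#' @param ... preprocessing options passed to [cohort_features()].
#' @return a `verp_development`: list with `features` (tidy table),
#'   `scores`, `roc`, `ci`, `rules`, `auc_comparison`, `group_model`,
#'   `latency`, `confound`, and `artifacts`.
#' @export
run_develop <- function(cohort, group_mode = c("all", "ccdc"), seed = 1,
                        cost_grid = 2^(-5:5), n_boot = 2000,
                        montage = standard_montage(), ...) {
  group_mode <- match.arg(group_mode)
  feats <- if (inherits(cohort, "verp_cohort"))
    cohort_features(cohort, ...) else cohort
  use <- if (group_mode == "ccdc") feats$group %in% c("CC", "DC")
         else rep(TRUE, nrow(feats))
  f <- feats[use, ]
  is_cc <- f$group == "CC"
  if (!any(is_cc) || all(is_cc)) stop("development cohort needs CC and non-CC")

  z <- posterior_z_matrix(f, montage)
  mpp1 <- f$mpp1
  model <- train_linear_svm(z, is_cc, cost_grid = cost_grid, seed = seed)
  svmp1 <- svmp1_score(model, z)

  roc_m <- roc_curve(mpp1, is_cc)
  roc_s <- roc_curve(svmp1, is_cc)
  rule_m <- youden_threshold(roc_m, "MPP1", source = group_mode)
  rule_s <- youden_threshold(roc_s, "SVMP1", source = group_mode)
  ci_m <- delong_ci(mpp1, is_cc)
  ci_s <- delong_ci(svmp1, is_cc)
  cmp <- bootstrap_auc_test(mpp1, svmp1, is_cc, n_boot = n_boot, seed = seed)

  pred_m <- classify_scores(mpp1, rule_m)
  pred_s <- classify_scores(svmp1, rule_s)
  conf_m <- confusion_metrics(ifelse(is_cc, "CC", "non-CC"), pred_m)
  conf_s <- confusion_metrics(ifelse(is_cc, "CC", "non-CC"), pred_s)

  group_model <- if (group_mode == "all" &&
                     length(unique(f$group)) == 3)
    ols_group_model(mpp1, f$group) else NULL
  latency <- tryCatch(group_mean_latency(attr(feats, "features")),
                      error = function(e) NULL)

  pat <- f$group %in% c("CC", "DC")
  confound <- if (sum(pat) >= 6) {
    truth <- ifelse(is_cc, "CC", "non-CC")
    list(
      mpp1 = logistic_confound_model((pred_m == truth)[pat],
                                     f$age_at_surgery[pat],
                                     f$time_since_surgery[pat]),
      svmp1 = logistic_confound_model((pred_s == truth)[pat],
                                      f$age_at_surgery[pat],
                                      f$time_since_surgery[pat]))
  } else NULL

  structure(list(
    features = feats, group_mode = group_mode,
    scores = data.frame(id = f$id, group = f$group, mpp1 = mpp1,
                        svmp1 = svmp1, pred_mpp1 = pred_m,
                        pred_svmp1 = pred_s),
    roc = list(mpp1 = roc_m, svmp1 = roc_s),
    ci = list(mpp1 = ci_m, svmp1 = ci_s),
    rules = list(mpp1 = rule_m, svmp1 = rule_s),
    confusion = list(mpp1 = conf_m, svmp1 = conf_s),
    auc_comparison = cmp,
    group_model = group_model, latency = latency, confound = confound,
    artifacts = frozen_artifacts(model, list(mpp1 = rule_m, svmp1 = rule_s),
                                 montage),
    seed = seed
  ), class = "verp_development")
}

#' Validate frozen biomarkers on a second cohort (experiment 2 role)
#'
#' Applies the frozen SVM weights and threshold rules from a development
#' run to a new cohort without any refitting: computes MPP1 and SVMP1
#' scores, classifies with the frozen thresholds, and reports confusion
#' metrics, ROC/AUC with DeLong CIs, the bootstrap AUC comparison, and —
#' when participants overlap with the development cohort — Cohen's kappa
#' between the two runs' classifications.
#'
#' @param cohort validation `verp_cohort` or feature table.
#' @param development a `verp_development` (its `artifacts` are used), or a
#'   `verp_artifacts` object directly.
#' @param group_mode participant subset; defaults to the development run's
#'   mode when available.
#' @param new_only if `TRUE`, restrict the patient groups to participants
#'   absent from the development cohort (controls are retained), the
#'   "new participants only" analysis.
#' @param seed bootstrap seed.
#' @param n_boot bootstrap replicates.
#' @param montage montage.
#' @param ... passed to [cohort_features()].
#' @return a `verp_validation`: list with `scores`, `confusion`, `roc`,
#'   `ci`, `auc_comparison`, `kappa`, `group_model`, `confound`.
#' @export
run_validate <- function(cohort, development, group_mode = NULL,
                         new_only = FALSE, seed = 1, n_boot = 2000,
                         montage = standard_montage(), ...) {
  if (inherits(development, "verp_development")) {
    art <- development$artifacts
    dev_scores <- development$scores
    if (is.null(group_mode)) group_mode <- development$group_mode
  } else {
    art <- development
    dev_scores <- NULL
    if (is.null(group_mode)) group_mode <- "all"
  }
  check_artifacts(art)
  if (!identical(art$montage_labels, montage$labels))
    stop("montage mismatch between development artifacts and validation")

  feats <- if (inherits(cohort, "verp_cohort"))
    cohort_features(cohort, ...) else cohort
  use <- if (group_mode == "ccdc") feats$group %in% c("CC", "DC")
         else rep(TRUE, nrow(feats))
  f <- feats[use, ]
  if (new_only && !is.null(dev_scores)) {
    drop <- f$group %in% c("CC", "DC") & f$id %in% dev_scores$id
    f <- f[!drop, ]
  }
  is_cc <- f$group == "CC"

  z <- posterior_z_matrix(f, montage)
  mpp1 <- f$mpp1
  svmp1 <- svmp1_score(art$model, z)
  pred_m <- classify_scores(mpp1, art$rules$mpp1)
  pred_s <- classify_scores(svmp1, art$rules$svmp1)
  truth <- ifelse(is_cc, "CC", "non-CC")

  kappa <- NULL
  if (!is.null(dev_scores)) {
    shared <- intersect(f$id, dev_scores$id)
    if (length(shared) >= 2) {
      i2 <- match(shared, f$id); i1 <- match(shared, dev_scores$id)
      kappa <- list(
        mpp1 = cohens_kappa(dev_scores$pred_mpp1[i1], pred_m[i2]),
        svmp1 = cohens_kappa(dev_scores$pred_svmp1[i1], pred_s[i2]),
        n_shared = length(shared))
    }
  }

  group_model <- if (group_mode == "all" && length(unique(f$group)) == 3)
    ols_group_model(mpp1, f$group) else NULL

  pat <- f$group %in% c("CC", "DC")
  confound <- if (sum(pat) >= 6) {
    list(
      mpp1 = logistic_confound_model((pred_m == truth)[pat],
                                     f$age_at_surgery[pat],
                                     f$time_since_surgery[pat]),
      svmp1 = logistic_confound_model((pred_s == truth)[pat],
                                      f$age_at_surgery[pat],
                                      f$time_since_surgery[pat]))
  } else NULL

  structure(list(
    features = feats, group_mode = group_mode, new_only = new_only,
    scores = data.frame(id = f$id, group = f$group, mpp1 = mpp1,
                        svmp1 = svmp1, pred_mpp1 = pred_m,
                        pred_svmp1 = pred_s),
    confusion = list(mpp1 = confusion_metrics(truth, pred_m),
                     svmp1 = confusion_metrics(truth, pred_s)),
    roc = list(mpp1 = roc_curve(mpp1, is_cc),
               svmp1 = roc_curve(svmp1, is_cc)),
    ci = list(mpp1 = delong_ci(mpp1, is_cc),
              svmp1 = delong_ci(svmp1, is_cc)),
    auc_comparison = bootstrap_auc_test(mpp1, svmp1, is_cc,
                                        n_boot = n_boot, seed = seed),
    kappa = kappa, group_model = group_model, confound = confound,
    seed = seed
  ), class = "verp_validation")
}

#' Performance table (development + validation rows)
#'
#' Summarizes one or more runs in the standard classifier-performance
#' layout: AUC with CI, sensitivity, specificity and likelihood ratios
#' (AUC/sens/spec to 3 decimals, LRs to 2).
#'
#' @param ... named `verp_development` / `verp_validation` objects.
#' @return data.frame, one row per run x biomarker.
#' @export
performance_table <- function(...) {
  runs <- list(...)
  rows <- list()
  for (nm in names(runs)) {
    r <- runs[[nm]]
    for (bm in c("mpp1", "svmp1")) {
      conf <- r$confusion[[bm]]
      ci <- r$ci[[bm]]
      rows[[paste(nm, bm)]] <- data.frame(
        run = nm, biomarker = toupper(sub("p1$", "P1", bm)),
        auc = round(r$roc[[bm]]$auc, 3),
        ci_low = round(ci$lower, 3), ci_high = round(ci$upper, 3),
        sensitivity = round(conf$sensitivity, 3),
        specificity = round(conf$specificity, 3),
        lr_pos = round(conf$lr_pos, 2), lr_neg = round(conf$lr_neg, 2))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.verp_development <- function(x, ...) {
  cat("<verp_development> mode:", x$group_mode, "\n")
  cat(sprintf("  MPP1  AUC %.3f, Youden threshold %.3f\n",
              x$roc$mpp1$auc, x$rules$mpp1$threshold))
  cat(sprintf("  SVMP1 AUC %.3f, Youden threshold %.3f (cost %g)\n",
              x$roc$svmp1$auc, x$rules$svmp1$threshold,
              x$artifacts$model$cost))
  invisible(x)
}

#' @export
print.verp_validation <- function(x, ...) {
  cat("<verp_validation> mode:", x$group_mode,
      if (x$new_only) "(new participants only)" else "", "\n")
  cat(sprintf("  MPP1  AUC %.3f, sens %.3f spec %.3f\n",
              x$roc$mpp1$auc, x$confusion$mpp1$sensitivity,
              x$confusion$mpp1$specificity))
  cat(sprintf("  SVMP1 AUC %.3f, sens %.3f spec %.3f\n",
              x$roc$svmp1$auc, x$confusion$svmp1$sensitivity,
              x$confusion$svmp1$specificity))
  if (!is.null(x$kappa))
    cat(sprintf("  test-retest kappa: MPP1 %.3f, SVMP1 %.3f (n=%d)\n",
                x$kappa$mpp1, x$kappa$svmp1, x$kappa$n_shared))
  invisible(x)
}
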