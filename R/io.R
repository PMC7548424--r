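# Serialization: models and threshold rules to JSON, feature/score tables
# to CSV, evaluation reports to JSON, and a BrainVision-style ASCII triplet
# (.vhdr/.vmrk/.dat) export/import for epoched recordings.

fmt_num <- function(x) as.numeric(sprintf("%.17g", x))

#' Save / load a frozen biomarker model to JSON
#'
#' Weights are keyed by electrode label; numbers are written with full
#' (17 significant digit) precision so that a save/load round trip scores
#' bit-identically.
#'
#' @param artifacts a `verp_artifacts` object (from a development run) or a
#'   bare `linear_biomarker_model`.
#' @param path output file.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the restored object.
#' @export
write_model_json <- function(artifacts, path) {
  if (inherits(artifacts, "linear_biomarker_model"))
    artifacts <- frozen_artifacts(artifacts, list(), standard_montage())
  check_artifacts(artifacts)
  m <- artifacts$model
  obj <- list(
    model = list(weights = as.list(stats::setNames(
                   sprintf("%.17g", m$w), names(m$w))),
                 bias = sprintf("%.17g", m$b),
                 cost = m$cost, orientation = m$orientation,
                 training_n = m$training_n),
    rules = lapply(artifacts$rules, function(r) list(
      biomarker = r$biomarker, threshold = sprintf("%.17g", r$threshold),
      direction = r$direction, source = r$source)),
    montage_labels = artifacts$montage_labels,
    checksum = artifacts$checksum)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  w <- vapply(obj$model$weights, function(v) as.numeric(v), numeric(1))
  model <- structure(list(
    w = w, b = as.numeric(obj$model$bias), cost = obj$model$cost,
    cv_accuracy = NULL, orientation = obj$model$orientation,
    training_n = obj$model$training_n), class = "linear_biomarker_model")
  rules <- lapply(obj$rules, function(r) {
    rl <- threshold_rule(r$biomarker, as.numeric(r$threshold),
                         r$direction, r$source %||% NA_character_)
    rl
  })
  art <- list(model = model, rules = rules,
              montage_labels = unlist(obj$montage_labels))
  art$checksum <- object_checksum(art[c("model", "rules", "montage_labels")])
  class(art) <- "verp_artifacts"
  art
}

#' Write a tidy feature/score table to CSV
#'
#' @param features data.frame (e.g. from [cohort_features()] or a run's
#'   `scores`).
#' @param path output file.
#' @export
write_features_csv <- function(features, path) {
  data.table::fwrite(as.data.frame(features), path)
  invisible(path)
}

#' Serialize an evaluation run to JSON
#'
#' Captures the reportable surface of a development or validation run
#' (AUCs, CIs, thresholds, confusion metrics, comparison statistics,
#' seeds); deterministic for a fixed run.
#'
#' @param run a `verp_development` or `verp_validation`.
#' @param path output file.
#' @export
write_report_json <- function(run, path) {
  bm_block <- function(bm) {
    out <- list(auc = run$roc[[bm]]$auc,
                ci = run$ci[[bm]][c("lower", "upper", "level")],
                sensitivity = run$confusion[[bm]]$sensitivity,
                specificity = run$confusion[[bm]]$specificity,
                accuracy = run$confusion[[bm]]$accuracy,
                lr_pos = run$confusion[[bm]]$lr_pos,
                lr_neg = run$confusion[[bm]]$lr_neg)
    if (!is.null(run$rules))
      out$threshold <- run$rules[[bm]]$threshold
    out
  }
  obj <- list(kind = class(run)[1], group_mode = run$group_mode,
              seed = run$seed,
              mpp1 = bm_block("mpp1"), svmp1 = bm_block("svmp1"),
              auc_comparison = run$auc_comparison[c("D", "p", "n_boot",
                                                    "seed")])
  if (!is.null(run$kappa)) obj$kappa <- run$kappa
  if (!is.null(run$group_model))
    obj$group_model <- run$group_model$coef
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Cohort manifest
#'
#' Writes the participant table (ids, groups, metadata, attenuation draws
#' and sub-seeds) of a simulated cohort as a JSON manifest, enough to
#' regenerate every recording exactly.
#'
#' @param cohort a `verp_cohort`.
#' @param path output file.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "verp_cohort"))
  obj <- list(trials_per_quadrant = cohort$trials_per_quadrant,
              srate = cohort$srate,
              participants = cohort$participants)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- BrainVision-style ASCII triplet ---------------------------------------

#' Export / import an epoch set as a BrainVision-style ASCII triplet
#'
#' Writes `<stem>.vhdr` (header), `<stem>.vmrk` (segment and stimulus
#' markers) and `<stem>.dat` (ASCII multiplexed data, one line per sample,
#' trials concatenated). The ASCII data format keeps the export plain text;
#' `read_brainvision()` restores the epoch set (events and keep-mask
#' round-trip through the marker file).
#'
#' @param epochs an [epoch_set()].
#' @param stem output path without extension.
#' @return `write_brainvision()` the stem, invisibly;
#'   `read_brainvision()` an `epoch_set`.
#' @export
write_brainvision <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$signal)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.dat", basename(stem)),
    sprintf("MarkerFile=%s.vmrk", basename(stem)),
    "DataFormat=ASCII", "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", d[2]),
    sprintf("SamplingInterval=%.6f", 1e6 / epochs$srate),
    sprintf("SegmentDataPoints=%d", d[3]),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(d[2]), epochs$montage$labels))
  writeLines(hdr, paste0(stem, ".vhdr"))

  ev <- epochs$events
  onset_idx <- which.min(abs(epochs$times))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Marker Infos]")
  k <- 0
  for (i in seq_len(d[1])) {
    k <- k + 1
    mrk <- c(mrk, sprintf("Mk%d=New Segment,,%d,1,0", k, (i - 1) * d[3] + 1))
    k <- k + 1
    desc <- sprintf("S %s/%s/%s/%s/%s", ev$field[i], ev$side[i],
                    as.integer(ev$target[i]),
                    ifelse(is.na(ev$rt[i]), "NA", format(ev$rt[i])),
                    as.integer(epochs$keep[i]))
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0", k, desc,
                          (i - 1) * d[3] + onset_idx))
  }
  writeLines(mrk, paste0(stem, ".vmrk"))

  flat <- matrix(aperm(epochs$signal, c(3, 1, 2)), d[1] * d[3], d[2])
  data.table::fwrite(as.data.frame(flat), paste0(stem, ".dat"),
                     sep = " ", col.names = FALSE)
  invisible(stem)
}

#' @rdname write_brainvision
#' @param montage montage to attach (labels must match the header).
#' @export
read_brainvision <- function(stem, montage = standard_montage()) {
  hdr <- readLines(paste0(stem, ".vhdr"))
  getv <- function(key) sub(paste0("^", key, "="), "",
                            grep(paste0("^", key, "="), hdr, value = TRUE)[1])
  n_ch <- as.integer(getv("NumberOfChannels"))
  n_t <- as.integer(getv("SegmentDataPoints"))
  srate <- 1e6 / as.numeric(getv("SamplingInterval"))
  labels <- sub(",.*$", "", sub("^Ch[0-9]+=", "",
                                grep("^Ch[0-9]+=", hdr, value = TRUE)))
  if (!identical(labels, montage$labels))
    stop("channel labels do not match the montage")

  mrk <- readLines(paste0(stem, ".vmrk"))
  stim <- grep("^Mk[0-9]+=Stimulus,", mrk, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=Stimulus,S ", "", stim), ",")
  desc <- vapply(parts, `[[`, character(1), 1)
  fields <- strsplit(desc, "/")
  ev <- data.frame(
    field = vapply(fields, `[[`, character(1), 1),
    side = vapply(fields, `[[`, character(1), 2),
    target = vapply(fields, `[[`, character(1), 3) == "1",
    rt = suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4))),
    stringsAsFactors = FALSE)
  keep <- vapply(fields, `[[`, character(1), 5) == "1"
  onset_pos <- as.integer(vapply(parts, `[[`, character(1), 2))[1]
  onset_idx <- onset_pos   # position within first segment

  flat <- as.matrix(data.table::fread(paste0(stem, ".dat"), header = FALSE))
  n_trial <- nrow(flat) / n_t
  sig <- aperm(array(flat, c(n_t, n_trial, n_ch)), c(2, 3, 1))
  times <- (seq_len(n_t) - onset_idx) * 1000 / srate
  epoch_set(sig, times, srate, montage, ev, keep = keep)
}
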