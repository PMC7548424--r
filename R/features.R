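# P1 feature extraction: peak search, individual latency, windowed means,
# across-electrode standard scores, and the MPP1 biomarker.

#' Largest peak of a single-electrode waveform in a window
#'
#' Scans the waveform of one electrode for strict local maxima (samples
#' strictly greater than both neighbours) whose latency lies inside
#' `window_ms`, and returns the one with the highest amplitude. Window
#' endpoints are eligible provided they are strict local maxima of the full
#' waveform; epoch-edge samples are never eligible. Ties in amplitude are
#' broken by the earliest latency.
#'
#' @param v a [verp()].
#' @param electrode electrode label.
#' @param window_ms search window in ms, default `c(100, 200)`.
#' @return list with `electrode`, `latency` (ms), `amplitude` (uV), and
#'   `found` (logical; when `FALSE` latency/amplitude are `NA`).
#' @export
find_largest_peak <- function(v, electrode, window_ms = c(100, 200)) {
  stopifnot(inherits(v, "verp"))
  if (window_ms[1] < min(v$times) || window_ms[2] > max(v$times))
    stop("search window outside the epoch")
  x <- v$data[electrode, ]
  n <- length(x)
  i <- 2:(n - 1)
  is_peak <- c(FALSE, x[i] > x[i - 1] & x[i] > x[i + 1], FALSE)
  in_win <- v$times >= window_ms[1] & v$times <= window_ms[2]
  cand <- which(is_peak & in_win)
  if (!length(cand))
    return(list(electrode = electrode, latency = NA_real_,
                amplitude = NA_real_, found = FALSE))
  best <- cand[order(-x[cand], v$times[cand])][1]
  list(electrode = electrode, latency = v$times[best],
       amplitude = unname(x[best]), found = TRUE)
}

#' Individual P1 latency
#'
#' Runs [find_largest_peak()] at each of the 13 posterior electrodes and
#' takes the latency at the electrode with the globally maximal peak
#' amplitude. `NA` when no posterior electrode shows a peak in the window.
#'
#' @param v a [verp()].
#' @param montage montage providing the posterior subset.
#' @param window_ms search window, default `c(100, 200)`.
#' @return list with `latency` (ms or `NA`), `electrode` (or `NA`),
#'   `amplitude`.
#' @export
individual_p1_latency <- function(v, montage = v$montage,
                                  window_ms = c(100, 200)) {
  peaks <- lapply(montage$posterior, function(e)
    find_largest_peak(v, e, window_ms))
  found <- vapply(peaks, `[[`, logical(1), "found")
  if (!any(found))
    return(list(latency = NA_real_, electrode = NA_character_,
                amplitude = NA_real_))
  peaks <- peaks[found]
  amps <- vapply(peaks, `[[`, numeric(1), "amplitude")
  lats <- vapply(peaks, `[[`, numeric(1), "latency")
  best <- order(-amps, lats)[1]
  list(latency = peaks[[best]]$latency, electrode = peaks[[best]]$electrode,
       amplitude = peaks[[best]]$amplitude)
}

#' Windowed mean amplitude per electrode
#'
#' Arithmetic mean per electrode over the samples in
#' `[center - halfwidth, center + halfwidth]` ms, bounds inclusive.
#'
#' @param v a [verp()].
#' @param center_ms window centre in ms.
#' @param halfwidth_ms half-width in ms (default 25, a 50 ms window).
#' @return named numeric vector, one mean per electrode.
#' @export
windowed_mean <- function(v, center_ms, halfwidth_ms = 25) {
  stopifnot(inherits(v, "verp"))
  lo <- center_ms - halfwidth_ms; hi <- center_ms + halfwidth_ms
  if (lo < min(v$times) || hi > max(v$times))
    stop("amplitude window clipped by the epoch edge")
  idx <- time_index(v$times, lo, hi)
  rowMeans(v$data[, idx, drop = FALSE])
}

#' Fixed-window P1 feature vector
#'
#' The per-electrode mean amplitude over the fixed 120-170 ms window (a
#' 50 ms period centred on the 145 ms group-mean P1 latency). This is the
#' feature vector used for all participants, including those with a
#' numerically absent P1 for whom no individual latency exists.
#'
#' @param v a [verp()].
#' @param window_ms window bounds, default `c(120, 170)`.
#' @return named numeric vector of per-electrode means.
#' @export
fixed_window_features <- function(v, window_ms = c(120, 170)) {
  windowed_mean(v, mean(window_ms), diff(window_ms) / 2)
}

#' Numerical presence of the P1 wave
#'
#' A participant's P1 counts as numerically absent when the mean amplitude
#' in the 50 ms window centred on the individual latency, at the latency
#' electrode, is negative for both the upper and the lower visual field
#' condition (or when no peak exists in either condition). Such
#' participants are excluded from latency statistics only — never from
#' classification.
#'
#' @param v_upper,v_lower the participant's two [verp()]s.
#' @param montage montage (posterior subset).
#' @param halfwidth_ms window half-width, default 25.
#' @return logical: `TRUE` when a P1 is numerically present.
#' @export
has_p1 <- function(v_upper, v_lower, montage = v_upper$montage,
                   halfwidth_ms = 25) {
  val <- function(v) {
    p <- individual_p1_latency(v, montage)
    if (is.na(p$latency)) return(NA_real_)
    windowed_mean(v, p$latency, halfwidth_ms)[[p$electrode]]
  }
  vu <- val(v_upper); vl <- val(v_lower)
  if (is.na(vu) && is.na(vl)) return(FALSE)
  !(isTRUE(vu < 0 | is.na(vu)) && isTRUE(vl < 0 | is.na(vl)))
}

#' Across-electrode standard scores of a topography
#'
#' Converts per-electrode mean amplitudes to standard scores across all
#' electrodes (sample SD, n-1): a topography-preserving normalization that
#' removes participant-level amplitude scaling, in particular the higher
#' VERP amplitudes of children. Affine-invariant: `z(a*m + b) = z(m)` for
#' any `a > 0`.
#'
#' @param means named per-electrode mean amplitudes (>= 2 electrodes).
#' @return named z-score vector (mean 0, SD 1).
#' @export
normalize_topography <- function(means) {
  if (length(means) < 2) stop("need >= 2 electrodes")
  s <- stats::sd(means)
  if (!is.finite(s) || s == 0)
    stop("zero variance across electrodes; topography cannot be normalized")
  (means - mean(means)) / s
}

#' Mean posterior P1 (MPP1)
#'
#' The arithmetic mean of the across-electrode z-scores over the 13
#' posterior electrodes — equivalently a weighted sum with weight 1/13 per
#' posterior electrode.
#'
#' @param z named z-score vector over the full montage.
#' @param montage montage providing the posterior subset.
#' @return scalar MPP1 score (unitless).
#' @export
compute_mpp1 <- function(z, montage) {
  stopifnot(all(montage$posterior %in% names(z)))
  mean(z[montage$posterior])
}

#' Participant-level P1 features
#'
#' Bundles the full feature extraction for one participant: individual P1
#' latency (upper field), numerical P1 presence, fixed-window per-electrode
#' means, z-scores and MPP1. Biomarkers are computed from the upper-field
#' VERP (the field with the larger P1); the lower-field VERP enters only
#' the latency/presence bookkeeping and the field-effect test.
#'
#' @param v_upper,v_lower the participant's [verp()]s.
#' @param montage montage.
#' @param window_ms fixed feature window, default `c(120, 170)`.
#' @return a `p1_features` list with `id`, `group`, `latency_upper`,
#'   `latency_lower`, `has_p1`, `means`, `z`, `mpp1`.
#' @export
p1_features <- function(v_upper, v_lower, montage = v_upper$montage,
                        window_ms = c(120, 170)) {
  lat_u <- individual_p1_latency(v_upper, montage)
  lat_l <- individual_p1_latency(v_lower, montage)
  means <- fixed_window_features(v_upper, window_ms)
  z <- normalize_topography(means)
  meta <- v_upper$meta
  # numerical P1 presence from the already-located peaks (same rule as
  # has_p1(), which re-runs the peak search)
  wmean <- function(v, lat) {
    if (is.na(lat$latency)) return(NA_real_)
    windowed_mean(v, lat$latency)[[lat$electrode]]
  }
  vu <- wmean(v_upper, lat_u); vl <- wmean(v_lower, lat_l)
  present <- if (is.na(vu) && is.na(vl)) FALSE else
    !(isTRUE(vu < 0 | is.na(vu)) && isTRUE(vl < 0 | is.na(vl)))
  structure(list(
    id = if (!is.null(meta)) meta$id else NA_character_,
    group = if (!is.null(meta)) meta$group else NA_character_,
    latency_upper = lat_u$latency, latency_lower = lat_l$latency,
    has_p1 = present,
    means = means, z = z,
    mpp1 = compute_mpp1(z, montage)
  ), class = "p1_features")
}

#' Group-mean P1 latencies
#'
#' Mean of the available individual latencies per group and condition,
#' restricted to participants with a numerically present P1, plus the grand
#' mean across groups and conditions.
#'
#' @param features list of `p1_features`.
#' @return list with `cell_means` (data.frame group x condition) and
#'   `grand_mean`.
#' @export
group_mean_latency <- function(features) {
  rows <- do.call(rbind, lapply(features, function(f) {
    if (!f$has_p1) return(NULL)
    data.frame(group = f$group,
               condition = c("upper", "lower"),
               latency = c(f$latency_upper, f$latency_lower))
  }))
  if (is.null(rows)) stop("no participant contributes a latency")
  rows <- rows[!is.na(rows$latency), ]
  if (!nrow(rows)) stop("no participant contributes a latency")
  cm <- stats::aggregate(latency ~ group + condition, rows, mean)
  list(cell_means = cm, grand_mean = mean(cm$latency))
}

#' Tidy feature table for a cohort
#'
#' Runs preprocessing and feature extraction for every participant of a
#' simulated cohort and returns one row per participant: metadata, latency,
#' P1 presence, MPP1, and the 32 z-score columns (prefixed `z_`).
#'
#' @param cohort a `verp_cohort` from [simulate_cohort()].
#' @param ... passed to [preprocess_recording()].
#' @return data.frame with attribute `"features"` holding the
#'   `p1_features` list and `"verps"` holding per-participant VERPs.
#' @export
cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "verp_cohort"))
  feats <- vector("list", nrow(cohort$participants))
  verps <- vector("list", nrow(cohort$participants))
  kept <- matrix(NA_real_, nrow(cohort$participants), 2,
                 dimnames = list(NULL, c("upper", "lower")))
  for (i in seq_along(cohort$recordings)) {
    pp <- preprocess_recording(cohort$recordings[[i]], ...)
    feats[[i]] <- p1_features(pp$upper, pp$lower)
    verps[[i]] <- pp[c("upper", "lower")]
    kept[i, ] <- pp$n_kept
  }
  tab <- cohort$participants
  zmat <- t(vapply(feats, function(f) f$z, numeric(length(feats[[1]]$z))))
  colnames(zmat) <- paste0("z_", names(feats[[1]]$z))
  out <- cbind(tab[c("id", "group", "age", "age_at_surgery",
                     "time_since_surgery")],
               latency_upper = vapply(feats, `[[`, numeric(1), "latency_upper"),
               has_p1 = vapply(feats, `[[`, logical(1), "has_p1"),
               mpp1 = vapply(feats, `[[`, numeric(1), "mpp1"),
               kept_upper = kept[, "upper"], kept_lower = kept[, "lower"],
               as.data.frame(zmat))
  attr(out, "features") <- feats
  attr(out, "verps") <- verps
  out
}

#' Posterior z-score matrix from a feature table
#'
#' @param features data.frame from [cohort_features()].
#' @param montage montage (posterior subset).
#' @return numeric matrix, participants x 13 posterior electrodes.
#' @export
posterior_z_matrix <- function(features, montage = standard_montage()) {
  cols <- paste0("z_", montage$posterior)
  as.matrix(features[, cols])
}
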