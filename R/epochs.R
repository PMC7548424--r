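# Core containers: epoch sets (trial x electrode x time) and trial-averaged
# VERPs, plus participant metadata.

#' Participant metadata record
#'
#' @param id participant identifier.
#' @param group one of `"CC"`, `"DC"`, `"Control"`.
#' @param age age in years.
#' @param age_at_surgery months; required for CC/DC, must be `NA` for controls.
#' @param time_since_surgery months; same rule as `age_at_surgery`.
#' @param responds logical; `TRUE` when the participant operated the response
#'   device (passive observers generate no response epochs to reject).
#' @return A `participant_meta` list.
#' @export
participant_meta <- function(id, group, age,
                             age_at_surgery = NA_real_,
                             time_since_surgery = NA_real_,
                             responds = TRUE) {
  group <- match.arg(group, c("CC", "DC", "Control"))
  if (group == "Control") {
    if (!is.na(age_at_surgery) || !is.na(time_since_surgery))
      stop("controls carry no surgery fields")
  } else {
    if (is.na(age_at_surgery) || is.na(time_since_surgery))
      stop("CC/DC participants require age_at_surgery and time_since_surgery")
  }
  structure(list(id = as.character(id), group = group, age = age,
                 age_at_surgery = age_at_surgery,
                 time_since_surgery = time_since_surgery,
                 responds = isTRUE(responds)),
            class = "participant_meta")
}

#' Construct an epoch set
#'
#' Bundles a trial x electrode x time signal tensor with its time axis,
#' sampling rate, montage, per-trial event metadata and a keep-mask.
#' Rejection steps never delete trials; they clear entries of `keep` so the
#' provenance of every trial survives.
#'
#' @param signal numeric array, trial x electrode x time (microvolts).
#' @param times numeric vector of sample times in ms relative to stimulus
#'   onset; strictly increasing and spanning 0.
#' @param srate sampling rate in Hz.
#' @param montage a `verp_montage`; electrode dimension must match.
#' @param events data.frame with one row per trial and columns
#'   `field` ("upper"/"lower"), `side` ("left"/"right"), `target` (logical),
#'   `rt` (response latency in ms, `NA` when none).
#' @param keep logical keep-mask, one entry per trial (default all `TRUE`).
#' @param meta optional `participant_meta`.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(signal, times, srate, montage, events,
                      keep = NULL, meta = NULL) {
  stopifnot(is.array(signal), length(dim(signal)) == 3L)
  n_trial <- dim(signal)[1]; n_elec <- dim(signal)[2]; n_time <- dim(signal)[3]
  if (n_elec != length(montage$labels))
    stop("electrode dimension (", n_elec, ") does not match montage (",
         length(montage$labels), ")")
  if (length(times) != n_time) stop("time axis length mismatch")
  if (any(diff(times) <= 0)) stop("time axis must be strictly increasing")
  if (min(times) > 0 || max(times) < 0) stop("time axis must span stimulus onset")
  if (nrow(events) != n_trial) stop("events must have one row per trial")
  if (is.null(keep)) keep <- rep(TRUE, n_trial)
  if (length(keep) != n_trial) stop("keep-mask length must equal trial count")
  dimnames(signal) <- list(NULL, montage$labels, NULL)
  structure(list(signal = signal, times = as.numeric(times),
                 srate = srate, montage = montage,
                 events = as.data.frame(events), keep = as.logical(keep),
                 meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$signal)[1], "trials x", dim(x$signal)[2],
      "electrodes x", dim(x$signal)[3], "samples @", x$srate, "Hz\n")
  cat("  kept:", sum(x$keep), "/", length(x$keep), "trials\n")
  if (!is.null(x$meta))
    cat("  participant:", x$meta$id, "(", x$meta$group, ")\n")
  invisible(x)
}

#' Construct a VERP (trial-averaged waveform)
#'
#' @param data electrode x time numeric matrix (microvolts), rows named by
#'   electrode.
#' @param times time axis in ms.
#' @param condition `"upper"` or `"lower"` visual field.
#' @param n_trials number of trials that entered the average.
#' @param montage the source montage.
#' @param meta optional `participant_meta`.
#' @return A `verp` object.
#' @export
verp <- function(data, times, condition, n_trials, montage, meta = NULL) {
  condition <- match.arg(condition, c("upper", "lower"))
  stopifnot(is.matrix(data), ncol(data) == length(times), n_trials >= 1)
  if (nrow(data) != length(montage$labels)) stop("electrode count mismatch")
  rownames(data) <- montage$labels
  structure(list(data = data, times = as.numeric(times),
                 condition = condition, n_trials = n_trials,
                 montage = montage, meta = meta),
            class = "verp")
}

#' @export
print.verp <- function(x, ...) {
  cat("<verp>", x$condition, "field,", x$n_trials, "trials,",
      nrow(x$data), "electrodes x", ncol(x$data), "samples\n")
  invisible(x)
}

# index of samples inside [lo, hi] ms, bounds inclusive
time_index <- function(times, lo, hi) which(times >= lo & times <= hi)
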