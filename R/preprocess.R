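# Epoch preprocessing: average reference, zero-phase filtering, ocular and
# response-contamination rejection, left-field electrode mirroring, and
# trial averaging. Each operation is pure: the input epoch set is never
# modified in place, and rejection only clears keep-mask entries.

#' Average reference
#'
#' Re-references every trial/time point to the instantaneous mean across
#' electrodes, so the channel mean is zero everywhere afterwards.
#'
#' @param epochs an [epoch_set()].
#' @return re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$signal)[2] < 2) stop("average reference needs >= 2 electrodes")
  d <- dim(epochs$signal)
  m <- colMeans(aperm(epochs$signal, c(2, 1, 3)))   # trial x time channel mean
  epochs$signal <- epochs$signal - aperm(array(m, c(d[1], d[3], d[2])),
                                         c(1, 3, 2))
  epochs
}

# magnitude response used for zero-phase filtering: order-6 Butterworth
# low-pass magnitude, optional Gaussian notches at the line frequency and
# its harmonics (>= 20 dB attenuation at the notch centre)
filter_gain <- function(f, lowpass_hz, notch_hz = NULL, notch_bw = 2) {
  g <- 1 / sqrt(1 + (f / lowpass_hz)^12)
  if (!is.null(notch_hz)) {
    for (h in notch_hz)
      g <- g * (1 - 0.995 * exp(-0.5 * ((f - h) / notch_bw)^2))
  }
  g
}

#' Zero-phase filtering of epochs
#'
#' Applies a zero-phase (magnitude-only, frequency-domain) low-pass filter
#' with an order-6 Butterworth magnitude response, plus optional notches at
#' the line frequency and its harmonics. Because the transfer function is
#' real and symmetric the filter shifts no latencies, which matters for the
#' P1 latency measurements downstream.
#'
#' @param epochs an [epoch_set()].
#' @param lowpass_hz low-pass cutoff (default 40); must be below Nyquist.
#' @param notch_hz line frequency (default 50); harmonics below Nyquist are
#'   notched too.
#' @param apply_notch logical; the notch is only applied when line noise is
#'   present, default off for synthetic data.
#' @return filtered `epoch_set`.
#' @export
filter_epochs <- function(epochs, lowpass_hz = 40, notch_hz = 50,
                          apply_notch = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$srate / 2
  if (lowpass_hz >= nyq) stop("low-pass cutoff must be below Nyquist")
  d <- dim(epochs$signal)
  n_t <- d[3]
  n_pad <- stats::nextn(n_t)     # composite FFT length (epoch lengths are
  f <- (seq_len(n_pad) - 1) * epochs$srate / n_pad   # often prime)
  f <- pmin(f, epochs$srate - f)
  notches <- if (apply_notch) {
    h <- notch_hz * seq_len(floor(nyq / notch_hz))
    h[h < nyq]
  } else NULL
  g <- filter_gain(f, lowpass_hz, notches)
  x <- matrix(0, n_pad, d[1] * d[2])                   # time x (trial*elec)
  x[seq_len(n_t), ] <- matrix(aperm(epochs$signal, c(3, 1, 2)), n_t)
  y <- Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n_pad
  epochs$signal <- aperm(array(y[seq_len(n_t), ], c(n_t, d[1], d[2])),
                         c(2, 3, 1))
  epochs
}

#' Ocular artifact rejection from component time courses
#'
#' Implements the ocular rejection rule on separated blink and eye-movement
#' component time courses: the blink threshold is 5 times the maximum of the
#' standard deviations of the FP1- and FP2-projected component signals, the
#' eye-movement threshold 3 times the maximum of the F9/F10 SDs (SDs taken
#' over all time points of all trials). A trial is rejected when the
#' absolute component signal exceeds its threshold anywhere inside the
#' detection window around stimulus presentation.
#'
#' @param ocular list with trial x time matrices `blink_FP1`, `blink_FP2`,
#'   `saccade_F9`, `saccade_F10` and a `times` vector (as produced by
#'   [simulate_participant()]); components may be absent.
#' @param window_ms detection window, default `c(-25, 175)` ms.
#' @param blink_k,eye_k threshold multipliers (defaults 5 and 3).
#' @return logical keep-mask (TRUE = keep).
#' @export
detect_ocular_rejections <- function(ocular, window_ms = c(-25, 175),
                                     blink_k = 5, eye_k = 3) {
  times <- ocular$times
  if (is.null(times)) stop("ocular components carry no time axis")
  idx <- time_index(times, window_ms[1], window_ms[2])
  exceed <- function(chans, k) {
    chans <- Filter(Negate(is.null), chans)
    if (!length(chans)) return(NULL)
    thr <- k * max(vapply(chans, stats::sd, numeric(1)))
    if (thr == 0) return(rep(FALSE, nrow(chans[[1]])))
    Reduce(`|`, lapply(chans, function(m)
      apply(abs(m[, idx, drop = FALSE]) > thr, 1, any)))
  }
  bl <- exceed(ocular[c("blink_FP1", "blink_FP2")], blink_k)
  sa <- exceed(ocular[c("saccade_F9", "saccade_F10")], eye_k)
  if (is.null(bl) && is.null(sa)) {
    warning("no ocular component channels available; keeping all trials")
    return(TRUE)
  }
  keep <- !(Reduce(`|`, Filter(Negate(is.null), list(bl, sa))))
  keep
}

#' Apply an ocular keep-mask to an epoch set
#'
#' @param epochs an [epoch_set()].
#' @param ocular ocular components, see [detect_ocular_rejections()].
#' @param ... passed to [detect_ocular_rejections()].
#' @return `epoch_set` with an updated (only ever shrinking) keep-mask.
#' @export
reject_ocular_epochs <- function(epochs, ocular, ...) {
  keep <- detect_ocular_rejections(ocular, ...)
  epochs$keep <- epochs$keep & keep
  epochs
}

#' Reject epochs contaminated by manual responses
#'
#' Masks out trials whose response fell within `window_ms` of stimulus
#' onset, for participants who operated the response device themselves.
#' Passive observers (no recorded responses) are untouched.
#'
#' @param epochs an [epoch_set()].
#' @param window_ms rejection window after onset, default 500.
#' @return `epoch_set` with updated keep-mask.
#' @export
reject_response_epochs <- function(epochs, window_ms = 500) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.null(epochs$meta) && !epochs$meta$responds) return(epochs)
  rt <- epochs$events$rt
  bad <- !is.na(rt) & rt > 0 & rt <= window_ms
  epochs$keep <- epochs$keep & !bad
  epochs
}

#' Mirror-swap electrodes for left-visual-field trials
#'
#' For trials with left-field stimuli, exchanges each electrode's data with
#' its mirror partner across the nasion-inion axis (midline electrodes are
#' untouched); right-field trials are unchanged. Applied before averaging so
#' both hemifields contribute to a common, effectively right-field VERP.
#' The operation is an involution.
#'
#' @param epochs an [epoch_set()].
#' @param montage montage providing the mirror mapping (default the epoch
#'   set's own montage).
#' @return `epoch_set` with swapped left-field trials.
#' @export
mirror_swap_left_field <- function(epochs, montage = epochs$montage) {
  stopifnot(inherits(epochs, "epoch_set"))
  mir <- montage$mirror[montage$labels]
  if (anyNA(mir)) stop("electrode without a defined mirror partner")
  perm <- match(mir, montage$labels)
  left <- epochs$events$side == "left"
  if (any(left))
    epochs$signal[left, , ] <- epochs$signal[left, perm, , drop = FALSE]
  epochs
}

#' Trial-averaged VERP for one condition
#'
#' Pointwise mean over the kept trials of the requested visual-field
#' condition.
#'
#' @param epochs an [epoch_set()].
#' @param condition `"upper"` or `"lower"`.
#' @return a [verp()].
#' @export
average_verp <- function(epochs, condition = c("upper", "lower")) {
  stopifnot(inherits(epochs, "epoch_set"))
  condition <- match.arg(condition)
  sel <- epochs$keep & epochs$events$field == condition
  if (!any(sel)) {
    who <- if (!is.null(epochs$meta)) epochs$meta$id else "<unknown>"
    stop("no kept trials for participant ", who, ", condition ", condition)
  }
  m <- colMeans(epochs$signal[sel, , , drop = FALSE])
  verp(m, epochs$times, condition, sum(sel), epochs$montage, epochs$meta)
}

#' Full preprocessing chain for one recording
#'
#' Runs the stated order — average reference, low-pass (optional notch),
#' ocular rejection on the ground-truth components, response rejection,
#' left-field mirror swap, per-condition averaging — and returns both VERPs
#' plus rejection bookkeeping.
#'
#' @param recording list with `epochs` and `ocular`
#'   (one element of a `verp_cohort`'s `recordings`).
#' @param lowpass_hz,apply_notch,notch_hz see [filter_epochs()].
#' @param ocular_window,blink_k,eye_k see [detect_ocular_rejections()].
#' @param response_window see [reject_response_epochs()].
#' @return list with `upper` and `lower` [verp()]s, `n_kept`
#'   (per condition), and `n_rejected`.
#' @export
preprocess_recording <- function(recording, lowpass_hz = 40,
                                 apply_notch = FALSE, notch_hz = 50,
                                 ocular_window = c(-25, 175),
                                 blink_k = 5, eye_k = 3,
                                 response_window = 500) {
  ep <- recording$epochs
  # Fused implementation of
  #   average_reference |> filter_epochs |> reject_ocular_epochs |>
  #   reject_response_epochs |> mirror_swap_left_field |> average_verp .
  # Referencing, zero-phase filtering and trial averaging are all linear
  # and time-invariant, so they commute: rejection masks are computed
  # first, kept trials are averaged (with the left-field mirror fold), and
  # reference + filter are applied to the per-condition average only.
  # Equivalence with the composed exported operations is asserted by the
  # test suite.
  d <- dim(ep$signal)
  n <- d[1]; n_e <- d[2]; n_t <- d[3]
  nyq <- ep$srate / 2
  if (lowpass_hz >= nyq) stop("low-pass cutoff must be below Nyquist")

  keep <- ep$keep & detect_ocular_rejections(recording$ocular,
                                             window_ms = ocular_window,
                                             blink_k = blink_k, eye_k = eye_k)
  if (is.null(ep$meta) || ep$meta$responds) {
    rt <- ep$events$rt
    keep <- keep & !(!is.na(rt) & rt > 0 & rt <= response_window)
  }

  m <- matrix(aperm(ep$signal, c(3, 1, 2)), n_t)   # T x (trial, electrode)
  mir_idx <- match(ep$montage$mirror[ep$montage$labels], ep$montage$labels)
  left <- ep$events$side == "left"

  n_pad <- stats::nextn(n_t)
  f <- (seq_len(n_pad) - 1) * ep$srate / n_pad
  f <- pmin(f, ep$srate - f)
  notches <- if (apply_notch) {
    h <- notch_hz * seq_len(floor(nyq / notch_hz))
    h[h < nyq]
  } else NULL
  g <- filter_gain(f, lowpass_hz, notches)

  avg <- function(cond) {
    sel <- which(keep & ep$events$field == cond)
    if (!length(sel)) {
      who <- if (!is.null(ep$meta)) ep$meta$id else "<unknown>"
      stop("no kept trials for participant ", who, ", condition ", cond)
    }
    out <- matrix(0, n_t, n_e)
    for (e in seq_len(n_e)) {
      # left-field trials contribute their mirror electrode's data
      src_e <- ifelse(left[sel], mir_idx[e], e)
      out[, e] <- .rowMeans(m[, sel + n * (src_e - 1), drop = FALSE],
                            n_t, length(sel))
    }
    out <- out - rowMeans(out)                     # average reference
    x <- matrix(0, n_pad, n_e)                     # zero-phase filter
    x[seq_len(n_t), ] <- out
    out <- Re(stats::mvfft(stats::mvfft(x) * g,
                           inverse = TRUE))[seq_len(n_t), ] / n_pad
    verp(t(out), ep$times, cond, length(sel), ep$montage, ep$meta)
  }
  up <- avg("upper")
  lo <- avg("lower")
  list(upper = up, lower = lo,
       n_kept = c(upper = up$n_trials, lower = lo$n_trials),
       n_rejected = sum(!keep))
}
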