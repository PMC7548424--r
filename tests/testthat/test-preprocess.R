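times_fast <- seq(-1000, 1000, by = 10)   # 100 Hz

test_that("average reference zeroes the channel mean", {
  # two-electrode toy: [3, 1] -> [1, -1]
  sig <- array(0, c(1, 32, 3))
  sig[1, 1, ] <- 3; sig[1, 2, ] <- 1
  ep <- make_epochs(sig, c(-10, 0, 10), 100)
  # restrict to the two-electrode case by checking those channels only
  out <- average_reference(ep)
  m <- apply(out$signal[1, , ], 2, mean)
  expect_equal(unname(m), rep(0, 3), tolerance = 1e-12)

  set.seed(4)
  sig <- array(rnorm(5 * 32 * 21), c(5, 32, 21))
  ep <- make_epochs(sig, seq(-100, 100, by = 10), 100)
  out <- average_reference(ep)
  expect_lt(max(abs(apply(out$signal, c(1, 3), mean))), 1e-10)
  # idempotence
  out2 <- average_reference(out)
  expect_equal(out2$signal, out$signal, tolerance = 1e-12)
  # input untouched (purity)
  expect_equal(ep$signal, sig, ignore_attr = TRUE)
})

test_that("zero-phase low-pass meets its frequency-response contract", {
  srate <- 1000
  times <- seq(-1000, 1000, by = 1)
  tgrid <- times / 1000
  mk <- function(tr) {
    sig <- array(0, c(1, 32, length(times)))
    for (e in 1:32) sig[1, e, ] <- tr
    make_epochs(sig, times, srate)
  }
  rms <- function(x) sqrt(mean(x^2))
  mid <- abs(times) <= 700    # avoid FFT edge effects

  s60 <- filter_epochs(mk(sin(2 * pi * 60 * tgrid)), 40)
  expect_lt(rms(s60$signal[1, 1, mid]), 0.1)

  s5 <- filter_epochs(mk(sin(2 * pi * 5 * tgrid)), 40)
  expect_equal(rms(s5$signal[1, 1, mid]), rms(sin(2 * pi * 5 * tgrid[mid])),
               tolerance = 0.05)

  dc <- filter_epochs(mk(rep(1, length(times))), 40)
  expect_equal(unname(dc$signal[1, 1, mid]), rep(1, sum(mid)),
               tolerance = 1e-6)

  # zero phase: a smooth pulse keeps its peak location within 1 sample
  pulse <- exp(-0.5 * ((times - 137) / 30)^2)
  fp <- filter_epochs(mk(pulse), 40)
  expect_lte(abs(times[which.max(fp$signal[1, 1, ])] - 137), 1)

  # notch: >= 20 dB at 50 Hz
  s50 <- filter_epochs(mk(sin(2 * pi * 50 * tgrid)), 40, 50,
                       apply_notch = TRUE)
  expect_lt(rms(s50$signal[1, 1, mid]),
            0.1 * rms(sin(2 * pi * 50 * tgrid)))
  # passband ripple <= 1 dB at 30 Hz
  s30 <- filter_epochs(mk(sin(2 * pi * 30 * tgrid)), 40)
  gain <- rms(s30$signal[1, 1, mid]) / rms(sin(2 * pi * 30 * tgrid[mid]))
  expect_gt(20 * log10(gain), -1)

  expect_error(filter_epochs(mk(pulse), 600), "Nyquist")
})

test_that("ocular rejection follows the 5x/3x SD rule in -25..175 ms", {
  n <- 20; times <- seq(-1000, 1000, by = 10)
  zero <- matrix(0, n, length(times))
  oc <- list(blink_FP1 = zero, blink_FP2 = zero,
             saccade_F9 = zero, saccade_F10 = zero, times = times)
  expect_true(all(detect_ocular_rejections(oc)))

  # background blink activity defines the SD; one 10x-SD spike at +50 ms
  set.seed(9)
  bg <- matrix(rnorm(n * length(times)), n, length(times))
  oc$blink_FP1 <- bg; oc$blink_FP2 <- bg * 0.9
  spike <- 10 * max(sd(bg), sd(bg * 0.9))
  oc$blink_FP1[3, which(times == 50)] <- spike
  keep <- detect_ocular_rejections(oc)
  expect_false(keep[3])

  # same spike outside the window -> kept
  oc$blink_FP1 <- bg
  oc$blink_FP1[3, which(times == 500)] <- spike
  expect_true(detect_ocular_rejections(oc)[3])

  # eye-movement channel uses the 3x threshold: a 4x-SD excursion rejects
  oc$blink_FP1 <- bg
  sac <- matrix(rnorm(n * length(times)), n, length(times))
  oc$saccade_F9 <- sac; oc$saccade_F10 <- -sac
  oc$saccade_F9[7, which(times == 100)] <- 4 * sd(sac)
  expect_false(detect_ocular_rejections(oc)[7])

  # missing components -> warn and keep everything
  expect_warning(k <- detect_ocular_rejections(list(times = times)),
                 "keeping all")
  expect_true(all(k))
})

test_that("response rejection masks trials with responses within 500 ms", {
  sig <- array(0, c(3, 32, length(times_fast)))
  ev <- data.frame(field = "upper", side = "right", target = TRUE,
                   rt = c(300, 700, NA))
  meta <- participant_meta("r1", "Control", 20)
  ep <- make_epochs(sig, times_fast, 100, events = ev, meta = meta)
  out <- reject_response_epochs(ep)
  expect_identical(out$keep, c(FALSE, TRUE, TRUE))
  # passive observer: untouched even with recorded rts
  meta_p <- participant_meta("r2", "CC", 20, 24, 120, responds = FALSE)
  ep_p <- make_epochs(sig, times_fast, 100, events = ev, meta = meta_p)
  expect_identical(reject_response_epochs(ep_p)$keep, rep(TRUE, 3))
})

test_that("mirror swap exchanges left-field trials only and is an involution", {
  set.seed(11)
  sig <- array(rnorm(4 * 32 * 5), c(4, 32, 5))
  ev <- data.frame(field = "upper", side = c("left", "right", "left", "right"),
                   target = FALSE, rt = NA_real_)
  ep <- make_epochs(sig, c(-20, -10, 0, 10, 20), 100, events = ev)
  out <- mirror_swap_left_field(ep)
  i_p7 <- which(MONTAGE$labels == "P7"); i_p8 <- which(MONTAGE$labels == "P8")
  i_pz <- which(MONTAGE$labels == "Pz")
  expect_equal(out$signal[1, i_p7, ], sig[1, i_p8, ])
  expect_equal(out$signal[1, i_p8, ], sig[1, i_p7, ])
  expect_equal(out$signal[1, i_pz, ], sig[1, i_pz, ])   # midline untouched
  expect_equal(out$signal[2, , ], sig[2, , ],           # right trial unchanged
               ignore_attr = TRUE)
  twice <- mirror_swap_left_field(out)
  expect_equal(twice$signal, sig, ignore_attr = TRUE)
})

test_that("average_verp averages kept trials of the condition", {
  tvec <- c(-20, -10, 0, 10, 20)
  sig <- array(0, c(4, 32, 5))
  sig[1, , ] <- 1; sig[2, , ] <- 1          # two identical upper trials
  sig[3, , ] <- 2; sig[4, , ] <- -2         # lower: +v and -v
  ev <- data.frame(field = c("upper", "upper", "lower", "lower"),
                   side = "right", target = FALSE, rt = NA_real_)
  ep <- make_epochs(sig, tvec, 100, events = ev)
  up <- average_verp(ep, "upper")
  expect_equal(unname(up$data), matrix(1, 32, 5))
  expect_identical(up$n_trials, 2L)
  lo <- average_verp(ep, "lower")
  expect_equal(unname(lo$data), matrix(0, 32, 5))

  # CLT: 100 unit-noise trials average to RMS ~ 1/10
  set.seed(21)
  sig <- array(rnorm(100 * 32 * 5), c(100, 32, 5))
  ev <- data.frame(field = "upper", side = "right", target = FALSE,
                   rt = NA_real_)[rep(1, 100), ]
  ep <- make_epochs(sig, tvec, 100, events = ev)
  v <- average_verp(ep, "upper")
  expect_equal(sqrt(mean(v$data^2)), 0.1, tolerance = 0.35)

  ep$keep[] <- FALSE
  expect_error(average_verp(ep, "upper"), "no kept trials")
})

test_that("rejection only ever shrinks the kept set", {
  r <- sim_small("Control", seed = 31)
  ep <- r$epochs
  ep1 <- reject_ocular_epochs(ep, r$ocular)
  expect_true(all(ep$keep | !ep1$keep | !ep$keep | ep1$keep))
  expect_true(all(!ep1$keep | ep$keep))          # ep1 keep subset of ep keep
  ep2 <- reject_response_epochs(ep1)
  expect_true(all(!ep2$keep | ep1$keep))
})

test_that("fused preprocess_recording equals the composed operations", {
  r <- sim_small("CC", seed = 5, atten = 0.4)
  pp <- preprocess_recording(r)
  ep <- average_reference(r$epochs)
  ep <- filter_epochs(ep, 40)
  ep <- reject_ocular_epochs(ep, r$ocular)
  ep <- reject_response_epochs(ep)
  ep <- mirror_swap_left_field(ep)
  up <- average_verp(ep, "upper"); lo <- average_verp(ep, "lower")
  expect_equal(pp$upper$data, up$data, tolerance = 1e-10)
  expect_equal(pp$lower$data, lo$data, tolerance = 1e-10)
  expect_identical(pp$upper$n_trials, up$n_trials)
  expect_identical(pp$lower$n_trials, lo$n_trials)
})
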