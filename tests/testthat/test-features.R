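test_that("find_largest_peak locates the highest strict local maximum", {
  times <- seq(-200, 400, by = 5)
  v <- make_verp(times)
  v$data["P8", ] <- gauss_bump(times, 145, 20, 5)
  p <- find_largest_peak(v, "P8")
  expect_true(p$found)
  expect_equal(p$latency, 145)
  expect_equal(p$amplitude, 5, tolerance = 1e-6)

  # monotone ramp: no interior local maximum
  v$data["O1", ] <- seq_along(times)
  expect_false(find_largest_peak(v, "O1")$found)

  # two equal maxima -> earliest latency (cross-checked by exhaustive scan)
  v$data["O2", ] <- gauss_bump(times, 120, 8, 3) + gauss_bump(times, 160, 8, 3)
  p2 <- find_largest_peak(v, "O2")
  win <- which(times >= 100 & times <= 200)
  tr <- v$data["O2", ]
  peaks <- win[tr[win] > tr[win - 1] & tr[win] > tr[win + 1]]
  best <- peaks[order(-tr[peaks], times[peaks])][1]
  expect_equal(p2$latency, times[best])
  expect_equal(p2$latency, 120)

  expect_error(find_largest_peak(v, "P8", window_ms = c(100, 1000)),
               "outside")
})

test_that("individual_p1_latency takes the globally maximal posterior peak", {
  times <- seq(-200, 400, by = 5)
  v <- make_verp(times)
  v$data["P8", ] <- gauss_bump(times, 150, 15, 5)
  v$data["O1", ] <- gauss_bump(times, 140, 15, 3)
  r <- individual_p1_latency(v)
  expect_equal(r$latency, 150)
  expect_identical(r$electrode, "P8")

  flat <- make_verp(times)
  expect_true(is.na(individual_p1_latency(flat)$latency))

  # flat everywhere plus one electrode bump: exhaustive comparison
  v2 <- make_verp(times)
  v2$data["CP5", ] <- gauss_bump(times, 130, 10, 2)
  amps <- vapply(MONTAGE$posterior, function(e)
    find_largest_peak(v2, e)$amplitude, numeric(1))
  expect_identical(individual_p1_latency(v2)$electrode,
                   MONTAGE$posterior[which.max(amps)])
  expect_equal(individual_p1_latency(v2)$latency, 130)
})

test_that("windowed_mean is an inclusive-bounds arithmetic mean", {
  times <- seq(-200, 400, by = 5)
  v <- make_verp(times, fill = 2)
  expect_equal(unname(windowed_mean(v, 145)[1]), 2)

  # linear ramp symmetric about the centre -> value at centre
  v$data["Pz", ] <- 0.01 * (times - 145)
  expect_equal(unname(windowed_mean(v, 145)[["Pz"]]), 0, tolerance = 1e-12)

  # full-period sampled sine averages to ~0
  v$data["O1", ] <- sin(2 * pi * (times - 120) / 50)   # 50 ms period
  expect_equal(unname(windowed_mean(v, 145)[["O1"]]), 0, tolerance = 0.05)

  expect_error(windowed_mean(v, -190), "edge")
})

test_that("has_p1 applies the both-conditions-negative exclusion rule", {
  times <- seq(-200, 400, by = 5)
  neg <- make_verp(times)
  neg$data["P8", ] <- -gauss_bump(times, 145, 20, 0.5) +
    gauss_bump(times, 145, 8, 0.2)  # small positive peak on a negative wave
  neg_l <- neg; neg_l$condition <- "lower"
  expect_false(has_p1(neg, neg_l))

  pos <- make_verp(times)
  pos$data["P8", ] <- gauss_bump(times, 145, 20, 1)
  expect_true(has_p1(pos, neg_l))     # only one condition negative
  pos_l <- pos; pos_l$condition <- "lower"
  expect_true(has_p1(pos, pos_l))
  # no peaks at all in either condition -> absent
  expect_false(has_p1(make_verp(times), make_verp(times)))
})

test_that("normalize_topography produces affine-invariant standard scores", {
  m <- c(a = 1, b = 2, c = 3)
  expect_equal(unname(normalize_topography(m)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(32); names(x) <- MONTAGE$labels
  z <- normalize_topography(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  z2 <- normalize_topography(4.2 * x + 17)
  expect_lt(max(abs(z - z2)), 1e-10)
  expect_error(normalize_topography(rep(1, 32)), "variance")
})

test_that("compute_mpp1 equals the brute-force posterior mean", {
  z <- rep(0, 32); names(z) <- MONTAGE$labels
  expect_equal(compute_mpp1(z, MONTAGE), 0)
  z[MONTAGE$posterior] <- 0.5
  expect_equal(compute_mpp1(z, MONTAGE), 0.5)
  set.seed(10)
  z <- rnorm(32); names(z) <- MONTAGE$labels
  acc <- 0
  for (e in MONTAGE$posterior) acc <- acc + z[[e]] / 13
  expect_equal(compute_mpp1(z, MONTAGE), acc, tolerance = 1e-12)
})

test_that("group_mean_latency averages available latencies", {
  f1 <- list(group = "CC", latency_upper = 140, latency_lower = 150,
             has_p1 = TRUE)
  f2 <- list(group = "CC", latency_upper = 150, latency_lower = 150,
             has_p1 = TRUE)
  f3 <- list(group = "CC", latency_upper = 100, latency_lower = 100,
             has_p1 = FALSE)   # excluded
  r <- group_mean_latency(list(f1, f2, f3))
  up <- r$cell_means$latency[r$cell_means$condition == "upper"]
  expect_equal(up, 145)
  expect_equal(group_mean_latency(list(f1))$cell_means$latency, c(150, 140))
  expect_error(group_mean_latency(list(f3)), "no participant")
})

test_that("latency estimator recovers the injected P1 latency", {
  comps <- lapply(default_components(), function(cp) {
    cp$jitter_sd <- 0; cp$latency_subject_sd <- 0; cp$topo_jitter <- 0
    cp
  })
  r <- sim_small("Control", seed = 19, artifacts = quiet_artifacts,
                 components = comps, srate = 200)
  pp <- preprocess_recording(r)
  lat <- individual_p1_latency(pp$upper)$latency
  expect_lte(abs(lat - 145), 5)     # one sample at 200 Hz
})

test_that("feature table carries MPP1, z-columns and trial bookkeeping", {
  d <- cohort_design(counts = c(CC = 2, DC = 2, Control = 2),
                     trials_per_quadrant = 11, srate = 100, seed = 77)
  f <- cohort_features(simulate_cohort(d))
  expect_identical(nrow(f), 6L)
  expect_true(all(paste0("z_", MONTAGE$labels) %in% names(f)))
  z <- posterior_z_matrix(f)
  expect_identical(dim(z), c(6L, 13L))
  expect_equal(unname(rowMeans(z)), f$mpp1, tolerance = 1e-12)
  expect_true(all(f$kept_upper >= 1))
})
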