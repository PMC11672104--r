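# dense triangular beat: onset t = 0, peak depth 10% of L0 at 0.1 s,
# linear recovery to baseline at 0.5 s
triangle_trace <- function(l0 = 100, dt = 0.001) {
  t <- seq(-0.2, 0.8, by = dt)
  depth <- 0.1 * l0
  y <- rep(l0, length(t))
  rise <- t >= 0 & t <= 0.1
  y[rise] <- l0 - depth * t[rise] / 0.1
  dec <- t > 0.1 & t <= 0.5
  y[dec] <- l0 - depth * (1 - (t[dec] - 0.1) / 0.4)
  tibble::tibble(time_s = t, length_um = y)
}

test_that("beat features match closed-form crossings of a triangle beat", {
  tr <- triangle_trace()
  f <- beat_features(tr, onset_time = 0, start_time = -0.2,
                     end_time = 0.8, smooth = 1L)
  expect_equal(f$L0, 100)
  # parabolic peak refinement rounds the triangle corner very slightly
  expect_equal(f$amplitude_pct, 10, tolerance = 1e-3)
  # 90% of peak shortening on the rise: t = 0.09
  expect_equal(f$ttp90, 0.09, tolerance = 1e-3)
  # 90% recovery of the amplitude: at 0.1 + 0.9 * 0.4 = 0.46 s absolute,
  # i.e. 0.36 s after the peak
  expect_equal(f$ttb90, 0.36, tolerance = 2e-3)
})

test_that("amplitude is percent shortening of resting length", {
  tr <- triangle_trace(l0 = 100)
  tr$length_um <- pmax(tr$length_um, 92)  # clip depth to 8 um
  f <- beat_features(tr, 0, -0.2, 0.8, smooth = 1L)
  expect_equal(f$amplitude_pct, 8, tolerance = 2e-3)
})

test_that("time-rescaling a beat doubles its crossing times", {
  tr <- triangle_trace()
  tr2 <- dplyr::mutate(tr, time_s = 2 * time_s)
  f1 <- beat_features(tr, 0, -0.2, 0.8, smooth = 1L)
  f2 <- beat_features(tr2, 0, -0.4, 1.6, smooth = 1L)
  expect_equal(f2$ttp90, 2 * f1$ttp90, tolerance = 1e-3)
  expect_equal(f2$ttb90, 2 * f1$ttb90, tolerance = 2e-3)
})

test_that("features are invariant to length offsets and time shifts", {
  tr <- simulate_transients(n_cells = 1, noise_sd = 0.05, cell_cv = 0,
                            seed = 19)
  f0 <- transient_features(tr)
  shifted <- dplyr::mutate(tr, time_s = time_s + 5,
                           length_um = length_um + 40)
  f1 <- transient_features(shifted)
  # absolute shortening (um) is offset-invariant; %L0 rescales with L0
  expect_equal(f1$amplitude_pct * f1$L0, f0$amplitude_pct * f0$L0,
               tolerance = 0.02)
  expect_equal(f1$ttp90, f0$ttp90, tolerance = 1e-6)
  expect_equal(f1$ttb90, f0$ttb90, tolerance = 1e-6)
  expect_equal(f1$L0 - 40, f0$L0, tolerance = 1e-6)
})

test_that("beat segmentation finds one window per stimulus", {
  tr <- simulate_transients(n_cells = 1, cell_cv = 0, seed = 23)
  beats <- segment_beats(tr)
  expect_equal(nrow(beats), 10L)
  expect_equal(diff(beats$onset_time), rep(1, 9), tolerance = 0.02)

  # a missed beat: replace one cycle with baseline
  miss <- tr
  drop <- miss$time_s >= 4 & miss$time_s < 5
  miss$length_um[drop] <- median(tr$length_um[tr$time_s < 0.05])
  expect_warning(b2 <- segment_beats(miss), "missed")
  expect_equal(nrow(b2), 9L)

  flat <- tibble::tibble(time_s = seq(0, 10, by = 0.004),
                         length_um = 120)
  expect_error(segment_beats(flat), "flat")
})

test_that("planted transient parameters are recovered from noisy traces", {
  tr <- simulate_transients(l0 = 120, amplitude_pct = 8, ttp90 = 0.15,
                            ttb90 = 0.50, n_cells = 10, noise_sd = 0.1,
                            seed = 29)
  truth <- attr(tr, "truth")
  feats <- tr |>
    dplyr::group_by(cell_id) |>
    dplyr::group_modify(~ transient_features(.x)) |>
    dplyr::ungroup()
  j <- dplyr::left_join(feats, truth, by = "cell_id",
                        suffix = c("", "_true"))
  expect_lt(median(abs(j$ttp90 - j$ttp90_true) / j$ttp90_true), 0.05)
  expect_lt(median(abs(j$ttb90 - j$ttb90_true) / j$ttb90_true), 0.05)
  expect_lt(median(abs(j$amplitude_pct - j$amplitude_pct_true) /
                     j$amplitude_pct_true), 0.05)

  # zero noise: features exact to about one sample interval
  tr0 <- simulate_transients(n_cells = 1, noise_sd = 0, drift_um = 0,
                             cell_cv = 0, seed = 31)
  f0 <- transient_features(tr0)
  expect_equal(f0$ttp90, 0.15, tolerance = 0.004 / 0.15)
  expect_equal(f0$ttb90, 0.50, tolerance = 0.004 / 0.50)
})

test_that("lusitropy is the fractional ttb90 change under dobutamine", {
  expect_equal(lusitropy(0.50, 0.395), 0.21)
  expect_equal(lusitropy(0.4, 0.4), 0)
  # a 9% slowing gives negative lusitropy (the uncoupled response)
  expect_equal(lusitropy(0.5, 0.5 * 1.09), -0.09)
  expect_error(lusitropy(0, 0.4), "positive")
  # monotone decreasing in the dobutamine ttb90
  expect_true(all(diff(lusitropy(0.5, seq(0.3, 0.6, 0.05))) < 0))
})

test_that("paired dobutamine analysis flags planted group effects", {
  set.seed(37)
  n <- 40
  pre <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:n), treatment = "baseline",
    amplitude_pct = rnorm(n, 8, 0.5), ttp90 = rnorm(n, 0.15, 0.01),
    ttb90 = rnorm(n, 0.50, 0.02)
  )
  post <- pre |>
    dplyr::mutate(treatment = "dobutamine",
                  ttb90 = ttb90 * rnorm(n, 0.80, 0.02))
  res <- paired_response(dplyr::bind_rows(pre, post))
  ttb <- res[res$measure == "ttb90", ]
  expect_lt(ttb$p_value, 0.01)
  expect_equal(ttb$stars, "**")
  lus <- res[res$measure == "lusitropy", ]
  expect_equal(lus$mean, 0.20, tolerance = 0.02)

  # null pairing through the same analysis path: the ttb90 p-value is
  # approximately uniform, so the false-positive rate sits near 5%
  set.seed(41)
  pvals <- replicate(200, {
    b <- dplyr::mutate(pre, ttb90 = rnorm(dplyr::n(), 0.50, 0.02))
    d <- dplyr::mutate(b, treatment = "dobutamine",
                       ttb90 = rnorm(dplyr::n(), 0.50, 0.02))
    r <- paired_response(dplyr::bind_rows(b, d))
    r$p_value[r$measure == "ttb90"]
  })
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.15)
  # and roughly uniform overall
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value),
            0.001)

  expect_error(paired_response(dplyr::bind_rows(pre[1:2, ],
                                                post[1:2, ])),
               "at least 3")
  expect_error(paired_response(dplyr::bind_rows(pre, post[-1, ])),
               "without both")
})
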