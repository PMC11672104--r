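test_that("trajectory specs validate their parameters", {
  expect_error(trajectory_spec(ab_angle = list(weights = c(0.5, 0.4),
                                               means = c(100, 110),
                                               sds = c(5, 5))),
               "sum to 1")
  expect_error(trajectory_spec(hinge = list(weights = 1, means = 120,
                                            sds = -1)), "> 0")
  expect_error(trajectory_spec(saltbridge_occupancy = 1.2), "\\[0, 1\\]")
  expect_error(trajectory_spec(ligand = list(label = "EGC",
                                             bound_fraction = 2)),
               "\\[0, 1\\]")
})

test_that("the same seed reproduces every generator bitwise", {
  spec <- trajectory_spec(n_frames = 60, n_runs = 2, variant = "G159D",
                          saltbridge_occupancy = 0.5,
                          ligand = list(label = "SLB",
                                        bound_fraction = 0.9,
                                        targets = 20L))
  s1 <- simulate_trajectory(spec, seed = 5, verify = FALSE)
  s2 <- simulate_trajectory(spec, seed = 5, verify = FALSE)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$runs[[2]]$xyz, s2$runs[[2]]$xyz)
  s3 <- simulate_trajectory(spec, seed = 6, verify = FALSE)
  expect_false(identical(s1$truth$ab_angle, s3$truth$ab_angle))

  t1 <- simulate_transients(n_cells = 2, seed = 8)
  t2 <- simulate_transients(n_cells = 2, seed = 8)
  expect_identical(t1, t2)
})

test_that("construction realises the planted geometry exactly", {
  spec <- trajectory_spec(n_frames = 50, n_runs = 1,
                          ab_angle = list(weights = c(0.6, 0.4),
                                          means = c(95, 115),
                                          sds = c(4, 6)))
  # verify = TRUE re-measures sampled frames and errors above 1e-6 deg
  sim <- simulate_trajectory(spec, seed = 9, verify = TRUE)
  rg <- default_regions()
  ab <- ab_angle_series(sim$runs[[1]], rg$helix_a, rg$helix_b)
  dd <- interdomain_distance_series(sim$runs[[1]], rg$domain_n,
                                    rg$domain_itc)
  expect_equal(ab$value, sim$truth$ab_angle, tolerance = 1e-9)
  expect_equal(dd$value, sim$truth$distance, tolerance = 1e-9)
})

test_that("generated trajectory files reload losslessly", {
  dir <- withr::local_tempdir()
  spec <- trajectory_spec(n_frames = 8, n_runs = 1, variant = "G159D",
                          saltbridge_occupancy = 0.4,
                          ligand = list(label = "EGC",
                                        bound_fraction = 0.8,
                                        targets = 20L))
  sim <- simulate_trajectory(spec, seed = 14, dir = dir, verify = FALSE)
  expect_true(file.exists(sim$paths$manifest))
  top <- read_topology(sim$paths$topology)
  expect_equal(nrow(top), nrow(sim$topology))
  back <- read_trajectory(sim$paths$runs[1], top)
  expect_lt(max(abs(back$xyz - sim$runs[[1]]$xyz)), 1e-3 + 1e-9)
  # metrics computed from the file round-trip match the manifest
  rg <- default_regions()
  ab <- ab_angle_series(back, rg$helix_a, rg$helix_b)
  expect_equal(ab$value, sim$truth$ab_angle, tolerance = 1e-3)
})

test_that("the two-state ligand chain attains its stationary fraction", {
  f <- 0.95
  p_off <- 1 / 25
  p_on <- p_off * f / (1 - f)
  set.seed(51)
  z1 <- tncoupling:::markov_chain(3750, p_on, p_off, f)
  expect_equal(mean(z1), f, tolerance = 0.015)
  z2 <- tncoupling:::markov_chain(37500, p_on, p_off, f)
  expect_equal(mean(z2), f, tolerance = 0.008)
  # longer chains concentrate harder around the stationary fraction
  set.seed(52)
  long_err <- mean(abs(replicate(4, {
    mean(tncoupling:::markov_chain(37500, p_on, p_off, f)) - f
  })))
  expect_lt(long_err, 0.01)
})

test_that("infeasible transient kinetics are rejected", {
  expect_error(simulate_transients(ttp90 = 0.4, ttb90 = 0.6),
               "Infeasible")
})

test_that("dobutamine pairs plant the requested lusitropy", {
  pair <- simulate_dobutamine_pair(n_cells = 6, ttb90_factor = 0.79,
                                   effect_cv = 0, seed = 55)
  truth <- attr(pair, "truth")
  wide <- tidyr::pivot_wider(truth[, c("cell_id", "treatment", "ttb90")],
                             names_from = "treatment",
                             values_from = "ttb90")
  expect_equal(lusitropy(wide$baseline, wide$dobutamine),
               rep(0.21, 6), tolerance = 1e-9)
})
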