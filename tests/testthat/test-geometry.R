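test_that("helix axis is the oriented principal component", {
  line <- cbind(0, 0, seq(0, 13.5, by = 1.5))
  expect_equal(helix_axis(line), c(0, 0, 1), tolerance = 1e-9)
  # known rotation maps the axis accordingly
  set.seed(21)
  r <- random_rotation()
  expect_equal(helix_axis(line %*% t(r)), as.numeric(r %*% c(0, 0, 1)),
               tolerance = 1e-6)
  # N-to-C orientation: reversing residue order flips the sign
  expect_equal(helix_axis(line[rev(seq_len(nrow(line))), ]), c(0, 0, -1),
               tolerance = 1e-9)
  expect_error(helix_axis(line[1:3, ]), "at least 4")
  expect_error(helix_axis(matrix(1, 5, 3)), "Degenerate")
})

test_that("interhelix angle matches construction and is symmetric", {
  a <- cbind(0, 0, seq(0, 9))
  expect_equal(interhelix_angle(a, sweep(a, 2, c(5, 0, 0), "+")), 0,
               tolerance = 1e-9)
  b90 <- cbind(seq(0, 9), 0, 0) + 5
  expect_equal(interhelix_angle(a, b90), 90, tolerance = 1e-9)
  # planted wild-type apo mean angle
  th <- 101.81 * pi / 180
  bpl <- cbind(0, -sin(th) * seq(0, 9), cos(th) * seq(0, 9)) + 10
  expect_equal(interhelix_angle(a, bpl), 101.81, tolerance = 0.1)
  expect_equal(interhelix_angle(bpl, a), interhelix_angle(a, bpl))
})

test_that("hinge angle handles collinear, right-angle and planted cases", {
  p <- c(0, 0, 0)
  expect_equal(hinge_angle(p, c(-5, 0, 0), c(7, 0, 0)), 180)
  expect_equal(hinge_angle(p, c(0, 4, 0), c(6, 0, 0)), 90)
  phi <- 121.61 * pi / 180
  expect_equal(hinge_angle(p, 12 * c(cos(phi), sin(phi), 0), c(9, 0, 0)),
               121.61, tolerance = 1e-9)
  expect_error(hinge_angle(c(1, 2, 3), c(1, 2, 3), c(4, 5, 6)),
               "coincides")
})

test_that("interdomain distance is the centroid distance, rigid-invariant", {
  top <- tiny_topology(n_res = 2, n_lig = 0)
  fr <- rbind(c(0, 0, 0), c(30.18, 0, 0))
  traj <- traj_from_frames(list(fr), top)
  d1 <- region("d1", "A", 1, 1, calpha = TRUE)
  d2 <- region("d2", "A", 2, 2, calpha = TRUE)
  expect_equal(interdomain_distance_series(traj, d1, d2)$value, 30.18)
  shifted <- traj_from_frames(list(fr + rep(c(3, 0, 0), each = 2)), top)
  expect_equal(interdomain_distance_series(shifted, d1, d2)$value, 30.18)
  set.seed(5)
  rot <- transform_traj(traj, random_rotation(), rnorm(3, 0, 10))
  expect_equal(interdomain_distance_series(rot, d1, d2)$value, 30.18,
               tolerance = 1e-9)
})

test_that("all trajectory metrics are invariant under rigid transforms", {
  spec <- trajectory_spec(n_frames = 40, n_runs = 1, variant = "G159D",
                          saltbridge_occupancy = 0.5,
                          ligand = list(label = "EGC",
                                        bound_fraction = 0.7,
                                        targets = 20L))
  sim <- simulate_trajectory(spec, seed = 8, verify = FALSE)
  traj <- sim$runs[[1]]
  set.seed(31)
  moved <- transform_traj(traj, random_rotation(), rnorm(3, 0, 20))
  rg <- default_regions()
  expect_equal(
    ab_angle_series(moved, rg$helix_a, rg$helix_b)$value,
    ab_angle_series(traj, rg$helix_a, rg$helix_b)$value,
    tolerance = 1e-6
  )
  expect_equal(
    hinge_angle_series(moved, rg$domain_n, rg$domain_itc, rg$pivot)$value,
    hinge_angle_series(traj, rg$domain_n, rg$domain_itc, rg$pivot)$value,
    tolerance = 1e-6
  )
  expect_equal(
    interdomain_distance_series(moved, rg$domain_n, rg$domain_itc)$value,
    interdomain_distance_series(traj, rg$domain_n, rg$domain_itc)$value,
    tolerance = 1e-6
  )
  expect_equal(
    pair_bond_occupancy(moved, rg$d159, rg$r83)$probability,
    pair_bond_occupancy(traj, rg$d159, rg$r83)$probability
  )
})

test_that("planted angle distributions are recovered within sampling error", {
  spec <- trajectory_spec(n_frames = 1500, n_runs = 1)
  sim <- simulate_trajectory(spec, seed = 13, verify = FALSE)
  rg <- default_regions()
  ab <- ab_angle_series(sim$runs[[1]], rg$helix_a, rg$helix_b)
  # exact per-frame realisation against the manifest
  expect_equal(ab$value, sim$truth$ab_angle, tolerance = 1e-9)
  # and the sample mean sits within 3 sd/sqrt(n) of the planted mean
  expect_lt(abs(mean(ab$value) - 101.81), 3 * 9.15 / sqrt(1500))
  hg <- hinge_angle_series(sim$runs[[1]], rg$domain_n, rg$domain_itc,
                           rg$pivot)
  expect_equal(hg$value, sim$truth$hinge_angle, tolerance = 1e-9)
})

test_that("salt-bridge occupancy counts frames below cutoff, strictly", {
  top <- tiny_topology(n_res = 2, n_lig = 0)
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  traj <- traj_from_frames(lapply(c(3.2, 4.5, 3.8), mk), top)
  a <- region("a", "A", 1, 1)
  b <- region("b", "A", 2, 2)
  occ <- pair_bond_occupancy(traj, a, b, cutoff = 4.0)
  expect_equal(occ$probability, 2 / 3)
  expect_equal(occ$series$bound, c(TRUE, FALSE, TRUE))
  expect_error(pair_bond_occupancy(traj, a, b, cutoff = 0), "positive")
  # empty charged selection (wild-type glycine): occupancy is 0
  none <- region("none", "A", 1, 1, atoms = "OD1")
  expect_equal(pair_bond_occupancy(traj, none, b)$probability, 0)
  # monotone in cutoff
  expect_gte(pair_bond_occupancy(traj, a, b, 4.5)$probability,
             pair_bond_occupancy(traj, a, b, 4.0)$probability)
})
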