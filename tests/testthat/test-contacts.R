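test_that("the 2.5-Angstrom contact criterion is strict", {
  top <- tiny_topology(n_res = 1, n_lig = 1)
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  traj <- traj_from_frames(lapply(c(2.4, 2.5, 2.6), mk), top)
  lig <- region("lig", "L")
  s <- residue_contact_series(traj, lig, "A", 1)
  expect_equal(s$contact, c(TRUE, FALSE, FALSE))
  expect_error(residue_contact_series(traj, lig, "A", 1, cutoff = -1),
               "positive")
  expect_error(residue_contact_series(traj, lig, "A", 99), "not found")
})

test_that("contact profile recovers planted occupancies exactly", {
  top <- tiny_topology(n_res = 3, n_lig = 1)
  base <- rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0))
  near <- function(i) rbind(base, base[i, ] + c(0, 2, 0))
  away <- rbind(base, c(0, 60, 0))
  # residue 1 contacted in 6/10 frames
  frames <- c(replicate(6, near(1), simplify = FALSE),
              replicate(4, away, simplify = FALSE))
  traj <- traj_from_frames(frames, top)
  prof <- contact_profile(traj, region("lig", "L"))
  expect_equal(prof$probability[prof$resno == 1], 0.60)
  expect_equal(prof$probability[prof$resno %in% 2:3], c(0, 0))

  # ligand never within 10 A: all-zero profile
  far <- traj_from_frames(replicate(5, away, simplify = FALSE), top)
  expect_true(all(contact_profile(far, region("lig", "L"))$probability == 0))

  # two planted sites at 0.3/0.3 recovered exactly
  frames2 <- c(replicate(3, near(1), simplify = FALSE),
               replicate(3, near(3), simplify = FALSE),
               replicate(4, away, simplify = FALSE))
  prof2 <- contact_profile(traj_from_frames(frames2, top),
                           region("lig", "L"))
  expect_equal(prof2$probability, c(0.3, 0, 0.3))
})

test_that("hotspot extraction uses a strict threshold and stable order", {
  prof <- tibble::tibble(chain = "A", resno = c(20L, 45L, 50L),
                         resname = "GLY",
                         probability = c(0.60, 0.10, 0.11))
  hot <- contact_hotspots(prof, threshold = 0.10)
  expect_equal(hot$resno, c(20L, 50L))  # 0.10 excluded: strictly above
  expect_true(nrow(contact_hotspots(dplyr::mutate(prof, probability = 0))) == 0)
  expect_equal(contact_hotspots(prof, threshold = 0)$resno,
               c(20L, 50L, 45L))
  expect_error(contact_hotspots(prof, threshold = 1), "\\[0, 1\\)")
  expect_error(contact_hotspots(prof, threshold = -0.1), "\\[0, 1\\)")
  # ties broken by (chain, residue) ascending
  tie <- tibble::tibble(chain = "A", resno = c(9L, 3L), resname = "GLY",
                        probability = c(0.5, 0.5))
  expect_equal(contact_hotspots(tie)$resno, c(3L, 9L))
})

test_that("attachment fraction and episodes partition the trajectory", {
  top <- tiny_topology(n_res = 2, n_lig = 1)
  near <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 2, 0))
  away <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 60, 0))
  lig <- region("lig", "L")
  pro <- region("pro", "A")

  always <- traj_from_frames(replicate(6, near, simplify = FALSE), top)
  att <- ligand_attachment(always, lig, pro)
  expect_equal(att$fraction_attached, 1.0)
  expect_equal(nrow(att$episodes), 1L)

  alt <- traj_from_frames(rep(list(near, away), 5), top)
  att2 <- ligand_attachment(alt, lig, pro)
  expect_equal(att2$fraction_attached, 0.5)
  expect_equal(nrow(att2$episodes), 10L)
  # episodes partition [1, n_frames] and fraction is the exact count
  expect_equal(att2$episodes$start_frame[1], 1L)
  expect_equal(att2$episodes$end_frame[nrow(att2$episodes)], 10L)
  expect_true(all(att2$episodes$start_frame[-1] ==
                    head(att2$episodes$end_frame, -1) + 1L))
  expect_equal(att2$fraction_attached,
               sum(att2$episodes$length[att2$episodes$bound]) / 10)
})

test_that("contact outputs equal a brute-force all-pairs scan", {
  # random small instances: <= 50 atoms, <= 20 frames
  set.seed(77)
  for (rep_i in 1:3) {
    n_res <- sample(3:8, 1)
    n_lig <- sample(1:3, 1)
    nf <- sample(5:20, 1)
    top <- tiny_topology(n_res = n_res, n_lig = n_lig)
    frames <- replicate(nf, matrix(rnorm((n_res + n_lig) * 3, 0, 3),
                                   ncol = 3), simplify = FALSE)
    traj <- traj_from_frames(frames, top)
    lig_idx <- resolve_region(top, region("lig", "L"))
    pro_idx <- setdiff(top$atom, lig_idx)

    prof <- contact_profile(traj, region("lig", "L"), cutoff = 2.5)
    oracle <- brute_contact_profile(traj, lig_idx, cutoff = 2.5)
    expect_equal(prof$probability, oracle$probability)
    expect_equal(
      contact_hotspots(prof, 0.1)$resno,
      contact_hotspots(oracle, 0.1)$resno
    )
    att <- ligand_attachment(traj, region("lig", "L"), region("pro", "A"))
    expect_equal(att$fraction_attached,
                 brute_attachment_fraction(traj, lig_idx, pro_idx, 2.5))
    # attachment dominates any single-residue contact probability
    expect_gte(att$fraction_attached, max(prof$probability))
  }
})

test_that("contact probabilities are non-decreasing in the cutoff", {
  set.seed(99)
  top <- tiny_topology(n_res = 5, n_lig = 2)
  frames <- replicate(15, matrix(rnorm(21, 0, 3), ncol = 3),
                      simplify = FALSE)
  traj <- traj_from_frames(frames, top)
  lig <- region("lig", "L")
  p1 <- contact_profile(traj, lig, cutoff = 2.0)$probability
  p2 <- contact_profile(traj, lig, cutoff = 3.5)$probability
  expect_true(all(p2 >= p1))
  a1 <- ligand_attachment(traj, lig, region("pro", "A"), cutoff = 2.0)
  a2 <- ligand_attachment(traj, lig, region("pro", "A"), cutoff = 3.5)
  expect_gte(a2$fraction_attached, a1$fraction_attached)
})
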