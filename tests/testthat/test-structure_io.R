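test_that("PDB topology readback keeps chains, residues and ligand flags", {
  pdb <- system.file("extdata", "toy.pdb", package = "tncoupling")
  top <- read_topology(pdb)
  expect_s3_class(top, "tn_topology")
  expect_equal(nrow(top), 9L)
  expect_setequal(unique(top$chain), c("A", "B", "L"))
  expect_equal(top$atom, 1:9)
  # HETATM ligand retained, flagged, and selectable as a region
  expect_true(all(top$het[top$chain == "L"]))
  lig <- resolve_region(top, region("ligand", "L"))
  expect_equal(top$resname[lig], c("EGC", "EGC"))
})

test_that("malformed topologies are rejected with informative errors", {
  ins <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1A      1.000   0.000   0.000  1.00  0.00           C",
    "END"), ins)
  expect_error(read_topology(ins), "insertion")

  dup <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END"), dup)
  expect_error(read_topology(dup), "Duplicate")

  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_topology(empty), "empty")
  expect_error(read_trajectory(empty), "empty")
  expect_error(read_topology(tempfile()), "not found")
})

test_that("trajectories round-trip through multi-model PDB and DCD", {
  top <- tiny_topology(n_res = 4, n_lig = 1)
  set.seed(11)
  frames <- lapply(1:5, function(i) matrix(round(rnorm(15, 0, 8), 3), 5, 3))
  traj <- traj_from_frames(frames, top, run_id = "rt")

  pdb <- tempfile(fileext = ".pdb")
  write_trajectory(traj, pdb)
  back <- read_trajectory(pdb, top, run_id = "rt")
  expect_equal(n_frames(back), 5L)
  # PDB stores 3 decimals; inputs were pre-rounded so this is bitwise
  expect_equal(back$xyz, traj$xyz, ignore_attr = TRUE)

  dcd <- tempfile(fileext = ".dcd")
  write_trajectory(traj, dcd)
  back_dcd <- read_trajectory(dcd, top)
  # single-precision DCD vs text PDB agree to coordinate precision
  expect_lt(max(abs(back_dcd$xyz - back$xyz)), 1e-3)

  # atom-count mismatch is caught with counts in the message
  top_bigger <- tiny_topology(n_res = 6, n_lig = 1)
  expect_error(read_trajectory(pdb, top_bigger), "mismatch")
})

test_that("region resolution is deterministic, unions ranges, honours CA filter", {
  spec <- trajectory_spec(n_frames = 1, n_runs = 1)
  sim <- simulate_trajectory(spec, seed = 1, verify = FALSE)
  top <- sim$topology

  ca_sel <- resolve_region(top, region("hA", "C", 14, 28, calpha = TRUE))
  expect_length(ca_sel, 15L)

  expect_error(resolve_region(top, region("bad", "Z", 1, 10)),
               "selects no atoms")
  expect_length(resolve_region(top, region("bad", "Z", 1, 10),
                               allow_empty = TRUE), 0L)

  # overlapping ranges: union without duplicates
  both <- resolve_region(top, region("ov", c("C", "C"), c(10L, 20L),
                                     c(25L, 30L), calpha = TRUE))
  expect_length(both, 21L)
  expect_false(anyDuplicated(both) > 0)

  # selection invariant to atom record order within a residue
  perm <- top
  r83 <- which(perm$chain == "C" & perm$resno == 83)
  shuffled <- perm[c(setdiff(seq_len(nrow(perm)), r83), rev(r83)), ]
  perm2 <- as_topology(shuffled[, setdiff(names(shuffled), "atom")])
  sel1 <- resolve_region(top, region("r83", "C", 83, 83))
  sel2 <- resolve_region(perm2, region("r83", "C", 83, 83))
  expect_equal(top$atom_name[sel1] |> sort(),
               perm2$atom_name[sel2] |> sort())
})

test_that("atom-name filters select charged side-chain sets", {
  sim <- simulate_trajectory(trajectory_spec(n_frames = 1, n_runs = 1,
                                             variant = "G159D"),
                             seed = 1, verify = FALSE)
  top <- sim$topology
  od <- resolve_region(top, region("d159", "C", 159, 159,
                                   atoms = c("OD1", "OD2")))
  expect_equal(top$atom_name[od], c("OD1", "OD2"))
  # wild-type Gly159 has no carboxylate: empty selection is allowed
  wt <- simulate_trajectory(trajectory_spec(n_frames = 1, n_runs = 1),
                            seed = 1, verify = FALSE)$topology
  expect_length(resolve_region(wt, region("d159", "C", 159, 159,
                                          atoms = c("OD1", "OD2")),
                               allow_empty = TRUE), 0L)
})
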