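# Shared fixtures: tiny hand-built topologies/trajectories and
# independent brute-force oracles used to cross-check the vectorised
# implementations.

# topology with one protein chain of `n_res` single-CA residues plus a
# `n_lig`-atom ligand chain
tiny_topology <- function(n_res = 5, n_lig = 2) {
  prot <- tibble::tibble(atom_name = "CA", element = "C",
                         resno = seq_len(n_res), resname = "GLY",
                         chain = "A", het = FALSE)
  if (n_lig == 0) return(as_topology(prot))
  lig <- tibble::tibble(atom_name = paste0("C", seq_len(n_lig)),
                        element = "C", resno = 1L, resname = "LIG",
                        chain = "L", het = TRUE)
  as_topology(dplyr::bind_rows(prot, lig))
}

# trajectory from an explicit list of n_atoms x 3 frame matrices
traj_from_frames <- function(frames, topology, ...) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  trajectory(xyz, topology, ...)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid transform (rotation + translation) to every frame
transform_traj <- function(traj, rot = diag(3), shift = c(0, 0, 0)) {
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(f) {
    sweep(frame_coords(traj, f) %*% t(rot), 2, shift, "+")
  })
  traj_from_frames(frames, traj$topology,
                   frame_interval_ns = traj$frame_interval_ns,
                   run_id = traj$run_id)
}

# brute-force all-pairs minimum distance between two atom index sets in
# one frame (independent oracle for the contact/occupancy code)
brute_min_dist <- function(fr, ia, ib) {
  best <- Inf
  for (a in ia) {
    for (b in ib) {
      best <- min(best, sqrt(sum((fr[a, ] - fr[b, ])^2)))
    }
  }
  best
}

brute_contact_profile <- function(traj, lig_idx, cutoff) {
  top <- traj$topology
  res <- unique(top[top$atom %in% setdiff(top$atom, lig_idx),
                    c("chain", "resno")])
  out <- list()
  for (i in seq_len(nrow(res))) {
    ir <- top$atom[top$chain == res$chain[i] & top$resno == res$resno[i]]
    ir <- setdiff(ir, lig_idx)
    hits <- vapply(seq_len(n_frames(traj)), function(f) {
      brute_min_dist(frame_coords(traj, f), lig_idx, ir) < cutoff
    }, logical(1))
    out[[i]] <- tibble::tibble(chain = res$chain[i], resno = res$resno[i],
                               probability = mean(hits))
  }
  dplyr::arrange(dplyr::bind_rows(out), chain, resno)
}

brute_attachment_fraction <- function(traj, lig_idx, pro_idx, cutoff) {
  mean(vapply(seq_len(n_frames(traj)), function(f) {
    brute_min_dist(frame_coords(traj, f), lig_idx, pro_idx) < cutoff
  }, logical(1)))
}

# printed trajectory-metric table rows (troponin condition, ligand,
# uP mean, printed delta, P mean) used for arithmetic-convention checks
printed_ab_means <- tibble::tribble(
  ~condition,        ~unp,   ~delta, ~p,
  "WT apo",          101.81, -5.65,  96.16,
  "G159D apo",       97.06,   1.91,  98.97,
  "G159D EGCG",      102.25, -13.25, 89.0,
  "G159D RVL",       105.48, -11.14, 94.34,
  "G159D SilybinA",  98.55,   4.88,  103.43,
  "G159D SilybinB",  103.61,  -3.09, 100.52,
  "G159D ECG",       98.1,    -0.2,  97.9
)

printed_hinge_means <- tibble::tribble(
  ~condition,        ~unp,   ~delta, ~p,
  "WT apo",          121.61,  1.65,  123.26,
  "G159D apo",       121.51, -5.31,  116.2,
  "G159D EGCG",      114.62, -7.03,  107.59,
  "G159D RVL",       112.61,  9.28,  121.89,
  "G159D SilybinA",  126.65, -6.35,  120.3,
  "G159D SilybinB",  117.74,  3.58,  121.32,
  "G159D ECG",       118.9,  -8.3,   110.6
)

printed_distance_means <- tibble::tribble(
  ~condition,        ~unp,  ~delta, ~p,
  "WT apo",          30.18, -0.28,  29.9,
  "G159D apo",       29.22,  0.35,  29.59,
  "G159D EGCG",      31.17,  0.81,  31.98,
  "G159D RVL",       32.13, -0.74,  31.39,
  "G159D SilybinA",  30.09,  0.75,  30.84,
  "G159D SilybinB",  31.83, -1.11,  30.72,
  "G159D ECG",       30.2,   0,     30.2
)
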