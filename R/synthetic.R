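#' Specification for a synthetic troponin-like trajectory
#'
#' Defines the planted ground truth of a synthetic run: per-frame helix
#' A/B and hinge angles drawn from Gaussian mixtures, interdomain
#' distance from a Gaussian, salt-bridge occupancy as an independent
#' Bernoulli per frame, and ligand attachment as a two-state Markov
#' chain. Defaults reproduce the wild-type apo unphosphorylated
#' condition: A/B angle N(101.81, 9.15) degrees, hinge N(121.61, 7.24)
#' degrees, interdomain distance N(30.18, 1.34) Angstrom, no Asp159
#' side chain (variant "WT", salt-bridge occupancy 0), no ligand. Runs of
#' 3750 frames at 0.4 ns/frame emulate 1500 ns sampled as 3750 frames;
#' five runs per condition.
#'
#' @param n_frames Frames per run (default 3750).
#' @param n_runs Independent runs (default 5).
#' @param frame_interval_ns ns per frame (default 0.4).
#' @param ab_angle,hinge Lists `(weights, means, sds)` in degrees
#'   describing Gaussian mixtures (weights must sum to 1, sds > 0).
#' @param distance List `(mean, sd)` in Angstrom for the interdomain
#'   centroid distance.
#' @param variant `"WT"` (Gly159: no carboxylate atoms, salt-bridge
#'   occupancy 0 by construction) or `"G159D"` (Asp159 side chain
#'   present).
#' @param saltbridge_occupancy Target Asp159-Arg83 bond occupancy in
#'   0-1; ignored for variant "WT".
#' @param ligand `NULL`, or a list with `label` (3-letter residue code),
#'   `bound_fraction` in 0-1, `targets` (chain-C residue numbers the
#'   bound ligand contacts), optional `weights` over targets, and either
#'   `p_on`/`p_off` transition probabilities in (0, 1] or
#'   `mean_bound_episode` (frames) from which they are derived so the
#'   stationary bound fraction is `p_on / (p_on + p_off)`.
#' @param condition Condition label carried into outputs.
#' @return A `tn_trajectory_spec` list.
#' @export
trajectory_spec <- function(n_frames = 3750L, n_runs = 5L,
                            frame_interval_ns = 0.4,
                            ab_angle = list(weights = 1, means = 101.81,
                                            sds = 9.15),
                            hinge = list(weights = 1, means = 121.61,
                                         sds = 7.24),
                            distance = list(mean = 30.18, sd = 1.34),
                            variant = c("WT", "G159D"),
                            saltbridge_occupancy = 0,
                            ligand = NULL,
                            condition = "WT apo") {
  variant <- match.arg(variant)
  check_mixture <- function(mx, what) {
    if (abs(sum(mx$weights) - 1) > 1e-8) {
      abort(paste0(what, " mixture weights must sum to 1."))
    }
    if (any(mx$sds <= 0)) abort(paste0(what, " mixture sds must be > 0."))
    if (length(mx$weights) != length(mx$means) ||
        length(mx$means) != length(mx$sds)) {
      abort(paste0(what, " mixture components have unequal lengths."))
    }
  }
  check_mixture(ab_angle, "ab_angle")
  check_mixture(hinge, "hinge")
  if (saltbridge_occupancy < 0 || saltbridge_occupancy > 1) {
    abort("saltbridge_occupancy must lie in [0, 1].")
  }
  if (!is.null(ligand)) {
    ligand$label <- ligand$label %||% "LIG"
    ligand$targets <- ligand$targets %||% 20L
    ligand$weights <- ligand$weights %||%
      rep(1 / length(ligand$targets), length(ligand$targets))
    f <- ligand$bound_fraction
    if (is.null(f) || f < 0 || f > 1) {
      abort("ligand$bound_fraction must lie in [0, 1].")
    }
    if (is.null(ligand$p_on) || is.null(ligand$p_off)) {
      mep <- ligand$mean_bound_episode %||% 25
      p_off <- min(1, 1 / mep)
      p_on <- if (f >= 1) 1 else min(1, p_off * f / (1 - f))
      ligand$p_on <- p_on
      ligand$p_off <- p_off
    }
    if (ligand$p_on <= 0 || ligand$p_on > 1 ||
        ligand$p_off <= 0 || ligand$p_off > 1) {
      abort("ligand transition probabilities must lie in (0, 1].")
    }
  }
  structure(
    list(n_frames = as.integer(n_frames), n_runs = as.integer(n_runs),
         frame_interval_ns = frame_interval_ns, ab_angle = ab_angle,
         hinge = hinge, distance = distance, variant = variant,
         saltbridge_occupancy = saltbridge_occupancy, ligand = ligand,
         condition = condition),
    class = "tn_trajectory_spec"
  )
}

# ---- scaffold ------------------------------------------------------------
# Abstract C-alpha-level troponin stand-in on which the planted angles and
# distances are realised exactly by rigid placement:
#   chain C  1-161  TnC-like chain: helix A (14-28) and helix B (38-48)
#                   straight C-alpha arms; 86-94 static central linker
#                   (pivot = residue 90 at the origin); 95-161 the
#                   ITC-like rigid body; Arg83 carries NE/NH1/NH2 and
#                   Asp159 carries OD1/OD2 pseudo side-chain atoms.
#   chain I  1-33   TnI N-terminal peptide stand-in (part of the NcTnC
#                   rigid body).
#   chain L         optional ligand residue (HETATM).
SPACING <- 3.8  # Angstrom between consecutive pseudo C-alpha atoms

scaffold_topology <- function(variant = "WT", ligand_label = NULL) {
  ca <- function(chain, resno, resname = "GLY") {
    tibble(atom_name = "CA", element = "C", resno = resno,
           resname = resname, chain = chain, het = FALSE)
  }
  resn <- rep("GLY", 161)
  resn[83] <- "ARG"
  resn[159] <- if (variant == "G159D") "ASP" else "GLY"
  rows <- list(ca("C", 1:161, resn), ca("I", 1:33, "ALA"))
  rows <- c(rows, list(tibble(
    atom_name = c("NE", "NH1", "NH2"), element = "N", resno = 83L,
    resname = "ARG", chain = "C", het = FALSE
  )))
  if (variant == "G159D") {
    rows <- c(rows, list(tibble(
      atom_name = c("OD1", "OD2"), element = "O", resno = 159L,
      resname = "ASP", chain = "C", het = FALSE
    )))
  }
  if (!is.null(ligand_label)) {
    rows <- c(rows, list(tibble(
      atom_name = paste0("C", 1:4), element = "C", resno = 1L,
      resname = ligand_label, chain = "L", het = TRUE
    )))
  }
  as_topology(bind_rows(rows))
}

# deterministic spread of n points on a coarse spiral around `centre`
spiral_points <- function(n, centre, radius = 8, rise = 1.2) {
  k <- seq_len(n)
  ang <- k * 2.399963  # golden angle, no two points close
  pts <- cbind(radius * cos(ang), radius * sin(ang), (k - (n + 1) / 2) * rise)
  sweep(pts, 2, centre, "+")
}

# local (pre-placement) coordinates of every atom; NcTnC body centred on
# its own C-alpha centroid so placement is a pure translation
scaffold_layout <- function(top) {
  xyz <- matrix(NA_real_, nrow = nrow(top), ncol = 3)
  idx <- function(chain, resno, name = "CA") {
    top$atom[top$chain == chain & top$resno %in% resno &
               top$atom_name %in% name]
  }
  # helix A and B: straight arms in the z direction
  ha <- idx("C", 14:28)
  xyz[ha, ] <- cbind(-10, 0, (seq_along(ha) - 8) * SPACING)
  hb <- idx("C", 38:48)
  xyz[hb, ] <- cbind(10, 0, (seq_along(hb) - 6) * SPACING)
  # remaining NcTnC-body residues + TnI peptide: spiral off to +y
  fill_c <- idx("C", c(1:13, 29:37, 49:85))
  xyz[fill_c, ] <- spiral_points(length(fill_c), c(0, 30, 0))
  fill_i <- idx("I", 1:33)
  xyz[fill_i, ] <- spiral_points(length(fill_i), c(0, 48, 0), radius = 6)
  # Arg83 side chain rides on its C-alpha
  r83 <- idx("C", 83)
  base <- xyz[r83, ]
  xyz[idx("C", 83, "NE"), ] <- base + c(1.5, 0, 0)
  xyz[idx("C", 83, "NH1"), ] <- base + c(2.4, 0.7, 0)
  xyz[idx("C", 83, "NH2"), ] <- base + c(2.4, -0.7, 0)
  # central linker, static; pivot residue 90 exactly at the origin
  lk <- idx("C", 86:94)
  lin <- seq(-2, 2, length.out = length(lk))
  xyz[lk, ] <- cbind(2.5 * lin, 1.2 * lin, 0)
  xyz[idx("C", 90), ] <- c(0, 0, 0)
  # ITC-like rigid body with C-alpha centroid at (8, 0, 0)
  itc <- idx("C", 95:161)
  pts <- spiral_points(length(itc), c(0, 0, 0), radius = 7)
  pts <- sweep(pts, 2, colMeans(pts))
  xyz[itc, ] <- sweep(pts, 2, c(8, 0, 0), "+")
  # Asp159 side chain / ligand are placed per frame later
  od <- idx("C", 159, c("OD1", "OD2"))
  if (length(od)) xyz[od, ] <- xyz[rep(idx("C", 159), length(od)), ]
  lig <- top$atom[top$chain == "L"]
  if (length(lig)) xyz[lig, ] <- 0
  xyz
}

sample_mixture <- function(n, mx) {
  comp <- sample.int(length(mx$weights), n, replace = TRUE,
                     prob = mx$weights)
  rnorm(n, mean = mx$means[comp], sd = mx$sds[comp])
}

#' Generate synthetic troponin-like trajectories with planted truth
#'
#' Builds the abstract C-alpha scaffold and, for every frame, realises
#' the sampled helix A/B angle exactly (rigid rotation of helix B about
#' its centroid), the sampled hinge angle and interdomain distance
#' exactly (rigid placement of the NcTnC-like body around the static
#' pivot), the salt-bridge state (Asp159 carboxylate placed at 3.0 or
#' 8.0 Angstrom from the Arg83 guanidinium against the 4.0 cutoff), and
#' the ligand state (bound frames put a ligand atom 2.0 Angstrom from a
#' target residue C-alpha; unbound frames park it far from the protein).
#' All randomness flows from `seed`; per-run sub-seeds are derived
#' deterministically.
#'
#' @param spec A [trajectory_spec()].
#' @param seed Integer seed.
#' @param dir Optional directory: when given, writes `topology.pdb`, one
#'   multi-model PDB per run and `manifest.json` with the full per-frame
#'   ground truth, and records the paths in the result.
#' @param verify Check the first frames of each run against the planted
#'   angles (tolerance 1e-6 degrees) and error on any mismatch.
#' @return A list of class `tn_synthetic_traj`: `topology`, `runs` (list
#'   of `tn_trajectory`), `truth` (tibble of per-frame planted values:
#'   `run_id`, `frame`, `ab_angle`, `hinge_angle`, `distance`,
#'   `saltbridge_bound`, `ligand_bound`, `ligand_target`), `spec`, and
#'   `paths` when `dir` was given.
#' @export
simulate_trajectory <- function(spec, seed = 1L, dir = NULL,
                                verify = TRUE) {
  stopifnot(inherits(spec, "tn_trajectory_spec"))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_runs)
  top <- scaffold_topology(spec$variant,
                           if (!is.null(spec$ligand)) spec$ligand$label)
  local <- scaffold_layout(top)
  runs <- vector("list", spec$n_runs)
  truths <- vector("list", spec$n_runs)
  for (r in seq_len(spec$n_runs)) {
    set.seed(run_seeds[r])
    run_id <- paste0("run", r)
    built <- build_run(spec, top, local, run_id)
    runs[[r]] <- built$traj
    truths[[r]] <- built$truth
    if (verify) verify_run(built$traj, built$truth, top)
  }
  out <- structure(
    list(topology = top, runs = runs,
         truth = bind_rows(truths), spec = spec),
    class = "tn_synthetic_traj"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    top_path <- file.path(dir, "topology.pdb")
    write_topology(top, frame_coords(runs[[1]], 1), top_path)
    run_paths <- vapply(seq_along(runs), function(r) {
      p <- file.path(dir, paste0("run", r, ".pdb"))
      write_trajectory(runs[[r]], p, format = "pdb")
      p
    }, character(1))
    manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(spec = unclass(spec), seed = seed,
           truth = out$truth),
      manifest_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
    out$paths <- list(topology = top_path, runs = run_paths,
                      manifest = manifest_path)
  }
  out
}

build_run <- function(spec, top, local, run_id) {
  nf <- spec$n_frames
  theta <- pmin(179, pmax(1, sample_mixture(nf, spec$ab_angle)))
  phi <- pmin(179, pmax(1, sample_mixture(nf, spec$hinge)))
  dist <- rnorm(nf, spec$distance$mean, spec$distance$sd)
  r2 <- 8  # |ITC centroid - pivot|
  # keep the planted distance geometrically realisable
  dist <- pmax(dist, r2 + 1)
  sb <- if (spec$variant == "G159D") {
    runif(nf) < spec$saltbridge_occupancy
  } else {
    rep(FALSE, nf)
  }
  lig_state <- rep(FALSE, nf)
  lig_target <- rep(NA_integer_, nf)
  if (!is.null(spec$ligand)) {
    lig_state <- markov_chain(nf, spec$ligand$p_on, spec$ligand$p_off,
                              spec$ligand$bound_fraction)
    nb <- sum(lig_state)
    if (nb > 0) {
      lig_target[lig_state] <- spec$ligand$targets[
        sample.int(length(spec$ligand$targets), nb, replace = TRUE,
                   prob = spec$ligand$weights)
      ]
    }
  }
  xyz <- place_frames(spec, top, local, theta, phi, dist, sb, lig_target)
  truth <- tibble(
    run_id = run_id, frame = seq_len(nf),
    ab_angle = theta, hinge_angle = phi, distance = dist,
    saltbridge_bound = sb, ligand_bound = lig_state,
    ligand_target = lig_target
  )
  list(
    traj = trajectory(xyz, top, frame_interval_ns = spec$frame_interval_ns,
                      run_id = run_id),
    truth = truth
  )
}

markov_chain <- function(n, p_on, p_off, stationary) {
  z <- logical(n)
  z[1] <- runif(1) < stationary
  u <- runif(n)
  for (i in 2:n) {
    z[i] <- if (z[i - 1]) u[i] >= p_off else u[i] < p_on
  }
  z
}

place_frames <- function(spec, top, local, theta, phi, dist, sb,
                         lig_target) {
  nf <- length(theta)
  natoms <- nrow(top)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * natoms)
  idx <- function(chain, resno, name = "CA") {
    top$atom[top$chain == chain & top$resno %in% resno &
               top$atom_name %in% name]
  }
  set_static <- function(i) {
    xyz[, 3 * i - 2] <<- rep(local[i, 1], each = nf)
    xyz[, 3 * i - 1] <<- rep(local[i, 2], each = nf)
    xyz[, 3 * i] <<- rep(local[i, 3], each = nf)
  }
  ncbody <- sort(c(idx("C", 1:85), idx("I", 1:33),
                   idx("C", 83, c("NE", "NH1", "NH2"))))
  ncbody_ca <- sort(c(idx("C", 1:85), idx("I", 1:33)))
  static <- setdiff(top$atom, c(
    ncbody, idx("C", 159, c("OD1", "OD2")), top$atom[top$chain == "L"]
  ))
  for (i in static) set_static(i)
  # rigid placement of the NcTnC-like body: centroid at c1(phi, dist)
  r2 <- 8
  phir <- phi * pi / 180
  r1 <- r2 * cos(phir) + sqrt(dist^2 - (r2 * sin(phir))^2)
  c1 <- cbind(r1 * cos(phir), r1 * sin(phir), 0)
  lcen <- colMeans(local[ncbody_ca, , drop = FALSE])
  hb <- idx("C", 38:48)
  hb_cen <- colMeans(local[hb, , drop = FALSE])
  thr <- theta * pi / 180
  for (i in ncbody) {
    p <- local[i, ] - lcen
    if (i %in% hb) {
      # rotate helix B about its centroid so its axis makes exactly
      # theta with the helix A axis (z)
      q <- local[i, ] - hb_cen
      base <- hb_cen - lcen
      xyz[, 3 * i - 2] <- c1[, 1] + base[1] + q[1]
      xyz[, 3 * i - 1] <- c1[, 2] + base[2] + q[2] * cos(thr) -
        q[3] * sin(thr)
      xyz[, 3 * i] <- c1[, 3] + base[3] + q[2] * sin(thr) + q[3] * cos(thr)
    } else {
      xyz[, 3 * i - 2] <- c1[, 1] + p[1]
      xyz[, 3 * i - 1] <- c1[, 2] + p[2]
      xyz[, 3 * i] <- c1[, 3] + p[3]
    }
  }
  # Asp159 side chain: minimum distance to the Arg83 guanidinium set
  # exactly at 3.0 (bonded) or 8.0 (unbonded) Angstrom
  od <- idx("C", 159, c("OD1", "OD2"))
  if (length(od)) {
    nh1 <- idx("C", 83, "NH1")
    ne <- idx("C", 83, "NE")
    e <- (local[nh1, ] - local[ne, ])
    e <- e / sqrt(sum(e^2))  # pointing away from NE through NH1
    d <- ifelse(sb, 3.0, 8.0)
    for (k in seq_along(od)) {
      off <- (k - 1) * 1.0
      xyz[, 3 * od[k] - 2] <- xyz[, 3 * nh1 - 2] + (d + off) * e[1]
      xyz[, 3 * od[k] - 1] <- xyz[, 3 * nh1 - 1] + (d + off) * e[2]
      xyz[, 3 * od[k]] <- xyz[, 3 * nh1] + (d + off) * e[3]
    }
  }
  # ligand: bound frames 2.0 Angstrom from the target C-alpha, unbound
  # frames parked far outside the protein envelope
  lig <- top$atom[top$chain == "L"]
  if (length(lig)) {
    offs <- rbind(c(0, -2, 0), c(0, -2.8, 0), c(0, -2.8, 0.6),
                  c(0, -3.6, 0))
    far <- c(200, 200, 200)
    bound <- !is.na(lig_target)
    for (k in seq_along(lig)) {
      xk <- rep(far[1] + k, nf)
      yk <- rep(far[2], nf)
      zk <- rep(far[3], nf)
      if (any(bound)) {
        tcol <- vapply(lig_target[bound], function(rn) idx("C", rn),
                       integer(1))
        xk[bound] <- xyz[cbind(which(bound), 3 * tcol - 2)] + offs[k, 1]
        yk[bound] <- xyz[cbind(which(bound), 3 * tcol - 1)] + offs[k, 2]
        zk[bound] <- xyz[cbind(which(bound), 3 * tcol)] + offs[k, 3]
      }
      xyz[, 3 * lig[k] - 2] <- xk
      xyz[, 3 * lig[k] - 1] <- yk
      xyz[, 3 * lig[k]] <- zk
    }
  }
  xyz
}

verify_run <- function(traj, truth, top, n_check = 5L, tol = 1e-6) {
  helix_a <- region("helix_A", "C", 14, 28, calpha = TRUE)
  helix_b <- region("helix_B", "C", 38, 48, calpha = TRUE)
  ia <- resolve_region(top, helix_a)
  ib <- resolve_region(top, helix_b)
  frames <- unique(round(seq(1, n_frames(traj),
                             length.out = min(n_check, n_frames(traj)))))
  for (f in frames) {
    got <- interhelix_angle(ca_matrix(traj, ia, f), ca_matrix(traj, ib, f))
    if (abs(got - truth$ab_angle[f]) > tol) {
      abort(paste0("Internal error: frame ", f, " realises A/B angle ",
                   got, " instead of ", truth$ab_angle[f]))
    }
  }
  invisible(TRUE)
}

#' @export
print.tn_synthetic_traj <- function(x, ...) {
  cat("<synthetic trajectory> ", x$spec$condition, ": ",
      length(x$runs), " run(s) x ", x$spec$n_frames, " frames, variant ",
      x$spec$variant,
      if (!is.null(x$spec$ligand)) paste0(", ligand ", x$spec$ligand$label),
      "\n", sep = "")
  invisible(x)
}

#' Default analysis regions for the synthetic scaffold
#'
#' The region set matching the synthetic scaffold: helices A and B, the
#' NcTnC-like and ITC-like domains, the hinge pivot, the Asp159/Arg83
#' charged atom sets, the ligand and the whole protein. Real structures
#' use the same constructors with their own chain map and residue
#' ranges.
#'
#' @return Named list of [region()] objects.
#' @export
default_regions <- function() {
  list(
    helix_a = region("helix_A", "C", 14, 28, calpha = TRUE),
    helix_b = region("helix_B", "C", 38, 48, calpha = TRUE),
    domain_n = region("NcTnC", c("C", "I"), c(1L, 1L), c(85L, 33L),
                      calpha = TRUE),
    domain_itc = region("ITC", "C", 95, 161, calpha = TRUE),
    pivot = region("hinge_pivot", "C", 90, 90, calpha = TRUE),
    d159 = region("D159_carboxylate", "C", 159, 159,
                  atoms = c("OD1", "OD2")),
    r83 = region("R83_guanidinium", "C", 83, 83,
                 atoms = c("NE", "NH1", "NH2")),
    ligand = region("ligand", "L"),
    protein = region("protein", c("C", "I"))
  )
}

#' Generate paired P/unP calcium-activation curves
#'
#' Simulates one unphosphorylated and one phosphorylated fraction-motile
#' curve per replicate from the four-parameter Hill model, with
#' EC50(P) = EC50(unP) x ratio and Gaussian noise on fraction motile.
#' Defaults plant the native thin-filament condition: EC50(unP)
#' 0.059 uM and ratio 2.24.
#'
#' @param ec50_unp Unphosphorylated EC50 (uM).
#' @param ratio EC50(P) / EC50(unP); > 1 means phosphorylation
#'   desensitises, the coupled behaviour.
#' @param n_h Hill coefficient (default 2, typical thin-filament
#'   cooperativity).
#' @param f_min,f_max Baseline and plateau fraction motile.
#' @param ca_um Concentration grid (uM); default 8 points log-spaced
#'   over 0.01-10 uM.
#' @param noise_sd Gaussian noise sd on fraction motile (default 0.05).
#' @param n_replicates Replicate curve pairs.
#' @param condition Condition label.
#' @param seed Integer seed.
#' @return Tibble (`condition`, `phospho`, `replicate_id`, `ca_um`,
#'   `fraction_motile`) with the planted parameters in attribute
#'   `"truth"`.
#' @export
simulate_activation_curves <- function(ec50_unp = 0.059, ratio = 2.24,
                                       n_h = 2, f_min = 0.05, f_max = 0.8,
                                       ca_um = 10^seq(-2, 1,
                                                      length.out = 8),
                                       noise_sd = 0.05, n_replicates = 1L,
                                       condition = "native", seed = 1L) {
  stopifnot(ec50_unp > 0, ratio > 0, n_h > 0, all(ca_um > 0),
            noise_sd >= 0, f_min <= f_max)
  set.seed(seed)
  hill <- function(ca, ec50) {
    f_min + (f_max - f_min) / (1 + (ec50 / ca)^n_h)
  }
  grid <- tidyr::expand_grid(
    replicate_id = seq_len(n_replicates),
    phospho = c("uP", "P"),
    ca_um = ca_um
  )
  grid |>
    mutate(
      condition = condition,
      ec50 = ifelse(.data$phospho == "P", ec50_unp * ratio, ec50_unp),
      fraction_motile = hill(.data$ca_um, .data$ec50) +
        rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    select(dplyr::all_of(c("condition", "phospho", "replicate_id",
                           "ca_um", "fraction_motile"))) |>
    structure(truth = list(ec50_unp = ec50_unp, ec50_p = ec50_unp * ratio,
                           ratio = ratio, n_h = n_h, f_min = f_min,
                           f_max = f_max, noise_sd = noise_sd))
}

# closed-form scaling between the raised-cosine template phases and the
# measured crossing-time conventions
rise_duration_for <- function(ttp90, onset_frac = 0.10) {
  ttp90 * pi / (acos(1 - 1.8) - acos(1 - 2 * onset_frac))
}
decay_duration_for <- function(ttb90) ttb90 * pi / acos(-0.8)

#' Generate synthetic cell-shortening transients
#'
#' Builds 1 Hz, 10 s cell-length traces from a smooth two-phase
#' raised-cosine beat template whose measured crossing times equal the
#' requested `ttp90` (onset at 10 percent amplitude to 90 percent of
#' peak) and `ttb90` (peak to 90 percent recovery). Per-cell parameters
#' vary around the group values with coefficient of variation `cell_cv`;
#' traces carry additive Gaussian noise and a slow baseline drift. The
#' per-cell planted values are recorded in attribute `"truth"`.
#'
#' @param l0 Resting cell length (um).
#' @param amplitude_pct Shortening amplitude, percent of `l0`.
#' @param ttp90,ttb90 Target contraction / relaxation times (s).
#' @param n_cells Number of cells.
#' @param duration_s Record length (s, default 10).
#' @param stimulus_rate Hz (default 1).
#' @param sample_rate_hz Sampling rate (default 250).
#' @param noise_sd Measurement noise sd (um).
#' @param drift_um Peak-to-peak slow baseline drift (um).
#' @param cell_cv Cell-to-cell coefficient of variation of the planted
#'   parameters (default 0.05).
#' @param treatment Treatment label stored with each trace.
#' @param cell_ids Optional explicit cell IDs (for pairing treatments).
#' @param seed Integer seed.
#' @return Long tibble (`cell_id`, `treatment`, `time_s`, `length_um`)
#'   with per-cell truth tibble in attribute `"truth"`.
#' @export
simulate_transients <- function(l0 = 120, amplitude_pct = 8, ttp90 = 0.15,
                                ttb90 = 0.50, n_cells = 40L,
                                duration_s = 10, stimulus_rate = 1,
                                sample_rate_hz = 250, noise_sd = 0.1,
                                drift_um = 0.3, cell_cv = 0.05,
                                treatment = "baseline", cell_ids = NULL,
                                seed = 1L) {
  stopifnot(l0 > 0, amplitude_pct > 0, ttp90 > 0, ttb90 > 0, n_cells >= 1)
  period <- 1 / stimulus_rate
  onset_offset <- 0.08 * period  # latency from stimulus to onset
  if (rise_duration_for(ttp90) + decay_duration_for(ttb90) >=
      period - onset_offset) {
    abort("Infeasible transient: contraction plus relaxation exceeds the stimulus period.")
  }
  set.seed(seed)
  cell_ids <- cell_ids %||% sprintf("cell%02d", seq_len(n_cells))
  t <- seq(0, duration_s - 1 / sample_rate_hz, by = 1 / sample_rate_hz)
  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    jit <- function(x) x * (1 + rnorm(1, 0, cell_cv))
    li <- jit(l0); ai <- jit(amplitude_pct)
    tpi <- jit(ttp90); tbi <- jit(ttb90)
    tr <- rise_duration_for(tpi); td <- decay_duration_for(tbi)
    over <- (tr + td) / (period - onset_offset)
    if (over >= 1) {
      # squeeze an infeasibly slow cell into its period and record the
      # realised (not requested) crossing times as truth
      tr <- tr / (over * 1.01)
      td <- td / (over * 1.01)
      tpi <- tr * (acos(1 - 1.8) - acos(1 - 2 * 0.10)) / pi
      tbi <- td * acos(-0.8) / pi
    }
    phase <- (t %% period) - onset_offset
    g <- numeric(length(t))
    rising <- phase >= 0 & phase < tr
    g[rising] <- 0.5 * (1 - cos(pi * phase[rising] / tr))
    decaying <- phase >= tr & phase < tr + td
    g[decaying] <- 0.5 * (1 + cos(pi * (phase[decaying] - tr) / td))
    drift <- drift_um / 2 * sin(2 * pi * t / duration_s + runif(1, 0, 2 * pi))
    y <- li - (ai / 100 * li) * g + drift + rnorm(length(t), 0, noise_sd)
    traces[[i]] <- tibble(cell_id = cell_ids[i], treatment = treatment,
                          time_s = t, length_um = y)
    truth[[i]] <- tibble(cell_id = cell_ids[i], treatment = treatment,
                         L0 = li, amplitude_pct = ai, ttp90 = tpi,
                         ttb90 = tbi)
  }
  structure(bind_rows(traces), truth = bind_rows(truth))
}

#' Generate paired baseline/dobutamine transients for a dish of cells
#'
#' Same cells measured twice: baseline, then with per-cell multiplicative
#' dobutamine effects applied to the planted parameters. Defaults emulate
#' the coupled wild-type response: amplitude up 47 percent, ttb90 down
#' 21 percent (lusitropy 0.21).
#'
#' @inheritParams simulate_transients
#' @param amplitude_factor,ttp90_factor,ttb90_factor Multiplicative
#'   dobutamine effects on the per-cell planted parameters.
#' @param effect_cv Cell-to-cell coefficient of variation of the
#'   dobutamine factors.
#' @param ... Further arguments (e.g. `duration_s`, `sample_rate_hz`)
#'   passed on to [simulate_transients()].
#' @return Long tibble over both treatments with per-cell truth in
#'   attribute `"truth"`.
#' @export
simulate_dobutamine_pair <- function(l0 = 120, amplitude_pct = 8,
                                     ttp90 = 0.15, ttb90 = 0.50,
                                     amplitude_factor = 1.47,
                                     ttp90_factor = 0.95,
                                     ttb90_factor = 0.79,
                                     effect_cv = 0.02,
                                     n_cells = 40L, noise_sd = 0.1,
                                     cell_cv = 0.05, seed = 1L, ...) {
  set.seed(seed)
  ids <- sprintf("cell%02d", seq_len(n_cells))
  base <- simulate_transients(l0, amplitude_pct, ttp90, ttb90,
                              n_cells = n_cells, noise_sd = noise_sd,
                              cell_cv = cell_cv, treatment = "baseline",
                              cell_ids = ids,
                              seed = sample.int(1e9, 1), ...)
  bt <- attr(base, "truth")
  jf <- function(f) f * (1 + rnorm(n_cells, 0, effect_cv))
  fa <- jf(amplitude_factor); fp <- jf(ttp90_factor); fb <- jf(ttb90_factor)
  dob_traces <- vector("list", n_cells)
  dob_truth <- vector("list", n_cells)
  dseed <- sample.int(1e9, n_cells)
  for (i in seq_len(n_cells)) {
    d <- simulate_transients(
      l0 = bt$L0[i], amplitude_pct = bt$amplitude_pct[i] * fa[i],
      ttp90 = bt$ttp90[i] * fp[i], ttb90 = bt$ttb90[i] * fb[i],
      n_cells = 1L, noise_sd = noise_sd, cell_cv = 0,
      treatment = "dobutamine", cell_ids = ids[i], seed = dseed[i], ...
    )
    dob_traces[[i]] <- d
    dob_truth[[i]] <- attr(d, "truth")
  }
  structure(
    bind_rows(base, bind_rows(dob_traces)),
    truth = bind_rows(bt, bind_rows(dob_truth))
  )
}
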