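#' Principal axis of a helix
#'
#' The helix axis is the first principal component of the centred
#' C-alpha coordinates, sign-oriented from the N-terminal to the
#' C-terminal atom (rows are assumed to be in N-to-C order). Reversing
#' the residue order therefore flips the axis.
#'
#' @param m n x 3 coordinate matrix of the helix C-alpha atoms (n >= 4),
#'   rows in residue order.
#' @return Unit 3-vector (norm 1 within 1e-9).
#' @export
helix_axis <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 4L) {
    abort("helix_axis() needs at least 4 C-alpha atoms.")
  }
  centred <- sweep(m, 2, colMeans(m))
  if (sum(centred^2) < 1e-12) {
    abort("Degenerate helix: all atoms coincide; no axis is defined.")
  }
  v <- svd(centred, nu = 0, nv = 1)$v[, 1]
  v <- v / sqrt(sum(v^2))
  span <- m[nrow(m), ] - m[1, ]
  if (sum(span * v) < 0) v <- -v
  v
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Interhelix angle between two helix axes
#'
#' Arc-cosine of the dot product of the two oriented unit axes, in
#' degrees within 0-180. Used for the TnC helix A / helix B angle,
#' the metric for opening and closing of the cNTnC hydrophobic patch.
#' Symmetric in its arguments.
#'
#' @param ma,mb C-alpha coordinate matrices of the two helices
#'   (see [helix_axis()]).
#' @return Angle in degrees.
#' @export
interhelix_angle <- function(ma, mb) {
  angle_deg(helix_axis(ma), helix_axis(mb))
}

#' Hinge angle at a pivot between two domain centroids
#'
#' Angle (degrees) at the pivot centroid between the vectors pointing to
#' the C-alpha centroids of the two quasi-rigid domains; the metric for
#' the hinge motion of NcTnC relative to the ITC domain.
#'
#' @param pivot Pivot coordinates (single point or matrix averaged to its
#'   centroid).
#' @param c1,c2 Domain C-alpha coordinate matrices (or centroids).
#' @return Angle in degrees within 0-180.
#' @export
hinge_angle <- function(pivot, c1, c2) {
  cen <- function(x) if (is.matrix(x)) colMeans(x) else as.numeric(x)
  p <- cen(pivot)
  v1 <- cen(c1) - p
  v2 <- cen(c2) - p
  if (sum(v1^2) < 1e-12 || sum(v2^2) < 1e-12) {
    abort("Hinge pivot coincides with a domain centroid; angle undefined.")
  }
  angle_deg(v1, v2)
}

ca_matrix <- function(traj, idx, frame) {
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  matrix(traj$xyz[frame, cols], ncol = 3L, byrow = TRUE)
}

# centroid of a selection for every frame: n_frames x 3
centroid_series <- function(traj, idx) {
  xs <- traj$xyz[, 3L * idx - 2L, drop = FALSE]
  ys <- traj$xyz[, 3L * idx - 1L, drop = FALSE]
  zs <- traj$xyz[, 3L * idx, drop = FALSE]
  cbind(rowMeans(xs), rowMeans(ys), rowMeans(zs))
}

metric_tibble <- function(traj, metric, value, condition) {
  tibble(
    run_id = traj$run_id,
    frame = seq_len(n_frames(traj)),
    time_ns = (seq_len(n_frames(traj)) - 1L) * traj$frame_interval_ns,
    metric = metric,
    value = value,
    condition = condition %||% NA_character_
  )
}

#' Per-frame helix A/B interhelix angle
#'
#' @param traj A `tn_trajectory`.
#' @param helix_a,helix_b [region()]s for the two helices; resolved with
#'   a C-alpha-only filter applied on top of the region definition.
#' @param condition Optional condition label carried into the output.
#' @return Tibble with columns `run_id`, `frame`, `time_ns`, `metric`
#'   (`"AB_helix"`), `value` (degrees), `condition`.
#' @export
ab_angle_series <- function(traj, helix_a, helix_b, condition = NULL) {
  top <- traj$topology
  ia <- resolve_region(top, helix_a)
  ib <- resolve_region(top, helix_b)
  ia <- ia[top$atom_name[ia] == "CA"]
  ib <- ib[top$atom_name[ib] == "CA"]
  if (length(ia) < 4L || length(ib) < 4L) {
    abort("Both helices need at least 4 C-alpha atoms.")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    interhelix_angle(ca_matrix(traj, ia, f), ca_matrix(traj, ib, f))
  }, numeric(1))
  metric_tibble(traj, "AB_helix", vals, condition)
}

#' Per-frame interdomain hinge angle
#'
#' @inheritParams ab_angle_series
#' @param domain1,domain2 [region()]s for the two quasi-rigid domains
#'   (C-alpha filtered); must be disjoint from the pivot.
#' @param pivot [region()] resolving to >= 1 atom; its centroid is the
#'   hinge vertex.
#' @return Tibble as in [ab_angle_series()] with metric `"hinge"`.
#' @export
hinge_angle_series <- function(traj, domain1, domain2, pivot,
                               condition = NULL) {
  top <- traj$topology
  i1 <- resolve_region(top, domain1)
  i2 <- resolve_region(top, domain2)
  ip <- resolve_region(top, pivot)
  i1 <- i1[top$atom_name[i1] == "CA"]
  i2 <- i2[top$atom_name[i2] == "CA"]
  if (length(intersect(ip, c(i1, i2)))) {
    abort("Hinge domains must be disjoint from the pivot selection.")
  }
  p <- centroid_series(traj, ip)
  v1 <- centroid_series(traj, i1) - p
  v2 <- centroid_series(traj, i2) - p
  n1 <- rowSums(v1^2)
  n2 <- rowSums(v2^2)
  if (any(n1 < 1e-12) || any(n2 < 1e-12)) {
    abort("Hinge pivot coincides with a domain centroid in some frame.")
  }
  cosang <- rowSums(v1 * v2) / sqrt(n1 * n2)
  vals <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  metric_tibble(traj, "hinge", vals, condition)
}

#' Per-frame distance between two domain centroids
#'
#' Euclidean distance (Angstrom) between the C-alpha centroids of two
#' domains, per frame.
#'
#' @inheritParams hinge_angle_series
#' @return Tibble as in [ab_angle_series()] with metric
#'   `"interdomain_distance"` and values in Angstrom.
#' @export
interdomain_distance_series <- function(traj, domain1, domain2,
                                        condition = NULL) {
  top <- traj$topology
  i1 <- resolve_region(top, domain1)
  i2 <- resolve_region(top, domain2)
  i1 <- i1[top$atom_name[i1] == "CA"]
  i2 <- i2[top$atom_name[i2] == "CA"]
  d <- centroid_series(traj, i1) - centroid_series(traj, i2)
  metric_tibble(traj, "interdomain_distance", sqrt(rowSums(d^2)), condition)
}

# per-frame minimum distance between two atom selections
min_dist_series <- function(traj, ia, ib) {
  nf <- n_frames(traj)
  best <- rep(Inf, nf)
  for (a in ia) {
    ax <- traj$xyz[, 3L * a - 2L]
    ay <- traj$xyz[, 3L * a - 1L]
    az <- traj$xyz[, 3L * a]
    for (b in ib) {
      d2 <- (ax - traj$xyz[, 3L * b - 2L])^2 +
        (ay - traj$xyz[, 3L * b - 1L])^2 +
        (az - traj$xyz[, 3L * b])^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Charged-pair (salt-bridge) bond occupancy
#'
#' Fraction of frames in which the minimum distance between any atom of
#' the two charged selections is below the cutoff (strict), e.g. the TnC
#' Asp159 carboxylate oxygens against the Arg83 guanidinium nitrogens
#' across the interdomain hinge. For wild-type Gly159 the acidic
#' selection is empty and the occupancy is 0 by definition.
#'
#' @param traj A `tn_trajectory`.
#' @param region_a,region_b [region()]s of the two charged atom sets
#'   (either may resolve empty, giving occupancy 0).
#' @param cutoff Distance cutoff in Angstrom (> 0); default 4.0, the
#'   conventional ionic-contact threshold.
#' @param condition Optional condition label.
#' @return A list of class `tn_occupancy`: `probability` in 0-1,
#'   `series` tibble (`run_id`, `frame`, `bound`, `min_dist`), `cutoff`.
#' @export
pair_bond_occupancy <- function(traj, region_a, region_b, cutoff = 4,
                                condition = NULL) {
  if (cutoff <= 0) abort("cutoff must be positive.")
  top <- traj$topology
  ia <- resolve_region(top, region_a, allow_empty = TRUE)
  ib <- resolve_region(top, region_b, allow_empty = TRUE)
  nf <- n_frames(traj)
  if (length(ia) == 0L || length(ib) == 0L) {
    dmin <- rep(Inf, nf)
  } else {
    dmin <- min_dist_series(traj, ia, ib)
  }
  bound <- dmin < cutoff
  structure(
    list(
      probability = mean(bound),
      series = tibble(run_id = traj$run_id, frame = seq_len(nf),
                      bound = bound, min_dist = dmin,
                      condition = condition %||% NA_character_),
      cutoff = cutoff
    ),
    class = "tn_occupancy"
  )
}

#' @export
print.tn_occupancy <- function(x, ...) {
  cat("<occupancy> ", format(x$probability, digits = 3), " of ",
      nrow(x$series), " frames bound (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}
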