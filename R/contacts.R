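#' Per-frame ligand-residue contact series
#'
#' A ligand is in contact with a residue in a frame when the minimal
#' distance between any atom of the ligand and any atom of the residue is
#' strictly lower than the cutoff (2.5 Angstrom by default). Hydrogens,
#' when present, participate; pass `heavy_only = TRUE` to restrict both
#' selections to non-hydrogen atoms.
#'
#' @param traj A `tn_trajectory`.
#' @param ligand [region()] selecting the ligand atoms.
#' @param chain,resno Chain ID and residue number of the residue.
#' @param cutoff Contact cutoff in Angstrom (> 0), strict `<`.
#' @param heavy_only Drop hydrogen atoms from both selections.
#' @return Tibble (`run_id`, `frame`, `chain`, `resno`, `contact`).
#' @export
residue_contact_series <- function(traj, ligand, chain, resno, cutoff = 2.5,
                                   heavy_only = FALSE) {
  if (cutoff <= 0) abort("cutoff must be positive.")
  top <- traj$topology
  il <- resolve_region(top, ligand)
  ir <- top$atom[top$chain == chain & top$resno == resno]
  if (length(ir) == 0L) {
    abort(paste0("Residue ", chain, ":", resno, " not found in topology."))
  }
  if (heavy_only) {
    il <- il[top$element[il] != "H"]
    ir <- ir[top$element[ir] != "H"]
  }
  dmin <- min_dist_series(traj, il, ir)
  tibble(run_id = traj$run_id, frame = seq_len(n_frames(traj)),
         chain = chain, resno = resno, contact = dmin < cutoff)
}

#' Per-residue ligand contact probabilities
#'
#' Applies the minimal-distance contact criterion residue-wise across the
#' whole protein, returning for every protein residue the fraction of
#' frames it is contacted by the ligand.
#'
#' @inheritParams residue_contact_series
#' @param protein Optional [region()] restricting which residues are
#'   profiled; default is every non-ligand residue (ligand atoms and any
#'   residue overlapping the ligand selection are excluded).
#' @return A `tn_contact_profile` tibble: `chain`, `resno`, `resname`,
#'   `probability`, plus attributes `cutoff` and `n_frames`.
#' @export
contact_profile <- function(traj, ligand, protein = NULL, cutoff = 2.5,
                            heavy_only = FALSE) {
  if (cutoff <= 0) abort("cutoff must be positive.")
  top <- traj$topology
  il <- resolve_region(top, ligand)
  if (heavy_only) il <- il[top$element[il] != "H"]
  if (is.null(protein)) {
    ipro <- setdiff(top$atom, il)
  } else {
    ipro <- setdiff(resolve_region(top, protein), il)
  }
  if (length(ipro) == 0L) abort("Protein selection is empty.")
  res <- top[top$atom %in% ipro, ] |>
    dplyr::distinct(.data$chain, .data$resno, .data$resname)
  probs <- purrr::map_dbl(seq_len(nrow(res)), function(i) {
    ir <- top$atom[top$chain == res$chain[i] & top$resno == res$resno[i]]
    ir <- intersect(ir, ipro)
    if (heavy_only) ir <- ir[top$element[ir] != "H"]
    mean(min_dist_series(traj, il, ir) < cutoff)
  })
  out <- res |>
    mutate(probability = probs) |>
    arrange(.data$chain, .data$resno)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- n_frames(traj)
  class(out) <- c("tn_contact_profile", class(out))
  out
}

#' Contact hotspots above a probability threshold
#'
#' Residues whose ligand-contact probability exceeds the threshold
#' (strictly), mirroring the "interactions present more than 10 percent
#' of the time" hotspot convention. Sorted by probability descending,
#' ties broken by (chain, residue) ascending.
#'
#' @param profile A [contact_profile()] result (or any tibble with
#'   `chain`, `resno`, `probability`).
#' @param threshold Probability threshold in [0, 1); strict `>`.
#' @return Tibble of hotspot residues.
#' @export
contact_hotspots <- function(profile, threshold = 0.10) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    abort("threshold must lie in [0, 1).")
  }
  profile |>
    as_tibble() |>
    filter(.data$probability > threshold) |>
    arrange(desc(.data$probability), .data$chain, .data$resno)
}

#' Ligand attachment fraction and bound/unbound episodes
#'
#' A frame is "attached" when the minimal ligand-protein atom distance is
#' strictly below the cutoff. Episodes are maximal runs of constant
#' bound/unbound state in raw per-frame order (no smoothing by default;
#' `debounce` merges runs shorter than the given number of frames into
#' their neighbours).
#'
#' @inheritParams residue_contact_series
#' @param protein [region()] of the protein atoms.
#' @param debounce Minimum episode length in frames; shorter runs are
#'   absorbed. Default 0 (raw states).
#' @return A list of class `tn_attachment`: `fraction_attached`,
#'   `episodes` tibble (`start_frame`, `end_frame`, `bound`, `length`),
#'   `mean_bound_episode_length`, `n_frames`, `cutoff`.
#' @export
ligand_attachment <- function(traj, ligand, protein, cutoff = 2.5,
                              heavy_only = FALSE, debounce = 0L) {
  if (cutoff <= 0) abort("cutoff must be positive.")
  top <- traj$topology
  il <- resolve_region(top, ligand)
  ipro <- setdiff(resolve_region(top, protein), il)
  if (heavy_only) {
    il <- il[top$element[il] != "H"]
    ipro <- ipro[top$element[ipro] != "H"]
  }
  if (length(il) == 0L || length(ipro) == 0L) {
    abort("Ligand and protein selections must be non-empty.")
  }
  bound <- min_dist_series(traj, il, ipro) < cutoff
  if (debounce > 0L) bound <- debounce_states(bound, debounce)
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  episodes <- tibble(
    start_frame = c(1L, head(ends, -1L) + 1L),
    end_frame = ends,
    bound = r$values,
    length = r$lengths
  )
  structure(
    list(
      fraction_attached = mean(bound),
      episodes = episodes,
      mean_bound_episode_length =
        if (any(episodes$bound)) mean(episodes$length[episodes$bound])
        else NA_real_,
      n_frames = n_frames(traj),
      cutoff = cutoff
    ),
    class = "tn_attachment"
  )
}

debounce_states <- function(x, min_len) {
  repeat {
    r <- rle(x)
    if (length(r$lengths) <= 1L) return(x)
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) return(x)
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    x <- inverse.rle(r)
  }
}

#' @export
print.tn_attachment <- function(x, ...) {
  cat("<attachment> fraction ", format(x$fraction_attached, digits = 3),
      " over ", x$n_frames, " frames; ", nrow(x$episodes),
      " episodes (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}
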