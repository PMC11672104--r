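#' Construct a trajectory object
#'
#' A trajectory binds an n_frames x (3 * n_atoms) coordinate matrix (in
#' Angstrom, bio3d "xyz" layout: x1, y1, z1, x2, ...) to a topology, with
#' a frame interval in ns and a run identifier.
#'
#' @param xyz Numeric matrix, frames x 3*n_atoms, finite.
#' @param topology A `tn_topology` with matching atom count.
#' @param frame_interval_ns Time between frames, ns. The default 0.4 ns
#'   corresponds to 1500 ns sampled as 3750 frames.
#' @param run_id Run label.
#' @return A `tn_trajectory` object.
#' @export
trajectory <- function(xyz, topology, frame_interval_ns = 0.4,
                       run_id = "run1") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(topology)) {
    abort(paste0("Coordinate columns (", ncol(xyz), ") do not match 3 x ",
                 nrow(topology), " topology atoms."))
  }
  if (nrow(xyz) < 1L) abort("Trajectory must contain at least one frame.")
  if (!all(is.finite(xyz))) abort("Trajectory coordinates must be finite.")
  structure(
    list(xyz = xyz, topology = topology,
         frame_interval_ns = frame_interval_ns, run_id = run_id),
    class = "tn_trajectory"
  )
}

#' @export
print.tn_trajectory <- function(x, ...) {
  cat("<trajectory> ", x$run_id, ": ", n_frames(x), " frames x ",
      nrow(x$topology), " atoms, ", x$frame_interval_ns, " ns/frame\n",
      sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `tn_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#' @param traj A `tn_trajectory`.
#' @param i Frame index (1-based).
#' @return n_atoms x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Read a trajectory file
#'
#' Reads a multi-model PDB or a (CHARMM-style) DCD trajectory against a
#' topology. Coordinates are returned in Angstrom; frame order is
#' preserved. XTC is not supported; convert to DCD or multi-model PDB
#' upstream.
#'
#' @param path Trajectory file (`.pdb` or `.dcd`; format sniffed from the
#'   extension unless given).
#' @param topology `tn_topology` the frames must match. For PDB input it
#'   may be NULL, in which case the topology is read from the same file.
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @param frame_interval_ns ns per frame (metadata only; default 0.4).
#' @param run_id Run label.
#' @return A `tn_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "pdb", "dcd"),
                            frame_interval_ns = 0.4, run_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Trajectory file not found: ", path))
  if (file.size(path) == 0L) abort(paste0("Trajectory file is empty: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  run_id <- run_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "pdb") {
    if (is.null(topology)) topology <- read_topology(path)
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) abort(paste0("Failed to parse multi-model PDB '",
                                       path, "': ", conditionMessage(e)))
    )
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * nrow(topology)) {
      abort(paste0("Atom count mismatch: file has ", ncol(xyz) / 3,
                   " atoms per frame, topology has ", nrow(topology), "."))
    }
  } else {
    if (is.null(topology)) abort("DCD input requires an explicit topology.")
    xyz <- tryCatch(
      bio3d::read.dcd(path, verbose = FALSE),
      error = function(e) abort(paste0("Failed to parse DCD '", path,
                                       "': ", conditionMessage(e)))
    )
    xyz <- unclass(xyz)
    if (ncol(xyz) != 3L * nrow(topology)) {
      abort(paste0("Atom count mismatch: DCD has ", ncol(xyz) / 3,
                   " atoms per frame, topology has ", nrow(topology), "."))
    }
  }
  trajectory(xyz, topology, frame_interval_ns = frame_interval_ns,
             run_id = run_id)
}

#' Write a trajectory to disk
#'
#' Writes either a multi-model PDB (via bio3d, one MODEL per frame,
#' 0.001 Angstrom coordinate precision) or a single-precision CHARMM DCD.
#'
#' @param traj A `tn_trajectory`.
#' @param path Output path.
#' @param format `"pdb"` or `"dcd"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  top <- traj$topology
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path, xyz = traj$xyz,
      type = ifelse(top$het, "HETATM", "ATOM"),
      resno = top$resno, chain = top$chain, resid = top$resname,
      elety = top$atom_name, elesy = top$element
    )
  } else {
    write_dcd(traj$xyz, path)
  }
  invisible(path)
}

#' Write a topology as a single-frame PDB
#'
#' @param topology A `tn_topology`.
#' @param xyz One frame of coordinates (n_atoms x 3 matrix or length-3n
#'   vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, xyz, path) {
  if (is.matrix(xyz) && ncol(xyz) == 3L) xyz <- as.numeric(t(xyz))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(topology$het, "HETATM", "ATOM"),
    resno = topology$resno, chain = topology$chain,
    resid = topology$resname, elety = topology$atom_name,
    elesy = topology$element
  )
  invisible(path)
}

# Minimal CHARMM-format DCD writer (single precision, no unit cell).
# bio3d reads DCD but does not write it; read.dcd serves as the
# independent reader in the round-trip tests.
write_dcd <- function(xyz, path) {
  xyz <- as.matrix(xyz)
  nframes <- nrow(xyz)
  natoms <- ncol(xyz) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length marker, payload, length marker
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nframes   # NSET
  icntrl[2] <- 1L        # ISTART
  icntrl[3] <- 1L        # NSAVC
  icntrl[4] <- nframes
  icntrl[20] <- 24L      # CHARMM version flag
  rec(function(c.) {
    writeChar("CORD", c., nchars = 4L, eos = NULL)
    writeBin(icntrl, c., size = 4L)
  })
  title <- sprintf("%-80s", "Synthetic trajectory written by tncoupling")
  rec(function(c.) {
    writeBin(1L, c., size = 4L)
    writeChar(title, c., nchars = 80L, eos = NULL)
  })
  rec(function(c.) writeBin(natoms, c., size = 4L))
  ix <- seq(1L, 3L * natoms, by = 3L)
  for (f in seq_len(nframes)) {
    fr <- xyz[f, ]
    rec(function(c.) writeBin(fr[ix], c., size = 4L))
    rec(function(c.) writeBin(fr[ix + 1L], c., size = 4L))
    rec(function(c.) writeBin(fr[ix + 2L], c., size = 4L))
  }
  invisible(path)
}
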