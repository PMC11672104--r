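#' Read a PDB topology
#'
#' Parses ATOM and HETATM records of a PDB file into a topology table.
#' HETATM atoms (ligands, ions) are retained and flagged in the `het`
#' column so they can be selected as a [region()]. Residue numbering is
#' kept 1-based per chain exactly as authored in the file; no renumbering
#' is performed, so residue identities such as Ser22/23, Arg83 or Gly159
#' refer to the source numbering.
#'
#' @param path Path to a PDB file.
#' @return A `tn_topology`: a tibble with one row per atom and columns
#'   `atom` (1-based index, contiguous), `atom_name`, `element`, `resno`,
#'   `resname`, `chain`, `het` (logical, TRUE for HETATM records).
#' @details Files with residue insertion codes are rejected with an error
#'   rather than silently renumbered. Duplicate (chain, resno, atom_name)
#'   keys are an error.
#' @examples
#' pdb <- system.file("extdata", "toy.pdb", package = "tncoupling")
#' top <- read_topology(pdb)
#' dplyr::count(top, chain)
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  if (file.size(path) == 0L) {
    abort(paste0("PDB file is empty: ", path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("Failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  atoms <- pdb$atom
  if (nrow(atoms) == 0L) abort(paste0("No ATOM/HETATM records in ", path))
  ins <- atoms$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    bad <- which(!is.na(ins) & nzchar(trimws(ins)))[1]
    abort(paste0(
      "Residue insertion codes are not supported (first at ",
      atoms$chain[bad], atoms$resno[bad], atoms$insert[bad],
      "); renumber the structure before loading."
    ))
  }
  elem <- atoms$elesy
  missing_elem <- is.na(elem) | !nzchar(trimws(elem))
  if (any(missing_elem)) {
    # fall back to the leading letter of the atom name
    elem[missing_elem] <- substr(gsub("[^A-Za-z].*", "",
                                      atoms$elety[missing_elem]), 1, 1)
  }
  top <- tibble(
    atom = seq_len(nrow(atoms)),
    atom_name = trimws(atoms$elety),
    element = trimws(elem),
    resno = as.integer(atoms$resno),
    resname = trimws(atoms$resid),
    chain = as.character(atoms$chain),
    het = atoms$type == "HETATM"
  )
  top$chain[is.na(top$chain)] <- " "
  key <- paste(top$chain, top$resno, top$atom_name, sep = "/")
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate atom key (chain/resno/atom_name): ",
                 key[duplicated(key)][1]))
  }
  new_topology(top)
}

new_topology <- function(df) {
  structure(as_tibble(df), class = c("tn_topology", class(as_tibble(df))))
}

#' Build a topology from an atom table
#'
#' Constructor used by the synthetic-trajectory generator and by tests;
#' validates the topology invariants (contiguous atom indices, unique
#' atom keys, every residue with at least one atom).
#'
#' @param atoms Data frame with columns `atom_name`, `element`, `resno`,
#'   `resname`, `chain` and optionally `het` (default FALSE).
#' @return A `tn_topology` tibble.
#' @export
as_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("atom_name", "element", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste0("Missing topology columns: ",
                                 paste(miss, collapse = ", ")))
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$atom <- seq_len(nrow(atoms))
  atoms <- atoms[, c("atom", need, "het")]
  key <- paste(atoms$chain, atoms$resno, atoms$atom_name, sep = "/")
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate atom key: ", key[duplicated(key)][1]))
  }
  new_topology(atoms)
}

#' Define a chain/residue region of a topology
#'
#' A region is a labelled selection: one or more (chain, residue-range)
#' members with an optional atom-name filter, resolved against a topology
#' with [resolve_region()]. Regions name the structural parts the metrics
#' operate on: helices A and B of cNTnC, the NcTnC and ITC domains, the
#' hinge pivot, charged side-chain atom sets, or the ligand.
#'
#' @param label Region label used in outputs and error messages.
#' @param chain Character vector of chain IDs (recycled against ranges).
#' @param res_start,res_end Integer vectors of 1-based residue-number
#'   ranges (inclusive); `NA` means all residues of the chain.
#' @param atoms Optional character vector of atom names to keep
#'   (e.g. `c("OD1", "OD2")`); `NULL` keeps every atom.
#' @param calpha Logical; keep only C-alpha (`CA`) atoms.
#' @return A `tn_region` object.
#' @examples
#' helix_a <- region("helix_A", chain = "C", res_start = 14, res_end = 28,
#'                   calpha = TRUE)
#' @export
region <- function(label, chain, res_start = NA_integer_,
                   res_end = NA_integer_, atoms = NULL, calpha = FALSE) {
  members <- tibble(
    chain = as.character(chain),
    res_start = as.integer(res_start),
    res_end = as.integer(res_end)
  )
  bad <- !is.na(members$res_start) & !is.na(members$res_end) &
    members$res_end < members$res_start
  if (any(bad)) abort(paste0("region '", label, "': res_end < res_start"))
  structure(
    list(label = label, members = members, atoms = atoms,
         calpha = isTRUE(calpha)),
    class = "tn_region"
  )
}

#' @export
print.tn_region <- function(x, ...) {
  rng <- ifelse(is.na(x$members$res_start), "all",
                paste0(x$members$res_start, "-", x$members$res_end))
  cat("<region> ", x$label, ": ",
      paste0(x$members$chain, ":", rng, collapse = ", "),
      if (x$calpha) " [CA only]" else "",
      if (!is.null(x$atoms)) paste0(" [atoms ",
                                    paste(x$atoms, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Resolve a region to atom indices
#'
#' Deterministically maps a [region()] onto a topology, returning the
#' selected atom indices in increasing order. Overlapping member ranges
#' yield the union without duplicates; the result is invariant to atom
#' record order within a residue because indices are sorted.
#'
#' @param topology A `tn_topology`.
#' @param region A `tn_region`.
#' @param allow_empty If FALSE (default) an empty selection is an error
#'   naming the region; if TRUE an empty integer vector is returned
#'   (needed e.g. for wild-type Gly159, which has no carboxylate atoms).
#' @return Sorted integer vector of atom indices.
#' @export
resolve_region <- function(topology, region, allow_empty = FALSE) {
  stopifnot(inherits(region, "tn_region"))
  sel <- rep(FALSE, nrow(topology))
  for (i in seq_len(nrow(region$members))) {
    m <- region$members[i, ]
    hit <- topology$chain == m$chain
    if (!is.na(m$res_start)) {
      hit <- hit & topology$resno >= m$res_start & topology$resno <= m$res_end
    }
    sel <- sel | hit
  }
  if (region$calpha) sel <- sel & topology$atom_name == "CA"
  if (!is.null(region$atoms)) sel <- sel & topology$atom_name %in% region$atoms
  idx <- sort(topology$atom[sel])
  if (length(idx) == 0L && !allow_empty) {
    abort(paste0("Region '", region$label,
                 "' selects no atoms in this topology."))
  }
  idx
}
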