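# Structure and trajectory I/O.
#
# All parsing and writing of PDB files is delegated to bio3d; this module
# wraps it in a uniform labeled-coordinate view ("eded_structure",
# "eded_trajectory") consumed by the rest of the pipeline. Atom order is
# never permuted by any operation here.

.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "HSD","HSE","HSP","HID","HIE","HIP","MSE")

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

# standard atomic masses of the elements seen in protein/ligand PDBs
.ELEMENT_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971, F = 18.998,
                   CL = 35.45, BR = 79.904, I = 126.904, FE = 55.845,
                   ZN = 65.38, MG = 24.305, CA = 40.078, MN = 54.938,
                   `NA` = 22.99, K = 39.098, CU = 63.546)

element_mass <- function(element) {
  m <- .ELEMENT_MASS[toupper(element)]
  m[is.na(m)] <- 12.011   # unknown elements fall back to carbon mass
  unname(m)
}

# (chain, resno, resname) key, one per atom
residue_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$resid, sep = ":")
}

new_structure <- function(atom, coords) {
  stopifnot(is.data.frame(atom), is.null(coords) || nrow(coords) == nrow(atom))
  structure(list(atom = atom, coords = coords), class = "eded_structure")
}

new_trajectory <- function(topology, xyz, frame_interval = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(topology$atom))
    abort_eded(sprintf("trajectory frames have %d coordinates but topology has %d atoms",
                       ncol(xyz), nrow(topology$atom)), "atom_mismatch")
  if (nrow(xyz) < 1L) abort_eded("trajectory contains no frames", "empty_trajectory")
  structure(list(topology = topology, xyz = xyz, frame_interval = frame_interval),
            class = "eded_trajectory")
}

#' @export
print.eded_structure <- function(x, ...) {
  cat(sprintf("<eded_structure> %d atoms, %d residues, %d ligand atoms\n",
              nrow(x$atom), length(unique(residue_key(x$atom))),
              sum(x$atom$is_ligand)))
  invisible(x)
}

#' @export
print.eded_trajectory <- function(x, ...) {
  cat(sprintf("<eded_trajectory> %d frames x %d atoms\n",
              nrow(x$xyz), nrow(x$topology$atom)))
  invisible(x)
}

# frame f of a trajectory as an n x 3 coordinate matrix
frame_coords <- function(traj, f) {
  matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
}

coords_to_xyz <- function(m) as.vector(t(m))

annotate_atoms <- function(atom, ligand_residue_name = NULL) {
  elety <- trimws(atom$elety)
  element <- atom$elesy
  need <- is.na(element) | !nzchar(trimws(element %||% ""))
  if (is.null(element)) {
    element <- rep(NA_character_, length(elety))
    need <- rep(TRUE, length(elety))
  }
  if (any(need))
    element[need] <- suppressWarnings(bio3d::atom2ele(elety[need], rescue = TRUE))
  element <- trimws(element)
  mass <- element_mass(element)
  is_ligand <- if (is.null(ligand_residue_name)) rep(FALSE, nrow(atom))
               else atom$resid %in% ligand_residue_name
  is_protein <- atom$resid %in% .AA3 & !is_ligand
  data.frame(
    eleno = atom$eleno, elety = elety, resid = atom$resid,
    chain = ifelse(is.na(atom$chain), "A", atom$chain), resno = atom$resno,
    element = element, mass = mass,
    is_hydrogen = element %in% c("H", "D"),
    is_backbone = is_protein & elety %in% .BACKBONE_NAMES,
    is_protein = is_protein, is_ligand = is_ligand,
    stringsAsFactors = FALSE)
}

# keep the first altloc of each (chain, resno, insert, name) site
drop_altlocs <- function(raw) {
  alt <- raw$alt
  if (all(is.na(alt))) return(raw)
  key <- paste(raw$chain, raw$resno, raw$insert, raw$elety)
  keep <- is.na(alt) | !duplicated(key)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    warning(sprintf("dropped %d alternate-location atoms (kept first altloc)", n_drop),
            call. = FALSE)
  raw[keep, , drop = FALSE]
}

#' Read a (single-model) PDB structure with atom role labels
#'
#' Parses a PDB file and returns a labeled structure: per-atom residue
#' identity, element, backbone/side-chain role, hydrogen flag, and ligand
#' membership. Only the first model of a multi-model file is used. When a
#' file carries alternate locations, the first altloc of each atom site is
#' kept and the rest dropped with a warning.
#'
#' @param path Path to a PDB file.
#' @param ligand_residue_name Residue name(s) identifying the ligand, e.g.
#'   `"LIG"`. Use `NULL` for a ligand-free structure (e.g. a trajectory
#'   topology).
#' @return An `eded_structure`: a list with `atom` (data frame of per-atom
#'   labels) and `coords` (n x 3 matrix, Angstrom).
#' @export
read_structure <- function(path, ligand_residue_name = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    abort_eded(sprintf("cannot parse PDB file '%s': %s",
                                       path, conditionMessage(e)), "parse_error"))
  raw <- drop_altlocs(pdb$atom)
  atom <- annotate_atoms(raw, ligand_residue_name)
  if (!is.null(ligand_residue_name) && !any(atom$is_ligand))
    abort_eded(sprintf("no atoms with ligand residue name '%s' found",
                       paste(ligand_residue_name, collapse = ",")),
               "ligand_not_found")
  new_structure(atom, cbind(raw$x, raw$y, raw$z))
}

#' Read an MD trajectory (multi-model PDB or DCD) against a PDB topology
#'
#' @param topology_path Path to a PDB file providing atom labels (its
#'   coordinates, if any, are ignored).
#' @param traj_path Path to the coordinate source: a multi-model PDB or a
#'   CHARMM/NAMD DCD file (recognised by its `.dcd` extension). Defaults to
#'   `topology_path`, covering the common case of a self-contained
#'   multi-model PDB.
#' @param frame_interval Optional time per frame, ps (metadata only).
#' @return An `eded_trajectory`: `topology` (an `eded_structure` without
#'   coordinates) plus `xyz`, an F x 3n frame matrix in file order.
#' @export
read_trajectory <- function(topology_path, traj_path = topology_path,
                            frame_interval = NULL) {
  top <- read_structure(topology_path)
  top$coords <- NULL
  ext <- tolower(tools::file_ext(traj_path))
  xyz <- if (ext == "dcd") {
    tryCatch(unclass(bio3d::read.dcd(traj_path, verbose = FALSE)),
             error = function(e)
               abort_eded(sprintf("cannot parse DCD file '%s': %s",
                                  traj_path, conditionMessage(e)), "parse_error"))
  } else {
    pdb <- tryCatch(bio3d::read.pdb(traj_path, multi = TRUE, verbose = FALSE),
                    error = function(e)
                      abort_eded(sprintf("cannot parse PDB file '%s': %s",
                                         traj_path, conditionMessage(e)), "parse_error"))
    unclass(pdb$xyz)
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 1L) abort_eded("trajectory contains no frames", "empty_trajectory")
  new_trajectory(top, xyz, frame_interval)
}

write_structure_file <- function(atom, coords, file, remarks = NULL) {
  bio3d::write.pdb(file = file, xyz = coords_to_xyz(coords),
                   resno = atom$resno, resid = atom$resid,
                   eleno = atom$eleno, elety = atom$elety,
                   chain = atom$chain, elesy = atom$element)
  if (!is.null(remarks)) {
    body <- readLines(file)
    writeLines(c(paste("REMARK  ", remarks), body), file)
  }
  invisible(file)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj An `eded_trajectory`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  a <- traj$topology$atom
  bio3d::write.pdb(file = file, xyz = traj$xyz,
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain, elesy = a$element)
  invisible(file)
}

#' Export representative frames as single-model PDB files
#'
#' Writes one PDB per selected frame, named by cluster label so that files
#' sort stably (`representative_c<label>_f<frame>.pdb`). The source frame
#' index is recorded in a REMARK header line.
#'
#' @param traj An `eded_trajectory`.
#' @param frame_indices Frame index per cluster (1-based).
#' @param out_dir Output directory (created if needed).
#' @param cluster_labels Optional cluster label per index; defaults to
#'   `seq_along(frame_indices) - 1` (clusters numbered from 0 by
#'   population).
#' @return Character vector of written file paths, ordered by cluster label.
#' @export
write_representatives <- function(traj, frame_indices, out_dir,
                                  cluster_labels = seq_along(frame_indices) - 1L) {
  n_frames <- nrow(traj$xyz)
  bad <- frame_indices < 1L | frame_indices > n_frames
  if (any(bad))
    abort_eded(sprintf("frame index out of range [1, %d]: %s", n_frames,
                       paste(frame_indices[bad], collapse = ",")),
               "index_out_of_range")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ord <- order(cluster_labels)
  paths <- character(length(ord))
  for (j in seq_along(ord)) {
    i <- ord[j]
    f <- frame_indices[i]
    path <- file.path(out_dir, sprintf("representative_c%d_f%06d.pdb",
                                       cluster_labels[i], f))
    write_structure_file(traj$topology$atom, frame_coords(traj, f), path,
                         remarks = sprintf("cluster %d representative, trajectory frame %d",
                                           cluster_labels[i], f))
    paths[j] <- path
  }
  paths
}
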