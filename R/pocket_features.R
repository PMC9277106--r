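# Pocket definition, frame superposition, and center-of-mass featurization.
#
# The binding pocket is taken from the static reference complex: every
# residue whose side chain comes within a cutoff (default 3 Angstrom) of
# any ligand atom. Each trajectory frame is then rigidly superposed on the
# reference over a core residue range (C-alpha atoms) and the mass-weighted
# centers of mass of the pocket residues become the frame's features.
# Distances use heavy atoms only and are plain Euclidean (frames are
# assumed whole, no periodic imaging).

min_cross_dist <- function(a, b) {
  # minimum Euclidean distance between two point sets (rows)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Select binding-pocket residues by side-chain contact with the ligand
#'
#' A residue belongs to the pocket iff the minimum distance between its
#' side-chain heavy atoms and any ligand heavy atom is at most `cutoff`.
#' Glycine has no side-chain heavy atoms, so its C-alpha substitutes (a
#' message is emitted when this rule fires).
#'
#' @param ref An `eded_structure` containing ligand atoms (see
#'   [read_structure()]).
#' @param cutoff Contact cutoff, Angstrom. Default 3.0.
#' @return An `eded_pocket`: `residues` (data frame chain/resno/resname,
#'   sorted, duplicate-free), `cutoff`, and `source`.
#' @export
select_pocket <- function(ref, cutoff = 3.0) {
  atom <- ref$atom
  lig <- which(atom$is_ligand & !atom$is_hydrogen)
  if (length(lig) == 0L)
    abort_eded("reference structure has no ligand heavy atoms", "ligand_not_found")
  lig_xyz <- ref$coords[lig, , drop = FALSE]

  prot <- atom$is_protein & !atom$is_hydrogen
  keys <- unique(residue_key(atom)[prot])
  sel <- character(0)
  info <- list()
  for (k in keys) {
    in_res <- residue_key(atom) == k & prot
    side <- which(in_res & !atom$is_backbone)
    if (length(side) == 0L) {        # Gly: fall back to C-alpha
      side <- which(in_res & atom$elety == "CA")
      if (length(side) > 0L)
        message(sprintf("residue %s has no side-chain heavy atoms; using CA for contact rule", k))
    }
    if (length(side) == 0L) next
    d <- min_cross_dist(ref$coords[side, , drop = FALSE], lig_xyz)
    if (d <= cutoff) {
      sel <- c(sel, k)
      info[[k]] <- d
    }
  }
  if (length(sel) == 0L)
    abort_eded(sprintf("no residue side chain within %.2f Angstrom of the ligand; consider a larger cutoff",
                       cutoff), "empty_pocket")
  parts <- do.call(rbind, strsplit(sel, ":", fixed = TRUE))
  residues <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                         resname = parts[, 3], stringsAsFactors = FALSE)
  ord <- order(residues$chain, residues$resno)
  residues <- residues[ord, , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(residues = residues, cutoff = cutoff,
                 source = attr(ref, "source") %||% "reference"),
            class = "eded_pocket")
}

# Kabsch: optimal rotation/translation mapping P onto Q (n x 3 each).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cq - as.vector(R %*% cp)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

ca_key_coords <- function(atom, coords, align_range = NULL) {
  idx <- which(atom$is_protein & atom$elety == "CA")
  if (!is.null(align_range))
    idx <- idx[atom$resno[idx] >= align_range[1] & atom$resno[idx] <= align_range[2]]
  list(keys = residue_key(atom)[idx], coords = coords[idx, , drop = FALSE])
}

#' Rigid least-squares superposition of a frame onto the reference
#'
#' Finds the Kabsch-optimal rotation and translation over C-alpha atoms of
#' the alignment range (matched by chain/residue number/residue name
#' between frame topology and reference) and applies it to all frame
#' atoms. The reference never moves: it defines the laboratory frame.
#'
#' @param coords Frame coordinates, n x 3 (Angstrom), in `atoms` order.
#' @param atoms Atom table of the frame's topology (an `eded_structure` or
#'   its `atom` data frame).
#' @param ref Reference `eded_structure`.
#' @param align_range Optional residue-number interval `c(lo, hi)` (author
#'   numbering) restricting the C-alpha set; `NULL` uses all protein
#'   C-alphas.
#' @return List with the rotation `R` (3 x 3), translation `t`, transformed
#'   `coords`, and post-fit C-alpha `rmsd` (Angstrom).
#' @export
superpose <- function(coords, atoms, ref, align_range = NULL) {
  if (inherits(atoms, "eded_structure")) atoms <- atoms$atom
  fr <- ca_key_coords(atoms, coords, align_range)
  rf <- ca_key_coords(ref$atom, ref$coords, align_range)
  common <- intersect(fr$keys, rf$keys)
  if (length(common) < 3L)
    abort_eded(sprintf("only %d alignment C-alpha atoms shared with reference (need >= 3)",
                       length(common)), "too_few_alignment_atoms")
  P <- fr$coords[match(common, fr$keys), , drop = FALSE]
  Q <- rf$coords[match(common, rf$keys), , drop = FALSE]
  fit <- kabsch(P, Q)
  moved <- coords %*% t(fit$R) + matrix(fit$t, nrow(coords), 3, byrow = TRUE)
  list(R = fit$R, t = fit$t, coords = moved, rmsd = fit$rmsd)
}

#' Extract pocket center-of-mass features from a trajectory
#'
#' Superposes every frame on the reference (C-alpha Kabsch over
#' `align_range`) and records, per frame, the concatenated mass-weighted
#' centers of mass of the pocket residues' heavy atoms. `com_mode =
#' "residue"` (default) uses all heavy atoms of the residue;
#' `"sidechain"` restricts to side-chain heavy atoms (C-alpha for Gly).
#'
#' @param traj An `eded_trajectory`.
#' @param pocket An `eded_pocket` from [select_pocket()].
#' @param ref Reference `eded_structure` defining the laboratory frame.
#' @param align_range Optional residue interval for superposition.
#' @param com_mode `"residue"` or `"sidechain"`.
#' @return An `eded_features` matrix, F x 3m, with columns named
#'   `<chain>:<resno>:<resname>:<x|y|z>` and attributes `residue_order`,
#'   `align_range`, `com_mode`.
#' @export
extract_features <- function(traj, pocket, ref, align_range = NULL,
                             com_mode = c("residue", "sidechain")) {
  com_mode <- match.arg(com_mode)
  atom <- traj$topology$atom
  keys <- residue_key(atom)
  pocket_keys <- paste(pocket$residues$chain, pocket$residues$resno,
                       pocket$residues$resname, sep = ":")
  idx_sets <- lapply(pocket_keys, function(k) {
    in_res <- which(keys == k & !atom$is_hydrogen)
    if (length(in_res) == 0L)
      abort_eded(sprintf("pocket residue %s not present in trajectory topology", k),
                 "missing_pocket_residue")
    if (com_mode == "sidechain") {
      side <- in_res[!atom$is_backbone[in_res]]
      if (length(side) == 0L) side <- in_res[atom$elety[in_res] == "CA"]
      if (length(side) > 0L) in_res <- side
    }
    in_res
  })
  masses <- lapply(idx_sets, function(i) atom$mass[i])

  n_frames <- nrow(traj$xyz)
  out <- matrix(NA_real_, n_frames, 3L * length(pocket_keys))
  for (f in seq_len(n_frames)) {
    co <- superpose(frame_coords(traj, f), atom, ref, align_range)$coords
    row <- vapply(seq_along(idx_sets), function(j) {
      i <- idx_sets[[j]]
      colSums(co[i, , drop = FALSE] * masses[[j]]) / sum(masses[[j]])
    }, numeric(3))
    out[f, ] <- as.vector(row)
  }
  colnames(out) <- as.vector(t(outer(pocket_keys, c("x", "y", "z"), paste, sep = ":")))
  structure(out, class = c("eded_features", "matrix", "array"),
            residue_order = pocket_keys, align_range = align_range,
            com_mode = com_mode)
}
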