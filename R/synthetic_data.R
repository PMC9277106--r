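# Synthetic fixtures with known ground truth: toy receptor-ligand
# complexes, multi-state pocket trajectories, and docking-score tables.
#
# Structures carry plausible PDB atom and residue names so the I/O and
# featurization paths are exercised exactly as with real data. Residues
# are rigid alanine-like templates (N, CA, C, O, CB heavy atoms) whose
# mass-weighted center of mass is placed analytically, which makes
# pocket-selection distances and per-frame features exact by
# construction. Frame states are drawn i.i.d. from the requested
# populations, so cluster occupancies and the occupancy free energies
# -ln(p_i/p_1) are recoverable ground truth.

# Alanine-like heavy-atom template; offsets re-centered so the
# mass-weighted mean is exactly zero.
.res_template <- local({
  offs <- rbind(N  = c(-1.20,  0.80, 0.00),
                CA = c( 0.00,  0.00, 0.00),
                C  = c( 1.25,  0.75, 0.00),
                O  = c( 2.00,  1.60, 0.40),
                CB = c( 0.10, -1.45, 0.55))
  elements <- c("N", "C", "C", "O", "C")
  masses <- c(14.007, 12.011, 12.011, 15.999, 12.011)
  com <- colSums(offs * masses) / sum(masses)
  list(offsets = sweep(offs, 2, com), names = rownames(offs),
       elements = elements, masses = masses)
})

# rotation taking unit vector a to unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {   # antiparallel: rotate pi about any orthogonal axis
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

ligand_atom_table <- function(n, start_eleno) {
  data.frame(eleno = start_eleno + seq_len(n) - 1L,
             elety = paste0("C", seq_len(n)), alt = NA, resid = "LIG",
             chain = "B", resno = 900L, insert = NA, elesy = "C",
             stringsAsFactors = FALSE)
}

ligand_coords <- function(n) cbind(0, 0, -1.5 * (seq_len(n) - 1L))

#' Build a toy receptor-ligand complex with exact contact distances
#'
#' Constructs a fake peptide of alanine-like residues arranged radially
#' around a small ligand so that the minimum side-chain-to-ligand
#' heavy-atom distance of residue j equals `contact_distances[j]`
#' exactly. This makes pocket-selection boundary cases (e.g. 2.9 Angstrom
#' in, 3.1 Angstrom out at a 3 Angstrom cutoff) constructible.
#'
#' @param n_residues Number of protein residues.
#' @param ligand_atoms Number of ligand heavy atoms (all carbon).
#' @param contact_distances Length-`n_residues` vector of requested
#'   minimum side-chain-ligand distances, Angstrom (all > 0).
#' @param seed Integer seed controlling the radial arrangement.
#' @param file Optional path; when given the complex is also written as a
#'   single-model PDB.
#' @return An `eded_structure` with ligand residue name `"LIG"`.
#' @export
make_toy_complex <- function(n_residues, ligand_atoms = 1L, contact_distances,
                             seed = 1L, file = NULL) {
  if (n_residues < 1L || ligand_atoms < 1L)
    abort_eded("need at least one residue and one ligand atom", "bad_argument")
  if (length(contact_distances) != n_residues)
    abort_eded("one contact distance per residue required", "bad_argument")
  if (any(!is.finite(contact_distances)) || any(contact_distances <= 0))
    abort_eded("contact distances must be positive and finite", "infeasible_geometry")

  angles <- with_seed(seed, 2 * pi * seq_len(n_residues) / n_residues +
                              stats::runif(1, 0, 2 * pi))
  rows <- list(); coords <- list(); eleno <- 1L
  for (j in seq_len(n_residues)) {
    u <- c(cos(angles[j]), sin(angles[j]), 0)
    d <- contact_distances[j]
    # CB exactly at distance d from the ligand atom at the origin; all other
    # atoms strictly farther out along / beside the same radial direction
    pos <- rbind(CB = d * u,
                 CA = (d + 1.53) * u,
                 N  = (d + 2.40) * u + c(-0.4 * u[2], 0.4 * u[1], 0.3),
                 C  = (d + 2.45) * u + c(0.4 * u[2], -0.4 * u[1], 0.3),
                 O  = (d + 3.10) * u)
    ord <- c("N", "CA", "C", "O", "CB")
    rows[[j]] <- data.frame(eleno = eleno + seq_along(ord) - 1L, elety = ord,
                            alt = NA, resid = "ALA", chain = "A", resno = j,
                            insert = NA,
                            elesy = c("N", "C", "C", "O", "C"),
                            stringsAsFactors = FALSE)
    coords[[j]] <- pos[ord, , drop = FALSE]
    eleno <- eleno + length(ord)
  }
  raw <- rbind(do.call(rbind, rows), ligand_atom_table(ligand_atoms, eleno))
  xyz <- rbind(do.call(rbind, coords), ligand_coords(ligand_atoms))
  st <- new_structure(annotate_atoms(raw, "LIG"), unname(xyz))
  if (!is.null(file)) write_structure_file(st$atom, st$coords, file)
  st
}

#' Specify one metastable pocket state
#'
#' @param population Equilibrium fraction of frames in this state.
#' @param pocket_centers m x 3 matrix of reference pocket-residue
#'   center-of-mass positions, Angstrom.
#' @param sigma Isotropic Gaussian fluctuation of each center-of-mass
#'   coordinate about its state value, Angstrom.
#' @return A `state_spec` list.
#' @export
state_spec <- function(population, pocket_centers, sigma) {
  if (sigma <= 0) abort_eded("sigma must be positive", "bad_argument")
  structure(list(population = population, pocket_centers = pocket_centers,
                 sigma = sigma), class = "state_spec")
}

# Shared receptor geometry: m pocket residues with CB pointing at the
# ligand, plus a fixed outer scaffold ring used for superposition.
receptor_geometry <- function(m_pocket = 12L, n_scaffold = 8L,
                              ligand_atoms = 4L, cb_contact = 2.5) {
  tpl <- .res_template
  cb_r <- sqrt(sum(tpl$offsets["CB", ]^2))
  r_pocket <- cb_contact + cb_r
  golden <- pi * (3 - sqrt(5))
  place <- function(i, n, radius) {
    z <- (2 * (i - 0.5) / n - 1) * 0.8          # avoid poles
    rho <- sqrt(1 - z^2)
    phi <- golden * i
    radius * c(rho * cos(phi), rho * sin(phi), abs(z))  # upper hemisphere
  }
  pocket_com <- t(vapply(seq_len(m_pocket), place, numeric(3),
                         n = m_pocket, radius = r_pocket))
  scaffold_com <- t(vapply(seq_len(n_scaffold), place, numeric(3),
                           n = n_scaffold, radius = 15))
  cb_dir <- tpl$offsets["CB", ] / cb_r
  rots <- lapply(seq_len(m_pocket), function(j)
    rotation_between(cb_dir, -pocket_com[j, ] / sqrt(sum(pocket_com[j, ]^2))))
  srots <- lapply(seq_len(n_scaffold), function(j) diag(3))
  list(m_pocket = m_pocket, n_scaffold = n_scaffold,
       ligand_atoms = ligand_atoms, pocket_com = pocket_com,
       scaffold_com = scaffold_com, rotations = c(rots, srots),
       template = tpl)
}

receptor_atom_table <- function(geom) {
  n_res <- geom$m_pocket + geom$n_scaffold
  tpl <- geom$template
  rows <- lapply(seq_len(n_res), function(j)
    data.frame(eleno = (j - 1L) * 5L + seq_len(5L), elety = tpl$names,
               alt = NA, resid = "ALA", chain = "A", resno = j, insert = NA,
               elesy = tpl$elements, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# full-atom receptor coordinates for given pocket residue COMs
receptor_coords <- function(geom, pocket_com) {
  coms <- rbind(pocket_com, geom$scaffold_com)
  out <- matrix(NA_real_, nrow(coms) * 5L, 3L)
  for (j in seq_len(nrow(coms))) {
    at <- geom$template$offsets %*% t(geom$rotations[[j]])
    out[(j - 1L) * 5L + 1:5, ] <- sweep(at, 2, coms[j, ], "+")
  }
  out
}

#' Reference receptor-ligand complex of a synthetic pocket geometry
#'
#' The pocket residues' side chains point at the ligand and sit within
#' contact range, so [select_pocket()] at the default 3 Angstrom cutoff
#' recovers exactly the pocket residue set; scaffold residues lie far
#' outside.
#'
#' @param geom Geometry from the `geometry` element of
#'   [make_multistate_system()] (or `receptor_geometry()` defaults when
#'   omitted).
#' @param file Optional PDB output path.
#' @return An `eded_structure` with ligand `"LIG"`.
#' @export
make_reference_complex <- function(geom = NULL, file = NULL) {
  geom <- geom %||% receptor_geometry()
  prot <- receptor_atom_table(geom)
  lig <- ligand_atom_table(geom$ligand_atoms, max(prot$eleno) + 1L)
  raw <- rbind(prot, lig)
  xyz <- rbind(receptor_coords(geom, geom$pocket_com),
               ligand_coords(geom$ligand_atoms))
  st <- new_structure(annotate_atoms(raw, "LIG"), xyz)
  if (!is.null(file)) write_structure_file(st$atom, st$coords, file)
  st
}

#' Four-state synthetic pocket system (multi-state preset)
#'
#' Emulates the statistical structure the selection stage assumes: a
#' pocket with k metastable states of distinct geometry and fixed
#' populations. State 0 is the reference geometry; state i displaces
#' pocket residue i's center of mass outward by `separation * sigma`
#' Angstrom, so all pairwise state distances in feature space are at
#' least `separation * sigma`.
#'
#' @param populations State populations, descending (default
#'   0.5, 0.3, 0.15, 0.05).
#' @param sigma Per-coordinate Gaussian fluctuation, Angstrom
#'   (default 0.25).
#' @param separation Minimum inter-state distance in units of sigma
#'   (default 25).
#' @param m_pocket Number of pocket residues (default 12).
#' @return List: `states` (list of [state_spec()]), `geometry`, and
#'   `dg_conf_true` (-ln(p_i/p_1), kT).
#' @export
make_multistate_system <- function(populations = c(0.5, 0.3, 0.15, 0.05),
                                   sigma = 0.25, separation = 25,
                                   m_pocket = 12L) {
  if (abs(sum(populations) - 1) > 1e-9)
    abort_eded("state populations must sum to 1", "bad_populations")
  k <- length(populations)
  if (m_pocket < k - 1L)
    abort_eded("need at least k-1 pocket residues for distinct state geometries",
               "bad_argument")
  geom <- receptor_geometry(m_pocket = m_pocket)
  L <- separation * sigma
  states <- vector("list", k)
  for (i in seq_len(k)) {
    centers <- geom$pocket_com
    if (i > 1L) {
      j <- i - 1L                       # displace residue j outward
      u <- centers[j, ] / sqrt(sum(centers[j, ]^2))
      centers[j, ] <- centers[j, ] + L * u
    }
    states[[i]] <- state_spec(populations[i], centers, sigma)
  }
  list(states = states, geometry = geom,
       dg_conf_true = -log(populations / max(populations)))
}

#' Generate a multi-state pocket trajectory with known state labels
#'
#' Frame states are drawn i.i.d. from the state populations; each pocket
#' residue is rigidly re-posed around its state center of mass plus
#' isotropic Gaussian noise. With `rigid_jitter` a random rigid rotation
#' and translation is applied to every frame as a whole — superposition
#' during featurization must undo it exactly.
#'
#' @param states List of [state_spec()] (e.g. from
#'   [make_multistate_system()]).
#' @param n_frames Number of frames.
#' @param seed Integer RNG seed.
#' @param rigid_jitter Apply a per-frame random rigid transform.
#' @param geometry Receptor geometry (defaults to the states' pocket size).
#' @return List: `trajectory` (an `eded_trajectory`), `labels` (0-based
#'   true state per frame), `feature_centers` (k x 3m true state centers
#'   in feature space), `populations`.
#' @export
make_state_trajectory <- function(states, n_frames, seed = 1L,
                                  rigid_jitter = FALSE, geometry = NULL) {
  k <- length(states)
  if (n_frames < k)
    abort_eded("need at least as many frames as states", "bad_argument")
  m <- nrow(states[[1]]$pocket_centers)
  geom <- geometry %||% receptor_geometry(m_pocket = m)
  pops <- vapply(states, `[[`, 0, "population")
  atom <- receptor_atom_table(geom)
  n_atoms <- nrow(atom)

  labels <- integer(n_frames)
  xyz <- matrix(NA_real_, n_frames, 3L * n_atoms)
  with_seed(seed, {
    labels <- sample.int(k, n_frames, replace = TRUE, prob = pops)
    for (f in seq_len(n_frames)) {
      st <- states[[labels[f]]]
      coms <- st$pocket_centers +
        matrix(stats::rnorm(3L * m, sd = st$sigma), m, 3L)
      co <- receptor_coords(geom, coms)
      if (rigid_jitter) {
        R <- random_rotation()
        tr <- stats::runif(3, -20, 20)
        co <- co %*% t(R) + matrix(tr, n_atoms, 3, byrow = TRUE)
      }
      xyz[f, ] <- coords_to_xyz(co)
    }
  })
  top <- new_structure(annotate_atoms(atom), NULL)
  feat_centers <- t(vapply(states, function(s) coords_to_xyz(s$pocket_centers),
                           numeric(3L * m)))
  list(trajectory = new_trajectory(top, xyz), labels = labels - 1L,
       feature_centers = feat_centers, populations = pops)
}

#' Generate a docking-score table with known ensemble-score ground truth
#'
#' Each compound gets a per-state true binding score (a compound-level
#' base affinity plus a state-specific shift); the observed table adds
#' Gaussian noise and drops cells at `missing_rate` (a compound losing
#' every cell has its missing mask redrawn, with a message). The true
#' ensemble scores are computed from the noiseless values and the
#' generative state free energies.
#'
#' @param states List of [state_spec()] (populations supply dG_conf).
#' @param n_compounds Number of compounds.
#' @param noise_sigma Score noise, kcal/mol (default 0.25).
#' @param missing_rate Fraction of missing poses in [0, 1) (default 0).
#' @param seed Integer RNG seed.
#' @param ctx A [thermal_context()].
#' @return List: `table` (an `eded_scores`), `true_dg_bind` (noiseless
#'   matrix), `true_ensemble` (true ensemble score per compound,
#'   kcal/mol), `dg_conf` (generative, kT).
#' @export
make_score_table <- function(states, n_compounds, noise_sigma = 0.25,
                             missing_rate = 0, seed = 1L,
                             ctx = thermal_context()) {
  if (missing_rate < 0 || missing_rate >= 1)
    abort_eded("missing_rate must lie in [0, 1)", "bad_argument")
  k <- length(states)
  pops <- vapply(states, `[[`, 0, "population")
  dg_conf <- -log(pops / max(pops))
  ids <- sprintf("CMP%04d", seq_len(n_compounds))
  conf_ids <- paste0("S", seq_len(k) - 1L)

  out <- with_seed(seed, {
    base <- stats::runif(n_compounds, -12, -6)
    shift <- matrix(stats::rnorm(n_compounds * k, sd = 1), n_compounds, k)
    true_dg <- base + shift
    obs <- true_dg + matrix(stats::rnorm(n_compounds * k, sd = noise_sigma),
                            n_compounds, k)
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_compounds * k) < missing_rate,
                     n_compounds, k)
      while (any(all_gone <- rowSums(!miss) == 0L)) {
        message(sprintf("redrawing missing mask for %d compound(s) with no scores left",
                        sum(all_gone)))
        miss[all_gone, ] <- matrix(stats::runif(sum(all_gone) * k) < missing_rate,
                                   sum(all_gone), k)
      }
      obs[miss] <- NA_real_
    }
    list(true_dg = true_dg, obs = obs)
  })
  dimnames(out$true_dg) <- dimnames(out$obs) <- list(ids, conf_ids)
  true_ens <- vapply(seq_len(n_compounds), function(i)
    ensemble_score(out$true_dg[i, ], dg_conf, ctx)$score, 0)
  list(table = score_table(ids, conf_ids, out$obs),
       true_dg_bind = out$true_dg,
       true_ensemble = stats::setNames(true_ens, ids), dg_conf = dg_conf)
}

#' Write a docking score table as CSV
#'
#' Inverse of [read_score_table()]; missing poses become empty cells.
#'
#' @param scores An `eded_scores`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_score_table <- function(scores, path) {
  df <- data.frame(compound_id = scores$compound_ids,
                   scores$dg_bind, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
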