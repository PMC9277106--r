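# Independent oracles used to check package results, deliberately kept on
# different algorithmic routes than the implementation.

# Brute-force partition-sum ensemble score: enumerate the unbound and
# bound Boltzmann sums directly (no log-sum-exp).
oracle_ensemble_score <- function(dg_bind, dg_conf, kT = 0.0019872041 * 300) {
  p_unbound <- sum(exp(-dg_conf))
  ok <- !is.na(dg_bind)
  p_bound <- sum(exp(-dg_conf[ok] - dg_bind[ok] / kT))
  kT * log(p_unbound / p_bound)
}

# Horn's quaternion method for the optimal superposition RMSD, an
# independent alternative to SVD-based Kabsch.
horn_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lam)) / nrow(P))
}

# Exhaustive all-pairs heavy-atom pocket scan (plain double loop over
# residues and atom pairs).
oracle_pocket_scan <- function(st, cutoff) {
  atom <- st$atom
  keys <- ededock:::residue_key(atom)
  lig <- which(atom$is_ligand & !atom$is_hydrogen)
  sel <- character(0)
  for (k in unique(keys[atom$is_protein])) {
    side <- which(keys == k & atom$is_protein & !atom$is_hydrogen & !atom$is_backbone)
    if (length(side) == 0L)
      side <- which(keys == k & atom$is_protein & atom$elety == "CA")
    dmin <- Inf
    for (i in side) for (j in lig)
      dmin <- min(dmin, sqrt(sum((st$coords[i, ] - st$coords[j, ])^2)))
    if (dmin <= cutoff) sel <- c(sel, k)
  }
  sort(sel)
}

pocket_keys <- function(pocket)
  sort(paste(pocket$residues$chain, pocket$residues$resno,
             pocket$residues$resname, sep = ":"))

# Minimal CHARMM-format DCD writer (little endian), used only to exercise
# the binary trajectory read path.
write_dcd <- function(xyz, path) {
  n_frames <- nrow(xyz); natom <- ncol(xyz) %/% 3L
  con <- file(path, "wb"); on.exit(close(con))
  rec <- function(payload) {
    len <- sum(vapply(payload, function(p)
      if (is.character(p)) nchar(p) else length(p) * attr(p, "bytes"), 0))
    writeBin(as.integer(len), con, size = 4, endian = "little")
    for (p in payload) {
      if (is.character(p)) writeChar(p, con, eos = NULL)
      else {
        b <- attr(p, "bytes"); v <- as.vector(p)
        writeBin(v, con, size = b, endian = "little")
      }
    }
    writeBin(as.integer(len), con, size = 4, endian = "little")
  }
  ints <- function(x) structure(as.integer(x), bytes = 4L)
  flts <- function(x) structure(as.numeric(x), bytes = 4L)
  icntrl <- integer(20)
  icntrl[1] <- n_frames; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[20] <- 24L
  rec(list("CORD", ints(icntrl)))
  rec(list(ints(1L), formatC("generated test trajectory", width = 80)))
  rec(list(ints(natom)))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    rec(list(flts(m[, 1]))); rec(list(flts(m[, 2]))); rec(list(flts(m[, 3])))
  }
  invisible(path)
}

# A bare C-alpha chain structure: one CA atom per residue at the given
# coordinates (n x 3). Convenient for superposition tests where every
# atom participates in the alignment.
ca_structure <- function(coords) {
  n <- nrow(coords)
  raw <- data.frame(eleno = seq_len(n), elety = "CA", alt = NA, resid = "ALA",
                    chain = "A", resno = seq_len(n), insert = NA, elesy = "C",
                    stringsAsFactors = FALSE)
  ededock:::new_structure(ededock:::annotate_atoms(raw), coords)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)
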