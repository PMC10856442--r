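# Independent brute-force oracles, written as plainly as possible (explicit
# loops, exhaustive image search) so they share no code path with the
# implementation they check.

# minimum-image distance by exhaustive search over lateral images (wide
# enough for separations of several box lengths)
bf_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -3:3) for (iy in -3:3) {
    d <- a - (b + c(ix * box[1], iy * box[2], 0))
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# all-pairs cross distance matrix
bf_dist_matrix <- function(A, B, box) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    out[i, j] <- bf_min_image(A[i, ], B[j, ], box)
  }
  out
}

bf_mindist <- function(A, B, box) min(bf_dist_matrix(A, B, box))

bf_count_within <- function(A, B, box, cutoff) {
  sum(bf_dist_matrix(A, B, box) <= cutoff)
}

# brute-force PC domain labels: DPPC touching any DLPC atom -> Lod, else Lo;
# DLPC touching any DPPC atom -> Lod, else Ld
bf_classify_pc <- function(system, pos, d) {
  at <- system$atoms
  box <- system$box
  out <- list()
  for (ty in c("DPPC", "DLPC")) {
    other <- if (ty == "DPPC") "DLPC" else "DPPC"
    oth_idx <- which(at$molecule_type == other)
    for (m in unique(at$molecule_id[at$molecule_type == ty])) {
      mi <- which(at$molecule_id == m)
      touching <- FALSE
      for (i in mi) for (j in oth_idx) {
        if (bf_min_image(pos[i, ], pos[j, ], box) <= d) touching <- TRUE
      }
      lab <- if (touching) "Lod" else if (ty == "DPPC") "Lo" else "Ld"
      out[[as.character(m)]] <- lab
    }
  }
  out
}

# brute-force whole-group pair energy with Lorentz-Berthelot combining
bf_group_energy <- function(system, pos, sel_a, sel_b, table, cutoff, f) {
  at <- system$atoms
  box <- system$box
  e_lj <- 0
  e_c <- 0
  for (i in sel_a) for (j in sel_b) {
    r <- bf_min_image(pos[i, ], pos[j, ], box)
    if (r > cutoff) next
    pi_ <- table[table$type_key == at$type_key[i], ]
    pj <- table[table$type_key == at$type_key[j], ]
    sig <- (pi_$sigma + pj$sigma) / 2
    eps <- sqrt(pi_$epsilon * pj$epsilon)
    e_lj <- e_lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    e_c <- e_c + f * pi_$charge * pj$charge / r
  }
  c(lj = e_lj, coulomb = e_c)
}

# random point cloud inside a box
rand_points <- function(n, box, zrange = NULL) {
  cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
        if (is.null(zrange)) runif(n, 0, box[3]) else
          runif(n, zrange[1], zrange[2]))
}

# tiny hand-built system: n_mol molecules of each listed type, n_atom beads
# per molecule at random positions (for oracle comparisons only)
toy_lipid_system <- function(n_mol, types, box, atoms_per_mol = 3L,
                             zrange = NULL) {
  rows <- list()
  pos <- list()
  mol <- 0L
  for (ty in types) {
    for (m in seq_len(n_mol)) {
      mol <- mol + 1L
      nm <- if (ty == "CHOL") c("ROH", "R1", "R2")[seq_len(atoms_per_mol)]
        else c(raftbind:::HEAD_BEADS[[ty]],
               paste0("C", seq_len(atoms_per_mol - 1L), "A"))
      rows[[mol]] <- data.frame(
        atom_index = NA_integer_, atom_name = nm,
        type_key = raftbind:::assign_type_key(nm),
        molecule_id = mol, molecule_type = ty,
        chain_id = NA_character_, residue_index = 1L, residue_name = ty,
        stringsAsFactors = FALSE)
      pos[[mol]] <- rand_points(atoms_per_mol, box, zrange)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$atom_index <- seq_len(nrow(atoms))
  new_system(atoms, do.call(rbind, pos), box)
}

# small jittered multi-atom-per-residue protein trajectory
make_walk_traj <- function(n_res, n_frames, atoms_per_res = 2, seed = 52) {
  set.seed(seed)
  n_at <- n_res * atoms_per_res
  atoms <- data.frame(
    atom_index = seq_len(n_at), atom_name = "BB", type_key = "BB",
    molecule_id = 1L, molecule_type = "PROTEIN", chain_id = "A",
    residue_index = rep(seq_len(n_res), each = atoms_per_res),
    residue_name = "ALA", stringsAsFactors = FALSE)
  base <- matrix(runif(n_at * 3, 2, 8), ncol = 3)
  sys <- new_system(atoms, base, c(10, 10, 10))
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    new_frame(t, base + matrix(rnorm(n_at * 3, 0, 0.1), ncol = 3),
              c(10, 10, 10))
  })
  new_trajectory(sys, frames, "AA")
}

# append a random protein blob to a system
add_toy_protein <- function(system, n_res, centre, spread = 0.8) {
  at <- system$atoms
  mol <- max(at$molecule_id) + 1L
  prow <- data.frame(
    atom_index = NA_integer_, atom_name = "BB", type_key = "BB",
    molecule_id = mol, molecule_type = "PROTEIN", chain_id = "A",
    residue_index = seq_len(n_res), residue_name = "ALA",
    stringsAsFactors = FALSE)
  ppos <- sweep(matrix(rnorm(n_res * 3, 0, spread), ncol = 3), 2L, -centre)
  atoms <- rbind(at, prow)
  atoms$atom_index <- seq_len(nrow(atoms))
  new_system(atoms, rbind(system$positions, ppos), system$box)
}
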