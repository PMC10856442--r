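# Cutoff-bounded nonbonded energetics: 12-6 Lennard-Jones plus vacuum-style
# Coulomb over all cross pairs of two atom groups within the sampling cutoff
# (default 1.2 nm). Plain truncation, no shift/switch, no long-range
# corrections: the sums are raw interaction energies, deterministic in the
# positions but discontinuous at the cutoff. Lorentz-Berthelot combining
# (arithmetic sigma, geometric epsilon).

#' Electrostatic conversion factor
#'
#' `1/(4 pi eps0)` expressed in kJ mol^-1 nm e^-2 from CODATA constants.
#' @export
COULOMB_F <- 138.935458

validate_forcefield <- function(table, coulomb_f = COULOMB_F) {
  req <- c("type_key", "sigma", "epsilon", "charge")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("force-field table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(table$sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(table$epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  if (coulomb_f <= 0) stop("coulomb_f must be > 0", call. = FALSE)
  if (anyDuplicated(table$type_key)) {
    stop("duplicate type_key in force-field table", call. = FALSE)
  }
  attr(table, "coulomb_f") <- coulomb_f
  table
}

#' Pairwise 12-6 Lennard-Jones energy
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6]`; zero at `r = sigma`, minimum `-eps`
#' at `r = 2^(1/6) sigma`.
#'
#' @param r distance(s), nm; must be positive.
#' @param sigma_ij,epsilon_ij combined pair parameters.
#' @return energy in kJ/mol.
#' @export
pair_lj <- function(r, sigma_ij, epsilon_ij) {
  if (any(r <= 0)) stop("Lennard-Jones energy is singular at r = 0",
                        call. = FALSE)
  sr6 <- (sigma_ij / r)^6
  4 * epsilon_ij * (sr6 * sr6 - sr6)
}

#' Pairwise Coulomb energy
#'
#' `f q_i q_j / r` with the electrostatic prefactor `f` (kJ mol^-1 nm e^-2).
#'
#' @param r distance(s), nm; must be positive.
#' @param q_i,q_j partial charges (e).
#' @param f electrostatic prefactor (default [COULOMB_F]).
#' @return energy in kJ/mol.
#' @export
pair_coulomb <- function(r, q_i, q_j, f = COULOMB_F) {
  if (any(r <= 0)) stop("Coulomb energy is singular at r = 0", call. = FALSE)
  f * q_i * q_j / r
}

# per-atom parameter lookup with a clear error on missing keys
ff_params <- function(type_keys, table) {
  idx <- match(type_keys, table$type_key)
  if (anyNA(idx)) {
    stop("type_key(s) absent from force-field table: ",
         paste(unique(type_keys[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  list(sigma = table$sigma[idx], epsilon = table$epsilon[idx],
       charge = table$charge[idx])
}

#' Group-group interaction energy
#'
#' Sums Lennard-Jones and Coulomb energies over all cross pairs of two
#' disjoint atom groups within the cutoff (inclusive, minimum-image).
#'
#' @param system a `raft_system`.
#' @param frame a `raft_frame`, or `NULL` for the system's coordinates.
#' @param sel_a,sel_b disjoint integer atom selections.
#' @param table force-field table (see [emit_forcefield_table()]).
#' @param cutoff energy sampling threshold (nm, default 1.2).
#' @return data.frame `E_lj`, `E_coulomb`, `E_total` (kJ/mol) with one row.
#' @export
group_interaction_energy <- function(system, frame = NULL, sel_a, sel_b,
                                     table, cutoff = 1.2) {
  if (length(intersect(sel_a, sel_b))) {
    stop("energy groups must be disjoint", call. = FALSE)
  }
  pos <- if (is.null(frame)) system$positions else frame$positions
  box <- if (is.null(frame)) system$box else frame$box
  f <- attr(table, "coulomb_f") %||% COULOMB_F
  pa <- ff_params(system$atoms$type_key[sel_a], table)
  pb <- ff_params(system$atoms$type_key[sel_b], table)
  cp <- close_pairs(pos[sel_a, , drop = FALSE], pos[sel_b, , drop = FALSE],
                    box, cutoff)
  if (nrow(cp) == 0L) {
    return(data.frame(E_lj = 0, E_coulomb = 0, E_total = 0))
  }
  sig <- (pa$sigma[cp$i] + pb$sigma[cp$j]) / 2
  eps <- sqrt(pa$epsilon[cp$i] * pb$epsilon[cp$j])
  e_lj <- sum(pair_lj(cp$dist, sig, eps))
  e_c <- sum(f * pa$charge[cp$i] * pb$charge[cp$j] / cp$dist)
  data.frame(E_lj = e_lj, E_coulomb = e_c, E_total = e_lj + e_c)
}

#' Protein interchain interaction energy
#'
#' Sum of the group energies over all unordered pairs of distinct protein
#' chains, time-averaged over the window; a list of replicate trajectories
#' adds the SEM. A single-chain system has no interchain energy and is
#' reported as not applicable (`NA` values).
#'
#' @param trajs a `raft_trajectory` or list of replicates.
#' @param table force-field table.
#' @param window analysis window or `NULL`.
#' @param cutoff energy sampling threshold (nm).
#' @return data.frame `E_lj`, `E_coulomb`, `E_total`, `sem` (SEM of the
#'   total).
#' @export
interchain_energy <- function(trajs, table, window = NULL, cutoff = 1.2) {
  if (inherits(trajs, "raft_trajectory")) trajs <- list(trajs)
  per_rep <- lapply(trajs, function(traj) {
    at <- traj$system$atoms
    chains <- unique(at$chain_id[at$molecule_type == "PROTEIN"])
    chains <- chains[!is.na(chains)]
    if (length(chains) < 2L) {
      return(c(E_lj = NA_real_, E_coulomb = NA_real_, E_total = NA_real_))
    }
    pairs <- utils::combn(chains, 2L)
    idx <- window_frames(traj, window)
    acc <- vapply(idx, function(k) {
      fr <- traj$frames[[k]]
      tot <- c(0, 0)
      for (p in seq_len(ncol(pairs))) {
        e <- group_interaction_energy(
          traj$system, fr,
          select_atoms(traj$system, chain_id = pairs[1L, p]),
          select_atoms(traj$system, chain_id = pairs[2L, p]),
          table, cutoff)
        tot <- tot + c(e$E_lj, e$E_coulomb)
      }
      tot
    }, numeric(2L))
    m <- rowMeans(acc)
    c(E_lj = m[1L], E_coulomb = m[2L], E_total = sum(m))
  })
  mat <- do.call(rbind, per_rep)
  data.frame(E_lj = mean(mat[, 1L]), E_coulomb = mean(mat[, 2L]),
             E_total = mean(mat[, 3L]), sem = sem(mat[, 3L]))
}

#' Protein-lipid interaction energies by lipid type
#'
#' One time-averaged energy breakdown per lipid type between the whole
#' protein and all lipids of that type; replicate lists add SEMs.
#'
#' @inheritParams interchain_energy
#' @param lipid_types character vector of types (defaults to those present).
#' @return data.frame `molecule_type`, `E_lj`, `E_coulomb`, `E_total`,
#'   `sem`.
#' @export
protein_lipidtype_energy <- function(trajs, table, lipid_types = NULL,
                                     window = NULL, cutoff = 1.2) {
  if (inherits(trajs, "raft_trajectory")) trajs <- list(trajs)
  if (is.null(lipid_types)) {
    lipid_types <- intersect(LIPID_TYPES,
                             unique(trajs[[1L]]$system$atoms$molecule_type))
  }
  per_rep <- lapply(trajs, function(traj) {
    prot <- select_atoms(traj$system, molecule_type = "PROTEIN")
    idx <- window_frames(traj, window)
    vapply(lipid_types, function(ty) {
      lsel <- select_atoms(traj$system, molecule_type = ty)
      acc <- vapply(idx, function(k) {
        e <- group_interaction_energy(traj$system, traj$frames[[k]],
                                      prot, lsel, table, cutoff)
        c(e$E_lj, e$E_coulomb)
      }, numeric(2L))
      rowMeans(acc)
    }, numeric(2L))
  })
  e_lj <- sapply(per_rep, function(m) m[1L, ])
  e_c <- sapply(per_rep, function(m) m[2L, ])
  if (is.null(dim(e_lj))) {
    e_lj <- matrix(e_lj, nrow = length(lipid_types))
    e_c <- matrix(e_c, nrow = length(lipid_types))
  }
  tot <- e_lj + e_c
  data.frame(molecule_type = lipid_types,
             E_lj = rowMeans(e_lj), E_coulomb = rowMeans(e_c),
             E_total = rowMeans(tot),
             sem = apply(tot, 1L, sem), row.names = NULL)
}
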