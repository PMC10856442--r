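# Acyl-chain orientational order profiles. For carbon n of a chain, the
# local molecular axis is the vector from carbon n-1 to carbon n+1 (the tilt
# of three sequentially connected carbons); its polar angle theta against
# the bilayer normal (the z axis) enters the second-Legendre order parameter
# S(n) = <(3 cos^2 theta - 1)/2>. This is the chain-axis order parameter of
# the three-carbon construction, not the deuterium order parameter: the two
# differ in sign and scale.

#' Local chain-axis angles of one acyl chain
#'
#' @param positions coordinate matrix of the frame.
#' @param chain_atoms ordered integer indices of the chain's carbon atoms
#'   (at least 3).
#' @param box orthorhombic box (nm).
#' @return numeric vector of polar angles (radians) for the interior carbons
#'   `2 .. N-1`.
#' @export
carbon_axis_angles <- function(positions, chain_atoms, box) {
  N <- length(chain_atoms)
  if (N < 3L) stop("a chain needs at least 3 carbons", call. = FALSE)
  p_next <- positions[chain_atoms[3:N], , drop = FALSE]
  p_prev <- positions[chain_atoms[1:(N - 2L)], , drop = FALSE]
  v <- cbind(wrap_delta(p_next[, 1L] - p_prev[, 1L], box[1L]),
             wrap_delta(p_next[, 2L] - p_prev[, 2L], box[2L]),
             p_next[, 3L] - p_prev[, 3L])
  cosang <- v[, 3L] / sqrt(rowSums(v * v))
  acos(pmin(1, pmax(-1, cosang)))
}

p2 <- function(cos_theta) (3 * cos_theta^2 - 1) / 2

#' Acyl-chain order profile
#'
#' S(n) per interior carbon, averaged over all molecules of the lipid type
#' (optionally restricted to the annular shell, re-evaluated per frame) and
#' over the window frames. A list of replicate trajectories adds the SEM
#' across replicates.
#'
#' @param trajs a `raft_trajectory` or list of replicate trajectories.
#' @param lipid_type lipid type carrying the chain (e.g. `"DPPC"`).
#' @param chain `"sn1"` or `"sn2"` (generator chains `A` and `B`).
#' @param shell `"all"`, `"AL"` or `"nAL"`; shell membership is re-evaluated
#'   every frame against the protein.
#' @param window analysis window `c(tmin, tmax)` or `NULL`.
#' @param d_shell annular-shell threshold (nm) used when filtering.
#' @return data.frame `carbon` (2 .. N-1), `S`, `sem`.
#' @export
order_profile <- function(trajs, lipid_type, chain = c("sn1", "sn2"),
                          shell = c("all", "AL", "nAL"), window = NULL,
                          d_shell = 0.5) {
  chain <- match.arg(chain)
  shell <- match.arg(shell)
  if (inherits(trajs, "raft_trajectory")) trajs <- list(trajs)
  lab <- if (chain == "sn1") "A" else "B"
  per_rep <- lapply(trajs, function(traj) {
    at <- traj$system$atoms
    mols <- unique(at$molecule_id[at$molecule_type == lipid_type])
    if (length(mols) == 0L) {
      stop("no ", lipid_type, " molecules in system", call. = FALSE)
    }
    len <- sum(at$molecule_id == mols[1L] &
                 grepl(paste0("^C[0-9]+", lab, "$"), at$atom_name))
    if (len < 3L) {
      stop(lipid_type, " chain ", chain, " has fewer than 3 carbons",
           call. = FALSE)
    }
    amat <- vapply(seq_len(len), function(k) {
      which(at$molecule_type == lipid_type &
              at$atom_name == paste0("C", k, lab))
    }, integer(length(mols)))
    if (is.null(dim(amat))) amat <- matrix(amat, nrow = length(mols))

    idx <- window_frames(traj, window)
    ssum <- numeric(len - 2L)
    nsum <- 0L
    for (k in idx) {
      fr <- traj$frames[[k]]
      keep <- seq_along(mols)
      if (shell != "all") {
        sh <- classify_annular_shell(traj$system, fr, d_shell)
        in_shell <- sh$molecule_id[sh$shell == shell]
        keep <- which(mols %in% in_shell)
        if (length(keep) == 0L) next
      }
      for (n in 2:(len - 1L)) {
        i_next <- amat[keep, n + 1L]
        i_prev <- amat[keep, n - 1L]
        v1 <- wrap_delta(fr$positions[i_next, 1L] - fr$positions[i_prev, 1L],
                         fr$box[1L])
        v2 <- wrap_delta(fr$positions[i_next, 2L] - fr$positions[i_prev, 2L],
                         fr$box[2L])
        v3 <- fr$positions[i_next, 3L] - fr$positions[i_prev, 3L]
        ct <- v3 / sqrt(v1^2 + v2^2 + v3^2)
        ssum[n - 1L] <- ssum[n - 1L] + sum(p2(ct))
      }
      nsum <- nsum + length(keep)
    }
    if (nsum == 0L) {
      stop("no molecules pass the ", shell, " filter in the window",
           call. = FALSE)
    }
    ssum / nsum
  })
  mat <- do.call(rbind, per_rep)
  data.frame(carbon = 2:(ncol(mat) + 1L), S = colMeans(mat),
             sem = apply(mat, 2L, sem), row.names = NULL)
}
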