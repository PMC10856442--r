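# Protein-membrane binding analysis: mindist kinetics, contact counting,
# binding-time detection, per-residue mindist spectra, and annular-shell
# extraction.

#' Minimum-distance time series
#'
#' Per frame, the smallest minimum-image distance between any atom of the
#' protein selection and any atom of the target group ("mindist").
#'
#' @param traj a `raft_trajectory`.
#' @param sel_protein,sel_group integer atom index vectors (see
#'   [select_atoms()]); both must be non-empty.
#' @return data.frame `time`, `mindist` (nm).
#' @export
mindist_series <- function(traj, sel_protein, sel_group) {
  if (length(sel_protein) == 0L || length(sel_group) == 0L) {
    stop("empty atom selection", call. = FALSE)
  }
  vals <- vapply(traj$frames, function(fr) {
    group_mindist(fr$positions[sel_protein, , drop = FALSE],
                  fr$positions[sel_group, , drop = FALSE], fr$box)
  }, numeric(1))
  data.frame(time = frame_times(traj), mindist = vals)
}

#' Contact-count time series
#'
#' Per frame, the number of cross atom pairs within the interaction
#' threshold (default 2 nm, the published convention).
#'
#' @inheritParams mindist_series
#' @param d_contact contact threshold (nm, inclusive).
#' @return data.frame `time`, `contacts`.
#' @export
contact_count_series <- function(traj, sel_protein, sel_group,
                                 d_contact = 2.0) {
  stopifnot(d_contact > 0)
  vals <- vapply(traj$frames, function(fr) {
    count_within(fr$positions[sel_protein, , drop = FALSE],
                 fr$positions[sel_group, , drop = FALSE], fr$box, d_contact)
  }, integer(1))
  data.frame(time = frame_times(traj), contacts = vals)
}

#' Detect the lipid-binding time
#'
#' The binding time is the onset of the persistent low-mindist plateau:
#' in `persistent_suffix` mode, the earliest frame from which the mindist
#' stays at or below `d_bind` until the end of the run; in `contact_onset`
#' mode, the first frame of the trailing run of nonzero contact counts. A
#' trajectory with no qualifying suffix is reported unbound (`NA`).
#'
#' @param series data.frame from [mindist_series()] (mode
#'   `persistent_suffix`) or [contact_count_series()] (mode `contact_onset`).
#' @param d_bind binding distance threshold (nm); defaults to 0.6 for CG
#'   series, above the ~0.5 nm stable plateau (use ~0.35 for AA, above the
#'   ~0.2 nm plateau). Ignored in `contact_onset` mode.
#' @param mode detection rule.
#' @return binding time (same units as `series$time`), or `NA_real_` when
#'   unbound.
#' @export
detect_binding_time <- function(series, d_bind = 0.6,
                                mode = c("persistent_suffix",
                                         "contact_onset")) {
  mode <- match.arg(mode)
  stopifnot(nrow(series) > 0L)
  ok <- if (mode == "persistent_suffix") {
    series$mindist <= d_bind
  } else {
    series$contacts > 0
  }
  n <- length(ok)
  if (!ok[n]) return(NA_real_)
  last_bad <- max(c(0L, which(!ok)))
  series$time[last_bad + 1L]
}

#' Per-residue mindist spectrum
#'
#' For each residue of the chain group: the per-frame minimum distance
#' between the residue's atoms and the target atoms, averaged over the
#' window frames, then over the equivalent chains of the group. A list of
#' replicate trajectories additionally yields the SEM across replicates.
#' All chains in the group must share one sequence length.
#'
#' @param trajs a `raft_trajectory` or list of replicate trajectories.
#' @param chain_ids chain identifiers of the equivalent chains to average
#'   (e.g. both amylin chains of the hetero-tetramer).
#' @param sel_group target atom selection (applied to each trajectory's own
#'   system via `molecule_type`), given as a character molecule type
#'   (e.g. `"POPS"`, `"WATER"`) or an integer atom index vector.
#' @param window analysis window `c(tmin, tmax)` or `NULL`.
#' @param smooth apply the presentation 5-point moving average?
#' @return data.frame `residue`, `mindist`, `sem`.
#' @export
mindist_spectrum <- function(trajs, chain_ids, sel_group, window = NULL,
                             smooth = FALSE) {
  if (inherits(trajs, "raft_trajectory")) trajs <- list(trajs)
  per_rep <- lapply(trajs, function(traj) {
    at <- traj$system$atoms
    tsel <- if (is.character(sel_group)) {
      select_atoms(traj$system, molecule_type = sel_group)
    } else sel_group
    chain_profiles <- lapply(chain_ids, function(cid) {
      csel <- which(at$molecule_type == "PROTEIN" & at$chain_id == cid)
      if (length(csel) == 0L) stop("chain ", cid, " not found",
                                   call. = FALSE)
      resid <- at$residue_index[csel]
      idx <- window_frames(traj, window)
      acc <- matrix(0, max(resid), length(idx))
      for (w in seq_along(idx)) {
        fr <- traj$frames[[idx[w]]]
        dmin <- rowmin_cross_dist(fr$positions[csel, , drop = FALSE],
                                  fr$positions[tsel, , drop = FALSE],
                                  fr$box)
        acc[, w] <- vapply(split(dmin, resid), min, numeric(1))
      }
      rowMeans(acc)
    })
    lens <- lengths(chain_profiles)
    if (length(unique(lens)) != 1L) {
      stop("chains of unequal length in one averaging group", call. = FALSE)
    }
    Reduce(`+`, chain_profiles) / length(chain_profiles)
  })
  mat <- do.call(rbind, per_rep)
  out <- data.frame(residue = seq_len(ncol(mat)),
                    mindist = colMeans(mat),
                    sem = apply(mat, 2L, sem))
  if (smooth) out$mindist <- moving_average(out$mindist, 5L)
  out
}

#' Annular-shell assignment
#'
#' A lipid belongs to the annular shell (AL) when any of its atoms lies
#' within `d_shell` (default 0.5 nm, inclusive) of any protein atom; all
#' other lipids form the non-annular region (nAL).
#'
#' @param system a `raft_system` containing a protein.
#' @param frame a `raft_frame`, or `NULL` for the system's coordinates.
#' @param d_shell shell threshold (nm).
#' @return data.frame `molecule_id`, `molecule_type`, `shell` (AL / nAL).
#' @export
classify_annular_shell <- function(system, frame = NULL, d_shell = 0.5) {
  at <- system$atoms
  pos <- if (is.null(frame)) system$positions else frame$positions
  box <- if (is.null(frame)) system$box else frame$box
  prot <- which(at$molecule_type == "PROTEIN")
  if (length(prot) == 0L) stop("system contains no protein", call. = FALSE)
  lip <- which(at$molecule_type %in% LIPID_TYPES)
  mols <- unique(at$molecule_id[lip])
  cp <- close_pairs(pos[lip, , drop = FALSE], pos[prot, , drop = FALSE],
                    box, d_shell)
  in_al <- mols %in% at$molecule_id[lip][cp$i]
  data.frame(molecule_id = mols,
             molecule_type = at$molecule_type[lip][!duplicated(
               at$molecule_id[lip])],
             shell = ifelse(in_al, "AL", "nAL"),
             stringsAsFactors = FALSE)
}

#' Annular-shell composition percentages
#'
#' Time-averaged per-type lipid counts in the AL shell and their percentages
#' of the shell total. When no lipid ever enters the shell the percentages
#' are reported absent (`NA`).
#'
#' @param traj a `raft_trajectory`.
#' @param window analysis window or `NULL`.
#' @param d_shell shell threshold (nm).
#' @return data.frame `molecule_type`, `n_al` (mean count), `pct_al`.
#' @export
al_composition <- function(traj, window = NULL, d_shell = 0.5) {
  idx <- window_frames(traj, window)
  types <- intersect(LIPID_TYPES, unique(traj$system$atoms$molecule_type))
  counts <- vapply(idx, function(k) {
    sh <- classify_annular_shell(traj$system, traj$frames[[k]], d_shell)
    vapply(types, function(ty) {
      sum(sh$shell == "AL" & sh$molecule_type == ty)
    }, numeric(1))
  }, numeric(length(types)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(types))
  n_al <- rowMeans(counts)
  tot <- sum(n_al)
  data.frame(molecule_type = types, n_al = n_al,
             pct_al = if (tot > 0) 100 * n_al / tot else NA_real_,
             row.names = NULL)
}
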