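# Lipid phase-domain classification. A DPPC or DLPC is a boundary (Lod)
# lipid when any of its atoms lies within the proximity threshold (default
# 0.5 nm, inclusive) of any atom of the opposite PC species; otherwise DPPC
# is liquid-ordered (Lo) and DLPC liquid-disordered (Ld). Cholesterol
# inherits the domain of the PC lipids it touches: one domain class -> that
# class, several -> Lod (it straddles the boundary), none -> the class of
# the nearest PC molecule. Distances are 3D minimum-image over both
# leaflets; bilayer thickness keeps inter-leaflet contacts out in practice.

#' Classify phosphatidylcholine lipids into Lo/Ld/Lod
#'
#' @param system a `raft_system` containing at least one PC lipid.
#' @param frame a `raft_frame`, or `NULL` for the system's own coordinates.
#' @param d_domain proximity threshold (nm, default 0.5, inclusive).
#' @return data.frame `molecule_id`, `molecule_type`, `label` for every DPPC
#'   and DLPC.
#' @export
classify_pc <- function(system, frame = NULL, d_domain = 0.5) {
  at <- system$atoms
  pos <- if (is.null(frame)) system$positions else frame$positions
  box <- if (is.null(frame)) system$box else frame$box
  idx_dppc <- which(at$molecule_type == "DPPC")
  idx_dlpc <- which(at$molecule_type == "DLPC")
  if (length(idx_dppc) + length(idx_dlpc) == 0L) {
    stop("system contains no PC lipids", call. = FALSE)
  }
  mols_dppc <- unique(at$molecule_id[idx_dppc])
  mols_dlpc <- unique(at$molecule_id[idx_dlpc])
  lab_dppc <- rep("Lo", length(mols_dppc))
  lab_dlpc <- rep("Ld", length(mols_dlpc))
  if (length(idx_dppc) && length(idx_dlpc)) {
    cp <- close_pairs(pos[idx_dppc, , drop = FALSE],
                      pos[idx_dlpc, , drop = FALSE], box, d_domain)
    if (nrow(cp)) {
      lab_dppc[mols_dppc %in% at$molecule_id[idx_dppc][cp$i]] <- "Lod"
      lab_dlpc[mols_dlpc %in% at$molecule_id[idx_dlpc][cp$j]] <- "Lod"
    }
  }
  data.frame(
    molecule_id = c(mols_dppc, mols_dlpc),
    molecule_type = c(rep("DPPC", length(mols_dppc)),
                      rep("DLPC", length(mols_dlpc))),
    label = c(lab_dppc, lab_dlpc),
    stringsAsFactors = FALSE)
}

#' Classify cholesterol by PC contact
#'
#' @inheritParams classify_pc
#' @param pc_labels result of [classify_pc()] for the same frame.
#' @return data.frame `molecule_id`, `molecule_type`, `label` for every CHOL.
#' @export
classify_chol <- function(system, frame = NULL, pc_labels,
                          d_domain = 0.5) {
  at <- system$atoms
  pos <- if (is.null(frame)) system$positions else frame$positions
  box <- if (is.null(frame)) system$box else frame$box
  idx_chol <- which(at$molecule_type == "CHOL")
  if (length(idx_chol) == 0L) {
    return(data.frame(molecule_id = integer(), molecule_type = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  idx_pc <- which(at$molecule_type %in% PC_TYPES)
  mols_chol <- unique(at$molecule_id[idx_chol])
  lab_of_pc <- stats::setNames(pc_labels$label, pc_labels$molecule_id)

  cp <- close_pairs(pos[idx_chol, , drop = FALSE],
                    pos[idx_pc, , drop = FALSE], box, d_domain)
  lab <- rep(NA_character_, length(mols_chol))
  if (nrow(cp)) {
    cm <- at$molecule_id[idx_chol][cp$i]
    pm <- at$molecule_id[idx_pc][cp$j]
    touched <- tapply(lab_of_pc[as.character(pm)], cm,
                      function(x) unique(x))
    for (nm in names(touched)) {
      k <- match(as.integer(nm), mols_chol)
      lab[k] <- if (length(touched[[nm]]) == 1L) touched[[nm]] else "Lod"
    }
  }
  # fallback: no PC contact -> domain of the nearest PC molecule
  for (k in which(is.na(lab))) {
    ai <- idx_chol[at$molecule_id[idx_chol] == mols_chol[k]]
    d <- rowmin_cross_dist(pos[idx_pc, , drop = FALSE],
                           pos[ai, , drop = FALSE], box)
    lab[k] <- unname(lab_of_pc[as.character(
      at$molecule_id[idx_pc][which.min(d)])])
  }
  data.frame(molecule_id = mols_chol, molecule_type = "CHOL", label = lab,
             stringsAsFactors = FALSE)
}

#' Classify all PC and CHOL lipids of one frame
#'
#' @inheritParams classify_pc
#' @return data.frame `molecule_id`, `molecule_type`, `label` covering every
#'   DPPC, DLPC and CHOL.
#' @export
classify_domains <- function(system, frame = NULL, d_domain = 0.5) {
  pc <- classify_pc(system, frame, d_domain)
  ch <- classify_chol(system, frame, pc, d_domain)
  rbind(pc, ch)
}

# composition percentages of one frame's labels
composition_from_labels <- function(labels) {
  chol <- labels[labels$molecule_type == "CHOL", ]
  pc <- labels[labels$molecule_type %in% PC_TYPES, ]
  chol_pct <- if (nrow(chol)) {
    100 * c(Lo = sum(chol$label == "Lo"), Ld = sum(chol$label == "Ld"),
            Lod = sum(chol$label == "Lod")) / nrow(chol)
  } else c(Lo = NA_real_, Ld = NA_real_, Lod = NA_real_)
  pc_pct <- 100 * c(
    Lo = sum(pc$label == "Lo" & pc$molecule_type == "DPPC"),
    Ld = sum(pc$label == "Ld" & pc$molecule_type == "DLPC"),
    Lod = sum(pc$label == "Lod")) / nrow(pc)
  list(chol = chol_pct, pc = pc_pct)
}

#' Time- and replicate-averaged domain composition
#'
#' Per frame of the analysis window the CHOL percentages in Lo/Ld/Lod (of
#' total CHOL) and the PC percentages Lo-DPPC / Ld-DLPC / Lod-PC (each of
#' total DPPC+DLPC) are computed; frame values are averaged per replicate and
#' the replicate means carry the SEM. Each triple sums to 100.
#'
#' @param trajs a `raft_trajectory` or a list of replicate trajectories.
#' @param window analysis window `c(tmin, tmax)` or `NULL` for all frames
#'   (the published convention is the last 5 us of a CG run).
#' @param d_domain proximity threshold (nm).
#' @return data.frame with `domain`, `chol_pct`, `chol_sem`, `pc_pct`,
#'   `pc_sem`.
#' @export
domain_composition <- function(trajs, window = NULL, d_domain = 0.5) {
  if (inherits(trajs, "raft_trajectory")) trajs <- list(trajs)
  per_rep <- lapply(trajs, function(traj) {
    idx <- window_frames(traj, window)
    acc <- vapply(idx, function(k) {
      comp <- composition_from_labels(
        classify_domains(traj$system, traj$frames[[k]], d_domain))
      c(comp$chol, comp$pc)
    }, numeric(6L))
    rowMeans(acc)
  })
  mat <- do.call(rbind, per_rep)
  data.frame(domain = c("Lo", "Ld", "Lod"),
             chol_pct = colMeans(mat[, 1:3, drop = FALSE]),
             chol_sem = apply(mat[, 1:3, drop = FALSE], 2L, sem),
             pc_pct = colMeans(mat[, 4:6, drop = FALSE]),
             pc_sem = apply(mat[, 4:6, drop = FALSE], 2L, sem),
             row.names = NULL)
}
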