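# Synthetic raft membranes, oligomers, binding trajectories, secondary-
# structure streams and a toy force-field table. The generators plant known
# ground truth (domain layout, leaflet asymmetry, binding time, chain order,
# SS fractions) that the analysis modules are expected to recover, standing
# in for coarse-grained / all-atom MD output. Everything is deterministic
# given its seed. Geometry, not chemistry: lipids are coarse bead chains
# (one headgroup reference bead plus ordered chain beads).

CHAIN_BOND <- 0.15       # nm, bead spacing along an acyl chain
HEAD_BEADS <- c(DPPC = "NC3", DLPC = "NC3", POPS = "CNO", GM1 = "GM0",
                CHOL = "ROH")

# published raft compositions (molecule counts); the CO-raft is the same
# bilayer without the anionic component
RAFT_COUNTS <- list(
  PS = c(POPS = 162, DPPC = 666, DLPC = 540, CHOL = 576),
  GM = c(GM1 = 36, DPPC = 709, DLPC = 407, CHOL = 410),
  CO = c(DPPC = 666, DLPC = 540, CHOL = 576))
RAFT_WATER <- c(PS = 65365, GM = 56114, CO = 65365)
ANIONIC_TYPES <- c("POPS", "GM1")

#' Specify a synthetic raft membrane
#'
#' Defaults reproduce the published asymmetric raft compositions: the PS-raft
#' holds 162 POPS / 666 DPPC / 540 DLPC / 576 CHOL (plus 65,365 waters when
#' requested), the GM-raft 36 GM1 / 709 DPPC / 407 DLPC / 410 CHOL (56,114
#' waters). `scale = "reduced"` divides the counts by 8 for desk-scale test
#' fixtures. The anionic species lives in exactly one leaflet; the other
#' types are split evenly between leaflets (extra odd lipid to the lower
#' leaflet), a documented convention since no per-leaflet split is published.
#'
#' @param raft `"PS"`, `"GM"` or `"CO"`.
#' @param scale `"reduced"` (counts / 8, the test default) or `"full"`.
#' @param counts optional named vector overriding the molecule counts.
#' @param box optional 3-vector (nm); sized from the counts by default.
#' @param area_per_lipid lateral area per lipid (nm^2, default 0.64).
#' @param leaflet_sep distance between headgroup planes (nm, default 2).
#' @param chain_length named integer vector of acyl beads per chain for the
#'   chain-bearing types (default 4 each, two chains per lipid).
#' @param anionic_leaflet leaflet holding the PS/GM1 cluster (default upper).
#' @param lo_radius optional Lo disc radius (nm); derived from the Lo lipid
#'   count by default. Must fit in the box and hold the Lo lipids.
#' @param include_water add a water slab with the published molecule count?
#' @param seed integer seed.
#' @return object of class `raft_spec`.
#' @export
raft_spec <- function(raft = c("PS", "GM", "CO"),
                      scale = c("reduced", "full"),
                      counts = NULL, box = NULL,
                      area_per_lipid = 0.64, leaflet_sep = 2,
                      chain_length = c(DPPC = 4L, DLPC = 4L, POPS = 4L,
                                       GM1 = 4L),
                      anionic_leaflet = c("upper", "lower"),
                      lo_radius = NULL, include_water = FALSE,
                      seed = 1L) {
  raft <- match.arg(raft)
  scale <- match.arg(scale)
  anionic_leaflet <- match.arg(anionic_leaflet)
  if (is.null(counts)) {
    counts <- RAFT_COUNTS[[raft]]
    if (scale == "reduced") {
      counts <- round(counts / 8)
      counts[counts < 1] <- 1
    }
  }
  if (any(counts < 0)) stop("lipid counts must be >= 0", call. = FALSE)
  n_anionic_types <- sum(names(counts) %in% ANIONIC_TYPES & counts > 0)
  if (n_anionic_types > 1L) {
    stop("at most one anionic lipid type per raft", call. = FALSE)
  }
  n_water <- if (include_water) {
    w <- RAFT_WATER[[raft]]
    if (scale == "reduced") round(w / 8) else w
  } else 0L

  # leaflet split: anionic confined to one leaflet, others split evenly
  upper <- lower <- stats::setNames(integer(length(counts)), names(counts))
  for (ty in names(counts)) {
    n <- counts[[ty]]
    if (ty %in% ANIONIC_TYPES) {
      if (anionic_leaflet == "upper") upper[ty] <- n else lower[ty] <- n
    } else {
      upper[ty] <- n %/% 2L
      lower[ty] <- n - upper[ty]
    }
  }
  s <- sqrt(area_per_lipid)
  if (is.null(box)) {
    nmax <- max(sum(upper), sum(lower))
    L <- s * (ceiling(sqrt(nmax)) + 2L)
    box <- c(L, L, 20)
  }
  lo_per_leaflet <- vapply(list(upper, lower), function(cl) {
    sum(cl[names(cl) %in% c("DPPC", "CHOL", ANIONIC_TYPES)])
  }, numeric(1))
  if (is.null(lo_radius)) {
    r_min <- sqrt(max(lo_per_leaflet) * area_per_lipid / pi)
    lo_radius <- min(r_min * 1.15, min(box[1:2]) / 2)
  }
  if (2 * lo_radius > min(box[1:2])) {
    stop("Lo patch does not fit in the box", call. = FALSE)
  }
  if (pi * lo_radius^2 < max(lo_per_leaflet) * area_per_lipid) {
    stop("Lo patch too small for the ordered-phase lipid count",
         call. = FALSE)
  }
  structure(list(raft = raft, scale = scale, counts = counts,
                 upper = upper, lower = lower, n_water = n_water,
                 box = box, area_per_lipid = area_per_lipid,
                 leaflet_sep = leaflet_sep, chain_length = chain_length,
                 anionic_leaflet = anionic_leaflet,
                 lo_center = box[1:2] / 2, lo_radius = lo_radius,
                 seed = as.integer(seed)),
            class = "raft_spec")
}

# bead layout of one lipid: head bead plus chains pointing toward the
# midplane (direction dz = -1 for the upper leaflet, +1 for the lower)
lipid_beads <- function(type, head_xy, head_z, dz, chain_len) {
  if (type == "CHOL") {
    nm <- c("ROH", "R1", "R2")
    off <- c(0, 1, 2) * CHAIN_BOND
    pos <- cbind(rep(head_xy[1L], 3L), rep(head_xy[2L], 3L),
                 head_z + dz * off)
    return(list(names = nm, pos = pos))
  }
  L <- chain_len[[type]]
  nm <- c(HEAD_BEADS[[type]],
          paste0("C", seq_len(L), "A"), paste0("C", seq_len(L), "B"))
  zoff <- c(0, seq_len(L) * CHAIN_BOND, seq_len(L) * CHAIN_BOND)
  # the two chains hang at a small fixed lateral offset so they are distinct
  xoff <- c(0, rep(0.05, L), rep(-0.05, L))
  pos <- cbind(head_xy[1L] + xoff, rep(head_xy[2L], 1L + 2L * L),
               head_z + dz * zoff)
  list(names = nm, pos = pos)
}

#' Build a synthetic raft membrane
#'
#' Places lipids on a jittered lattice, leaflet by leaflet: lattice sites are
#' ranked by lateral (periodic) distance to the Lo disc centre; the anionic
#' cluster takes the innermost sites of its leaflet, DPPC and CHOL interleave
#' over the remaining sites inside the disc, and DLPC fills the sites outside
#' (the disordered phase). Chains start all-trans along the bilayer normal.
#'
#' @param spec a [raft_spec()].
#' @return a `raft_system` carrying the spec in attribute `"spec"`.
#' @export
build_raft <- function(spec) {
  stopifnot(inherits(spec, "raft_spec"))
  set.seed(spec$seed)
  box <- spec$box
  s <- sqrt(spec$area_per_lipid)
  nx <- floor(box[1L] / s)
  ny <- floor(box[2L] / s)
  z_mid <- box[3L] / 2

  atoms_names <- character(0)
  atoms_res <- character(0)
  atoms_mol <- integer(0)
  pos_list <- list()
  mol_counter <- 0L

  for (leaflet in c("upper", "lower")) {
    cl <- spec[[leaflet]]
    total <- sum(cl)
    if (total == 0L) next
    if (nx * ny < total) {
      stop(sprintf("lattice capacity %d < %d lipids in %s leaflet",
                   nx * ny, total, leaflet), call. = FALSE)
    }
    gx <- (rep(seq_len(nx), ny) - 0.5) * box[1L] / nx
    gy <- (rep(seq_len(ny), each = nx) - 0.5) * box[2L] / ny
    gx <- gx + stats::runif(nx * ny, -0.05, 0.05)
    gy <- gy + stats::runif(nx * ny, -0.05, 0.05)
    dlat <- sqrt(wrap_delta(gx - spec$lo_center[1L], box[1L])^2 +
                   wrap_delta(gy - spec$lo_center[2L], box[2L])^2)
    ord <- order(dlat)

    anionic <- intersect(names(cl)[cl > 0], ANIONIC_TYPES)
    seq_types <- character(0)
    if (length(anionic)) seq_types <- rep(anionic, cl[[anionic]])
    # interleave DPPC and CHOL through the rest of the Lo disc
    n_dppc <- if ("DPPC" %in% names(cl)) cl[["DPPC"]] else 0L
    n_chol <- if ("CHOL" %in% names(cl)) cl[["CHOL"]] else 0L
    if (n_dppc + n_chol > 0L) {
      inter <- character(n_dppc + n_chol)
      pick <- order(c(seq_len(n_dppc) / max(n_dppc, 1L),
                      seq_len(n_chol) / max(n_chol, 1L)))
      inter[] <- c(rep("DPPC", n_dppc), rep("CHOL", n_chol))[pick]
      seq_types <- c(seq_types, inter)
    }
    n_dlpc <- if ("DLPC" %in% names(cl)) cl[["DLPC"]] else 0L
    seq_types <- c(seq_types, rep("DLPC", n_dlpc))

    head_z <- z_mid + (if (leaflet == "upper") 1 else -1) * spec$leaflet_sep / 2
    dz <- if (leaflet == "upper") -1 else 1
    for (k in seq_along(seq_types)) {
      ty <- seq_types[k]
      site <- ord[k]
      bb <- lipid_beads(ty, c(gx[site], gy[site]), head_z, dz,
                        spec$chain_length)
      mol_counter <- mol_counter + 1L
      atoms_names <- c(atoms_names, bb$names)
      atoms_res <- c(atoms_res, rep(ty, length(bb$names)))
      atoms_mol <- c(atoms_mol, rep(mol_counter, length(bb$names)))
      pos_list[[length(pos_list) + 1L]] <- bb$pos
    }
  }

  if (spec$n_water > 0L) {
    wpos <- water_slab(spec$n_water, box, z_mid, spec$leaflet_sep)
    ids <- mol_counter + seq_len(spec$n_water)
    mol_counter <- mol_counter + spec$n_water
    atoms_names <- c(atoms_names, rep("W", spec$n_water))
    atoms_res <- c(atoms_res, rep("SOL", spec$n_water))
    atoms_mol <- c(atoms_mol, ids)
    pos_list[[length(pos_list) + 1L]] <- wpos
  }

  positions <- do.call(rbind, pos_list)
  n <- length(atoms_names)
  mt <- ifelse(atoms_res == "SOL", "WATER", atoms_res)
  atoms <- data.frame(atom_index = seq_len(n), atom_name = atoms_names,
                      type_key = assign_type_key(atoms_names),
                      molecule_id = atoms_mol, molecule_type = mt,
                      chain_id = NA_character_, residue_index = 1L,
                      residue_name = atoms_res, stringsAsFactors = FALSE)
  sys <- new_system(atoms, positions, box)
  attr(sys, "spec") <- spec
  sys
}

# one-bead waters on a cubic grid in the two slabs flanking the bilayer
water_slab <- function(n, box, z_mid, leaflet_sep) {
  margin <- 1.2
  zlo <- c(0.5, z_mid + leaflet_sep / 2 + margin)
  zhi <- c(z_mid - leaflet_sep / 2 - margin, box[3L] - 0.5)
  sp <- 0.31
  pts <- list()
  for (slab in 1:2) {
    zs <- seq(zlo[slab], zhi[slab], by = sp)
    xs <- seq(sp / 2, box[1L] - sp / 2, by = sp)
    ys <- seq(sp / 2, box[2L] - sp / 2, by = sp)
    pts[[slab]] <- as.matrix(expand.grid(xs, ys, zs))
  }
  all <- rbind(pts[[2L]], pts[[1L]])
  if (nrow(all) < n) stop("water slab capacity exceeded", call. = FALSE)
  all[seq_len(n), , drop = FALSE]
}

#' Build a synthetic oligomer
#'
#' One backbone bead per residue; each chain is a compact random walk (bond
#' 0.38 nm) confined to a sphere. Successive chains are slid toward the
#' already-placed ones until the minimum inter-chain bead distance lies just
#' inside the attractive Lennard-Jones well (0.55-0.60 nm), so the monomers
#' of an aggregate are distinct but genuinely coupled. Deterministic given
#' the seed.
#'
#' @param model oligomer model name (see [oligomer_chains()]).
#' @param seed integer seed.
#' @return list with `atoms` (protein atom table) and `positions` (relative
#'   coordinates, nm, centred on the lowest bead).
#' @export
build_oligomer <- function(model, seed = 1L) {
  chains <- oligomer_chains(model)
  set.seed(seed)
  atoms <- list()
  pos <- list()
  for (ci in seq_len(nrow(chains))) {
    sq <- strsplit(chains$sequence[ci], "")[[1L]]
    L <- length(sq)
    rmax <- 0.38 * ceiling(sqrt(L)) / 2 + 0.5
    p <- matrix(0, L, 3L)
    centre <- c(0, 0, 0)
    for (k in 2:L) {
      repeat {
        step <- stats::rnorm(3L)
        step <- 0.38 * step / sqrt(sum(step^2))
        cand <- p[k - 1L, ] + step
        if (sqrt(sum((cand - centre)^2)) <= rmax) break
      }
      p[k, ] <- cand
    }
    # slide the chain in from far out along its own ring direction until it
    # touches the already-placed chains (min bead distance <= 0.6 nm; the
    # 0.05 step bounds it below by ~0.55 nm)
    if (ci > 1L) {
      ang <- 2 * pi * (ci - 1L) / nrow(chains)
      dir <- c(cos(ang), sin(ang), 0)
      placed <- do.call(rbind, pos)
      p0 <- sweep(p, 2L, colMeans(p))
      t_off <- max(8, 2 * rmax + 4)
      repeat {
        cand <- sweep(p0, 2L, -dir * t_off)
        dmin <- min(rowmin_cross_dist(cand, placed,
                                      c(1e6, 1e6, 1e6)))
        if (dmin <= 0.6 || t_off <= 0) break
        t_off <- t_off - 0.05
      }
      p <- cand
    }
    atoms[[ci]] <- data.frame(
      atom_index = NA_integer_, atom_name = "BB", type_key = "BB",
      molecule_id = ci, molecule_type = "PROTEIN",
      chain_id = chains$chain_id[ci], residue_index = seq_len(L),
      residue_name = aa_three_letter(chains$sequence[ci]),
      stringsAsFactors = FALSE)
    pos[[ci]] <- p
  }
  atoms <- do.call(rbind, atoms)
  positions <- do.call(rbind, pos)
  # centre laterally on the lowest bead so placement over an anchor is exact
  low <- which.min(positions[, 3L])
  positions <- sweep(positions, 2L, positions[low, ])
  list(atoms = atoms, positions = positions, model = model)
}

#' Combine a raft and an oligomer into one System
#'
#' The oligomer's lowest bead is placed directly above the anchor headgroup
#' bead (the anionic head nearest the Lo disc centre, or the head nearest the
#' centre when no anionic lipid is present) at the given clearance. Replicate
#' 2 and 3 shift the protein +2 / -2 nm along x, mirroring the replicated
#' starting placements of the binding simulations.
#'
#' @param raft a `raft_system` from [build_raft()].
#' @param oligomer result of [build_oligomer()].
#' @param height initial clearance between protein and membrane surface (nm,
#'   default 5).
#' @param replicate 1, 2 or 3.
#' @return a `raft_system` containing the raft plus the protein.
#' @export
build_complex <- function(raft, oligomer, height = 5, replicate = 1L) {
  stopifnot(replicate %in% 1:3)
  anchor <- anchor_head(raft)
  zmax <- max(raft$positions[raft$atoms$molecule_type %in% LIPID_TYPES, 3L])
  shift <- c(0, 2, -2)[replicate]
  target <- c(raft$positions[anchor, 1L] + shift,
              raft$positions[anchor, 2L], zmax + height)
  ppos <- sweep(oligomer$positions, 2L, -target)
  pat <- oligomer$atoms
  pat$molecule_id <- pat$molecule_id + max(raft$atoms$molecule_id)
  atoms <- rbind(raft$atoms, pat)
  atoms$atom_index <- seq_len(nrow(atoms))
  sys <- new_system(atoms, rbind(raft$positions, ppos), raft$box)
  attr(sys, "spec") <- attr(raft, "spec")
  attr(sys, "anchor") <- anchor
  attr(sys, "model") <- oligomer$model
  sys
}

# index of the anchor headgroup atom the protein binds over
anchor_head <- function(system) {
  at <- system$atoms
  spec <- attr(system, "spec")
  centre <- if (!is.null(spec)) spec$lo_center else system$box[1:2] / 2
  heads <- which(at$molecule_type %in% ANIONIC_TYPES &
                   at$atom_name %in% HEAD_BEADS)
  if (length(heads) == 0L) {
    heads <- which(at$molecule_type %in% LIPID_TYPES &
                     at$atom_name %in% HEAD_BEADS)
  }
  if (length(heads) == 0L) stop("no headgroup beads found", call. = FALSE)
  # upper-leaflet heads only: the protein approaches from above
  topz <- max(system$positions[heads, 3L])
  heads <- heads[system$positions[heads, 3L] > topz - 0.5]
  d <- sqrt(wrap_delta(system$positions[heads, 1L] - centre[1L],
                       system$box[1L])^2 +
              wrap_delta(system$positions[heads, 2L] - centre[2L],
                         system$box[2L])^2)
  heads[which.min(d)]
}

#' Specify a synthetic binding trajectory
#'
#' The schedule emulates the observed binding kinetics: the oligomer hovers
#' and diffuses above the membrane (minimum distance fluctuating between the
#' detachment floor and the release height), then at `t_bind` attaches and
#' stays at the stable minimum distance (about 0.5 nm for coarse-grained
#' resolution) plus Gaussian noise for the rest of the run. Acyl chains are
#' re-oriented every frame so their second-Legendre order parameter matches
#' `s_target`.
#'
#' @param n_frames number of frames (default 150).
#' @param frame_spacing time between frames (microseconds CG; default 0.1).
#' @param t_bind binding time (same units; default 3).
#' @param pre_floor lowest pre-binding clearance (nm, default 3; above the
#'   2 nm contact threshold so contacts are zero while unbound).
#' @param pre_height highest pre-binding clearance (nm, default 6).
#' @param stable_mindist post-binding minimum distance (nm, default 0.5).
#' @param noise_sd Gaussian noise on the post-binding clearance (nm,
#'   default 0.05), truncated at 1.96 sd so the bound state is a genuine
#'   plateau (the firmly-attached regime has no detachment excursions).
#' @param bound_flatten compression factor applied to the protein's internal
#'   z extent while bound (default 0.4), emulating the spreading of an
#'   adsorbed oligomer over the membrane surface.
#' @param s_target planted chain order parameter in `[-0.5, 1]` (default 0.8,
#'   an ordered-phase value).
#' @param seed integer seed.
#' @export
trajectory_spec <- function(n_frames = 150L, frame_spacing = 0.1,
                            t_bind = 3, pre_floor = 3, pre_height = 6,
                            stable_mindist = 0.5, noise_sd = 0.05,
                            s_target = 0.8, bound_flatten = 0.4,
                            seed = 1L) {
  final_t <- (n_frames - 1L) * frame_spacing
  if (t_bind < 0 || t_bind > final_t) {
    stop("t_bind must lie within [0, final frame time]", call. = FALSE)
  }
  if (s_target < -0.5 || s_target > 1) {
    stop("s_target must lie in [-0.5, 1]", call. = FALSE)
  }
  stopifnot(pre_floor > stable_mindist, pre_height >= pre_floor,
            noise_sd >= 0)
  structure(list(n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, t_bind = t_bind,
                 pre_floor = pre_floor, pre_height = pre_height,
                 stable_mindist = stable_mindist, noise_sd = noise_sd,
                 s_target = s_target, bound_flatten = bound_flatten,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Sample acyl-chain tilt angles with a prescribed order parameter
#'
#' Draws polar angles whose second-Legendre average `(3 cos^2 t - 1)/2`
#' equals `s_target` in expectation: a mixture of a delta component at the
#' pole (or, for negative targets, in the plane) and an isotropic component
#' whose order parameter is zero.
#'
#' @param s_target target order parameter in `[-0.5, 1]`.
#' @param n number of angles.
#' @param seed optional seed (the caller's RNG stream is used when `NULL`).
#' @return numeric vector of polar angles in `[0, pi/2]`.
#' @export
sample_chain_tilts <- function(s_target, n, seed = NULL) {
  if (s_target < -0.5 || s_target > 1) {
    stop("s_target must lie in [-0.5, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  iso <- acos(stats::runif(n))          # isotropic on the hemisphere
  if (s_target >= 0) {
    fixed <- 0
    p <- s_target
  } else {
    fixed <- pi / 2
    p <- -2 * s_target
  }
  pick <- stats::runif(n) < p
  ifelse(pick, fixed, iso)
}

#' Generate a synthetic binding trajectory
#'
#' Applies the [trajectory_spec()] schedule to a raft + oligomer System: the
#' protein translates rigidly (lateral diffusion while unbound, locked over
#' its anchor once bound) and every lipid acyl chain is re-oriented per frame
#' at tilt angles drawn for the planted order parameter. With `noise_sd = 0`
#' the post-binding minimum distance equals `stable_mindist` exactly.
#'
#' @param system a `raft_system` from [build_complex()] (one protein group).
#' @param spec a [trajectory_spec()].
#' @param resolution trajectory resolution tag (default `"CG"`).
#' @return a `raft_trajectory`.
#' @export
generate_binding_trajectory <- function(system, spec, resolution = "CG") {
  stopifnot(inherits(spec, "trajectory_spec"))
  at <- system$atoms
  prot <- which(at$molecule_type == "PROTEIN")
  if (length(prot) == 0L) stop("system contains no protein", call. = FALSE)
  lip <- which(at$molecule_type %in% LIPID_TYPES)
  set.seed(spec$seed)

  base <- system$positions
  zmax <- max(base[lip, 3L])
  anchor <- attr(system, "anchor") %||% anchor_head(system)
  lowest <- prot[which.min(base[prot, 3L])]

  # chain bookkeeping for per-frame re-orientation, grouped by chain length
  chains <- chain_index(system)

  times <- (seq_len(spec$n_frames) - 1L) * spec$frame_spacing
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    pos <- base
    bound <- times[f] >= spec$t_bind
    if (bound) {
      eps <- if (spec$noise_sd > 0) {
        max(-1.96, min(1.96, stats::rnorm(1L))) * spec$noise_sd
      } else 0
      gap <- max(spec$stable_mindist + eps, 0.05)
      lat <- c(0, 0)
    } else {
      gap <- stats::runif(1L, spec$pre_floor, spec$pre_height)
      lat <- stats::runif(2L, -1, 1)
    }
    ppos <- sweep(base[prot, , drop = FALSE], 2L, base[lowest, ])
    if (bound) ppos[, 3L] <- ppos[, 3L] * spec$bound_flatten
    pos[prot, ] <- sweep(ppos, 2L,
                         -c(base[anchor, 1L] + lat[1L],
                            base[anchor, 2L] + lat[2L], zmax + gap))
    # re-orient acyl chains at planted order
    for (g in chains) {
      nch <- nrow(g$anchor_idx)
      theta <- sample_chain_tilts(spec$s_target, nch)
      phi <- stats::runif(nch, 0, 2 * pi)
      dir <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                   -g$updown * cos(theta))
      apos <- base[g$anchor_idx[, 1L], , drop = FALSE]
      for (k in seq_len(g$len)) {
        pos[g$bead_idx[, k], ] <- apos + dir * (CHAIN_BOND * k)
      }
    }
    frames[[f]] <- new_frame(times[f], pos, system$box)
  }
  traj <- new_trajectory(system, frames, resolution)
  attr(traj, "spec") <- spec
  traj
}

# group lipid chains by bead count; each group holds the head-bead index each
# chain hangs from, the matrix of chain-bead indices, and the leaflet sign
chain_index <- function(system) {
  at <- system$atoms
  spec <- attr(system, "spec")
  z_mid <- system$box[3L] / 2
  groups <- list()
  for (ty in intersect(unique(at$molecule_type),
                       c("DPPC", "DLPC", "POPS", "GM1"))) {
    mols <- unique(at$molecule_id[at$molecule_type == ty])
    for (lab in c("A", "B")) {
      sel <- at$molecule_type == ty &
        grepl(paste0("^C[0-9]+", lab, "$"), at$atom_name)
      if (!any(sel)) next
      len <- sum(sel & at$molecule_id == mols[1L])
      bead <- matrix(0L, length(mols), len)
      for (k in seq_len(len)) {
        bead[, k] <- which(at$atom_name == paste0("C", k, lab) &
                             at$molecule_type == ty)
      }
      head <- which(at$molecule_type == ty &
                      at$atom_name == HEAD_BEADS[[ty]])
      updown <- ifelse(system$positions[head, 3L] >= z_mid, 1, -1)
      groups[[paste(ty, lab)]] <- list(
        anchor_idx = cbind(head), bead_idx = bead, len = len,
        updown = updown, type = ty, chain = lab)
    }
  }
  groups
}

#' Specify a synthetic secondary-structure stream
#'
#' @param fractions named numeric vector over `beta`, `alpha`, `turn`,
#'   `random`, non-negative and summing to 1 (tolerance 1e-9).
#' @param n_residues,n_frames trace dimensions.
#' @param seed integer seed.
#' @export
sstrace_spec <- function(fractions, n_residues, n_frames, seed = 1L) {
  stopifnot(setequal(names(fractions), SS_CATEGORIES))
  fractions <- fractions[SS_CATEGORIES]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(fractions = fractions, n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "sstrace_spec")
}

#' Generate a DSSP code stream with planted category fractions
#'
#' Every residue-frame cell draws its regrouped category from the planted
#' fractions and then a concrete DSSP letter uniformly within the category
#' (beta: E/B, alpha: H/G/I, turn: T, random: S/C).
#'
#' @param spec an [sstrace_spec()].
#' @return character matrix, frames in rows, residues in columns.
#' @export
generate_ss_trace <- function(spec) {
  stopifnot(inherits(spec, "sstrace_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames * spec$n_residues
  cats <- sample(SS_CATEGORIES, n, replace = TRUE, prob = spec$fractions)
  letters_of <- list(beta = c("E", "B"), alpha = c("H", "G", "I"),
                     turn = "T", random = c("S", "C"))
  codes <- vapply(cats, function(cg) {
    ls <- letters_of[[cg]]
    if (length(ls) == 1L) ls else sample(ls, 1L)
  }, character(1))
  matrix(codes, nrow = spec$n_frames, ncol = spec$n_residues)
}

#' Toy force-field table for the synthetic bead types
#'
#' Lennard-Jones sigma/epsilon and partial charges for every bead type the
#' generators emit. Whole-molecule charges sum to the formal charges: PS and
#' GM1 heads carry -1 e, phosphatidylcholine, cholesterol and water are
#' neutral, protein backbone beads carry a small +0.1 e so anionic contacts
#' are electrostatically favourable. The electrostatic prefactor
#' f = 138.935458 kJ mol^-1 nm e^-2 is stored as attribute `coulomb_f`.
#'
#' @return data.frame `type_key`, `sigma` (nm), `epsilon` (kJ/mol),
#'   `charge` (e).
#' @export
emit_forcefield_table <- function() {
  tab <- data.frame(
    type_key = c("NC3", "CNO", "GM0", "ROH", "RB", "CH", "W", "BB"),
    sigma = c(0.47, 0.47, 0.55, 0.43, 0.43, 0.47, 0.47, 0.47),
    epsilon = c(3.5, 3.5, 4.0, 3.0, 3.0, 2.5, 4.0, 3.0),
    charge = c(0, -1, -1, 0, 0, 0, 0, 0.1),
    stringsAsFactors = FALSE)
  validate_forcefield(tab, COULOMB_F)
}

#' Manifest for the synthetic systems
#'
#' @param model optional oligomer model whose chains the manifest should
#'   declare.
#' @return a `raft_manifest` covering the generator's residue names (lipids,
#'   water and, when `model` is given, the amino acids of its chains).
#' @export
synthetic_manifest <- function(model = NULL) {
  residues <- data.frame(
    residue_name = c("DPPC", "DLPC", "CHOL", "POPS", "GM1", "SOL", AA3),
    molecule_type = c("DPPC", "DLPC", "CHOL", "POPS", "GM1", "WATER",
                      rep("PROTEIN", length(AA3))),
    stringsAsFactors = FALSE)
  chains <- if (!is.null(model)) {
    oligomer_chains(model)[c("chain_id", "monomer_type", "sequence")]
  } else NULL
  manifest(residues, chains)
}
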