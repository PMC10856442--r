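# Molecular system and trajectory containers. Lightweight S3: a System is an
# atom table plus a position matrix and an orthorhombic box; a Trajectory is a
# System plus an ordered list of frames. Units are nm throughout.

MOLECULE_TYPES <- c("DPPC", "DLPC", "CHOL", "POPS", "GM1",
                    "WATER", "ION", "PROTEIN")
LIPID_TYPES <- c("DPPC", "DLPC", "CHOL", "POPS", "GM1")
PC_TYPES <- c("DPPC", "DLPC")

#' Construct a molecular System
#'
#' @param atoms data.frame with one row per atom and columns `atom_index`,
#'   `atom_name`, `type_key`, `molecule_id`, `molecule_type`, `chain_id`
#'   (protein only, `NA` otherwise), `residue_index` (1-based within chain),
#'   `residue_name`.
#' @param positions n-by-3 numeric matrix of coordinates (nm).
#' @param box numeric 3-vector of orthorhombic box edge lengths (nm).
#' @return object of class `raft_system`.
#' @export
new_system <- function(atoms, positions, box) {
  stopifnot(is.data.frame(atoms), is.matrix(positions), ncol(positions) == 3L)
  req <- c("atom_index", "atom_name", "type_key", "molecule_id",
           "molecule_type", "chain_id", "residue_index", "residue_name")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(atoms) != nrow(positions)) {
    stop("atoms and positions disagree on atom count", call. = FALSE)
  }
  if (!all(is.finite(positions))) stop("non-finite positions", call. = FALSE)
  if (!all(box > 0) || length(box) != 3L) {
    stop("box must be three positive edge lengths (orthorhombic only)",
         call. = FALSE)
  }
  bad <- setdiff(unique(atoms$molecule_type), MOLECULE_TYPES)
  if (length(bad)) stop("unknown molecule_type: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(atoms$residue_index < 1L, na.rm = TRUE)) {
    stop("residue_index must be >= 1", call. = FALSE)
  }
  structure(list(atoms = atoms, positions = positions, box = as.numeric(box)),
            class = "raft_system")
}

#' @export
print.raft_system <- function(x, ...) {
  tab <- table(x$atoms$molecule_type[!duplicated(x$atoms$molecule_id)])
  cat("<raft_system> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$molecule_id)), " molecules\n", sep = "")
  cat("  box: ", paste(sprintf("%.2f", x$box), collapse = " x "), " nm\n",
      sep = "")
  cat("  molecules:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(system) nrow(system$atoms)

#' Select atom indices
#'
#' @param system a `raft_system`.
#' @param molecule_type optional character vector of molecule types to keep.
#' @param chain_id optional chain identifier(s) (protein).
#' @param molecule_id optional molecule id(s).
#' @return integer vector of atom row indices; errors if empty.
#' @export
select_atoms <- function(system, molecule_type = NULL, chain_id = NULL,
                         molecule_id = NULL) {
  keep <- rep(TRUE, nrow(system$atoms))
  if (!is.null(molecule_type)) {
    keep <- keep & system$atoms$molecule_type %in% molecule_type
  }
  if (!is.null(chain_id)) keep <- keep & system$atoms$chain_id %in% chain_id
  if (!is.null(molecule_id)) {
    keep <- keep & system$atoms$molecule_id %in% molecule_id
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty atom selection", call. = FALSE)
  idx
}

#' Construct a trajectory Frame
#'
#' @param time frame time (microseconds for CG runs, nanoseconds for AA runs).
#' @param positions n-by-3 coordinate matrix (nm).
#' @param box orthorhombic box edge lengths (nm).
#' @export
new_frame <- function(time, positions, box) {
  stopifnot(is.matrix(positions), ncol(positions) == 3L, all(box > 0))
  if (!all(is.finite(positions))) stop("non-finite positions", call. = FALSE)
  structure(list(time = as.numeric(time), positions = positions,
                 box = as.numeric(box)), class = "raft_frame")
}

#' Construct a Trajectory
#'
#' @param system the owning `raft_system`.
#' @param frames list of `raft_frame` objects with strictly increasing times
#'   and the system's atom count.
#' @param resolution `"CG"` (coarse-grained, times in microseconds) or `"AA"`
#'   (all-atom, times in nanoseconds).
#' @export
new_trajectory <- function(system, frames, resolution = c("CG", "AA")) {
  resolution <- match.arg(resolution)
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  nat <- n_atoms(system)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$positions) != nat) {
      stop(sprintf("frame %d has %d atoms, system has %d",
                   k, nrow(frames[[k]]$positions), nat), call. = FALSE)
    }
  }
  structure(list(system = system, frames = frames, resolution = resolution),
            class = "raft_trajectory")
}

#' @export
print.raft_trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat("<raft_trajectory> ", length(x$frames), " frames (", x$resolution,
      "), t = ", if (length(times)) paste(range(times), collapse = " .. ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj a `raft_trajectory`.
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, function(f) f$time, numeric(1))
}

#' Frame indices inside an analysis window
#'
#' @param traj a `raft_trajectory`.
#' @param window numeric length-2 `c(tmin, tmax)` inclusive, or `NULL` for all
#'   frames.
#' @return integer vector of frame indices; errors when the window is empty.
#' @export
window_frames <- function(traj, window = NULL) {
  times <- frame_times(traj)
  if (is.null(window)) return(seq_along(times))
  stopifnot(length(window) == 2L)
  idx <- which(times >= window[1L] & times <= window[2L])
  if (length(idx) == 0L) {
    stop("analysis window contains no frames", call. = FALSE)
  }
  idx
}

# default per-type leaflet reference atom (headgroup bead / CHOL hydroxyl)
DEFAULT_REF_ATOMS <- c(DPPC = "NC3", DLPC = "NC3", POPS = "CNO",
                       GM1 = "GM0", CHOL = "ROH")

#' Assign lipids to bilayer leaflets
#'
#' Each lipid is labelled `upper` or `lower` by comparing the z coordinate of
#' its headgroup reference atom against the per-frame midplane, defined as the
#' mean reference-atom z over all lipids. Ties resolve to `upper`.
#'
#' @param system a `raft_system`.
#' @param frame a `raft_frame`, or `NULL` to use the system's own coordinates.
#' @param ref_atoms named character vector mapping lipid type to its reference
#'   atom name.
#' @return data.frame with `molecule_id`, `molecule_type`, `leaflet`.
#' @export
assign_leaflets <- function(system, frame = NULL,
                            ref_atoms = DEFAULT_REF_ATOMS) {
  pos <- if (is.null(frame)) system$positions else frame$positions
  at <- system$atoms
  lip <- at$molecule_type %in% LIPID_TYPES
  if (!any(lip)) stop("system contains no lipids", call. = FALSE)
  is_ref <- lip & at$atom_name == unname(ref_atoms[at$molecule_type])
  ref <- which(is_ref)
  mols <- unique(at$molecule_id[lip])
  if (!setequal(at$molecule_id[ref], mols)) {
    missing <- setdiff(mols, at$molecule_id[ref])
    stop("missing leaflet reference atom for molecule(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  z <- pos[ref, 3L]
  mid <- mean(z)
  data.frame(molecule_id = at$molecule_id[ref],
             molecule_type = at$molecule_type[ref],
             leaflet = ifelse(z >= mid, "upper", "lower"),
             stringsAsFactors = FALSE)
}
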