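# Periodic-boundary geometry kernels. All distances are in nm. The bilayer
# normal is the z axis: the minimum-image convention is applied laterally
# (x, y) always and in z only on request, since a planar bilayer breaks the
# symmetry along its normal.

wrap_delta <- function(d, L) d - L * round(d / L)

#' Minimum-image distance between points
#'
#' Euclidean distance under the minimum-image convention in x and y;
#' z is treated as non-periodic unless `periodic_z = TRUE`.
#'
#' @param a,b numeric 3-vectors or n-by-3 matrices of positions (nm).
#' @param box numeric 3-vector of orthorhombic box edge lengths (nm).
#' @param periodic_z apply the minimum image along z as well?
#' @return numeric vector of distances (nm).
#' @export
min_image_distance <- function(a, b, box, periodic_z = FALSE) {
  stopifnot(all(box > 0))
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  dx <- wrap_delta(a[, 1L] - b[, 1L], box[1L])
  dy <- wrap_delta(a[, 2L] - b[, 2L], box[2L])
  dz <- a[, 3L] - b[, 3L]
  if (periodic_z) dz <- wrap_delta(dz, box[3L])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Full cross squared-distance computation between point sets, chunked to bound
# memory. Returns, per row of A, the minimum distance to any row of B.
rowmin_cross_dist <- function(A, B, box, periodic_z = FALSE) {
  nA <- nrow(A)
  nB <- nrow(B)
  out <- numeric(nA)
  chunk <- max(1L, floor(4e6 / max(nB, 1L)))
  for (start in seq(1L, nA, by = chunk)) {
    idx <- start:min(nA, start + chunk - 1L)
    dx <- wrap_delta(outer(A[idx, 1L], B[, 1L], "-"), box[1L])
    dy <- wrap_delta(outer(A[idx, 2L], B[, 2L], "-"), box[2L])
    dz <- outer(A[idx, 3L], B[, 3L], "-")
    if (periodic_z) dz <- wrap_delta(dz, box[3L])
    d2 <- dx * dx + dy * dy + dz * dz
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Minimum distance between two atom groups
#'
#' The mindist of a pair of groups: the smallest minimum-image distance over
#' all cross pairs of atoms.
#'
#' @param A,B n-by-3 position matrices (nm).
#' @inheritParams min_image_distance
#' @return single numeric distance (nm).
#' @export
group_mindist <- function(A, B, box, periodic_z = FALSE) {
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop("empty selection: both groups need at least one atom", call. = FALSE)
  }
  min(rowmin_cross_dist(A, B, box, periodic_z))
}

#' Neighbour pairs within a cutoff (cell-list search)
#'
#' Finds all cross pairs (i in A, j in B) whose minimum-image distance is at
#' most `cutoff`, using spatial binning at the cutoff length so the search is
#' close to linear in atom count. Results are identical to the all-pairs scan.
#'
#' @param A,B n-by-3 position matrices (nm).
#' @param box orthorhombic box (nm).
#' @param cutoff distance threshold (nm); the comparison is inclusive.
#' @param periodic_z apply the minimum image along z as well?
#' @return data.frame with columns `i` (row in A), `j` (row in B), `dist` (nm).
#' @export
close_pairs <- function(A, B, box, cutoff, periodic_z = FALSE) {
  stopifnot(cutoff > 0, all(box > 0))
  nA <- nrow(A)
  nB <- nrow(B)
  if (nA == 0L || nB == 0L) {
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  }
  # lateral cells are periodic; z cells are clamped unless periodic_z
  ncell <- pmax(1L, floor(box / cutoff))
  if (!periodic_z) {
    # non-periodic z: derive cells from the data extent instead of the box
    zr <- range(c(A[, 3L], B[, 3L]))
    zspan <- max(zr[2L] - zr[1L], cutoff)
    ncell[3L] <- max(1L, floor(zspan / cutoff))
  }
  cellsize <- c(box[1L] / ncell[1L], box[2L] / ncell[2L], NA_real_)
  z0 <- if (periodic_z) 0 else min(c(A[, 3L], B[, 3L]))
  zspan <- if (periodic_z) box[3L] else
    max(max(c(A[, 3L], B[, 3L])) - z0, cutoff)
  cellsize[3L] <- zspan / ncell[3L]

  cell_of <- function(P) {
    ix <- floor(((P[, 1L] %% box[1L]) / cellsize[1L])) %% ncell[1L]
    iy <- floor(((P[, 2L] %% box[2L]) / cellsize[2L])) %% ncell[2L]
    if (periodic_z) {
      iz <- floor(((P[, 3L] %% box[3L]) / cellsize[3L])) %% ncell[3L]
    } else {
      iz <- pmin(ncell[3L] - 1L, pmax(0L, floor((P[, 3L] - z0) / cellsize[3L])))
    }
    cbind(ix, iy, iz)
  }
  key_of <- function(ixyz) {
    ixyz[, 1L] + ncell[1L] * (ixyz[, 2L] + ncell[2L] * ixyz[, 3L])
  }

  cA <- cell_of(A)
  cB <- cell_of(B)
  binsB <- split(seq_len(nB), key_of(cB))

  # neighbour offsets; when a dimension has < 3 cells every cell is its own
  # neighbour, so collapse offsets to the unique set after wrapping
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  keyA <- key_of(cA)
  res_i <- vector("list", 0L)
  res_j <- vector("list", 0L)
  res_d <- vector("list", 0L)
  for (ka in unique(keyA)) {
    ia <- which(keyA == ka)
    base <- cA[ia[1L], ]
    nx <- (base[1L] + offs$dx) %% ncell[1L]
    ny <- (base[2L] + offs$dy) %% ncell[2L]
    nz <- base[3L] + offs$dz
    if (periodic_z) {
      nz <- nz %% ncell[3L]
      keep <- rep(TRUE, length(nz))
    } else {
      keep <- nz >= 0L & nz < ncell[3L]
    }
    nkeys <- unique(nx[keep] + ncell[1L] * (ny[keep] + ncell[2L] * nz[keep]))
    jb <- unlist(binsB[as.character(nkeys)], use.names = FALSE)
    if (is.null(jb) || length(jb) == 0L) next
    dx <- wrap_delta(outer(A[ia, 1L], B[jb, 1L], "-"), box[1L])
    dy <- wrap_delta(outer(A[ia, 2L], B[jb, 2L], "-"), box[2L])
    dz <- outer(A[ia, 3L], B[jb, 3L], "-")
    if (periodic_z) dz <- wrap_delta(dz, box[3L])
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    res_i[[length(res_i) + 1L]] <- ia[hit[, 1L]]
    res_j[[length(res_j) + 1L]] <- jb[hit[, 2L]]
    res_d[[length(res_d) + 1L]] <- d[hit]
  }
  if (length(res_i) == 0L) {
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  }
  data.frame(i = unlist(res_i), j = unlist(res_j), dist = unlist(res_d))
}

#' Count cross pairs within a cutoff
#'
#' @inheritParams close_pairs
#' @return integer pair count.
#' @export
count_within <- function(A, B, box, cutoff, periodic_z = FALSE) {
  nrow(close_pairs(A, B, box, cutoff, periodic_z))
}
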