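# Protein-level analyses: hydropathy profiles, DSSP secondary-structure
# regrouping and accounting, and time-averaged residue contact maps.

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 standard one-letter codes, on the
#'   original scale (range -4.5 to 4.5, Ile highest, Arg lowest).
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Hydropathy profile of a sequence
#'
#' Per-residue Kyte-Doolittle index followed by a centered moving average
#' (default 5 points, the convention used for hydrophobicity profiles of
#' amyloid peptides). The window truncates at the termini rather than padding.
#'
#' @param sequence one-letter amino-acid string.
#' @param window odd moving-average window length (default 5); `window = 1`
#'   returns the raw lookup.
#' @return data.frame with `residue`, `raw`, `smoothed`.
#' @export
hydropathy_profile <- function(sequence, window = 5L) {
  aa <- strsplit(sequence, "")[[1L]]
  scale <- kyte_doolittle()
  raw <- unname(scale[aa])
  if (anyNA(raw)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(aa[is.na(raw)]), collapse = ", "), call. = FALSE)
  }
  data.frame(residue = seq_along(raw), raw = raw,
             smoothed = moving_average(raw, window))
}

#' Local maxima of a profile
#'
#' Indices whose value is >= both neighbours (plateau edges count); used to
#' locate hydrophobic anchor residues on smoothed profiles.
#'
#' @param x numeric vector.
#' @return integer vector of indices.
#' @export
local_maxima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    x[i] >= max(x[max(1L, i - 1L):min(n, i + 1L)])
  }, logical(1)))
}

# DSSP one-letter code -> regrouped category
DSSP_GROUPS <- c(E = "beta", B = "beta",
                 H = "alpha", G = "alpha", I = "alpha",
                 T = "turn",
                 S = "random", C = "random", "~" = "random", " " = "random")
SS_CATEGORIES <- c("beta", "alpha", "turn", "random")

#' Regroup DSSP codes into beta/alpha/turn/random counts
#'
#' Collapses the eight DSSP states: sheets and bridges (E, B) into `beta`;
#' the alpha-, 3-10- and pi-helices (H, G, I) into `alpha`; turns (T) stay
#' `turn`; bends and coil (S, C, blank or `~`) become `random` -- the
#' non-hydrogen-bonded states.
#'
#' @param trace character matrix of DSSP codes, frames in rows, residues in
#'   columns.
#' @return data.frame with one row per frame and columns `frame`, `beta`,
#'   `alpha`, `turn`, `random`; each row sums to the residue count.
#' @export
regroup_dssp <- function(trace) {
  if (!is.matrix(trace)) trace <- matrix(trace, nrow = 1L)
  codes <- unique(as.vector(trace))
  bad <- setdiff(codes, names(DSSP_GROUPS))
  if (length(bad)) {
    stop("unknown DSSP code(s): ", paste(shQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  cat_mat <- matrix(DSSP_GROUPS[trace], nrow = nrow(trace))
  counts <- t(apply(cat_mat, 1L, function(row) {
    tab <- table(factor(row, levels = SS_CATEGORIES))
    as.integer(tab)
  }))
  out <- data.frame(frame = seq_len(nrow(trace)), counts)
  names(out) <- c("frame", SS_CATEGORIES)
  out
}

#' Summarise secondary-structure counts over replicates
#'
#' Per replicate, the per-frame category counts (optionally restricted to a
#' residue subset, e.g. one constituent chain of a hetero-oligomer) are
#' averaged over the window frames; the summary reports the replicate mean
#' and SEM per category.
#'
#' @param traces list of DSSP code matrices, one per replicate, aligned in
#'   the residue dimension.
#' @param frames optional integer vector of frame rows to use (the analysis
#'   window); defaults to all frames.
#' @param residues optional integer vector of residue columns to keep.
#' @return data.frame `category`, `mean`, `sem`, with attribute
#'   `n_residues` (size of the accounted residue set).
#' @export
ss_summary <- function(traces, frames = NULL, residues = NULL) {
  if (is.matrix(traces)) traces <- list(traces)
  nres <- unique(vapply(traces, ncol, integer(1)))
  if (length(nres) != 1L) {
    stop("replicate traces disagree in residue dimension", call. = FALSE)
  }
  per_rep <- lapply(traces, function(tr) {
    if (!is.null(frames)) {
      if (any(frames < 1L | frames > nrow(tr))) {
        stop("window frames outside trace span", call. = FALSE)
      }
      tr <- tr[frames, , drop = FALSE]
    }
    if (!is.null(residues)) tr <- tr[, residues, drop = FALSE]
    colMeans(regroup_dssp(tr)[SS_CATEGORIES])
  })
  mat <- do.call(rbind, per_rep)
  out <- data.frame(category = SS_CATEGORIES,
                    mean = colMeans(mat),
                    sem = apply(mat, 2L, sem),
                    row.names = NULL)
  attr(out, "n_residues") <- if (is.null(residues)) nres else length(residues)
  out
}

#' Stack secondary-structure summaries
#'
#' Sums the category means (and residue totals) of several summaries, e.g.
#' to compare the sum of a homo-tau and a homo-amylin oligomer against the
#' hetero-oligomer of matching total size. SEMs combine in quadrature under
#' independence.
#'
#' @param ... summaries from [ss_summary()].
#' @export
ss_stack <- function(...) {
  parts <- list(...)
  mean_sum <- Reduce(`+`, lapply(parts, function(p) p$mean))
  sem_sum <- sqrt(Reduce(`+`, lapply(parts, function(p) {
    ifelse(is.na(p$sem), 0, p$sem)^2
  })))
  out <- data.frame(category = SS_CATEGORIES, mean = mean_sum, sem = sem_sum)
  attr(out, "n_residues") <-
    sum(vapply(parts, function(p) attr(p, "n_residues"), numeric(1)))
  out
}

# ---- residue contact maps --------------------------------------------------

# residue keys of the protein atoms, in order of first appearance
protein_residue_keys <- function(system) {
  at <- system$atoms
  sel <- which(at$molecule_type == "PROTEIN")
  if (length(sel) == 0L) stop("system contains no protein", call. = FALSE)
  key <- paste(at$chain_id[sel], at$residue_index[sel], sep = ":")
  list(sel = sel, key = key, levels = unique(key))
}

#' Time-averaged residue-residue minimum-distance map
#'
#' For every residue pair (across all protein chains) the per-frame minimum
#' atom-pair distance is computed; the map holds its time mean over the
#' window together with a per-entry standard deviation (population SD over
#' frames, so a single frame yields an identically zero SD matrix). No pairs
#' are excluded: the diagonal is zero and sequence-adjacent pairs are kept.
#'
#' @param traj a `raft_trajectory` containing protein atoms.
#' @param window analysis window `c(tmin, tmax)` or `NULL` for all frames.
#' @return object of class `raft_contact_map`: list with `mean` and `sd`
#'   matrices (nm) and `residues` (chain:index labels).
#' @export
residue_contact_map <- function(traj, window = NULL) {
  rk <- protein_residue_keys(traj$system)
  nres <- length(rk$levels)
  grp <- match(rk$key, rk$levels)
  idx <- window_frames(traj, window)
  # Welford accumulation: exact zero SD for constant entries
  mean_m <- matrix(0, nres, nres)
  m2 <- matrix(0, nres, nres)
  nseen <- 0L
  for (k in idx) {
    pos <- traj$frames[[k]]$positions[rk$sel, , drop = FALSE]
    box <- traj$frames[[k]]$box
    dx <- wrap_delta(outer(pos[, 1L], pos[, 1L], "-"), box[1L])
    dy <- wrap_delta(outer(pos[, 2L], pos[, 2L], "-"), box[2L])
    dz <- outer(pos[, 3L], pos[, 3L], "-")
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    # reduce atoms -> residues by min, rows then columns
    dr <- rowsum_min(d, grp)
    dm <- t(rowsum_min(t(dr), grp))
    nseen <- nseen + 1L
    delta <- dm - mean_m
    mean_m <- mean_m + delta / nseen
    m2 <- m2 + delta * (dm - mean_m)
  }
  out <- list(mean = mean_m, sd = sqrt(m2 / nseen), residues = rk$levels,
              n_frames = nseen)
  class(out) <- "raft_contact_map"
  out
}

# per-group row minimum of a matrix (groups along rows)
rowsum_min <- function(m, grp) {
  ng <- max(grp)
  out <- matrix(Inf, ng, ncol(m))
  for (g in seq_len(ng)) {
    rows <- which(grp == g)
    out[g, ] <- if (length(rows) == 1L) m[rows, ] else
      do.call(pmin, lapply(rows, function(r) m[r, ]))
  }
  out
}

#' @export
print.raft_contact_map <- function(x, ...) {
  cat("<raft_contact_map> ", length(x$residues), " residues, averaged over ",
      x$n_frames, " frame(s)\n", sep = "")
  invisible(x)
}

#' Cross-chain block of a contact map
#'
#' Extracts the rectangular mean/SD block describing the interface between
#' two disjoint residue sets (typically two chains), e.g. the 130 x 37
#' tau-amylin interface of the hetero-dimer.
#'
#' @param map a `raft_contact_map`.
#' @param residues_a,residues_b disjoint integer vectors of residue indices
#'   into `map$residues`.
#' @return list with `mean` and `sd` submatrices and dimnames from the
#'   residue labels.
#' @export
interface_map <- function(map, residues_a, residues_b) {
  if (length(intersect(residues_a, residues_b))) {
    stop("interface residue ranges overlap", call. = FALSE)
  }
  nres <- length(map$residues)
  if (any(c(residues_a, residues_b) < 1L) ||
      any(c(residues_a, residues_b) > nres)) {
    stop("residue indices outside the map", call. = FALSE)
  }
  sub <- function(m) {
    s <- m[residues_a, residues_b, drop = FALSE]
    dimnames(s) <- list(map$residues[residues_a], map$residues[residues_b])
    s
  }
  list(mean = sub(map$mean), sd = sub(map$sd))
}

#' Residue indices of one chain inside a contact map
#' @param map a `raft_contact_map`.
#' @param chain_id chain identifier.
#' @export
map_chain_residues <- function(map, chain_id) {
  idx <- grep(paste0("^", chain_id, ":"), map$residues)
  if (length(idx) == 0L) stop("chain ", chain_id, " not in map",
                              call. = FALSE)
  idx
}
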