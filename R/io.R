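# Structure and trajectory file I/O. GRO files (fixed width, nm) are the
# native dialect; PDB (Angstrom, converted on read) is supported for single
# structures. Boxes must be orthorhombic; triclinic records are rejected.
# Multi-frame GRO trajectories carry the frame time in a "t=" token of the
# title line.

# ---- topology manifest -----------------------------------------------------

#' Build a topology manifest
#'
#' A manifest maps residue names in a structure file to molecule types and,
#' for proteins, defines the chains (id, monomer type, sequence) in the order
#' their residues appear in the file.
#'
#' @param residues data.frame with columns `residue_name`, `molecule_type`.
#' @param chains optional data.frame with columns `chain_id`, `monomer_type`,
#'   `sequence` (one-letter amino acids).
#' @export
manifest <- function(residues, chains = NULL) {
  stopifnot(is.data.frame(residues),
            all(c("residue_name", "molecule_type") %in% names(residues)))
  if (!is.null(chains)) {
    stopifnot(all(c("chain_id", "monomer_type", "sequence") %in%
                    names(chains)))
  }
  structure(list(residues = residues, chains = chains),
            class = "raft_manifest")
}

#' Write a manifest to JSON
#' @param m a `raft_manifest`.
#' @param path output file.
#' @export
write_manifest <- function(m, path) {
  jsonlite::write_json(list(residues = m$residues, chains = m$chains),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a manifest from JSON
#' @param path manifest file written by [write_manifest()].
#' @export
read_manifest <- function(path) {
  x <- jsonlite::fromJSON(path)
  manifest(residues = as.data.frame(x$residues),
           chains = if (is.null(x$chains)) NULL else as.data.frame(x$chains))
}

# package rule mapping generator bead names to force-field type keys; real
# structures can override via the force-field table's own keys
assign_type_key <- function(atom_name) {
  out <- atom_name
  out[grepl("^C[0-9]+[AB]$", atom_name)] <- "CH"
  out[atom_name %in% c("R1", "R2")] <- "RB"
  out
}

# ---- GRO -------------------------------------------------------------------

parse_gro_box <- function(line, path) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (length(vals) < 3L || anyNA(vals[1:3])) {
    stop("malformed GRO box line in ", path, ": ", line, call. = FALSE)
  }
  if (length(vals) > 3L && any(abs(vals[-(1:3)]) > 1e-9)) {
    stop("triclinic box in ", path, " is not supported", call. = FALSE)
  }
  vals[1:3]
}

parse_gro_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m) == 0L) return(NA_real_)
  as.numeric(sub("t=\\s*", "", m))
}

# parse one GRO frame starting at line `at`; returns fields + next line index
parse_gro_frame <- function(lines, at, path) {
  title <- lines[at]
  nat <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
  if (is.na(nat) || nat < 0L) {
    stop("malformed atom-count line ", at + 1L, " in ", path, call. = FALSE)
  }
  rows <- lines[(at + 2L):(at + 1L + nat)]
  resid <- suppressWarnings(as.integer(substr(rows, 1L, 5L)))
  resname <- trimws(substr(rows, 6L, 10L))
  atname <- trimws(substr(rows, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(rows, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(rows, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(rows, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("malformed fixed-width GRO record at line ", at + 1L + bad[1L],
         " in ", path, call. = FALSE)
  }
  box <- parse_gro_box(lines[at + 2L + nat], path)
  list(title = title, time = parse_gro_time(title), resid = resid,
       resname = resname, atom_name = atname,
       positions = cbind(x, y, z, deparse.level = 0L),
       box = box, next_at = at + 3L + nat)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  at <- 1L
  while (at <= length(lines) && nzchar(trimws(lines[at]))) {
    fr <- parse_gro_frame(lines, at, path)
    frames[[length(frames) + 1L]] <- fr
    at <- fr$next_at
  }
  if (length(frames) == 0L) stop("no frames in ", path, call. = FALSE)
  frames
}

format_gro_frame <- function(resid, resname, atom_name, positions, box,
                             title) {
  n <- length(resid)
  rows <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  resid %% 100000L, resname, atom_name,
                  seq_len(n) %% 100000L,
                  positions[, 1L], positions[, 2L], positions[, 3L])
  c(title, sprintf("%5d", n), rows,
    sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]))
}

#' Write a System to a GRO file
#'
#' @param system a `raft_system`.
#' @param path output file.
#' @param positions optional coordinate matrix overriding the system's own
#'   (used when writing a specific frame).
#' @param title title line; a `t=` token is appended when `time` is given.
#' @param time optional frame time stored in the title line.
#' @param append append a frame to an existing multi-frame file?
#' @export
write_gro <- function(system, path, positions = NULL, title = "raftbind",
                      time = NULL, append = FALSE) {
  pos <- positions %||% system$positions
  if (!is.null(time)) title <- sprintf("%s t= %.6f", title, time)
  key <- paste(system$atoms$molecule_id, system$atoms$residue_index)
  resid <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  out <- format_gro_frame(resid, system$atoms$residue_name,
                          system$atoms$atom_name, pos, system$box, title)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write a Trajectory to a multi-frame GRO file
#'
#' @param traj a `raft_trajectory`.
#' @param path output file.
#' @export
write_trajectory_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$system$atoms
  key <- paste(at$molecule_id, at$residue_index)
  resid <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  for (fr in traj$frames) {
    out <- format_gro_frame(resid, at$residue_name, at$atom_name,
                            fr$positions, fr$box,
                            sprintf("raftbind t= %.6f", fr$time))
    writeLines(out, con)
  }
  invisible(path)
}

# ---- PDB -------------------------------------------------------------------

read_pdb_frame <- function(path) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) == 0L) {
    stop("PDB file ", path, " has no CRYST1 record (box required)",
         call. = FALSE)
  }
  a <- as.numeric(substr(cryst[1L], 7L, 15L))
  b <- as.numeric(substr(cryst[1L], 16L, 24L))
  c_ <- as.numeric(substr(cryst[1L], 25L, 33L))
  angles <- as.numeric(c(substr(cryst[1L], 34L, 40L),
                         substr(cryst[1L], 41L, 47L),
                         substr(cryst[1L], 48L, 54L)))
  if (any(abs(angles - 90) > 1e-6)) {
    stop("triclinic PDB box in ", path, " is not supported", call. = FALSE)
  }
  rows <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(rows) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  x <- suppressWarnings(as.numeric(substr(rows, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(rows, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(rows, 47L, 54L)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("malformed ATOM record in ", path, call. = FALSE)
  }
  resid <- suppressWarnings(as.integer(substr(rows, 23L, 26L)))
  # columns 18-21: tolerate the 4-character residue names common in
  # simulation-derived PDB files
  list(resid = resid,
       resname = trimws(substr(rows, 18L, 21L)),
       atom_name = trimws(substr(rows, 13L, 16L)),
       positions = cbind(x, y, z, deparse.level = 0L) / 10,  # Angstrom -> nm
       box = c(a, b, c_) / 10,
       time = NA_real_)
}

# ---- assembling a System from parsed records -------------------------------

assemble_system <- function(fr, m) {
  lut <- stats::setNames(m$residues$molecule_type, m$residues$residue_name)
  mt <- unname(lut[fr$resname])
  if (anyNA(mt)) {
    unknown <- unique(fr$resname[is.na(mt)])
    stop("residue name(s) absent from manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # residue runs: consecutive records sharing a file residue id
  rkey <- paste(fr$resid, fr$resname)
  res_run <- cumsum(c(TRUE, rkey[-1L] != rkey[-length(rkey)]))

  n <- length(mt)
  molecule_id <- integer(n)
  chain_id <- rep(NA_character_, n)
  residue_index <- rep(1L, n)

  is_prot <- mt == "PROTEIN"
  # non-protein: one molecule per residue run
  molecule_id[!is_prot] <- res_run[!is_prot]
  if (any(is_prot)) {
    if (is.null(m$chains)) {
      stop("protein residues present but manifest defines no chains",
           call. = FALSE)
    }
    prot_runs <- unique(res_run[is_prot])
    lens <- nchar(m$chains$sequence)
    if (sum(lens) != length(prot_runs)) {
      stop(sprintf(
        "manifest chains define %d residues but file has %d protein residues",
        sum(lens), length(prot_runs)), call. = FALSE)
    }
    chain_of_run <- rep(seq_along(lens), lens)
    residx_of_run <- unlist(lapply(lens, seq_len), use.names = FALSE)
    pos_in <- match(res_run[is_prot], prot_runs)
    chain_id[is_prot] <- m$chains$chain_id[chain_of_run[pos_in]]
    residue_index[is_prot] <- residx_of_run[pos_in]
    # each chain is one molecule, numbered after the last non-protein molecule
    base <- max(c(0L, molecule_id[!is_prot]))
    molecule_id[is_prot] <- base + chain_of_run[pos_in]
  }
  atoms <- data.frame(atom_index = seq_len(n),
                      atom_name = fr$atom_name,
                      type_key = assign_type_key(fr$atom_name),
                      molecule_id = molecule_id,
                      molecule_type = mt,
                      chain_id = chain_id,
                      residue_index = residue_index,
                      residue_name = fr$resname,
                      stringsAsFactors = FALSE)
  new_system(atoms, fr$positions, fr$box)
}

#' Read a structure file into a System
#'
#' @param path GRO or PDB file.
#' @param format `"gro"` or `"pdb"`; guessed from the extension by default.
#' @param manifest a `raft_manifest` classifying every residue name in the
#'   file (see [manifest()]).
#' @return a `raft_system`.
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"), manifest) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  fr <- if (format == "gro") read_gro_frames(path)[[1L]] else
    read_pdb_frame(path)
  assemble_system(fr, manifest)
}

#' Read a multi-frame trajectory
#'
#' Reads one or more (multi-frame) GRO files against an existing System.
#' Frames are ordered by their `t=` times; duplicate times are rejected and
#' every frame must carry the System's atom count.
#'
#' @param paths character vector of GRO files.
#' @param system the `raft_system` the frames belong to.
#' @param resolution `"CG"` or `"AA"`.
#' @return a `raft_trajectory`.
#' @export
read_trajectory <- function(paths, system, resolution = c("CG", "AA")) {
  resolution <- match.arg(resolution)
  nat <- n_atoms(system)
  frames <- list()
  for (p in paths) {
    for (fr in read_gro_frames(p)) {
      k <- length(frames) + 1L
      if (nrow(fr$positions) != nat) {
        stop(sprintf("frame %d (%s) has %d atoms, system has %d",
                     k, p, nrow(fr$positions), nat), call. = FALSE)
      }
      tm <- if (is.na(fr$time)) k - 1 else fr$time
      frames[[k]] <- new_frame(tm, fr$positions, fr$box)
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyDuplicated(times)) {
    stop("duplicate frame times: ",
         paste(unique(times[duplicated(times)]), collapse = ", "),
         call. = FALSE)
  }
  new_trajectory(system, frames[order(times)], resolution)
}

# ---- force-field table -----------------------------------------------------

#' Write a force-field table
#'
#' Tab-separated columns `type_key`, `sigma` (nm), `epsilon` (kJ/mol),
#' `charge` (e); the electrostatic prefactor is stored in a `# coulomb_f`
#' header comment.
#'
#' @param table force-field data.frame (see [emit_forcefield_table()]).
#' @param path output file.
#' @export
write_forcefield <- function(table, path) {
  f <- attr(table, "coulomb_f") %||% COULOMB_F
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coulomb_f %.9g", f), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a force-field table
#' @param path file written by [write_forcefield()].
#' @export
read_forcefield <- function(path) {
  first <- readLines(path, n = 1L)
  f <- if (grepl("^# coulomb_f", first)) {
    as.numeric(sub("^# coulomb_f\\s+", "", first))
  } else COULOMB_F
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  validate_forcefield(tab, f)
}
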