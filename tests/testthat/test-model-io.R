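make_one_atom_system <- function() {
  atoms <- data.frame(atom_index = 1L, atom_name = "NC3", type_key = "NC3",
                      molecule_id = 1L, molecule_type = "DPPC",
                      chain_id = NA_character_, residue_index = 1L,
                      residue_name = "DPPC", stringsAsFactors = FALSE)
  new_system(atoms, matrix(c(1.234, 2.345, 3.456), 1L), c(10, 11, 12))
}

test_that("GRO write/read round-trips a one-atom system", {
  sys <- make_one_atom_system()
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(sys, path)
  got <- read_structure(path, "gro", synthetic_manifest())
  expect_equal(got$atoms$atom_name, sys$atoms$atom_name)
  expect_equal(got$atoms$molecule_type, sys$atoms$molecule_type)
  expect_equal(got$positions, sys$positions, tolerance = 1e-9)
  expect_equal(got$box, sys$box)
})

test_that("unknown residue names raise a classification error naming them", {
  sys <- make_one_atom_system()
  sys$atoms$residue_name <- "XXX"
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(sys, path)
  expect_error(read_structure(path, "gro", synthetic_manifest()), "XXX")
})

test_that("raft fixture round-trips with molecule identity and ordering", {
  m <- build_raft(raft_spec("PS", "reduced", seed = 3))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(m, path)
  got <- read_structure(path, "gro", synthetic_manifest())
  expect_equal(got$atoms$atom_name, m$atoms$atom_name)
  expect_equal(got$atoms$molecule_type, m$atoms$molecule_type)
  expect_equal(got$atoms$molecule_id, m$atoms$molecule_id)
  expect_equal(got$positions, round(m$positions, 3), tolerance = 1e-9)
})

test_that("protein chains are reconstructed from the manifest", {
  m <- build_raft(raft_spec("PS", "reduced", seed = 4))
  sys <- build_complex(m, build_oligomer("1tam", seed = 5))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(sys, path)
  got <- read_structure(path, "gro", synthetic_manifest("1tam"))
  prot <- got$atoms[got$atoms$molecule_type == "PROTEIN", ]
  expect_equal(sum(prot$chain_id == "A"), 130)  # tau chain
  expect_equal(sum(prot$chain_id == "B"), 37)   # amylin chain
  expect_equal(prot$residue_index[prot$chain_id == "B"], 1:37)
  expect_equal(prot$residue_name,
               sys$atoms$residue_name[sys$atoms$molecule_type == "PROTEIN"])
})

test_that("trajectory reader orders frames, rejects bad atom counts", {
  sys <- make_one_atom_system()
  paths <- vapply(1:3, function(k) {
    p <- tempfile(fileext = ".gro")
    write_gro(sys, p, positions = matrix(c(k, k, k), 1L), time = k)
    p
  }, character(1))
  traj <- read_trajectory(paths[c(2, 3, 1)], sys)  # shuffled input order
  expect_equal(frame_times(traj), c(1, 2, 3))
  expect_equal(traj$frames[[2]]$positions[1, 1], 2)

  bad <- tempfile(fileext = ".gro")
  writeLines(c("broken t= 4", "    2",
               "    1DPPC   NC3    1   1.000   1.000   1.000",
               "    1DPPC   C1A    2   1.000   1.000   1.200",
               "  10.00000  11.00000  12.00000"), bad)
  expect_error(read_trajectory(c(paths[1], bad), sys), "frame 2")
  file.remove(c(paths, bad))
})

test_that("multi-frame trajectory round-trips at printed precision", {
  m <- build_raft(raft_spec("PS", "reduced",
                            counts = c(POPS = 4, DPPC = 12, DLPC = 8,
                                       CHOL = 6), seed = 6))
  sys <- build_complex(m, build_oligomer("1am", seed = 6))
  traj <- generate_binding_trajectory(
    sys, trajectory_spec(n_frames = 100, frame_spacing = 0.05, t_bind = 2,
                         seed = 6))
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory_gro(traj, path)
  got <- read_trajectory(path, sys)
  expect_equal(length(got$frames), 100)
  expect_equal(frame_times(got), frame_times(traj), tolerance = 1e-9)
  for (k in c(1, 37, 100)) {
    expect_identical(got$frames[[k]]$positions,
                     round(traj$frames[[k]]$positions, 3))
  }
})

test_that("duplicate frame times are rejected", {
  sys <- make_one_atom_system()
  p <- withr::local_tempfile(fileext = ".gro")
  write_gro(sys, p, time = 1)
  write_gro(sys, p, time = 1, append = TRUE)
  expect_error(read_trajectory(p, sys), "duplicate")
})

test_that("PDB reader converts Angstrom to nm and needs CRYST1", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1", 100, 110, 120,
            90, 90, 90),
    "ATOM      1  NC3 DPPC    1      12.340  23.450  34.560  1.00  0.00"),
    p)
  got <- read_structure(p, "pdb", synthetic_manifest())
  expect_equal(got$box, c(10, 11, 12))
  expect_equal(got$positions[1, ], c(1.234, 2.345, 3.456))
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  NC3 DPPC    1      12.340  23.450  34.560", p2)
  expect_error(read_structure(p2, "pdb", synthetic_manifest()), "CRYST1")
})

test_that("triclinic boxes are rejected", {
  sys <- make_one_atom_system()
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "    1",
               "    1DPPC   NC3    1   1.000   1.000   1.000",
               "  10.0  10.0  10.0  0.0  0.0  1.5  0.0  0.0  0.0"), p)
  expect_error(read_structure(p, "gro", synthetic_manifest()), "triclinic")
})

test_that("leaflet assignment splits by the reference-atom midplane", {
  atoms <- do.call(rbind, lapply(1:2, function(m) {
    data.frame(atom_index = m, atom_name = "NC3", type_key = "NC3",
               molecule_id = m, molecule_type = "DPPC",
               chain_id = NA_character_, residue_index = 1L,
               residue_name = "DPPC", stringsAsFactors = FALSE)
  }))
  sys <- new_system(atoms, rbind(c(1, 1, 5), c(1, 1, 3)), c(10, 10, 10))
  lf <- assign_leaflets(sys)
  expect_equal(lf$leaflet, c("upper", "lower"))
  # degenerate: identical z -> all upper (tie to upper)
  sys2 <- new_system(atoms, rbind(c(1, 1, 4), c(2, 2, 4)), c(10, 10, 10))
  expect_equal(assign_leaflets(sys2)$leaflet, c("upper", "upper"))
})

test_that("synthetic anionic lipids live in exactly one leaflet", {
  m <- build_raft(raft_spec("PS", "reduced", seed = 9))
  lf <- assign_leaflets(m)
  ps <- lf$leaflet[lf$molecule_type == "POPS"]
  expect_true(all(ps == "upper"))
  # leaflet labels partition the lipids
  expect_equal(sum(lf$leaflet %in% c("upper", "lower")), nrow(lf))
})

test_that("manifest and force-field tables round-trip through files", {
  mn <- synthetic_manifest("2tam")
  p <- withr::local_tempfile(fileext = ".json")
  write_manifest(mn, p)
  got <- read_manifest(p)
  expect_equal(got$residues, mn$residues)
  expect_equal(got$chains$sequence, mn$chains$sequence)

  tab <- emit_forcefield_table()
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_forcefield(tab, pf)
  got2 <- read_forcefield(pf)
  expect_equal(got2$sigma, tab$sigma)
  expect_equal(attr(got2, "coulomb_f"), attr(tab, "coulomb_f"))
})
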