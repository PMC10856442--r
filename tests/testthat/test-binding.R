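static_traj <- function(sys, n = 3) {
  frames <- lapply(seq_len(n) - 1L, function(t) {
    new_frame(t, sys$positions, sys$box)
  })
  new_trajectory(sys, frames, "CG")
}

test_that("mindist and contact series match the brute-force oracles", {
  set.seed(21)
  sys <- toy_lipid_system(10, c("DPPC", "POPS"), c(6, 6, 6),
                          atoms_per_mol = 4)
  sys <- add_toy_protein(sys, 20, centre = c(3, 3, 3))
  frames <- lapply(0:9, function(t) {
    new_frame(t, sys$positions + rnorm(length(sys$positions), 0, 0.3),
              sys$box)
  })
  traj <- new_trajectory(sys, frames, "CG")
  prot <- select_atoms(sys, molecule_type = "PROTEIN")
  lip <- select_atoms(sys, molecule_type = c("DPPC", "POPS"))
  md <- mindist_series(traj, prot, lip)
  cc <- contact_count_series(traj, prot, lip, 1.0)
  for (k in seq_along(frames)) {
    A <- frames[[k]]$positions[prot, , drop = FALSE]
    B <- frames[[k]]$positions[lip, , drop = FALSE]
    expect_equal(md$mindist[k], bf_mindist(A, B, sys$box))
    expect_equal(cc$contacts[k], bf_count_within(A, B, sys$box, 1.0))
  }
})

test_that("trivial mindist geometries come out exact", {
  atoms <- data.frame(atom_index = 1:2, atom_name = c("BB", "NC3"),
                      type_key = c("BB", "NC3"), molecule_id = 1:2,
                      molecule_type = c("PROTEIN", "DPPC"),
                      chain_id = c("A", NA), residue_index = 1L,
                      residue_name = c("ALA", "DPPC"),
                      stringsAsFactors = FALSE)
  sys <- new_system(atoms, rbind(c(0, 0, 0), c(0, 0, 1)), c(10, 10, 10))
  traj <- static_traj(sys)
  md <- mindist_series(traj, 1L, 2L)
  expect_equal(md$mindist, rep(1, 3))
  sys$positions[2, ] <- c(0, 0, 0)
  md0 <- mindist_series(static_traj(sys), 1L, 2L)
  expect_equal(md0$mindist, rep(0, 3))
  expect_error(mindist_series(traj, integer(0), 2L), "empty")
})

test_that("contact counting is multiplicative over close pairs", {
  # 2 protein atoms each within threshold of the same 3 group atoms -> 6
  atoms <- data.frame(atom_index = 1:5,
                      atom_name = c("BB", "BB", "NC3", "NC3", "NC3"),
                      type_key = c("BB", "BB", "NC3", "NC3", "NC3"),
                      molecule_id = c(1L, 1L, 2L, 3L, 4L),
                      molecule_type = c("PROTEIN", "PROTEIN", "DPPC",
                                        "DPPC", "DPPC"),
                      chain_id = c("A", "A", NA, NA, NA),
                      residue_index = 1L,
                      residue_name = c("ALA", "ALA", "DPPC", "DPPC", "DPPC"),
                      stringsAsFactors = FALSE)
  pos <- rbind(c(5, 5, 5), c(5.2, 5, 5),
               c(5.5, 5, 5), c(5, 5.5, 5), c(5, 5, 5.5))
  sys <- new_system(atoms, pos, c(10, 10, 10))
  cc <- contact_count_series(static_traj(sys, 1), 1:2, 3:5, 1.0)
  expect_equal(cc$contacts, 6L)
  # monotone in the threshold
  cc_small <- contact_count_series(static_traj(sys, 1), 1:2, 3:5, 0.4)
  expect_lte(cc_small$contacts, cc$contacts)
})

test_that("binding-time detector handles plateaus, onsets and unbound", {
  s <- data.frame(time = 0:4, mindist = c(5, 4, 0.5, 0.5, 0.5))
  expect_equal(detect_binding_time(s, 0.6), 2)
  s2 <- data.frame(time = 0:4, mindist = rep(0.5, 5))
  expect_equal(detect_binding_time(s2, 0.6), 0)
  s3 <- data.frame(time = 0:4, mindist = c(0.5, 0.5, 5, 0.5, 5))
  expect_true(is.na(detect_binding_time(s3, 0.6)))
  cc <- data.frame(time = 0:4, contacts = c(0, 0, 12, 30, 28))
  expect_equal(detect_binding_time(cc, mode = "contact_onset"), 2)
  # monotone non-increasing in d_bind
  s4 <- data.frame(time = 0:4, mindist = c(3, 1.2, 0.8, 0.55, 0.5))
  bts <- vapply(c(0.5, 0.8, 1.2, 3), function(d) {
    detect_binding_time(s4, d)
  }, numeric(1))
  expect_true(all(diff(bts) <= 0))
})

test_that("mindist spectrum averages residues, chains and replicates", {
  # two chains of two 1-bead residues against one target atom
  atoms <- data.frame(
    atom_index = 1:5,
    atom_name = c(rep("BB", 4), "NC3"),
    type_key = c(rep("BB", 4), "NC3"),
    molecule_id = c(1L, 1L, 2L, 2L, 3L),
    molecule_type = c(rep("PROTEIN", 4), "DPPC"),
    chain_id = c("A", "A", "B", "B", NA),
    residue_index = c(1L, 2L, 1L, 2L, 1L),
    residue_name = c(rep("ALA", 4), "DPPC"),
    stringsAsFactors = FALSE)
  pos <- rbind(c(5, 5, 5.2), c(5, 5, 5.6), c(5, 5, 5.4), c(5, 5, 5.8),
               c(5, 5, 5))
  sys <- new_system(atoms, pos, c(10, 10, 10))
  traj <- static_traj(sys, 2)
  sp <- mindist_spectrum(traj, chain_ids = c("A", "B"), sel_group = "DPPC")
  expect_equal(sp$mindist, c(0.3, 0.7), tolerance = 1e-9)
  # whole-protein spectrum equals per-chain minimum composition per frame
  spA <- mindist_spectrum(traj, "A", "DPPC")
  spB <- mindist_spectrum(traj, "B", "DPPC")
  expect_equal(sp$mindist, (spA$mindist + spB$mindist) / 2)
})

test_that("single-residue static spectrum returns the pair distance", {
  atoms <- data.frame(atom_index = 1:2, atom_name = c("BB", "NC3"),
                      type_key = c("BB", "NC3"), molecule_id = 1:2,
                      molecule_type = c("PROTEIN", "DPPC"),
                      chain_id = c("A", NA), residue_index = 1L,
                      residue_name = c("ALA", "DPPC"),
                      stringsAsFactors = FALSE)
  sys <- new_system(atoms, rbind(c(1, 1, 1), c(1, 1, 1.7)), c(10, 10, 10))
  sp <- mindist_spectrum(static_traj(sys, 1), "A", "DPPC")
  expect_equal(sp$mindist, 0.7)
  expect_true(is.na(sp$sem))
})

test_that("planted contact residues appear as spectrum minima", {
  m <- build_raft(raft_spec("PS", "reduced", seed = 22))
  sys <- build_complex(m, build_oligomer("1am", seed = 22))
  # bind immediately, flattened pose: the residues nearest the membrane are
  # exactly those with smallest internal z in the oligomer
  traj <- generate_binding_trajectory(
    sys, trajectory_spec(n_frames = 10, frame_spacing = 0.1, t_bind = 0,
                         noise_sd = 0, seed = 22))
  sp <- mindist_spectrum(traj, "A",
                         select_atoms(sys, molecule_type =
                                        raftbind:::LIPID_TYPES))
  prot <- select_atoms(sys, molecule_type = "PROTEIN")
  zrel <- traj$frames[[1]]$positions[prot, 3]
  expect_equal(which.min(sp$mindist), which.min(zrel))
  # residues low in the pose are closer than residues high in the pose
  expect_lt(sp$mindist[which.min(zrel)], sp$mindist[which.max(zrel)])
})

test_that("annular shell matches its rule and the oracle", {
  set.seed(23)
  sys <- toy_lipid_system(20, c("DPPC", "DLPC", "CHOL", "POPS"), c(7, 7, 4))
  sys <- add_toy_protein(sys, 15, centre = c(3.5, 3.5, 2))
  sh <- classify_annular_shell(sys)
  at <- sys$atoms
  prot <- which(at$molecule_type == "PROTEIN")
  for (m in sh$molecule_id) {
    mi <- which(at$molecule_id == m)
    dmin <- bf_mindist(sys$positions[mi, , drop = FALSE],
                       sys$positions[prot, , drop = FALSE], sys$box)
    expect_equal(sh$shell[sh$molecule_id == m],
                 if (dmin <= 0.5) "AL" else "nAL")
  }
  # AL and nAL partition the lipids
  expect_equal(nrow(sh), length(unique(
    at$molecule_id[at$molecule_type %in% raftbind:::LIPID_TYPES])))
})

test_that("shell threshold is an inclusive boundary at 0.5 nm", {
  atoms <- data.frame(
    atom_index = 1:3, atom_name = c("BB", "NC3", "NC3"),
    type_key = c("BB", "NC3", "NC3"), molecule_id = 1:3,
    molecule_type = c("PROTEIN", "DPPC", "DLPC"),
    chain_id = c("A", NA, NA), residue_index = 1L,
    residue_name = c("ALA", "DPPC", "DLPC"), stringsAsFactors = FALSE)
  pos <- rbind(c(5, 5, 5), c(5, 5, 5.45), c(5, 5, 5.55))
  sys <- new_system(atoms, pos, c(10, 10, 10))
  sh <- classify_annular_shell(sys)
  expect_equal(sh$shell[sh$molecule_type == "DPPC"], "AL")
  expect_equal(sh$shell[sh$molecule_type == "DLPC"], "nAL")
})

test_that("empty shells report absent percentages", {
  atoms <- data.frame(
    atom_index = 1:2, atom_name = c("BB", "NC3"),
    type_key = c("BB", "NC3"), molecule_id = 1:2,
    molecule_type = c("PROTEIN", "DPPC"), chain_id = c("A", NA),
    residue_index = 1L, residue_name = c("ALA", "DPPC"),
    stringsAsFactors = FALSE)
  sys <- new_system(atoms, rbind(c(1, 1, 1), c(5, 5, 5)), c(10, 10, 10))
  al <- al_composition(static_traj(sys, 2))
  expect_true(all(is.na(al$pct_al)))
  expect_equal(al$n_al, 0)
})
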