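test_that("12-6 pair energy has its root, minimum and decay", {
  expect_equal(pair_lj(0.47, 0.47, 3.5), 0)
  rmin <- 2^(1 / 6) * 0.47
  expect_equal(pair_lj(rmin, 0.47, 3.5), -3.5)
  # long range: negative and equal to the directly evaluated 12-6 tail
  far <- pair_lj(10 * 0.47, 0.47, 3.5)
  expect_lt(far, 0)
  expect_equal(far, 4 * 3.5 * (0.1^12 - 0.1^6), tolerance = 1e-12)
  expect_lt(abs(far), 1e-5 * 3.5)
  expect_error(pair_lj(0, 0.47, 3.5), "singular")
})

test_that("Coulomb pair energy matches the CODATA-derived constant", {
  # independent derivation: e^2 N_A / (4 pi eps0) in kJ mol^-1 nm e^-2
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  NA_ <- 6.02214076e23
  f_indep <- e^2 * NA_ / (4 * pi * eps0) / 1e3 / 1e-9
  expect_equal(COULOMB_F, f_indep, tolerance = 1e-7)
  expect_equal(pair_coulomb(1, 1, 1), f_indep, tolerance = 1e-7)
  expect_equal(pair_coulomb(1, 1, -1), -f_indep, tolerance = 1e-7)
  expect_equal(pair_coulomb(2, 0, 1), 0)
  expect_error(pair_coulomb(0, 1, 1), "singular")
})

test_that("group energies match the brute-force all-pairs oracle", {
  set.seed(41)
  tab <- emit_forcefield_table()
  f <- attr(tab, "coulomb_f")
  for (rep in 1:6) {
    sys <- toy_lipid_system(8, c("DPPC", "POPS", "CHOL"), c(5, 5, 5),
                            atoms_per_mol = 3)
    sys <- add_toy_protein(sys, 10, centre = c(2.5, 2.5, 2.5))
    sel_a <- select_atoms(sys, molecule_type = "PROTEIN")
    sel_b <- select_atoms(sys, molecule_type = c("DPPC", "POPS", "CHOL"))
    got <- group_interaction_energy(sys, NULL, sel_a, sel_b, tab,
                                    cutoff = 1.2)
    want <- bf_group_energy(sys, sys$positions, sel_a, sel_b, tab, 1.2, f)
    expect_equal(got$E_lj, unname(want["lj"]), tolerance = 1e-9)
    expect_equal(got$E_coulomb, unname(want["coulomb"]), tolerance = 1e-9)
    expect_equal(got$E_total, got$E_lj + got$E_coulomb, tolerance = 1e-12)
  }
})

test_that("energy is symmetric in group order and additive over partitions", {
  set.seed(42)
  tab <- emit_forcefield_table()
  sys <- toy_lipid_system(10, c("DPPC", "POPS"), c(5, 5, 5))
  sys <- add_toy_protein(sys, 12, centre = c(2.5, 2.5, 2.5))
  a <- select_atoms(sys, molecule_type = "PROTEIN")
  b <- select_atoms(sys, molecule_type = c("DPPC", "POPS"))
  e_ab <- group_interaction_energy(sys, NULL, a, b, tab)
  e_ba <- group_interaction_energy(sys, NULL, b, a, tab)
  expect_equal(e_ab$E_total, e_ba$E_total, tolerance = 1e-9)
  b1 <- select_atoms(sys, molecule_type = "DPPC")
  b2 <- select_atoms(sys, molecule_type = "POPS")
  e1 <- group_interaction_energy(sys, NULL, a, b1, tab)
  e2 <- group_interaction_energy(sys, NULL, a, b2, tab)
  expect_equal(e_ab$E_total, e1$E_total + e2$E_total, tolerance = 1e-9)
})

test_that("pairs beyond the cutoff contribute nothing", {
  atoms <- data.frame(
    atom_index = 1:2, atom_name = c("BB", "NC3"),
    type_key = c("BB", "NC3"), molecule_id = 1:2,
    molecule_type = c("PROTEIN", "DPPC"), chain_id = c("A", NA),
    residue_index = 1L, residue_name = c("ALA", "DPPC"),
    stringsAsFactors = FALSE)
  sys <- new_system(atoms, rbind(c(1, 1, 1), c(1, 1, 3)), c(10, 10, 10))
  tab <- emit_forcefield_table()
  e <- group_interaction_energy(sys, NULL, 1L, 2L, tab, cutoff = 1.2)
  expect_equal(e$E_total, 0)
  # two neutral atoms at the LJ minimum -> exactly -epsilon
  tab0 <- tab
  tab0$charge[] <- 0
  tab0 <- raftbind:::validate_forcefield(tab0)
  sig <- (0.47 + 0.47) / 2
  sys$positions[2, ] <- c(1, 1, 1 + 2^(1 / 6) * sig)
  eps <- sqrt(3.0 * 3.5)  # BB x NC3 combined
  e2 <- group_interaction_energy(sys, NULL, 1L, 2L, tab0, cutoff = 1.2)
  expect_equal(e2$E_lj, -eps, tolerance = 1e-9)
  expect_equal(e2$E_coulomb, 0)
})

test_that("missing type keys and overlapping groups are errors", {
  sys <- toy_lipid_system(2, "DPPC", c(5, 5, 5))
  tab <- emit_forcefield_table()
  sel <- select_atoms(sys, molecule_type = "DPPC")
  expect_error(group_interaction_energy(sys, NULL, sel, sel, tab),
               "disjoint")
  sys$atoms$type_key[1] <- "MYSTERY"
  expect_error(group_interaction_energy(sys, NULL, 1L, 4L, tab), "MYSTERY")
})

test_that("interchain energy sums chain pairs; monomers are not applicable", {
  m <- build_raft(raft_spec("PS", "reduced",
                            counts = c(POPS = 4, DPPC = 10, DLPC = 6,
                                       CHOL = 4), seed = 43))
  tab <- emit_forcefield_table()
  for (model in c("1tam", "2tam")) {
    sys <- build_complex(m, build_oligomer(model, seed = 43))
    traj <- generate_binding_trajectory(
      sys, trajectory_spec(n_frames = 3, frame_spacing = 0.1, t_bind = 0,
                           noise_sd = 0, seed = 43))
    got <- interchain_energy(traj, tab)
    chains <- oligomer_chains(model)$chain_id
    pairs <- utils::combn(chains, 2)
    manual <- 0
    fr <- traj$frames[[1]]
    for (p in seq_len(ncol(pairs))) {
      e <- group_interaction_energy(
        sys, fr, select_atoms(sys, chain_id = pairs[1, p]),
        select_atoms(sys, chain_id = pairs[2, p]), tab)
      manual <- manual + e$E_total
    }
    # noiseless bound state: every frame identical, so mean == frame sum
    expect_equal(got$E_total, manual, tolerance = 1e-9)
    expect_equal(ncol(pairs), if (model == "1tam") 1 else 6)
  }
  sys1 <- build_complex(m, build_oligomer("1am", seed = 43))
  traj1 <- generate_binding_trajectory(
    sys1, trajectory_spec(n_frames = 2, frame_spacing = 0.1, t_bind = 0,
                          seed = 43))
  expect_true(is.na(interchain_energy(traj1, tab)$E_total))
})

test_that("Coulomb terms scale bilinearly in the charges", {
  set.seed(44)
  sys <- toy_lipid_system(6, c("POPS", "DPPC"), c(5, 5, 5))
  sys <- add_toy_protein(sys, 8, centre = c(2.5, 2.5, 2.5))
  tab <- emit_forcefield_table()
  tab2 <- tab
  tab2$charge <- 2 * tab$charge
  tab2 <- raftbind:::validate_forcefield(tab2)
  a <- select_atoms(sys, molecule_type = "PROTEIN")
  b <- select_atoms(sys, molecule_type = c("POPS", "DPPC"))
  e1 <- group_interaction_energy(sys, NULL, a, b, tab)
  e2 <- group_interaction_energy(sys, NULL, a, b, tab2)
  expect_equal(e2$E_coulomb, 4 * e1$E_coulomb, tolerance = 1e-9)
  expect_equal(e2$E_lj, e1$E_lj, tolerance = 1e-9)
})

test_that("a protein parked on the anionic cluster ranks POPS first", {
  m <- build_raft(raft_spec("PS", "reduced", seed = 45))
  sys <- build_complex(m, build_oligomer("1tam", seed = 45))
  traj <- generate_binding_trajectory(
    sys, trajectory_spec(n_frames = 6, frame_spacing = 0.1, t_bind = 0,
                         seed = 45))
  tab <- emit_forcefield_table()
  e <- protein_lipidtype_energy(traj, tab)
  eps_total <- abs(e$E_total[e$molecule_type == "POPS"])
  others <- abs(e$E_total[e$molecule_type != "POPS"])
  expect_true(all(eps_total > 5 * others))
})
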