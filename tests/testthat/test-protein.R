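test_that("hydropathy profile: lookup, smoothing identity, poly-Ile", {
  p <- hydropathy_profile(strrep("I", 10))
  expect_equal(p$raw, rep(4.5, 10))
  expect_equal(p$smoothed, rep(4.5, 10))  # smoothing preserves constants
  p1 <- hydropathy_profile("KCNTAT", window = 1)
  expect_equal(p1$smoothed, p1$raw)
  expect_error(hydropathy_profile("AXA"), "X")
  expect_true(all(abs(hydropathy_profile(amylin_sequence())$raw) <= 4.5))
})

test_that("amylin's smoothed profile peaks at its hydrophobic anchors", {
  p <- hydropathy_profile(amylin_sequence())
  peaks <- local_maxima(p$smoothed)
  for (anchor in c(7, 16, 26, 32)) {
    expect_true(min(abs(peaks - anchor)) <= 1,
                label = sprintf("peak near residue %d", anchor))
  }
})

test_that("packaged sequences have the published lengths", {
  expect_equal(nchar(amylin_sequence()), 37)
  expect_equal(nchar(tau_sequence()), 130)
  expect_equal(oligomer_residues("1tam"), 167)
  expect_equal(oligomer_residues("2tam"), 334)
})

test_that("DSSP regrouping maps the eight states to four categories", {
  counts <- regroup_dssp(matrix(strsplit("HGIEBTSC", "")[[1]], nrow = 1))
  expect_equal(counts$alpha, 3)
  expect_equal(counts$beta, 2)
  expect_equal(counts$turn, 1)
  expect_equal(counts$random, 2)
  all_c <- regroup_dssp(matrix("C", 1, 37))
  expect_equal(all_c$random, 37)
  expect_equal(all_c$beta + all_c$alpha + all_c$turn, 0)
  expect_error(regroup_dssp(matrix("Z", 1, 3)), "Z")
})

test_that("category counts partition the residues every frame", {
  tr <- generate_ss_trace(sstrace_spec(
    c(beta = 0.3, alpha = 0.25, turn = 0.15, random = 0.3),
    n_residues = 167, n_frames = 50, seed = 51))
  counts <- regroup_dssp(tr)
  expect_true(all(rowSums(counts[c("beta", "alpha", "turn",
                                   "random")]) == 167))
})

test_that("ss_summary averages replicates and supports chain subsets", {
  tr1 <- matrix("E", 4, 20)
  tr2 <- matrix("C", 4, 20)
  tr2[, 1:14] <- "E"  # 14 beta per frame
  s <- ss_summary(list(tr1, tr2))
  expect_equal(s$mean[s$category == "beta"], (20 + 14) / 2)
  expect_equal(s$sem[s$category == "beta"], 3)  # sd(c(20,14))/sqrt(2)
  sub <- ss_summary(list(tr1, tr2), residues = 1:10)
  expect_equal(sub$mean[sub$category == "beta"], 10)
  expect_error(ss_summary(list(tr1, tr2), frames = 1:9), "span")
  expect_error(ss_summary(list(tr1, matrix("C", 4, 21))), "residue")
})

test_that("stacked homo sums match hetero totals (167 and 334 residues)", {
  mk <- function(model, seed) {
    n <- oligomer_residues(model)
    ss_summary(generate_ss_trace(sstrace_spec(
      c(beta = 0.25, alpha = 0.25, turn = 0.25, random = 0.25),
      n_residues = n, n_frames = 20, seed = seed)))
  }
  dimer <- ss_stack(mk("1tau", 1), mk("1am", 2))
  expect_equal(attr(dimer, "n_residues"), 167)
  expect_equal(attr(ss_stack(mk("2tau", 3), mk("2am", 4)), "n_residues"),
               334)
  expect_equal(attr(mk("1tam", 5), "n_residues"), 167)
  expect_equal(attr(mk("2tam", 6), "n_residues"), 334)
  # stacked means still sum to the residue total
  expect_equal(sum(dimer$mean), 167, tolerance = 1e-9)
})

test_that("planted SS fractions are recovered within 3 SE", {
  fr <- c(beta = 0.4, alpha = 0.3, turn = 0.1, random = 0.2)
  traces <- lapply(1:3, function(k) {
    generate_ss_trace(sstrace_spec(fr, 167, 100, seed = 50 + k))
  })
  s <- ss_summary(traces)
  for (cat in names(fr)) {
    want <- 167 * fr[[cat]]
    se <- sqrt(167 * fr[[cat]] * (1 - fr[[cat]]) / 300)
    expect_lt(abs(s$mean[s$category == cat] - want), 3 * se)
  }
})

test_that("contact maps match brute-force averaging and are symmetric", {
  traj <- make_walk_traj(10, 20)
  cm <- residue_contact_map(traj)
  expect_equal(cm$mean, t(cm$mean), tolerance = 1e-12)
  expect_equal(cm$sd, t(cm$sd), tolerance = 1e-12)
  expect_equal(diag(cm$mean), rep(0, 10))
  # oracle: per-frame min over residue atom pairs, then mean/population SD
  at <- traj$system$atoms
  for (i in c(1, 4)) for (j in c(2, 9)) {
    ai <- which(at$residue_index == i)
    aj <- which(at$residue_index == j)
    vals <- vapply(traj$frames, function(fr) {
      bf_mindist(fr$positions[ai, , drop = FALSE],
                 fr$positions[aj, , drop = FALSE], c(10, 10, 10))
    }, numeric(1))
    expect_equal(cm$mean[i, j], mean(vals), tolerance = 1e-9)
    expect_equal(cm$sd[i, j], sqrt(mean((vals - mean(vals))^2)),
                 tolerance = 1e-9)
  }
})

test_that("static frames give an identically zero SD matrix", {
  traj <- make_walk_traj(5, 1)
  traj3 <- new_trajectory(traj$system,
                          lapply(0:2, function(t) {
                            new_frame(t, traj$frames[[1]]$positions,
                                      c(10, 10, 10))
                          }), "AA")
  cm <- residue_contact_map(traj3)
  expect_equal(max(abs(cm$sd)), 0)
  cm1 <- residue_contact_map(traj)
  expect_equal(max(abs(cm1$sd)), 0)  # single frame: population SD is zero
})

test_that("two-residue toy with constant separation reports it exactly", {
  atoms <- data.frame(
    atom_index = 1:2, atom_name = "BB", type_key = "BB",
    molecule_id = 1L, molecule_type = "PROTEIN", chain_id = "A",
    residue_index = 1:2, residue_name = "ALA", stringsAsFactors = FALSE)
  sys <- new_system(atoms, rbind(c(1, 1, 1), c(1, 1, 1.8)), c(10, 10, 10))
  frames <- lapply(0:4, function(t) new_frame(t, sys$positions, sys$box))
  cm <- residue_contact_map(new_trajectory(sys, frames, "AA"))
  expect_equal(cm$mean[1, 2], 0.8, tolerance = 1e-9)
  expect_equal(cm$sd[1, 2], 0)
})

test_that("interface extraction returns the cross-chain block", {
  m <- build_raft(raft_spec("PS", "reduced",
                            counts = c(POPS = 4, DPPC = 8, DLPC = 6,
                                       CHOL = 4), seed = 53))
  sys <- build_complex(m, build_oligomer("1tam", seed = 53))
  traj <- generate_binding_trajectory(
    sys, trajectory_spec(n_frames = 4, frame_spacing = 0.1, t_bind = 0,
                         seed = 53))
  cm <- residue_contact_map(traj)
  tau_idx <- map_chain_residues(cm, "A")
  am_idx <- map_chain_residues(cm, "B")
  blk <- interface_map(cm, tau_idx, am_idx)
  expect_equal(dim(blk$mean), c(130, 37))
  # symmetric map: the swapped request is the transpose
  blk_t <- interface_map(cm, am_idx, tau_idx)
  expect_equal(blk$mean, t(blk_t$mean), tolerance = 1e-12)
  expect_error(interface_map(cm, tau_idx, tau_idx), "overlap")
})
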