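#!/usr/bin/env Rscript
# Three-panel binding data for one condition (1tam on the PS-raft, three
# replicates): mindist vs time, contacts vs time, and the per-residue
# time-averaged mindist spectrum of each constituent chain against every
# lipid type, chain- and replicate-averaged with SEM.
#
# Outputs: results/three_panel_r<k>.tsv, results/mindist_spectrum_<chain>.tsv

library(raftbind)

dir.create("results", showWarnings = FALSE)
seed0 <- 20240205L
trajs <- list()
for (rep in 1:3) {
  seed <- derive_seed(seed0, sprintf("spectra_r%d", rep))
  m <- build_raft(raft_spec("PS", "reduced", seed = seed))
  sys <- build_complex(m, build_oligomer("1tam", seed = seed + 1L),
                       replicate = rep)
  set.seed(seed + 2L)
  t_bind <- runif(1, 0.5, 8)
  traj <- generate_binding_trajectory(
    sys, trajectory_spec(n_frames = 60, frame_spacing = 0.25,
                         t_bind = t_bind, seed = seed + 3L))
  trajs[[rep]] <- traj

  prot <- select_atoms(sys, molecule_type = "PROTEIN")
  lip <- select_atoms(sys, molecule_type = c("DPPC", "DLPC", "CHOL",
                                             "POPS"))
  md <- mindist_series(traj, prot, lip)
  cc <- contact_count_series(traj, prot, lip)
  panel <- data.frame(time = md$time, mindist = md$mindist,
                      contacts = cc$contacts)
  write.table(panel, sprintf("results/three_panel_r%d.tsv", rep),
              sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf(
    "replicate %d: planted t_bind %.2f us, detected %.2f (mindist) / %.2f (contacts)",
    rep, t_bind, detect_binding_time(md, 0.6),
    detect_binding_time(cc, mode = "contact_onset")))
}

window <- c(10, 14.75)  # last 5 us of the emulated run
for (chain in c(tau = "A", amylin = "B")) {
  out <- NULL
  for (ty in c("DPPC", "DLPC", "CHOL", "POPS")) {
    sp <- mindist_spectrum(trajs, chain, ty, window = window,
                           smooth = TRUE)
    sp$target <- ty
    out <- rbind(out, sp)
  }
  lab <- names(which(c(tau = "A", amylin = "B") == chain))
  write.table(out, sprintf("results/mindist_spectrum_%s.tsv", lab),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
message(paste(
  "Spectra written. The residues with the smallest time-averaged mindist",
  "are those the generator flattens onto the membrane surface; POPS",
  "carries the lowest spectral baseline, matching the anchored pose over",
  "the anionic cluster."))
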