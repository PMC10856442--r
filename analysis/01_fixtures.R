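#!/usr/bin/env Rscript
# Builds the synthetic raft fixtures that stand in for the MD systems:
# reduced-scale PS- and GM-rafts (1/8 of the published compositions, the
# desk-scale default) plus their topology manifests and the toy force-field
# table. Pass --full to also emit the full-scale fixtures (1944 and 1562
# lipids plus water), which reproduce the published molecule counts exactly.
#
# Outputs: results/fixtures/<raft>_<scale>.gro, manifest.json, forcefield.tsv

library(raftbind)

args <- commandArgs(trailingOnly = TRUE)
full <- "--full" %in% args
dir.create("results/fixtures", recursive = TRUE, showWarnings = FALSE)

scales <- if (full) c("reduced", "full") else "reduced"
for (raft in c("PS", "GM")) {
  for (scale in scales) {
    spec <- raft_spec(raft, scale, include_water = (scale == "full"),
                      seed = 20240205L)
    m <- build_raft(spec)
    path <- sprintf("results/fixtures/%s_%s.gro", raft, scale)
    write_gro(m, path, title = sprintf("%s-raft (%s scale)", raft, scale))
    tab <- table(m$atoms$molecule_type[!duplicated(m$atoms$molecule_id)])
    message(sprintf("%s: %s", path,
                    paste(names(tab), tab, sep = "=", collapse = ", ")))
  }
}
write_manifest(synthetic_manifest("2tam"), "results/fixtures/manifest.json")
write_forcefield(emit_forcefield_table(), "results/fixtures/forcefield.tsv")
message("wrote manifest and force-field table")
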