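#!/usr/bin/env Rscript
# Rigid-body DED-chain geometry from a tandem-domain interface.
#
# Builds a toy tandem death-effector-domain structure with a known
# DED1->DED2 transform, recovers that transform by least-squares
# superposition over the residue correspondence, propagates it into an
# 8-copy chain, and characterizes the chain's helical geometry (screw twist
# and rise), steric plausibility (non-adjacent clashes) and the sensitivity
# of the helix to 0.5 A interface jitter. Writes the chain as a multi-chain
# PDB plus a JSON geometry report.

library(discstoich)

out <- "results/chain"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260923L

tandem <- make_toy_tandem(jitter_sd = 0.3, seed = seed)
report <- chain_geometry_report(tandem$ded1, tandem$ded2, tandem$pairing,
                                n_copies = 8, jitter_sd = 0.5,
                                jitter_reps = 50, seed = seed)

write_chain_pdb(report$chain, file.path(out, "ded_chain.pdb"))
jsonlite::write_json(
  list(interface_rmsd = report$rmsd,
       screw = report$screw,
       clashes = report$clashes[c("n_clashes", "n_interface_contacts")],
       sensitivity = list(twist_range = report$sensitivity$twist_range,
                          rise_range = report$sensitivity$rise_range,
                          n_rejected = report$sensitivity$n_rejected)),
  file.path(out, "geometry_report.json"),
  auto_unbox = TRUE, digits = 6, pretty = TRUE)

truth_screw <- screw_decompose(tandem$truth)
cat(sprintf("interface superposition rmsd: %.3f A (threshold 3 A)\n", report$rmsd))
cat(sprintf("recovered screw: twist %.2f deg, rise %.2f A (truth: %.2f deg, %.2f A)\n",
            report$screw$twist, report$screw$rise,
            truth_screw$twist, truth_screw$rise))
cat(sprintf("8-copy chain: %d non-adjacent clashes, %d adjacent interface contacts\n",
            report$clashes$n_clashes, report$clashes$n_interface_contacts))
cat(sprintf("helix sensitivity to 0.5 A jitter: twist %.1f..%.1f deg, rise %.2f..%.2f A\n",
            report$sensitivity$twist_range[1], report$sensitivity$twist_range[2],
            report$sensitivity$rise_range[1], report$sensitivity$rise_range[2]))
cat("the long-range topology is reported, not asserted: small interface\n")
cat("changes move the helix, so the chain's helical character is uncertain\n")
cat("wrote chain PDB and geometry report under", out, "\n")
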