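# discstoich

Quantitative stoichiometry of death-receptor signaling complexes from
label-free AP-MS spectral counts, plus rigid-body geometry of death
effector domain (DED) chains.

When TRAIL ligates its receptors, the cell assembles a death-inducing
signaling complex (DISC): receptors → the adaptor FADD → DED-only proteins
(procaspase-8/-10, c-FLIP). Whether those components sit at 1:1:1 or
whether FADD is substoichiometric — implying chains of DED-only proteins
growing from each FADD — is a question spectral counting can answer.
`discstoich` is for proteomics analysts who have affinity-purified a
complex, searched the spectra, and need the downstream arithmetic done
right: identification filtering with an auditable trail, SAF/NSAF
quantitation, FADD-normalized grouped ratios with honest dispersion, and a
structural module that turns a tandem-DED interface into a propagated chain
model with screw-axis (helix) parameters.

## The statistics at the core

For protein *i* with spectral count SpC<sub>i</sub> and length
L<sub>i</sub> (residues):

* **SAF** = SpC<sub>i</sub> / L<sub>i</sub> — length-corrected abundance;
* **NSAF** = SAF<sub>i</sub> / Σ<sub>j∈N</sub> SAF<sub>j</sub> — mole
  fraction over the normalization set N (sums to 1 per replicate);
* **grouped stoichiometry** — NSAF summed per recruitment category
  (receptor / FADD / DED-only), averaged over replicates, corrected to
  FADD so FADD = 1; dispersion as SEM (n ≥ 3) or range (n = 2).

Retention criteria before any quantitation: peptide probability ≥ 0.95,
protein probability ≥ 0.50, Mascot ion score > 30, |parent-ion mass error|
≤ 0.2 Da, not a biotin-carboxylase/bead contaminant, and absent from the
unstimulated control unless at dramatically lower abundance (fold ≥ 5 and
control count ≤ 2, both configurable). A whitelist mechanism retains — and
flags — known components that would otherwise fall to the control rule.

The geometry module derives the DED1→DED2 rigid transform from a
tandem-DED structure by least-squares superposition (refusing interfaces
with RMSD ≥ 3 Å), propagates it into an n-copy chain, and reports the
chain's screw parameters (twist, rise), steric clashes, and the
sensitivity of the helix to interface jitter.

## Worked example

The `analysis/` scripts run the whole study on synthetic data with known
ground truth (receptor:FADD:DED-only = 3:1:9, depth 5,000 spectra,
3 replicates, carboxylase background in treated and control runs):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter.R
Rscript analysis/03_quantify.R
Rscript analysis/04_stoichiometry.R
Rscript analysis/05_chain_geometry.R
```

or, equivalently, in R:

```r
library(discstoich)
truth <- disc_preset(n_replicates = 3, depth = 5000)
ds    <- simulate_counts(truth, seed = 20260923)
cats  <- setNames(truth$components$category, truth$components$accession)
res   <- estimate_stoichiometry(ds$replicates, cats)
res$stoichiometry
#>   category combined_nsaf ratio_to_fadd dispersion dispersion_type n_replicates
#> 1 receptor        0.2368          3.06     0.0666             sem            3
#> 2     FADD        0.0773          1.00     0.0000             sem            3
#> 3 DED_only        0.6859          8.87     0.0396             sem            3
```

The 12 contaminant-run records (4 background proteins × 3 replicates) are
removed with reason `contaminant` in the audit table; the retained
components yield NSAF sums of exactly 1 per replicate; and the grouped
ratios recover the 3:1:9 truth — here 3.06 receptors and 8.87 DED-only
proteins per FADD, i.e. roughly three receptors and about nine DED-only
proteins per adaptor. Across 100 seeds the estimates center on 3.01 ± 0.17
and 9.06 ± 0.44 (99/100 seeds within ±15%).

The chain script recovers a known 60°-twist/8 Å-rise interface operator
from a jittered toy tandem (superposition RMSD 0.54 Å, well under the 3 Å
acceptance threshold), propagates an 8-copy chain with zero non-adjacent
clashes, and reports the helix's sensitivity to 0.5 Å interface jitter
(twist 55.5–70.9°, rise 7.2–8.7 Å) — the long-range topology is reported
with its uncertainty, never asserted.

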