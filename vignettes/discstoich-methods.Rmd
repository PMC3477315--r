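---
title: "Methods: spectral-count stoichiometry and DED-chain geometry"
author: "discstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count stoichiometry and DED-chain geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discstoich)
```

## The problem

When a death ligand such as TRAIL engages its receptors, the cell assembles
a death-inducing signaling complex (DISC): receptors recruit the adaptor
FADD through death-domain contacts, and FADD in turn recruits DED-only
proteins — procaspase-8, procaspase-10 and c-FLIP — through death effector
domain (DED) contacts. Affinity-purifying the ligand-bound complex and
counting peptide-spectrum matches per protein gives a label-free estimate
of the complex's internal stoichiometry. If FADD turns out to be
substoichiometric relative to both receptors and DED-only proteins, the
textbook 1:1:1 model cannot hold, and a chain of DED-only proteins growing
from each FADD — built by reusing the intramolecular DED1–DED2 interface as
a repeat operator — becomes the natural structural explanation.

`discstoich` implements both halves of that argument as a tested pipeline:
the spectral-count quantitation (filtering, SAF/NSAF, FADD-normalized
grouped ratios) and the rigid-body chain geometry (interface transform,
propagation, screw decomposition, clash and sensitivity reports), exercised
end to end on synthetic data with known ground truth.

## Identification filtering

Raw AP-MS identification lists are dominated by background. A protein-run
record is retained only if all of the following hold:

* peptide posterior probability ≥ 0.95 and protein posterior probability
  ≥ 0.50 (both inclusive; the probabilities come from upstream inference
  tools and are consumed, never recomputed);
* Mascot ion score strictly greater than 30;
* absolute parent-ion mass error within 0.2 Da (QTof-class accuracy; a ppm
  mode is available, and mixed units within one table are an error rather
  than a silent conversion);
* not a known contaminant — by default the biotin-dependent carboxylases,
  which bind streptavidin beads through their covalent biotin cofactor,
  plus common bead background (keratins, albumin, trypsin); the table is
  user-extensible;
* not present in the matched unstimulated-receptor control, *unless* at
  dramatically lower abundance there.

"Dramatically lower abundance" is not a number anywhere in the field's
informal usage, so the package quantifies it explicitly and configurably:
treated:control spectral-count ratio ≥ 5 **and** control count ≤ 2. Both
knobs sit in `filter_criteria()`; the defaults are deliberately
conservative (a protein with solid control evidence never survives on fold
change alone). Control subtraction operates per replicate pairing by
default — pooling controls would let one noisy control run veto every
replicate.

Two deliberate mechanisms deserve note. First, the *whitelist*: a known
complex component can be genuinely present yet fall below the control rule
in a low-yield cell background. Rather than hard-coding any protein, the
filter takes a whitelist of accessions that survive control subtraction;
every whitelist retention is flagged in all outputs so the exception is
visible, never silent. Second, the *audit*: `filter_proteins()` partitions
its input into retained and removed records, each removal carrying an
exhaustive reason (`contaminant`, `protein probability`, `control`), and
the criteria are echoed into every run's provenance block. Shared peptides
are razor-assigned: all PSMs of a peptide claimed by several proteins in
one run are credited to the protein with the highest protein probability,
ties broken lexicographically, so counts remain integers that sum to the
number of retained spectra.

Duplicate accessions within one run are refused rather than merged; merged
duplicates usually indicate a malformed upstream export, and merging would
silently double counts.

## SAF, NSAF and grouped stoichiometry

Let $\mathrm{SpC}_i$ be the spectral count of protein $i$ in one run and
$L_i$ its length in residues. The spectral abundance factor and its
normalized form are

$$\mathrm{SAF}_i = \frac{\mathrm{SpC}_i}{L_i}, \qquad
\mathrm{NSAF}_i = \frac{\mathrm{SAF}_i}{\sum_{j \in N} \mathrm{SAF}_j},$$

with $N$ the normalization set. Dividing by length corrects for the larger
number of observable tryptic peptides a longer protein yields; NSAF then
estimates protein $i$'s mole fraction of the set. NSAF sums to 1 over $N$
in every replicate (asserted to $10^{-9}$) and is invariant to uniform
count scaling.

The normalization set defaults to the retained protein set. The choice is
immaterial for the quantity of interest: stoichiometry ratios are formed as
category NSAF divided by FADD NSAF, and the shared denominator cancels, so
the ratios are invariant to any normalization set containing the category
members (asserted numerically in the test suite).

Replicates are aggregated per accession as median protein probability,
median relative SAF (SAF divided by a declared reference protein's SAF
within the same replicate), and mean NSAF. An accession undetected in a
replicate contributes NSAF 0 to that replicate rather than being treated as
missing at random — non-detection in a counting experiment carries
information — and the `n_detected` column flags how often it was seen.
Dispersion follows the reporting convention of small-n proteomics figures:
SEM ($s/\sqrt{n}$) for $n \ge 3$ replicates, the range for $n = 2$, and
not-available for $n = 1$.

Grouped stoichiometry sums NSAF over each recruitment category (receptor,
FADD, DED-only, other) within each replicate, averages the per-replicate
category sums, and divides by the FADD average, so FADD's ratio is exactly
1. The ratio is formed from replicate-averaged sums (a ratio of means)
rather than averaging per-replicate ratios, because the ratio-of-means is
less biased under Poisson-level count noise in the denominator; the
per-replicate ratios still provide the dispersion (SEM or range as above).
A zero FADD denominator raises an error instead of emitting an infinite
ratio. For gradient-fraction (MudPit-style) inputs, spectral counts are
summed across fractions before SAF, as an explicit, logged combining step.

For cleaved species quantified against a shorter form (e.g. a p43
fragment), a per-accession length override table can replace the full-length
database length; the default keeps the database length.

## The synthetic-data generator

No raw identification data accompany the analysis this package models, so
the generator defines the study conditions under which the pipeline is
validated. The `disc_preset()` composition fixes ground-truth mole ratios
receptor : FADD : DED-only = 3 : 1 : 9 — two TRAIL-R1-like and one
TRAIL-R2-like receptor copy per FADD, and nine DED-only copies dominated by
procaspase-8 (7) with one copy each of procaspase-10 and c-FLIP — using
canonical full-length residue counts (468, 440, 208, 479, 521, 480 aa).
Three replicate pairs at an expected depth of 5,000 spectra per run mirror
a realistic small-n AP-MS experiment.

Counts are drawn per protein as Poisson with mean `depth × weight`, the
weight proportional to copy_number × length under the default
length-proportional detectability model — exactly the assumption SAF makes,
so NSAF ratios are asymptotically unbiased for copy-number ratios. A
negative-binomial option adds replicate overdispersion for robustness
experiments, and a uniform-detectability option deliberately violates the
SAF assumption: the test suite asserts that NSAF ratios are then biased by
the length ratio, documenting the assumption instead of hiding it.

Contaminants (biotin carboxylases and a bead binder) are sampled at the
same expected intensity in treated and control runs, at levels high enough
to be clearly detected in controls — the regime the control-subtraction
rule addresses. A configurable control-leakage rate (default 0) lets a
small fraction of each component's treated signal appear in controls to
exercise the dramatically-lower-abundance branch.

What the generator does *not* emulate: ion suppression and peptide
competition between co-eluting species, protein-dependent peptide
detectability beyond the length model, shared-peptide ambiguity between
homologs, and probability miscalibration of the upstream tools. Passing
recovery tests therefore show that the pipeline's arithmetic and filtering
are correct under the stated sampling model, not that NSAF is an absolute
quantitation on real spectra.

At these conditions (depth 5,000, 3 replicates), the estimated
receptor:FADD and DED-only:FADD ratios land within ±15% of 3 and 9 in at
least 95 of 100 seeds — the FADD denominator, with only ~110 expected
spectra, dominates the estimator's variance.

## Chain geometry

The structural module treats the tandem-DED interface as a rigid-body
repeat operator. `superpose()` implements the closed-form least-squares
superposition (SVD of the cross-covariance with the determinant correction)
over one designated atom per residue — the backbone alpha-carbon by
default, since alignment tools differ in their atom sets and a single
well-defined choice keeps the operator reproducible. Mirror-image inputs
are fitted with a proper rotation (det = +1) always; a reflection is never
returned, so chirality errors surface as large RMSD instead of silently
inverted chains.

`derive_interface_transform()` maps the DED1 frame onto the DED2 frame over
an explicit residue correspondence. The correspondence is a required input,
not an inferred alignment: automatic sequence alignment could silently
diverge from a structure-based pairing, and the pairing is precisely the
scientific claim being propagated. The fit is accepted only when its RMSD
is below 3 Å (configurable) — domains that do not superpose are refused
rather than propagated. Because the direction of propagation (DED1→DED2
versus its inverse) is a modeling choice, both are computable via the
`inverse` flag.

`propagate_chain()` applies the operator k times to place copy k. By
Chasles' theorem every rigid transform is a screw — rotation by a twist
angle about a unique axis plus a rise along it — so a repeated interface
traces a helix; `screw_decompose()` reports twist (degrees, in (−180, 180],
with the axis oriented so the rise is nonnegative) and rise (Å per repeat),
and `screw_to_transform()` reconstructs the operator exactly (the round
trip is asserted to 10⁻⁶ Å; twists below 10⁻⁹ rad are reported as pure
translations with the axis along the translation). `clash_check()` counts
backbone-representative atom pairs closer than 4 Å between non-adjacent
copies, reporting adjacent-copy contacts separately since those *are* the
modeled interface.

The long-range topology of such a chain is reported, never asserted: small
interface changes have large effects far down the chain. Accordingly
`interface_sensitivity()` re-derives the operator under seeded 0.5 Å
Gaussian jitter of the interface coordinates and reports the twist and rise
ranges, and the geometry report carries that spread alongside the point
estimate. Catalytic-subunit placement is out of scope; only the DED-chain
geometry is modeled.

The toy structures used in tests and the analysis scripts are synthetic
helical coils with a known ground-truth transform (`make_toy_tandem()`);
noiseless recovery is exact to 10⁻⁶, and recovery at 0.3 Å jitter stays
well inside the 3 Å interface threshold.

## Numerical conventions and degenerate inputs

* Superposition requires ≥ 3 non-collinear paired positions; collinear
  configurations raise a degeneracy error (the rotation about the line is
  unobservable).
* All writers are deterministic: fixed column order, doubles at 6
  significant digits, so identical configuration + seed reproduce outputs
  byte for byte.
* Every simulation consumes a single integer seed recorded in the output
  provenance block.
* Empty PSM input filters to empty output (not an error); an all-zero SAF
  replicate is a degenerate-replicate error; zero total sampling weight is
  a degenerate-truth error.

## Problem sizes

The shipped analyses and tests use 3 replicates at depth 5,000 with a
6-component complex, 100-seed recovery experiments, 10⁴-record filter
oracles, 20-residue toy domains and 8-copy chains — sizes at which every
experiment is exactly reproducible in seconds while leaving the estimators
in the realistic small-count regime described above.

## Known limitations

* Spectral counting only; no intensity-based (XIC/iBAQ) quantitation.
* Descriptive ratios only; no inferential comparison of stoichiometries
  between conditions or cell lines.
* NSAF mole-fraction interpretation inherits the length-proportional
  detectability assumption; the uniform-detectability simulations quantify
  the bias when it fails.
* The chain model is rigid-body geometry: no energetics, docking or
  flexibility, and the helical parameters carry the jitter-sensitivity
  caveat above.
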