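---
title: "Methods: the two-type MICA partition and its functional read-outs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-type MICA partition and its functional read-outs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micatype)
```

## The problem

MICA is a stress-induced ligand of the activating NK-cell receptor NKG2D
and the most polymorphic of the NKG2D ligands: 280 distinct protein
variants are known. Serology with reciprocal allosera, a discriminating
monoclonal antibody, and NKG2D-Ig binding all show that the common
variants fall into two reciprocal reactivity groups, and the grouping
tracks a haplotype of six linked residues in the ectodomain. `micatype`
turns that observation into a reusable classifier and implements the
downstream quantitative analyses — bead-panel MFI summaries, reporter-cell
EC50s, NK killing curves, and population carrier coverage — together with
seeded generators that emulate each assay.

## The classifier

The six signature sites and their residues are, on mature-protein
numbering (position 1 = first residue after signal-peptide cleavage):

| position | 36 | 129 | 173 | 206 | 210 | 215 |
|----------|----|-----|-----|-----|-----|-----|
| Type-I   | C  | M   | K   | G   | W   | S   |
| Type-II  | Y  | V   | E   | S   | R   | T   |

A strict "matches the full tuple" rule would be wrong on real data: in the
packaged 29-allele panel, MICA\*036 carries E173 in an otherwise Type-I
haplotype, MICA\*051 carries Y36, MICA\*042 keeps M129+K173 in a largely
Type-II haplotype, and MICA\*028 / MICA\*037 split the six sites 3–3.
The classifier is therefore a **majority vote**: `score_I` and `score_II`
count the sites matching each tuple (unknown residues `X`, and residues
matching neither tuple, count for neither side — so novel alleles among
the 280 remain classifiable rather than erroring), and a 3–3 tie is broken
by the residue at position 129, the M/V dimorphism long known to modulate
NKG2D affinity and tightly linked to the other five sites. An allele still
tied after the tie-break is reported as `unclassified`, a first-class
outcome. This is the minimal rule that reproduces the published 18/11
grouping for all 29 panel alleles, tie cases included; the package tests
verify that agreement exactly, and also that the call is a pure function
of the six signature residues (mutating any other position never changes
it) and that swapping the two tuples swaps every call.

Whether MICA\*051's Y36 inside a Type-I row is genuine or a transcription
artifact of the source alignment cannot be decided from the data at hand;
the majority-plus-129 rule classifies it Type-I either way, so the design
is robust to both readings.

## Alignment handling

Dash-notation tables (first row positions, second row the explicit
MICA\*001 reference, then one row per allele with `-` meaning
reference-identical) are read and written losslessly; hyphen, en dash and
em dash are all accepted on input because published tables mix them. A
dash never means a gap. The packaged panel counts MICA\*001 both as the
reference and as one of the 29 alleles (it is one of the 29 bead
antigens), which is why the panel classifies 18/11 rather than 17/11.

`polymorphic_sites()` reports positions with ≥ 2 distinct residues,
ignoring `X` so partial sequences cannot create spurious polymorphism.
Sequences must be positionally comparable; there is no gap or indel
handling, and an allele with different coverage is a named error. On the
packaged panel the scan returns exactly the 27 tabulated ectodomain
positions. For full-length FASTA input longer than the ectodomain the
scan will report additional sites beyond the tabulated 27 — the boundary
of the "extracellular" region is not encoded.

## Bead-panel (Luminex) summaries

Replicate wells are averaged per allele first; group statistics are
across alleles, not wells (the source tables' SDs are ambiguous on this
point — across-allele is the reading implemented, and per-type SD is the
sample SD with the n−1 denominator). The two-group comparison defaults to
the Welch unequal-variance *t* because the source description of the
statistics ("independent sample t-test (non-parametric and unpaired
tests)") is self-contradictory; Mann-Whitney U is exposed as the
alternative, and at the separations seen in these panels the conclusion
does not depend on the choice. Two degenerate cases are defined rather
than errors: identical constant groups give t = 0, p = 1, and constant
groups with different means give |t| = ∞, p = 0. With fewer than two
alleles in a group the summary is returned with the test marked
unavailable.

`bimodal_split()` is the 1-D Otsu criterion: every midpoint between
consecutive distinct sorted values is scanned and the threshold maximising
the between-group variance `w_lo · w_hi · (m_hi − m_lo)²` is returned.
The test suite checks it against an independent brute-force
implementation (minimising within-group variance) and verifies that
panels generated with ≥ 6-SD group separation are split exactly on the
generating partition.

## Dose-response and the EC50

The reporter read-out (%GFP⁺ cells vs coated-protein dose) is fitted with
the increasing four-parameter logistic

y(x) = bottom + (top − bottom) / (1 + (midpoint/x)^hill).

The **EC50 is defined as the absolute 50%-GFP⁺ crossing** of the fitted
curve, solved in closed form as
x₅₀ = midpoint · ((top − 50)/(50 − bottom))^(−1/hill); it is undefined
(`NA`) when the plateau never reaches 50%. This is deliberately *not* the
half-maximum midpoint: for a curve with top = 90 the two differ by ~12%,
and the assay's published definition is the absolute crossing.

Numerical choices: replicates enter the least-squares loss individually;
parameters are bounded (bottom ∈ [0, 20], top ∈ [20, 100] %GFP⁺,
hill ∈ (0, 10], midpoint ∈ [min dose/10, max dose·10]) and optimised with
L-BFGS-B from a deterministic grid of five starts (hill ∈ {0.5, 1, 2, 4}
crossed with geometric dose quantiles), keeping the lowest-RSS converged
fit. Constant responses and monotone-decreasing data are rejected — this
is an activation assay. On noiseless data the fit recovers generating
parameters to ≤ 10⁻⁴ relative error; with 3-percentage-point replicate
noise the median recovered crossing over 200 seeded datasets stays within
a few percent of truth (the tests assert ≤ 5% at SD 1 and ≤ 15% at SD 3).

The six concentrations used in the published titrations are not printed;
the generator's default ladder is 2-fold from 5 to 160 µg/mL, bracketing
the 80 µg/mL coating dose. This is an assumption, stated here once.

## Cytotoxicity

Killing efficiency is the raw ratio `100 · n(CFSE⁺7-AAD⁺) / n(CFSE⁺)`;
no spontaneous-death subtraction is applied because the assay's stated
formula has none. Curves are per-ratio replicate means ± sample SD over
the standard E:T ladder 1, 3, 5, 10. `compare_killing_curves()` reports
per-ratio differences and a one-sided paired test across ratios (Wilcoxon
signed-rank with ≥ 5 ratios, paired *t* below that) — but with four
ratios any such test is underpowered, so the per-ratio sign pattern of
the differences is the primary read-out, and that is what the package's
stochastic checks assert (a 0.1 generating-rate gap produces a uniformly
positive difference vector in ≥ 95% of 200 seeds).

## Population arithmetic

Frequencies are stored in percent exactly as printed and converted to
fractions only at the probability boundary, so class sums reproduce the
printed arithmetic bit-for-bit. One printed population column (Japanese)
sums to 100.10 rather than 100.00; the conservation check in the test
suite reports it, and the package does not silently renormalise.

Carrier coverage offers two models: the diploid Hardy-Weinberg form
1 − (1 − p)² (default) and the Poisson approximation 1 − e^(−2p), kept
because the source describes its estimate as Poisson-based even though
the quantity is a diploid carrier probability. They differ by at most p²
for small p; the Poisson form drops below p as p → 1, so it should not be
used near saturation. The published coverage range "91.6–99.4%" is not
derivable from the printed frequency table under either model with any
obvious class combination, so the package reports model outputs and
asserts nothing about that range. Phenotype groups are the plain
Hardy-Weinberg expansion (f_I², f_II², 2 f_I f_II), summing to
(f_I + f_II)².

## What the generators emulate — and what they do not

* `simulate_alleles()` draws each allele's type
  (`p_type_I = 18/29`, the packaged panel's proportion), writes the
  type's six-site tuple with independent per-site flips to the opposite
  residue (`discordance_rate = 0.06`: the packaged panel has 11
  discordant residues over 29 × 6 signature sites), and mutates each of
  the 21 background positions away from the reference with probability
  0.15 (the panel's off-signature variant density), drawing from that
  position's observed spectrum. Real alleles have *correlated*
  discordance (haplotype blocks); the alignment gives no basis to model
  that, so flips are independent — which makes synthetic accuracy
  slightly pessimistic at a given rate.
* `simulate_mfi_panel()` draws per-replicate MFI from a normal with the
  published per-reagent group means/SDs (negative draws truncated to 0 —
  inactive at those CVs). Bead chemistry, saturation and instrument
  drift are not modelled.
* `simulate_dose_response()` adds i.i.d. Gaussian noise to the 4PL and
  clips to [0, 100]; real %positive flow data are heteroscedastic near
  the plateaus.
* `simulate_killing()` draws binomial dead-cell counts at the true
  per-ratio rates; effector exhaustion and well-to-well effects are not
  modelled.

Passing the stochastic tests therefore demonstrates that the estimators
recover the structure these generators encode — not that they are robust
to every artefact of real bead or cytometry data.

All generators take an explicit seed and are pure functions of
(arguments, seed); the test suite checks determinism directly.

## Problem sizes

The stochastic checks use 200 seeded datasets per configuration for
dose-response recovery and killing-curve sign patterns, 500 synthetic
alleles for classifier truth-recovery, and 2000 alleles for MFI moment
convergence (tolerance 3 SE). These sizes make every stochastic
assertion stable across seeds while keeping the full suite fast on a
single CPU.

## Known limitations

* Only 29 of the 280 known protein variants carry published labels; the
  claim that *all* variants fall cleanly into the two types is not
  verifiable from packaged data, and `unclassified` exists precisely for
  future alleles that defeat the majority rule.
* The ectodomain boundary is not modelled, so FASTA input longer than
  the ectodomain inflates the polymorphic-site count.
* EC50 comparisons inherit the small group sizes of the source assay
  (6 vs 5 alleles); the Welch test is exact-size only asymptotically.
* No linkage with HLA-B, and no estimation of allele frequencies from
  genotypes — frequency tables are taken as given.
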