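# micatype

Human **MICA** — the most polymorphic ligand of the NK-cell activating
receptor NKG2D — encodes 280 known protein variants, yet serological and
receptor-binding data show these variants collapse into just **two
functional types**. `micatype` implements that two-type partition and the
analyses built on it:

* **Typing (the core).** Type-I MICA carries the linked residues
  C36 + M129 + K173 + G206 + W210 + S215 on the mature protein; Type-II
  carries Y36 + V129 + E173 + S206 + R210 + T215. Because real alleles
  occasionally break the linkage, the classifier takes a **majority vote
  over the six sites with the M/V dimorphism at position 129 breaking
  3–3 ties**. On the packaged 29-allele alignment this reproduces the
  published 18 Type-I / 11 Type-II grouping exactly, including the two
  tie alleles (MICA\*028 → Type-II via V129, MICA\*037 → Type-I via M129).
* **Polymorphic-site analysis.** Extraction of the 27 polymorphic
  ectodomain positions from an alignment, and per-allele diffs against
  the MICA\*001 reference (dash-notation tables read and written
  losslessly).
* **Luminex single-antigen-bead panels.** Per-type MFI means ± SD with a
  Welch *t* (or Mann-Whitney) comparison, reagent reactivity-pattern
  correlation, and an Otsu-style bimodal split of a panel.
* **NKG2D reporter dose-response.** Bounded multi-start least-squares
  fits of the four-parameter logistic
  `y = bottom + (top − bottom) / (1 + (midpoint/x)^hill)`, with the EC50
  defined as the **absolute 50%-GFP⁺ crossing** of the fitted curve,
  `x₅₀ = midpoint · ((top − 50)/(50 − bottom))^(−1/hill)` — not the
  half-maximum midpoint.
* **NK cytotoxicity.** Killing efficiency `100 · n(CFSE⁺7-AAD⁺) / n(CFSE⁺)`
  per E:T ratio, killing curves and curve comparison.
* **Population genetics.** Carrier coverage `1 − (1 − p)²` (binomial /
  Hardy-Weinberg, with a Poisson alternative `1 − e^(−2p)`) and the three
  Hardy-Weinberg phenotype groups (`f_I²`, `f_II²`, `2 f_I f_II`).
* **Synthetic data.** Seeded generators for alleles with two-haplotype
  linkage (and tunable discordance), two-group MFI panels, 4PL titrations
  and binomial killing counts, so every stage runs and is tested without
  wet-lab data.

Everything takes and returns tibbles, so calls chain with the pipe;
fitted curves have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(micatype)

panel <- mica_alignment()            # packaged 29-allele alignment, 27 sites
calls <- classify_alleles(panel)
type_counts(calls)
#> # A tibble: 1 × 3
#>   n_type_I n_type_II n_unclassified
#>      <int>     <int>          <int>
#> 1       18        11              0

calls[calls$allele %in% c("MICA*002", "MICA*008", "MICA*028"), ]
#> # A tibble: 3 × 5
#>   allele   type    score_I score_II tiebroken
#>   <chr>    <chr>     <int>    <int> <lgl>
#> 1 MICA*002 type_I        6        0 FALSE
#> 2 MICA*008 type_II       0        6 FALSE
#> 3 MICA*028 type_II       3        3 TRUE
```

MICA\*002 matches the Type-I tuple at all six sites, MICA\*008 the Type-II
tuple; MICA\*028 splits 3–3 and is resolved to Type-II by its V129.

```r
freqs <- mica_frequencies()       # packaged population frequencies (%)
p29 <- class_total(freqs, "common_29")
p29$carrier <- carrier_probability(p29$total_pct / 100)
p29
#> # A tibble: 5 × 3
#>   population total_pct carrier
#>   <chr>          <dbl>   <dbl>
#> 1 African         98.7   1.000
#> 2 American        84.6   0.976
#> 3 Chinese         73.3   0.929
#> 4 European        90.6   0.991
#> 5 Japanese        88.1   0.986
```

So 93–100% of individuals, depending on population, carry at least one of
the 29 common expressed alleles.

```r
ref <- mica_ec50()                # published per-allele 50%-GFP+ crossings
ec50_group_means(ref[, c("allele", "ec50")], ref[, c("allele", "type")])
#> # A tibble: 1 × 10
#>   mean_I  sd_I   n_I mean_II sd_II  n_II statistic p_value method test_available
#>    <dbl> <dbl> <int>   <dbl> <dbl> <int>     <dbl>   <dbl> <chr>  <lgl>
#> 1   24.9  2.72     6    39.7  3.30     5     -7.97 5.14e-5 welch  TRUE
```

Type-I molecules reach 50% reporter activation at a significantly lower
dose (mean 24.95 µg/mL) than Type-II molecules (39.68 µg/mL): Type-I MICA
is the stronger NKG2D agonist.

```r
sim <- simulate_alleles(200, discordance_rate = 0.06, seed = 42)
signature_concordance(classify_alleles(sim$table), sim$truth)
#> [1] 0.995
```

A command-line entry point for the classifier ships in
`inst/scripts/classify.R` (`--table` dash-notation TSV or `--fasta`
mature-protein sequences).

## Notes on conventions

* Positions are 1-based on the **mature protein** (signal peptide
  removed), the numbering behind "MICA-129". FASTA input must already be
  trimmed to the mature protein.
* In dash-notation tables `-` always means "identical to the reference",
  never a gap; unknown residues are `X`.
* Frequencies are stored in percent as printed in the source tables and
  converted to fractions only inside probability calculations.
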