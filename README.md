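# tcrcomp

Comparative analysis of T cell receptor (TCR) CDR3 repertoires in R.

`tcrcomp` is for immunologists who have sorted an antigen-specific T cell
population (for example by activation-induced markers such as CD154 on
CD4+ or CD137 on CD8+ cells), sequenced the TCR α- and/or β-chains of
those cells and of randomly sorted control cells from the same donors, and
want to ask: *does the antigen-specific repertoire differ systematically
from the random repertoire* — in its CDR3 amino-acid composition, in
position-specific residue preferences, or in V/J gene-segment usage? This
question arises naturally for chemical sensitizers (haptens), whose
epitopes can engage unusually broad sets of TCRs through preferred CDR3
residues rather than through a single dominant clonotype.

## What it computes

Starting from clonotype tables as emitted by standard V(D)J pipelines
(MIXCR/VDJtools-style TSV), the package:

1. **Collapses records into clonotypes.** Sequences with identical V, (D)
   and J gene segments and identical CDR3 nucleotide sequence are one
   clonotype; allele suffixes (`*01`) are stripped so identity works at
   the gene level.
2. **Removes non-functional clonotypes** (CDR3s with a stop `*` or
   frameshift `_` marker) and renormalizes frequencies.
3. **Computes repertoire descriptors**, each under *diversity* weighting
   (every unique clonotype counts once — the default) or *counts*
   weighting (clonotypes weighted by UMI-derived molecule counts):
   - `aa_occurrence()` — for each amino acid *X*, the percentage of
     clonotypes whose CDR3 (first C and last F anchors included) contains
     at least one *X*;
   - `positional_occurrence()` — occurrence of residue *X* at CDR3
     position *p*, numbered 1-based from the conserved cysteine;
   - `segment_usage()` — percentage of clonotypes using each V or J gene;
   - `cdr3_length_distribution()` — the CDR3 length spectratype.
4. **Compares donor groups.** For each feature family (the 20 amino
   acids; the positions of one residue; the observed segments),
   `compare_composition()` runs per-feature two-sample t-tests (pooled
   variance by default) between case and control donors and adjusts the
   family with the **step-down Holm–Šídák procedure**: with p-values
   sorted ascending, the *i*-th of *m* becomes
   `p_i' = max_j<=i { 1 − (1 − p_(j))^(m − j + 1) }`.
   `two_way_anova()` provides the classical two-factor decomposition for
   per-donor single-feature values (for example condition × chain).
   Effect sizes are reported as differences in percentage points and as
   percent change `100 · (case − control) / control`.
5. **Simulates ground-truth cohorts.** `simulation_config()` /
   `simulate_cohort()` generate seedable synthetic donor repertoires —
   germline C/F-anchored flanks, geometric junctional insertions, a
   configurable non-functional fraction, power-law clone sizes, per-donor
   segment-usage jitter — with injectable case-arm enrichment effects
   (`enrichment()`), so the whole pipeline can be validated by parameter
   recovery without any sequencing data.

## Worked example

Simulate a cohort of 5 antigen-specific ("case") and 5 random ("control")
donor repertoires with a known +15-percentage-point tryptophan enrichment
at CDR3 position 5, then recover it:

```r
library(tcrcomp)

cfg <- simulation_config(
  n_donors_case = 5, n_donors_control = 5,
  clonotypes_per_repertoire = 2000, seed = 1,
  enrichments = list(enrichment("positional", "W", position = 5, effect = 15))
)
cohort <- lapply(simulate_cohort(cfg), filter_functional)
cmp <- compare_composition(cohort, "positional", positional_aa = "W",
                           max_position = 12)
head(cmp, 3)
#> # A tibble: 3 × 9
#>   feature case_mean control_mean case_n control_n difference percent_change    p_raw    p_adj
#>   <chr>       <dbl>        <dbl>  <int>     <int>      <dbl>          <dbl>    <dbl>    <dbl>
#> 1 pos05:W    16.8          1.25       5         5     15.6           1247.  1.24e-13 1.49e-12
#> 2 pos07:W     0.645        0.827      5         5     -0.181          -21.9 1.89e- 1 9.01e- 1
#> 3 pos08:W     0.567        0.389      5         5      0.179           46.0 2.27e- 1 9.24e- 1
```

The injected feature `pos05:W` tops its 12-position family: the case arm
shows tryptophan at position 5 in 16.8% of clonotypes versus 1.3% in
controls, a difference of 15.6 points (the injected 15 within Monte-Carlo
noise), with a Holm–Šídák-adjusted p of 1.5e-12; every other position is
far from significance. The same call with
`descriptor = "aa_occurrence"` scans all 20 residues, and
`descriptor = "segment_usage"` scans V or J genes.

The file-based pipeline mirrors this: `run_simulate(cfg, dir)` writes
VDJtools-style TSVs plus a YAML manifest, and
`run_compare(manifest, out_dir)` writes per-sample descriptor tables and
per-stratum comparison reports with significance stars, reproducibly
(identical inputs and settings give byte-identical outputs). A thin
command-line wrapper lives at `inst/cli/tcrcomp.R`.

## Validation against real repertoires

For study data processed with the usual MIGEC → MIXCR → VDJtools chain,
write a YAML manifest mapping each sample table to its donor, subset
(CD4/CD8), chain (TRA/TRB) and condition, and run `run_compare()`. The
per-amino-acid comparison report then lets the direction of change for
residues of interest (for example tryptophan and lysine) be inspected
directly. This is an optional validation path: the test suite and the
acceptance script rely only on simulated cohorts.
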