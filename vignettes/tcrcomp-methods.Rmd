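---
title: "Methods: comparing antigen-specific and random TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing antigen-specific and random TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcomp)
```

## The analytical problem

T cell receptor (TCR) diversity is generated by V(D)J recombination plus
random junctional insertions and deletions, concentrated in the third
complementarity-determining region (CDR3) of each chain — the loop that
dominates antigen contact. When an antigen activates an unusually broad
set of T cells, as chemical sensitizers (haptens) can, the signature one
expects is not a single expanded clonotype but a *statistical shift* of
the repertoire: certain amino acids appearing in more clonotypes, at
preferred CDR3 positions, or certain V/J gene segments used more often in
the antigen-specific population than in randomly sorted control cells
from the same donors.

`tcrcomp` implements that comparison as a pipeline of small, testable
steps: clonotype construction, functional filtering, repertoire
descriptors, and group statistics, plus a generative simulator so that
every step can be validated by parameter recovery.

## Units of analysis

A **clonotype** is the set of sequences with identical V, (D) and J gene
segments and identical CDR3 *nucleotide* sequence. Segment names are
normalized to gene level first (allele suffixes such as `*01` stripped),
so `TRBV20-1*01` and `TRBV20-1` merge; repertoire-level questions in this
package are gene-level questions, and the analysis is thereby insensitive
to whether the upstream aligner emitted alleles. Merging sums the member
counts and recomputes frequencies; output order is deterministic
(descending count, then CDR3 nucleotide sequence, then V segment), which
makes every downstream table byte-reproducible.

Clonotypes whose CDR3 amino-acid sequence carries a stop (`*`) or
frameshift (`_`) marker are non-functional rearrangements and are removed
before analysis, with frequencies renormalized over the survivors.

All descriptors support two weightings. Under **diversity** weighting
each unique clonotype contributes weight 1; under **counts** weighting it
contributes its UMI-derived molecule count. Diversity is the default:
in a cross-sectional comparison of antigen-specific versus random
repertoires there is no exposure-driven expansion to capture, and small
sorted populations make count frequencies vulnerable to coincidental
expansions of individual memory clones. With a heavy-tailed clone-size
law the two weightings can differ noticeably even in large repertoires
(a few clones can hold percent-scale count weight), which is another
reason the clonotype-level metric is the primary one.

## Descriptors

**Amino-acid occurrence** is a *containment* percentage: the share of
clonotype weight whose CDR3 contains at least one copy of the residue,
anchors included. It is deliberately not a per-position residue
frequency; a containment metric is what makes statements like "60% of
α-chain clonotypes carry a lysine" well defined, and values across the 20
residues do not sum to 100.

**Positional occurrence** indexes residues by CDR3 position, 1-based from
the conserved N-terminal cysteine in the N→C (5′→3′) direction, anchors
included — position 1 therefore reports C at 100% for anchor-conserved
repertoires. The default denominator is the whole repertoire: a clonotype
shorter than position *p* counts as non-occurrence. This keeps profiles
comparable across repertoires with different length distributions and
gives an exact bookkeeping identity (the sum over residues at position
*p* equals the percentage of clonotype weight with CDR3 length ≥ *p*).
The alternative convention — conditioning on length ≥ *p* — is available
via `conditional = TRUE`; it answers "given the CDR3 reaches position
*p*, what sits there?" and is the right choice when length distributions
differ strongly between arms. We default to the unconditional form
because it preserves the sum identity the tests rely on and never
inflates sparse long-CDR3 cells. For α-chains, where length variation is
driven from both junction sides, note that N-terminal anchoring is an
analysis convention, not a biological alignment; profiles can be computed
on reversed sequences if C-terminal anchoring is wanted.

**Segment usage** is the clonotype-weight share per V (or J) gene and
sums to 100. **CDR3 length distributions** (spectratypes) support
interpretation of positional profiles.

Non-standard residue letters that survive filtering (they should not
occur) are tallied under a reserved `other` bin and reported, never
silently dropped.

## Group statistics

Per-donor descriptor values are compared between arms with two-sample
t-tests, one per feature, pooled-variance by default (`var_equal =
FALSE` gives Welch). The **correction family** is explicit: the 20
standard amino acids for composition, all profiled positions of the
queried residue for positional analysis, all observed segments for usage.
Families are adjusted with the step-down Holm–Šídák procedure

\[ p'_{(i)} = \max_{j \le i}\; 1 - (1 - p_{(j)})^{\,m - j + 1}, \]

which controls the family-wise error rate and is uniformly between the
raw p-values and the Holm(-Bonferroni) adjustment. Two degenerate-case
conventions keep families intact: a feature with zero variance in both
arms and equal means gets p = 1 (not NaN, not dropped), and a zero
control mean makes the percent change an explicit `NA` flag rather than
an infinity.

`two_way_anova()` fits the classical two-factor decomposition with
interaction (additive with a warning when only one replicate per cell is
available; an empty cell is an error), for designs such as per-donor
lysine occurrence crossed as condition × chain. The factor pairing is the
caller's choice; condition × chain is the natural default for
single-residue occurrence measured on both chains.

Repertoires with fewer than `min_clonotypes` unique clonotypes (default
50) are excluded from comparisons: with very small sorted populations the
descriptor estimates are binomially unstable, and 50 clonotypes bounds
the standard error of a mid-range occurrence percentage at roughly ±7
points. Comparisons require at least 2 donors per arm.

## The simulator

The generator emulates the structural features the analysis assumes,
with defaults chosen to be realistic for human TRB repertoires rather
than fitted to any dataset:

* **Segment pools** — 15 V and 10 J synthetic segments with Zipf-like
  weights (`1/rank`), each V flank beginning with a cysteine codon and
  each J flank ending with a phenylalanine codon (2–4 codons each). The
  flank peptides avoid lysine and tryptophan so that injected K/W effects
  sit on a junction-driven baseline.
* **Junctions** — insertions drawn codon-wise from the 61 sense codons
  with a geometric codon count (mean 6 nt), so intended-functional
  clonotypes are stop-free by construction and the nucleotide/protein
  consistency invariant holds everywhere.
* **Non-functional fraction** — a configurable rate (default 0.1) of
  rearrangements disrupted by a stop-codon substitution or a
  single-nucleotide frameshift, exercising the filtering step.
* **Clone sizes** — a discrete power law `P(k) ∝ k^−2.5` truncated at
  10⁴, giving realistic skew (most clonotypes singletons, a heavy tail of
  expansions), drawn independently of CDR3 content.
* **Donor variability** — per-donor segment weights are jittered with a
  Dirichlet-style gamma draw (concentration 50), reproducing the
  considerable donor-to-donor variation in gene-segment usage seen in
  real cohorts while leaving amino-acid composition comparatively stable.
* **Reproducibility** — one root seed; each (donor, condition) stream is
  derived by a stable string hash, so adding a donor never perturbs the
  other donors' draws, and identical configurations are byte-identical.

Independent draws can produce the same (V, J, junction) rearrangement;
such collisions are merged, so a repertoire holds slightly fewer unique
clonotypes than `clonotypes_per_repertoire` (roughly 75% at the default
insertion length) and public-style clonotypes acquire larger counts.

**Enrichment injection** is performed on the merged (unique-clonotype)
table of case-arm repertoires: an exactly-sized random subset of
functional clonotypes lacking the target feature receives a codon
substitution (or flank swap, for segment enrichment) that rewrites both
`cdr3_nt` and `cdr3_aa`. A substitution that would duplicate an existing
clonotype key is rejected and replaced by a fresh candidate. Both choices
exist for the same reason: the realized effect is defined on
diversity-weighted occurrence, and either raw-draw injection or
collision-losing substitution would erode the requested effect by one to
three percentage points at default settings. Enrichment at anchor
positions (position 1, or the terminal residue) is rejected as a
configuration error because it would break anchor conservation.
Infeasible requests — more substitutions than eligible clonotypes — are
configuration errors, not silent truncations.

### What the simulator does *not* model

Real germline sequences (the pools are synthetic, IMGT-style in name
only), exonuclease chewing and non-templated N/P nucleotide structure,
thymic selection, α/β pairing, sequencing error, or cross-donor sharing
beyond chance collisions. Passing parameter-recovery tests therefore
demonstrates that the *pipeline* is correct and calibrated — not that any
particular biological effect exists; conclusions about real repertoires
still require the real data.

## Numerical and design choices

* Occurrence values are percentages in [0, 100] throughout; tolerances in
  tests are absolute (1e-9 to 1e-12 for exact identities, Monte-Carlo
  bands for stochastic checks).
* Sample sizes used in the validation suite — cohorts of 5 + 5 donors
  with 2000 clonotypes per repertoire, 100–200 replicate runs for
  power/calibration estimates, 50,000 clonotypes for single-repertoire
  effect checks — were chosen to give stable Monte-Carlo estimates at
  interactive runtimes.
* Tie-breaks are lexicographic everywhere an order matters, so outputs
  are platform-independent.
* Empty repertoires raise typed empty-input errors from descriptors;
  all-non-functional repertoires filter to empty with a warning.
* Metadata (donor, subset, chain, condition) comes from an explicit
  manifest rather than from file-name parsing: file-naming conventions
  vary across labs, and a manifest keeps the mapping auditable.
* The MIXCR input dialect maps `cloneCount`/`cloneFraction`/`nSeqCDR3`/
  `aaSeqCDR3`/`bestVHit`/`bestDHit`/`bestJHit`; the VDJtools dialect maps
  `count`/`freq`/`cdr3nt`/`cdr3aa`/`v`/`d`/`j`.

## Known limitations

The t-tests treat donors as exchangeable replicates; paired designs
(case and control sorted from the same donor) would gain power from a
paired test, which is not yet implemented. The Šídák step assumes
non-negative dependence between features for strict FWER control;
composition features are mildly positively dependent (shared clonotypes),
and the simulated null keeps the realized family-wise error at or below
nominal (about 0.03 at α = 0.05 in the calibration runs). Percent change
is undefined for features absent in controls — reported as `NA`, these
features are still ranked by their adjusted p-values.
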