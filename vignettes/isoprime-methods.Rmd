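---
title: "Designing and quantifying paralog-specific qPCR assays with isoprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying paralog-specific qPCR assays with isoprime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoprime)
library(dplyr)
```

isoprime builds quantitative RT-PCR assays that resolve individual members
of closely related multigene families. This vignette explains the models
and procedures behind each step, the parameters that matter, the design
choices made where the methodology left them open, and what the synthetic
test bed does and does not demonstrate.

## 1. SNP classification in a labelled alignment

The unit of information is an aligned family of coding sequences in which
every record carries a gene label and an allele label. For each polymorphic
column, `discover_snps()` classifies per gene:

* **gene-differentiating for g** — every allele of *g* carries the same
  concrete residue *x*, and no allele of any other gene carries *x*. These
  columns are the substrate of primer specificity: a primer whose 3′
  terminus sits on such a column matches all alleles of *g* and mismatches
  every paralog.
* **allele-differentiating in g** — alleles of *g* disagree at the column.
  A primer footprint over such a column risks missing some alleles of its
  own target, so these columns are tolerated only at a primer's 5′ end.

The two classes are mutually exclusive by construction (gene-level status
requires within-gene unanimity), and classification is invariant under
record order; both are property-tested on simulated families.

Three conventions needed fixing where the underlying methodology is silent:

* **Gaps are not residues.** A gene with a gap in any allele at a column
  cannot be gene-differentiating there, because exploiting an indel as if
  it were a substitution would require explicit indel-priming logic that is
  out of scope. Within-gene disagreement is likewise judged on non-gap
  residues only.
* **IUPAC ambiguity codes mismatch everything.** An `N` (or any partial
  code) never supports unanimity and counts as within-gene disagreement.
  This is deliberately conservative: a specificity claim must not rest on
  ambiguous evidence.
* **The consensus for `snp_cons`** (the per-primer count of mismatches to
  the family consensus, as annotated in primer panels) is the column-wise
  majority over all records, ties broken alphabetically. A majority
  consensus is the natural reading of a consensus-highlighted family
  alignment, but no tie rule is ever stated anywhere we know of, so the
  alphabetical rule is declared here to make the counts reproducible. With
  only the panel's printed counts and no deposited 380-sequence alignment,
  this convention cannot be cross-validated against the shipped fixture;
  its counts are carried as data.
* A **single-gene family** yields no gene-differentiating sites at all:
  there is nothing to differentiate from. `design_panel()` then waives the
  anchoring requirement with an explicit warning and flags the row.

## 2. Primer design

`enumerate_candidates()` slides every window of 18–24 nt over the target
gene's reference cds on both strands and keeps windows that contain only
unambiguous ACGT bases, fall in the 20–80 % GC band, and carry no
allele-differentiating SNP outside the 5′-terminal tolerance window
(default 2 nt). A candidate is *anchored* when a gene-differentiating SNP
lies within `three_prime_anchor_window` nt of its 3′ terminus.

The anchor window defaults to **1 nt** — the terminal base — because
3′-terminal mismatch discrimination is strongest there, and the published
*Mal d 1* panel anchors on terminal bases in most rows. It is configurable
for chemistries with more tolerant polymerases.

`pair_primers()` accepts a pair when:

* the amplicon is 80–200 bp — as a **soft** constraint: pairs up to 15 %
  outside the band are kept with a warning, because published panels built
  under the same nominal rule contain 79 bp and 228 bp products. The slack
  is configurable; set `amplicon_slack = 0` for a hard rule.
* at least one primer is anchored (shared primers across genes are
  legitimate exactly when the partner primer carries the anchor, as in the
  subfamily-I pairs of the shipped panel);
* allele-SNP-bearing primers occupy at most one of the two positions;
* the pair's Tm spread is ≤ 3 °C;
* homo- and heterodimer scores pass the screen (below).

Ranking is lexicographic: total allele-SNP count ascending, total gene-SNP
count descending, Tm difference ascending, amplicon length ascending, then
template position — i.e. coverage safety first, discrimination strength
second, PCR practicality third. Dimer screening is applied to the ranked
shortlist (default 200 pairs; 50 in `design_panel()`, which keeps only the
best pair), so the returned pairs are the fully validated head of the
ranking.

### Oligo melting temperature

`primer_tm()` uses nearest-neighbour ΔH/ΔS summation with the unified
parameter set, terminal initiation terms, a symmetry correction for
self-complementary oligos, and the entropic salt correction
ΔS + 0.368 (N−1) ln[Na⁺]. Defaults: 250 nM total oligo, 50 mM monovalent.
Tm enters design only through the pair-spread constraint and the annealing
recommendation, so the absolute calibration matters less than internal
consistency; the implementation is checked against an independent
summation to 0.01 °C.

The recommended annealing temperature is `min(Tm_f, Tm_r) − 2 °C`, clamped
to **61–63 °C** — the range in which paralog-specific assays of this kind
are empirically optimized; the exact rule used in practice (specificity was
obtained by *raising* Ta) is not derivable, so the clamp range is exposed
as a constraint parameter.

### Dimer scoring

`dimer_score()` slides the two oligos against each other antiparallel at
every offset and takes the best contiguous complementary run, scoring +1
per match and ×2 when the matched position is the 3′-terminal base of
either oligo (3′-ended duplexes are the ones a polymerase extends into
artifacts). The default acceptance threshold is **12**: scoring the 62
primers of the shipped published panel gives homo-/heterodimer scores up to
exactly 12, so the default accepts precisely the complementarity level that
panel's wet-lab validation accepted. Lower it for stricter screens.

## 3. In-silico PCR and melt-curve QC

`find_sites()` scans both strands at every offset. A site is *productive*
when it has **zero mismatches in the 3′-terminal window (default 4 nt)**
and at most `max_mm = 2` elsewhere. These two knobs are the model of
polymerase extension: the true mismatch tolerance of any particular
enzyme/buffer/Ta combination is not knowable from sequence alone, so the
model is parameterized rather than calibrated, and near-misses (one
mismatch over the limit) are still reported for inspection. Partial
3′-overhang priming is not modelled. The scanner is verified against a
naive all-offset oracle on hundreds of random instances.

`predict_amplicons()` emits one product per convergent pair of productive
sites within 1 500 bp (either primer may serve either strand);
`specificity_report()` renders the closed-loop verdict — *specific* means
every allele of the target amplifies and nothing else does — plus a note
when a single primer binds an off-target without co-amplification (the
shared-primer situation).

Melt-curve QC takes −dF/dT by central differences after a centred
moving-average smooth (window 3 points), and calls peaks as local maxima
with prominence ≥ 5 % of the derivative maximum by default. A flat or
monotone trace yields zero peaks and fails QC; so do two products ≥ a few
degrees apart. The synthetic melt generator superimposes descending
sigmoids, whose −dF/dT peaks sit at the product Tm by construction; peak
recovery is asserted to within one grid step (0.5 °C).

## 4. Standard-curve quantification

The amplification model is log-linear: Ct = baseline − log₁₀(q)/log₁₀(1+E).
Per assay, `fit_standard_curve()` regresses Ct on log₁₀(input) over a
dilution series (the canonical design is 6 serial 1:10 dilutions in
duplicate) and derives E = 10^(−1/slope) − 1. Quantities are *relative*
(dilution step 0 ≡ 1.0) since the final output is reference-normalized
arbitrary units, which cancels any absolute scale.

The **dCt-slope rule** decides the quantification method: regress
(Ct_target − Ct_reference) on log₁₀(input); when the slope leaves the
±0.1 band, target and reference efficiencies differ too much for the
comparative ΔΔCt shortcut, and the standard-curve method is required. The
package checks this per assay and reports the recommendation alongside the
results. At exactly equal 100 % efficiencies the two methods coincide; that
limit equivalence is tested on noiseless simulations.

Workflow conventions:

* technical replicates are **averaged on the Ct scale** before the quantity
  transform (instrument convention);
* `Undetermined` wells are parsed as censored at the cycle count (default
  40) and propagate as censored quantities;
* a gene is called **expressed** in a condition when at least one
  biological replicate has all technical replicates detected and median Ct
  at least 3 cycles below any NTC signal. The 3-cycle guard is a declared,
  configurable default — real assays publish no numeric call rule — and a
  censored NTC counts as signal at the censoring cycle, which keeps the
  guard meaningful even on clean plates. Non-expressed groups report
  0 A.U. with a censoring note rather than a spurious small number.
* duplicate standard wells enter the regression individually (regressing on
  per-step means is algebraically close but discards within-step
  information; both are supported through ordinary data manipulation).

Reference genes are ranked by the standard deviation of their mean Ct
across tissue × cultivar groups — the stable-Ct criterion under which actin
is the classic winner. Group comparisons use fixed-effects ANOVA at the
conventional 0.05 level via `stats::lm`/`anova`.

## 5. Phenetics

`p_distance_matrix()` uses pairwise deletion: identity is computed over
columns where neither sequence is gapped. This is stated explicitly
(alignment programs differ silently on this point) so that identity ranges
are auditable. `nj_tree()` is an in-package Saitou–Nei implementation with
the standard Q-criterion; ties in the Q minimisation break to the lowest
index pair for determinism, and negative branch-length estimates are
clamped to zero with a warning. On additive matrices NJ provably recovers
the generating tree; the tests assert exact topology and path-length
recovery against random additive matrices (n ≤ 8) and, at n = 5, against
an exhaustive enumeration of all 15 unrooted topologies.

`assign_subfamilies(tree, k)` cuts branches longest-first (ties by edge
index) until the leaves fall into exactly *k* groups. A rule that cuts
only *internal* branches can never isolate a single leaf, so the
all-branches rule was chosen to make the whole range 1 ≤ k ≤ n_leaves
well-defined; any visual clade cut of a drawn tree is a judgement call,
and this rule is the package's deterministic proxy for it.

## 6. The synthetic test bed

`simulate_family()` mutates an ancestor along a **star phylogeny** of
genes, then alleles within genes, with uniform per-site substitution and
equal exchange among the three alternative bases. A star keeps the expected
pairwise difference analytic — with per-lineage rate m = divergence/2, two
lineages differ per site with probability 2m(1−m) + (2/3)m² — which the
tests exploit as a 3-sd binomial check at length 1 000. Defaults (5 genes,
2 alleles, 500 bp, 10 % gene divergence, 0.5 % allele divergence) mirror a
moderately diverged isoallergen family; the specificity property suite runs
at 5 % gene divergence, the harder end of the realistic range.

`simulate_qpcr()` generates full plates under the log-linear model with
Gaussian well noise (default sd 0.15 Ct) and the canonical design: 6×1:10
standards in duplicate, unknowns in technical triplicate, duplicate NTCs,
censoring at cycle 40.

What the simulations do **not** emulate: indels and codon structure,
subfamily-shaped (non-star) divergence by default, PCR inhibitors,
plate/batch effects, non-Gaussian Ct outliers, and amplification curves
(only melt curves are synthesized). Passing the closed-loop properties
therefore demonstrates the internal consistency of design, screening and
quantification under the stated model — not wet-lab performance on any
particular family.

### Problem sizes and stochastic checks

The test suite runs simulated families of 2–5 genes at 120–1 000 bp, 20
seeds for the specificity property, 20 replicate plates for ratio recovery,
and 2 000 null datasets for the ANOVA type-I check — sizes chosen so the
whole suite exercises every stochastic claim while staying comfortably
interactive. One sizing choice deserves a note: with the canonical plate
design (two biological replicates, triplicate technicals, 0.15 Ct noise) a
*single* simulated experiment estimates a 4:1 expression ratio with ~8–9 %
sampling error, so a one-shot 10 % assertion would be a coin flip on the
experiment's own noise. The recovery checks therefore run 20 replicate
experiments and assert the median relative error and the mean estimate —
the statement that is actually stable at this design size.

## 7. Known limitations

* Specificity verdicts inherit the parameterized mismatch model; they are a
  screen, not a guarantee — end-point PCR, amplicon sequencing and melt
  analysis remain the wet-lab arbiters.
* No thermodynamic (ΔG) off-target ranking, secondary-structure folding,
  multiplexing optimisation, or probe-based chemistries (the workflow is
  intercalating-dye based).
* Single-reference normalization only; multi-reference geometric-mean
  schemes are out of scope.
* Indel-based discrimination is deliberately unsupported.
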