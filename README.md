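# isoprime

Gene-specific qPCR assay design and quantification for paralogous gene
families.

## The problem

Large plant gene families — the motivating case is the 31-locus apple
allergen family *Mal d 1* — contain paralogs that are 53–98 % identical at
the coding-sequence level, with alleles of a single gene 95–99.8 %
identical. Quantifying the expression of *one* family member by qRT-PCR
therefore requires primers that discriminate a target gene from siblings
that may differ by only a handful of nucleotides, while still amplifying
*every allele* of the target. isoprime implements the computational side of
that assay-building workflow for anyone designing paralog-resolved
expression panels:

1. **SNP classification.** Every polymorphic alignment column is classified
   per gene as *gene-differentiating* (all alleles of gene *g* share a
   residue no allele of any other gene carries — usable for specificity) or
   *allele-differentiating* (alleles of *g* disagree — a threat to
   within-gene coverage). Mutual exclusion of the two classes is a package
   invariant.
2. **Primer design.** Candidates are enumerated under the standard
   constraints (length 18–24 nt, GC 20–80 %, amplicon 80–200 bp) with the
   placement rules that give paralog discrimination: a gene-differentiating
   SNP under the 3′-terminal base of at least one primer of each pair, and
   allele-differentiating SNPs tolerated only at the 5′ end of at most one
   primer. Oligo Tm uses nearest-neighbour ΔH/ΔS summation with salt
   correction; homo-/heterodimers are screened by an antiparallel
   complementarity run score with 3′-weighted matches.
3. **In-silico validation.** A mismatch-aware binding-site scan (zero
   mismatches allowed in the 3′-terminal window, ≤ 2 elsewhere by default)
   predicts amplicons across the whole family and renders per-gene
   specificity verdicts; melt-curve QC passes only single-peak −dF/dT
   traces.
4. **Quantification.** The standard-curve method: per-assay OLS of Ct on
   log₁₀(input) over 6×1:10 dilution series, efficiency
   `E = 10^(−1/slope) − 1`, the ±0.1 dCt-slope rule for deciding when the
   comparative ΔΔCt shortcut is invalid, reference-gene normalization to
   arbitrary units (A.U.), SEM over biological replicates, expression calls
   against no-template controls, and fixed-effects ANOVA.

Neighbour-joining phenetics (`nj_tree()`, `assign_subfamilies()`) and a
synthetic-data generator for paralog families and qPCR plates with known
ground truth (`simulate_family()`, `simulate_qpcr()`) round out the
toolkit. The published 31-pair *Mal d 1* panel ships as a fixture
(`mald1_panel()`).

All user-facing functions take a data frame first and return tibbles, so
steps chain with the pipe; fitted curves have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Design a panel for a simulated 5-gene family (10 % gene divergence, two
alleles per gene at 0.5 % divergence) and verify it in silico:

```r
library(isoprime)
library(dplyr)

sim <- simulate_family(n_genes = 5, alleles_per_gene = 2, seq_length = 500,
                       gene_divergence = 0.10, allele_divergence = 0.005,
                       seed = 42)
panel <- design_panel(sim$family)
panel |> select(gene_id, start, amplicon_length, snp_gene_f, snp_gene_r, ta)
#> # A tibble: 5 × 6
#>   gene_id start amplicon_length snp_gene_f snp_gene_r    ta
#> 1 g01       318             183          5          2  61
#> 2 g02       202             210          3          3  61
#> 3 g03       368              77          4          3  61
#> 4 g04       207              73          3          3  61
#> 5 g05       338             111          3          4  61.4

panel_specificity(panel, sim$family) |> select(gene_id, verdict)
#> all five verdicts: "specific"
```

Every pair carries gene-differentiating SNPs (`snp_gene_*`) under its 3′
anchor, amplifies both alleles of its target and no other gene. Amplicons
slightly outside 80–200 bp are kept with a warning (the published panel
itself contains 79 bp and 228 bp products).

Fit a standard curve on a noisy simulated dilution series with true
efficiency 0.93:

```r
std <- tibble::tibble(q = rep(10^-(0:5), each = 2))
set.seed(1)
std$ct <- 19.8 - log10(std$q) / log10(1.93) + rnorm(12, 0, 0.15)
fit_standard_curve(std, q, ct)
#> <standard_curve> slope = -3.5276, intercept = 19.776, r2 = 0.9997, E = 0.921, n = 12
```

The slope of −3.53 corresponds to an amplification efficiency of 92 %
(perfect doubling would give −3.32 and E = 1); `r²` near 1 is the expected
quality of a good dilution series. `quantify_expression()` then converts a
full Ct table (unknowns in technical triplicate, per-assay standards,
NTCs) into reference-normalized A.U. with SEM and expression calls.

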