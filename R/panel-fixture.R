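# packaged Mal d 1 primer panel

#' The Mal d 1 gene-specific primer panel
#'
#' The published panel of 31 gene-specific qRT-PCR primer pairs for the
#' apple *Mal d 1* isoallergen family, shipped as a plain-text fixture.  One
#' row per gene: primer names and sequences (5'->3'), per-primer SNP counts
#' (`snp_cons` = mismatches to the family consensus, `snp_gene` =
#' gene-differentiating SNPs, `snp_allele` = allele-differentiating SNPs),
#' the forward-primer start position on the reference cds, amplicon length
#' (bp), optimized primer concentration (nM), annealing temperature Ta
#' (deg C), measured amplicon Tm (deg C) and the dCt-vs-log-input slope
#' against the actin reference.
#'
#' Twelve of the 31 pairs carry allele-differentiating SNPs (always at the
#' 5' end of at most one primer); all Ta values lie in the optimized
#' 61--63 deg C range.  Subfamily-I genes share a forward primer
#' (`qMd1.01/02F`) whose partner primer is the gene-anchored one.
#'
#' @return a primer-panel tibble (see [read_primer_panel()]).
#' @export
#' @examples
#' panel <- mald1_panel()
#' nrow(panel)  # 31
mald1_panel <- function() {
  path <- system.file("extdata", "mald1_primer_panel.tsv", package = "isoprime",
                      mustWork = TRUE)
  read_primer_panel(path)
}
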