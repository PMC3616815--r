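# snp_atlas: discovery and classification of gene- vs allele-differentiating SNPs

#' Classify one alignment column
#'
#' Given the residues each gene's alleles carry at a column, decide for which
#' genes the column is *gene-differentiating* (all alleles of the gene share
#' one concrete residue that no allele of any other gene carries) and in
#' which genes it is *allele-differentiating* (the gene's own alleles
#' disagree).
#'
#' Gaps are not residues: a gene with a gap in any allele cannot be
#' gene-differentiating at that column.  IUPAC ambiguity codes are treated
#' conservatively as mismatching every concrete residue, so an ambiguous
#' residue can never support unanimity, and within a gene it counts as
#' disagreement.
#'
#' The two sets are mutually exclusive by construction: gene-differentiating
#' status requires within-gene unanimity.
#'
#' @param residues_by_gene named list, one character vector of residues per
#'   gene (one element per allele; `"-"` for a gap).
#' @return a list with character vectors `gene_diff` and `allele_diff`.
#' @export
#' @examples
#' classify_column(list(g1 = c("A", "A"), g2 = c("C", "C")))
classify_column <- function(residues_by_gene) {
  genes <- names(residues_by_gene)
  info <- lapply(residues_by_gene, function(v) {
    v <- toupper(v)
    nongap <- v[v != "-"]
    concrete <- nongap[nongap %in% DNA_BASES]
    unanimous <- length(v) > 0L && all(v != "-") &&
      length(concrete) == length(v) && length(unique(concrete)) == 1L
    disagree <- length(nongap) >= 2L &&
      (length(unique(nongap)) > 1L || any(!nongap %in% DNA_BASES))
    list(unanimous = unanimous,
         shared = if (unanimous) concrete[1L] else NA_character_,
         concrete = unique(concrete),
         disagree = disagree)
  })
  allele_diff <- genes[vapply(info, `[[`, logical(1), "disagree")]
  gene_diff <- character(0)
  for (g in genes) {
    if (length(genes) < 2L) break   # nothing to differentiate from
    if (!info[[g]]$unanimous) next
    x <- info[[g]]$shared
    others <- unlist(lapply(info[setdiff(genes, g)], `[[`, "concrete"))
    if (!x %in% others) gene_diff <- c(gene_diff, g)
  }
  list(gene_diff = gene_diff, allele_diff = allele_diff)
}

#' Discover polymorphic sites in a labelled alignment
#'
#' Scans every alignment column and keeps those with at least two distinct
#' non-gap residues; each kept site is classified with [classify_column()].
#' Monomorphic and all-gap columns are excluded.
#'
#' @param fam an aligned gene-family tibble with >= 2 records.
#' @return a tibble with one row per polymorphic column: `column`,
#'   `residues` (a `gene=residues;...` summary string), and list-columns
#'   `gene_diff` and `allele_diff` holding the gene sets.
#' @export
discover_snps <- function(fam) {
  if (nrow(fam) < 2L) abort("need at least 2 records to discover SNPs",
                            class = "isoprime_value_error")
  if (!is_aligned(fam)) abort("family is not aligned", class = "isoprime_format_error")
  m <- aln_matrix(fam)
  genes <- fam$gene_id
  poly <- which(apply(m, 2L, function(col) {
    r <- col[col != "-"]
    length(unique(r)) >= 2L
  }))
  if (length(poly) == 0L) {
    return(tibble(column = integer(0), residues = character(0),
                  gene_diff = list(), allele_diff = list()))
  }
  rows <- lapply(poly, function(j) {
    by_gene <- split(m[, j], genes)
    cls <- classify_column(by_gene)
    tibble(column = j,
           residues = paste(vapply(names(by_gene), function(g)
             paste0(g, "=", paste0(by_gene[[g]], collapse = "")), character(1)),
             collapse = ";"),
           gene_diff = list(cls$gene_diff),
           allele_diff = list(cls$allele_diff))
  })
  bind_rows(rows)
}

#' Majority consensus sequence of an alignment
#'
#' Column-wise majority residue over all records, ignoring gaps; ties are
#' broken alphabetically.  All-gap columns yield `"-"`.
#'
#' @param fam an aligned gene-family tibble.
#' @return a single character string of length `n_columns`.
#' @export
consensus_sequence <- function(fam) {
  m <- aln_matrix(fam)
  cons <- apply(m, 2L, function(col) {
    r <- col[col != "-"]
    if (length(r) == 0L) return("-")
    tab <- table(r)
    cand <- sort(names(tab)[tab == max(tab)])
    cand[1L]
  })
  paste0(cons, collapse = "")
}

#' Count SNPs under a primer footprint
#'
#' For a contiguous footprint on the reference cds of the target gene,
#' counts the three SNP classes reported in a primer panel:
#' `snp_cons` (footprint columns where the reference residue differs from
#' the whole-alignment majority consensus), `snp_gene` (columns
#' gene-differentiating for the target gene) and `snp_allele` (columns
#' allele-differentiating within the target gene).
#'
#' @param fam an aligned gene-family tibble.
#' @param target_gene the gene the primer targets.
#' @param start 1-based start of the footprint on the reference cds
#'   (ungapped coordinates).
#' @param length footprint length in nt.
#' @param sites optional precomputed [discover_snps()] table.
#' @param consensus optional precomputed [consensus_sequence()] string.
#' @return a one-row tibble with `snp_cons`, `snp_gene`, `snp_allele`.
#' @export
annotate_primer_snps <- function(fam, target_gene, start, length,
                                 sites = NULL, consensus = NULL) {
  rid <- reference_record_id(fam, target_gene)
  refseq <- fam$seq[match(rid, fam$record_id)]
  L <- nchar(gsub("-", "", refseq, fixed = TRUE))
  if (start < 1L || start + length - 1L > L) {
    abort("primer footprint outside the reference cds", class = "isoprime_bounds_error")
  }
  cols <- ungapped_to_aligned(fam, rid, seq.int(start, start + length - 1L))
  sites <- sites %||% discover_snps(fam)
  consensus <- consensus %||% consensus_sequence(fam)
  ref_ch <- seq_chars(refseq)[cols]
  cons_ch <- seq_chars(consensus)[cols]
  in_fp <- sites$column %in% cols
  n_gene <- sum(vapply(sites$gene_diff[in_fp], function(g) target_gene %in% g, logical(1)))
  n_allele <- sum(vapply(sites$allele_diff[in_fp], function(g) target_gene %in% g, logical(1)))
  tibble(snp_cons = sum(ref_ch != cons_ch),
         snp_gene = as.integer(n_gene),
         snp_allele = as.integer(n_allele))
}

#' Flatten a SNP site table for export
#'
#' Turns the list-columns of [discover_snps()] output into comma-separated
#' strings, suitable for writing as TSV.
#'
#' @param sites a [discover_snps()] tibble.
#' @return a plain tibble with character columns.
#' @export
flatten_snp_sites <- function(sites) {
  mutate(sites,
         gene_diff = map_chr(.data$gene_diff, paste, collapse = ","),
         allele_diff = map_chr(.data$allele_diff, paste, collapse = ","))
}
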