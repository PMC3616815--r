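# synth: simulated paralog families and qPCR experiments with known truth

#' Simulate a paralogous gene family
#'
#' Generates an ancestor sequence, mutates it independently along a star
#' phylogeny of genes (uniform substitution process, equal exchange among
#' the three alternative bases), then mutates alleles within each gene the
#' same way.  A star phylogeny keeps expected pairwise distances analytic:
#' with per-lineage substitution probability `m = divergence / 2`, two
#' lineages differ at a site with probability `2 m (1 - m) + (2/3) m^2`.
#'
#' The emulated structure mirrors a real isoallergen family: between-gene
#' identity well below within-gene identity (e.g. 53--98 % between genes vs
#' 95--99.8 % between alleles of a gene).
#'
#' @param n_genes number of genes (default 5).
#' @param alleles_per_gene alleles per gene (default 2).
#' @param seq_length sequence length in bp (default 500).
#' @param gene_divergence expected substitutions/site between genes
#'   (default 0.10).
#' @param allele_divergence expected substitutions/site between alleles of a
#'   gene (default 0.005); must be below `gene_divergence`.
#' @param gc_bias stationary GC fraction of the ancestor (default 0.5).
#' @param seed mandatory RNG seed: the same seed gives byte-identical output.
#' @return a list with `family` (a gene-family tibble, records
#'   `g01_a1` ...), `truth` (a tibble of every mutated position:
#'   `record_id`, `gene_id`, `level` gene/allele, `position`, `from`, `to`),
#'   `ancestor`, and `params`.
#' @export
simulate_family <- function(n_genes = 5, alleles_per_gene = 2, seq_length = 500,
                            gene_divergence = 0.10, allele_divergence = 0.005,
                            gc_bias = 0.5, seed) {
  if (missing(seed)) abort("seed is mandatory", class = "isoprime_value_error")
  if (!(allele_divergence >= 0 && allele_divergence < gene_divergence &&
        gene_divergence <= 0.75)) {
    abort("need 0 <= allele_divergence < gene_divergence <= 0.75",
          class = "isoprime_value_error")
  }
  set.seed(seed)
  probs <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  ancestor <- sample(DNA_BASES, seq_length, replace = TRUE, prob = probs)
  mutate_seq <- function(base_seq, rate) {
    hit <- which(stats::runif(seq_length) < rate)
    out <- base_seq
    for (p in hit) {
      out[p] <- sample(setdiff(DNA_BASES, base_seq[p]), 1L)
    }
    list(seq = out, positions = hit, from = base_seq[hit], to = out[hit])
  }
  recs <- list(); truth <- list()
  for (gi in seq_len(n_genes)) {
    g <- sprintf("g%02d", gi)
    founder <- mutate_seq(ancestor, gene_divergence / 2)
    for (ai in seq_len(alleles_per_gene)) {
      a <- paste0("a", ai)
      al <- mutate_seq(founder$seq, allele_divergence / 2)
      rid <- paste(g, a, sep = "_")
      recs[[rid]] <- tibble(record_id = rid, gene_id = g, allele_id = a,
                            molecule = "cds", seq = paste0(al$seq, collapse = ""))
      tr <- bind_rows(
        if (length(founder$positions))
          tibble(level = "gene", position = founder$positions,
                 from = founder$from, to = founder$to),
        if (length(al$positions))
          tibble(level = "allele", position = al$positions,
                 from = al$from, to = al$to)
      )
      if (!is.null(tr) && nrow(tr)) {
        tr$record_id <- rid; tr$gene_id <- g
        truth[[rid]] <- tr[, c("record_id", "gene_id", "level", "position", "from", "to")]
      }
    }
  }
  fam <- bind_rows(recs)
  validate_family(fam)
  list(family = fam,
       truth = bind_rows(truth) %||% tibble(record_id = character(0)),
       ancestor = paste0(ancestor, collapse = ""),
       params = list(n_genes = n_genes, alleles_per_gene = alleles_per_gene,
                     seq_length = seq_length, gene_divergence = gene_divergence,
                     allele_divergence = allele_divergence, gc_bias = gc_bias,
                     seed = seed))
}

#' Expected per-site difference between two star-phylogeny lineages
#'
#' Closed form used to check realized p-distances of [simulate_family()]:
#' `2 m (1 - m) + (2/3) m^2` with `m = divergence / 2`.
#'
#' @param divergence the generator's divergence parameter.
#' @return expected pairwise per-site difference.
#' @export
expected_pairwise_difference <- function(divergence) {
  m <- divergence / 2
  2 * m * (1 - m) + (2 / 3) * m^2
}

#' Simulate a qPCR experiment
#'
#' Generates a full Ct table for a set of assays and samples under the
#' log-linear amplification model `Ct = baseline - log10(q) / log10(1 + E)`
#' plus Gaussian well noise, with the plate design used throughout:
#' a per-assay dilution series (default 6 serial 1:10 dilutions in
#' duplicate), unknown wells in technical triplicate, and no-template
#' controls in duplicate.  Wells whose Ct exceeds `max_cycle` are censored.
#'
#' @param assays tibble with `assay_id`, `efficiency` (fraction, e.g. 0.95),
#'   `baseline_ct` (Ct at unit quantity).
#' @param samples tibble with `sample_id`, `tissue`, `cultivar`, `assay_id`,
#'   `quantity` (true relative input per sample x assay).
#' @param n_technical technical replicates per unknown well (default 3).
#' @param dilution_levels number of standard dilutions (default 6).
#' @param dilution_replicates standard replicates per level (default 2).
#' @param dilution_factor fold-dilution between levels (default 10).
#' @param n_ntc no-template controls per assay (default 2).
#' @param noise_sd Gaussian Ct noise sd (default 0.15).
#' @param max_cycle censoring cycle (default 40).
#' @param seed mandatory RNG seed.
#' @return a Ct tibble in [read_ct_table()] layout (with `censored`).
#' @export
simulate_qpcr <- function(assays, samples, n_technical = 3, dilution_levels = 6,
                          dilution_replicates = 2, dilution_factor = 10,
                          n_ntc = 2, noise_sd = 0.15, max_cycle = 40, seed) {
  if (missing(seed)) abort("seed is mandatory", class = "isoprime_value_error")
  if (any(assays$efficiency <= 0.5 | assays$efficiency > 1.1)) {
    abort("efficiency must be in (0.5, 1.1]", class = "isoprime_value_error")
  }
  if (noise_sd < 0) abort("noise sd must be >= 0", class = "isoprime_value_error")
  set.seed(seed)
  true_ct <- function(q, E, baseline) baseline - log10(q) / log10(1 + E)
  rows <- list()
  for (i in seq_len(nrow(assays))) {
    a <- assays$assay_id[i]; E <- assays$efficiency[i]; b <- assays$baseline_ct[i]
    for (lev in seq_len(dilution_levels) - 1L) {
      q <- dilution_factor^(-lev)
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = paste0("std_", a, "_", lev),
        tissue = "standard", cultivar = "standard", assay_id = a,
        replicate_type = "standard", dilution_step = lev,
        ct = true_ct(q, E, b) + rnorm(dilution_replicates, 0, noise_sd))
    }
    if (n_ntc > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = paste0("ntc_", a), tissue = "ntc", cultivar = "ntc",
        assay_id = a, replicate_type = "ntc", dilution_step = NA_integer_,
        ct = rep(Inf, n_ntc))
    }
  }
  for (i in seq_len(nrow(samples))) {
    a <- samples$assay_id[i]
    j <- match(a, assays$assay_id)
    if (is.na(j)) abort(paste0("sample references unknown assay: ", a),
                        class = "isoprime_value_error")
    rows[[length(rows) + 1L]] <- tibble(
      sample_id = samples$sample_id[i], tissue = samples$tissue[i],
      cultivar = samples$cultivar[i], assay_id = a,
      replicate_type = "technical", dilution_step = NA_integer_,
      ct = true_ct(samples$quantity[i], assays$efficiency[j], assays$baseline_ct[j]) +
        rnorm(n_technical, 0, noise_sd))
  }
  out <- bind_rows(rows)
  out$censored <- out$ct > max_cycle
  out$ct[out$censored] <- max_cycle
  out
}

#' Simulate a dissociation (melt) curve
#'
#' Each product contributes a descending sigmoid
#' `h / (1 + exp((T - Tm) / w))`; the negative first derivative then peaks
#' at each product's Tm.  A single product gives the single sharp peak that
#' passes [single_peak_qc()]; two products of different Tm give two peaks.
#'
#' @param tm melting temperature(s) of the product(s), deg C.
#' @param heights relative amounts (recycled against `tm`).
#' @param width sigmoid transition width, deg C (default 1).
#' @param temperature temperature grid (default 60--95 by 0.5, the
#'   instrument's default melt ramp).
#' @param noise_sd fluorescence noise sd (default 0).
#' @param seed RNG seed, required when `noise_sd > 0`.
#' @return a tibble `temperature`, `fluorescence`.
#' @export
simulate_melt_curve <- function(tm, heights = 1, width = 1,
                                temperature = seq(60, 95, by = 0.5),
                                noise_sd = 0, seed = NULL) {
  heights <- rep_len(heights, length(tm))
  f <- rowSums(vapply(seq_along(tm), function(i) {
    heights[i] / (1 + exp((temperature - tm[i]) / width))
  }, numeric(length(temperature))))
  if (noise_sd > 0) {
    if (is.null(seed)) abort("seed required for noisy melt curves",
                             class = "isoprime_value_error")
    set.seed(seed)
    f <- f + rnorm(length(f), 0, noise_sd)
  }
  tibble(temperature = temperature, fluorescence = f)
}
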