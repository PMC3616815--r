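# Independent oracles and fixture builders shared across tests.
# Oracles are deliberately written with different mechanics than the
# implementation paths they check.

# -- toy families -------------------------------------------------------------

toy_family <- function(seqs, genes, alleles = NULL) {
  alleles <- alleles %||% stats::ave(genes, genes, FUN = function(x) paste0("a", seq_along(x)))
  tibble::tibble(record_id = paste(genes, alleles, sep = "_"),
                 gene_id = genes, allele_id = alleles,
                 molecule = "cds", seq = toupper(seqs))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# -- naive binding-site scanner (per-offset substring comparison) -------------

naive_find_sites <- function(primer, template, max_mm = 2, w = 4) {
  Lp <- nchar(primer); Lt <- nchar(template)
  rows <- list()
  if (Lt >= Lp) {
    pl <- strsplit(toupper(primer), "")[[1]]
    rc <- strsplit(revcomp(primer), "")[[1]]
    for (st in seq_len(Lt - Lp + 1L)) {
      win <- strsplit(substr(toupper(template), st, st + Lp - 1L), "")[[1]]
      for (strand in c("+", "-")) {
        q <- if (strand == "+") pl else rc
        mm <- q != win | !q %in% c("A", "C", "G", "T")
        tot <- sum(mm)
        if (tot > max_mm + 1) next
        m3 <- if (strand == "+") sum(utils::tail(mm, w)) else sum(utils::head(mm, w))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strand = strand, start = st, end = st + Lp - 1L,
          mismatches = tot, mm_three_prime = m3,
          productive = tot <= max_mm && m3 == 0L)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(strand = character(0), start = integer(0), end = integer(0),
                          mismatches = integer(0), mm_three_prime = integer(0),
                          productive = logical(0))
  }
  out[order(out$strand, out$start), ]
}

# -- brute-force dimer score (explicit run state machine) ---------------------

naive_dimer_score <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]; B <- strsplit(toupper(b), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  na <- length(A); nb <- length(B)
  best <- 0
  for (s in (-(nb - 1L)):(na - 1L)) {
    cur <- 0
    for (i in seq_len(na)) {
      k <- i - s
      matched <- FALSE
      if (k >= 1L && k <= nb) {
        bpos <- nb - k + 1L
        if (A[i] %in% names(comp) && comp[[A[i]]] == B[bpos]) {
          wgt <- if (i == na || bpos == nb) 2 else 1
          cur <- cur + wgt
          best <- max(best, cur)
          matched <- TRUE
        }
      }
      if (!matched) cur <- 0
    }
  }
  best
}

# -- additive distance matrices from random trees -----------------------------

random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1   # keep branches clearly positive
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# topology equality for unrooted trees
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# -- independent NN thermodynamic summation (spreadsheet-style) ---------------

oracle_nn_tm <- function(s, oligo_nM = 250, na_mM = 50) {
  dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
          GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  ch <- strsplit(toupper(s), "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  H <- sum(dh[di]); S <- sum(ds[di])
  for (term in c(ch[1], ch[length(ch)])) {
    if (term %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  selfc <- identical(toupper(s), revcomp(s))
  if (selfc) S <- S - 1.4
  x <- if (selfc) 1 else 4
  S <- S + 0.368 * (length(ch) - 1) * log(na_mM / 1000)
  H * 1000 / (S + 1.987 * log(oligo_nM * 1e-9 / x)) - 273.15
}

# -- simulated two-cultivar qPCR experiment with known expression ratio -------

ratio_experiment <- function(seed, ratio = 4, noise_sd = 0.15,
                             eff_target = 0.93, eff_ref = 1.0) {
  assays <- tibble::tibble(assay_id = c("target", "actin"),
                           efficiency = c(eff_target, eff_ref),
                           baseline_ct = c(20, 18))
  samples <- tidyr::expand_grid(sample_id = c("hi_1", "hi_2", "lo_1", "lo_2"),
                                assay_id = assays$assay_id)
  samples$tissue <- "peel"
  samples$cultivar <- ifelse(startsWith(samples$sample_id, "hi"), "hi", "lo")
  samples$quantity <- ifelse(samples$assay_id == "actin", 0.05,
                             ifelse(samples$cultivar == "hi", 0.05 * ratio, 0.05))
  ct <- simulate_qpcr(assays, samples, noise_sd = noise_sd, seed = seed)
  res <- suppressWarnings(quantify_expression(ct, "actin"))
  res$au_mean[res$cultivar == "hi"] / res$au_mean[res$cultivar == "lo"]
}

`%||%` <- rlang::`%||%`
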