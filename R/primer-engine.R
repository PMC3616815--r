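# primer_engine: candidate enumeration, scoring and pairing under SNP-placement rules

# Unified nearest-neighbour parameter set (duplex formation, 1 M NaCl):
# dH in kcal/mol, dS in cal/(mol K).  Keys are the 16 template dinucleotides;
# a dinucleotide and its reverse complement describe the same stacked pair.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal base pair
INIT_DS <- c(GC = -2.8, AT = 4.1)
SYM_DS <- -1.4
GAS_R <- 1.987  # cal/(mol K)

#' GC content of a sequence
#'
#' @param seq character vector of sequences.
#' @return percent G+C, `100 * (G + C) / length`.
#' @export
#' @examples
#' gc_content("ATGC")
gc_content <- function(seq) {
  s <- toupper(seq)
  100 * str_count(s, "[GC]") / nchar(s)
}

#' Oligonucleotide melting temperature (nearest-neighbour model)
#'
#' Duplex melting temperature from nearest-neighbour enthalpy/entropy
#' summation with the unified parameter set, an entropic salt correction
#' (`dS + 0.368 (N-1) ln[Na+]`) and a symmetry correction for
#' self-complementary oligos.
#'
#' @param seq character vector of primer sequences (ACGT only, length >= 8).
#' @param oligo_conc_nM total oligo concentration in nM (default 250).
#' @param monovalent_mM monovalent cation concentration in mM (default 50).
#' @return melting temperatures in degrees Celsius.
#' @export
primer_tm <- function(seq, oligo_conc_nM = 250, monovalent_mM = 50) {
  vapply(seq, function(s) {
    s <- toupper(s)
    ch <- seq_chars(s)
    if (length(ch) < 8L) abort("primer too short for NN model (< 8 nt)",
                               class = "isoprime_value_error")
    if (any(!ch %in% DNA_BASES)) abort("ambiguity codes not allowed in primer_tm",
                                       class = "isoprime_value_error")
    dinuc <- paste0(ch[-length(ch)], ch[-1L])
    dH <- sum(NN_DH[dinuc])
    dS <- sum(NN_DS[dinuc])
    for (term in c(ch[1L], ch[length(ch)])) {
      key <- if (term %in% c("G", "C")) "GC" else "AT"
      dH <- dH + INIT_DH[[key]]
      dS <- dS + INIT_DS[[key]]
    }
    selfcomp <- identical(s, revcomp(s))
    if (selfcomp) dS <- dS + SYM_DS
    x <- if (selfcomp) 1 else 4
    dS_salt <- dS + 0.368 * (length(ch) - 1L) * log(monovalent_mM / 1000)
    ct <- oligo_conc_nM * 1e-9
    dH * 1000 / (dS_salt + GAS_R * log(ct / x)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer-dimer complementarity score
#'
#' Slides the two oligos against each other in antiparallel orientation at
#' every offset and scores the best contiguous run of Watson--Crick
#' complementary positions: +1 per match, x2 when the matched position is
#' the 3'-terminal base of either oligo.  The returned score is the maximum
#' run score over all offsets; 0 when no position is complementary.
#'
#' @param seq_a,seq_b primer sequences (5'->3').
#' @return a non-negative numeric score.
#' @export
#' @examples
#' dimer_score("AAAA", "TTTT")
dimer_score <- function(seq_a, seq_b) {
  a <- seq_chars(seq_a)
  b <- seq_chars(seq_b)
  na <- length(a); nb <- length(b)
  brev <- rev(b)                     # brev[k] is base nb - k + 1 of b
  bcomp <- unname(COMP[brev])
  best <- 0
  for (s in (-(nb - 1L)):(na - 1L)) {
    i <- seq_len(na)
    j <- i - s                       # index into brev
    ok <- j >= 1L & j <= nb
    if (!any(ok)) next
    ii <- i[ok]; jj <- j[ok]
    match <- a[ii] == bcomp[jj] & a[ii] %in% DNA_BASES
    if (!any(match)) next
    w <- 1 + as.numeric(ii == na | jj == 1L)   # jj == 1 is b's 3' terminus
    w[w > 1] <- 2
    r <- rle(match)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      sc <- sum(w[starts[q]:ends[q]])
      if (sc > best) best <- sc
    }
  }
  best
}

#' Primer design constraints
#'
#' Container for the physicochemical and SNP-placement constraints used in
#' candidate enumeration and pairing.
#'
#' @param primer_len allowed primer length range in nt (default 18--24).
#' @param gc allowed GC-content range in percent (default 20--80).
#' @param amplicon_len target amplicon length range in bp (default 80--200);
#'   treated as a soft constraint (see `amplicon_slack`).
#' @param amplicon_slack fractional tolerance outside `amplicon_len` within
#'   which a pair is kept with a warning rather than rejected (default 0.15).
#' @param tm_window maximum Tm spread within a pair, deg C (default 3).
#' @param dimer_score_max maximum tolerated [dimer_score()] (default 12, the
#'   largest score observed among the primers of the published Mal d 1
#'   panel, so the screen accepts exactly the complementarity level that
#'   panel's validation accepted).
#' @param three_prime_anchor_window window (nt from the 3' terminus) in which
#'   a gene-differentiating SNP must sit for a primer to count as anchored
#'   (default 1, i.e. the terminal base).
#' @param five_prime_allele_window window (nt from the 5' terminus) within
#'   which allele-differentiating SNPs are tolerated (default 2).
#' @param ta_range clamp range for the recommended annealing temperature,
#'   deg C (default 61--63).
#' @return a list of class `design_constraints`.
#' @export
design_constraints <- function(primer_len = c(18, 24),
                               gc = c(20, 80),
                               amplicon_len = c(80, 200),
                               amplicon_slack = 0.15,
                               tm_window = 3,
                               dimer_score_max = 12,
                               three_prime_anchor_window = 1,
                               five_prime_allele_window = 2,
                               ta_range = c(61, 63)) {
  stopifnot(length(primer_len) == 2L, primer_len[1] <= primer_len[2],
            length(gc) == 2L, gc[1] <= gc[2],
            length(amplicon_len) == 2L, amplicon_len[1] <= amplicon_len[2],
            three_prime_anchor_window >= 1, five_prime_allele_window >= 1)
  structure(list(primer_len = as.integer(primer_len), gc = gc,
                 amplicon_len = amplicon_len, amplicon_slack = amplicon_slack,
                 tm_window = tm_window, dimer_score_max = dimer_score_max,
                 three_prime_anchor_window = as.integer(three_prime_anchor_window),
                 five_prime_allele_window = as.integer(five_prime_allele_window),
                 ta_range = ta_range),
            class = "design_constraints")
}

#' Enumerate gene-specific primer candidates
#'
#' Slides every window of the allowed lengths over the target gene's
#' reference cds, on both strands, and keeps windows that (i) contain only
#' unambiguous ACGT template bases, (ii) satisfy the GC constraint and
#' (iii) carry no allele-differentiating SNP outside the 5'-terminal
#' tolerance window.  A candidate is *anchored* when a gene-differentiating
#' SNP lies within `three_prime_anchor_window` nt of its 3' terminus --
#' anchoring is what gives a primer its mismatch discrimination against
#' non-target paralogs.
#'
#' When the target gene has no gene-differentiating site at all, an empty
#' candidate set is returned with attribute `undesignable` explaining why
#' (this is a report, not an error).
#'
#' @param fam an aligned gene-family tibble.
#' @param target_gene gene to design for.
#' @param constraints a [design_constraints()] object.
#' @param sites,consensus optional precomputed [discover_snps()] /
#'   [consensus_sequence()] results (recomputed when `NULL`).
#' @return a tibble of candidates: `sequence`, `strand`, `start`, `length`
#'   (footprint on the reference cds), `gc`, `tm`, `snp_cons`, `snp_gene`,
#'   `snp_allele`, `anchored`; attributes `template`, `target_gene`,
#'   `reference_record`.
#' @export
enumerate_candidates <- function(fam, target_gene, constraints = design_constraints(),
                                 sites = NULL, consensus = NULL) {
  rid <- reference_record_id(fam, target_gene)
  aln <- seq_chars(fam$seq[match(rid, fam$record_id)])
  nongap <- aln != "-"
  template_ch <- aln[nongap]
  template <- paste0(template_ch, collapse = "")
  L <- length(template_ch)
  single_gene <- length(unique(fam$gene_id)) == 1L
  sites <- sites %||% (if (single_gene && nrow(fam) < 2L) NULL else discover_snps(fam))
  consensus <- consensus %||% consensus_sequence(fam)

  # per-template-position flags
  col_of_pos <- which(nongap)                      # aligned column of each template position
  gene_flag <- allele_flag <- cons_flag <- rep(FALSE, L)
  if (!is.null(sites) && nrow(sites) > 0L) {
    idx <- match(sites$column, col_of_pos)        # template position of each site (NA if ref gapped)
    hit <- !is.na(idx)
    gene_flag[idx[hit]] <- vapply(sites$gene_diff[hit], function(g) target_gene %in% g, logical(1))
    allele_flag[idx[hit]] <- vapply(sites$allele_diff[hit], function(g) target_gene %in% g, logical(1))
  }
  cons_ch <- seq_chars(consensus)[col_of_pos]
  cons_flag <- template_ch != cons_ch
  ok_base <- template_ch %in% DNA_BASES

  empty <- tibble(sequence = character(0), strand = character(0),
                  start = integer(0), length = integer(0), gc = numeric(0),
                  tm = numeric(0), snp_cons = integer(0), snp_gene = integer(0),
                  snp_allele = integer(0), anchored = logical(0))
  attr(empty, "template") <- template
  attr(empty, "target_gene") <- target_gene
  attr(empty, "reference_record") <- rid
  if (!single_gene && !any(gene_flag)) {
    attr(empty, "undesignable") <- "no gene-differentiating SNP for target gene"
    return(empty)
  }

  csum <- function(flag) c(0, cumsum(as.numeric(flag)))
  cg <- csum(gene_flag); ca <- csum(allele_flag); cc <- csum(cons_flag)
  cb <- csum(ok_base); cgc <- csum(template_ch %in% c("G", "C"))
  # dinucleotide cumulative dH/dS for vectorised NN Tm (reverse-complement
  # windows form the same duplex, so forward sums apply to both strands)
  dinuc <- paste0(template_ch[-L], template_ch[-1L])
  dHv <- NN_DH[dinuc]; dSv <- NN_DS[dinuc]
  dHv[is.na(dHv)] <- 0; dSv[is.na(dSv)] <- 0   # windows spanning ambiguous bases are dropped anyway
  cH <- c(0, cumsum(dHv)); cS <- c(0, cumsum(dSv))

  aw <- constraints$three_prime_anchor_window
  w5 <- constraints$five_prime_allele_window
  chunks <- list()
  for (len in seq.int(constraints$primer_len[1], constraints$primer_len[2])) {
    if (len > L) next
    start <- seq_len(L - len + 1L)
    end <- start + len - 1L
    valid <- (cb[end + 1L] - cb[start]) == len
    gcp <- 100 * (cgc[end + 1L] - cgc[start]) / len
    gc_ok <- gcp >= constraints$gc[1] & gcp <= constraints$gc[2]
    n_gene <- cg[end + 1L] - cg[start]
    n_allele <- ca[end + 1L] - ca[start]
    n_cons <- cc[end + 1L] - cc[start]
    # forward: 5' at start; allele SNPs allowed only in start..start+w5-1
    allele_out_f <- (ca[end + 1L] - ca[pmin(start + w5, end + 1L)]) > 0
    # reverse: 5' at end; allele SNPs allowed only in end-w5+1..end
    allele_out_r <- (ca[pmax(end - w5 + 1L, start)] - ca[start]) > 0
    anch_f <- (cg[end + 1L] - cg[pmax(end - aw + 1L, start)]) > 0
    anch_r <- (cg[pmin(start + aw, end + 1L)] - cg[start]) > 0
    # NN Tm (shared by both strands)
    dH <- cH[end] - cH[start]
    dS <- cS[end] - cS[start]
    for (side in list(start, end)) {
      isgc <- template_ch[side] %in% c("G", "C")
      dH <- dH + ifelse(isgc, INIT_DH[["GC"]], INIT_DH[["AT"]])
      dS <- dS + ifelse(isgc, INIT_DS[["GC"]], INIT_DS[["AT"]])
    }
    dS_salt <- dS + 0.368 * (len - 1L) * log(50 / 1000)
    tm <- dH * 1000 / (dS_salt + GAS_R * log(250e-9 / 4)) - 273.15
    keep_f <- valid & gc_ok & !allele_out_f
    keep_r <- valid & gc_ok & !allele_out_r
    if (any(keep_f)) {
      chunks[[length(chunks) + 1L]] <- tibble(
        strand = "forward", start = start[keep_f], length = len,
        gc = gcp[keep_f], tm = tm[keep_f],
        snp_cons = as.integer(n_cons[keep_f]), snp_gene = as.integer(n_gene[keep_f]),
        snp_allele = as.integer(n_allele[keep_f]), anchored = anch_f[keep_f])
    }
    if (any(keep_r)) {
      chunks[[length(chunks) + 1L]] <- tibble(
        strand = "reverse", start = start[keep_r], length = len,
        gc = gcp[keep_r], tm = tm[keep_r],
        snp_cons = as.integer(n_cons[keep_r]), snp_gene = as.integer(n_gene[keep_r]),
        snp_allele = as.integer(n_allele[keep_r]), anchored = anch_r[keep_r])
    }
  }
  if (length(chunks) == 0L) {
    attr(empty, "undesignable") <- "no window satisfies the length/GC/allele-SNP constraints"
    return(empty)
  }
  cand <- bind_rows(chunks)
  slice <- substring(template, cand$start, cand$start + cand$length - 1L)
  cand$sequence <- ifelse(cand$strand == "forward", slice, revcomp(slice))
  cand <- cand[, c("sequence", "strand", "start", "length", "gc", "tm",
                   "snp_cons", "snp_gene", "snp_allele", "anchored")]
  attr(cand, "template") <- template
  attr(cand, "target_gene") <- target_gene
  attr(cand, "reference_record") <- rid
  cand
}

#' Pair primer candidates
#'
#' Builds forward/reverse pairs that satisfy the pairing rules: amplicon
#' length within the (soft) constraint range, at least one primer anchored
#' on a gene-differentiating SNP, allele-SNP-bearing primers in at most one
#' of the two positions, Tm spread within `tm_window`, and homo-/hetero-dimer
#' scores at most `dimer_score_max`.  Pairs are ranked lexicographically:
#' total allele-SNP count ascending, total gene-SNP count descending, Tm
#' difference ascending, amplicon length ascending, then forward position.
#' Dimer screening is applied to the top `shortlist` pairs after the cheap
#' filters, so the returned list is the fully validated head of the ranking.
#'
#' @param candidates output of [enumerate_candidates()].
#' @param constraints a [design_constraints()] object.
#' @param shortlist number of top-ranked pairs carried into dimer screening.
#' @param require_anchor require at least one anchored primer per pair
#'   (disabled automatically for single-gene families by [design_panel()]).
#' @return a tibble of ranked pairs with primer sequences, footprints, Tm,
#'   SNP counts, dimer scores, recommended `ta` and predicted `tm_amplicon`;
#'   attribute `rejections` tallies per-constraint rejection counts.  An
#'   empty tibble (with the tallies) means no valid pair.
#' @export
pair_primers <- function(candidates, constraints = design_constraints(),
                         shortlist = 200L, require_anchor = TRUE) {
  template <- attr(candidates, "template")
  empty_pairs <- tibble(seq_f = character(0), seq_r = character(0),
                        start = integer(0), amplicon_length = integer(0))
  fwd <- filter(candidates, .data$strand == "forward")
  rev_ <- filter(candidates, .data$strand == "reverse")
  rej <- c(no_candidates = 0, amplicon_length = 0, overlap = 0,
           allele_rule = 0, anchor_rule = 0, tm_spread = 0, dimer = 0)
  if (nrow(fwd) == 0L || nrow(rev_) == 0L) {
    rej["no_candidates"] <- 1
    attr(empty_pairs, "rejections") <- rej
    return(empty_pairs)
  }
  nf <- nrow(fwd); nr <- nrow(rev_)
  if (require_anchor) {
    fi_a <- which(fwd$anchored); ri_a <- which(rev_$anchored)
    fi <- c(rep(fi_a, each = nr), rep(seq_len(nf), times = length(ri_a)))
    ri <- c(rep(seq_len(nr), times = length(fi_a)), rep(ri_a, each = nf))
    if (length(fi) == 0L) {
      rej["anchor_rule"] <- 1
      attr(empty_pairs, "rejections") <- rej
      return(empty_pairs)
    }
    key <- (fi - 1) * nr + ri
    dedupe <- !duplicated(key)
    fi <- fi[dedupe]; ri <- ri[dedupe]
  } else {
    fi <- rep(seq_len(nf), each = nr)
    ri <- rep(seq_len(nr), times = nf)
  }
  amp <- rev_$start[ri] + rev_$length[ri] - fwd$start[fi]
  lo <- constraints$amplicon_len[1]; hi <- constraints$amplicon_len[2]
  slack <- constraints$amplicon_slack
  f_len <- fwd$length[fi]; r_len <- rev_$length[ri]
  f_tm <- fwd$tm[fi]; r_tm <- rev_$tm[ri]
  f_allele <- fwd$snp_allele[fi]; r_allele <- rev_$snp_allele[ri]
  f_anch <- fwd$anchored[fi]; r_anch <- rev_$anchored[ri]
  hard_ok <- amp >= lo * (1 - slack) & amp <= hi * (1 + slack)
  rej["amplicon_length"] <- sum(!hard_ok)
  ov_ok <- amp > f_len & amp > r_len
  rej["overlap"] <- sum(hard_ok & !ov_ok)
  allele_ok <- (f_allele > 0) + (r_allele > 0) <= 1
  rej["allele_rule"] <- sum(hard_ok & ov_ok & !allele_ok)
  anchor_ok <- if (require_anchor) f_anch | r_anch else rep(TRUE, length(fi))
  rej["anchor_rule"] <- rej["anchor_rule"] + sum(hard_ok & ov_ok & allele_ok & !anchor_ok)
  tm_ok <- abs(f_tm - r_tm) <= constraints$tm_window
  rej["tm_spread"] <- sum(hard_ok & ov_ok & allele_ok & anchor_ok & !tm_ok)
  keep <- which(hard_ok & ov_ok & allele_ok & anchor_ok & tm_ok)
  if (length(keep) == 0L) {
    attr(empty_pairs, "rejections") <- rej
    return(empty_pairs)
  }
  fi <- fi[keep]; ri <- ri[keep]; amp <- amp[keep]
  rank_ord <- order(fwd$snp_allele[fi] + rev_$snp_allele[ri],
                    -(fwd$snp_gene[fi] + rev_$snp_gene[ri]),
                    abs(fwd$tm[fi] - rev_$tm[ri]), amp, fwd$start[fi])
  take <- head(rank_ord, shortlist)
  fi <- fi[take]; ri <- ri[take]; amp <- amp[take]
  f <- fwd[fi, ]; r <- rev_[ri, ]
  out_of_range <- amp < lo | amp > hi
  homo_f <- vapply(f$sequence, function(s) dimer_score(s, s), numeric(1), USE.NAMES = FALSE)
  homo_r <- vapply(r$sequence, function(s) dimer_score(s, s), numeric(1), USE.NAMES = FALSE)
  hetero <- vapply(seq_len(nrow(f)), function(i) dimer_score(f$sequence[i], r$sequence[i]),
                   numeric(1))
  dim_ok <- homo_f <= constraints$dimer_score_max &
    homo_r <= constraints$dimer_score_max & hetero <= constraints$dimer_score_max
  rej["dimer"] <- sum(!dim_ok)
  if (!any(dim_ok)) {
    attr(empty_pairs, "rejections") <- rej
    return(empty_pairs)
  }
  f <- f[dim_ok, ]; r <- r[dim_ok, ]; amp <- amp[dim_ok]
  out_of_range <- out_of_range[dim_ok]
  homo_f <- homo_f[dim_ok]; homo_r <- homo_r[dim_ok]; hetero <- hetero[dim_ok]
  amp_seq <- substring(template, f$start, f$start + amp - 1L)
  pairs <- tibble(
    seq_f = f$sequence, seq_r = r$sequence,
    start = f$start, amplicon_length = as.integer(amp),
    len_f = f$length, len_r = r$length,
    tm_f = f$tm, tm_r = r$tm,
    snp_cons_f = f$snp_cons, snp_gene_f = f$snp_gene, snp_allele_f = f$snp_allele,
    snp_cons_r = r$snp_cons, snp_gene_r = r$snp_gene, snp_allele_r = r$snp_allele,
    anchored_f = f$anchored, anchored_r = r$anchored,
    homodimer_f = homo_f, homodimer_r = homo_r, heterodimer = hetero,
    ta = pmin(pmax(pmin(f$tm, r$tm) - 2, constraints$ta_range[1]), constraints$ta_range[2]),
    tm_amplicon = amplicon_tm(amp_seq),
    amplicon_out_of_range = out_of_range
  )
  if (any(pairs$amplicon_out_of_range[1])) {
    warn(sprintf("best pair amplicon (%d bp) is outside the %d-%d bp range (within slack)",
                 pairs$amplicon_length[1], lo, hi))
  }
  attr(pairs, "rejections") <- rej
  attr(pairs, "target_gene") <- attr(candidates, "target_gene")
  attr(pairs, "template") <- template
  pairs
}

#' Design a gene-specific primer panel for a whole family
#'
#' Runs [enumerate_candidates()] and [pair_primers()] for every gene in the
#' family and keeps the best pair per gene.  Genes for which no valid pair
#' exists are listed in the design report (attribute `report`) with the
#' reason, rather than raising an error.  For a single-gene family there is
#' no paralog to discriminate against: the gene-SNP anchoring requirement is
#' waived with a warning and the report flags `uniqueness_waived`.
#'
#' @param fam an aligned gene-family tibble.
#' @param constraints a [design_constraints()] object.
#' @param primer_conc primer concentration (nM) to record in the panel rows.
#' @param shortlist passed to [pair_primers()].
#' @return a primer-panel tibble (one row per designable gene, columns as in
#'   [read_primer_panel()]) with attribute `report`.
#' @export
design_panel <- function(fam, constraints = design_constraints(),
                         primer_conc = 100, shortlist = 50L) {
  genes <- unique(fam$gene_id)
  if (length(genes) == 0L || nrow(fam) == 0L) {
    abort("empty family", class = "isoprime_value_error")
  }
  single_gene <- length(genes) == 1L
  if (single_gene) warn("single-gene family: gene-specificity requirement waived")
  sites <- if (nrow(fam) >= 2L) discover_snps(fam) else NULL
  consensus <- consensus_sequence(fam)
  rows <- list(); report <- list()
  for (g in genes) {
    cand <- enumerate_candidates(fam, g, constraints, sites = sites, consensus = consensus)
    if (nrow(cand) == 0L) {
      report[[g]] <- tibble(gene_id = g, status = "undesignable",
                            reason = attr(cand, "undesignable") %||% "no candidates")
      next
    }
    pairs <- pair_primers(cand, constraints, shortlist = shortlist,
                          require_anchor = !single_gene)
    if (nrow(pairs) == 0L) {
      rej <- attr(pairs, "rejections")
      top <- names(rej)[which.max(rej)]
      report[[g]] <- tibble(gene_id = g, status = "undesignable",
                            reason = paste0("no valid pair (main filter: ", top, ")"))
      next
    }
    best <- pairs[1L, ]
    rows[[g]] <- tibble(
      gene_id = g,
      primer_name_f = paste0("q", g, "F"), seq_f = best$seq_f,
      snp_cons_f = best$snp_cons_f, snp_gene_f = best$snp_gene_f,
      snp_allele_f = best$snp_allele_f,
      primer_name_r = paste0("q", g, "R"), seq_r = best$seq_r,
      snp_cons_r = best$snp_cons_r, snp_gene_r = best$snp_gene_r,
      snp_allele_r = best$snp_allele_r,
      start = best$start, amplicon_length = best$amplicon_length,
      primer_conc = primer_conc, ta = best$ta,
      tm_amplicon = best$tm_amplicon, dct_slope = NA_real_)
    report[[g]] <- tibble(gene_id = g,
                          status = if (single_gene) "designed_uniqueness_waived" else "designed",
                          reason = NA_character_)
  }
  panel <- bind_rows(rows)
  attr(panel, "report") <- bind_rows(report)
  panel
}

#' Check a primer panel against the pairing rules
#'
#' Validates the annotation-level pairing rules on an existing panel: at
#' least one primer of each pair carries a gene-differentiating SNP (shared
#' primers across genes are allowed exactly because the partner primer is
#' anchored), and allele-differentiating SNPs occur in at most one primer of
#' a pair.
#'
#' @param panel a primer-panel tibble.
#' @return a tibble with `gene_id`, `anchored_ok`, `allele_ok`, `pass`.
#' @export
validate_pair_rules <- function(panel) {
  tibble(gene_id = panel$gene_id,
         anchored_ok = panel$snp_gene_f > 0 | panel$snp_gene_r > 0,
         allele_ok = (panel$snp_allele_f > 0) + (panel$snp_allele_r > 0) <= 1) |>
    mutate(pass = .data$anchored_ok & .data$allele_ok)
}
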