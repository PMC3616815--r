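# insilico_pcr: binding-site search, amplicon prediction, specificity, melt QC

#' Find primer binding sites on a template
#'
#' Scans both strands of the template at every offset and counts mismatches
#' against the primer.  Sites with at most `max_mm + 1` total mismatches are
#' reported (near-misses are kept for reporting); a site is *productive* --
#' expected to prime -- when it has at most `max_mm` total mismatches and
#' none at all within the 3'-terminal window.  That 3' rule is the
#' computational analogue of SNP-anchored discrimination: a single
#' 3'-terminal mismatch kills extension.
#'
#' Ambiguous (non-ACGT) characters never match.  Reverse-strand sites are
#' reported in forward-strand coordinates, 1-based inclusive; for a `"-"`
#' site the primer's 3' end sits at `start`.
#'
#' @param primer primer sequence, 5'->3', at least 10 nt.
#' @param template template sequence (forward strand).
#' @param max_mm maximum total mismatches for a productive site (default 2).
#' @param three_prime_window length of the 3'-terminal zero-mismatch window
#'   (default 4).
#' @return a tibble: `strand`, `start`, `end`, `mismatches`,
#'   `mm_three_prime`, `productive`.  Empty when the template is shorter
#'   than the primer.
#' @export
find_sites <- function(primer, template, max_mm = 2, three_prime_window = 4) {
  pch <- seq_chars(primer)
  tch <- seq_chars(template)
  Lp <- length(pch); Lt <- length(tch)
  if (Lp < 10L) abort("primer must be at least 10 nt", class = "isoprime_value_error")
  empty <- tibble(strand = character(0), start = integer(0), end = integer(0),
                  mismatches = integer(0), mm_three_prime = integer(0),
                  productive = logical(0))
  if (Lt < Lp) return(empty)
  noff <- Lt - Lp + 1L
  scan <- function(qch, three_prime_at) {
    mmtot <- integer(noff); mm3 <- integer(noff)
    w_idx <- if (three_prime_at == "end") {
      seq.int(max(1L, Lp - three_prime_window + 1L), Lp)
    } else {
      seq_len(min(three_prime_window, Lp))
    }
    for (p in seq_len(Lp)) {
      tslice <- tch[seq.int(p, p + noff - 1L)]
      mm <- !(qch[p] == tslice & qch[p] %in% DNA_BASES)
      mmtot <- mmtot + mm
      if (p %in% w_idx) mm3 <- mm3 + mm
    }
    tibble(start = seq_len(noff), mismatches = mmtot, mm_three_prime = mm3)
  }
  plus <- scan(pch, "end")
  plus$strand <- "+"
  minus <- scan(seq_chars(revcomp(primer)), "start")
  minus$strand <- "-"
  out <- bind_rows(plus, minus)
  out$end <- out$start + Lp - 1L
  out <- filter(out, .data$mismatches <= max_mm + 1)
  out$productive <- out$mismatches <= max_mm & out$mm_three_prime == 0L
  out[, c("strand", "start", "end", "mismatches", "mm_three_prime", "productive")]
}

#' Predict PCR amplicons for a primer pair
#'
#' One amplicon is predicted per convergent combination of a productive
#' forward-strand site of one primer and a productive reverse-strand site of
#' the other, with product length at most `length_cap`.  Both role
#' assignments are scanned (either primer may bind either strand).
#'
#' @param seq_f,seq_r the two primer sequences, 5'->3'.
#' @param templates a gene-family tibble, or a named character vector of
#'   template sequences.
#' @param max_mm,three_prime_window passed to [find_sites()].
#' @param length_cap maximum product length in bp (default 1500).
#' @return a tibble: `record_id`, `start`, `length`, `sequence`, `tm`
#'   (predicted product melting temperature).  Empty = no amplification.
#' @export
predict_amplicons <- function(seq_f, seq_r, templates, max_mm = 2,
                              three_prime_window = 4, length_cap = 1500) {
  tpl <- as_template_table(templates)
  out <- map_dfr(seq_len(nrow(tpl)), function(i) {
    tmpl <- tpl$seq[i]
    sf <- find_sites(seq_f, tmpl, max_mm, three_prime_window)
    sr <- find_sites(seq_r, tmpl, max_mm, three_prime_window)
    combos <- bind_rows(
      convergent_products(filter(sf, .data$strand == "+", .data$productive),
                          filter(sr, .data$strand == "-", .data$productive),
                          length_cap),
      convergent_products(filter(sr, .data$strand == "+", .data$productive),
                          filter(sf, .data$strand == "-", .data$productive),
                          length_cap)
    )
    if (nrow(combos) == 0L) return(NULL)
    combos <- distinct(combos, .data$start, .data$length)
    combos$record_id <- tpl$record_id[i]
    combos$sequence <- substring(tmpl, combos$start, combos$start + combos$length - 1L)
    combos$tm <- amplicon_tm(combos$sequence)
    combos[, c("record_id", "start", "length", "sequence", "tm")]
  })
  out
}

as_template_table <- function(templates) {
  if (is.data.frame(templates)) {
    if (nrow(templates) == 0L) abort("empty template family", class = "isoprime_value_error")
    tibble(record_id = templates$record_id,
           gene_id = if ("gene_id" %in% names(templates)) templates$gene_id else templates$record_id,
           seq = gsub("-", "", templates$seq, fixed = TRUE))
  } else {
    if (length(templates) == 0L) abort("empty template set", class = "isoprime_value_error")
    nm <- names(templates) %||% paste0("t", seq_along(templates))
    tibble(record_id = nm, gene_id = nm, seq = gsub("-", "", unname(templates), fixed = TRUE))
  }
}

convergent_products <- function(plus_sites, minus_sites, length_cap) {
  if (nrow(plus_sites) == 0L || nrow(minus_sites) == 0L) {
    return(tibble(start = integer(0), length = integer(0)))
  }
  g <- expand.grid(p = seq_len(nrow(plus_sites)), m = seq_len(nrow(minus_sites)))
  st <- plus_sites$start[g$p]
  en <- minus_sites$end[g$m]
  len <- en - st + 1L
  lp <- plus_sites$end[g$p] - plus_sites$start[g$p] + 1L
  lm <- minus_sites$end[g$m] - minus_sites$start[g$m] + 1L
  keep <- len > lp & len > lm & len <= length_cap
  tibble(start = as.integer(st[keep]), length = as.integer(len[keep]))
}

#' Specificity report for a primer pair against a family
#'
#' Predicts amplification on every record of the family and renders a
#' verdict: `"specific"` when every allele of the target gene yields at
#' least one productive amplicon and no record of any other gene does;
#' `"cross-reactive"` when an off-target record amplifies; `"incomplete"`
#' when some target allele fails to amplify.  When a single primer has a
#' productive site on a non-target record but the pair does not co-amplify
#' it (the shared-primer situation), a note lists those records.
#'
#' @param seq_f,seq_r primer sequences.
#' @param fam a gene-family tibble (the templates).
#' @param target_gene the gene the pair is meant to amplify.
#' @inheritParams predict_amplicons
#' @return a one-row tibble: `gene_id`, `verdict`, `n_target_alleles`,
#'   `n_target_amplified`, `n_offtarget_amplified`, `shared_primer_note`;
#'   attribute `detail` holds the per-record amplification matrix.
#' @export
specificity_report <- function(seq_f, seq_r, fam, target_gene, max_mm = 2,
                               three_prime_window = 4, length_cap = 1500) {
  tpl <- as_template_table(fam)
  if (!target_gene %in% tpl$gene_id) {
    abort(paste0("target gene not in family: ", target_gene), class = "isoprime_value_error")
  }
  amps <- predict_amplicons(seq_f, seq_r, fam, max_mm, three_prime_window, length_cap)
  n_amp <- vapply(tpl$record_id, function(r) sum(amps$record_id == r), integer(1))
  detail <- tibble(record_id = tpl$record_id, gene_id = tpl$gene_id,
                   n_amplicons = unname(n_amp), amplified = unname(n_amp) > 0L)
  is_target <- detail$gene_id == target_gene
  n_target <- sum(is_target)
  n_target_amp <- sum(detail$amplified[is_target])
  n_off <- sum(detail$amplified[!is_target])
  verdict <- if (n_off > 0L) "cross-reactive"
  else if (n_target_amp == n_target) "specific"
  else "incomplete"
  # shared-primer note: single primer binds an off-target but pair does not co-amplify
  shared <- character(0)
  for (i in which(!is_target & !detail$amplified)) {
    tmpl <- tpl$seq[i]
    hit <- any(find_sites(seq_f, tmpl, max_mm, three_prime_window)$productive) ||
      any(find_sites(seq_r, tmpl, max_mm, three_prime_window)$productive)
    if (hit) shared <- c(shared, tpl$record_id[i])
  }
  note <- if (length(shared)) {
    paste0("single-primer match without co-amplification on: ",
           paste(shared, collapse = ","))
  } else {
    NA_character_
  }
  out <- tibble(gene_id = target_gene, verdict = verdict,
                n_target_alleles = n_target, n_target_amplified = n_target_amp,
                n_offtarget_amplified = n_off, shared_primer_note = note)
  attr(out, "detail") <- detail
  out
}

#' Specificity screen for a whole panel
#'
#' @param panel a primer-panel tibble.
#' @param fam a gene-family tibble.
#' @inheritParams specificity_report
#' @return a tibble with one verdict row per panel row.
#' @export
panel_specificity <- function(panel, fam, max_mm = 2, three_prime_window = 4,
                              length_cap = 1500) {
  map_dfr(seq_len(nrow(panel)), function(i) {
    specificity_report(panel$seq_f[i], panel$seq_r[i], fam, panel$gene_id[i],
                       max_mm, three_prime_window, length_cap)
  })
}

#' Predicted melting temperature of a PCR product
#'
#' Empirical product-melt estimate
#' `Tm = 81.5 + 0.41 %GC - 675 / length + 16.6 log10(monovalent molarity)`.
#' A heuristic for melt-curve interpretation, not a thermodynamic model.
#'
#' @param sequence amplicon sequence(s); alternatively give `gc` and
#'   `length` directly.
#' @param gc percent GC (used when `sequence` is `NULL`).
#' @param length product length in bp (used when `sequence` is `NULL`).
#' @param monovalent_mM monovalent cation concentration in mM (default 50).
#' @return predicted Tm in degrees Celsius.
#' @export
amplicon_tm <- function(sequence = NULL, gc = NULL, length = NULL, monovalent_mM = 50) {
  if (!is.null(sequence)) {
    gc <- gc_content(sequence)
    length <- nchar(sequence)
  }
  81.5 + 0.41 * gc - 675 / length + 16.6 * log10(monovalent_mM / 1000)
}

# ---- melt-curve QC ----------------------------------------------------------

#' Detect peaks in a melt curve
#'
#' Smooths the fluorescence trace with a centred moving average, takes the
#' negative first derivative `-dF/dT` by central differences, and reports
#' local maxima with prominence at least `min_prominence`.
#'
#' @param curve a data frame with ascending `temperature` (deg C) and
#'   `fluorescence` columns, at least 5 points.
#' @param smoothing_window moving-average window in points (default 3).
#' @param min_prominence minimum peak prominence; default 5 % of the
#'   derivative maximum.
#' @return a tibble of peaks sorted by temperature: `temperature`, `height`,
#'   `prominence`.
#' @export
melt_peaks <- function(curve, smoothing_window = 3, min_prominence = NULL) {
  tt <- curve$temperature
  ff <- curve$fluorescence
  if (length(tt) < 5L) abort("melt curve needs at least 5 grid points",
                             class = "isoprime_value_error")
  if (any(diff(tt) <= 0)) abort("temperature grid must be strictly ascending",
                                class = "isoprime_value_error")
  fs <- moving_average(ff, smoothing_window)
  n <- length(tt)
  inner <- 2:(n - 1L)
  deriv <- -(fs[inner + 1L] - fs[inner - 1L]) / (tt[inner + 1L] - tt[inner - 1L])
  dT <- tt[inner]
  if (is.null(min_prominence)) {
    mx <- max(deriv)
    min_prominence <- if (mx > 0) 0.05 * mx else Inf
  }
  m <- length(deriv)
  is_peak <- which(vapply(seq_len(m), function(i) {
    (i == 1L || deriv[i] > deriv[i - 1L]) && (i == m || deriv[i] >= deriv[i + 1L]) &&
      i > 1L && i < m
  }, logical(1)))
  if (length(is_peak) == 0L) {
    return(tibble(temperature = numeric(0), height = numeric(0), prominence = numeric(0)))
  }
  prom <- vapply(is_peak, function(i) {
    h <- deriv[i]
    base_side <- function(idxs) {
      lo <- h
      for (j in idxs) {
        if (deriv[j] > h) break
        lo <- min(lo, deriv[j])
      }
      lo
    }
    left <- base_side(rev(seq_len(i - 1L)))
    right <- base_side(seq.int(i + 1L, m))
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence
  out <- tibble(temperature = dT[is_peak][keep], height = deriv[is_peak][keep],
                prominence = prom[keep])
  arrange(out, .data$temperature)
}

#' Single-peak melt-curve QC
#'
#' A dissociation curve passes QC when its `-dF/dT` trace has exactly one
#' peak: a single homogeneous PCR product, no nonspecific amplification or
#' primer dimers.
#'
#' @inheritParams melt_peaks
#' @return a one-row tibble: `pass` (logical), `n_peaks`, `peak_tm` (the
#'   single peak position, `NA` otherwise).
#' @export
single_peak_qc <- function(curve, smoothing_window = 3, min_prominence = NULL) {
  pk <- melt_peaks(curve, smoothing_window, min_prominence)
  tibble(pass = nrow(pk) == 1L,
         n_peaks = nrow(pk),
         peak_tm = if (nrow(pk) == 1L) pk$temperature[1] else NA_real_)
}

#' @importFrom dplyr arrange
NULL
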