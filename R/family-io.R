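# family_io: labelled gene-family sequences, panels, Ct tables, trees

#' Read a labelled gene-family FASTA
#'
#' Reads a multi-FASTA of gene-family sequences whose headers carry the gene
#' and allele labels.  The default header scheme is
#' `geneID|alleleID|recordID` with the third field optional; pass another
#' `label_pattern` (a regex with 2--3 capture groups) for other schemes.
#'
#' @param path path to a FASTA file.
#' @param label_pattern regular expression with capture groups
#'   `(gene)(allele)(record)`; the third group is optional.
#' @param molecule one of `"cds"`, `"gdna"`, `"protein"`.
#' @param aligned force aligned (`TRUE`, gaps kept) or unaligned (`FALSE`,
#'   gaps stripped) interpretation; default `NULL` auto-detects: records of
#'   equal length are treated as aligned.
#' @return a tibble with columns `record_id`, `gene_id`, `allele_id`,
#'   `molecule`, `seq`; one row per sequence record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1|a1", "ACGTACGT", ">g2|a1", "ACGAACGT"), fa)
#' read_fasta_family(fa)
read_fasta_family <- function(path,
                              label_pattern = "^([^|]+)\\|([^|]+)(?:\\|(.+))?$",
                              molecule = c("cds", "gdna", "protein"),
                              aligned = NULL) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "isoprime_io_error")
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA: ", conditionMessage(e)),
                              class = "isoprime_format_error")
  )
  if (length(seqs) == 0L) abort("no records in FASTA stream", class = "isoprime_format_error")
  headers <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(headers, regexec(label_pattern, headers))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    abort(paste0("FASTA header not parseable under label scheme: ", headers[bad][1]),
          class = "isoprime_format_error")
  }
  gene <- vapply(m, `[`, character(1), 2L)
  allele <- vapply(m, `[`, character(1), 3L)
  rec <- vapply(m, function(g) if (length(g) >= 4L && nzchar(g[4L])) g[4L] else NA_character_,
                character(1))
  rec <- ifelse(is.na(rec), paste(gene, allele, sep = "_"), rec)
  residues <- toupper(as.character(seqs))
  if (is.null(aligned)) {
    aligned <- length(unique(nchar(residues))) == 1L && length(residues) > 1L
  }
  if (!aligned) residues <- gsub("-", "", residues, fixed = TRUE)
  fam <- tibble(record_id = rec, gene_id = gene, allele_id = allele,
                molecule = molecule, seq = unname(residues))
  validate_family(fam, aligned = aligned)
  fam
}

#' Validate a gene-family tibble
#'
#' Checks the family invariants: non-empty residues, a molecule-appropriate
#' alphabet, and uniqueness of `(gene_id, allele_id, record_id)`.
#'
#' @param fam a gene-family tibble (see [read_fasta_family()]).
#' @param aligned if `TRUE`, additionally require equal sequence lengths;
#'   gaps (`-`) are only legal in aligned families.
#' @return `fam`, invisibly.
#' @export
validate_family <- function(fam, aligned = is_aligned(fam)) {
  req <- c("record_id", "gene_id", "allele_id", "seq")
  miss <- setdiff(req, names(fam))
  if (length(miss)) abort(paste0("missing family columns: ", paste(miss, collapse = ", ")),
                          class = "isoprime_schema_error")
  if (nrow(fam) == 0L) abort("no records", class = "isoprime_format_error")
  if (any(!nzchar(fam$seq))) abort("empty residue strings", class = "isoprime_format_error")
  mol <- if ("molecule" %in% names(fam)) fam$molecule else rep("cds", nrow(fam))
  alpha_ok <- vapply(seq_len(nrow(fam)), function(i) {
    ch <- unique(seq_chars(fam$seq[i]))
    allowed <- if (mol[i] == "protein") c(AA_ALPHABET, "-") else c(DNA_ALPHABET, "-")
    all(ch %in% allowed)
  }, logical(1))
  if (any(!alpha_ok)) {
    abort(paste0("invalid residues in record ", fam$record_id[!alpha_ok][1]),
          class = "isoprime_format_error")
  }
  key <- paste(fam$gene_id, fam$allele_id, fam$record_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (gene_id, allele_id, record_id) in family",
          class = "isoprime_uniqueness_error")
  }
  if (aligned && length(unique(nchar(fam$seq))) != 1L) {
    abort("aligned family has unequal sequence lengths", class = "isoprime_format_error")
  }
  if (!aligned && any(grepl("-", fam$seq, fixed = TRUE))) {
    abort("gaps are only allowed in aligned families", class = "isoprime_format_error")
  }
  invisible(fam)
}

#' Is the family aligned?
#'
#' A family counts as aligned when all records have the same length.
#' @param fam a gene-family tibble.
#' @return logical scalar.
#' @export
is_aligned <- function(fam) {
  nrow(fam) > 0L && length(unique(nchar(fam$seq))) == 1L
}

#' Write a gene family to FASTA
#'
#' Headers are written as `geneID|alleleID|recordID`, so
#' `read_fasta_family(write_fasta_family(fam, f))` round-trips.
#'
#' @param fam a gene-family tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_family <- function(fam, path) {
  validate_family(fam, aligned = is_aligned(fam) && any(grepl("-", fam$seq, fixed = TRUE)))
  headers <- sprintf("%s|%s|%s", fam$gene_id, fam$allele_id, fam$record_id)
  x <- Biostrings::BStringSet(setNames(fam$seq, headers))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Reference record of a gene
#'
#' The design-template allele for a gene: the one named in the family's
#' `reference` attribute (a named character map `gene_id -> record_id`), or
#' the gene's first record.
#'
#' @param fam a gene-family tibble.
#' @param gene_id a gene identifier.
#' @return the `record_id` of the reference allele.
#' @export
reference_record_id <- function(fam, gene_id) {
  ref <- attr(fam, "reference")
  if (!is.null(ref) && gene_id %in% names(ref)) {
    rid <- ref[[gene_id]]
    if (!rid %in% fam$record_id) abort("reference map points to a missing record",
                                       class = "isoprime_value_error")
    return(rid)
  }
  rows <- fam$record_id[fam$gene_id == gene_id]
  if (length(rows) == 0L) abort(paste0("gene not in family: ", gene_id),
                                class = "isoprime_value_error")
  rows[1L]
}

# ---- coordinate maps --------------------------------------------------------

#' Alignment coordinate map
#'
#' For every record of an aligned family, the map between aligned columns and
#' 1-based ungapped positions.  Gap columns have `position = NA`.
#'
#' @param fam an aligned gene-family tibble.
#' @return a tibble with columns `record_id`, `column`, `position`, `residue`.
#' @export
alignment_map <- function(fam) {
  if (!is_aligned(fam)) abort("family is not aligned", class = "isoprime_format_error")
  map_dfr(seq_len(nrow(fam)), function(i) {
    ch <- seq_chars(fam$seq[i])
    nongap <- ch != "-"
    pos <- cumsum(nongap)
    pos[!nongap] <- NA_integer_
    tibble(record_id = fam$record_id[i], column = seq_along(ch),
           position = as.integer(pos), residue = ch)
  })
}

#' Map ungapped positions to aligned columns
#'
#' @param fam an aligned gene-family tibble.
#' @param record_id a record identifier.
#' @param positions 1-based ungapped positions on that record.
#' @return integer vector of aligned column indices.
#' @export
ungapped_to_aligned <- function(fam, record_id, positions) {
  ch <- seq_chars(fam$seq[match(record_id, fam$record_id)])
  nz <- which(ch != "-")
  if (any(positions < 1L | positions > length(nz))) {
    abort("ungapped position out of bounds", class = "isoprime_bounds_error")
  }
  nz[positions]
}

#' Map aligned columns to ungapped positions
#'
#' @inheritParams ungapped_to_aligned
#' @param columns aligned column indices.
#' @return integer vector of ungapped positions (`NA` at gap columns).
#' @export
aligned_to_ungapped <- function(fam, record_id, columns) {
  ch <- seq_chars(fam$seq[match(record_id, fam$record_id)])
  if (any(columns < 1L | columns > length(ch))) {
    abort("aligned column out of bounds", class = "isoprime_bounds_error")
  }
  pos <- cumsum(ch != "-")
  out <- as.integer(pos[columns])
  out[ch[columns] == "-"] <- NA_integer_
  out
}

# ---- primer panels ----------------------------------------------------------

panel_columns <- c("gene_id", "primer_name_f", "seq_f",
                   "snp_cons_f", "snp_gene_f", "snp_allele_f",
                   "primer_name_r", "seq_r",
                   "snp_cons_r", "snp_gene_r", "snp_allele_r",
                   "start", "amplicon_length", "primer_conc", "ta",
                   "tm_amplicon", "dct_slope")

#' Read a primer-panel table
#'
#' A tab-separated table with one row per primer pair.  Required columns:
#' `gene_id`, `primer_name_f`, `seq_f`, `snp_cons_f`, `snp_gene_f`,
#' `snp_allele_f`, `primer_name_r`, `seq_r`, `snp_cons_r`, `snp_gene_r`,
#' `snp_allele_r`, `start` (1-based position of the forward primer 5' end on
#' the reference cds), `amplicon_length` (bp), `primer_conc` (nM),
#' `ta` (deg C), `tm_amplicon` (deg C), `dct_slope`.
#'
#' @param path path to a TSV file.
#' @return a tibble of primer-pair rows (possibly empty if the stream is
#'   header-only).
#' @export
read_primer_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "isoprime_io_error")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  miss <- setdiff(panel_columns, names(raw))
  if (length(miss)) abort(paste0("primer panel missing columns: ", paste(miss, collapse = ", ")),
                          class = "isoprime_schema_error")
  num_cols <- c("snp_cons_f", "snp_gene_f", "snp_allele_f",
                "snp_cons_r", "snp_gene_r", "snp_allele_r",
                "start", "amplicon_length", "primer_conc", "ta",
                "tm_amplicon", "dct_slope")
  panel <- raw
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(panel[[cc]]))
    bad <- is.na(v) & !is.na(panel[[cc]]) & !panel[[cc]] %in% c("NA", "")
    if (any(bad)) abort(paste0("non-numeric value in column ", cc, ": ", panel[[cc]][bad][1]),
                        class = "isoprime_value_error")
    panel[[cc]] <- v
  }
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  if (nrow(panel) == 0L) return(invisible(panel))
  if (any(!grepl("^[ACGT]+$", panel$seq_f)) || any(!grepl("^[ACGT]+$", panel$seq_r))) {
    abort("primer sequences must be uppercase ACGT", class = "isoprime_value_error")
  }
  cnt <- c("snp_cons_f", "snp_gene_f", "snp_allele_f",
           "snp_cons_r", "snp_gene_r", "snp_allele_r")
  for (cc in cnt) {
    if (any(panel[[cc]] < 0, na.rm = TRUE)) abort("negative SNP count", class = "isoprime_value_error")
  }
  short <- panel$amplicon_length <= pmax(nchar(panel$seq_f), nchar(panel$seq_r))
  if (any(short, na.rm = TRUE)) {
    abort("amplicon_length must exceed each primer length", class = "isoprime_value_error")
  }
  invisible(panel)
}

#' Write a primer-panel table
#'
#' @param panel a primer-panel tibble (see [read_primer_panel()] for columns).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_primer_panel <- function(panel, path) {
  readr::write_tsv(panel[, intersect(c(panel_columns, setdiff(names(panel), panel_columns)),
                                     names(panel))], path, progress = FALSE)
  invisible(path)
}

# ---- Ct tables --------------------------------------------------------------

ct_columns <- c("sample_id", "tissue", "cultivar", "assay_id",
                "replicate_type", "dilution_step", "ct")
replicate_types <- c("technical", "biological", "standard", "ntc")

#' Read a Ct table
#'
#' A CSV of qPCR wells with columns `sample_id`, `tissue`, `cultivar`,
#' `assay_id`, `replicate_type` (one of technical, biological, standard,
#' ntc), `dilution_step` (0-based, standards only) and `ct`.  A `ct` of
#' `"Undetermined"` (no signal within `max_cycle` cycles) is parsed as
#' censored at `max_cycle` and flagged in the logical `censored` column.
#'
#' @param path path to a CSV file.
#' @param max_cycle the instrument's cycle count (default 40).
#' @return a tibble with the columns above plus `censored`.
#' @export
read_ct_table <- function(path, max_cycle = 40) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "isoprime_io_error")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  miss <- setdiff(ct_columns, names(raw))
  if (length(miss)) abort(paste0("Ct table missing columns: ", paste(miss, collapse = ", ")),
                          class = "isoprime_schema_error")
  bad_type <- setdiff(unique(raw$replicate_type), replicate_types)
  if (length(bad_type)) abort(paste0("unknown replicate_type: ", bad_type[1]),
                              class = "isoprime_value_error")
  censored <- grepl("^undetermined$", raw$ct, ignore.case = TRUE)
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- is.na(ct) & !censored & !is.na(raw$ct)
  if (any(bad)) abort(paste0("non-numeric ct value: ", raw$ct[bad][1]),
                      class = "isoprime_value_error")
  ct[censored] <- max_cycle
  tibble(sample_id = raw$sample_id, tissue = raw$tissue, cultivar = raw$cultivar,
         assay_id = raw$assay_id, replicate_type = raw$replicate_type,
         dilution_step = suppressWarnings(as.integer(raw$dilution_step)),
         ct = ct, censored = censored)
}

#' Write a Ct table
#'
#' Censored wells are written back as `"Undetermined"`, so
#' [read_ct_table()] round-trips.
#'
#' @param ct a Ct tibble (see [read_ct_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  out <- ct
  cens <- if ("censored" %in% names(out)) out$censored else rep(FALSE, nrow(out))
  out$ct <- ifelse(cens, "Undetermined", as.character(out$ct))
  out$censored <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# ---- trees ------------------------------------------------------------------

#' Read / write newick trees
#'
#' Thin wrappers around ape with a documented single-leaf dialect: a
#' one-tip tree is written as `"label;"`.
#'
#' @param tree an `ape::phylo` object, or a single leaf label.
#' @param path file path.
#' @return `read_newick()` returns an `ape::phylo` (or a character scalar for
#'   a single-leaf file); `write_newick()` returns `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.character(tree) && length(tree) == 1L) {
    writeLines(paste0(tree, ";"), path)
    return(invisible(path))
  }
  if (!inherits(tree, "phylo")) abort("not a phylo object", class = "isoprime_value_error")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (grepl("^[^();,]+;\\s*$", txt)) {
    return(sub(";\\s*$", "", txt))
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) abort("could not parse newick", class = "isoprime_format_error")
  tr
}
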