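# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")
# IUPAC nucleotide codes (gap handled separately everywhere)
DNA_ALPHABET <- c(DNA_BASES, "U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
AA_ALPHABET <- c(LETTERS, "*")

COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
          R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
          B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-")

#' Reverse complement
#'
#' @param x character vector of nucleotide sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    out <- COMP[ch]
    if (anyNA(out)) abort("sequence contains non-IUPAC characters", class = "isoprime_value_error")
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence string into a character vector
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# records x columns character matrix of an aligned family
aln_matrix <- function(fam) {
  w <- nchar(fam$seq)
  if (length(unique(w)) != 1L) {
    abort("records have unequal aligned lengths", class = "isoprime_format_error")
  }
  m <- do.call(rbind, strsplit(toupper(fam$seq), "", fixed = TRUE))
  rownames(m) <- fam$record_id
  m
}

# centred moving average, partial windows at the edges
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
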