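# phenetics: identities, distances, neighbour joining, subfamily assignment

#' Pairwise percent identity between two aligned records
#'
#' Identity is computed over columns where neither record has a gap
#' (pairwise deletion): `100 * matches / comparable columns`.
#'
#' @param fam an aligned gene-family tibble.
#' @param a,b record identifiers.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(fam, a, b) {
  ia <- match(a, fam$record_id); ib <- match(b, fam$record_id)
  if (is.na(ia) || is.na(ib)) abort("record not in family", class = "isoprime_value_error")
  x <- seq_chars(fam$seq[ia]); y <- seq_chars(fam$seq[ib])
  if (length(x) != length(y)) abort("records have unequal aligned length",
                                    class = "isoprime_format_error")
  comp <- x != "-" & y != "-"
  if (!any(comp)) abort("no comparable columns between records",
                        class = "isoprime_value_error")
  100 * sum(x[comp] == y[comp]) / sum(comp)
}

#' Count substitutions between two aligned records
#'
#' Number of columns where both records are non-gap and the residues differ.
#'
#' @inheritParams pairwise_identity
#' @return a non-negative integer count.
#' @export
substitution_count <- function(fam, a, b) {
  ia <- match(a, fam$record_id); ib <- match(b, fam$record_id)
  if (is.na(ia) || is.na(ib)) abort("record not in family", class = "isoprime_value_error")
  x <- seq_chars(fam$seq[ia]); y <- seq_chars(fam$seq[ib])
  comp <- x != "-" & y != "-"
  if (!any(comp)) abort("no comparable columns between records",
                        class = "isoprime_value_error")
  sum(x[comp] != y[comp])
}

#' Full identity matrix of an aligned family
#'
#' @param fam an aligned gene-family tibble.
#' @return a symmetric matrix of percent identities with `record_id`
#'   dimnames (diagonal 100).
#' @export
identity_matrix <- function(fam) {
  n <- nrow(fam)
  m <- matrix(100, n, n, dimnames = list(fam$record_id, fam$record_id))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- pairwise_identity(fam, fam$record_id[i], fam$record_id[j])
    }
  }
  m
}

#' p-distance matrix of an aligned family
#'
#' `d = 1 - identity/100` per pair, pairwise deletion of gapped columns.
#'
#' @param fam an aligned gene-family tibble.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(fam) {
  1 - identity_matrix(fam) / 100
}

#' Translate a coding sequence
#'
#' Standard genetic code; gaps are removed before translation and the
#' trailing stop codon is trimmed.  An internal stop truncates the
#' translation with a warning (the result carries attribute
#' `truncated = TRUE`).
#'
#' @param cds a single coding sequence (may contain alignment gaps).
#' @return the protein sequence as a character scalar.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(cds) {
  s <- gsub("-", "", toupper(cds), fixed = TRUE)
  if (nchar(s) == 0L || nchar(s) %% 3L != 0L) {
    abort("ungapped cds length not divisible by 3", class = "isoprime_value_error")
  }
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # ambiguous codons
  truncated <- FALSE
  stops <- which(aa == "*")
  if (length(stops)) {
    if (stops[1L] < length(aa)) {
      warn("internal stop codon; translation truncated")
      truncated <- TRUE
    }
    aa <- aa[seq_len(stops[1L] - 1L)]
  }
  out <- paste0(aa, collapse = "")
  attr(out, "truncated") <- truncated
  out
}

#' Translate every record of a cds family
#'
#' @param fam a gene-family tibble of coding sequences.
#' @return the family with `seq` replaced by protein sequences and
#'   `molecule = "protein"`.
#' @export
translate_family <- function(fam) {
  out <- fam
  out$seq <- vapply(fam$seq, function(s) as.character(translate_cds(s)), character(1),
                    USE.NAMES = FALSE)
  if ("molecule" %in% names(out)) out$molecule <- "protein"
  out
}

#' Neighbour-joining tree
#'
#' Saitou--Nei agglomeration with the standard Q-criterion and three-point
#' branch-length formulas.  Ties in the Q minimisation are broken by the
#' lowest index pair, making the result deterministic.  Negative branch
#' length estimates are clamped to zero with a warning.
#'
#' @param d a symmetric distance matrix (or `dist`) with labels; `n >= 3`.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3L) abort("neighbour joining needs at least 3 taxa", class = "isoprime_value_error")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("distance matrix is not symmetric", class = "isoprime_value_error")
  }
  labels <- rownames(m) %||% paste0("t", seq_len(n))
  reps <- labels
  D <- m
  clamped <- FALSE
  cl <- function(x) {
    if (any(x < 0)) clamped <<- TRUE
    pmax(x, 0)
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    k <- nrow(D)
    rs <- rowSums(D)
    Q <- (k - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    li <- cl(li); lj <- cl(lj)
    newrep <- paste0("(", reps[i], ":", fmt(li), ",", reps[j], ":", fmt(lj), ")")
    others <- setdiff(seq_len(k), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- D[others, others, drop = FALSE]
    D2 <- rbind(cbind(D2, newd), c(newd, 0))
    reps <- c(reps[others], newrep)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  # final three-point closed form
  la <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", reps[1], ":", fmt(la), ",", reps[2], ":", fmt(lb),
                ",", reps[3], ":", fmt(lc), ");")
  if (clamped) warn("negative NJ branch length estimate clamped to 0")
  ape::read.tree(text = nwk)
}

#' Assign subfamilies by cutting long branches
#'
#' Cuts the tree's longest branches (longest first, ties by edge index)
#' until the leaves fall into exactly `k` connected groups; each group is a
#' subfamily.  With `k = 1` the whole family is one group; with `k` equal to
#' the number of leaves every leaf is its own subfamily.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param k number of subfamilies, `1 <= k <=` number of leaves.
#' @return a tibble with columns `label` and `subfamily` (integers numbered
#'   in tip order).
#' @export
assign_subfamilies <- function(tree, k) {
  if (!inherits(tree, "phylo")) abort("not a phylo object", class = "isoprime_value_error")
  ntip <- length(tree$tip.label)
  if (k < 1L || k > ntip) abort("k must be between 1 and the leaf count",
                                class = "isoprime_value_error")
  edges <- tree$edge
  wt <- tree$edge.length %||% rep(1, nrow(edges))
  tips <- seq_len(ntip)
  nv <- max(edges)
  ord <- order(-wt, seq_along(wt))
  memb_for <- function(ncut) {
    keep <- setdiff(seq_len(nrow(edges)), ord[seq_len(ncut)])
    g <- igraph::make_graph(t(edges[keep, , drop = FALSE]), n = nv, directed = FALSE)
    igraph::components(g)$membership[tips]
  }
  ncut <- 0L
  memb <- memb_for(0L)
  while (length(unique(memb)) < k && ncut < nrow(edges)) {
    ncut <- ncut + 1L
    memb <- memb_for(ncut)
  }
  # renumber in tip order
  ids <- match(memb, unique(memb))
  tibble(label = tree$tip.label, subfamily = as.integer(ids))
}
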