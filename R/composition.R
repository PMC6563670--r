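## Nucleotide composition at each codon position. GC-type quantities are
## computed over all counted codons (stops included: they are codons of the
## CDS); the synonymous third-position quantities GC3s and A3s/T3s/C3s/G3s
## are computed over the 59 synonymous sense codons only (AUG, UGG and the
## three stop codons excluded).

#' Codon-position composition profile
#'
#' Computes per-position G+C fractions and synonymous third-position base
#' fractions from a codon-count table. All values are fractions in `[0, 1]`;
#' formatting as percentages is left to the report layer.
#'
#' `x3s` (for x in A, U/T, C, G) is the fraction of synonymous sense codons
#' whose third base is x, so `a3s + t3s + c3s + g3s == 1` whenever any
#' synonymous codon was counted and `gc3s == c3s + g3s`. With no synonymous
#' codons (e.g. a gene of only AUG/UGG), these fields are `NA`, never
#' fabricated zeros.
#'
#' @param counts A `codon_counts` object with `n_codons >= 1`.
#' @return A list with `n_codons`, `n_syn` (synonymous codons counted),
#'   `gc`, `gc1`, `gc2`, `gc12`, `gc3`, `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`.
#' @examples
#' composition_profile(count_codons("ATGGCGCTGTAA"))
#' @export
composition_profile <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  v <- counts$counts
  n <- counts$n_codons
  if (n < 1L) stop("composition_profile needs at least one counted codon")
  gc1 <- sum(v[.GC_P$p1]) / n
  gc2 <- sum(v[.GC_P$p2]) / n
  gc3 <- sum(v[.GC_P$p3]) / n

  n_syn <- sum(v[.SYN_MASK])
  if (n_syn > 0L) {
    a3s <- sum(v[.SYN_P3$A]) / n_syn
    t3s <- sum(v[.SYN_P3$U]) / n_syn
    c3s <- sum(v[.SYN_P3$C]) / n_syn
    g3s <- sum(v[.SYN_P3$G]) / n_syn
    gc3s <- c3s + g3s
  } else {
    a3s <- t3s <- c3s <- g3s <- gc3s <- NA_real_
  }

  list(n_codons = n, n_syn = n_syn,
       gc = (gc1 + gc2 + gc3) / 3,
       gc1 = gc1, gc2 = gc2, gc12 = (gc1 + gc2) / 2, gc3 = gc3,
       gc3s = gc3s, a3s = a3s, t3s = t3s, c3s = c3s, g3s = g3s)
}
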