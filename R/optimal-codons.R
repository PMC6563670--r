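## Optimal-codon detection: contrast RSCU between high-bias and low-bias
## gene pools ranked by ENC.

#' Partition genes into high- and low-bias pools by ENC
#'
#' Sorts genes ascending by ENC (ties broken by gene id for determinism) and
#' takes the first `ceiling(fraction * N)` genes as the high-bias pool
#' (lowest ENC, the proxy for highly expressed genes) and the last as the
#' low-bias pool. Genes with undefined ENC are excluded before ranking.
#'
#' @param indices Data frame with `gene_id` and `enc` columns.
#' @param counts_list Named list of per-gene `codon_counts` (defaults to the
#'   counts attached to `indices`).
#' @param fraction Pool fraction in (0, 0.5].
#' @return A `bias_partition` list: `high_genes`, `low_genes` (disjoint id
#'   vectors), `high_pool`, `low_pool` (pooled `codon_counts`), `fraction`,
#'   `n_excluded` (genes dropped for undefined ENC).
#' @export
partition_by_enc <- function(indices, counts_list = attr(indices, "counts"),
                             fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (is.null(counts_list)) stop("no per-gene counts available")
  ok <- is.finite(indices$enc)
  n_excluded <- sum(!ok)
  df <- indices[ok, c("gene_id", "enc")]
  ord <- order(df$enc, df$gene_id)
  n <- nrow(df)
  n_pool <- ceiling(fraction * n)
  if (n < 2L * n_pool) stop("too few ranked genes for disjoint pools")
  high <- df$gene_id[ord[seq_len(n_pool)]]
  low <- df$gene_id[ord[seq.int(n - n_pool + 1L, n)]]
  structure(list(high_genes = high, low_genes = low,
                 high_pool = pool_counts(counts_list[high]),
                 low_pool = pool_counts(counts_list[low]),
                 fraction = fraction, n_excluded = n_excluded),
            class = "bias_partition")
}

#' Detect optimal codons from a high/low bias contrast
#'
#' Computes RSCU separately in the high- and low-bias pools and tests each
#' synonymous sense codon with a 2x2 chi-square of (this codon vs the rest
#' of its family) x (high vs low pool), applying Yates continuity correction
#' whenever any expected cell is below 5. A codon is called optimal when
#' `rscu_high > 1`, `delta_rscu = rscu_high - rscu_low >= delta_threshold`
#' and `p < alpha`. AUG, UGG and stop codons are never optimal. Codons whose
#' family is absent from either pool are flagged untestable.
#'
#' @param partition A `bias_partition` from [partition_by_enc()], or any
#'   list with `high_pool`/`low_pool` `codon_counts`.
#' @param delta_threshold Minimum RSCU difference (default 0.08).
#' @param alpha Significance level (default 0.01).
#' @param test `"chisq"` (default) or `"fisher"` for small fixtures.
#' @return A data frame over the 59 synonymous sense codons: `amino_acid`,
#'   `codon`, `rscu_high`, `n_high`, `rscu_low`, `n_low`, `delta_rscu`,
#'   `chi2` (`NA` under `"fisher"`), `p`, `optimal`, `untestable`.
#' @export
detect_optimal_codons <- function(partition, delta_threshold = 0.08,
                                  alpha = 0.01,
                                  test = c("chisq", "fisher")) {
  test <- match.arg(test)
  high <- partition$high_pool
  low <- partition$low_pool
  stopifnot(inherits(high, "codon_counts"), inherits(low, "codon_counts"))
  if (high$n_codons == 0L || low$n_codons == 0L)
    stop("both pools must be non-empty")
  rs_h <- compute_rscu(high)
  rs_l <- compute_rscu(low)
  keep <- rs_h$codon %in% .SYN_CODONS
  rs_h <- rs_h[keep, ]; rs_l <- rs_l[keep, ]

  fam_tot_h <- ave(as.numeric(rs_h$count), rs_h$aa, FUN = sum)
  fam_tot_l <- ave(as.numeric(rs_l$count), rs_l$aa, FUN = sum)

  n <- nrow(rs_h)
  chi2 <- p <- rep(NA_real_, n)
  untestable <- fam_tot_h == 0 | fam_tot_l == 0
  for (i in seq_len(n)) {
    if (untestable[i]) next
    tab <- matrix(c(rs_h$count[i], fam_tot_h[i] - rs_h$count[i],
                    rs_l$count[i], fam_tot_l[i] - rs_l$count[i]),
                  nrow = 2L)
    if (test == "fisher") {
      p[i] <- stats::fisher.test(tab)$p.value
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      ht <- suppressWarnings(
        stats::chisq.test(tab, correct = any(expected < 5)))
      chi2[i] <- unname(ht$statistic)
      p[i] <- ht$p.value
    }
  }
  delta <- rs_h$rscu - rs_l$rscu
  optimal <- !untestable & !is.na(delta) &
    rs_h$rscu > 1 & delta >= delta_threshold & !is.na(p) & p < alpha
  data.frame(amino_acid = rs_h$amino_acid, codon = rs_h$codon,
             rscu_high = rs_h$rscu, n_high = rs_h$count,
             rscu_low = rs_l$rscu, n_low = rs_l$count,
             delta_rscu = delta, chi2 = chi2, p = p,
             optimal = optimal, untestable = untestable,
             stringsAsFactors = FALSE, row.names = NULL)
}
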