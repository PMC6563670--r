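## Genome-level analyses over per-gene indices: neutrality-plot regression,
## the ENC-GC3s mutational null curve, correspondence analysis of RSCU
## profiles, and the Spearman correlation matrix of indices.

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 (mean G+C at codon positions 1
#' and 2) on GC3. Under pure mutational (neutral) pressure all three
#' positions drift together and the slope approaches 1; under selective
#' constraint on positions 1-2 the slope approaches 0. The slope is read as
#' the percent contribution of mutation pressure (`mutation_pct = 100 *
#' slope`), the remainder as other factors.
#'
#' @param gc12,gc3 Equal-length numeric vectors of per-gene fractions (or
#'   percentages: the fit is scale-consistent); at least 3 genes.
#' @return A `neutrality_fit` list: `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `p_value`, `mutation_pct`, `other_pct`, `n_genes`. With
#'   zero variance in `gc3` the slope is `NA`.
#' @export
neutrality_regression <- function(gc12, gc3) {
  stopifnot(length(gc12) == length(gc3))
  keep <- stats::complete.cases(gc12, gc3)
  gc12 <- gc12[keep]; gc3 <- gc3[keep]
  n <- length(gc3)
  if (n < 3L) stop("neutrality regression needs at least 3 genes")
  if (stats::sd(gc3) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          pearson_r = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_, mutation_pct = NA_real_,
                          other_pct = NA_real_, n_genes = n),
                     class = "neutrality_fit"))
  }
  fit <- stats::lm(gc12 ~ gc3)
  if (stats::sd(gc12) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(gc3, gc12, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  slope <- unname(stats::coef(fit)[2L])
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 pearson_r = r, r_squared = r^2, p_value = p,
                 mutation_pct = 100 * slope,
                 other_pct = 100 * (1 - slope),
                 n_genes = n),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(paste0("neutrality fit (n = %d): slope = %.4f, r = %.4f ",
                     "(p = %.3g)\n  mutation pressure %.2f%%, ",
                     "other factors %.2f%%\n"),
              x$n_genes, x$slope, x$pearson_r, x$p_value,
              x$mutation_pct, x$other_pct))
  invisible(x)
}

#' Expected ENC under mutation alone
#'
#' Wright's null curve for the ENC of a gene whose codon usage is shaped
#' purely by third-position G+C content s:
#' `ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#' Genes lying on the curve are consistent with mutational pressure alone;
#' genes falling below it use fewer codons than their GC3s predicts,
#' indicating additional (e.g. selective) constraint.
#'
#' @param gc3s Numeric vector of GC3s fractions, strictly inside (0, 1).
#' @return Expected ENC values.
#' @examples
#' expected_enc_curve(0.5)  # 60.5
#' @export
expected_enc_curve <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s <= 0) || any(gc3s >= 1))
    stop("gc3s must lie strictly inside (0, 1)")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot data
#'
#' Per-gene observed ENC, expected ENC at the gene's GC3s, and the residual
#' `enc - expected_enc`; `below_curve` flags residual < 0.
#'
#' @param indices Data frame with columns `gene_id`, `gc3s`, `enc` (as from
#'   [compute_gene_indices()]).
#' @return A data frame `gene_id`, `gc3s`, `enc`, `expected_enc`,
#'   `residual`, `below_curve`. Genes with undefined ENC or GC3s outside
#'   (0, 1) get `NA` expectation.
#' @export
enc_plot_data <- function(indices) {
  s <- indices$gc3s
  ok <- is.finite(s) & s > 0 & s < 1 & is.finite(indices$enc)
  expected <- rep(NA_real_, nrow(indices))
  expected[ok] <- expected_enc_curve(s[ok])
  residual <- indices$enc - expected
  data.frame(gene_id = indices$gene_id, gc3s = s, enc = indices$enc,
             expected_enc = expected, residual = residual,
             below_curve = residual < 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene RSCU matrix for correspondence analysis
#'
#' Builds the genes x 59 synonymous-sense-codon RSCU matrix. A gene lacking
#' an amino-acid family entirely has that family's RSCU undefined; those
#' entries are filled with the family-neutral value 1 so every row is
#' complete, and affected genes are flagged.
#'
#' @param counts_list Named list of per-gene `codon_counts`.
#' @return Numeric matrix (rownames = gene ids, colnames = the 59 codons)
#'   with attribute `"filled"`, the ids of genes with any filled family.
#' @export
rscu_matrix <- function(counts_list) {
  m <- t(vapply(counts_list, function(x) {
    rs <- compute_rscu(x)
    rs$rscu[match(.SYN_CODONS, rs$codon)]
  }, numeric(length(.SYN_CODONS))))
  colnames(m) <- .SYN_CODONS
  rownames(m) <- names(counts_list)
  filled <- rownames(m)[apply(is.na(m), 1L, any)]
  m[is.na(m)] <- 1
  attr(m, "filled") <- filled
  m
}

#' Correspondence analysis of a nonnegative matrix
#'
#' Standard (simple) correspondence analysis: the matrix is treated as
#' nonnegative mass, the correspondence matrix P and its row/column margins
#' r and c are formed, the standardized residuals
#' `S = Dr^(-1/2) (P - r c') Dc^(-1/2)` are decomposed by SVD, and principal
#' coordinates are returned for rows (genes) and columns (codons).
#' Eigenvalues are the squared singular values; their fractions of total
#' inertia are reported. The axis sign is unidentifiable, so each axis is
#' oriented to make the column with the largest absolute loading positive.
#'
#' @param x Nonnegative numeric matrix, at least 3 rows.
#' @param n_axes Number of axes to return (fewer if the matrix has lower
#'   rank; flagged via `rank_deficient`).
#' @return A `coa_result` list: `row_coords`, `col_coords` (principal
#'   coordinates), `eigenvalues`, `inertia_fraction`, `n_axes`,
#'   `rank_deficient`.
#' @export
correspondence_analysis <- function(x, n_axes = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("correspondence analysis needs at least 3 rows")
  if (any(x < 0) || any(!is.finite(x))) stop("matrix must be finite and nonnegative")
  keep_col <- colSums(x) > 0
  x <- x[, keep_col, drop = FALSE]
  P <- x / sum(x)
  r <- rowSums(P); cc <- colSums(P)
  S <- sweep(sweep(P - tcrossprod(r, cc), 1L, sqrt(r), "/"), 2L, sqrt(cc), "/")
  sv <- svd(S)
  tol <- 1e-12
  k_avail <- sum(sv$d > tol)
  k <- min(n_axes, k_avail)
  rank_deficient <- k_avail < n_axes

  rc <- matrix(0, nrow(x), n_axes,
               dimnames = list(rownames(x), paste0("axis", seq_len(n_axes))))
  cco <- matrix(0, ncol(x), n_axes,
                dimnames = list(colnames(x), paste0("axis", seq_len(n_axes))))
  if (k > 0L) {
    idx <- seq_len(k)
    rc[, idx] <- sweep(sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], k),
                       1L, sqrt(r), "/")
    cco[, idx] <- sweep(sv$v[, idx, drop = FALSE] %*% diag(sv$d[idx], k),
                        1L, sqrt(cc), "/")
    for (j in idx) {
      lead <- which.max(abs(cco[, j]))
      if (cco[lead, j] < 0) {
        cco[, j] <- -cco[, j]
        rc[, j] <- -rc[, j]
      }
    }
  }
  eig <- sv$d^2
  structure(list(row_coords = rc, col_coords = cco,
                 eigenvalues = eig[seq_len(max(k, 1L))],
                 inertia_fraction = if (sum(eig) > 0)
                   eig[seq_len(max(k, 1L))] / sum(eig) else
                   rep(0, max(k, 1L)),
                 n_axes = k, rank_deficient = rank_deficient),
            class = "coa_result")
}

#' Attach correspondence-analysis axes to a gene-index table
#'
#' Runs [correspondence_analysis()] on the per-gene RSCU matrix and writes
#' the first two row principal coordinates into the `axis1`/`axis2` columns.
#'
#' @param indices Data frame from [compute_gene_indices()].
#' @param counts_list Per-gene `codon_counts` list (defaults to the counts
#'   attached to `indices`).
#' @return `indices` with `axis1`/`axis2` filled; the `coa_result` is
#'   attached as attribute `"coa"`.
#' @export
add_ca_axes <- function(indices, counts_list = attr(indices, "counts")) {
  if (is.null(counts_list)) stop("no per-gene counts available")
  m <- rscu_matrix(counts_list[indices$gene_id])
  ca <- correspondence_analysis(m, n_axes = 2L)
  indices$axis1 <- ca$row_coords[indices$gene_id, 1L]
  indices$axis2 <- ca$row_coords[indices$gene_id, 2L]
  attr(indices, "coa") <- ca
  indices
}

#' Spearman correlation matrix of codon-usage indices
#'
#' Pairwise-complete Spearman rank correlations with average ranks for
#' ties, plus two-sided p-values: the exact rank-permutation null for pair
#' sizes up to 10 (falling back to the approximation when ties make the
#' exact null unavailable), the t approximation above. Variables with zero
#' variance on a pair give `NA` for that pair.
#'
#' @param df Data frame of per-gene numeric variables (one column each).
#' @return A `correlation_matrix` list: `rho`, `p` (symmetric matrices,
#'   unit diagonal), `n` (pairwise complete sizes).
#' @export
spearman_matrix <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(vapply(df, is.numeric, logical(1))))
  if (nrow(df) < 5L) stop("spearman_matrix needs at least 5 genes")
  vars <- names(df)
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(0L, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(df[[i]], df[[j]])
      x <- df[[i]][ok]; y <- df[[j]][ok]
      n[i, j] <- n[j, i] <- length(x)
      if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) next
      r <- stats::cor(x, y, method = "spearman")
      pv <- .spearman_p(x, y, r)
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- pv
    }
  }
  diag(n) <- nrow(df)
  structure(list(rho = rho, p = p, n = n), class = "correlation_matrix")
}

.spearman_p <- function(x, y, r) {
  m <- length(x)
  if (m <= 10L) {
    pv <- tryCatch(
      suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                       exact = TRUE)$p.value),
      error = function(e) NA_real_)
    if (!is.na(pv)) return(pv)
  }
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((m - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = m - 2)
}

#' Format a correlation matrix with significance stars
#'
#' Lower-triangle display mirroring published codon-usage correlation
#' tables: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param cm A `correlation_matrix`.
#' @param digits Decimals for rho.
#' @return A character matrix.
#' @export
format_correlation <- function(cm, digits = 3L) {
  stopifnot(inherits(cm, "correlation_matrix"))
  k <- nrow(cm$rho)
  out <- matrix("", k, k, dimnames = dimnames(cm$rho))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    r <- cm$rho[i, j]; pv <- cm$p[i, j]
    if (is.na(r)) { out[i, j] <- "NA"; next }
    stars <- if (is.na(pv)) "" else if (pv < 0.01) "**" else
      if (pv < 0.05) "*" else ""
    out[i, j] <- paste0(formatC(r, digits = digits, format = "f"), stars)
  }
  out
}
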