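## Per-gene and pooled codon-usage indices: RSCU, Wright's ENC, CAI with
## reference-weight derivation, GRAVY and aromaticity.

#' Relative synonymous codon usage
#'
#' For codon j of an amino-acid family of size n with within-family counts
#' x, `RSCU = n * x_j / sum(x)`: the observed count relative to the count
#' expected under uniform usage within the family. RSCU 1 means no bias;
#' values above 1 mark preferentially used codons. The single-codon families
#' (AUG, UGG) have RSCU 1 whenever observed, and the stop family's RSCU is
#' reported as well (family size 3) although stops never enter ENC, CAI,
#' GC3s or optimal-codon statistics. Families with zero total count yield
#' `NA`.
#'
#' @param counts A `codon_counts` object (per gene or pooled).
#' @return A 64-row data frame in lexicographic RNA-codon order with columns
#'   `amino_acid`, `codon`, `aa`, `count`, `family_size`, `rscu`, `is_stop`.
#' @examples
#' rs <- compute_rscu(table3_fixture())
#' rs[rs$codon == "CGC", ]
#' @export
compute_rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  ci <- .CODON_INFO
  v <- as.numeric(counts$counts)
  fam_tot <- rowsum(v, .FAM_INT)[.FAM_INT]
  rscu <- ifelse(fam_tot > 0, ci$family_size * v / fam_tot, NA_real_)
  data.frame(amino_acid = ci$amino_acid, codon = ci$codon, aa = ci$aa,
             count = counts$counts, family_size = ci$family_size,
             rscu = rscu, is_stop = ci$is_stop,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's estimator of how far a gene departs from uniform synonymous
#' codon usage. For each family with total count n >= 2, the codon
#' homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)` with p the
#' within-family codon proportions. With `Fk` the mean F over informative
#' families of degeneracy k,
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`
#' (2 single-codon amino acids; 9 two-fold, 1 three-fold, 5 four-fold and 3
#' six-fold families; stop codons excluded). ENC runs from 20 (one codon per
#' amino acid) to 61 (uniform usage); estimates exceeding 61 through
#' sampling noise are capped at 61 and flagged.
#'
#' Missing-class handling: a family is informative when its total count is
#' at least 2. If Ile (the only 3-fold family) is uninformative,
#' `F3 = (F2 + F4)/2`. For the other classes the mean is taken over
#' informative families provided at least half of the class's families are
#' informative; otherwise ENC is undefined (`NA`).
#'
#' @param counts A `codon_counts` object.
#' @return An `enc_result` list: `enc` (capped, or `NA` if undefined),
#'   `enc_raw`, `capped`, `fbar` (named mean homozygosity per degeneracy
#'   class), `n_informative` (informative families per class).
#' @examples
#' uniform <- new_codon_counts(stats::setNames(rep(10, 64), codon_info()$codon))
#' compute_enc(uniform)$enc  # 61
#' @export
compute_enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  v <- counts$counts

  fam_F <- function(idx_list) {
    vapply(idx_list, function(idx) {
      x <- v[idx]
      n <- sum(x)
      if (n < 2L) return(NA_real_)
      p <- x / n
      (n * sum(p^2) - 1) / (n - 1)
    }, numeric(1))
  }

  Fs <- lapply(.ENC_FAM_IDX, fam_F)
  n_inf <- vapply(Fs, function(f) sum(!is.na(f)), integer(1))
  fbar <- vapply(Fs, function(f) {
    if (any(!is.na(f))) mean(f, na.rm = TRUE) else NA_real_
  }, numeric(1))

  ## class sizes: 9, 1, 5, 3; require at least half informative (Ile has its
  ## own fallback below)
  need <- c(`2` = 5L, `4` = 3L, `6` = 2L)
  ok <- n_inf[names(need)] >= need
  f2 <- fbar[["2"]]; f4 <- fbar[["4"]]; f6 <- fbar[["6"]]
  f3 <- fbar[["3"]]
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2

  enc_raw <- NA_real_
  if (all(ok) && !is.na(f3) &&
      all(c(f2, f3, f4, f6) > 0)) {
    enc_raw <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  }
  capped <- !is.na(enc_raw) && enc_raw > 61
  structure(list(enc = if (is.na(enc_raw)) NA_real_ else min(enc_raw, 61),
                 enc_raw = enc_raw, capped = capped,
                 fbar = c(`2` = f2, `3` = f3, `4` = f4, `6` = f6),
                 n_informative = n_inf),
            class = "enc_result")
}

#' Derive CAI relative-adaptiveness weights
#'
#' Computes relative adaptiveness `w = RSCU / max(RSCU within family)` from
#' a reference codon pool representing highly expressed genes, for the 59
#' synonymous sense codons. Codons unobserved in the reference receive a
#' small floor weight instead of zero so that `log(w)` stays finite; floored
#' codons are recorded.
#'
#' @param reference A pooled `codon_counts` reference (e.g. the most biased
#'   genes); must contain at least one codon.
#' @param provenance Free-text identifier of the reference set, carried into
#'   outputs.
#' @param floor Weight assigned to reference-unobserved codons (default
#'   0.01).
#' @return A `cai_weights` object: list with `w` (named vector over the 59
#'   synonymous codons, max 1 within each family), `floored` (codons given
#'   the floor), `provenance`.
#' @export
derive_cai_weights <- function(reference, provenance = "reference",
                               floor = 0.01) {
  stopifnot(inherits(reference, "codon_counts"))
  if (reference$n_codons == 0L) stop("empty CAI reference pool")
  rs <- compute_rscu(reference)
  rs <- rs[rs$codon %in% .SYN_CODONS, ]
  wmax <- ave(rs$rscu, rs$aa, FUN = function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  w <- rs$rscu / wmax
  floored <- is.na(w) | w <= 0
  w[floored] <- floor
  names(w) <- rs$codon
  structure(list(w = w, floored = rs$codon[floored],
                 provenance = provenance),
            class = "cai_weights")
}

#' Codon adaptation index
#'
#' Geometric mean of the relative-adaptiveness weights over a gene's codons,
#' excluding AUG, UGG and stop codons:
#' `CAI = exp( sum(x_j * log(w_j)) / L )` with L the number of included
#' codons. CAI lies in (0, 1]; higher values indicate codon usage closer to
#' the reference (proxy for higher expression).
#'
#' @param gene A `codon_counts` object for one gene.
#' @param weights A `cai_weights` object from [derive_cai_weights()].
#' @return A single number in (0, 1], or `NA` if the gene has no
#'   contributing codons.
#' @export
compute_cai <- function(gene, weights) {
  stopifnot(inherits(gene, "codon_counts"), inherits(weights, "cai_weights"))
  v <- gene$counts[names(weights$w)]
  L <- sum(v)
  if (L == 0L) return(NA_real_)
  exp(sum(v * log(weights$w)) / L)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of a translated product,
#' after dropping stop (`*`) and unknown (`X`) symbols.
#'
#' @param protein Amino-acid string.
#' @return Mean hydropathy, or `NA` if no scored residue remains.
#' @examples
#' compute_gravy("IR")  # 0: 4.5 + (-4.5)
#' @export
compute_gravy <- function(protein) {
  aa <- .protein_residues(protein)
  if (!length(aa)) return(NA_real_)
  mean(.KD_SCALE[aa])
}

#' Aromaticity
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) in a translated product,
#' after dropping `*` and `X`.
#'
#' @param protein Amino-acid string.
#' @return Fraction in `[0, 1]`, or `NA` if no residue remains.
#' @export
compute_aromo <- function(protein) {
  aa <- .protein_residues(protein)
  if (!length(aa)) return(NA_real_)
  mean(aa %in% .AROMATIC)
}

.protein_residues <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  aa <- strsplit(toupper(protein), "")[[1]]
  aa <- aa[!aa %in% c("*", "X")]
  bad <- !aa %in% names(.KD_SCALE)
  if (any(bad)) stop("unknown residue: ", paste(unique(aa[bad]), collapse = ", "))
  aa
}

#' Per-gene codon-usage index table
#'
#' Computes the full per-gene row of statistics used by the genome-level
#' analyses: length, composition profile, ENC, CAI, GRAVY and aromaticity.
#' The correspondence-analysis coordinates `axis1`/`axis2` are initialized
#' to `NA` and filled by [add_ca_axes()].
#'
#' If no CAI weights are supplied, the reference pool defaults to the most
#' biased genes: the fraction `cai_fraction` of genes with the lowest ENC,
#' pooled (a standard proxy for highly expressed genes when no expression
#' data exist).
#'
#' @param records A `cds_set` of in-frame CDS.
#' @param counts Optional precomputed list of per-gene `codon_counts`
#'   (parallel to `records`).
#' @param cai_weights Optional `cai_weights`; derived automatically when
#'   `NULL`.
#' @param cai_fraction Fraction of lowest-ENC genes pooled for the automatic
#'   CAI reference.
#' @return A data frame with one row per gene (columns `gene_id`,
#'   `length_nt`, `length_codons`, `n_skipped`, the composition fields,
#'   `enc`, `cai`, `gravy`, `aromo`, `axis1`, `axis2`). The per-gene counts
#'   are attached as attribute `"counts"` and the CAI weights as attribute
#'   `"cai_weights"`.
#' @export
compute_gene_indices <- function(records, counts = NULL, cai_weights = NULL,
                                 cai_fraction = 0.05) {
  ids <- names(records)
  if (is.null(counts)) counts <- lapply(records, count_codons)
  names(counts) <- ids

  comp <- lapply(counts, composition_profile)
  enc <- vapply(counts, function(x) compute_enc(x)$enc, numeric(1))

  if (is.null(cai_weights)) {
    ord <- order(enc, ids, na.last = NA)
    n_ref <- max(1L, ceiling(cai_fraction * length(ord)))
    ref_ids <- ids[ord[seq_len(min(n_ref, length(ord)))]]
    if (!length(ref_ids)) stop("no gene with defined ENC to build a CAI reference")
    cai_weights <- derive_cai_weights(
      pool_counts(counts[ref_ids]),
      provenance = sprintf("auto: pooled %d lowest-ENC genes (fraction %.3g)",
                           length(ref_ids), cai_fraction))
  }
  cai <- vapply(counts, compute_cai, numeric(1), weights = cai_weights)

  prot <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unname(records)), if.fuzzy.codon = "X"))
  gravy <- vapply(prot, compute_gravy, numeric(1))
  aromo <- vapply(prot, compute_aromo, numeric(1))

  comp_df <- do.call(rbind, lapply(comp, function(p)
    as.data.frame(p[c("gc", "gc1", "gc2", "gc12", "gc3", "gc3s",
                      "a3s", "t3s", "c3s", "g3s")])))
  out <- data.frame(
    gene_id = ids,
    length_nt = unname(nchar(records)),
    length_codons = vapply(counts, function(x) x$n_codons, integer(1)),
    n_skipped = vapply(counts, function(x) x$n_skipped, integer(1)),
    comp_df,
    enc = unname(enc), cai = unname(cai),
    gravy = unname(gravy), aromo = unname(aromo),
    axis1 = NA_real_, axis2 = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "counts") <- counts
  attr(out, "cai_weights") <- cai_weights
  out
}
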