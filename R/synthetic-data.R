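## Synthetic CDS generator with controlled mutational GC pressure and
## translational selection, plus loaders for the packaged codon-count
## fixtures transcribed from a published genome-wide survey.

.SENSE_AAS <- setdiff(names(.AA3), "*")
.STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Default preferred-codon set
#'
#' One codon per degenerate amino-acid family: the lexicographically first
#' C-ending codon, or the G-ending codon for families without one (Gln,
#' Glu, Lys). This emulates the G/C-ending optima typical of GC-rich fungal
#' genomes.
#'
#' @return Named character vector (names = one-letter amino acids, 18
#'   degenerate families).
#' @export
default_preferred_codons <- function() {
  ci <- .CODON_INFO[.CODON_INFO$is_synonymous, ]
  out <- vapply(split(ci, ci$aa), function(fam) {
    cands <- sort(fam$codon[fam$p3 == "C"])
    if (!length(cands)) cands <- sort(fam$codon[fam$p3 == "G"])
    cands[1L]
  }, character(1))
  out
}

.gene_seed <- function(seed, i) {
  ## counter-based substream: gene i's draws depend only on (seed, i), so
  ## changing n_genes never reshuffles earlier genes
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

#' Simulate a synthetic CDS set
#'
#' Generates stop-terminated ORFs under a two-force model of codon usage:
#' mutational GC pressure and translational selection.
#'
#' Per gene, a length is drawn log-normally and a mutational third-position
#' GC bias `m` from `Beta(gc3_alpha, gc3_beta)`; amino acids are sampled
#' i.i.d.; each codon's third base is G/C with probability `m` (split
#' uniformly within the compatible synonymous subset, A/U otherwise; for
#' Ile, whose family has no G-ending codon, the G/C outcome maps to AUC). A
#' fraction of genes is marked highly expressed; each of their codons is
#' replaced by the family's preferred codon with probability `selection`.
#' The `coupling` parameter tilts each gene's amino-acid frequencies toward
#' residues with G/C-rich first/second codon positions in proportion to
#' `m`, which induces a neutrality-plot slope: 0 coupling gives slope ~0.
#'
#' Defaults mirror a GC-rich ascomycete gene set: mean third-position GC
#' bias 2/3 with genuine spread, median length 300 codons, 10% of genes
#' under selection strength 0.5 toward C/G-ending codons, and coupling 0.12
#' (a weak mutational slope of the size reported for such genomes).
#'
#' @param n_genes Number of genes (>= 1).
#' @param median_codons Median gene length in codons (log-normal).
#' @param sigma_log Log-scale standard deviation of gene length.
#' @param aa_freq Optional base amino-acid frequency vector (named by
#'   one-letter code; default uniform over the 20 sense amino acids).
#' @param gc3_alpha,gc3_beta Beta parameters of the per-gene mutational GC3
#'   bias `m`.
#' @param coupling Position-coupling `k` in `[0, 1]` linking first/second
#'   position GC to `m`.
#' @param selected_fraction Fraction of genes marked highly expressed.
#' @param selection Selection strength `s` in `[0, 1]` for those genes.
#' @param preferred Named preferred-codon set (one codon per degenerate
#'   family), default [default_preferred_codons()].
#' @param seed Integer seed; the same spec and seed reproduce the output
#'   byte-identically.
#' @return A list with `records` (a `cds_set`, DNA alphabet,
#'   stop-terminated) and `truth`, a data frame `gene_id`, `m`,
#'   `highly_expressed`, `length_codons` (sense codons, stop excluded), with
#'   the generator parameters attached as attribute `"params"`.
#' @export
simulate_genome <- function(n_genes, median_codons = 300, sigma_log = 0.4,
                            aa_freq = NULL, gc3_alpha = 12, gc3_beta = 6,
                            coupling = 0.12, selected_fraction = 0.1,
                            selection = 0.5,
                            preferred = default_preferred_codons(),
                            seed = 1L) {
  stopifnot(n_genes >= 1, median_codons >= 2, sigma_log >= 0,
            gc3_alpha > 0, gc3_beta > 0,
            coupling >= 0, coupling <= 1,
            selected_fraction >= 0, selected_fraction <= 1,
            selection >= 0, selection <= 1)
  if (selection > 0 && selected_fraction > 0) {
    deg <- unique(.CODON_INFO$aa[.CODON_INFO$is_synonymous])
    if (!all(deg %in% names(preferred)))
      stop("preferred set must cover every degenerate family")
    if (!all(preferred[deg] %in% .SYN_CODONS))
      stop("preferred codons must be synonymous sense codons")
  }
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / 20, 20L), .SENSE_AAS)
  } else {
    stopifnot(all(.SENSE_AAS %in% names(aa_freq)), all(aa_freq >= 0))
    aa_freq <- aa_freq[.SENSE_AAS] / sum(aa_freq[.SENSE_AAS])
  }

  ci <- .CODON_INFO
  ## per amino acid: codons by third-base type, and mean GC at positions 1-2
  by_aa <- split(ci[!ci$is_stop, ], ci$aa[!ci$is_stop])
  gc_sub <- lapply(by_aa, function(f) f$codon[f$p3 %in% c("G", "C")])
  at_sub <- lapply(by_aa, function(f) f$codon[f$p3 %in% c("A", "U")])
  g12 <- vapply(by_aa, function(f)
    mean(c(f$p1, f$p2) %in% c("G", "C")), numeric(1))
  mbar <- gc3_alpha / (gc3_alpha + gc3_beta)

  records <- character(n_genes)
  m_true <- numeric(n_genes)
  he <- logical(n_genes)
  len <- integer(n_genes)

  for (g in seq_len(n_genes)) {
    set.seed(.gene_seed(seed, g))
    L <- max(10L, as.integer(round(stats::rlnorm(1, log(median_codons),
                                                 sigma_log))))
    m <- stats::rbeta(1, gc3_alpha, gc3_beta)
    is_he <- stats::runif(1) < selected_fraction

    w <- pmax(aa_freq * (1 + 3 * coupling * (m - mbar) * (2 * g12[.SENSE_AAS] - 1)),
              1e-4)
    aas <- sample(.SENSE_AAS, L, replace = TRUE, prob = w)
    use_pref <- is_he & (stats::runif(L) < selection)
    gc_draw <- stats::runif(L) < m

    codons <- character(L)
    for (a in unique(aas)) {
      idx <- which(aas == a)
      pref_idx <- idx[use_pref[idx]]
      if (length(pref_idx)) {
        codons[pref_idx] <- if (a %in% names(preferred)) preferred[[a]] else
          by_aa[[a]]$codon[1L]
      }
      rest <- idx[!use_pref[idx]]
      if (length(rest)) {
        gcs <- gc_sub[[a]]; ats <- at_sub[[a]]
        want_gc <- gc_draw[rest]
        if (!length(gcs)) want_gc[] <- FALSE
        if (!length(ats)) want_gc[] <- TRUE
        n_gc <- sum(want_gc)
        if (n_gc) codons[rest[want_gc]] <-
            gcs[sample.int(length(gcs), n_gc, replace = TRUE)]
        if (length(rest) - n_gc) codons[rest[!want_gc]] <-
            ats[sample.int(length(ats), length(rest) - n_gc, replace = TRUE)]
      }
    }
    stop_codon <- .STOP_CODONS[sample.int(3L, 1L)]
    records[g] <- chartr("U", "T", paste(c(codons, stop_codon), collapse = ""))
    m_true[g] <- m; he[g] <- is_he; len[g] <- L
  }

  ids <- sprintf("gene%05d", seq_len(n_genes))
  names(records) <- ids
  truth <- data.frame(gene_id = ids, m = m_true, highly_expressed = he,
                      length_codons = len, stringsAsFactors = FALSE)
  attr(truth, "params") <- list(
    gc3_alpha = gc3_alpha, gc3_beta = gc3_beta, coupling = coupling,
    selected_fraction = selected_fraction, selection = selection,
    preferred = preferred, seed = seed)
  list(records = structure(records, class = "cds_set"), truth = truth)
}

#' Write a simulated genome to disk
#'
#' Writes the FASTA plus a ground-truth TSV (`gene_id`, `m`,
#' `highly_expressed`, `length_codons`).
#'
#' @param sim Result of [simulate_genome()].
#' @param fasta_path,truth_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_simulated_genome <- function(sim, fasta_path, truth_path) {
  write_cds_fasta(sim$records, fasta_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "codonbias")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

#' Genome-wide codon-count fixture
#'
#' The pooled genome-wide codon counts of *Beauveria bassiana* (10,363 CDS)
#' as transcribed from a published codon-usage survey, packaged so the RSCU
#' machinery can be exercised against printed values without any download.
#'
#' @return A `codon_counts` object over all 64 codons, with the printed
#'   RSCU column attached as attribute `"printed"` (data frame
#'   `amino_acid`, `codon`, `count`, `rscu_printed`).
#' @export
table3_fixture <- function() {
  df <- utils::read.delim(.extdata("bbassiana_codon_usage.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  out <- new_codon_counts(stats::setNames(df$count, df$codon))
  attr(out, "printed") <- df
  out
}

#' High/low-bias pool codon-count fixture
#'
#' The per-pool codon counts of the ENC-ranked high-bias and low-bias gene
#' pools of *B. bassiana*, transcribed from the optimal-codon table of the
#' same survey. Two garbled low-pool cells are stored under their natural
#' reading and flagged (`ambiguous == 1`) so assertions can exclude them.
#'
#' @return A list with `high` and `low` (`codon_counts`) and `table`, the
#'   transcription with printed RSCU columns and flags.
#' @export
table4_fixture <- function() {
  df <- utils::read.delim(.extdata("bbassiana_enc_pools.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  list(high = new_codon_counts(stats::setNames(df$n_high, df$codon)),
       low = new_codon_counts(stats::setNames(df$n_low, df$codon)),
       table = df)
}
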