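## End-to-end pipeline: read -> QC -> counts -> composition/indices -> CA ->
## correlations -> neutrality -> ENC plot -> partition -> optimal codons,
## with a TSV report bundle and a JSON manifest.

.CORR_VARS <- c("length_nt", "gc", "gc1", "gc2", "gc3", "gc3s", "a3s",
                "t3s", "c3s", "g3s", "gravy", "aromo", "enc", "cai",
                "axis1", "axis2")

.BUNDLE_TSVS <- c("gene_indices.tsv", "codon_counts.tsv", "rscu_pooled.tsv",
                  "neutrality_fit.tsv", "enc_plot.tsv", "coa_genes.tsv",
                  "coa_codons.tsv", "correlation_matrix.tsv",
                  "optimal_codons.tsv")

.write_tsv <- function(df, path, digits = 6L) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full codon-usage-bias pipeline
#'
#' Executes every analysis stage on a CDS FASTA and writes the report
#' bundle: per-gene indices and codon counts, pooled RSCU, neutrality fit,
#' ENC-plot data, correspondence-analysis coordinates, the Spearman
#' correlation matrix (rho and p blocks in one TSV) and the optimal-codon
#' table, plus `manifest.json` recording the configuration, input checksum
#' and per-stage gene counts. The run is deterministic: identical input and
#' configuration yield byte-identical TSVs.
#'
#' @param input Path to a CDS FASTA (plain or gzip), or a `cds_set`.
#' @param out_dir Output directory (created if needed).
#' @param min_codons,reject_internal_stops QC settings (see [qc_filter()]).
#' @param pool_fraction Fraction for the ENC-ranked high/low pools.
#' @param delta_threshold,alpha Optimal-codon thresholds
#'   (see [detect_optimal_codons()]).
#' @param cai_reference `NULL` for the automatic lowest-ENC reference, or a
#'   path to a reference FASTA / codon-count TSV.
#' @param cai_fraction Fraction of lowest-ENC genes for the automatic CAI
#'   reference.
#' @param enc_bias_cutoff ENC below which a gene is counted as strongly
#'   biased in the summary (default 35).
#' @param verbose Emit stage-tagged progress messages.
#' @return Invisibly, a list with `out_dir`, `files`, `indices`,
#'   `neutrality`, `optimal`, `manifest`.
#' @export
run_pipeline <- function(input, out_dir,
                         min_codons = 0L, reject_internal_stops = FALSE,
                         pool_fraction = 0.05,
                         delta_threshold = 0.08, alpha = 0.01,
                         cai_reference = NULL, cai_fraction = 0.05,
                         enc_bias_cutoff = 35, verbose = TRUE) {
  say <- function(stage, ...) if (verbose)
    message("[", stage, "] ", ...)
  stopifnot(pool_fraction > 0, pool_fraction <= 0.5,
            delta_threshold >= 0, alpha > 0, alpha < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  input_md5 <- NA_character_
  if (inherits(input, "cds_set")) {
    records <- input
  } else {
    say("read", "reading ", input)
    records <- read_cds_fasta(input)
    input_md5 <- unname(tools::md5sum(input))
  }

  qc <- qc_filter(records, min_codons = min_codons,
                  reject_internal_stops = reject_internal_stops)
  say("qc", qc$report$n_kept, "/", qc$report$n_input, " genes kept")
  if (qc$report$n_kept < 5L)
    stop("qc: fewer than 5 genes passed filtering (",
         qc$report$n_kept, " of ", qc$report$n_input, ")")
  records <- qc$records

  say("counts", "tokenizing codons")
  counts <- lapply(records, count_codons)

  cai_weights <- NULL
  if (!is.null(cai_reference)) {
    say("cai", "reading reference ", cai_reference)
    ref <- if (grepl("\\.(tsv|txt)$", cai_reference))
      read_codon_counts_tsv(cai_reference) else
      pool_counts(lapply(read_cds_fasta(cai_reference), count_codons))
    cai_weights <- derive_cai_weights(ref, provenance = cai_reference)
  }

  say("indices", "computing per-gene indices")
  indices <- compute_gene_indices(records, counts = counts,
                                  cai_weights = cai_weights,
                                  cai_fraction = cai_fraction)

  say("coa", "correspondence analysis of RSCU")
  indices <- add_ca_axes(indices, counts)
  coa <- attr(indices, "coa")

  say("correlations", "Spearman matrix over ", length(.CORR_VARS), " indices")
  corr <- spearman_matrix(indices[.CORR_VARS])

  say("neutrality", "regressing GC12 on GC3")
  neut <- neutrality_regression(indices$gc12, indices$gc3)

  say("enc_plot", "expected-ENC residuals")
  encp <- enc_plot_data(indices)

  say("optimal", "high/low pools at fraction ", pool_fraction)
  part <- partition_by_enc(indices, counts, fraction = pool_fraction)
  optimal <- detect_optimal_codons(part, delta_threshold = delta_threshold,
                                   alpha = alpha)

  say("report", "writing bundle to ", out_dir)
  p <- function(f) file.path(out_dir, f)
  .write_tsv(indices, p("gene_indices.tsv"))
  write_gene_counts_tsv(counts, p("codon_counts.tsv"))
  pooled_rscu <- compute_rscu(pool_counts(counts))
  .write_tsv(pooled_rscu[c("amino_acid", "codon", "count", "rscu")],
             p("rscu_pooled.tsv"))
  .write_tsv(as.data.frame(unclass(neut)), p("neutrality_fit.tsv"))
  .write_tsv(encp, p("enc_plot.tsv"))
  .write_tsv(data.frame(gene_id = rownames(coa$row_coords),
                        coa$row_coords, stringsAsFactors = FALSE),
             p("coa_genes.tsv"))
  .write_tsv(data.frame(codon = rownames(coa$col_coords),
                        coa$col_coords, stringsAsFactors = FALSE),
             p("coa_codons.tsv"))
  corr_df <- rbind(
    data.frame(block = "rho", variable = rownames(corr$rho), corr$rho,
               stringsAsFactors = FALSE),
    data.frame(block = "p", variable = rownames(corr$p), corr$p,
               stringsAsFactors = FALSE))
  .write_tsv(corr_df, p("correlation_matrix.tsv"))
  .write_tsv(optimal, p("optimal_codons.tsv"))

  manifest <- list(
    tool = "codonbias",
    version = as.character(utils::packageVersion("codonbias")),
    input_md5 = input_md5,
    config = list(min_codons = min_codons,
                  reject_internal_stops = reject_internal_stops,
                  pool_fraction = pool_fraction,
                  delta_threshold = delta_threshold, alpha = alpha,
                  cai_reference = if (is.null(cai_reference)) "auto-enc"
                    else cai_reference,
                  cai_fraction = cai_fraction,
                  enc_bias_cutoff = enc_bias_cutoff),
    cai_provenance = attr(indices, "cai_weights")$provenance,
    stages = list(n_input = qc$report$n_input,
                  n_kept = qc$report$n_kept,
                  qc_reasons = as.list(qc$report$reasons),
                  n_high_pool = length(part$high_genes),
                  n_low_pool = length(part$low_genes),
                  n_codons_high = part$high_pool$n_codons,
                  n_codons_low = part$low_pool$n_codons,
                  coa_inertia_axis12 = coa$inertia_fraction[1:2]),
    files = .BUNDLE_TSVS)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, files = c(.BUNDLE_TSVS, "manifest.json"),
                 indices = indices, neutrality = neut, optimal = optimal,
                 manifest = manifest))
}

#' Summarize a report bundle
#'
#' Recomputes the headline tallies from the TSVs alone (no hidden state):
#' gene count, mean and sd of the main indices, number of synonymous codons
#' with RSCU > 1, optimal codons and their G/C-ending tally, the neutrality
#' decomposition, and the count of strongly biased genes (ENC below the
#' cutoff).
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param enc_bias_cutoff ENC cutoff for the strong-bias tally.
#' @return Invisibly, a list of the printed quantities.
#' @export
summarize_bundle <- function(out_dir, enc_bias_cutoff = 35) {
  need <- c("gene_indices.tsv", "rscu_pooled.tsv", "neutrality_fit.tsv",
            "optimal_codons.tsv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("incomplete bundle, missing: ", paste(missing, collapse = ", "))
  rd <- function(f) utils::read.delim(file.path(out_dir, f),
                                      stringsAsFactors = FALSE)
  gi <- rd("gene_indices.tsv")
  rs <- rd("rscu_pooled.tsv")
  nt <- rd("neutrality_fit.tsv")
  oc <- rd("optimal_codons.tsv")

  ms <- function(x) sprintf("%.4f +/- %.4f", mean(x, na.rm = TRUE),
                            stats::sd(x, na.rm = TRUE))
  syn <- rs$codon %in% .SYN_CODONS
  n_rscu_gt1 <- sum(rs$rscu[syn] > 1, na.rm = TRUE)
  opt <- oc$codon[which(oc$optimal == TRUE | oc$optimal == "TRUE")]
  gc_ending <- sum(substr(opt, 3L, 3L) %in% c("G", "C"))
  n_biased <- sum(gi$enc < enc_bias_cutoff, na.rm = TRUE)

  cat("genes analyzed: ", nrow(gi), "\n",
      "GC: ", ms(gi$gc), "   GC3s: ", ms(gi$gc3s), "\n",
      "ENC: ", ms(gi$enc), "   CAI: ", ms(gi$cai), "\n",
      "GRAVY: ", ms(gi$gravy), "   Aromo: ", ms(gi$aromo), "\n",
      "codons with RSCU > 1: ", n_rscu_gt1, "\n",
      "optimal codons: ", length(opt),
      " (G/C-ending: ", gc_ending, ")\n",
      "neutrality slope: ", sprintf("%.4f", nt$slope),
      " (mutation ", sprintf("%.2f", nt$mutation_pct),
      "%, other ", sprintf("%.2f", nt$other_pct), "%)\n",
      "genes with ENC < ", enc_bias_cutoff, ": ", n_biased, "\n",
      sep = "")
  invisible(list(n_genes = nrow(gi), n_rscu_gt1 = n_rscu_gt1,
                 optimal_codons = opt, n_gc_ending = gc_ending,
                 slope = nt$slope, mutation_pct = nt$mutation_pct,
                 other_pct = nt$other_pct, n_biased = n_biased))
}
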