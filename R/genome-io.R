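## Reading, validation and codon tokenization of CDS sets. A CDS set is a
## named character vector of uppercase DNA sequences; codon-count tables are
## the common currency handed to every downstream module.

.IUPAC_DNA_RE <- "^[ACGTRYSWKMBDHVN]*$"

#' Read a CDS FASTA file
#'
#' Reads a multi-record FASTA file (plain or gzip-compressed) of coding
#' sequences. Sequences are uppercased and U is mapped to T so that RNA
#' input is accepted; all downstream reporting re-emits codons in the RNA
#' alphabet. Record identifiers are the first whitespace-delimited token of
#' each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase DNA sequences
#'   (class `"cds_set"`), in file order.
#' @seealso [write_cds_fasta()], [qc_filter()], [count_codons()]
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seqs <- chartr("U", "T", toupper(as.character(x)))
  names(seqs) <- ids
  validate_cds_set(seqs)
}

#' Validate a CDS set
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @return The validated set (uppercase DNA, class `"cds_set"`).
#' @keywords internal
#' @export
validate_cds_set <- function(seqs) {
  seqs <- vapply(seqs, function(s) chartr("U", "T", toupper(s)), character(1))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every record needs a non-empty identifier")
  if (anyDuplicated(ids))
    stop("duplicate record identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record with empty sequence: ", paste(ids[empty], collapse = ", "))
  short <- nchar(seqs) < 3L
  if (any(short))
    stop("sequence shorter than one codon: ",
         paste(ids[short], collapse = ", "))
  bad <- !grepl(.IUPAC_DNA_RE, seqs)
  if (any(bad))
    stop("non-IUPAC characters in record: ",
         paste(ids[bad], collapse = ", "))
  structure(seqs, class = "cds_set")
}

#' Write a CDS set as FASTA
#'
#' Deterministic writer (fixed line width, `\n` line endings) so that
#' identical inputs always produce byte-identical files.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Quality-filter a CDS set
#'
#' Retains genes whose length is a multiple of 3; optionally also requires a
#' minimum codon count and/or the absence of internal stop codons (both off
#' by default: genome-wide codon surveys conventionally analyze every
#' annotated CDS). Filtering never raises; every rejection is tallied in the
#' report. A gene is counted under the first filter it fails.
#'
#' @param seqs A `cds_set` (or named character vector of DNA sequences).
#' @param min_codons Minimum number of codons (0 disables).
#' @param reject_internal_stops If `TRUE`, drop genes with a stop codon
#'   before the final position.
#' @return A list with `records` (the retained `cds_set`) and `report`, a
#'   list with `n_input`, `n_kept` and `reasons` (named integer vector of
#'   rejection counts; `sum(reasons) == n_input - n_kept`).
#' @export
qc_filter <- function(seqs, min_codons = 0L, reject_internal_stops = FALSE) {
  n_input <- length(seqs)
  reasons <- integer(0)
  keep <- rep(TRUE, n_input)

  fail <- keep & (nchar(seqs) %% 3L != 0L)
  if (any(fail)) reasons["length_not_multiple_of_3"] <- sum(fail)
  keep <- keep & !fail

  if (min_codons > 0L) {
    fail <- keep & (nchar(seqs) %/% 3L < min_codons)
    if (any(fail)) reasons["too_few_codons"] <- sum(fail)
    keep <- keep & !fail
  }

  if (reject_internal_stops) {
    has_internal <- vapply(seqs, function(s) {
      if (nchar(s) %% 3L != 0L) return(FALSE)
      p <- translate_cds(s)
      grepl("\\*", substr(p, 1L, nchar(p) - 1L))
    }, logical(1))
    fail <- keep & has_internal
    if (any(fail)) reasons["internal_stop"] <- sum(fail)
    keep <- keep & !fail
  }

  kept <- seqs[keep]
  class(kept) <- "cds_set"
  list(records = kept,
       report = list(n_input = n_input, n_kept = sum(keep),
                     reasons = reasons))
}

#' Count codons in a coding sequence
#'
#' Tokenizes a sequence into non-overlapping triplets in frame 0. Triplets
#' containing any non-ACGT base are skipped and tallied separately, so
#' `n_codons + n_skipped == nchar(seq) / 3` always holds.
#'
#' @param seq A single nucleotide sequence (DNA or RNA alphabet); length
#'   must be a multiple of 3.
#' @return A `codon_counts` object: list with `counts` (named integer vector
#'   over all 64 RNA codons in lexicographic order), `n_codons` and
#'   `n_skipped`.
#' @examples
#' count_codons("ATGCGCTAA")$counts[c("AUG", "CGC", "UAA")]
#' @export
count_codons <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  L <- nchar(s)
  if (L %% 3L != 0L)
    stop("sequence length (", L, ") is not a multiple of 3")
  starts <- seq.int(1L, L - 2L, by = 3L)
  triplets <- substring(s, starts, starts + 2L)
  ## triplets containing ambiguity letters find no match and are skipped
  v <- tabulate(match(triplets, .CODON_INFO$dna), nbins = 64L)
  names(v) <- .CODONS
  structure(list(counts = v, n_codons = sum(v),
                 n_skipped = L %/% 3L - sum(v)),
            class = "codon_counts")
}

#' Construct a codon-count table
#'
#' @param counts Named numeric vector of codon counts (RNA or DNA alphabet;
#'   duplicate codon names are summed; codons not named get count 0).
#' @param n_skipped Number of codons dropped by QC (ambiguous triplets).
#' @return A `codon_counts` object.
#' @export
new_codon_counts <- function(counts = integer(0), n_skipped = 0L) {
  v <- integer(64L)
  names(v) <- .CODONS
  if (length(counts)) {
    if (is.null(names(counts))) stop("counts must be a named vector")
    nm <- .as_rna_codon(names(counts))
    if (any(counts < 0)) stop("codon counts must be non-negative")
    agg <- tapply(as.integer(round(counts)), nm, sum)
    v[names(agg)] <- as.integer(agg)
  }
  structure(list(counts = v, n_codons = sum(v),
                 n_skipped = as.integer(n_skipped)),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts: ", x$n_codons, " codons (",
      x$n_skipped, " skipped)\n", sep = "")
  used <- x$counts[x$counts > 0]
  if (length(used)) print(utils::head(sort(used, decreasing = TRUE), 10))
  invisible(x)
}

#' Pool codon-count tables
#'
#' Elementwise sum of codon counts; totals and skip counts add. Pooling is
#' associative and commutative, and pooling per-gene tables equals counting
#' the concatenated sequence.
#'
#' @param counts_list List of `codon_counts` objects.
#' @return A single pooled `codon_counts`.
#' @export
pool_counts <- function(counts_list) {
  if (inherits(counts_list, "codon_counts")) counts_list <- list(counts_list)
  if (!length(counts_list)) return(new_codon_counts())
  v <- Reduce(`+`, lapply(counts_list, function(x) x$counts))
  new_codon_counts(v, n_skipped = sum(vapply(counts_list,
                                             function(x) x$n_skipped,
                                             integer(1))))
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code (translation table 1). Stop codons are
#' rendered as `"*"`; codons containing ambiguous bases as `"X"`.
#'
#' @param seq A single nucleotide sequence; length must be a multiple of 3.
#' @return The amino-acid string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
#' @export
translate_cds <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  if (nchar(s) %% 3L != 0L)
    stop("sequence length (", nchar(s), ") is not a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X"))
}

#' Read a codon-count TSV
#'
#' Accepts the two-column `codon`/`count` dialect (RNA or DNA alphabet,
#' `#` comments allowed), as written alongside published codon-usage tables.
#'
#' @param path Path to a TSV with columns `codon` and `count`.
#' @return A `codon_counts` object.
#' @export
read_codon_counts_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("codon", "count") %in% names(df)))
    stop("count table needs 'codon' and 'count' columns: ", path)
  new_codon_counts(stats::setNames(df$count, df$codon))
}

#' Write per-gene codon counts as TSV
#'
#' One row per gene: `gene_id`, the 64 codon columns in fixed lexicographic
#' RNA order, then `n_skipped`.
#'
#' @param counts_list Named list of `codon_counts` (names are gene ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_counts_tsv <- function(counts_list, path) {
  m <- do.call(rbind, lapply(counts_list, function(x) x$counts))
  df <- data.frame(gene_id = names(counts_list), m,
                   n_skipped = vapply(counts_list, function(x) x$n_skipped,
                                      integer(1)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
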