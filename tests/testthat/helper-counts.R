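# Fixtures built in code: random codon-count tables and random CDS.

random_counts <- function(seed, lambda = 20) {
  set.seed(seed)
  new_codon_counts(stats::setNames(stats::rpois(64, lambda),
                                   codon_info()$codon))
}

random_cds <- function(seed, n_codons = 100) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}

syn_codons <- function() {
  ci <- codon_info()
  ci$codon[ci$is_synonymous]
}

# one sense codon per amino-acid family (lexicographically first)
one_codon_per_family <- function() {
  ci <- codon_info()
  ci <- ci[!ci$is_stop, ]
  vapply(split(ci$codon, ci$aa), min, character(1))
}
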