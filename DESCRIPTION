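Package: codonbias
Title: Genome-Wide Codon Usage Bias Analysis from Coding Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide codon usage bias analysis of coding
    sequence (CDS) sets: nucleotide composition at each codon position
    (including synonymous third-position fractions), relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENC), the
    codon adaptation index (CAI), hydropathicity (GRAVY) and aromaticity
    of translated products, neutrality-plot regression of GC12 on GC3,
    comparison of ENC against its mutational null curve, correspondence
    analysis of per-gene RSCU profiles, Spearman correlation of indices,
    and detection of optimal codons by contrasting high- and low-bias
    gene pools. Includes a synthetic CDS simulator with controlled
    mutational GC pressure and translational selection for end-to-end
    validation, and packaged codon-count fixtures from a published
    survey of the entomopathogenic fungus Beauveria bassiana.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
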