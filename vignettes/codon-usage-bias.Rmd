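---
title: "Measuring codon usage bias: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# The problem

Synonymous codons encode the same amino acid but are not used equally. In a
genome, this codon usage bias (CUB) is shaped by two broad forces:
*mutational pressure* (a genome-wide tendency of mutation to push base
composition toward G/C or A/T, felt most clearly at the nearly neutral third
codon position) and *natural selection* (most prominently translational
selection, which favours codons matching the abundant tRNAs in highly
expressed genes). `codonbias` implements the standard genome-wide analysis
that disentangles these forces for a set of coding sequences (CDS), as
routinely applied to fungal genomes such as the entomopathogen *Beauveria
bassiana*: composition statistics, RSCU, Wright's ENC, CAI, GRAVY and
aromaticity per gene, then the neutrality plot, the ENC-GC3s null curve,
correspondence analysis, a Spearman correlation matrix, and optimal-codon
detection from high/low-bias gene pools.

# Conventions shared by every stage

* **Genetic code.** The standard nuclear code (translation table 1), fixed:
  the package targets nuclear CDS sets of organisms using the universal
  code. No alternative code support in this version.
* **Frame and tokenization.** Codons are non-overlapping triplets from
  position 1 (frame 0); no ORF finding or frameshift repair. Triplets
  containing any non-ACGT base are *skipped and counted* (`n_skipped`), not
  imputed — every downstream statistic is count-based, so an imputed codon
  would manufacture evidence. `n_codons + n_skipped = length/3` always
  holds, keeping totals auditable.
* **Stop codons.** Internal stops are not rejected by default (published
  genome-wide codon tables count stop codons like any other codon, and an
  annotated CDS set may legitimately contain read-through or misannotated
  genes; a `reject_internal_stops` flag exists). Stops are counted and get
  a family RSCU of their own, but they never enter ENC, CAI, GC3s or the
  optimal-codon analysis.
* **Alphabets.** Input FASTA may be DNA or RNA, any case; sequences are
  normalized internally to uppercase DNA and all reporting re-emits codons
  in the RNA alphabet, the convention of published codon-usage tables.
* **QC defaults.** Only one filter is on by default: gene length must be a
  multiple of 3. No minimum length is imposed, since genome-wide surveys
  analyze every annotated CDS; `min_codons` exists because ENC is noisy on
  very short genes.

# The indices

## Composition

`composition_profile()` reports G+C fractions overall and at each codon
position (`gc`, `gc1`, `gc2`, `gc3`), `gc12 = (gc1 + gc2)/2`, and the
synonymous third-position fractions. GC-type quantities are computed over
*all* counted codons, stops included; `gc3s` and `a3s`/`t3s`/`c3s`/`g3s`
are computed over the 59 synonymous sense codons only (all sense codons
minus AUG and UGG). `x3s` is defined as the fraction of synonymous codons
whose third base is x, so the four fractions sum to 1 and
`gc3s = c3s + g3s` exactly. (An alternative normalization restricts each
base's denominator to families where that base is usable; it breaks the
sum-to-one identity and is not implemented.) With no synonymous codons the
fields are `NA`, never fabricated zeros. All internal values are fractions;
percent formatting belongs to the report layer.

## RSCU

For codon *j* in a family of size *n* with counts *x*:
`RSCU_j = n * x_j / sum(x)` — observed over expected-under-uniformity.
Family sums equal family sizes whenever the family was observed (a
conservation property the tests exercise on random tables), AUG and UGG are
1 by construction, and unobserved families give `NA`.

## ENC

Wright's effective number of codons. Per family with total `n >= 2`, the
homozygosity is `F = (n * sum(p^2) - 1)/(n - 1)`; with `Fk` the mean over
informative families of degeneracy `k` (families of 2, 3, 4 and 6; the
three 6-fold families Leu, Ser, Arg are kept whole),

```
ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6
```

Numerical choices:

* A family with `n < 2` is uninformative (`F` is undefined at `n = 1`).
* If Ile — the only 3-fold family — is uninformative, `F3 = (F2 + F4)/2`
  (Wright's recommendation). For the other classes the mean is over
  informative families, required to be at least half the class; otherwise
  the gene's ENC is `NA`. This keeps short genes analyzable without letting
  a single noisy family stand in for a whole class.
* Finite-sample noise can push the estimate above 61 (a uniform-usage gene
  does so deterministically, since `F` at equal finite counts exceeds the
  asymptotic `1/k`); such values are capped at 61 and flagged. Published
  surveys reporting a maximum of exactly 61.00 imply the same cap.
* A non-positive class mean (possible at tiny counts, e.g. an even 1/1
  split giving `F = 0` everywhere) leaves ENC undefined rather than
  dividing by zero.

## CAI

`derive_cai_weights()` computes relative adaptiveness
`w = RSCU / max(family RSCU)` on a reference pool, and `compute_cai()` the
geometric mean of `w` over a gene's codons, excluding AUG, UGG and stops.
Because no expression data accompany a genome-wide CDS set, the default
reference is the pooled counts of the 5% of genes with lowest ENC — the
most biased genes, the standard proxy for highly expressed ones — and the
provenance string records exactly that. A user-supplied reference (FASTA or
count TSV) overrides it. Codons absent from the reference receive a floor
weight of 0.01 rather than 0 (log(0) would annihilate the geometric mean on
a single unlucky codon); floored codons are listed in the weights object.

## GRAVY and aromaticity

Mean Kyte-Doolittle hydropathy and the F/Y/W residue fraction of the
translated product, with `*` and `X` dropped first. The hydropathy scale is
embedded as a constant.

# Genome-level analyses

## Neutrality plot

Unweighted OLS of per-gene GC12 on GC3 (a length-weighted variant sits
behind a flag, but the classical analysis weights genes equally), with the
Pearson correlation and its two-sided p-value. The slope is read as the
percent contribution of mutation pressure, the remainder as other factors
(selection, drift, constraint); slope and correlation are invariant to
percent-vs-fraction units.

## ENC vs GC3s

The mutational null curve `ENC_exp(s) = 2 + s + 29/(s^2 + (1-s)^2)` is the
expected ENC of a gene whose third positions are shaped by composition `s`
alone. Genes are annotated with their residual; "below the curve" is simply
`residual < 0` — no tolerance band, since none is standard.

## Correspondence analysis

CA runs on the genes x 59 RSCU matrix (codonW's default "COA on RSCU",
which removes amino-acid-composition effects that a raw-count CA would
conflate with synonymous preference). A gene missing an entire family gets
that family's codons filled with the neutral value 1 — the fill is mass,
not signal — and is flagged. The implementation is the standard SVD of
standardized residuals; row and column principal coordinates are returned,
eigenvalues and inertia fractions reported. Axis signs are not identified,
so each axis is oriented to make its largest-|loading| codon positive;
cross-implementation tests compare up to sign regardless. Zero-mass columns
are dropped; rank-deficient inputs return fewer axes with a flag.

## Spearman matrix

Pairwise-complete Spearman correlations over the standard 16 variables
(length, GC fields, x3s fields, GRAVY, aromaticity, ENC, CAI, the two CA
axes), average ranks for ties, exact permutation p for pair sizes up to 10
(falling back to the approximation when ties preclude exactness), t
approximation above. Reports star raw significance at 0.05/0.01, mirroring
the field's tables; a Benjamini-Hochberg adjustment is the user's to apply
(`stats::p.adjust`) since published matrices report raw stars.

## Optimal codons

Genes are ranked by ENC; the lowest-ENC fraction (default 5%) forms the
high-bias pool, the highest-ENC fraction the low-bias pool, with ties
broken by gene id so partitions are reproducible. Per codon, a 2x2
chi-square (this codon vs rest of family, high vs low pool) with Yates
correction whenever an expected cell is below 5 (Fisher's exact test sits
behind a flag for small fixtures; chi-square is the default for
genome-scale counts). A codon is *optimal* when `RSCU_high > 1`,
`delta RSCU >= 0.08` and `p < 0.01` — the conventional criterion; all three
thresholds are configurable. The 5% default pool fraction was chosen
because, applied to a ~10,000-gene fungal CDS set, it produces pool codon
totals of the magnitude published surveys report; it is a first-class
config value recorded in the manifest.

# The synthetic-data generator

`simulate_genome()` exists so every stage can be validated against known
ground truth without any genome download. Its model:

* **Lengths** log-normal, median 300 codons, sigma 0.4 — a realistic
  fungal CDS length distribution.
* **Mutational pressure**: per gene, a third-position G/C probability `m`
  drawn from Beta(12, 6) (mean 2/3, sd ~0.11), matching the GC3s mean and
  spread of a GC-rich ascomycete gene set. Within a family, the drawn
  G/C-vs-A/U outcome selects uniformly among compatible codons. Ile has no
  G-ending codon, so its G/C outcome collapses onto AUC and its A/U outcome
  splits over AUU/AUA; third-position composition targets stay exact at the
  cost of a predictable within-family skew (RSCU(AUC) tends to `3m`), which
  the tests assert rather than pretend away.
* **Selection**: a fraction (default 10%) of genes is highly expressed;
  each of their codons is independently replaced by the family's preferred
  codon with probability `s` (default 0.5). The default preferred set is
  the C-ending (else G-ending) codon of each degenerate family, emulating
  the G/C-ending optima of GC-rich genomes.
* **Position coupling** `k` tilts a gene's amino-acid frequencies toward
  residues with G/C-rich first/second codon positions in proportion to
  `m`, inducing a neutrality slope that is 0 at `k = 0` and increases
  monotonically in `k`; the default 0.12 produces the weak mutational
  slope scale typical of such genomes. This is a deliberate caricature:
  real GC12-GC3 coupling arises from mutation acting on all positions,
  not from amino-acid composition shifts, so only the regression's
  *behaviour* (slope recovery, monotonicity), not its biological pathway,
  is being validated.
* **Determinism**: one global seed; each gene's draws come from a
  counter-based substream, so growing `n_genes` never reshuffles earlier
  genes, and identical specs give byte-identical FASTA.

What the generator does *not* emulate: amino-acid composition differences
between real proteomes and the uniform default, codon-pair and
dinucleotide effects, within-gene composition gradients, isochores, or
phylogenetic correlation among genes. Tests passing on this model therefore
validate the estimators and the pipeline plumbing, not any biological claim
about a particular genome.

Packaged alongside the generator are two plain-text count fixtures
transcribed from a published genome-wide codon-usage survey of *B.
bassiana* (10,363 CDS): the pooled 64-codon table and the high/low-bias
pool counts from its optimal-codon table. Two garbled cells in the source's
low-pool column are stored under their natural reading and flagged
`ambiguous`, and assertions exclude them. These fixtures let the RSCU and
optimal-codon machinery be checked against printed values exactly.

# Problem sizes and runtime

The shipped tests run the generator at 200-500 genes (median 300 codons)
for the statistical recovery checks and 10,000 random count tables for the
conservation/bounds sweeps; the full pipeline test uses 40-150 genes.
These sizes give the law-of-large-numbers assertions comfortable margins
(e.g. pooled-RSCU noise ~0.04 sd against a 0.1 tolerance) while keeping
the whole suite under a minute. The pipeline itself handles a 10,000-gene
genome in well under ten minutes on one core; memory is dominated by the
genes x 59 RSCU matrix.

# Known limitations

* Single genetic code; no ORF extraction from genomic coordinates.
* The ENC missing-class policy, while close to codonW's behaviour, is one
  of several defensible choices; genes near the informativeness threshold
  can differ from other tools in the second decimal.
* The automatic CAI reference (lowest-ENC pool) is a proxy; with real
  expression data a user-supplied reference is strictly better.
* The exact Spearman p-value is only available without ties at small n;
  tied small-sample pairs silently use the approximation.
* CA coordinates are comparable across runs only up to the documented sign
  convention.
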