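## Static codon metadata shared by every module. All reporting uses the RNA
## alphabet (AUG, CUC, ...); sequences are handled internally as DNA.

.RNA_BASES <- c("A", "C", "G", "U")

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

## Kyte-Doolittle hydropathy scale.
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

.AROMATIC <- c("F", "Y", "W")

.build_codon_info <- function() {
  ## expand.grid varies its first factor fastest, so listing p3 first yields
  ## codons in lexicographic RNA order (A < C < G < U), the fixed order used
  ## by every count vector in the package.
  g <- expand.grid(p3 = .RNA_BASES, p2 = .RNA_BASES, p1 = .RNA_BASES,
                   stringsAsFactors = FALSE)
  codon <- paste0(g$p1, g$p2, g$p3)
  dna <- chartr("U", "T", codon)
  aa <- unname(Biostrings::GENETIC_CODE[dna])
  fam <- as.integer(ave(rep(1L, 64L), aa, FUN = sum))
  info <- data.frame(
    codon = codon, dna = dna, aa = aa,
    amino_acid = unname(.AA3[aa]),
    p1 = g$p1, p2 = g$p2, p3 = g$p3,
    family_size = fam,
    is_stop = aa == "*",
    stringsAsFactors = FALSE
  )
  ## 59 synonymous sense codons: all sense codons minus AUG and UGG.
  info$is_synonymous <- !info$is_stop & info$family_size > 1L
  info
}

.CODON_INFO <- .build_codon_info()
.CODONS <- .CODON_INFO$codon
.SYN_CODONS <- .CODON_INFO$codon[.CODON_INFO$is_synonymous]

## Sense amino acids grouped by synonymous-family degeneracy, the classes of
## Wright's ENC estimator (6-fold families kept whole, not split 2 + 4).
.ENC_CLASSES <- list(
  `2` = c("C", "D", "E", "F", "H", "K", "N", "Q", "Y"),
  `3` = "I",
  `4` = c("A", "G", "P", "T", "V"),
  `6` = c("L", "R", "S")
)

## precomputed masks for the per-gene hot paths
.FAM_INT <- as.integer(factor(.CODON_INFO$aa, levels = unique(.CODON_INFO$aa)))
.GC_P <- lapply(c(p1 = "p1", p2 = "p2", p3 = "p3"),
                function(p) .CODON_INFO[[p]] %in% c("G", "C"))
.SYN_MASK <- .CODON_INFO$is_synonymous
.SYN_P3 <- lapply(c(A = "A", U = "U", C = "C", G = "G"),
                  function(b) .SYN_MASK & .CODON_INFO$p3 == b)

## per ENC class: codon indices of each family, precomputed for the per-gene
## hot path
.ENC_FAM_IDX <- lapply(.ENC_CLASSES, function(aas)
  lapply(aas, function(a) which(.CODON_INFO$aa == a & !.CODON_INFO$is_stop)))

#' Codon metadata table
#'
#' Static per-codon metadata used throughout the package: the standard
#' nuclear genetic code (translation table 1), codon family sizes, and
#' position-wise bases.
#'
#' @return A 64-row data frame in lexicographic RNA-codon order with columns
#'   `codon` (RNA alphabet), `dna`, `aa` (one-letter, `"*"` for stops),
#'   `amino_acid` (three-letter), `p1`/`p2`/`p3` (bases at the three codon
#'   positions), `family_size` (synonymous-family degeneracy; the stop family
#'   has size 3), `is_stop`, and `is_synonymous` (`TRUE` for the 59 sense
#'   codons belonging to degenerate families, i.e. excluding AUG and UGG).
#' @examples
#' ci <- codon_info()
#' table(ci$family_size[!ci$is_stop])
#' @export
codon_info <- function() .CODON_INFO

.as_rna_codon <- function(x) {
  x <- chartr("T", "U", toupper(x))
  bad <- !(x %in% .CODONS)
  if (any(bad))
    stop("not valid codons: ", paste(unique(x[bad]), collapse = ", "))
  x
}
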