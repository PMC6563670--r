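test_that("RSCU reproduces printed arginine and glycine values", {
  arg <- new_codon_counts(c(CGU = 44390, CGC = 125865, CGA = 47855,
                            CGG = 40937, AGA = 36237, AGG = 29101))
  rs <- compute_rscu(arg)
  expect_equal(round(rs$rscu[rs$codon == "CGC"], 2), 2.33)

  gly <- new_codon_counts(c(GGU = 72400, GGC = 192920, GGA = 52839,
                            GGG = 39116))
  rs <- compute_rscu(gly)
  expect_equal(round(rs$rscu[rs$codon == "GGC"], 2), 2.16)
})

test_that("uniform within-family usage gives RSCU 1 everywhere", {
  cc <- new_codon_counts(stats::setNames(rep(7, 64), codon_info()$codon))
  rs <- compute_rscu(cc)
  expect_equal(rs$rscu, rep(1, 64))
})

test_that("RSCU family sums equal family sizes on arbitrary random counts", {
  for (seed in 1:20) {
    cc <- random_counts(seed, lambda = sample(1:40, 1))
    rs <- compute_rscu(cc)
    sums <- tapply(rs$rscu, rs$aa, sum)
    sizes <- tapply(rs$family_size, rs$aa, unique)
    defined <- !is.na(sums)
    expect_equal(as.numeric(sums[defined]), as.numeric(sizes[defined]),
                 tolerance = 1e-12)
    expect_true(all(rs$rscu >= 0, na.rm = TRUE))
  }
  # zero-count family yields NA, observed single-codon families yield 1
  cc <- new_codon_counts(c(AUG = 3, UUU = 1, UUC = 3))
  rs <- compute_rscu(cc)
  expect_equal(rs$rscu[rs$codon == "AUG"], 1)
  expect_true(is.na(rs$rscu[rs$codon == "GGG"]))
})

test_that("ENC hits its theoretical limits", {
  uniform <- new_codon_counts(stats::setNames(rep(10, 64), codon_info()$codon))
  e <- compute_enc(uniform)
  expect_equal(e$enc, 61)
  expect_true(e$capped)  # finite-sample homozygosity overshoots, then caps

  one <- one_codon_per_family()
  biased <- new_codon_counts(stats::setNames(rep(5, length(one)), one))
  e <- compute_enc(biased)
  expect_equal(e$enc, 20)
  expect_equal(unname(e$fbar), rep(1, 4))
})

test_that("ENC matches a direct evaluation of Wright's formula", {
  # 200-codon gene with fixed per-family counts; oracle computed in place
  cc <- random_counts(31, lambda = 3)
  ci <- codon_info()
  v <- cc$counts
  fam_F <- sapply(split(seq_len(64)[!ci$is_stop], ci$aa[!ci$is_stop]),
                  function(idx) {
                    n <- sum(v[idx])
                    if (n < 2 || length(idx) == 1) return(NA_real_)
                    p <- v[idx] / n
                    (n * sum(p^2) - 1) / (n - 1)
                  })
  size <- sapply(split(ci$family_size[!ci$is_stop], ci$aa[!ci$is_stop]), unique)
  fbar <- sapply(c(2, 3, 4, 6), function(k)
    mean(fam_F[size == k], na.rm = TRUE))
  oracle <- 2 + 9 / fbar[1] + 1 / fbar[2] + 5 / fbar[3] + 3 / fbar[4]
  e <- compute_enc(cc)
  expect_equal(e$enc_raw, oracle, tolerance = 1e-9)
})

test_that("concentrating a family's counts never increases ENC", {
  base <- random_counts(5, lambda = 15)
  e0 <- compute_enc(base)$enc_raw
  # move all Gly counts onto GGC, totals fixed
  v <- base$counts
  gly <- c("GGU", "GGC", "GGA", "GGG")
  v["GGC"] <- sum(v[gly]); v[setdiff(gly, "GGC")] <- 0L
  e1 <- compute_enc(new_codon_counts(v))$enc_raw
  expect_lte(e1, e0)
  # and concentrating a 2-fold family too
  v["UAC"] <- v["UAC"] + v["UAU"]; v["UAU"] <- 0L
  e2 <- compute_enc(new_codon_counts(v))$enc_raw
  expect_lte(e2, e1)
})

test_that("ENC bounds are respected across many random genes", {
  encs <- vapply(1:500, function(seed) {
    e <- compute_enc(random_counts(seed, lambda = sample(2:30, 1)))
    if (is.na(e$enc)) return(NA_real_)
    expect_true(e$enc <= 61 && e$enc >= 20)
    if (e$capped) expect_gt(e$enc_raw, 61)
    e$enc
  }, numeric(1))
  expect_true(any(!is.na(encs)))
})

test_that("ENC missing-class fallback keeps Ile-free genes analyzable", {
  # all families present except Ile
  v <- stats::setNames(rep(4L, 64), codon_info()$codon)
  v[c("AUU", "AUC", "AUA")] <- 0L
  e <- compute_enc(new_codon_counts(v))
  expect_false(is.na(e$enc))
  expect_equal(unname(e$fbar["3"]),
               unname((e$fbar["2"] + e$fbar["4"]) / 2))
  # a gene with only one family has no defined ENC
  e2 <- compute_enc(new_codon_counts(c(GGA = 10, GGC = 10)))
  expect_true(is.na(e2$enc))
})

test_that("CAI weights: uniform reference gives w = 1, zero counts get the floor", {
  uniform <- new_codon_counts(stats::setNames(rep(9, 64), codon_info()$codon))
  w <- derive_cai_weights(uniform)
  expect_equal(unname(w$w), rep(1, 59))

  t3 <- table3_fixture()
  w3 <- derive_cai_weights(t3)
  rs <- compute_rscu(t3)
  r <- function(cod) rs$rscu[rs$codon == cod]
  expect_equal(w3$w[["CGC"]], 1)
  expect_equal(w3$w[["AGG"]], r("AGG") / r("CGC"), tolerance = 1e-12)

  v <- t3$counts; v["CGG"] <- 0L
  wf <- derive_cai_weights(new_codon_counts(v))
  expect_equal(wf$w[["CGG"]], 0.01)
  expect_true("CGG" %in% wf$floored)
  expect_error(derive_cai_weights(new_codon_counts()), "empty")
})

test_that("CAI is the geometric mean of weights and is length-invariant", {
  t3 <- table3_fixture()
  w <- derive_cai_weights(t3)
  # all-preferred gene: only codons with w == 1
  pref <- names(w$w)[w$w == 1]
  g <- new_codon_counts(stats::setNames(rep(3, length(pref)), pref))
  expect_equal(compute_cai(g, w), 1)

  # constant-weight reference: every w = 0.5 except family maxima
  wc <- w; wc$w[] <- 0.5
  expect_equal(compute_cai(random_counts(2), wc), 0.5)

  # log-sum oracle on a random gene
  g2 <- random_counts(13)
  v <- g2$counts[names(w$w)]
  oracle <- prod(w$w ^ (v / sum(v)))
  expect_equal(compute_cai(g2, w), oracle, tolerance = 1e-12)

  # doubling all counts leaves CAI unchanged
  doubled <- pool_counts(list(g2, g2))
  expect_equal(compute_cai(doubled, w), compute_cai(g2, w), tolerance = 1e-12)

  # no contributing codons -> NA
  expect_equal(compute_cai(new_codon_counts(c(AUG = 5)), w), NA_real_)
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(compute_gravy("III"), 4.5)
  expect_equal(compute_gravy("IR"), 0)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  set.seed(4)
  p <- paste(sample(names(kd), 100, replace = TRUE), collapse = "")
  expect_equal(compute_gravy(p),
               mean(kd[strsplit(p, "")[[1]]]), tolerance = 1e-12)
  expect_true(is.na(compute_gravy("*X")))
})

test_that("aromaticity is the F/Y/W fraction", {
  expect_equal(compute_aromo("FFFF"), 1)
  expect_equal(compute_aromo("GGGG"), 0)
  expect_equal(compute_aromo("FYWG"), 0.75)
  expect_equal(compute_aromo("MFYW*"), 0.75)  # stop dropped before counting
})

test_that("per-gene index table is complete and internally consistent", {
  sim <- simulate_genome(40, seed = 19)
  idx <- compute_gene_indices(sim$records)
  expect_equal(nrow(idx), 40L)
  expect_equal(idx$gene_id, names(sim$records))
  expect_equal(idx$length_nt, unname(nchar(sim$records)))
  # stop codon included in counts, so length_codons = truth + 1
  expect_equal(idx$length_codons, sim$truth$length_codons + 1L)
  expect_true(all(idx$cai > 0 & idx$cai <= 1, na.rm = TRUE))
  expect_true(all(idx$aromo >= 0 & idx$aromo <= 1))
  expect_true(all(is.na(idx$axis1)))
  w <- attr(idx, "cai_weights")
  expect_match(w$provenance, "lowest-ENC")
})
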