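test_that("neutrality regression recovers the trivial limits", {
  set.seed(1)
  gc3 <- runif(30, 0.2, 0.9)
  fit <- neutrality_regression(gc3, gc3)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$mutation_pct, 100, tolerance = 1e-9)

  flat <- neutrality_regression(rep(0.5, 30), gc3)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$other_pct, 100, tolerance = 1e-9)

  degenerate <- neutrality_regression(gc3, rep(0.5, 30))
  expect_true(is.na(degenerate$slope))
})

test_that("neutrality regression recovers a planted slope from noisy data", {
  set.seed(42)
  gc3 <- runif(50, 0.2, 0.9)
  gc12 <- 0.3 * gc3 + rnorm(50, sd = 0.01)
  fit <- neutrality_regression(gc12, gc3)
  expect_gt(fit$slope, 0.25); expect_lt(fit$slope, 0.35)
  expect_equal(fit$mutation_pct + fit$other_pct, 100)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)

  # scale consistency: percent units leave slope and r unchanged
  fit_pct <- neutrality_regression(100 * gc12, 100 * gc3)
  expect_equal(fit_pct$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit_pct$pearson_r, fit$pearson_r, tolerance = 1e-12)
})

test_that("expected ENC null curve matches its closed form", {
  expect_equal(expected_enc_curve(0.5), 60.5)
  s <- seq(0.01, 0.99, length.out = 99)
  oracle <- 2 + s + 29 / (s^2 + (1 - s)^2)
  expect_equal(expected_enc_curve(s), oracle, tolerance = 1e-12)
  # symmetry identity: f(s) - f(1-s) = 2s - 1
  expect_equal(expected_enc_curve(s) - expected_enc_curve(1 - s), 2 * s - 1,
               tolerance = 1e-12)
  expect_error(expected_enc_curve(0), "inside")
  expect_error(expected_enc_curve(1.2), "inside")
})

test_that("enc_plot_data flags genes below the null curve", {
  idx <- data.frame(gene_id = c("a", "b", "c"),
                    gc3s = c(0.5, 0.5, NA),
                    enc = c(61, 45, 50))
  ep <- enc_plot_data(idx)
  expect_equal(ep$expected_enc[1:2], c(60.5, 60.5))
  expect_equal(ep$below_curve[1:2], c(FALSE, TRUE))
  expect_true(is.na(ep$expected_enc[3]))
})

test_that("identical RSCU rows give zero inertia and zero coordinates", {
  m <- matrix(rep(c(2, 1, 3), each = 4), nrow = 4)
  ca <- correspondence_analysis(m)
  expect_equal(ca$n_axes, 0L)
  expect_true(all(ca$row_coords == 0))
  expect_true(ca$rank_deficient)
})

test_that("CA axis 1 separates two planted codon-preference clusters", {
  sim_a <- simulate_genome(10, selection = 1, selected_fraction = 1, seed = 2)
  sim_b <- simulate_genome(10, selection = 0, selected_fraction = 0,
                           gc3_alpha = 2, gc3_beta = 8, seed = 3)
  recs <- c(unclass(sim_a$records),
            stats::setNames(unclass(sim_b$records), paste0("b", 1:10)))
  counts <- lapply(recs, count_codons)
  m <- rscu_matrix(counts)
  ca <- correspondence_analysis(m)
  ax1 <- ca$row_coords[, 1]
  expect_true(all(sign(ax1[1:10]) == sign(ax1[1])))
  expect_true(all(sign(ax1[11:20]) == -sign(ax1[1])))
})

test_that("CA row coordinates agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- matrix(rexp(10 * 59), 10, 59)
  ca <- correspondence_analysis(x)
  cr <- suppressWarnings(MASS::corresp(x, nf = 2))
  pc <- cr$rscore %*% diag(cr$cor)
  for (j in 1:2) {
    agree <- min(max(abs(ca$row_coords[, j] - pc[, j])),
                 max(abs(ca$row_coords[, j] + pc[, j])))
    expect_lt(agree, 1e-8)
  }
})

test_that("CA operates on profiles: proportional rows share coordinates", {
  set.seed(9)
  x <- matrix(rexp(8 * 20), 8, 20)
  x <- rbind(x, 7.5 * x[3, ])  # same profile, different mass
  ca <- correspondence_analysis(x)
  expect_equal(ca$row_coords[9, ], ca$row_coords[3, ], tolerance = 1e-12)
})

test_that("rscu_matrix fills absent families with the neutral value 1", {
  counts <- list(g1 = new_codon_counts(c(UUU = 3, UUC = 5, GGA = 2)),
                 g2 = random_counts(1), g3 = random_counts(2))
  m <- rscu_matrix(counts)
  expect_equal(dim(m), c(3L, 59L))
  expect_equal(unname(m["g1", "CGC"]), 1)  # Arg absent from g1
  expect_true("g1" %in% attr(m, "filled"))
  expect_false(anyNA(m))
})

test_that("spearman matrix matches rank-then-Pearson brute force", {
  set.seed(12)
  df <- as.data.frame(matrix(rnorm(30 * 5), 30, 5))
  df$V5 <- -df$V1  # planted perfect anticorrelation
  cm <- spearman_matrix(df)
  expect_equal(unname(diag(cm$rho)), rep(1, 5))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$rho["V1", "V5"], -1)
  brute <- stats::cor(apply(df, 2, rank))
  expect_equal(unname(cm$rho), unname(brute), tolerance = 1e-12)
  expect_true(all(abs(cm$rho) <= 1))
  # t-approximation p-value oracle for one pair
  r <- cm$rho["V1", "V2"]; n <- 30
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cm$p["V1", "V2"], 2 * stats::pt(-abs(tt), n - 2),
               tolerance = 1e-12)
})

test_that("zero-variance variables are marked NA, and stars format correctly", {
  set.seed(3)
  df <- data.frame(a = rnorm(20), b = rnorm(20), c = rep(1, 20))
  cm <- spearman_matrix(df)
  expect_true(is.na(cm$rho["a", "c"]))
  fm <- format_correlation(cm)
  expect_equal(fm["c", "a"], "NA")
  strong <- spearman_matrix(data.frame(x = 1:20, y = (1:20)^2))
  expect_match(format_correlation(strong)["y", "x"], "^1\\.000\\*\\*$")
})

test_that("ENC couples strongly to CA axis 1 on selection-structured data", {
  sim <- simulate_genome(150, selection = 0.9, selected_fraction = 0.3,
                         seed = 44)
  idx <- compute_gene_indices(sim$records)
  idx <- add_ca_axes(idx)
  rho <- stats::cor(idx$enc, idx$axis1, method = "spearman",
                    use = "complete.obs")
  expect_gt(abs(rho), 0.5)
})
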