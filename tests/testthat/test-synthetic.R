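test_that("generation is bit-identical under the same spec and seed", {
  spec <- synthetic_spec(n_drugs = 50, n_proteins = 40, n_cells = 600)
  d1 <- generate_dti(spec, seed = 4)
  d2 <- generate_dti(spec, seed = 4)
  expect_identical(d1$cells, d2$cells)
  expect_identical(d1$U, d2$U)
  d3 <- generate_dti(spec, seed = 5)
  expect_false(identical(d1$cells, d3$cells))
})

test_that("without biases and interactions labels are coin flips at pos_fraction", {
  spec <- synthetic_spec(n_drugs = 80, n_proteins = 60, n_cells = 4000,
                         bias_scale = 0, interaction_scale = 0,
                         pos_fraction = 0.3, curation = 0)
  ds <- generate_dti(spec, seed = 2)
  expect_lt(abs(mean(ds$cells$value) - 0.3), 0.03)
  # labels carry no entity structure: polarization stays near the
  # few-cells-per-entity baseline of independent coins
  drug_counts <- table(ds$cells$row)
  expect_gt(mean(drug_counts), 10)
  expect_lt(polarization_report(ds$cells)$overall, 0.3)
})

test_that("the realized positive fraction is calibrated", {
  frs <- vapply(1:5, function(s)
    mean(generate_dti(synthetic_spec(n_cells = 6000), seed = s)$cells$value),
    numeric(1))
  expect_true(all(abs(frs - 0.5) < 0.02))
  fr2 <- mean(generate_dti(synthetic_spec(n_cells = 6000,
                                          pos_fraction = 0.25),
                           seed = 9)$cells$value)
  expect_lt(abs(fr2 - 0.25), 0.02)
})

test_that("polarization increases with bias_scale and hits the curated regime", {
  pols <- vapply(c(0, 1, 3, 6), function(b) {
    mean(vapply(1:3, function(s)
      polarization_report(generate_dti(polarized_spec(bias_scale = b),
                                       seed = s)$cells)$overall, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(pols) >= -0.02))  # monotone up to seed noise
  expect_gt(pols[4], 0.9)
  # the polarized preset reproduces ~94% single-label entities
  pol <- mean(vapply(1:5, function(s)
    polarization_report(generate_dti(polarized_spec(), seed = s)$cells)$overall,
    numeric(1)))
  expect_lt(abs(pol - 0.94), 0.03)
})

test_that("affinity generation matches its closed-form moments", {
  spec <- synthetic_spec(n_drugs = 100, n_proteins = 100, n_cells = 10000,
                         noise_sd = 0.8)
  ds <- generate_affinity(spec, seed = 6)
  # the oracle predictor (true mean) achieves MSE ~ noise_sd^2
  expect_lt(abs(mse(ds$truth_mean, ds$cells$value) - 0.64), 0.05)
  # noiseless data is perfectly concordant with the oracle predictor
  ds0 <- generate_affinity(synthetic_spec(n_drugs = 40, n_proteins = 30,
                                          n_cells = 500, noise_sd = 0),
                           seed = 7)
  expect_equal(concordance_index(ds0$cells$value, ds0$truth_mean), 1)
  # overwhelming noise drives the oracle's CI toward chance
  dsn <- generate_affinity(synthetic_spec(n_drugs = 60, n_proteins = 50,
                                          n_cells = 3000, noise_sd = 500),
                           seed = 8)
  expect_lt(abs(concordance_index(dsn$cells$value, dsn$truth_mean) - 0.5),
            0.05)
})

test_that("derived similarities are symmetric, bounded and latent-faithful", {
  X <- withr_seed(3, matrix(rnorm(60 * 4), 60, 4))
  S <- derive_similarity(X, noise_sd = 0.05, seed = 4)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(S >= 0 & S <= 1))
  S0 <- derive_similarity(X)
  expect_equal(unname(diag(S0)), rep(1, 60))
  # similarity decreases with latent distance
  d <- as.matrix(dist(X))
  off <- upper.tri(d)
  expect_lt(cor(S[off], d[off], method = "spearman"), -0.3)
})

test_that("derived annotations cover every entity and respect n_terms", {
  X <- withr_seed(5, matrix(rnorm(50 * 3), 50, 3))
  A <- derive_annotations(X, n_terms = 6, seed = 6)
  expect_equal(dim(A), c(50, 6))
  expect_true(all(rowSums(A) >= 1))
  A1 <- derive_annotations(X, n_terms = 1, seed = 7)
  expect_equal(ncol(A1), 1)
  expect_true(all(A1 == 1))
})

test_that("synthetic datasets write the standard TSV interchange files", {
  ds <- generate_dti(synthetic_spec(n_drugs = 20, n_proteins = 15,
                                    n_cells = 80), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir, n_terms = 4)
  inter <- read_interactions(paths[["interactions"]])
  expect_equal(nrow(inter$cells), 80)
  S <- read_similarity(paths[["drug_similarity"]], inter$drug_ids)
  expect_equal(dim(S), rep(length(inter$drug_ids), 2L))
  ann <- read_annotations(paths[["annotations"]])
  expect_true(all(names(ann) %in% sprintf("P%04d", 1:15)))
})
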