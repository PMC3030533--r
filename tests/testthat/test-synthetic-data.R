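test_that("noiseless module members are perfectly correlated", {
  ds <- generate_dataset(n_genes = 30, n_tfs = 5, n_conditions = 40,
                         n_experiments = 2, n_modules = 2,
                         module_size_range = c(5, 6), n_motifs = 6,
                         motifs_per_module = 2, background_motif_rate = 0,
                         noise_sd = 0, missing_rate = 0, seed = 3)
  for (mod in ds$truth$modules) {
    vals <- ds$expr$values[mod$members, ]
    P <- stats::cor(t(vals))
    S <- stats::cor(apply(vals, 1, rank))
    expect_true(all(abs(P - 1) < 1e-12))
    expect_true(all(abs(S - 1) < 1e-12))
    # members all carry the planted combination
    expect_true(all(ds$motifs$values[mod$members, mod$motifs] == 1L))
  }
})

test_that("refitting the regression on emitted matrices recovers cross-term sign", {
  ds <- generate_dataset(n_genes = 30, n_tfs = 6, n_conditions = 100,
                         n_experiments = 2, n_modules = 1,
                         module_size_range = c(5, 5), n_motifs = 4,
                         motifs_per_module = 1, background_motif_rate = 0,
                         interaction_mix = c(synergistic = 0,
                                             competitive = 1, none = 0),
                         mechanism_orders = 2, noise_sd = 0.1,
                         missing_rate = 0, seed = 11)
  mod <- ds$truth$modules[[1]]
  expect_true(all(mod$beta_cross < 0))
  prof <- concatenated_module_profile(mod$members, ds$expr, ds$tf_expr)
  fit <- fit_regression_mechanism(prof$response,
                                  prof$tf_matrix[, mod$tfs, drop = FALSE])
  cross <- fit$coefficients[names(mod$beta_cross)]
  expect_true(all(sign(cross) == sign(mod$beta_cross)))
})

test_that("generation is reproducible from the seed", {
  a <- generate_dataset(n_genes = 25, n_tfs = 4, n_conditions = 30,
                        n_experiments = 2, n_modules = 2,
                        module_size_range = c(5, 5), n_motifs = 5,
                        motifs_per_module = 1, noise_sd = 0.3,
                        missing_rate = 0.1, seed = 42)
  b <- generate_dataset(n_genes = 25, n_tfs = 4, n_conditions = 30,
                        n_experiments = 2, n_modules = 2,
                        module_size_range = c(5, 5), n_motifs = 5,
                        motifs_per_module = 1, noise_sd = 0.3,
                        missing_rate = 0.1, seed = 42)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$tf_expr$values, b$tf_expr$values)
  expect_identical(a$motifs$values, b$motifs$values)
  d <- generate_dataset(n_genes = 25, n_tfs = 4, n_conditions = 30,
                        n_experiments = 2, n_modules = 2,
                        module_size_range = c(5, 5), n_motifs = 5,
                        motifs_per_module = 1, noise_sd = 0.3,
                        missing_rate = 0.1, seed = 43)
  expect_false(identical(a$expr$values, d$expr$values))
})

test_that("experiment labels form contiguous near-equal blocks", {
  ds <- generate_dataset(n_genes = 25, n_tfs = 4, n_conditions = 50,
                         n_experiments = 5, n_modules = 2,
                         module_size_range = c(5, 5), n_motifs = 5,
                         motifs_per_module = 1, seed = 1)
  labs <- unname(experiments(ds$expr))
  expect_identical(labs, labs[order(match(labs, unique(labs)))])  # contiguous
  expect_true(max(table(labs)) - min(table(labs)) <= 1)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(generate_dataset(n_conditions = 10), "n_conditions")
  expect_error(generate_dataset(module_size_range = c(3, 6)), ">= 5")
  expect_error(generate_dataset(missing_rate = 1), "missing_rate")
  expect_error(generate_dataset(n_modules = 10, n_motifs = 5,
                                motifs_per_module = 2), "too small")
})

test_that("homolog map honours dropout and conserved modules transfer exactly", {
  ds <- generate_dataset(n_genes = 30, n_tfs = 5, n_conditions = 40,
                         n_experiments = 2, n_modules = 2,
                         module_size_range = c(5, 6), n_motifs = 6,
                         motifs_per_module = 2, background_motif_rate = 0,
                         noise_sd = 0, missing_rate = 0, seed = 5)
  tr <- generate_homolog_map(ds, dropout_rate = 0, seed = 8)
  expect_length(tr$map, 35L)  # all genes + TFs mapped
  # noiseless conserved module: target members equal the latent profile,
  # so carried-over mechanisms predict with correlation 1
  for (tm in tr$target_truth) {
    mech <- list(tfs = tm$tfs,
                 coefficients = c("(Intercept)" = tm$beta0, tm$beta,
                                  tm$beta_cross))
    rho <- mechanism_prediction_correlation(mech, tm$members,
                                            tr$target_expr, tr$target_tf_expr)
    expect_gt(rho, 1 - 1e-12)
  }
  empty <- generate_homolog_map(ds, dropout_rate = 1, seed = 8)
  expect_length(empty$map, 0L)
})

test_that("rewired modules get regulators disjoint from their source set", {
  ds <- generate_dataset(n_genes = 30, n_tfs = 8, n_conditions = 40,
                         n_experiments = 2, n_modules = 2,
                         module_size_range = c(5, 6), n_motifs = 6,
                         motifs_per_module = 2, mechanism_orders = c(2, 2),
                         seed = 9)
  tr <- generate_homolog_map(ds, conserved = c(FALSE, FALSE), seed = 10)
  for (i in 1:2) {
    src_tfs <- ds$truth$modules[[i]]$tfs
    tgt_tfs <- sub("^at_", "", tr$target_truth[[i]]$tfs)
    expect_length(intersect(src_tfs, tgt_tfs), 0L)
  }
})
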