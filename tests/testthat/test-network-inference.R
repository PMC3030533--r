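make_profile_fixture <- function(n_genes = 2, n_cond = 10, seed = 1) {
  set.seed(seed)
  cond <- sprintf("c%02d", seq_len(n_cond))
  expr <- make_expr(matrix(rnorm(n_genes * n_cond), n_genes, n_cond,
                           dimnames = list(paste0("g", seq_len(n_genes)),
                                           cond)))
  tfe <- make_expr(matrix(rnorm(2 * n_cond), 2, n_cond,
                          dimnames = list(c("tfA", "tfB"), cond)))
  list(expr = expr, tf = tfe)
}

test_that("concatenated profiles tile TF predictors and drop missing rows", {
  fx <- make_profile_fixture()
  prof <- concatenated_module_profile(c("g1", "g2"), fx$expr, fx$tf)
  expect_length(prof$response, 20L)
  expect_identical(prof$tf_matrix[1:10, "tfA"], prof$tf_matrix[11:20, "tfA"])
  expect_identical(prof$condition[1:10], prof$condition[11:20])

  # 3 missing responses in one gene
  fx2 <- make_profile_fixture(seed = 2)
  fx2$expr$values["g1", 1:3] <- NA
  prof2 <- concatenated_module_profile(c("g1", "g2"), fx2$expr, fx2$tf)
  expect_length(prof2$response, 17L)

  # one TF missing at a condition drops that condition for all genes
  fx3 <- make_profile_fixture(seed = 3)
  fx3$tf$values["tfB", "c04"] <- NA
  prof3 <- concatenated_module_profile(c("g1", "g2"), fx3$expr, fx3$tf)
  expect_length(prof3$response, 18L)
  expect_false("c04" %in% prof3$condition)
})

test_that("least squares interpolates noiseless mechanisms exactly", {
  set.seed(5)
  t1 <- rnorm(60); t2 <- rnorm(60)
  X <- cbind(tfA = t1, tfB = t2)
  y <- 1 + 2 * t1 - t2 + 0.5 * t1 * t2
  fit <- fit_regression_mechanism(y, X)
  expect_equal(unname(fit$coefficients[c("(Intercept)", "tfA", "tfB",
                                         "tfA:tfB")]),
               c(1, 2, -1, 0.5), tolerance = 1e-8)
  fit1 <- fit_regression_mechanism(3 * t1, cbind(tfA = t1))
  expect_equal(unname(fit1$coefficients), c(0, 3), tolerance = 1e-10)
  expect_error(fit_regression_mechanism(y, cbind(tfA = t1, tfA2 = t1)),
               "rank-deficient")
})

test_that("T-statistics are calibrated on noise-only responses", {
  hits <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    X <- cbind(tfA = rnorm(400))
    y <- rnorm(400)
    fit <- fit_regression_mechanism(y, X)
    crit <- qt(0.975, fit$df_residual)
    if (abs(fit$t_stats[["tfA"]]) < crit) hits <- hits + 1L
  }
  # nominal 95% coverage: central binomial band at n = 40
  expect_gte(hits, qbinom(0.005, n_seeds, 0.95))
})

test_that("cross-validated correlation separates signal from noise and is deterministic", {
  set.seed(11)
  n_cond <- 200
  cond <- sprintf("c%03d", 1:n_cond)
  t1 <- rnorm(n_cond)
  prof_signal <- list(response = 0.5 + 2 * t1,
                      tf_matrix = cbind(tfA = t1), condition = cond)
  cv <- cv_prediction_correlation(prof_signal$response, prof_signal$tf_matrix,
                                  prof_signal$condition, seed = 1)
  expect_gte(cv$mean_rho, 0.999)

  noise_rhos <- vapply(1:5, function(s) {
    set.seed(500 + s)
    y <- rnorm(n_cond)
    cv_prediction_correlation(y, cbind(tfA = rnorm(n_cond)), cond,
                              seed = s)$mean_rho
  }, numeric(1))
  # CV predictions on pure noise hover near (slightly below) zero correlation
  expect_gte(mean(abs(noise_rhos) < 0.2), 0.8)
  expect_lt(mean(noise_rhos), 0.1)

  a <- cv_prediction_correlation(prof_signal$response, prof_signal$tf_matrix,
                                 prof_signal$condition, seed = 7)
  b <- cv_prediction_correlation(prof_signal$response, prof_signal$tf_matrix,
                                 prof_signal$condition, seed = 7)
  expect_identical(a, b)
})

test_that("pooled CV predictions are equivariant under condition reordering", {
  set.seed(21)
  n_cond <- 40
  cond <- sprintf("c%02d", 1:n_cond)
  t1 <- rnorm(n_cond)
  y <- 1 + t1 + rnorm(n_cond, sd = 0.3)
  fa <- make_fold_assignments_test(cond, reps = 3, folds = 4, seed = 2)
  cv1 <- cv_prediction_correlation(y, cbind(tfA = t1), cond,
                                   fold_assignments = fa)
  perm <- sample(n_cond)
  cv2 <- cv_prediction_correlation(y[perm], cbind(tfA = t1[perm]), cond[perm],
                                   fold_assignments = fa)
  expect_equal(cv2$pooled_prediction, cv1$pooled_prediction[perm],
               tolerance = 1e-10)
})

test_that("the dependent-correlation test behaves like Williams' t", {
  z <- dependent_correlation_test(0.6, 0.6, 0.4, 30)
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  a <- dependent_correlation_test(0.8, 0.5, 0.6, 50)
  b <- dependent_correlation_test(0.5, 0.8, 0.6, 50)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_error(dependent_correlation_test(1, 0.5, 0.5, 30), "degenerate")
  expect_error(dependent_correlation_test(0.5, 0.4, 0.3, 3), "n_points")
  # formula oracle
  o <- williams_oracle(0.8, 0.5, 0.6, 50)
  expect_equal(a$t, o$t, tolerance = 1e-10)
  expect_equal(a$p, o$p, tolerance = 1e-10)
})

test_that("mechanism selection recovers planted regulators and stops correctly", {
  ds <- generate_dataset(n_genes = 30, n_tfs = 6, n_conditions = 120,
                         n_experiments = 2, n_modules = 2,
                         module_size_range = c(5, 6), n_motifs = 6,
                         motifs_per_module = 1, background_motif_rate = 0,
                         mechanism_orders = c(1, 2), noise_sd = 0,
                         missing_rate = 0, seed = 31)
  m1 <- select_regulatory_mechanism(ds$truth$modules[[1]]$members,
                                    ds$expr, ds$tf_expr, seed = 1)
  expect_identical(m1$tfs, ds$truth$modules[[1]]$tfs)
  expect_true(is.na(m1$bonferroni_p))
  m2 <- select_regulatory_mechanism(ds$truth$modules[[2]]$members,
                                    ds$expr, ds$tf_expr, seed = 1)
  expect_identical(sort(m2$tfs), sort(ds$truth$modules[[2]]$tfs))
  expect_lt(m2$bonferroni_p, 0.05)
})

test_that("module members are excluded as their own regulators", {
  set.seed(41)
  n_cond <- 80
  tfA <- rnorm(n_cond); tfB <- rnorm(n_cond)
  # gene profiles follow tfA exactly, and tfA is itself a module member
  expr <- make_expr(rbind(tfA = tfA, g2 = tfA, g3 = tfA))
  tfe <- make_expr(rbind(tfA = tfA, tfB = tfB))
  mech <- select_regulatory_mechanism(c("tfA", "g2", "g3"), expr, tfe,
                                      max_order = 1, seed = 1)
  expect_identical(mech$tfs, "tfB")
  expect_error(select_regulatory_mechanism(c("tfA", "tfB"), expr, tfe),
               "no candidate TFs")
})

test_that("regulation classification follows coefficient signs and T significance", {
  set.seed(51)
  t1 <- rnorm(300); t2 <- rnorm(300)
  y <- 1 + 1.2 * t1 - 0.5 * t2 + 0.8 * t1 * t2
  fit <- fit_regression_mechanism(y, cbind(tfA = t1, tfB = t2))
  mech <- structure(c(fit, list(module_id = "M", tfs = c("tfA", "tfB"))),
                    class = "RegulatoryMechanism")
  cls <- classify_regulation(mech)
  expect_identical(cls$label[cls$coefficient == "tfA"], "positive")
  expect_identical(cls$label[cls$coefficient == "tfB"], "negative")
  expect_identical(cls$label[cls$coefficient == "tfA:tfB"], "synergistic")
  expect_true(all(cls$significant[cls$kind != "intercept"]))

  y2 <- 1 - 0.7 * t1 + 0.9 * t2 - 0.6 * t1 * t2 + rnorm(300, sd = 0.1)
  fit2 <- fit_regression_mechanism(y2, cbind(tfA = t1, tfB = t2))
  mech2 <- structure(c(fit2, list(module_id = "M", tfs = c("tfA", "tfB"))),
                     class = "RegulatoryMechanism")
  cls2 <- classify_regulation(mech2)
  expect_identical(cls2$label[cls2$coefficient == "tfA:tfB"], "competitive")
})

test_that("networks assemble with per-TF tallies and reject duplicates", {
  mk <- function(id, tfs) structure(list(module_id = id, tfs = tfs),
                                    class = "RegulatoryMechanism")
  net <- build_network(list(mk("M1", c("tfA", "tfB")), mk("M2", "tfA")))
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$tf_summary$n_modules[net$tf_summary$tf == "tfA"], 2L)
  empty <- build_network(list())
  expect_equal(nrow(empty$edges), 0L)
  expect_error(build_network(list(mk("M1", "a"), mk("M1", "b"))), "duplicate")
})

test_that("power-law fits recover exact parameters and reject degenerate input", {
  x <- 1:6
  y <- 0.62 * x^(-1.1)
  fit <- power_law_fit(x, y)
  expect_equal(fit$a, 0.62, tolerance = 1e-10)
  expect_equal(fit$b, -1.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # noisy sample: slope within the confidence interval of an lm oracle
  set.seed(61)
  ylog <- log(0.5 * x^(-1.3)) + rnorm(6, sd = 0.05)
  fit2 <- power_law_fit(x, exp(ylog))
  lm_o <- stats::lm(ylog ~ log(x))
  ci <- stats::confint(lm_o)[2, ]
  expect_gte(fit2$b, ci[1]); expect_lte(fit2$b, ci[2])

  mk <- function(id, tfs) structure(list(module_id = id, tfs = tfs),
                                    class = "RegulatoryMechanism")
  single <- build_network(list(mk("M1", "tfA"), mk("M2", "tfA")))
  expect_error(fit_degree_power_law(single), "degenerate")
})
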