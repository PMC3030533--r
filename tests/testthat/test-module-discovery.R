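test_that("pairwise-complete Spearman handles monotone transforms, overlap and ties", {
  x <- as.numeric(1:10)
  expect_equal(spearman_pairwise_complete(x, 2 * x + 3, min_overlap = 5), 1)
  expect_true(is.na(spearman_pairwise_complete(c(1, 2, 3, NA),
                                               c(NA, 1, 5, 2),
                                               min_overlap = 3)))
  # rank-formula oracle: rho = 1 - 6*sum(d^2)/(n(n^2-1)) without ties
  xs <- c(1, 2, 3, 4, 5); ys <- c(3, 1, 2, 5, 4)
  d2 <- sum((rank(xs) - rank(ys))^2)
  expect_equal(spearman_pairwise_complete(xs, ys, min_overlap = 3),
               1 - 6 * d2 / (5 * 24))
  expect_equal(spearman_pairwise_complete(xs, ys, min_overlap = 3), 0.6)
})

test_that("ranks are computed on the shared subset, not whole profiles", {
  # classic failure mode of column-wise ranking: the missing entry changes
  # the ranks of the remaining values
  x <- c(10, 1, 2, 3, 4)
  y <- c(NA, 1.5, 2.5, 3.5, 0.5)
  manual <- stats::cor(rank(x[-1]), rank(y[-1]))
  expect_equal(spearman_pairwise_complete(x, y, min_overlap = 3), manual)
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_overlap_p(20, 5, 4, 0), 1.0)
  expect_equal(hypergeom_overlap_p(20, 5, 4, 4), 5 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_overlap_p(10, 10, 3, 3), 1.0)
  for (N in c(6, 9, 12)) {
    for (K in seq(0, N, by = 3)) {
      for (n in seq(0, N, by = 2)) {
        for (k in max(0, n + K - N):min(K, n)) {
          expect_equal(hypergeom_overlap_p(N, K, n, k),
                       hyper_upper_oracle(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeom_overlap_p(10, 12, 3, 3), "inconsistent")
  expect_error(hypergeom_overlap_p(10, 5, 3, 4), "inconsistent")
})

test_that("rule enumeration recovers a planted module at every threshold", {
  ds <- generate_dataset(n_genes = 30, n_tfs = 4, n_conditions = 40,
                         n_experiments = 2, n_modules = 1,
                         module_size_range = c(8, 8), n_motifs = 5,
                         motifs_per_module = 2, background_motif_rate = 0,
                         noise_sd = 0, missing_rate = 0, seed = 21)
  mod <- ds$truth$modules[[1]]
  rules <- enumerate_rules(ds$expr, ds$motifs)
  hits <- rules[vapply(rules$motifs, function(m) setequal(m, mod$motifs),
                       logical(1)) &
                vapply(rules$positive_genes, function(g)
                  setequal(g, mod$members), logical(1)), ]
  # the exact planted combination is found at all 10 thresholds for the
  # centers inside the module
  expect_setequal(unique(hits$threshold), seq(0.50, 0.95, by = 0.05))
  expect_true(all(hits$n_positive == 8))
})

test_that("motifs carried by fewer than min_pos genes never form rules", {
  set.seed(2)
  nc <- 30
  vals <- matrix(rnorm(20 * nc), 20, nc,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:nc)))
  # 6 perfectly co-expressed genes
  vals[1:6, ] <- matrix(vals[1, ], 6, nc, byrow = TRUE)
  expr <- make_expr(vals)
  occ <- matrix(0L, 20, 2, dimnames = list(rownames(vals), c("rare", "good")))
  occ[1:4, "rare"] <- 1L   # only 4 carriers
  occ[1:6, "good"] <- 1L
  rules <- enumerate_rules(expr, motif_matrix(occ), min_overlap = 5)
  expect_true(nrow(rules) > 0)
  expect_false(any(vapply(rules$motifs, function(m) "rare" %in% m,
                          logical(1))))
})

test_that("rule enumeration is invariant to gene-row permutation", {
  ds <- generate_dataset(n_genes = 25, n_tfs = 4, n_conditions = 40,
                         n_experiments = 2, n_modules = 2,
                         module_size_range = c(5, 6), n_motifs = 6,
                         motifs_per_module = 1, background_motif_rate = 0.1,
                         noise_sd = 0.2, missing_rate = 0, seed = 13)
  rules1 <- enumerate_rules(ds$expr, ds$motifs)
  set.seed(1)
  perm <- sample(nrow(ds$expr$values))
  expr2 <- expression_matrix(ds$expr$values[perm, ], experiments(ds$expr))
  perm2 <- sample(nrow(ds$motifs$values))
  motifs2 <- motif_matrix(ds$motifs$values[perm2, ])
  rules2 <- enumerate_rules(expr2, motifs2)
  expect_equal(rules1, rules2)
})

test_that("BH q-values dominate p-values and respect the FDR cut", {
  ds <- generate_dataset(n_genes = 25, n_tfs = 4, n_conditions = 40,
                         n_experiments = 2, n_modules = 2,
                         module_size_range = c(5, 6), n_motifs = 6,
                         motifs_per_module = 1, background_motif_rate = 0.1,
                         noise_sd = 0.2, missing_rate = 0, seed = 13)
  rules <- enumerate_rules(ds$expr, ds$motifs, fdr = 0.05)
  expect_true(all(rules$q_value >= rules$p_value))
  expect_true(all(rules$q_value <= 0.05))
  ord <- order(rules$p_value)
  expect_true(all(diff(rules$q_value[ord]) >= -1e-15))
})

test_that("library selection replays the greedy competition", {
  mk_rules <- function(p, pos, center = "g0") {
    data.frame(center = center, threshold = 0.5,
               motifs = I(list("m1")), positive_genes = I(list(pos)),
               n_positive = length(pos), n_negative = 0L,
               p_value = p, q_value = p, stringsAsFactors = FALSE)
  }
  # identical positive sets -> one module
  two_same <- rbind(mk_rules(1e-6, paste0("g", 1:6)),
                    mk_rules(1e-5, paste0("g", 1:6)))
  expect_length(select_module_library(two_same), 1L)
  # disjoint sets -> both kept
  disjoint <- rbind(mk_rules(1e-6, paste0("g", 1:6)),
                    mk_rules(1e-5, paste0("h", 1:6)))
  expect_length(select_module_library(disjoint), 2L)

  # six rules with known overlap structure, hand-replayed:
  # r1 (best) accepted; r2 = r1 shifted by 2/8 overlap -> Jaccard 6/10 > 0.5
  # rejected; r3 disjoint accepted; r4 overlaps r3 by half (J = 5/11 <= 0.5)
  # accepted; r5 subset of r1 (J = 5/8) rejected; r6 overlaps r4 only
  # slightly (J = 2/12) accepted.
  r1 <- mk_rules(1e-9, paste0("a", 1:8))
  r2 <- mk_rules(1e-8, c(paste0("a", 3:8), "b1", "b2"))
  r3 <- mk_rules(1e-7, paste0("c", 1:8))
  r4 <- mk_rules(1e-6, c(paste0("c", 1:5), paste0("d", 1:3)))
  r5 <- mk_rules(1e-5, paste0("a", 1:5))
  r6 <- mk_rules(1e-4, c("d1", "d2", paste0("e", 1:6)))
  lib <- select_module_library(rbind(r1, r2, r3, r4, r5, r6))
  expect_length(lib, 4L)
  expect_identical(lapply(lib, `[[`, "members"),
                   lapply(list(r1, r3, r4, r6),
                          function(r) sort(r$positive_genes[[1]])))
})

test_that("planted modules are co-expressed in every experiment, noise genes are not", {
  ds <- generate_dataset(n_genes = 40, n_tfs = 5, n_conditions = 60,
                         n_experiments = 3, n_modules = 1,
                         module_size_range = c(6, 6), n_motifs = 4,
                         motifs_per_module = 1, background_motif_rate = 0,
                         noise_sd = 0, missing_rate = 0, seed = 4)
  mod <- structure(list(module_id = "T",
                        members = ds$truth$modules[[1]]$members),
                   class = "TranscriptionalModule")
  res <- experiment_coexpression(mod, ds$expr, n_perm = 199, seed = 1)
  expect_equal(res$mean_correlation, rep(1, 3), tolerance = 1e-12)
  expect_true(all(res$significant))
  # random noise genes: never a mean correlation near 1
  noise <- setdiff(genes(ds$expr), mod$members)[1:6]
  res2 <- experiment_coexpression(structure(list(module_id = "N",
                                                 members = noise),
                                            class = "TranscriptionalModule"),
                                  ds$expr, n_perm = 199, seed = 2)
  expect_true(all(abs(res2$mean_correlation) < 0.5))
})

test_that("empirical permutation p is calibrated for noise modules", {
  # i.i.d. noise genes: the significance flag should fire at ~alpha
  set.seed(7)
  flags <- logical(0)
  for (s in 1:10) {
    vals <- matrix(rnorm(25 * 30), 25, 30,
                   dimnames = list(paste0("g", 1:25), paste0("c", 1:30)))
    expr <- make_expr(vals, experiment = rep(c("e1", "e2"), each = 15))
    mod <- structure(list(module_id = "N",
                          members = rownames(vals)[sample(25, 5)]),
                     class = "TranscriptionalModule")
    res <- experiment_coexpression(mod, expr, n_perm = 99, alpha = 0.05,
                                   seed = 100 + s)
    flags <- c(flags, res$significant)
  }
  # 20 flags at nominal 0.05: central binomial band
  expect_lte(sum(flags), qbinom(0.995, length(flags), 0.05))
})
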