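# Statistical validation of the inferred network: bootstrap stability and
# hold-out prediction, the theoretically optimal within-module reference, and
# leave-one-experiment-out prediction.

#' Mean hold-out fraction of bootstrap resampling
#'
#' Draws `B` resamples of `n_conditions` condition indices with replacement
#' and returns the mean fraction of conditions absent from a resample. For
#' large n this converges to (1 - 1/n)^n, about 36.8%.
#'
#' @param n_conditions number of conditions resampled.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return mean unseen-condition fraction in \[0, 1\].
#' @export
bootstrap_holdout_fraction <- function(n_conditions, B = 100, seed = NULL) {
  with_seed(seed, {
    mean(vapply(seq_len(B), function(b) {
      1 - length(unique(sample.int(n_conditions, replace = TRUE))) / n_conditions
    }, numeric(1)))
  })
}

#' Bootstrap stability and hold-out prediction analysis
#'
#' The module library stays fixed; for each of `B` bootstrap resamples of the
#' conditions (drawn with replacement) the regulatory mechanism of every
#' module is re-selected on the resample, and the resample's mechanism
#' predicts each module's expression at the conditions the resample missed.
#' Per gene, predictions at each condition are averaged across the resamples
#' in which that condition was held out, then Pearson-correlated with the
#' observed profile (so hold-out correlations never touch conditions used for
#' fitting in the same resample). Per edge of the full-data network, support
#' is the fraction of bootstrap networks containing the edge.
#'
#' @param expr,tf_expr expression matrices.
#' @param modules a `module_library`.
#' @param candidates candidate TF ids (default all TFs).
#' @param B number of resamples (>= 2).
#' @param seed integer master seed; each resample uses a derived seed.
#' @param alpha,max_order,reps,folds passed to
#'   [select_regulatory_mechanism()].
#' @param network optional precomputed full-data network (with its
#'   mechanisms) to avoid refitting; a list with elements `network` and
#'   `mechanisms` as returned by [infer_network()].
#' @return a `BootstrapReport`: `B`, `network` (edges carrying support),
#'   `edge_support`, `gene_holdout` (`gene`, `module`, `rho`,
#'   `n_conditions`), `module_holdout` (mean per-gene rho), and
#'   `mean_holdout_fraction`.
#' @export
bootstrap_analysis <- function(expr, tf_expr, modules, candidates = NULL,
                               B = 100, seed = NULL, alpha = 0.05,
                               max_order = 4, reps = 5, folds = 5,
                               network = NULL) {
  if (B < 2) stopf("B must be >= 2")
  if (is.null(network)) {
    network <- infer_network(expr, tf_expr, modules, candidates = candidates,
                             alpha = alpha, max_order = max_order,
                             reps = reps, folds = folds, seed = seed)
  }
  cond <- conditions(expr)
  n_cond <- length(cond)
  module_ids <- vapply(modules, `[[`, "", "module_id")
  edge_key <- paste(network$network$edges$tf, network$network$edges$module)
  edge_hits <- numeric(length(edge_key))
  pred_sum <- matrix(0, length(modules), n_cond,
                     dimnames = list(module_ids, cond))
  pred_n <- matrix(0L, length(modules), n_cond,
                   dimnames = list(module_ids, cond))
  holdout_frac <- numeric(B)

  for (b in seq_len(B)) {
    seed_b <- derive_seed(seed, b)
    idx <- with_seed(seed_b, sample.int(n_cond, replace = TRUE))
    held_out <- cond[-unique(idx)]
    holdout_frac[b] <- length(held_out) / n_cond
    boot_ids <- sprintf("%s.b%03d", cond[idx], seq_along(idx))
    boot_expr <- expression_matrix(
      `colnames<-`(expr$values[, idx, drop = FALSE], boot_ids),
      stats::setNames(experiments(expr)[idx], boot_ids))
    boot_tf <- expression_matrix(
      `colnames<-`(tf_expr$values[, idx, drop = FALSE], boot_ids),
      stats::setNames(experiments(tf_expr)[idx], boot_ids))
    for (m in seq_along(modules)) {
      mech_b <- select_regulatory_mechanism(
        modules[[m]], boot_expr, boot_tf, candidates = candidates,
        alpha = alpha, max_order = max_order, reps = reps, folds = folds,
        seed = derive_seed(seed_b, m))
      key_b <- paste(mech_b$tfs, module_ids[m])
      edge_hits <- edge_hits + (edge_key %in% key_b)
      if (length(held_out) > 0) {
        pred <- predict_mechanism(mech_b, tf_expr, held_out)
        ok <- !is.na(pred)
        pred_sum[m, held_out[ok]] <- pred_sum[m, held_out[ok]] + pred[ok]
        pred_n[m, held_out[ok]] <- pred_n[m, held_out[ok]] + 1L
      }
    }
  }

  support <- edge_hits / B
  net <- network$network
  net$edges$support <- support
  edge_support <- data.frame(tf = net$edges$tf, module = net$edges$module,
                             support = support)

  gene_rows <- list()
  for (m in seq_along(modules)) {
    avg_pred <- ifelse(pred_n[m, ] > 0, pred_sum[m, ] / pmax(pred_n[m, ], 1L),
                       NA_real_)
    for (g in modules[[m]]$members) {
      obs <- expr$values[g, ]
      ok <- !is.na(obs) & !is.na(avg_pred)
      rho <- if (sum(ok) >= 3 && stats::sd(obs[ok]) > 0 &&
                 stats::sd(avg_pred[ok]) > 0) {
        stats::cor(obs[ok], avg_pred[ok])
      } else NA_real_
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(gene = g, module = module_ids[m], rho = rho,
                   n_conditions = sum(ok), stringsAsFactors = FALSE)
    }
  }
  gene_holdout <- do.call(rbind, gene_rows)
  module_holdout <- do.call(rbind, lapply(module_ids, function(id) {
    data.frame(module = id,
               mean_rho = mean(gene_holdout$rho[gene_holdout$module == id],
                               na.rm = TRUE))
  }))

  structure(list(B = B, network = net, mechanisms = network$mechanisms,
                 edge_support = edge_support, gene_holdout = gene_holdout,
                 module_holdout = module_holdout,
                 mean_holdout_fraction = mean(holdout_frac)),
            class = "BootstrapReport")
}

#' @export
print.BootstrapReport <- function(x, ...) {
  cat(sprintf(paste0("BootstrapReport: B=%d, mean hold-out fraction %.3f, ",
                     "median edge support %.2f\n"),
              x$B, x$mean_holdout_fraction,
              stats::median(x$edge_support$support)))
  invisible(x)
}

#' Full-data network inference over a module library
#'
#' Convenience wrapper: selects the regulatory mechanism of every module and
#' assembles the bipartite network.
#'
#' @inheritParams bootstrap_analysis
#' @param seed master seed; module `m` uses a derived seed.
#' @return list `mechanisms` (one `RegulatoryMechanism` per module) and
#'   `network` (a `RegulatoryNetwork`).
#' @export
infer_network <- function(expr, tf_expr, modules, candidates = NULL,
                          alpha = 0.05, max_order = 4, reps = 5, folds = 5,
                          seed = NULL) {
  mechanisms <- lapply(seq_along(modules), function(m) {
    select_regulatory_mechanism(modules[[m]], expr, tf_expr,
                                candidates = candidates, alpha = alpha,
                                max_order = max_order, reps = reps,
                                folds = folds, seed = derive_seed(seed, m))
  })
  list(mechanisms = mechanisms,
       network = build_network(mechanisms, modules))
}

#' Theoretically optimal within-module prediction
#'
#' The ceiling for any predictor that emits one profile per module: predict
#' every member gene by the per-condition mean profile of the module's genes
#' (missing-aware), and report each gene's Pearson correlation to that mean.
#'
#' @param module a `TranscriptionalModule` or member gene vector (>= 2
#'   genes).
#' @param expr gene [expression_matrix()].
#' @return data frame `gene`, `rho` (`NA` where the correlation is
#'   degenerate).
#' @export
optimal_module_prediction <- function(module, expr) {
  members <- module_members(module)
  if (length(members) < 2) stopf("need >= 2 member genes")
  vals <- expr$values[members, , drop = FALSE]
  mean_profile <- colMeans(vals, na.rm = TRUE)
  rho <- vapply(members, function(g) {
    obs <- vals[g, ]
    ok <- !is.na(obs) & !is.na(mean_profile)
    if (sum(ok) < 3 || stats::sd(obs[ok]) == 0 ||
        stats::sd(mean_profile[ok]) == 0) return(NA_real_)
    stats::cor(obs[ok], mean_profile[ok])
  }, numeric(1))
  data.frame(gene = members, rho = unname(rho), stringsAsFactors = FALSE)
}

# One-sided p-value for a positive Pearson correlation at sample size n.
cor_pvalue_onesided <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- max(-1 + 1e-12, min(1 - 1e-12, r))
  t <- r * sqrt((n - 2) / (1 - r^2))
  stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Leave-one-experiment-out prediction
#'
#' Re-selects every module's regulatory mechanism on all conditions outside
#' the named experiment, predicts expression at the held-out conditions, and
#' counts the genes and modules whose observed/predicted Pearson correlation
#' is significantly positive at the held-out sample size (one-sided t-test
#' on r).
#'
#' @param expr,tf_expr expression matrices.
#' @param modules a `module_library`.
#' @param candidates candidate TF ids.
#' @param experiment experiment label to hold out (>= 5 conditions).
#' @param alpha significance level.
#' @param max_order,reps,folds,seed passed to mechanism selection.
#' @return list `genes` (per-gene rho and p), `modules` (per-module mean rho
#'   and p), `fraction_genes_significant`, `fraction_modules_significant`.
#' @export
leave_one_experiment_out <- function(expr, tf_expr, modules, candidates = NULL,
                                     experiment, alpha = 0.05, max_order = 4,
                                     reps = 5, folds = 5, seed = NULL) {
  exps <- experiments(expr)
  if (!experiment %in% exps) stopf("unknown experiment label '%s'", experiment)
  test_cond <- names(exps)[exps == experiment]
  if (length(test_cond) < 5) stopf("held-out experiment needs >= 5 conditions")
  train_cond <- setdiff(conditions(expr), test_cond)
  train_expr <- subset_conditions(expr, train_cond)
  train_tf <- subset_conditions(tf_expr, train_cond)

  gene_rows <- list(); module_rows <- list()
  for (m in seq_along(modules)) {
    mod <- modules[[m]]
    mech <- select_regulatory_mechanism(mod, train_expr, train_tf,
                                        candidates = candidates,
                                        alpha = alpha, max_order = max_order,
                                        reps = reps, folds = folds,
                                        seed = derive_seed(seed, m))
    pred <- predict_mechanism(mech, tf_expr, test_cond)
    rhos <- vapply(mod$members, function(g) {
      obs <- expr$values[g, test_cond]
      ok <- !is.na(obs) & !is.na(pred)
      if (sum(ok) < 3 || stats::sd(obs[ok]) == 0 ||
          stats::sd(pred[ok]) == 0) return(NA_real_)
      stats::cor(obs[ok], pred[ok])
    }, numeric(1))
    n_test <- length(test_cond)
    p_gene <- vapply(rhos, cor_pvalue_onesided, numeric(1), n = n_test)
    gene_rows[[m]] <- data.frame(gene = mod$members, module = mod$module_id,
                                 rho = unname(rhos), p_value = unname(p_gene),
                                 stringsAsFactors = FALSE)
    mean_rho <- mean(rhos, na.rm = TRUE)
    module_rows[[m]] <- data.frame(module = mod$module_id,
                                   mean_rho = mean_rho,
                                   p_value = cor_pvalue_onesided(mean_rho, n_test),
                                   stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, gene_rows)
  modules_df <- do.call(rbind, module_rows)
  list(genes = genes_df, modules = modules_df,
       fraction_genes_significant =
         mean(genes_df$p_value < alpha, na.rm = TRUE),
       fraction_modules_significant =
         mean(modules_df$p_value < alpha, na.rm = TRUE))
}
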