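# Regression-based inference of regulatory mechanisms. The expression of a
# module is the concatenation of its member genes' profiles and is modeled as
# m = beta0 + sum_j beta_j t_j + sum_{j<k} beta_jk t_j t_k over a set R of
# transcription factors. Model order grows while a more complex TF set
# predicts held-out expression significantly better, judged by a Bonferroni
# corrected test for the difference between two dependent Pearson
# correlations.

module_members <- function(module) {
  if (inherits(module, "TranscriptionalModule")) module$members
  else as.character(module)
}

#' Concatenated module profile and tiled TF predictors
#'
#' The response is the member genes' expression profiles appended
#' gene-by-gene; each TF's predictor is its profile tiled once per member
#' gene. A condition at which any TF of `tf_expr` is unmeasured is dropped
#' for all genes (predictor completeness), and rows with a missing response
#' are dropped individually. Each row keeps its originating condition id so
#' cross-validation can split by condition rather than by concatenated row
#' (rows of one condition are dependent across genes).
#'
#' @param module a `TranscriptionalModule` or character vector of member
#'   genes.
#' @param expr gene [expression_matrix()].
#' @param tf_expr TF [expression_matrix()] (restrict to the candidate TFs of
#'   interest before calling: its TF set defines predictor completeness).
#' @return list with `response` (numeric), `tf_matrix` (rows x TFs),
#'   `condition` and `gene` (character per row).
#' @export
concatenated_module_profile <- function(module, expr, tf_expr) {
  members <- module_members(module)
  missing_members <- setdiff(members, genes(expr))
  if (length(missing_members) > 0) {
    stopf("module genes absent from expression matrix: %s",
          paste(utils::head(missing_members, 5), collapse = ", "))
  }
  cond <- conditions(expr)
  if (!identical(cond, conditions(tf_expr))) {
    tf_vals <- tf_expr$values[, cond, drop = FALSE]
  } else tf_vals <- tf_expr$values
  ok_cond <- cond[colSums(is.na(tf_vals)) == 0]
  tf_vals <- tf_vals[, ok_cond, drop = FALSE]

  response <- as.vector(t(expr$values[members, ok_cond, drop = FALSE]))
  gene <- rep(members, each = length(ok_cond))
  condition <- rep(ok_cond, times = length(members))
  keep <- !is.na(response)
  if (!any(keep)) stopf("empty module profile after missing-value removal")
  tf_matrix <- t(tf_vals)[condition[keep], , drop = FALSE]
  rownames(tf_matrix) <- NULL
  list(response = response[keep], tf_matrix = tf_matrix,
       condition = condition[keep], gene = gene[keep])
}

# Design matrix [1, t_j ..., t_j t_k ...] for a TF set (columns of tf_matrix).
build_design <- function(tf_matrix, tfs = colnames(tf_matrix)) {
  tfs <- sort(tfs)
  X <- cbind(`(Intercept)` = 1, tf_matrix[, tfs, drop = FALSE])
  if (length(tfs) >= 2) {
    pairs <- utils::combn(tfs, 2)
    prods <- matrix(0, nrow(tf_matrix), ncol(pairs))
    for (i in seq_len(ncol(pairs))) {
      prods[, i] <- tf_matrix[, pairs[1, i]] * tf_matrix[, pairs[2, i]]
    }
    colnames(prods) <- paste(pairs[1, ], pairs[2, ], sep = ":")
    X <- cbind(X, prods)
  }
  X
}

#' Fit a regulatory mechanism by ordinary least squares
#'
#' Fits the full interaction design (intercept, one linear term per TF, one
#' cross term per TF pair) and reports coefficient T-statistics
#' (coefficient / standard error).
#'
#' @param response concatenated module profile.
#' @param predictors rows x TFs matrix of TF expression, column names = TF
#'   ids.
#' @return list with `coefficients`, `t_stats`, `se`, `sigma`,
#'   `df_residual`, `fitted`, `tfs`.
#' @export
fit_regression_mechanism <- function(response, predictors) {
  X <- build_design(predictors)
  n <- length(response)
  if (n <= ncol(X)) stopf("need more rows (%d) than coefficients (%d)", n, ncol(X))
  fit <- stats::lm.fit(X, response)
  if (fit$rank < ncol(X)) stopf("rank-deficient design (duplicate or collinear TFs)")
  df <- n - ncol(X)
  resid <- fit$residuals
  sigma <- sqrt(sum(resid^2) / df)
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  se <- (sigma * sqrt(diag(chol2inv(R))))[order(piv)]
  names(se) <- colnames(X)
  coefs <- fit$coefficients[colnames(X)]
  list(coefficients = coefs, t_stats = coefs / se, se = se, sigma = sigma,
       df_residual = df, fitted = X %*% coefs, tfs = sort(colnames(predictors)))
}

# Fold assignments: reps x conditions matrix of fold labels, one column per
# distinct condition. Shared across candidate TF sets so CV comparisons are
# paired.
make_fold_assignments <- function(conds, reps, folds, seed = NULL) {
  if (length(conds) < folds) {
    stopf("fewer conditions (%d) than folds (%d)", length(conds), folds)
  }
  with_seed(seed, {
    m <- t(vapply(seq_len(reps), function(r) {
      sample(rep_len(seq_len(folds), length(conds)))
    }, integer(length(conds))))
  })
  colnames(m) <- conds
  m
}

#' Cross-validated prediction correlation for one TF set
#'
#' Five iterations of 5-fold cross-validation by default. Folds partition the
#' condition ids, so all concatenated rows of one condition are held out
#' together. Per repetition, out-of-fold predictions are assembled into one
#' vector and Pearson-correlated with the observed response; the mean over
#' repetitions is reported. The pooled prediction is the per-row mean of the
#' out-of-fold predictions across repetitions.
#'
#' @param response,predictors,condition as produced by
#'   [concatenated_module_profile()] (predictors restricted to the TF set).
#' @param reps,folds cross-validation scheme.
#' @param seed integer seed for the fold draws.
#' @param fold_assignments optional precomputed matrix from repeated calls
#'   (reps x conditions, column names = condition ids); overrides `seed`.
#' @return list `mean_rho`, `pooled_prediction`, `per_rep_rho`.
#' @export
cv_prediction_correlation <- function(response, predictors, condition,
                                      reps = 5, folds = 5, seed = NULL,
                                      fold_assignments = NULL) {
  conds <- unique(condition)
  if (is.null(fold_assignments)) {
    fold_assignments <- make_fold_assignments(conds, reps, folds, seed)
  }
  X <- build_design(predictors)
  n <- length(response)
  preds <- matrix(NA_real_, n, nrow(fold_assignments))
  rho <- numeric(nrow(fold_assignments))
  row_fold_all <- matrix(fold_assignments[, condition, drop = FALSE],
                         nrow = nrow(fold_assignments))
  for (r in seq_len(nrow(fold_assignments))) {
    row_fold <- row_fold_all[r, ]
    pred <- numeric(n)
    for (k in seq_len(max(row_fold))) {
      test <- row_fold == k
      fit <- stats::lm.fit(X[!test, , drop = FALSE], response[!test])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred[test] <- X[test, , drop = FALSE] %*% beta
    }
    preds[, r] <- pred
    r_ <- suppressWarnings(stats::cor(response, pred))
    rho[r] <- if (is.na(r_)) 0 else r_
  }
  list(mean_rho = mean(rho), pooled_prediction = rowMeans(preds),
       per_rep_rho = rho)
}

#' T-test for the difference between two dependent Pearson correlations
#'
#' Williams' test for comparing `cor(observed, pred_A)` against
#' `cor(observed, pred_B)` when both predictions share the observed variable,
#' with `r_ab = cor(pred_A, pred_B)`. The statistic is referred to a t
#' distribution on `n_points - 3` degrees of freedom; the p-value is
#' two-sided.
#'
#' @param r_oa,r_ob correlations of the two predictions with the shared
#'   observed variable.
#' @param r_ab correlation between the two predictions.
#' @param n_points sample size behind the correlations (>= 4).
#' @return list `t`, `p`, `df`.
#' @export
dependent_correlation_test <- function(r_oa, r_ob, r_ab, n_points) {
  rs <- c(r_oa, r_ob, r_ab)
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) stopf("correlations must lie in [-1,1]")
  if (any(abs(rs) >= 1)) stopf("degenerate correlation of magnitude 1")
  if (n_points < 4) stopf("n_points must be >= 4")
  if (r_oa == r_ob) return(list(t = 0, p = 1, df = n_points - 3))
  n <- n_points
  rbar <- (r_oa + r_ob) / 2
  detR <- 1 - r_oa^2 - r_ob^2 - r_ab^2 + 2 * r_oa * r_ob * r_ab
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_ab)^3
  t <- (r_oa - r_ob) * sqrt((n - 1) * (1 + r_ab) / denom)
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 3), df = n - 3)
}

# Guarded one-sided improvement p-value used during order selection.
# Near-perfect predictions make the Williams determinant collapse; a strictly
# larger correlation with a degenerate denominator is treated as decisive.
improvement_p <- function(observed, pred_new, pred_old) {
  safe_cor <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b))
    if (is.na(r)) 0 else r
  }
  r_oa <- safe_cor(observed, pred_new)
  r_ob <- safe_cor(observed, pred_old)
  if (r_oa <= r_ob) return(1)
  r_ab <- safe_cor(pred_new, pred_old)
  eps <- 1e-12
  clamp <- function(r) max(-1 + eps, min(1 - eps, r))
  res <- tryCatch(
    dependent_correlation_test(clamp(r_oa), clamp(r_ob), clamp(r_ab),
                               length(observed)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$t)) return(0)
  res$p
}

#' Select the regulatory mechanism of a module
#'
#' Starting from the best single TF (order 1), all TF sets of the next order
#' are evaluated by cross-validated prediction correlation; the best
#' challenger replaces the incumbent only if the Williams test comparing the
#' two pooled out-of-fold predictions against the observed profile, with its
#' p-value multiplied by the number of TF combinations tested at that order
#' (Bonferroni), stays below `alpha`. Orders 1-3 are searched exhaustively;
#' order 4 extends the incumbent set by one TF at a time. TFs that are
#' themselves module members are excluded (no auto-regulation). The returned
#' mechanism is refitted on all data.
#'
#' @param module a `TranscriptionalModule` or member gene vector.
#' @param expr,tf_expr expression matrices.
#' @param candidates candidate TF ids (default: all TFs in `tf_expr`).
#' @param alpha significance level of the order-admission test.
#' @param max_order largest TF set considered.
#' @param reps,folds cross-validation scheme.
#' @param seed integer seed (fold draws are shared across TF sets, so
#'   comparisons are paired).
#' @return a `RegulatoryMechanism`: `module_id`, `tfs`, `coefficients`,
#'   `t_stats`, `se`, `df_residual`, `cv_rho`, `bonferroni_p` (NA for an
#'   unchallenged order-1 mechanism), `n_rows`.
#' @export
select_regulatory_mechanism <- function(module, expr, tf_expr,
                                        candidates = NULL, alpha = 0.05,
                                        max_order = 4, reps = 5, folds = 5,
                                        seed = NULL) {
  members <- module_members(module)
  if (is.null(candidates)) candidates <- genes(tf_expr)
  candidates <- sort(setdiff(candidates, members))
  if (length(candidates) == 0) stopf("no candidate TFs after auto-regulation exclusion")
  tf_sub <- expression_matrix(tf_expr$values[candidates, , drop = FALSE],
                              experiments(tf_expr))
  prof <- concatenated_module_profile(members, expr, tf_sub)
  fold_assignments <- make_fold_assignments(unique(prof$condition), reps,
                                            folds, seed)

  evaluate_sets <- function(sets) {
    best <- NULL
    for (tfs in sets) {
      cv <- cv_prediction_correlation(
        prof$response, prof$tf_matrix[, tfs, drop = FALSE], prof$condition,
        fold_assignments = fold_assignments)
      key <- paste(sort(tfs), collapse = "+")
      if (is.null(best) || cv$mean_rho > best$rho ||
          (cv$mean_rho == best$rho && key < best$key)) {
        best <- list(tfs = sort(tfs), rho = cv$mean_rho,
                     pooled = cv$pooled_prediction, key = key)
      }
    }
    best
  }

  incumbent <- evaluate_sets(as.list(candidates))
  incumbent$bonferroni_p <- NA_real_
  order <- 1L
  while (order < max_order) {
    order <- order + 1L
    sets <- if (order <= 3) {
      if (length(candidates) < order) break
      combn_list(candidates, order)
    } else {
      extra <- setdiff(candidates, incumbent$tfs)
      if (length(extra) == 0) break
      lapply(extra, function(tf) c(incumbent$tfs, tf))
    }
    challenger <- evaluate_sets(sets)
    p <- improvement_p(prof$response, challenger$pooled, incumbent$pooled)
    bonf <- min(1, p * length(sets))
    if (bonf < alpha) {
      challenger$bonferroni_p <- bonf
      incumbent <- challenger
    } else break
  }

  fit <- fit_regression_mechanism(prof$response,
                                  prof$tf_matrix[, incumbent$tfs, drop = FALSE])
  structure(list(module_id = if (inherits(module, "TranscriptionalModule")) {
                   module$module_id
                 } else NA_character_,
                 tfs = incumbent$tfs,
                 coefficients = fit$coefficients, t_stats = fit$t_stats,
                 se = fit$se, df_residual = fit$df_residual,
                 cv_rho = incumbent$rho,
                 bonferroni_p = incumbent$bonferroni_p,
                 n_rows = length(prof$response)),
            class = "RegulatoryMechanism")
}

combn_list <- function(x, m) {
  cm <- utils::combn(x, m)
  lapply(seq_len(ncol(cm)), function(i) cm[, i])
}

#' @export
print.RegulatoryMechanism <- function(x, ...) {
  cat(sprintf("RegulatoryMechanism %s: order %d {%s}, cv_rho=%.3f\n",
              x$module_id, length(x$tfs), paste(x$tfs, collapse = ", "),
              x$cv_rho))
  invisible(x)
}

#' Classify a mechanism's coefficients
#'
#' Linear coefficients are labeled by sign (positive / negative regulation);
#' cross terms are synergistic when positive and competitive when negative.
#' A coefficient is flagged significant when its |T| exceeds the two-sided
#' critical value of the t distribution at the fit's residual degrees of
#' freedom.
#'
#' @param mechanism a fitted `RegulatoryMechanism`.
#' @param alpha two-sided significance level.
#' @return data frame `coefficient`, `kind`, `estimate`, `t_stat`,
#'   `significant`, `label`.
#' @export
classify_regulation <- function(mechanism, alpha = 0.05) {
  coefs <- mechanism$coefficients
  kind <- ifelse(names(coefs) == "(Intercept)", "intercept",
                 ifelse(grepl(":", names(coefs), fixed = TRUE),
                        "interaction", "linear"))
  crit <- stats::qt(1 - alpha / 2, mechanism$df_residual)
  label <- character(length(coefs))
  label[kind == "intercept"] <- ""
  label[kind == "linear"] <- ifelse(coefs[kind == "linear"] > 0, "positive",
                                    ifelse(coefs[kind == "linear"] < 0,
                                           "negative", "zero"))
  label[kind == "interaction"] <- ifelse(coefs[kind == "interaction"] > 0,
                                         "synergistic",
                                         ifelse(coefs[kind == "interaction"] < 0,
                                                "competitive", "none"))
  data.frame(coefficient = names(coefs), kind = kind,
             estimate = unname(coefs), t_stat = unname(mechanism$t_stats),
             significant = abs(unname(mechanism$t_stats)) > crit,
             label = label, stringsAsFactors = FALSE)
}

#' Assemble the bipartite TF-to-module network
#'
#' One edge per (TF, module) pair with the TF in the module's best regulatory
#' mechanism. When the module library is supplied, per-TF tallies of modules
#' and distinct genes regulated are included.
#'
#' @param mechanisms list of `RegulatoryMechanism` objects (one per module).
#' @param modules optional `module_library` for gene tallies.
#' @return a `RegulatoryNetwork`: `edges` (`tf`, `module`, `support`),
#'   `tf_nodes`, `module_nodes`, `tf_summary`.
#' @export
build_network <- function(mechanisms, modules = NULL) {
  ids <- vapply(mechanisms, `[[`, "", "module_id")
  assert_no_duplicates(ids, "module ids")
  edges <- do.call(rbind, c(list(data.frame(tf = character(0),
                                            module = character(0))),
                            lapply(mechanisms, function(m) {
    data.frame(tf = m$tfs, module = m$module_id, stringsAsFactors = FALSE)
  })))
  edges$support <- rep(NA_real_, nrow(edges))
  edges <- edges[order(edges$tf, edges$module), , drop = FALSE]
  rownames(edges) <- NULL
  tf_nodes <- sort(unique(edges$tf))
  member_of <- if (!is.null(modules)) {
    stats::setNames(lapply(modules, `[[`, "members"),
                    vapply(modules, `[[`, "", "module_id"))
  } else NULL
  tf_summary <- do.call(rbind, lapply(tf_nodes, function(tf) {
    mods <- edges$module[edges$tf == tf]
    data.frame(tf = tf, n_modules = length(mods),
               n_genes = if (is.null(member_of)) NA_integer_ else {
                 length(unique(unlist(member_of[mods])))
               }, stringsAsFactors = FALSE)
  }))
  structure(list(edges = edges, tf_nodes = tf_nodes,
                 module_nodes = sort(unique(ids)), tf_summary = tf_summary),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d TFs -> %d modules, %d edges\n",
              length(x$tf_nodes), length(x$module_nodes), nrow(x$edges)))
  invisible(x)
}

#' Least-squares power-law fit in log-log space
#'
#' Fits `y = a * x^b` by regressing `log(y)` on `log(x)`.
#'
#' @param x,y positive numeric vectors.
#' @return list `a`, `b`, `r_squared` (R-squared in log space).
#' @export
power_law_fit <- function(x, y) {
  if (length(unique(x)) < 3) stopf("need >= 3 distinct x values for a power-law fit")
  if (any(x <= 0) || any(y <= 0)) stopf("power-law fit needs positive values")
  ly <- log(y)
  fit <- stats::lm(ly ~ log(x))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  list(a = unname(exp(stats::coef(fit)[1])), b = unname(stats::coef(fit)[2]),
       r_squared = r2)
}

#' Power-law fit of the TF out-degree distribution
#'
#' For every distinct out-degree d >= 1, the fraction of network TFs with
#' that out-degree is computed and `fraction = a * degree^b` is fitted by
#' least squares in log-log space.
#'
#' @param network a `RegulatoryNetwork`.
#' @return list `a`, `b`, `r_squared`.
#' @export
fit_degree_power_law <- function(network) {
  deg <- table(network$edges$tf)
  deg <- deg[deg >= 1]
  tab <- table(as.integer(deg))
  if (length(tab) < 3) stopf("degenerate degree distribution (< 3 distinct degrees)")
  power_law_fit(as.numeric(names(tab)), as.numeric(tab) / sum(tab))
}

#' Predict a module profile at given conditions from a fitted mechanism
#'
#' Applies the mechanism's coefficients to TF expression; a condition at
#' which any mechanism TF is unmeasured predicts `NA`.
#'
#' @param mechanism a `RegulatoryMechanism` (or any list with `tfs` and
#'   `coefficients`).
#' @param tf_expr TF [expression_matrix()].
#' @param cond condition ids (default: all).
#' @return named numeric vector of predictions per condition.
#' @export
predict_mechanism <- function(mechanism, tf_expr, cond = conditions(tf_expr)) {
  tf_matrix <- t(tf_expr$values[mechanism$tfs, cond, drop = FALSE])
  X <- build_design(tf_matrix, mechanism$tfs)
  pred <- as.vector(X %*% mechanism$coefficients[colnames(X)])
  stats::setNames(pred, cond)
}

#' Observed-versus-predicted correlation of a module's concatenated profile
#'
#' @param mechanism a `RegulatoryMechanism`.
#' @param members member gene ids (or a `TranscriptionalModule`).
#' @param expr,tf_expr expression matrices.
#' @return Pearson correlation between the concatenated member profiles and
#'   the tiled mechanism predictions (rows with missing values dropped), or
#'   `NA` if degenerate.
#' @export
mechanism_prediction_correlation <- function(mechanism, members, expr, tf_expr) {
  members <- module_members(members)
  pred <- predict_mechanism(mechanism, tf_expr)
  cond <- conditions(expr)
  pred <- pred[cond]
  obs <- as.vector(t(expr$values[members, cond, drop = FALSE]))
  prd <- rep(unname(pred), times = length(members))
  ok <- !is.na(obs) & !is.na(prd)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(obs[ok], prd[ok]))
}
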