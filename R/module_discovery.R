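# Transcriptional module discovery: for every (center gene, correlation
# threshold) pair, a level-wise search finds motif combinations whose carrier
# genes are over-represented among the genes co-expressed with the center;
# FDR-significant rules then compete for a non-redundant module library.

#' Spearman correlation over pairwise-complete conditions
#'
#' Ranks are computed on the conditions where *both* profiles are observed
#' (not on each full profile), so missing values never distort ranks. With
#' fewer than `min_overlap` shared observed conditions the correlation is
#' undefined and `NA` is returned; downstream code treats `NA` as
#' "not co-expressed".
#'
#' @param x,y numeric profiles over the same condition index.
#' @param min_overlap minimum shared observed conditions.
#' @return Spearman's rho, or `NA` when the overlap rule fails or either
#'   subprofile is constant.
#' @export
spearman_pairwise_complete <- function(x, y, min_overlap = 10) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  xr <- rank(x[ok]); yr <- rank(y[ok])
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) return(NA_real_)
  stats::cor(xr, yr)
}

#' All-pairs pairwise-complete Spearman correlation matrix
#'
#' @param expr an [expression_matrix()].
#' @param min_overlap minimum shared observed conditions per pair.
#' @return symmetric genes x genes matrix with unit diagonal; `NA` where the
#'   overlap rule fails.
#' @export
spearman_matrix <- function(expr, min_overlap = 10) {
  v <- expr$values
  n <- nrow(v)
  if (!anyNA(v)) {
    ranks <- t(apply(v, 1, rank))
    S <- suppressWarnings(stats::cor(t(ranks)))
    S[is.na(S)] <- NA_real_
  } else {
    S <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        S[i, j] <- S[j, i] <- spearman_pairwise_complete(v[i, ], v[j, ],
                                                         min_overlap)
      }
    }
  }
  diag(S) <- 1
  dimnames(S) <- list(rownames(v), rownames(v))
  S
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` genes in the overlap between a
#' co-expressed set of size `K` and a motif-combination carrier set of size
#' `n`, drawn from a universe of `N` genes.
#'
#' @param N universe size.
#' @param K co-expressed gene count.
#' @param n carrier gene count.
#' @param k observed overlap.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
hypergeom_overlap_p <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stopf("inconsistent hypergeometric counts (N=%s K=%s n=%s k=%s)", N, K, n, k)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enumerate FDR-significant motif-combination rules
#'
#' For every center gene and every correlation threshold in `thresholds`, the
#' co-expressed set is the genes whose pairwise-complete Spearman correlation
#' to the center is at least the threshold (the center itself included).
#' Motif combinations are searched level-wise (size 1, then 2, ...): a
#' combination is only expanded while the genes carrying all its motifs still
#' include at least `min_pos` co-expressed genes (anti-monotone support
#' pruning). A combination is emitted as a rule when at least `min_pos`
#' carriers are co-expressed and at most `max_neg` carriers are not. Each
#' rule's significance is the upper-tail hypergeometric p-value for the
#' carrier / co-expressed overlap; Benjamini-Hochberg control at `fdr` is
#' applied jointly over all emitted rules, and only significant rules are
#' returned.
#'
#' @param expr an [expression_matrix()] of the (non-TF) study genes.
#' @param motifs a [motif_matrix()] covering at least the genes of `expr`.
#' @param thresholds correlation threshold grid.
#' @param min_pos minimum co-expressed carriers ("at least five genes over
#'   the threshold").
#' @param max_neg maximum carriers below the threshold.
#' @param max_combination_size largest motif combination searched.
#' @param fdr false discovery rate for Benjamini-Hochberg control.
#' @param min_overlap minimum shared conditions for a correlation to count.
#' @return data frame with one row per retained rule: `center`, `threshold`,
#'   `motifs` (list column), `positive_genes` (list column), `n_positive`,
#'   `n_negative`, `p_value`, `q_value`; sorted by p-value.
#' @export
enumerate_rules <- function(expr, motifs,
                            thresholds = seq(0.50, 0.95, by = 0.05),
                            min_pos = 5, max_neg = 50,
                            max_combination_size = 5, fdr = 0.05,
                            min_overlap = 10) {
  if (length(thresholds) == 0) stopf("empty threshold grid")
  gene_ids <- sort(genes(expr))
  missing_genes <- setdiff(gene_ids, rownames(motifs$values))
  if (length(missing_genes) > 0) {
    stopf("motif matrix does not cover genes: %s",
          paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  occ <- motifs$values[gene_ids, sort(colnames(motifs$values)), drop = FALSE] == 1
  S <- spearman_matrix(expr, min_overlap)[gene_ids, gene_ids]
  n_genes <- length(gene_ids)
  motif_ids <- colnames(occ)
  n_motifs <- length(motif_ids)

  centers <- character(0); taus <- numeric(0); combos <- list()
  pos_sets <- list(); n_pos <- integer(0); n_neg <- integer(0); pvals <- numeric(0)

  for (ci in seq_len(n_genes)) {
    cors <- S[ci, ]
    for (tau in thresholds) {
      coexpr <- !is.na(cors) & cors >= tau
      K <- sum(coexpr)
      if (K < min_pos) next
      # level 1 frontier: single motifs still supported by >= min_pos
      # co-expressed carriers
      frontier <- list()
      for (j in seq_len(n_motifs)) {
        carrier <- occ[, j]
        np <- sum(carrier & coexpr)
        if (np < min_pos) next
        frontier[[length(frontier) + 1L]] <- list(idx = j, carrier = carrier,
                                                  np = np)
      }
      level <- 1L
      while (length(frontier) > 0) {
        for (f in frontier) {
          nn <- sum(f$carrier) - f$np
          if (nn <= max_neg) {
            centers[length(centers) + 1L] <- gene_ids[ci]
            taus[length(taus) + 1L] <- tau
            combos[[length(combos) + 1L]] <- motif_ids[f$idx]
            pos_sets[[length(pos_sets) + 1L]] <- gene_ids[f$carrier & coexpr]
            n_pos[length(n_pos) + 1L] <- f$np
            n_neg[length(n_neg) + 1L] <- nn
            pvals[length(pvals) + 1L] <-
              hypergeom_overlap_p(n_genes, K, sum(f$carrier), f$np)
          }
        }
        if (level >= max_combination_size) break
        nxt <- list()
        for (f in frontier) {
          last <- f$idx[length(f$idx)]
          if (last >= n_motifs) next
          for (j in (last + 1L):n_motifs) {
            carrier <- f$carrier & occ[, j]
            np <- sum(carrier & coexpr)
            if (np < min_pos) next
            nxt[[length(nxt) + 1L]] <- list(idx = c(f$idx, j),
                                            carrier = carrier, np = np)
          }
        }
        frontier <- nxt
        level <- level + 1L
      }
    }
  }

  if (length(pvals) == 0) {
    return(data.frame(center = character(0), threshold = numeric(0),
                      motifs = I(list()), positive_genes = I(list()),
                      n_positive = integer(0), n_negative = integer(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  qvals <- stats::p.adjust(pvals, method = "BH")
  keep <- which(qvals <= fdr)
  out <- data.frame(center = centers[keep], threshold = taus[keep],
                    n_positive = n_pos[keep], n_negative = n_neg[keep],
                    p_value = pvals[keep], q_value = qvals[keep],
                    stringsAsFactors = FALSE)
  out$motifs <- combos[keep]
  out$positive_genes <- pos_sets[keep]
  ord <- order(out$p_value, -out$n_positive, out$center, out$threshold,
               vapply(out$motifs, paste, "", collapse = "+"))
  out <- out[ord, c("center", "threshold", "motifs", "positive_genes",
                    "n_positive", "n_negative", "p_value", "q_value")]
  rownames(out) <- NULL
  out
}

#' Select a representative non-redundant module library
#'
#' Rules compete greedily: sorted by ascending p-value (ties: larger positive
#' set, then center id, threshold, motif ids), a rule becomes a module only
#' if the Jaccard index between its positive gene set and every already
#' accepted module's member set is at most `max_overlap`.
#'
#' @param rules rule table from [enumerate_rules()].
#' @param max_overlap maximum allowed member-set Jaccard between accepted
#'   modules.
#' @return a list of `TranscriptionalModule` objects (class
#'   `module_library`), each holding the winning rule's center, threshold,
#'   motif combination, member genes and significance.
#' @export
select_module_library <- function(rules, max_overlap = 0.5) {
  ord <- order(rules$p_value, -rules$n_positive, rules$center, rules$threshold,
               vapply(rules$motifs, paste, "", collapse = "+"))
  accepted <- list()
  for (i in ord) {
    members <- rules$positive_genes[[i]]
    ok <- all(vapply(accepted, function(m) {
      jaccard(members, m$members) <= max_overlap
    }, logical(1)))
    if (ok) {
      accepted[[length(accepted) + 1L]] <- structure(
        list(module_id = sprintf("M%02d", length(accepted) + 1L),
             center = rules$center[i], threshold = rules$threshold[i],
             motifs = rules$motifs[[i]], members = sort(members),
             p_value = rules$p_value[i], q_value = rules$q_value[i]),
        class = "TranscriptionalModule")
    }
  }
  structure(accepted, class = "module_library")
}

#' @export
print.module_library <- function(x, ...) {
  cat(sprintf("module_library: %d modules covering %d genes\n", length(x),
              length(unique(unlist(lapply(x, `[[`, "members"))))))
  invisible(x)
}

#' @export
print.TranscriptionalModule <- function(x, ...) {
  cat(sprintf("%s: IF %s THEN corr(center=%s) >= %.2f  [%d genes, p=%.3g]\n",
              x$module_id, paste(x$motifs, collapse = " AND "), x$center,
              x$threshold, length(x$members), x$p_value))
  invisible(x)
}

# Mean pairwise pairwise-complete Spearman correlation within a gene set.
mean_pairwise_spearman <- function(values, min_overlap = 3) {
  k <- nrow(values)
  if (k < 2) return(NA_real_)
  if (!anyNA(values)) {
    ranks <- t(apply(values, 1, rank))
    C <- suppressWarnings(stats::cor(t(ranks)))
    return(mean(C[upper.tri(C)], na.rm = TRUE))
  }
  cors <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      cors <- c(cors, spearman_pairwise_complete(values[i, ], values[j, ],
                                                 min_overlap))
    }
  }
  mean(cors, na.rm = TRUE)
}

#' Per-experiment co-expression significance of a module
#'
#' Within each experiment block, the statistic is the mean pairwise Spearman
#' correlation among module members over that experiment's conditions. The
#' null distribution is the same statistic for random gene sets of equal
#' size drawn from the expression matrix; the empirical p-value uses the
#' add-one rule. Flags are descriptive (no multiplicity correction across
#' experiments).
#'
#' @param module a `TranscriptionalModule`.
#' @param expr the full [expression_matrix()].
#' @param n_perm random gene sets per experiment.
#' @param alpha significance level for the flag.
#' @param seed integer seed for the permutation draw.
#' @param min_conditions experiments with fewer conditions are skipped.
#' @param min_overlap minimum shared conditions for within-experiment
#'   correlations.
#' @return data frame: `experiment`, `n_conditions`, `mean_correlation`,
#'   `p_value`, `significant`.
#' @export
experiment_coexpression <- function(module, expr, n_perm = 1000, alpha = 0.05,
                                    seed = NULL, min_conditions = 3,
                                    min_overlap = 3) {
  exps <- experiments(expr)
  labs <- unique(unname(exps))
  members <- intersect(module$members, genes(expr))
  if (length(members) < 2) stopf("module needs >= 2 members with expression")
  with_seed(seed, {
    rows <- lapply(labs, function(lab) {
      cond <- names(exps)[exps == lab]
      if (length(cond) < min_conditions) return(NULL)
      sub <- expr$values[, cond, drop = FALSE]
      obs <- mean_pairwise_spearman(sub[members, , drop = FALSE], min_overlap)
      null <- vapply(seq_len(n_perm), function(b) {
        rnd <- sample(genes(expr), length(members))
        mean_pairwise_spearman(sub[rnd, , drop = FALSE], min_overlap)
      }, numeric(1))
      p <- (1 + sum(null >= obs, na.rm = TRUE)) / (n_perm + 1)
      data.frame(experiment = lab, n_conditions = length(cond),
                 mean_correlation = obs, p_value = p,
                 significant = p < alpha, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
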