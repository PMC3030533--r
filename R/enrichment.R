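# Functional annotation enrichment against the study-specific background,
# and the promoter-shuffling randomization used to check that discovered
# modules beat chance.

#' Annotation enrichment of a module's member genes
#'
#' Upper-tail hypergeometric test of each annotation term against the
#' background gene universe (the study's leaf-specific genes, not a whole
#' genome, so background-driven terms do not dominate). Only terms with at
#' least `min_assigned` members inside the module are tested;
#' Benjamini-Hochberg q-values are computed across the tested terms of this
#' module.
#'
#' @param module_genes character vector of member genes (must lie inside the
#'   annotation background).
#' @param annotations an [annotation_set()].
#' @param min_assigned minimum module members carrying a term for the term to
#'   be tested.
#' @param fdr significance level used for the `significant` flag.
#' @return data frame `term`, `k` (module members with the term), `K` (term
#'   size in background), `p_value`, `q_value`, `significant`, sorted by
#'   p-value.
#' @export
enrich_annotations <- function(module_genes, annotations, min_assigned = 2,
                               fdr = 0.05) {
  bg <- annotations$background
  outside <- setdiff(module_genes, bg)
  if (length(outside) > 0) {
    stopf("module genes outside the annotation background: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(bg)
  n <- length(unique(module_genes))
  rows <- lapply(names(annotations$terms), function(tm) {
    term_genes <- annotations$terms[[tm]]
    k <- length(intersect(term_genes, module_genes))
    if (k < min_assigned) return(NULL)
    K <- length(term_genes)
    data.frame(term = tm, k = k, K = K,
               p_value = hypergeom_overlap_p(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= fdr
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}

#' Promoter-shuffling randomization
#'
#' Generates random datasets by shuffling whole promoters among the genes:
#' each shuffle permutes the rows of the motif occurrence matrix, so every
#' motif keeps its carrier count and every promoter keeps its motif content,
#' but the gene-to-promoter assignment is destroyed. Module discovery run on
#' shuffled data calibrates how much significance arises by chance.
#'
#' @param motifs a [motif_matrix()].
#' @param n_shuffles number of shuffled datasets.
#' @param seed integer seed.
#' @return object of class `promoter_shuffles` holding the permutation
#'   indices; extract shuffle `i` with [get_shuffle()].
#' @export
shuffle_promoters <- function(motifs, n_shuffles = 1000, seed = NULL) {
  n_genes <- nrow(motifs$values)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) sample.int(n_genes),
             integer(n_genes)))
  })
  structure(list(motifs = motifs, perms = perms), class = "promoter_shuffles")
}

#' @rdname shuffle_promoters
#' @param shuffles a `promoter_shuffles` object.
#' @param i shuffle index in `1..n_shuffles`.
#' @return `get_shuffle()` returns the i-th shuffled [motif_matrix()]: gene
#'   ids keep their original order, gene g receives the promoter of gene
#'   `perm[g]`.
#' @export
get_shuffle <- function(shuffles, i) {
  v <- shuffles$motifs$values[shuffles$perms[i, ], , drop = FALSE]
  rownames(v) <- rownames(shuffles$motifs$values)
  motif_matrix(v)
}

#' @export
print.promoter_shuffles <- function(x, ...) {
  cat(sprintf("promoter_shuffles: %d shuffles of %d promoters\n",
              nrow(x$perms), ncol(x$perms)))
  invisible(x)
}
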