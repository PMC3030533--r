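# Containers and tab-separated I/O for every table the pipeline touches.
# All files use "NA" for missing values and "." as the decimal mark.

#' Expression matrix with condition-to-experiment labels
#'
#' Holds a genes x conditions matrix of log-ratio expression values (missing
#' entries allowed) together with a label assigning every condition to the
#' experimental study (e.g. budset, drought stress) it came from. Experiment
#' labels drive leave-one-experiment-out validation and the per-experiment
#' co-expression statistics.
#'
#' @param values numeric matrix, rows named by gene ids, columns by condition
#'   ids; `NA` marks an unmeasured value.
#' @param experiment_of character vector of experiment labels, named by
#'   condition id; must cover every column of `values`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `experiment_of`.
#' @export
expression_matrix <- function(values, experiment_of) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("expression values need gene row names and condition column names")
  }
  assert_no_duplicates(rownames(values), "gene ids")
  assert_no_duplicates(colnames(values), "condition ids")
  experiment_of <- unlist(experiment_of)
  if (is.null(names(experiment_of))) stopf("experiment_of must be named by condition id")
  assert_no_duplicates(names(experiment_of), "condition labels")
  missing_lab <- setdiff(colnames(values), names(experiment_of))
  if (length(missing_lab) > 0) {
    stopf("conditions without an experiment label: %s",
          paste(missing_lab, collapse = ", "))
  }
  experiment_of <- experiment_of[colnames(values)]
  structure(list(values = values,
                 experiment_of = as.character(stats::setNames(experiment_of, colnames(values)))),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("ExpressionMatrix: %d genes x %d conditions (%d experiments), %.1f%% missing\n",
              nrow(v), ncol(v), length(unique(experiments(x))),
              100 * mean(is.na(v))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
conditions <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
experiments <- function(x) stats::setNames(x$experiment_of, colnames(x$values))

# Subset an ExpressionMatrix by condition ids (used by hold-out analyses).
subset_conditions <- function(x, cond) {
  expression_matrix(x$values[, cond, drop = FALSE],
                    stats::setNames(experiments(x)[cond], cond))
}

#' Binary motif occurrence matrix
#'
#' A genes x motifs indicator table: entry 1 means the motif occurs at least
#' once in the gene's promoter. Occurrence matrices are produced upstream by a
#' promoter scanner (or by [generate_dataset()]); this package consumes them.
#'
#' @param values numeric or logical matrix with gene row names and motif
#'   column names; entries must be 0 or 1.
#' @return An object of class `MotifOccurrenceMatrix` wrapping the integer
#'   matrix.
#' @export
motif_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("motif occurrences need gene row names and motif column names")
  }
  assert_no_duplicates(rownames(values), "gene ids")
  assert_no_duplicates(colnames(values), "motif ids")
  if (anyNA(values) || !all(values %in% c(0, 1))) {
    stopf("motif occurrence values must all be 0 or 1")
  }
  storage.mode(values) <- "integer"
  structure(list(values = values), class = "MotifOccurrenceMatrix")
}

#' @export
print.MotifOccurrenceMatrix <- function(x, ...) {
  cat(sprintf("MotifOccurrenceMatrix: %d genes x %d motifs, density %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Read an expression table and its condition-to-experiment labels
#'
#' @param path tab-separated table: first column gene ids, header row holds
#'   condition ids, missing values written as `NA`.
#' @param labels_path tab-separated two-column table (`condition`,
#'   `experiment`) mapping every condition in `path` to one experiment label.
#' @return An [expression_matrix()]. A condition absent from the labels file
#'   is an error.
#' @export
read_expression <- function(path, labels_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  labs <- utils::read.delim(labels_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(labs) < 2) stopf("labels file must have columns condition, experiment")
  expression_matrix(values, stats::setNames(as.character(labs[[2]]), as.character(labs[[1]])))
}

#' Write an expression matrix (and optionally its labels) to TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path output table path.
#' @param labels_path optional path for the condition/experiment table.
#' @export
write_expression <- function(x, path, labels_path = NULL) {
  df <- data.frame(gene = genes(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(labels_path)) {
    labs <- data.frame(condition = conditions(x),
                       experiment = unname(experiments(x)))
    utils::write.table(labs, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a binary motif occurrence table
#'
#' @param path tab-separated table: first column gene ids, remaining columns
#'   motif ids, cells 0/1. Any other cell value is an error.
#' @return A [motif_matrix()].
#' @export
read_motif_occurrences <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  motif_matrix(values)
}

#' @rdname read_motif_occurrences
#' @param x a `MotifOccurrenceMatrix`.
#' @export
write_motif_occurrences <- function(x, path) {
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Functional annotation sets over a gene background
#'
#' @param terms named list: term id -> character vector of member genes.
#' @param background character vector, the gene universe (here: the
#'   leaf-specific genes, not the whole genome). Every annotated gene must be
#'   in the background.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(terms, background) {
  background <- as.character(background)
  assert_no_duplicates(background, "background genes")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  outside <- setdiff(unique(unlist(terms)), background)
  if (length(outside) > 0) {
    stopf("annotated genes outside the background: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  structure(list(terms = terms, background = background), class = "AnnotationSet")
}

#' Read annotations from a GMT file
#'
#' GMT lines are `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Annotated genes not present in `background` are dropped (annotation
#' transfer happens upstream and may cover more genes than the study set).
#'
#' @param path GMT file path.
#' @param background gene universe for enrichment tests.
#' @export
read_annotations_gmt <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- stats::setNames(
    lapply(parts, function(p) intersect(p[-(1:2)], background)),
    vapply(parts, `[[`, "", 1))
  annotation_set(terms, background)
}

#' @rdname read_annotations_gmt
#' @param x an `AnnotationSet`.
#' @export
write_annotations_gmt <- function(x, path) {
  lines <- vapply(names(x$terms), function(tm) {
    paste(c(tm, tm, x$terms[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Homolog map between two species' gene ids
#'
#' A partial function source gene id -> best-hit target gene id. Each source
#' maps to at most one target; unmapped sources are simply absent.
#'
#' @param map named character vector (names: source ids, values: target ids).
#' @export
homolog_map <- function(map) {
  map <- unlist(map)
  if (length(map) > 0 && is.null(names(map))) stopf("homolog map must be named by source id")
  assert_no_duplicates(names(map), "homolog map source ids")
  structure(stats::setNames(as.character(map), names(map)), class = "HomologMap")
}

#' @rdname homolog_map
#' @param path two-column TSV (`source`, `target`).
#' @export
read_homolog_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  homolog_map(stats::setNames(as.character(tab[[2]]), as.character(tab[[1]])))
}

#' @rdname homolog_map
#' @param x a `HomologMap`.
#' @export
write_homolog_map <- function(x, path) {
  utils::write.table(data.frame(source = names(x), target = as.character(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a regulatory network as a Cytoscape-ready edge table
#'
#' One line per edge: source TF, the interaction label `regulates`, target
#' module, and bootstrap support (blank when no bootstrap has been run).
#' Edges are written sorted by source then target so output is deterministic.
#'
#' @param network a `RegulatoryNetwork` from [build_network()].
#' @param path output TSV path.
#' @export
write_network_edges <- function(network, path) {
  e <- network$edges
  df <- data.frame(source = character(0), interaction = character(0),
                   target = character(0), support = character(0))
  if (nrow(e) > 0) {
    e <- e[order(e$tf, e$module), , drop = FALSE]
    supp <- if ("support" %in% names(e)) {
      ifelse(is.na(e$support), "", format(e$support, trim = TRUE))
    } else rep("", nrow(e))
    df <- data.frame(source = e$tf, interaction = "regulates",
                     target = e$module, support = supp)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edges
#' @return `read_network_edges()` returns the edge data frame (`tf`,
#'   `module`, `support`).
#' @export
read_network_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character", "character"))
  data.frame(tf = tab$source, module = tab$target,
             support = suppressWarnings(as.numeric(tab$support)))
}

#' Serialize discovered rules as IF-THEN text
#'
#' Mirrors the rule rendering of module figures:
#' `IF m1 AND m2 THEN corr(center=g) >= 0.55 (p=..., q=...)`.
#'
#' @param rules rule table from [enumerate_rules()].
#' @param path output text path.
#' @export
write_rules <- function(rules, path) {
  lines <- vapply(seq_len(nrow(rules)), function(i) {
    sprintf("IF %s THEN corr(center=%s) >= %.2f (p=%.3g, q=%.3g)",
            paste(rules$motifs[[i]], collapse = " AND "),
            rules$center[i], rules$threshold[i],
            rules$p_value[i], rules$q_value[i])
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write fitted regulatory mechanisms as a TSV summary
#'
#' One row per module: order, TF ids, fitted coefficients with their
#' T-statistics, cross-validated prediction correlation and the Bonferroni
#' corrected p-value of the order-admission test.
#'
#' @param mechanisms list of `RegulatoryMechanism` objects.
#' @param path output TSV path.
#' @export
write_mechanisms <- function(mechanisms, path) {
  rows <- lapply(mechanisms, function(m) {
    data.frame(module = m$module_id, order = length(m$tfs),
               tfs = paste(m$tfs, collapse = ","),
               coefficients = paste(sprintf("%s=%.6g", names(m$coefficients),
                                            m$coefficients), collapse = ";"),
               t_stats = paste(sprintf("%s=%.4g", names(m$t_stats), m$t_stats),
                               collapse = ";"),
               cv_rho = m$cv_rho,
               bonferroni_p = if (is.null(m$bonferroni_p)) NA_real_ else m$bonferroni_p)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
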