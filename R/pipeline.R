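# Pipeline orchestration: a flat configuration of all tunables (defaults =
# the analysis' standard values), subcommands that chain the stages through
# files, and a structured log with config hash, seeds, input checksums and
# stage timings.

#' Default pipeline configuration
#'
#' All tunable parameters with their standard values: correlation threshold
#' grid 0.50-0.95 in steps of 0.05, at least 5 positive and at most 50
#' negative genes per rule, FDR 0.05, five iterations of 5-fold
#' cross-validation, significance level 0.05, 100 bootstrap resamples,
#' conservation threshold 0.40, motif distance threshold 0.3, and 1000
#' randomization draws. Every stochastic stage consumes a seed derived from
#' the single master `seed`.
#'
#' @param ... overrides as `name = value` pairs; unknown names are an error.
#' @return named list of class `PipelineConfig`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # module discovery
    thresholds = seq(0.50, 0.95, by = 0.05), min_pos = 5, max_neg = 50,
    max_combination_size = 5, fdr = 0.05, min_overlap = 10, max_overlap = 0.5,
    # network inference
    alpha = 0.05, max_order = 4, reps = 5, folds = 5,
    # validation / transfer
    B = 100, conservation_threshold = 0.40, n_perm = 1000, n_runs = 1000,
    holdout_experiment = NULL,
    # motif reduction
    motif_distance_threshold = 0.3, motif_min_overlap = 4,
    # synthetic data
    n_genes = 200, n_tfs = 35, n_conditions = 200, n_experiments = 8,
    n_modules = 8, module_size_min = 5, module_size_max = 12, n_motifs = 40,
    motifs_per_module = 2, background_motif_rate = 0.05,
    coefficient_min = 0.5, coefficient_max = 1.5,
    noise_sd = 0.2, missing_rate = 0.05, dropout_rate = 0,
    conserved_fraction = 1,
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "PipelineConfig")
}

pipeline_subcommands <- c("simulate", "reduce-motifs", "discover-modules",
                          "enrich", "infer-network", "bootstrap",
                          "holdout-experiment", "transfer")

log_line <- function(log_path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE, sep = "")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

require_inputs <- function(paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    stopf("missing input file(s): %s", paste(unlist(missing), collapse = ", "))
  }
}

# Module library <-> JSON (stage hand-off format).
write_modules_json <- function(modules, path) {
  jsonlite::write_json(lapply(modules, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_modules_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(lapply(raw, function(m) {
    structure(list(module_id = m$module_id, center = m$center,
                   threshold = m$threshold, motifs = unlist(m$motifs),
                   members = unlist(m$members), p_value = m$p_value,
                   q_value = m$q_value), class = "TranscriptionalModule")
  }), class = "module_library")
}

write_mechanisms_json <- function(mechanisms, path) {
  # named numeric vectors must become lists or jsonlite drops the names
  out <- lapply(mechanisms, function(m) {
    m <- unclass(m)
    for (f in c("coefficients", "t_stats", "se")) m[[f]] <- as.list(m[[f]])
    m
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_mechanisms_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(m) {
    structure(list(module_id = m$module_id, tfs = unlist(m$tfs),
                   coefficients = unlist(m$coefficients),
                   t_stats = unlist(m$t_stats), se = unlist(m$se),
                   df_residual = m$df_residual, cv_rho = m$cv_rho,
                   bonferroni_p = if (is.null(m$bonferroni_p)) NA_real_ else m$bonferroni_p,
                   n_rows = m$n_rows),
              class = "RegulatoryMechanism")
  })
}

#' Run one pipeline stage
#'
#' Orchestrates the stages through files in `dir` (fixed file names, the TSV
#' and JSON formats of the I/O module). Stage seeds are derived from the
#' master seed by a fixed per-stage offset, so stages are individually
#' reproducible. A structured log (config hash, derived seed, input
#' checksums, timing) is appended to `<dir>/pipeline.log`.
#'
#' Subcommands: `simulate` (writes all synthetic inputs including the
#' target-species data and homolog map), `reduce-motifs` (needs
#' `motifs.jaspar`), `discover-modules`, `enrich` (needs
#' `annotations.gmt`), `infer-network`, `bootstrap`,
#' `holdout-experiment` (needs `config$holdout_experiment`), `transfer`.
#'
#' @param name subcommand name.
#' @param config a [default_config()].
#' @param dir working directory holding stage inputs and outputs.
#' @return invisibly, a named list of the files written. Missing inputs or an
#'   invalid configuration raise an error.
#' @export
run_subcommand <- function(name, config = default_config(), dir = ".") {
  name <- match.arg(name, pipeline_subcommands)
  if (!inherits(config, "PipelineConfig")) stopf("config must come from default_config()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(dir, "pipeline.log")
  p <- function(f) file.path(dir, f)
  stage_seed <- derive_seed(config$seed, match(name, pipeline_subcommands))
  t0 <- proc.time()[["elapsed"]]
  log_line(log_path, "stage=%s config_hash=%s seed=%d", name,
           config_hash(config), stage_seed)

  outputs <- switch(
    name,
    "simulate" = {
      ds <- generate_dataset(
        n_genes = config$n_genes, n_tfs = config$n_tfs,
        n_conditions = config$n_conditions,
        n_experiments = config$n_experiments, n_modules = config$n_modules,
        module_size_range = c(config$module_size_min, config$module_size_max),
        n_motifs = config$n_motifs, motifs_per_module = config$motifs_per_module,
        background_motif_rate = config$background_motif_rate,
        coefficient_range = c(config$coefficient_min, config$coefficient_max),
        noise_sd = config$noise_sd, missing_rate = config$missing_rate,
        seed = stage_seed)
      write_expression(ds$expr, p("expression.tsv"), p("condition_labels.tsv"))
      write_expression(ds$tf_expr, p("tf_expression.tsv"), p("tf_condition_labels.tsv"))
      write_motif_occurrences(ds$motifs, p("motif_occurrences.tsv"))
      write_ground_truth(ds$truth, p("ground_truth.json"))
      n_mod <- length(ds$truth$modules)
      conserved <- seq_len(n_mod) <= round(config$conserved_fraction * n_mod)
      tr <- generate_homolog_map(ds, dropout_rate = config$dropout_rate,
                                 conserved = conserved,
                                 seed = derive_seed(stage_seed, 99))
      write_homolog_map(tr$map, p("homolog_map.tsv"))
      write_expression(tr$target_expr, p("target_expression.tsv"),
                       p("target_condition_labels.tsv"))
      write_expression(tr$target_tf_expr, p("target_tf_expression.tsv"),
                       p("target_tf_condition_labels.tsv"))
      list(expression = p("expression.tsv"),
           condition_labels = p("condition_labels.tsv"),
           tf_expression = p("tf_expression.tsv"),
           motif_occurrences = p("motif_occurrences.tsv"),
           ground_truth = p("ground_truth.json"),
           homolog_map = p("homolog_map.tsv"),
           target_expression = p("target_expression.tsv"))
    },
    "reduce-motifs" = {
      require_inputs(list(p("motifs.jaspar")))
      pfms <- read_jaspar(p("motifs.jaspar"))
      kept <- reduce_redundant_motifs(pfms,
                                      threshold = config$motif_distance_threshold,
                                      min_overlap = config$motif_min_overlap)
      write_motif_ids(kept, p("retained_motifs.txt"))
      list(retained_motifs = p("retained_motifs.txt"))
    },
    "discover-modules" = {
      require_inputs(list(p("expression.tsv"), p("condition_labels.tsv"),
                          p("motif_occurrences.tsv")))
      expr <- read_expression(p("expression.tsv"), p("condition_labels.tsv"))
      motifs <- read_motif_occurrences(p("motif_occurrences.tsv"))
      rules <- enumerate_rules(expr, motifs, thresholds = config$thresholds,
                               min_pos = config$min_pos,
                               max_neg = config$max_neg,
                               max_combination_size = config$max_combination_size,
                               fdr = config$fdr,
                               min_overlap = config$min_overlap)
      modules <- select_module_library(rules, max_overlap = config$max_overlap)
      write_rules(rules, p("rules.txt"))
      write_modules_json(modules, p("modules.json"))
      list(rules = p("rules.txt"), modules = p("modules.json"))
    },
    "enrich" = {
      require_inputs(list(p("modules.json"), p("annotations.gmt"),
                          p("expression.tsv"), p("condition_labels.tsv")))
      expr <- read_expression(p("expression.tsv"), p("condition_labels.tsv"))
      ann <- read_annotations_gmt(p("annotations.gmt"), genes(expr))
      modules <- read_modules_json(p("modules.json"))
      rows <- do.call(rbind, lapply(modules, function(mod) {
        res <- enrich_annotations(mod$members, ann, fdr = config$fdr)
        if (nrow(res) == 0) return(NULL)
        cbind(module = mod$module_id, res)
      }))
      if (is.null(rows)) {
        rows <- data.frame(module = character(0), term = character(0),
                           k = integer(0), K = integer(0),
                           p_value = numeric(0), q_value = numeric(0),
                           significant = logical(0))
      }
      utils::write.table(rows, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(enrichment = p("enrichment.tsv"))
    },
    "infer-network" = {
      require_inputs(list(p("expression.tsv"), p("condition_labels.tsv"),
                          p("tf_expression.tsv"), p("modules.json")))
      expr <- read_expression(p("expression.tsv"), p("condition_labels.tsv"))
      tf_expr <- read_expression(p("tf_expression.tsv"), p("condition_labels.tsv"))
      modules <- read_modules_json(p("modules.json"))
      res <- infer_network(expr, tf_expr, modules, alpha = config$alpha,
                           max_order = config$max_order, reps = config$reps,
                           folds = config$folds, seed = stage_seed)
      write_mechanisms_json(res$mechanisms, p("mechanisms.json"))
      write_mechanisms(res$mechanisms, p("mechanisms.tsv"))
      write_network_edges(res$network, p("network_edges.tsv"))
      list(mechanisms = p("mechanisms.json"),
           network_edges = p("network_edges.tsv"))
    },
    "bootstrap" = {
      require_inputs(list(p("expression.tsv"), p("condition_labels.tsv"),
                          p("tf_expression.tsv"), p("modules.json")))
      expr <- read_expression(p("expression.tsv"), p("condition_labels.tsv"))
      tf_expr <- read_expression(p("tf_expression.tsv"), p("condition_labels.tsv"))
      modules <- read_modules_json(p("modules.json"))
      report <- bootstrap_analysis(expr, tf_expr, modules, B = config$B,
                                   seed = stage_seed, alpha = config$alpha,
                                   max_order = config$max_order,
                                   reps = config$reps, folds = config$folds)
      write_network_edges(report$network, p("bootstrap_edges.tsv"))
      utils::write.table(report$gene_holdout, p("bootstrap_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(bootstrap_edges = p("bootstrap_edges.tsv"),
           bootstrap_genes = p("bootstrap_genes.tsv"))
    },
    "holdout-experiment" = {
      require_inputs(list(p("expression.tsv"), p("condition_labels.tsv"),
                          p("tf_expression.tsv"), p("modules.json")))
      if (is.null(config$holdout_experiment)) {
        stopf("config$holdout_experiment must name the experiment to hold out")
      }
      expr <- read_expression(p("expression.tsv"), p("condition_labels.tsv"))
      tf_expr <- read_expression(p("tf_expression.tsv"), p("condition_labels.tsv"))
      modules <- read_modules_json(p("modules.json"))
      res <- leave_one_experiment_out(expr, tf_expr, modules,
                                      experiment = config$holdout_experiment,
                                      alpha = config$alpha,
                                      max_order = config$max_order,
                                      reps = config$reps,
                                      folds = config$folds, seed = stage_seed)
      out <- p(sprintf("holdout_%s.tsv", config$holdout_experiment))
      utils::write.table(res$genes, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(holdout = out)
    },
    "transfer" = {
      require_inputs(list(p("mechanisms.json"), p("modules.json"),
                          p("homolog_map.tsv"), p("target_expression.tsv"),
                          p("target_condition_labels.tsv"),
                          p("target_tf_expression.tsv")))
      mechanisms <- read_mechanisms_json(p("mechanisms.json"))
      modules <- read_modules_json(p("modules.json"))
      map <- read_homolog_map(p("homolog_map.tsv"))
      target_expr <- read_expression(p("target_expression.tsv"),
                                     p("target_condition_labels.tsv"))
      target_tf <- read_expression(p("target_tf_expression.tsv"),
                                   p("target_condition_labels.tsv"))
      proj <- project_mechanisms(mechanisms, modules, map, target_expr,
                                 target_tf)
      scores <- conservation_scores(proj, target_expr, target_tf,
                                    threshold = config$conservation_threshold)
      null <- module_randomization_null(proj, target_expr, target_tf,
                                        n_runs = config$n_runs,
                                        seed = stage_seed)
      scores$null_q95 <- null$q95
      utils::write.table(scores, p("conservation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA")
      list(conservation = p("conservation.tsv"))
    })

  for (f in unlist(outputs)) {
    log_line(log_path, "stage=%s output=%s md5=%s", name, basename(f),
             unname(tools::md5sum(f)))
  }
  log_line(log_path, "stage=%s elapsed=%.1fs", name,
           proc.time()[["elapsed"]] - t0)
  invisible(outputs)
}
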