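# Synthetic benchmark generator: expression, motif occurrences, annotations
# and homolog maps with planted transcriptional modules and regulatory
# mechanisms, so every pipeline stage can be checked against ground truth.

#' Generate a synthetic dataset with planted modules and mechanisms
#'
#' Emulates the structure of a leaf co-expression compendium: transcription
#' factor profiles are drawn i.i.d. standard normal per condition; each
#' planted module has a latent profile computed from its planted regulatory
#' mechanism (intercept, linear TF terms, and pairwise TF-product cross
#' terms); member genes are the latent profile plus independent Gaussian
#' noise and share the module's motif combination in their promoters; all
#' genes additionally carry each motif at a background rate; entries are
#' masked missing independently; remaining genes are unstructured noise.
#' Conditions are split into contiguous, near-equal experiment blocks.
#'
#' Defaults mirror a compendium with a few hundred profiled genes, ~35
#' transcription factors, and mostly positive linear regulation with a slight
#' excess of synergistic over competitive cross terms.
#'
#' @param n_genes number of non-TF genes profiled.
#' @param n_tfs number of transcription factors (profiled separately).
#' @param n_conditions number of expression conditions (>= 20).
#' @param n_experiments number of experiment blocks the conditions divide into.
#' @param n_modules number of planted transcriptional modules.
#' @param module_size_range integer range of module sizes (min >= 5).
#' @param n_motifs total number of motifs in the occurrence matrix; must
#'   accommodate `n_modules * motifs_per_module` disjoint planted motifs.
#' @param motifs_per_module motifs in each planted combination (1..5).
#' @param background_motif_rate probability that any gene carries any motif
#'   irrespective of planting.
#' @param coefficient_range magnitude range for linear and cross-term
#'   coefficients.
#' @param interaction_mix named probabilities `synergistic` / `competitive` /
#'   `none` for the sign of each cross term (mechanisms of order >= 2 only).
#' @param linear_positive_rate probability a linear coefficient is positive.
#' @param mechanism_orders optional integer vector (recycled over modules) of
#'   mechanism orders, each in 1..4; default samples 1..3.
#' @param noise_sd standard deviation of gene-level noise around the latent
#'   module profile.
#' @param missing_rate independent missingness probability for every
#'   expression entry (genes and TFs).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return A list of class `leafnet_dataset`: `expr` and `tf_expr`
#'   ([expression_matrix()]), `motifs` ([motif_matrix()]), and `truth`, a
#'   `SyntheticGroundTruth` list describing every planted module (members,
#'   motif combination, TF set, coefficients, interaction labels).
#' @export
generate_dataset <- function(n_genes = 200, n_tfs = 35, n_conditions = 200,
                             n_experiments = 8, n_modules = 8,
                             module_size_range = c(5, 12), n_motifs = 40,
                             motifs_per_module = 2,
                             background_motif_rate = 0.05,
                             coefficient_range = c(0.5, 1.5),
                             interaction_mix = c(synergistic = 0.56,
                                                 competitive = 0.44,
                                                 none = 0),
                             linear_positive_rate = 0.88,
                             mechanism_orders = NULL,
                             noise_sd = 0.2, missing_rate = 0.05, seed = 1) {
  if (n_conditions < 20) stopf("n_conditions must be >= 20")
  if (module_size_range[1] < 5) stopf("module sizes must be >= 5")
  if (motifs_per_module < 1 || motifs_per_module > 5) {
    stopf("motifs_per_module must be in 1..5")
  }
  if (n_motifs < n_modules * motifs_per_module) {
    stopf("n_motifs too small for %d disjoint combinations of %d motifs",
          n_modules, motifs_per_module)
  }
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0,1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  mix <- interaction_mix[c("synergistic", "competitive", "none")]
  mix[is.na(mix)] <- 0
  if (sum(mix) <= 0) stopf("interaction_mix must have positive mass")
  mix <- mix / sum(mix)
  if (n_modules * module_size_range[2] > n_genes) {
    stopf("n_genes too small for %d modules of up to %d genes",
          n_modules, module_size_range[2])
  }

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  tf_ids <- sprintf("tf%03d", seq_len(n_tfs))
  cond_ids <- sprintf("c%04d", seq_len(n_conditions))
  motif_ids <- sprintf("mot%03d", seq_len(n_motifs))
  experiment_of <- stats::setNames(
    sprintf("exp%02d", as.integer(cut(seq_len(n_conditions), n_experiments,
                                      labels = FALSE))),
    cond_ids)

  with_seed(seed, {
    tf_values <- matrix(stats::rnorm(n_tfs * n_conditions), n_tfs, n_conditions,
                        dimnames = list(tf_ids, cond_ids))

    orders <- if (is.null(mechanism_orders)) {
      sample(1:3, n_modules, replace = TRUE)
    } else rep_len(as.integer(mechanism_orders), n_modules)
    if (any(orders < 1 | orders > 4)) stopf("mechanism orders must be in 1..4")
    if (max(orders) > n_tfs) stopf("n_tfs smaller than the largest mechanism order")

    size_choices <- seq(module_size_range[1], module_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_modules,
                                     replace = TRUE)]
    member_pool <- sample(gene_ids, sum(sizes))
    member_split <- split(member_pool, rep(seq_len(n_modules), times = sizes))
    motif_pool <- sample(motif_ids, n_modules * motifs_per_module)
    motif_split <- split(motif_pool, rep(seq_len(n_modules), each = motifs_per_module))

    modules <- vector("list", n_modules)
    expr_values <- matrix(stats::rnorm(n_genes * n_conditions), n_genes,
                          n_conditions, dimnames = list(gene_ids, cond_ids))
    for (m in seq_len(n_modules)) {
      mech <- draw_mechanism(tf_ids, orders[m], coefficient_range, mix,
                             linear_positive_rate)
      latent <- evaluate_mechanism(mech, tf_values)
      members <- sort(member_split[[m]])
      for (g in members) {
        expr_values[g, ] <- latent +
          stats::rnorm(n_conditions, sd = noise_sd)
      }
      modules[[m]] <- c(list(module = sprintf("P%02d", m),
                             members = members,
                             motifs = sort(motif_split[[m]])), mech)
    }

    occ <- matrix(as.integer(stats::runif(n_genes * n_motifs) < background_motif_rate),
                  n_genes, n_motifs, dimnames = list(gene_ids, motif_ids))
    for (mod in modules) occ[mod$members, mod$motifs] <- 1L

    if (missing_rate > 0) {
      expr_values[stats::runif(length(expr_values)) < missing_rate] <- NA_real_
      tf_values[stats::runif(length(tf_values)) < missing_rate] <- NA_real_
    }

    truth <- structure(list(modules = modules, noise_sd = noise_sd,
                            missing_rate = missing_rate,
                            background_motif_rate = background_motif_rate,
                            coefficient_range = coefficient_range,
                            interaction_mix = mix,
                            linear_positive_rate = linear_positive_rate,
                            seed = seed),
                       class = "SyntheticGroundTruth")
    structure(list(expr = expression_matrix(expr_values, experiment_of),
                   tf_expr = expression_matrix(tf_values, experiment_of),
                   motifs = motif_matrix(occ),
                   truth = truth),
              class = "leafnet_dataset")
  })
}

# Draw one regulatory mechanism: TF set, intercept, linear coefficients with
# sign from linear_positive_rate, and a cross term per TF pair whose sign (or
# absence) follows the interaction mix.
draw_mechanism <- function(tf_ids, order, coefficient_range, mix,
                           linear_positive_rate) {
  tfs <- sort(sample(tf_ids, order))
  beta0 <- stats::runif(1, -0.5, 0.5)
  beta <- stats::runif(order, coefficient_range[1], coefficient_range[2]) *
    ifelse(stats::runif(order) < linear_positive_rate, 1, -1)
  names(beta) <- tfs
  beta_cross <- numeric(0)
  interaction <- character(0)
  if (order >= 2) {
    pairs <- utils::combn(tfs, 2)
    kinds <- sample(c("synergistic", "competitive", "none"), ncol(pairs),
                    replace = TRUE, prob = mix)
    mag <- stats::runif(ncol(pairs), coefficient_range[1], coefficient_range[2])
    beta_cross <- ifelse(kinds == "none", 0,
                         ifelse(kinds == "synergistic", mag, -mag))
    names(beta_cross) <- paste(pairs[1, ], pairs[2, ], sep = ":")
    interaction <- stats::setNames(kinds, names(beta_cross))
  }
  list(tfs = tfs, beta0 = beta0, beta = beta, beta_cross = beta_cross,
       interaction = interaction)
}

# Latent module profile m = beta0 + sum_j beta_j t_j + sum_{j<k} beta_jk t_j t_k.
evaluate_mechanism <- function(mech, tf_values) {
  out <- rep(mech$beta0, ncol(tf_values))
  for (tf in names(mech$beta)) out <- out + mech$beta[[tf]] * tf_values[tf, ]
  if (length(mech$beta_cross) > 0) {
    pairs <- strsplit(names(mech$beta_cross), ":", fixed = TRUE)
    for (i in seq_along(pairs)) {
      out <- out + mech$beta_cross[[i]] *
        tf_values[pairs[[i]][1], ] * tf_values[pairs[[i]][2], ]
    }
  }
  stats::setNames(out, colnames(tf_values))
}

#' Simulate a homolog map and a target-species dataset
#'
#' Builds the inputs for the cross-species transfer analysis: a best-hit
#' homolog map from the source gene/TF ids to renamed target ids (each source
#' omitted with probability `dropout_rate`), and a target-species dataset
#' re-simulated on freshly drawn TF profiles. A module flagged conserved
#' keeps its planted mechanism (same TFs, same coefficients) so its regulation
#' transfers; a diverged module is rewired: it gets a freshly drawn mechanism
#' whose regulator set is disjoint from its source regulators, emulating
#' regulation that changed between the species while the genes still exist.
#'
#' @param dataset a `leafnet_dataset` from [generate_dataset()].
#' @param dropout_rate probability, in \[0,1\], that a source gene or TF has
#'   no homolog (rate 1 gives an empty map).
#' @param conserved logical vector (recycled over planted modules): keep the
#'   mechanism (`TRUE`) or rewire it (`FALSE`). Default: all conserved.
#' @param n_target_conditions number of target-species conditions; defaults
#'   to the source condition count.
#' @param noise_sd,missing_rate target-side noise and missingness; default to
#'   the source values.
#' @param seed integer seed.
#' @return A list of class `leafnet_transfer_dataset`: `map`
#'   ([homolog_map()]), `target_expr`, `target_tf_expr`, `conserved` (named
#'   logical per planted module), and `target_truth` (the mechanisms actually
#'   used in the target species).
#' @export
generate_homolog_map <- function(dataset, dropout_rate = 0, conserved = NULL,
                                 n_target_conditions = NULL,
                                 noise_sd = NULL, missing_rate = NULL,
                                 seed = 1) {
  if (dropout_rate < 0 || dropout_rate > 1) stopf("dropout_rate must be in [0,1]")
  truth <- dataset$truth
  n_mod <- length(truth$modules)
  conserved <- if (is.null(conserved)) rep(TRUE, n_mod) else rep_len(conserved, n_mod)
  names(conserved) <- vapply(truth$modules, `[[`, "", "module")
  noise_sd <- if (is.null(noise_sd)) truth$noise_sd else noise_sd
  missing_rate <- if (is.null(missing_rate)) truth$missing_rate else missing_rate

  src_genes <- genes(dataset$expr)
  src_tfs <- genes(dataset$tf_expr)
  n_cond <- if (is.null(n_target_conditions)) ncol(dataset$expr$values) else n_target_conditions
  cond_ids <- sprintf("tc%04d", seq_len(n_cond))
  n_experiments <- length(unique(experiments(dataset$expr)))
  experiment_of <- stats::setNames(
    sprintf("texp%02d", as.integer(cut(seq_len(n_cond), n_experiments,
                                       labels = FALSE))),
    cond_ids)

  with_seed(seed, {
    all_src <- c(src_genes, src_tfs)
    kept <- all_src[stats::runif(length(all_src)) >= dropout_rate]
    map <- if (length(kept) == 0) homolog_map(character(0)) else {
      homolog_map(stats::setNames(paste0("at_", kept), kept))
    }

    tgt_tf_values <- matrix(stats::rnorm(length(src_tfs) * n_cond),
                            length(src_tfs), n_cond,
                            dimnames = list(paste0("at_", src_tfs), cond_ids))
    tgt_expr <- matrix(stats::rnorm(length(src_genes) * n_cond),
                       length(src_genes), n_cond,
                       dimnames = list(paste0("at_", src_genes), cond_ids))

    target_mechs <- vector("list", n_mod)
    for (m in seq_len(n_mod)) {
      mod <- truth$modules[[m]]
      mech <- if (conserved[m]) {
        mod[c("tfs", "beta0", "beta", "beta_cross", "interaction")]
      } else {
        other_tfs <- setdiff(src_tfs, mod$tfs)
        draw_mechanism(other_tfs, min(length(mod$tfs), length(other_tfs)),
                       truth$coefficient_range, truth$interaction_mix,
                       truth$linear_positive_rate)
      }
      tgt_mech <- mech
      tgt_mech$tfs <- paste0("at_", mech$tfs)
      names(tgt_mech$beta) <- paste0("at_", names(mech$beta))
      if (length(mech$beta_cross) > 0) {
        names(tgt_mech$beta_cross) <- vapply(
          strsplit(names(mech$beta_cross), ":", fixed = TRUE),
          function(p) paste(paste0("at_", p), collapse = ":"), "")
      }
      latent <- evaluate_mechanism(tgt_mech, tgt_tf_values)
      for (g in paste0("at_", mod$members)) {
        tgt_expr[g, ] <- latent + stats::rnorm(n_cond, sd = noise_sd)
      }
      target_mechs[[m]] <- c(list(module = mod$module,
                                  members = paste0("at_", mod$members),
                                  conserved = unname(conserved[m])), tgt_mech)
    }

    if (missing_rate > 0) {
      tgt_expr[stats::runif(length(tgt_expr)) < missing_rate] <- NA_real_
      tgt_tf_values[stats::runif(length(tgt_tf_values)) < missing_rate] <- NA_real_
    }

    structure(list(map = map,
                   target_expr = expression_matrix(tgt_expr, experiment_of),
                   target_tf_expr = expression_matrix(tgt_tf_values, experiment_of),
                   conserved = conserved,
                   target_truth = target_mechs),
              class = "leafnet_transfer_dataset")
  })
}

#' Write the planted ground truth as JSON
#'
#' @param truth the `SyntheticGroundTruth` element of a dataset.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
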