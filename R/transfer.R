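# Cross-species mechanism transfer: project fitted mechanisms through a
# best-hit homolog map into a second species' expression data, score module
# conservation by observed-vs-predicted correlation with carried-over
# coefficients (no refitting), and compare against a gene-shuffling null.

#' Project regulatory mechanisms through a homolog map
#'
#' Every module's member genes and mechanism TFs are replaced by their
#' homologs; coefficients are carried over unchanged (the question is whether
#' the TF-to-module relationship is conserved, not whether it can be
#' refitted). A module is marked unmapped when any member gene or mechanism
#' TF lacks a homolog or the homolog lacks target expression.
#'
#' @param mechanisms list of `RegulatoryMechanism` objects.
#' @param modules the `module_library` the mechanisms were fitted on.
#' @param map a [homolog_map()].
#' @param target_expr,target_tf_expr target-species expression matrices.
#' @return list `projected` (per mapped module: `module_id`, `members` in
#'   target ids, `mechanism` with renamed TFs/coefficients) and `unmapped`
#'   (data frame `module`, `reason`).
#' @export
project_mechanisms <- function(mechanisms, modules, map, target_expr,
                               target_tf_expr) {
  module_ids <- vapply(modules, `[[`, "", "module_id")
  projected <- list()
  unmapped <- list()
  for (i in seq_along(mechanisms)) {
    mech <- mechanisms[[i]]
    mod <- modules[[match(mech$module_id, module_ids)]]
    reason <- NULL
    if (!all(mod$members %in% names(map))) {
      reason <- "member gene without homolog"
    } else if (!all(mech$tfs %in% names(map))) {
      reason <- "regulator without homolog"
    } else {
      tgt_members <- unname(map[mod$members])
      tgt_tfs <- unname(map[mech$tfs])
      if (!all(tgt_members %in% genes(target_expr))) {
        reason <- "homolog without target expression"
      } else if (!all(tgt_tfs %in% genes(target_tf_expr))) {
        reason <- "regulator homolog without target expression"
      }
    }
    if (!is.null(reason)) {
      unmapped[[length(unmapped) + 1L]] <-
        data.frame(module = mech$module_id, reason = reason,
                   stringsAsFactors = FALSE)
      next
    }
    tf_map <- stats::setNames(unname(map[mech$tfs]), mech$tfs)
    coefs <- mech$coefficients
    new_names <- vapply(names(coefs), function(nm) {
      if (nm == "(Intercept)") return(nm)
      if (grepl(":", nm, fixed = TRUE)) {
        pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
        paste(sort(unname(tf_map[pair])), collapse = ":")
      } else unname(tf_map[nm])
    }, "")
    names(coefs) <- new_names
    projected[[length(projected) + 1L]] <- list(
      module_id = mech$module_id,
      members = sort(unname(map[mod$members])),
      mechanism = list(module_id = mech$module_id,
                       tfs = sort(unname(tf_map)), coefficients = coefs))
  }
  list(projected = projected,
       unmapped = if (length(unmapped) > 0) do.call(rbind, unmapped) else
         data.frame(module = character(0), reason = character(0)))
}

#' Conservation scores of projected mechanisms
#'
#' Per mapped module: the concatenated homolog-gene profile is predicted
#' from homolog-TF expression with the carried-over coefficients and the
#' observed-versus-predicted Pearson correlation computed; the module is
#' conserved when the correlation reaches `threshold`. The theoretically
#' optimal reference (mean per-gene correlation to the module's mean target
#' profile) is reported alongside.
#'
#' @param projection result of [project_mechanisms()].
#' @param target_expr,target_tf_expr target-species expression matrices.
#' @param threshold conservation correlation cut-off.
#' @return a `ConservationReport` data frame: `module`, `status` (conserved /
#'   non-conserved / unmapped), `rho`, `optimal_rho`; the threshold is kept
#'   as an attribute.
#' @export
conservation_scores <- function(projection, target_expr, target_tf_expr,
                                threshold = 0.40) {
  if (length(projection$projected) == 0) stopf("no mapped modules to score")
  rows <- lapply(projection$projected, function(pm) {
    rho <- mechanism_prediction_correlation(pm$mechanism, pm$members,
                                            target_expr, target_tf_expr)
    opt <- mean(optimal_module_prediction(pm$members, target_expr)$rho,
                na.rm = TRUE)
    data.frame(module = pm$module_id,
               status = if (!is.na(rho) && rho >= threshold) "conserved"
                        else "non-conserved",
               rho = rho, optimal_rho = opt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (nrow(projection$unmapped) > 0) {
    out <- rbind(out, data.frame(module = projection$unmapped$module,
                                 status = "unmapped", rho = NA_real_,
                                 optimal_rho = NA_real_))
  }
  out <- out[order(out$module), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("ConservationReport", class(out))
  out
}

#' Gene-shuffling conservation null
#'
#' Random reassignment of the target genes to modules (module sizes
#' preserved, gene pool = union of mapped module members): per run, each
#' module's conservation correlation is recomputed for its random member
#' set. The pooled null distribution and its 95th percentile (an implied
#' data-driven conservation threshold) are returned.
#'
#' @param projection result of [project_mechanisms()] (>= 1 mapped module).
#' @param target_expr,target_tf_expr target-species expression matrices.
#' @param n_runs number of random assignments.
#' @param seed integer seed.
#' @return list `null` (pooled correlations), `per_module` (runs x modules
#'   matrix), `q95` (implied threshold).
#' @export
module_randomization_null <- function(projection, target_expr, target_tf_expr,
                                      n_runs = 1000, seed = NULL) {
  pms <- projection$projected
  if (length(pms) == 0) stopf("no mapped modules")
  pool <- unlist(lapply(pms, `[[`, "members"))
  sizes <- vapply(pms, function(pm) length(pm$members), integer(1))
  # precompute per-module predictions once; only gene assignment varies
  preds <- lapply(pms, function(pm) {
    predict_mechanism(pm$mechanism, target_tf_expr)
  })
  cond <- conditions(target_expr)
  per_module <- matrix(NA_real_, n_runs, length(pms),
                       dimnames = list(NULL, vapply(pms, `[[`, "", "module_id")))
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      shuffled <- sample(pool)
      start <- 1L
      for (m in seq_along(pms)) {
        members <- shuffled[start:(start + sizes[m] - 1L)]
        start <- start + sizes[m]
        obs <- as.vector(t(target_expr$values[members, cond, drop = FALSE]))
        prd <- rep(unname(preds[[m]][cond]), times = sizes[m])
        ok <- !is.na(obs) & !is.na(prd)
        if (sum(ok) >= 3) {
          per_module[run, m] <- suppressWarnings(stats::cor(obs[ok], prd[ok]))
        }
      }
    }
  })
  null <- as.vector(per_module)
  list(null = null[!is.na(null)], per_module = per_module,
       q95 = stats::quantile(null, 0.95, na.rm = TRUE, names = FALSE))
}
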