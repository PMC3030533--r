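# Shared fixture builders. Everything is generated in code; no stored data.

# Tiny expression matrix from a plain matrix (one experiment unless given).
make_expr <- function(values, experiment = NULL) {
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(ncol(values)))
  if (is.null(experiment)) experiment <- rep("e1", ncol(values))
  expression_matrix(values, stats::setNames(experiment, colnames(values)))
}

# The benchmark scale used throughout: 60 genes, 10 TFs, 200 conditions,
# 4 planted modules with mechanism orders 1, 2, 3, 3.
benchmark_dataset <- function(seed = 7, noise_sd = 0, missing_rate = 0,
                              background_motif_rate = 0) {
  generate_dataset(n_genes = 60, n_tfs = 10, n_conditions = 200,
                   n_experiments = 5, n_modules = 4,
                   module_size_range = c(6, 9), n_motifs = 12,
                   motifs_per_module = 2,
                   background_motif_rate = background_motif_rate,
                   mechanism_orders = c(1, 2, 3, 3),
                   noise_sd = noise_sd, missing_rate = missing_rate,
                   seed = seed)
}

# Best member-set Jaccard of each planted module against a discovered library;
# returns a data frame with the best index and Jaccard per planted module.
match_planted <- function(library, truth) {
  do.call(rbind, lapply(truth$modules, function(mod) {
    jacs <- vapply(library, function(m) {
      length(intersect(m$members, mod$members)) /
        length(union(m$members, mod$members))
    }, numeric(1))
    best <- which.max(jacs)
    data.frame(planted = mod$module, best = best, jaccard = jacs[best])
  }))
}

# Exact-rational enumeration oracle for the upper-tail hypergeometric
# probability: counts favorable draws directly via binomial coefficients
# (exact in doubles at these sizes).
hyper_upper_oracle <- function(N, K, n, k) {
  num <- 0
  for (x in seq(k, min(K, n))) {
    if (x <= K && (n - x) <= (N - K)) num <- num + choose(K, x) * choose(N - K, n - x)
  }
  num / choose(N, n)
}

# Independently coded Williams formula (kept separate from the package code).
williams_oracle <- function(r_oa, r_ob, r_ab, n) {
  rb <- (r_oa + r_ob) / 2
  detR <- 1 - r_oa^2 - r_ob^2 - r_ab^2 + 2 * r_oa * r_ob * r_ab
  tt <- (r_oa - r_ob) *
    sqrt(((n - 1) * (1 + r_ab)) /
         (2 * detR * (n - 1) / (n - 3) + rb^2 * (1 - r_ab)^3))
  list(t = tt, p = 2 * stats::pt(-abs(tt), n - 3))
}

# Monte-Carlo null oracle for the dependent-correlation test: simulate the
# trivariate-normal null (rho_oa = rho_ob = mean r, rho_ab as observed) and
# estimate P(|r1 - r2| >= observed difference).
mc_nullsim_p <- function(r_oa, r_ob, r_ab, n, nsim = 10000, seed = 1) {
  rbar <- (r_oa + r_ob) / 2
  Sigma <- matrix(c(1, rbar, rbar, rbar, 1, r_ab, rbar, r_ab, 1), 3, 3)
  L <- chol(Sigma)
  obs <- abs(r_oa - r_ob)
  cnt <- 0
  set.seed(seed)
  for (i in seq_len(nsim)) {
    X <- matrix(stats::rnorm(3 * n), n, 3) %*% L
    if (abs(stats::cor(X[, 1], X[, 2]) - stats::cor(X[, 1], X[, 3])) >=
        obs - 1e-12) cnt <- cnt + 1
  }
  cnt / nsim
}

make_fold_assignments_test <- function(...) leafnet:::make_fold_assignments(...)

# PFM with fixed probabilities from a seed (columns normalized).
random_pfm <- function(id, len, seed) {
  set.seed(seed)
  pfm(id, matrix(stats::runif(4 * len, 0.05, 1), 4, len))
}
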