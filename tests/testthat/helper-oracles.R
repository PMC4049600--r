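# Independent oracles and shared fixtures. Oracles never call the code paths
# they check.

# --- oracles ----------------------------------------------------------------

# OLS via explicit normal equations
normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# Pearson correlation of average ranks
rank_pearson <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# pooled-variance two-sample t from first principles
pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# mixed-design (one between, one within) ANOVA by cell-means decomposition
cellmeans_mixed_anova <- function(M, groups) {
  groups <- factor(groups)
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  subj_mean <- rowMeans(M)
  comp_mean <- colMeans(M)
  group_mean <- tapply(subj_mean, groups, mean)
  cell_mean <- apply(M, 2, function(col) tapply(col, groups, mean))  # g x k
  ng <- table(groups)

  ss_group <- k * sum(ng * (group_mean - grand)^2)
  ss_subj_within <- k * sum((subj_mean - group_mean[groups])^2)
  ss_comp <- n * sum((comp_mean - grand)^2)
  ss_cells <- sum(as.numeric(ng) * (cell_mean - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_comp
  resid <- M
  for (g in levels(groups)) {
    for (j in seq_len(k)) {
      resid[groups == g, j] <- M[groups == g, j] - cell_mean[g, j] -
        (subj_mean[groups == g] - group_mean[g])
    }
  }
  ss_err_within <- sum(resid^2)

  df_group <- nlevels(groups) - 1
  df_subj <- n - nlevels(groups)
  df_comp <- k - 1
  df_inter <- df_group * df_comp
  df_err <- df_subj * df_comp
  list(
    group = c(F = (ss_group / df_group) / (ss_subj_within / df_subj),
              df1 = df_group, df2 = df_subj),
    component = c(F = (ss_comp / df_comp) / (ss_err_within / df_err),
                  df1 = df_comp, df2 = df_err),
    interaction = c(F = (ss_inter / df_inter) / (ss_err_within / df_err),
                    df1 = df_inter, df2 = df_err))
}

# Amari index between a mixing matrix and an unmixing estimate (0 = perfect
# recovery up to scale/permutation)
amari_distance <- function(W, A) {
  P <- abs(W %*% A)
  k <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * k * (k - 1))
}

# analytic time derivative g'(t) of the double-gamma HRF: the limit of the
# backward finite difference (g(t) - g(t - s)) / s as the onset shift s -> 0
analytic_time_derivative <- function(t, d1 = 6, d2 = 16, ratio = 1 / 6) {
  dg <- function(tt, a) {
    out <- numeric(length(tt))
    pos <- tt > 0
    out[pos] <- stats::dgamma(tt[pos], shape = a) *
      ((a - 1) / tt[pos] - 1)
    out
  }
  dg(t, d1) - ratio * dg(t, d2)
}

# --- shared fixtures (computed once per test run) ---------------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

small_schedule <- function() {
  fixture("schedule", function() build_schedule(seed = 3))
}

# 8 planted sources, 6 + 6 subjects, low noise: the workhorse dataset for
# ICA, regression and reporting tests
small_study <- function() {
  fixture("study", function() {
    cfg <- simulation_config(grid_dims = c(12, 12, 8), n_sources = 8,
                             n_subjects_per_group = 6, noise_sd = 0.02,
                             drift_amplitude = 0.01,
                             hrf_delay_jitter_sd = 0.25, blob_sigma = 1.2,
                             coupling_strength = 0.06, seed = 7)
    truth <- generate_ground_truth(cfg)
    sched <- small_schedule()
    runs <- lapply(seq_len(12), function(i)
      generate_subject_bold(truth, sched, i))
    mats <- lapply(runs, function(r) {
      d <- dim(r$bold)
      matrix(r$bold, prod(d[1:3]), d[4])
    })
    dataset <- group_dataset(mats, subjects = truth$subjects$subject)
    list(config = cfg, truth = truth, schedule = sched, runs = runs,
         dataset = dataset)
  })
}

small_decomposition <- function() {
  fixture("decomposition", function() {
    st <- small_study()
    run_group_ica(st$dataset, n_components = 8, n_runs = 4, seed = 11)
  })
}

# map each planted source to its best-matching component
source_component_match <- function(dec = small_decomposition(),
                                   truth = small_study()$truth) {
  cc <- abs(stats::cor(truth$source_maps, t(dec$maps)))
  list(index = apply(cc, 1, which.max), correlation = apply(cc, 1, max))
}
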