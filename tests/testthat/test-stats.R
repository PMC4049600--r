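test_that("mixed ANOVA reproduces the cell-means decomposition and df bookkeeping", {
  set.seed(80)
  # small instance vs the brute-force oracle
  M <- matrix(rnorm(12 * 4), 12, 4)
  g <- rep(c("young", "old"), each = 6)
  res <- rm_anova(M, g)
  oracle <- cellmeans_mixed_anova(M, factor(g))
  for (eff in c("group", "component")) {
    row <- res[res$effect == eff, ]
    expect_equal(row$F, unname(oracle[[if (eff == "group") "group" else
      "component"]]["F"]), tolerance = 1e-8)
  }
  ia <- res[res$effect == "group:component", ]
  expect_equal(ia$F, unname(oracle$interaction["F"]), tolerance = 1e-8)
  expect_equal(c(ia$df1, ia$df2), unname(oracle$interaction[c("df1", "df2")]))
  # the published cohort's geometry: 38 + 37 subjects, 8 components
  M2 <- matrix(rnorm(75 * 8), 75, 8)
  g2 <- rep(c("young", "old"), c(38, 37))
  ia2 <- rm_anova(M2, g2)
  ia2 <- ia2[ia2$effect == "group:component", ]
  expect_equal(c(ia2$df1, ia2$df2), c(7, 511))
  expect_true(all(res$F >= 0))
})

test_that("ANOVA rejects incomplete or degenerate input and corrects sphericity", {
  M <- matrix(rnorm(20), 5, 4)
  expect_error(rm_anova(M, rep("a", 5)), "two groups")
  M[2, 3] <- NA
  expect_error(rm_anova(M, c("a", "a", "a", "b", "b")), "missing")
  expect_error(rm_anova(matrix(rnorm(8), 2, 4), c("a", "b")), "at least 2")
  set.seed(81)
  res <- rm_anova(matrix(rnorm(40 * 5), 40, 5), rep(c("y", "o"), 20))
  eps <- res$gg_epsilon[res$effect == "group:component"]
  expect_gt(eps, 1 / 4)   # lower bound 1/(k-1)
  expect_lte(eps, 1 + 1e-8)
})

test_that("null interaction F is centered on its theoretical mean", {
  set.seed(82)
  n <- 20; k <- 4; reps <- 300
  Fs <- replicate(reps, {
    M <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject effects, no interaction
    res <- rm_anova(M, rep(c("young", "old"), each = n / 2))
    res$F[res$effect == "group:component"]
  })
  df2 <- (n - 2) * (k - 1)
  expect_lt(abs(mean(Fs) - df2 / (df2 - 2)), 0.2)
})

test_that("t-tests match hand arithmetic and the pooled-variance oracle", {
  # printed toy set: two groups of three
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  M <- matrix(c(x, y), 6, 1)
  res <- load_ttests(M, rep(c("a", "b"), each = 3))
  two <- res[res$test == "two_sample", ]
  # hand computation: pooled sd = sqrt((2*1 + 2*4)/4) = sqrt(2.5)
  expect_equal(two$statistic, (2 - 4) / sqrt(2.5 * (2 / 3)), tolerance = 1e-10)
  expect_equal(two$df, 4)
  expect_equal(two$statistic, pooled_t(x, y), tolerance = 1e-10)
  one <- res[res$test == "one_sample_a", ]
  expect_equal(one$statistic, mean(x) / (sd(x) / sqrt(3)), tolerance = 1e-10)
})

test_that("two-sample t power at a planted standardized difference of 1", {
  set.seed(83)
  reps <- 500
  hits <- replicate(reps, {
    M <- matrix(c(rnorm(40, 1), rnorm(40, 0)), 80, 1)
    res <- load_ttests(M, rep(c("t", "c"), each = 40))
    res$p[res$test == "two_sample"] < 0.05
  })
  # noncentral-t oracle: power ~ 0.994 at delta = 1, n = 40 + 40
  expect_gte(mean(hits), 0.97)
})

test_that("degenerate zero-variance cells are flagged or rejected", {
  M <- matrix(rep(1, 8), 8, 1)
  res <- load_ttests(M, rep(c("a", "b"), each = 4))
  expect_true(all(is.na(res$statistic)))
  expect_true(all(res$note == "zero variance"))
  M2 <- matrix(rep(c(0, 1), each = 4), 8, 1)
  expect_error(load_ttests(M2, rep(c("a", "b"), each = 4)),
               "zero variance with nonzero mean difference")
})

test_that("interaction regression handles exact cases and matches the oracle", {
  g <- rep(c("young", "old"), each = 6)
  pred <- c(1:6, 1:6)  # identical distribution per group
  # constant outcome: no slopes, nothing explained
  r0 <- interaction_regression(rep(2, 12), g, pred)
  expect_lt(max(abs(r0$coefficients$estimate[-1])), 1e-6)
  expect_lt(r0$r_squared, 1e-6)
  # outcome an exact linear function of the predictor, no group effect
  y1 <- 3 + 2 * pred
  r1 <- suppressWarnings(interaction_regression(y1, g, pred))
  co <- r1$coefficients
  expect_equal(co$estimate[co$term == "age:z"], 0, tolerance = 1e-10)
  expect_equal(r1$r_squared, 1, tolerance = 1e-10)
  # 8-row worked dataset vs normal equations
  set.seed(84)
  g8 <- factor(rep(c("young", "old"), each = 4), levels = c("young", "old"))
  p8 <- rnorm(8); y8 <- rnorm(8)
  r8 <- interaction_regression(y8, g8, p8)
  z8 <- numeric(8)
  for (gg in unique(g8)) {
    ix <- g8 == gg
    z8[ix] <- (p8[ix] - mean(p8[ix])) / sd(p8[ix])
  }
  age8 <- ifelse(g8 == "old", 1, -1); age8 <- age8 - mean(age8)
  X8 <- cbind(1, age8, z8, age8 * z8)
  expect_lt(max(abs(r8$coefficients$estimate - normal_equations(X8, y8))),
            1e-10)
  expect_equal(r8$coefficients$df[1], 8 - 3 - 1)
})

test_that("interaction regression is invariant to affine predictor rescaling", {
  set.seed(85)
  g <- rep(c("young", "old"), each = 10)
  pred <- rnorm(20); y <- rnorm(20)
  a <- interaction_regression(y, g, pred)
  b <- interaction_regression(y, g, 100 * pred - 7)
  expect_equal(a$coefficients$estimate, b$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(a$r_squared, b$r_squared, tolerance = 1e-10)
  expect_error(interaction_regression(y, g, rep(1, 20)), "constant within")
})

test_that("Spearman rho equals Pearson on ranks, with tie handling", {
  x <- 1:10
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  set.seed(86)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_rho(a, b), rank_pearson(a, b), tolerance = 1e-12)
  # ties get average ranks
  a2 <- c(1, 1, 2, 3, 4); b2 <- c(2, 2, 2, 5, 7)
  expect_equal(spearman_rho(a2, b2), rank_pearson(a2, b2), tolerance = 1e-12)
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("correlation comparison is antisymmetric and null at equality", {
  cc <- compare_correlations(0.3, 30, 0.3, 50)
  expect_equal(cc$z, 0)
  expect_equal(cc$p, 1)
  a <- compare_correlations(0.1, 20, 0.6, 35)
  b <- compare_correlations(0.6, 35, 0.1, 20)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(compare_correlations(1, 10, 0.5, 10), "Fisher")
  expect_error(compare_correlations(0.2, 3, 0.5, 10))
})

test_that("the analysis report runs the full chain on aligned tables", {
  st <- small_study()
  dec <- small_decomposition()
  basis <- hrf_basis_set(0.5)
  designs <- lapply(st$runs, function(r) build_design(st$schedule, r$motion,
                                                      basis))
  act <- compute_activation_table(dec, designs, basis,
                                  groups = st$truth$subjects$group)
  beh <- cost_indices(summarize_behavior(filter_trials(
    generate_behavior(st$config, st$truth))))
  rep <- analysis_report(act, beh, components = 1:8)
  expect_s3_class(rep, "wm_report")
  expect_equal(rep$n_subjects, 12)
  ia <- rep$anova[rep$anova$effect == "group:component", ]
  expect_equal(c(ia$df1, ia$df2), c(7, 70))  # (12-2)*(8-1)
  expect_equal(nrow(rep$correlations), 8 * 3)
  expect_true(all(is.finite(rep$correlations$z)))
  expect_equal(nrow(rep$interaction), 8 * 2 * 4)  # comp x outcome x term
  # output well-formed: every per-condition model carries t, df, p, R2
  expect_true(all(c("estimate", "t", "df", "p", "r_squared") %in%
                    names(rep$per_condition)))
})

test_that("the report rejects misaligned tables and empty selections", {
  st <- small_study()
  dec <- small_decomposition()
  basis <- hrf_basis_set(0.5)
  designs <- lapply(st$runs, function(r) build_design(st$schedule, r$motion,
                                                      basis))
  act <- compute_activation_table(dec, designs, basis,
                                  groups = st$truth$subjects$group)
  beh <- cost_indices(summarize_behavior(filter_trials(
    generate_behavior(st$config, st$truth))))
  expect_warning(empty <- analysis_report(act, beh, integer(0)), "empty")
  expect_null(empty$anova)
  beh_bad <- beh
  beh_bad$by_subject$subject <- paste0("x", beh_bad$by_subject$subject)
  expect_error(analysis_report(act, beh_bad, 1:3), "alignment")
})
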