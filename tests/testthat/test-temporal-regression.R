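test_that("OLS reproduces exact fits and matches the normal-equations oracle", {
  st <- small_study()
  des <- build_design(st$schedule, st$runs[[1]]$motion, hrf_basis_set(0.5))
  X <- des$values
  # a time course equal to one design column loads 1 on it, 0 elsewhere
  fit <- fit_component(X[, "2back.canonical"], des)
  expect_equal(unname(fit$coefficients["2back.canonical"]), 1,
               tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[names(fit$coefficients) !=
                                       "2back.canonical"])), 1e-8)
  expect_lt(fit$residual_variance, 1e-16)
  # linearity on two columns
  y2 <- 2 * X[, "0back.canonical"] + 3 * X[, "1back.time_derivative"]
  fit2 <- fit_component(y2, des)
  expect_equal(unname(fit2$coefficients["0back.canonical"]), 2,
               tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients["1back.time_derivative"]), 3,
               tolerance = 1e-8)
  # noisy fit vs independent normal-equations solve (on the unconvolved-
  # motion design, whose conditioning keeps the oracle itself accurate)
  des_u <- build_design(st$schedule, st$runs[[1]]$motion, hrf_basis_set(0.5),
                        convolve_motion = FALSE)
  Xu <- des_u$values
  set.seed(55)
  y3 <- Xu %*% rnorm(ncol(Xu)) + rnorm(nrow(Xu))
  fit3 <- fit_component(y3, des_u)
  oracle <- normal_equations(Xu, y3)
  expect_lt(max(abs(fit3$coefficients - oracle)), 1e-8)
})

test_that("rank-deficient designs are rejected with the offending columns named", {
  st <- small_study()
  des <- build_design(st$schedule, st$runs[[1]]$motion, hrf_basis_set(0.5))
  des$values <- cbind(des$values, dup = des$values[, "0back.canonical"])
  expect_error(fit_component(rnorm(nrow(des$values)), des),
               "rank deficient.*dup")
  expect_error(fit_component(rnorm(5), build_design(st$schedule,
                                                    st$runs[[1]]$motion,
                                                    hrf_basis_set(0.5))),
               "must equal design rows")
})

test_that("AUC activation follows its closed form and is linear", {
  basis <- hrf_basis_set(0.5)
  # canonical-only loading collapses to the canonical coefficient
  expect_equal(auc_activation(c(1.7, 0, 0), basis), 1.7)
  # synthetic basis with zero-sum derivatives: AUC = b1 for any b2, b3
  toy <- list(canonical = c(4, 6), time_derivative = c(1, -1),
              dispersion_derivative = c(-2, 2))
  expect_equal(auc_activation(c(2, 5, -3), toy), 2)
  # independent quadrature oracle for (1, 1, 0)
  s1 <- sum(basis$canonical); s2 <- sum(basis$time_derivative)
  expect_equal(auc_activation(c(1, 1, 0), basis), (s1 + s2) / s1)
  # linearity in each coefficient
  set.seed(66)
  for (i in 1:5) {
    a <- rnorm(3); b <- rnorm(3); l1 <- rnorm(1); l2 <- rnorm(1)
    expect_equal(auc_activation(l1 * a + l2 * b, basis),
                 l1 * auc_activation(a, basis) + l2 * auc_activation(b, basis),
                 tolerance = 1e-10)
  }
  expect_error(auc_activation(c(1, 0, 0), list(canonical = c(1, -1),
                                               time_derivative = 0,
                                               dispersion_derivative = 0)),
               "sums to zero")
  expect_error(auc_activation(c(1, 0, 0), list(canonical = c(-1, -1),
                                               time_derivative = 0,
                                               dispersion_derivative = 0)),
               "negative sum")
})

test_that("planted load effects appear only in the planted component", {
  # one active source (silent at 0-back, active at 2-back) and one
  # load-insensitive source
  # a largeish voxel count keeps the finite-sample ICA leakage small
  cfg <- simulation_config(grid_dims = c(16, 16, 12), n_sources = 2,
                           n_subjects_per_group = 2, noise_sd = 0,
                           drift_amplitude = 0, hrf_delay_jitter_sd = 0,
                           seed = 70)
  truth <- generate_ground_truth(cfg)
  truth$amplitudes[, 1, ] <- rep(c(0, 0.5, 1), each = 4)   # load-driven
  truth$amplitudes[, 2, ] <- 0.8                           # flat
  sched <- small_schedule()
  runs <- lapply(1:4, function(i) generate_subject_bold(truth, sched, i))
  mats <- lapply(runs, function(r) matrix(r$bold, prod(cfg$grid_dims),
                                          sched$n_scans))
  ds <- group_dataset(mats, subjects = truth$subjects$subject)
  dec <- run_group_ica(ds, n_components = 2, n_runs = 2, seed = 71)
  basis <- hrf_basis_set(0.5)
  designs <- lapply(runs, function(r) build_design(sched, r$motion, basis))
  act <- compute_activation_table(dec, designs, basis,
                                  groups = truth$subjects$group)
  cc <- abs(cor(truth$source_maps, t(dec$maps)))
  planted <- which.max(cc[1, ]); flat <- which.max(cc[2, ])
  le <- act$load_effect
  le_planted <- le$load_effect[le$component == planted]
  le_flat <- le$load_effect[le$component == flat]
  expect_true(all(le_planted > 0))
  expect_lt(max(abs(le_flat)), 0.05 * mean(le_planted))
})

test_that("all-zero time courses yield zero activations", {
  st <- small_study()
  basis <- hrf_basis_set(0.5)
  des <- build_design(st$schedule, st$runs[[1]]$motion, basis)
  stub <- structure(list(
    subject_timecourses = list(matrix(0, st$schedule$n_scans, 2)),
    subjects = "s1", n_components = 2), class = "ica_decomposition")
  act <- compute_activation_table(stub, list(des), basis)
  expect_true(all(act$activation$activation == 0))
  expect_true(all(act$load_effect$load_effect == 0))
})

test_that("the derivative-augmented AUC absorbs HRF latency shifts", {
  sched <- small_schedule()
  amp <- 1.3
  # subject whose response is delayed by 1 s relative to the canonical model
  shifted <- nbackica:::condition_regressors(sched, response_delay = 7,
                                             undershoot_delay = 17)
  y <- amp * colSums(shifted)   # same amplitude in all conditions
  set.seed(72)
  motion <- matrix(rnorm(sched$n_scans * 6, sd = 0.01), ncol = 6)
  basis <- hrf_basis_set(0.5)
  des <- build_design(sched, motion, basis)
  fit <- fit_component(y, des)
  auc <- vapply(rownames(fit$condition_betas), function(cond)
    auc_activation(fit$condition_betas[cond, ], basis), numeric(1))
  expect_true(all(abs(auc - amp) / amp < 0.10))
  # AUC measures response area: the exact planted value on the AUC scale is
  # the amplitude times the area ratio of the subject's (peak-normalized,
  # delayed) response to the canonical one — computed here independently
  tgrid <- seq(0, 32, by = 0.5)
  g_subj <- dgamma(tgrid, shape = 7) - dgamma(tgrid, shape = 17) / 6
  g_can <- dgamma(tgrid, shape = 6) - dgamma(tgrid, shape = 16) / 6
  target <- amp * sum(g_subj / max(g_subj)) / sum(g_can / max(g_can))
  expect_true(all(abs(auc - target) / target < 0.02))
  # a canonical-only model (no derivative regressors) errs more
  keep <- des$labels$basis %in% c(NA, "canonical") |
    des$labels$kind != "condition"
  des_c <- des
  des_c$values <- des$values[, keep]
  des_c$labels <- des$labels[keep, ]
  fit_c <- fit_component(y, des_c)
  canonical_only <- fit_c$coefficients[paste0(rownames(fit$condition_betas),
                                              ".canonical")]
  expect_true(all(abs(auc - target) < abs(canonical_only - target)))
})

test_that("task-uncorrelated components have activation centered on zero", {
  st <- small_study()
  basis <- hrf_basis_set(0.5)
  des <- build_design(st$schedule, st$runs[[1]]$motion, basis)
  set.seed(73)
  n_rep <- 100
  aucs <- vapply(seq_len(n_rep), function(r) {
    y <- rnorm(st$schedule$n_scans)
    fit <- fit_component(y, des)
    auc_activation(fit$condition_betas["2back", ], basis)
  }, numeric(1))
  expect_lt(abs(mean(aucs)), 2 * sd(aucs) / sqrt(n_rep))
})

test_that("load-effect matrices align subjects and components", {
  st <- small_study()
  dec <- small_decomposition()
  basis <- hrf_basis_set(0.5)
  designs <- lapply(st$runs, function(r) build_design(st$schedule, r$motion,
                                                      basis))
  act <- compute_activation_table(dec, designs, basis,
                                  groups = st$truth$subjects$group)
  M <- load_effect_matrix(act)
  expect_equal(dim(M), c(12, 8))
  expect_identical(rownames(M), sort(st$truth$subjects$subject))
  le <- act$load_effect
  i <- which(le$subject == "sub005" & le$component == 3)
  expect_equal(M["sub005", "IC3"], le$load_effect[i])
  # the load effect is identically the 2-back minus 0-back difference
  a <- act$activation
  d <- a$activation[a$condition == "2back"] -
    a$activation[a$condition == "0back"]
  key_a <- paste(a$subject[a$condition == "2back"],
                 a$component[a$condition == "2back"])
  key_le <- paste(le$subject, le$component)
  expect_equal(d[match(key_le, key_a)], le$load_effect)
})
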