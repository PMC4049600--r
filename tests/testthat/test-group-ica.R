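test_that("MDL order estimation brackets planted ranks", {
  set.seed(101)
  # pure white noise: essentially order zero
  noise <- matrix(rnorm(500 * 200), 500, 200)
  expect_lte(estimate_order(noise), 3)
  # 5 strong sources + weak noise
  S <- matrix(rnorm(5 * 500), 500, 5)
  A <- matrix(rnorm(5 * 200), 5, 200)
  expect_true(estimate_order(S %*% A + 0.1 * noise) %in% 4:7)
  # exact rank-k mixing, zero noise (ridge handles the zero tail)
  expect_equal(estimate_order(S %*% A), 5)
  expect_error(estimate_order(matrix(0, 50, 20)), "rank-deficient")
})

test_that("lossless single-subject reduction is invertible", {
  set.seed(7)
  X <- matrix(rnorm(300 * 40), 300, 40)
  ds <- group_dataset(list(X))
  # voxelwise mean removal leaves rank scans - 1: that is the lossless k
  red <- reduce_group(ds, k_subject = 39, k_group = 39)
  G <- red$G[[1]]
  expect_lt(max(abs(ds$data[[1]] %*% G %*% t(G) - ds$data[[1]])), 1e-8)
  # whitening is exactly invertible at full rank
  Z <- t(ds$data[[1]] %*% G)
  Z_back <- red$H %*% diag(sqrt(red$d)) %*% red$Y
  expect_lt(max(abs(Z - Z_back)), 1e-6)
})

test_that("group PCA variance accounting matches the eigenvalue oracle", {
  set.seed(8)
  mats <- lapply(1:3, function(i) matrix(rnorm(200 * 30), 200, 30))
  ds <- group_dataset(mats)
  red <- reduce_group(ds, k_subject = 20, k_group = 10)
  Z <- do.call(rbind, lapply(1:3, function(i) t(ds$data[[i]] %*% red$G[[i]])))
  ev <- eigen(tcrossprod(Z), symmetric = TRUE, only.values = TRUE)$values
  # reconstruction error at k equals the discarded eigenvalue mass
  for (k in c(5, 10, 20)) {
    H <- eigen(tcrossprod(Z), symmetric = TRUE)$vectors[, 1:k]
    err <- sum((Z - H %*% t(H) %*% Z)^2)
    expect_equal(err, sum(ev[-(1:k)]), tolerance = 1e-6)
  }
  # variance explained non-decreasing in k
  expect_true(all(diff(cumsum(ev)) >= 0))
  expect_error(reduce_group(ds, k_subject = 31, k_group = 5), "exceeds")
  expect_error(reduce_group(ds, k_subject = 10, k_group = 31), "exceeds")
})

test_that("infomax recovers independent super-Gaussian sources at identity mixing", {
  set.seed(30)
  k <- 5; n <- 3000
  S <- matrix(rnorm(k * n)^3, k, n)              # super-Gaussian
  S <- S / apply(S, 1, sd)
  S <- S - rowMeans(S)
  W <- infomax(S, k, seed = 2)
  rec <- W %*% S
  cc <- abs(cor(t(rec), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.99))
  expect_identical(infomax(S, k, seed = 2), W)   # determinism
  expect_false(identical(infomax(S, k, seed = 3), W))
})

test_that("infomax + reduction separates randomly mixed blob sources", {
  cfg <- simulation_config(grid_dims = c(15, 15, 10), n_sources = 5, seed = 33)
  maps <- generate_source_maps(cfg)                # voxel x 5, sparse
  set.seed(34)
  A <- matrix(rnorm(40), 8, 5)                     # random mixing, 8 scans
  X <- t(A %*% t(maps))                            # voxel x scan
  ds <- group_dataset(list(X))
  red <- reduce_group(ds, k_subject = 5, k_group = 5)
  W <- infomax(red$Y, 5, seed = 4)
  rec <- W %*% red$Y
  cc <- abs(cor(t(rec), maps))
  expect_true(all(apply(cc, 2, max) > 0.95))
})

test_that("composed unmixing attains a small Amari index on square noiseless mixtures", {
  set.seed(35)
  k <- 5; n <- 4000
  S <- matrix(rnorm(k * n)^3, k, n); S <- S - rowMeans(S)
  A <- matrix(rnorm(k * k), k, k)
  X <- A %*% S
  e <- eigen(tcrossprod(X) / n, symmetric = TRUE)
  K <- diag(1 / sqrt(e$values)) %*% t(e$vectors)   # whitening
  W <- infomax(K %*% X, k, seed = 6)
  expect_lt(amari_distance(W %*% K, A), 0.05)
})

test_that("icasso clusters duplicated runs into perfectly tight clusters", {
  set.seed(40)
  k <- 4; n <- 2000
  S <- matrix(rnorm(k * n)^3, k, n); S <- S - rowMeans(S)
  res <- icasso(S, k, n_runs = 2, seeds = c(9, 9))
  # identical seeds: each cluster is a duplicated pair, within-corr exactly 1
  expect_true(all(table(res$clusters) == 2))
  pooled <- rbind(infomax(S, k, seed = 9), infomax(S, k, seed = 9)) %*% S
  sim <- abs(cor(t(pooled)))
  for (c_ in seq_len(k)) {
    mem <- which(res$clusters == c_)
    expect_equal(sim[mem[1], mem[2]], 1)
    between <- mean(sim[mem, -mem])
    expect_equal(res$stability[c_], 1 - between, tolerance = 1e-12)
  }
})

test_that("icasso is stable on well-separated sources and validates n_runs", {
  st <- small_study()
  dec <- small_decomposition()
  expect_true(all(dec$stability > 0.9))
  expect_error(icasso(matrix(rnorm(40), 2, 20), 2, n_runs = 1), "at least 2")
  # the study default is 10 stability runs
  expect_equal(eval(formals(icasso)$n_runs), 10L)
  expect_equal(eval(formals(run_group_ica)$n_runs), 10L)
})

test_that("back-projection is exact for a lossless single-subject pipeline", {
  set.seed(50)
  X <- matrix(rnorm(400 * 20), 400, 20)
  ds <- group_dataset(list(X))
  red <- reduce_group(ds, k_subject = 19, k_group = 19)
  W <- infomax(red$Y, 19, seed = 5, tol = 1e-7)
  bp <- back_project(W, red, ds)
  # with one subject the reconstruction A_i S_i reproduces the data exactly
  recon <- bp$subject_timecourses[[1]] %*% bp$subject_maps[[1]]
  expect_lt(max(abs(t(recon) - ds$data[[1]])), 1e-6)
  # and the subject map IS the group map
  group_maps <- W %*% red$Y
  expect_lt(max(abs(bp$subject_maps[[1]] - group_maps)), 1e-8)
})

test_that("subject maps average to the group maps and match planted sources", {
  st <- small_study()
  dec <- small_decomposition()
  avg <- Reduce(`+`, dec$unscaled$subject_maps) /
    length(dec$unscaled$subject_maps)
  cc_avg <- abs(diag(cor(t(avg), t(dec$unscaled$maps))))
  expect_true(all(cc_avg > 0.99))
  m <- source_component_match()
  expect_true(all(m$correlation > 0.9))
  # subject time courses track the planted source time courses
  for (i in c(1, 7)) {
    amp <- matrix(st$truth$amplitudes[i, , ], st$config$n_sources, 3)
    src_tc <- amp %*% st$runs[[i]]$regressors
    tc <- dec$subject_timecourses[[i]]
    cors <- vapply(seq_len(st$config$n_sources), function(s)
      abs(cor(src_tc[s, ], tc[, m$index[s]])), numeric(1))
    expect_true(all(cors > 0.9))
  }
})

test_that("decomposition respects sign, z-scoring and ordering conventions", {
  dec <- small_decomposition()
  for (j in seq_len(dec$n_components)) {
    v <- dec$unscaled$maps[j, ]
    expect_gt(v[which.max(abs(v))], 0)   # peak voxel positive
  }
  expect_true(all(abs(rowMeans(dec$maps)) < 1e-8))
  expect_true(all(abs(apply(dec$maps, 1, sd) - 1) < 1e-6))
  expect_true(all(abs(rowMeans(dec$timecourses)) < 1e-8))
  for (tc in dec$subject_timecourses) {
    expect_true(all(abs(colMeans(tc)) < 1e-8))
    expect_true(all(abs(apply(tc, 2, sd) - 1) < 1e-6))
  }
  # ordering: explained variance non-increasing
  ev <- vapply(seq_len(dec$n_components), function(j)
    sum(dec$unscaled$maps[j, ]^2) *
      sum(vapply(dec$unscaled$subject_timecourses, function(tc)
        sum(tc[, j]^2), numeric(1))), numeric(1))
  expect_true(all(diff(ev) <= 1e-6 * ev[1]))
})

test_that("full decomposition is deterministic given data and seeds", {
  st <- small_study()
  dec1 <- run_group_ica(st$dataset, n_components = 4, n_runs = 2, seed = 77)
  dec2 <- run_group_ica(st$dataset, n_components = 4, n_runs = 2, seed = 77)
  expect_identical(dec1$maps, dec2$maps)
  expect_identical(dec1$subject_timecourses, dec2$subject_timecourses)
})

test_that("template matching selects, thresholds and guards duplicates", {
  dec <- small_decomposition()
  st <- small_study()
  # a template equal to a group map selects that component with correlation 1
  tmpl <- dec$maps[3, , drop = FALSE]
  sel <- select_components(dec, tmpl)
  expect_equal(unname(sel[1]), 3)
  expect_equal(unname(attr(sel, "correlation")[1]), 1, tolerance = 1e-8)
  # templates built from all planted sources recover distinct components
  sel8 <- select_components(dec, t(st$truth$source_maps))
  expect_false(any(is.na(sel8)))
  expect_equal(length(unique(sel8)), st$config$n_sources)
  # an unmatched template is reported NA with a warning, not assigned
  set.seed(60)
  noise_tmpl <- matrix(rnorm(ncol(dec$maps)), 1)
  expect_warning(sel_na <- select_components(dec, noise_tmpl), "unmatched")
  expect_true(is.na(sel_na[1]))
  # duplicated selection raises without an override
  dup <- rbind(dec$maps[3, ], dec$maps[3, ] + 0.01 * dec$maps[4, ])
  expect_error(select_components(dec, dup), "same component")
  sel_ov <- select_components(dec, dup, override = c(a = 3L, b = 4L))
  expect_equal(unname(sel_ov), c(3L, 4L))
})
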