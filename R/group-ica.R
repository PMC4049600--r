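#' @title Temporal-concatenation group spatial ICA
#' @description Group spatial ICA in the GIFT tradition: per-subject temporal
#'   PCA reduction, concatenation across subjects, group PCA, infomax ICA on
#'   the whitened group data, stability analysis over repeated randomized
#'   runs (ICASSO-style), and subject-level back-reconstruction of component
#'   maps and time courses through the retained reduction operators.
#' @name group_ica_pipeline
NULL

#' Assemble a group dataset
#'
#' Collects per-subject voxel x scan matrices under a shared voxel mask,
#' removing each voxel's mean within subject. All subjects must share the
#' mask and the scan count.
#'
#' @param subject_data list of voxel x scan matrices (already masked), or of
#'   4D arrays (then `mask` is applied).
#' @param mask logical/0-1 array or vector selecting the analyzed voxels.
#' @param subjects optional character subject identifiers.
#' @return object of class `group_dataset`.
#' @export
group_dataset <- function(subject_data, mask = NULL, subjects = NULL) {
  stopifnot(is.list(subject_data), length(subject_data) >= 1)
  mats <- lapply(subject_data, function(x) {
    if (is.array(x) && length(dim(x)) == 4) {
      if (is.null(mask)) stop("a mask is required for 4D array input")
      apply_mask(x, mask)
    } else as.matrix(x)
  })
  nscan <- unique(vapply(mats, ncol, integer(1)))
  nvox <- unique(vapply(mats, nrow, integer(1)))
  if (length(nscan) != 1 || length(nvox) != 1) {
    stop("all subjects must share the voxel mask and scan count")
  }
  mats <- lapply(mats, function(m) m - rowMeans(m))
  if (is.null(subjects)) subjects <- sprintf("sub%03d", seq_along(mats))
  structure(list(data = mats, mask = mask, subjects = subjects,
                 n_voxels = nvox, n_scans = nscan),
            class = "group_dataset")
}

#' Apply a voxel mask to a 4D volume
#'
#' @param bold 4D array (x, y, z, time).
#' @param mask array or vector; nonzero entries select voxels.
#' @return voxel x scan matrix.
#' @export
apply_mask <- function(bold, mask) {
  d <- dim(bold)
  stopifnot(length(d) == 4)
  m <- as.logical(as.vector(mask) != 0)
  if (length(m) != prod(d[1:3])) stop("mask does not match volume dimensions")
  matrix(bold, prod(d[1:3]), d[4])[m, , drop = FALSE]
}

#' Estimate the number of components by minimum description length
#'
#' Gaussian-source MDL order selection on the eigenvalue spectrum of the data
#' covariance, with the number of i.i.d. samples taken as the scan count.
#' Eigenvalues below a ridge floor (relative to the largest) are raised to it
#' so that exactly rank-deficient inputs are handled.
#'
#' @param x a voxel x scan matrix or a `group_dataset` (then the median of
#'   per-subject estimates is returned).
#' @param ridge relative eigenvalue floor.
#' @return integer order estimate.
#' @export
estimate_order <- function(x, ridge = 1e-10) {
  if (inherits(x, "group_dataset")) {
    ks <- vapply(x$data, estimate_order, numeric(1), ridge = ridge)
    return(as.integer(round(stats::median(ks))))
  }
  x <- as.matrix(x)
  n_scans <- ncol(x)
  x <- x - rowMeans(x)
  # nonzero spectrum of the voxel-space covariance = spectrum of the
  # temporal Gram, cheaper when voxels >> scans
  ev <- if (nrow(x) >= n_scans) {
    eigen(crossprod(x) / nrow(x), symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(tcrossprod(x) / nrow(x), symmetric = TRUE, only.values = TRUE)$values
  }
  if (max(ev) <= 0) stop("rank-deficient input: data covariance is zero")
  ev <- pmax(ev, ridge * max(ev))
  mdl_order(ev, n_scans)
}

mdl_order <- function(lambda, n_samples) {
  p <- length(lambda)
  crit <- vapply(0:(p - 1L), function(k) {
    tail <- lambda[(k + 1L):p]
    loglik <- mean(log(tail)) - log(mean(tail))
    -n_samples * (p - k) * loglik + 0.5 * k * (2 * p - k + 1) * log(n_samples)
  }, numeric(1))
  as.integer(which.min(crit) - 1L)
}

#' Two-stage PCA reduction for group ICA
#'
#' Stage one reduces each subject's data to `k_subject` temporal principal
#' components; the reduced data are concatenated across subjects along the
#' reduced-time axis and reduced again to `k_group` group components, which
#' are whitened for the ICA step. All operators are retained for
#' back-reconstruction.
#'
#' @param dataset a `group_dataset`.
#' @param k_subject per-subject temporal dimension (<= scans).
#' @param k_group group dimension (<= subjects x `k_subject`).
#' @return object of class `ica_reduction`: list with `Y` (whitened
#'   `k_group` x voxel matrix), per-subject operators `G` (scans x
#'   `k_subject`), group operator `H`, eigenvalues of both stages, and the
#'   dataset geometry.
#' @export
reduce_group <- function(dataset, k_subject, k_group) {
  stopifnot(inherits(dataset, "group_dataset"))
  m <- length(dataset$data)
  T_ <- dataset$n_scans
  if (k_subject > T_) stop("k_subject (", k_subject, ") exceeds scan count (", T_, ")")
  if (k_group > m * k_subject) {
    stop("k_group (", k_group, ") exceeds total reduced dimension (", m * k_subject, ")")
  }
  G <- vector("list", m); subject_ev <- vector("list", m)
  Z <- matrix(0, m * k_subject, dataset$n_voxels)
  for (i in seq_len(m)) {
    Xi <- dataset$data[[i]]                       # voxel x scan
    eg <- eigen(crossprod(Xi), symmetric = TRUE)  # scan x scan
    if (eg$values[k_subject] <= max(eg$values) * 1e-12) {
      stop("subject ", i, ": rank below k_subject = ", k_subject)
    }
    G[[i]] <- eg$vectors[, seq_len(k_subject), drop = FALSE]
    subject_ev[[i]] <- eg$values
    Z[(i - 1L) * k_subject + seq_len(k_subject), ] <- t(Xi %*% G[[i]])
  }
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  if (eg$values[k_group] <= max(eg$values) * 1e-12) {
    stop("group rank below k_group = ", k_group)
  }
  H <- eg$vectors[, seq_len(k_group), drop = FALSE]
  d <- eg$values[seq_len(k_group)]
  Y <- diag(1 / sqrt(d), k_group) %*% t(H) %*% Z
  structure(list(Y = Y, Z_group_eigenvalues = eg$values, G = G,
                 subject_eigenvalues = subject_ev, H = H, d = d,
                 k_subject = k_subject, k_group = k_group,
                 n_scans = T_, n_subjects = m, n_voxels = dataset$n_voxels),
            class = "ica_reduction")
}

#' Infomax ICA
#'
#' Natural-gradient infomax with the logistic nonlinearity for super-Gaussian
#' (sparse) sources: the classic stochastic update
#' `W <- W + lrate * (I + (1 - 2 g(WX)) (WX)') W` over randomized sample
#' blocks, with the learning rate annealed (factor `anneal`) whenever the
#' weight update direction oscillates by more than 60 degrees. Convergence is
#' declared when the weight-change norm drops below `tol`.
#'
#' @param reduced whitened component x sample matrix (square mixing; rows =
#'   `n_components`).
#' @param n_components number of components; must equal `nrow(reduced)`.
#' @param seed integer seed for the sample permutations.
#' @param lrate initial learning rate; default `0.005 / log(n_components)`.
#' @param tol convergence tolerance on the relative weight-change Frobenius
#'   norm `||dW|| / ||W||` (scale-free: infomax inflates the weight scale for
#'   very sparse sources).
#' @param max_sweeps maximum data sweeps; exceeding it raises a condition of
#'   class `infomax_nonconvergence` carrying the partial unmixing matrix.
#' @param anneal learning-rate annealing factor on oscillation.
#' @return the unmixing matrix `W` (`n_components` x `n_components`), with
#'   attributes `sweeps` and `converged`; components are `W %*% reduced`.
#' @export
infomax <- function(reduced, n_components = nrow(reduced), seed = 1L,
                    lrate = NULL, tol = 1e-6, max_sweeps = 512L,
                    anneal = 0.9) {
  reduced <- as.matrix(reduced)
  k <- n_components
  if (k != nrow(reduced)) {
    stop("n_components (", k, ") must equal the number of rows of `reduced` (",
         nrow(reduced), ")")
  }
  if (k < 2) stop("infomax needs at least 2 components")
  n <- ncol(reduced)
  if (is.null(lrate)) lrate <- 0.005 / log(k)
  block <- max(8L, min(n, as.integer(ceiling(sqrt(n / 3)))))
  W <- diag(k)
  I_blk <- NULL
  old_dW <- NULL
  sweeps <- 0L
  converged <- FALSE

  with_substream(seed, "infomax", expr = {
    repeat {
      sweeps <- sweeps + 1L
      W_old <- W
      perm <- sample.int(n)
      blown <- FALSE
      for (start in seq(1L, n, by = block)) {
        ix <- perm[start:min(start + block - 1L, n)]
        u <- W %*% reduced[, ix, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        dW <- (length(ix) * diag(k) + (1 - 2 * y) %*% t(u)) %*% W
        W <- W + (lrate / length(ix)) * dW
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) { blown <- TRUE; break }
      }
      if (blown) {  # restart colder
        W <- diag(k); lrate <- lrate * 0.5; old_dW <- NULL
        if (lrate < 1e-8) stop("infomax diverged at the smallest learning rate")
        next
      }
      dW_sweep <- W - W_old
      change <- sqrt(sum(dW_sweep^2) / sum(W^2))
      if (!is.null(old_dW)) {
        denom <- sqrt(sum(dW_sweep^2) * sum(old_dW^2))
        cosang <- if (denom > 0) sum(dW_sweep * old_dW) / denom else 1
        if (cosang < cos(60 * pi / 180)) lrate <- lrate * anneal
      }
      old_dW <- dW_sweep
      if (change < tol) { converged <- TRUE; break }
      if (sweeps >= max_sweeps) break
    }
  })
  attr(W, "sweeps") <- sweeps
  attr(W, "converged") <- converged
  if (!converged) {
    cond <- errorCondition(
      paste0("infomax did not converge within ", max_sweeps,
             " sweeps (last change above tol)"),
      class = "infomax_nonconvergence", W = W, sweeps = sweeps)
    stop(cond)
  }
  W
}

#' ICASSO-style stability analysis
#'
#' Runs infomax `n_runs` times with distinct seeds, pools all estimated
#' component maps, clusters them by the dissimilarity `1 - |correlation|`
#' (average-linkage agglomerative clustering into `n_components` clusters)
#' and returns each cluster's centrotype (the member with the largest summed
#' within-cluster similarity) together with a stability index: mean
#' within-cluster |correlation| minus mean between-cluster |correlation|.
#'
#' @param reduced whitened component x sample matrix.
#' @param n_components components per run.
#' @param n_runs number of randomized runs (default 10).
#' @param seeds optional integer vector of per-run seeds.
#' @param ... passed to [infomax()].
#' @return list with `unmixing` (centrotype rows, `n_components` x
#'   `n_components`), `stability` (per cluster), `clusters` (assignment of
#'   all pooled components), `runs_succeeded`.
#' @export
icasso <- function(reduced, n_components = nrow(reduced), n_runs = 10L,
                   seeds = NULL, ...) {
  if (n_runs < 2) stop("icasso needs at least 2 runs")
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- tryCatch(infomax(reduced, n_components, seed = seeds[r], ...),
                          infomax_nonconvergence = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1), "condition")
  if (sum(ok) < ceiling(n_runs / 2)) {
    stop("icasso: only ", sum(ok), " of ", n_runs,
         " infomax runs converged (need at least half)")
  }
  runs <- runs[ok]
  pooled_W <- do.call(rbind, runs)                     # (runs*k) x k
  pooled_maps <- pooled_W %*% reduced                  # component maps
  sim <- abs(stats::cor(t(pooled_maps)))
  dis <- stats::as.dist(1 - sim)
  cl <- stats::cutree(stats::hclust(dis, method = "average"), k = n_components)

  centro <- integer(n_components); stability <- numeric(n_components)
  for (c_ in seq_len(n_components)) {
    members <- which(cl == c_)
    others <- which(cl != c_)
    within <- sim[members, members, drop = FALSE]
    centro[c_] <- members[which.max(rowSums(within))]
    mean_within <- if (length(members) > 1)
      mean(within[upper.tri(within)]) else 1
    mean_between <- if (length(others) > 0)
      mean(sim[members, others]) else 0
    stability[c_] <- mean_within - mean_between
  }
  list(unmixing = pooled_W[centro, , drop = FALSE],
       stability = stability, clusters = cl,
       centrotypes = centro, runs_succeeded = sum(ok))
}

#' GICA back-reconstruction of subject maps and time courses
#'
#' Reconstructs subject-specific spatial maps and time courses from the group
#' unmixing matrix through the pseudo-inverse of the composed reduction
#' pipeline: subject map `S_i = W D^{-1/2} H_i' G_i' X_i'` and subject time
#' course `A_i = G_i H_i D^{1/2} W^{-1}`, where `H_i` is subject i's block of
#' the group reduction operator. Subject maps sum, across subjects, exactly
#' to the group maps.
#'
#' @param unmixing `k x k` unmixing matrix from [infomax()]/[icasso()].
#' @param reduction an `ica_reduction` from [reduce_group()].
#' @param dataset the `group_dataset` the reduction was computed from.
#' @return list with `subject_maps` (list of `k` x voxel matrices),
#'   `subject_timecourses` (list of scans x `k` matrices).
#' @export
back_project <- function(unmixing, reduction, dataset) {
  stopifnot(inherits(reduction, "ica_reduction"),
            inherits(dataset, "group_dataset"))
  if (length(dataset$data) != reduction$n_subjects ||
      dataset$n_voxels != reduction$n_voxels) {
    stop("reduction operators do not correspond to this dataset")
  }
  k <- reduction$k_group
  W <- as.matrix(unmixing)
  stopifnot(nrow(W) == k, ncol(W) == k)
  Winv <- solve(W)
  Dmh <- diag(1 / sqrt(reduction$d), k)
  Dph <- diag(sqrt(reduction$d), k)
  maps <- vector("list", reduction$n_subjects)
  tcs <- vector("list", reduction$n_subjects)
  for (i in seq_len(reduction$n_subjects)) {
    rows <- (i - 1L) * reduction$k_subject + seq_len(reduction$k_subject)
    Hi <- reduction$H[rows, , drop = FALSE]           # k_subject x k_group
    Gi <- reduction$G[[i]]                            # scans x k_subject
    Xi <- dataset$data[[i]]                           # voxel x scan
    maps[[i]] <- W %*% Dmh %*% t(Hi) %*% t(Gi) %*% t(Xi)  # k x voxel
    tcs[[i]] <- Gi %*% Hi %*% Dph %*% Winv                # scans x k
  }
  list(subject_maps = maps, subject_timecourses = tcs)
}

#' Run the full group spatial ICA
#'
#' Convenience wrapper: two-stage reduction, ICASSO-stabilized infomax (or a
#' single run when `n_runs = 1`), back-reconstruction, and the package's
#' fixed conventions: components ordered by explained variance (descending),
#' each map sign-flipped so its largest-magnitude voxel is positive (time
#' courses flipped along), and all stored maps and time courses z-scored.
#'
#' @param dataset a `group_dataset`.
#' @param n_components number of independent components (the study default
#'   is 50; scale down for small synthetic problems).
#' @param n_runs ICASSO repetitions (default 10).
#' @param seed master seed for the ICA runs.
#' @param k_subject,k_group reduction dimensions; defaults
#'   `min(ceiling(1.5 * n_components), scans)` and `n_components`.
#' @param ... passed to [infomax()].
#' @return object of class `ica_decomposition`: list with `maps`
#'   (component x voxel, z-scored), `timecourses` (z-scored group time
#'   courses, component x (subjects*scans)), `subject_maps`,
#'   `subject_timecourses` (z-scored), `stability`, `order` (explained-
#'   variance ranking applied), `unmixing`, `reduction`, `subjects`,
#'   `unscaled` (raw maps/time courses before z-scoring).
#' @export
run_group_ica <- function(dataset, n_components, n_runs = 10L, seed = 1L,
                          k_subject = NULL, k_group = n_components, ...) {
  stopifnot(inherits(dataset, "group_dataset"))
  if (is.null(k_subject)) {
    # default 1.5x the model order, capped at the scan count and at the
    # smallest per-subject numerical rank (noiseless task data can be very
    # low rank: a handful of condition regressors)
    ranks <- vapply(dataset$data, function(Xi) {
      ev <- eigen(crossprod(Xi), symmetric = TRUE, only.values = TRUE)$values
      sum(ev > max(ev) * 1e-10)
    }, numeric(1))
    k_subject <- max(2L, min(ceiling(1.5 * n_components), dataset$n_scans,
                             min(ranks)))
  }
  red <- reduce_group(dataset, k_subject, k_group)
  if (n_runs >= 2) {
    ic <- icasso(red$Y, n_components, n_runs,
                 seeds = vapply(seq_len(n_runs), function(r)
                   substream_seed(seed, "icasso", r), integer(1)), ...)
    W <- ic$unmixing; stability <- ic$stability
  } else {
    W <- infomax(red$Y, n_components, seed = substream_seed(seed, "infomax"), ...)
    stability <- rep(NA_real_, n_components)
  }
  bp <- back_project(W, red, dataset)
  maps_raw <- W %*% red$Y
  A_stacked <- do.call(rbind, bp$subject_timecourses)  # (m*T) x k

  # explained-variance ordering and sign convention
  ev <- colSums(A_stacked^2) * rowSums(maps_raw^2)
  ord <- order(ev, decreasing = TRUE)
  signs <- vapply(seq_len(nrow(maps_raw)), function(j) {
    v <- maps_raw[j, ]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  flip <- function(M, byrow = TRUE) {
    if (byrow) (M * signs)[ord, , drop = FALSE]
    else t(t(M) * signs)[, ord, drop = FALSE]
  }
  maps_raw <- flip(maps_raw)
  A_stacked <- flip(A_stacked, byrow = FALSE)
  stability <- stability[ord]
  sub_maps <- lapply(bp$subject_maps, flip)
  sub_tcs <- lapply(bp$subject_timecourses, flip, byrow = FALSE)

  zrow <- function(M) t(apply(M, 1, zscore))
  zcol <- function(M) apply(M, 2, zscore)
  structure(list(maps = zrow(maps_raw),
                 timecourses = zcol(A_stacked) |> t(),
                 subject_maps = lapply(sub_maps, zrow),
                 subject_timecourses = lapply(sub_tcs, zcol),
                 stability = stability,
                 n_components = n_components,
                 unmixing = W, reduction = red,
                 subjects = dataset$subjects, mask = dataset$mask,
                 unscaled = list(maps = maps_raw, subject_maps = sub_maps,
                                 subject_timecourses = sub_tcs)),
            class = "ica_decomposition")
}

zscore <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("group ICA decomposition:", x$n_components, "components,",
      length(x$subject_maps), "subjects\n")
  if (!all(is.na(x$stability))) {
    cat("  stability index range:",
        paste(round(range(x$stability), 3), collapse = " - "), "\n")
  }
  invisible(x)
}

#' Match components against spatial templates
#'
#' Programmatic stand-in for visual component selection: each template mask
#' is matched to the decomposition component with the largest absolute
#' spatial correlation, subject to a minimum-correlation threshold.
#' Templates falling below the threshold are reported as unmatched (`NA`)
#' rather than silently assigned; two templates resolving to the same
#' component raise an error unless an explicit override is supplied.
#'
#' @param decomposition an `ica_decomposition`.
#' @param templates matrix (template x voxel) or list of voxel vectors on the
#'   decomposition's mask.
#' @param threshold minimum |spatial correlation| (default 0.3).
#' @param override optional named integer vector of manual assignments,
#'   honored verbatim.
#' @return integer vector (one per template, `NA` = unmatched) with the
#'   matched correlations in `attr(, "correlation")`.
#' @export
select_components <- function(decomposition, templates, threshold = 0.3,
                              override = NULL) {
  stopifnot(inherits(decomposition, "ica_decomposition"))
  if (is.list(templates)) templates <- do.call(rbind, lapply(templates, as.numeric))
  templates <- as.matrix(templates)
  if (ncol(templates) != ncol(decomposition$maps)) {
    stop("templates must share the decomposition's voxel mask (",
         ncol(templates), " vs ", ncol(decomposition$maps), " voxels)")
  }
  if (!is.null(override)) {
    sel <- as.integer(override)
    names(sel) <- names(override)
    return(sel)
  }
  cors <- abs(stats::cor(t(templates), t(decomposition$maps)))
  sel <- apply(cors, 1, which.max)
  best <- cors[cbind(seq_len(nrow(cors)), sel)]
  sel[best < threshold] <- NA_integer_
  matched <- sel[!is.na(sel)]
  if (anyDuplicated(matched)) {
    stop("templates ", paste(which(sel %in% matched[duplicated(matched)]),
                             collapse = ", "),
         " select the same component; provide an override")
  }
  if (any(is.na(sel))) {
    warning(sum(is.na(sel)), " template(s) unmatched (|correlation| below ",
            threshold, ")")
  }
  storage.mode(sel) <- "integer"
  attr(sel, "correlation") <- best
  sel
}
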