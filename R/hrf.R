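#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: the difference of two gamma densities, a
#' positive response peaking near 5 s and an undershoot peaking later, scaled
#' to unit peak amplitude. Parameters follow the widely used convention
#' (response delay 6 s, undershoot delay 16 s, unit dispersions, undershoot
#' ratio 1/6, 32 s support).
#'
#' @param step sampling step in seconds (> 0).
#' @param duration support of the response in seconds.
#' @param response_delay,undershoot_delay gamma delays (shape x scale), seconds.
#' @param response_dispersion,undershoot_dispersion gamma scale parameters.
#' @param undershoot_ratio relative amplitude of the undershoot gamma.
#' @return numeric vector: the HRF sampled at `seq(0, duration, by = step)`,
#'   with `attr(, "time")` holding the sample times.
#' @export
canonical_hrf <- function(step,
                          duration = 32,
                          response_delay = 6,
                          undershoot_delay = 16,
                          response_dispersion = 1,
                          undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    stop("`step` must be a single positive number")
  }
  t <- seq(0, duration, by = step)
  h <- double_gamma(t, response_delay, undershoot_delay,
                    response_dispersion, undershoot_dispersion,
                    undershoot_ratio)
  h <- h / max(h)
  attr(h, "time") <- t
  h
}

double_gamma <- function(t, d1, d2, s1, s2, ratio) {
  stats::dgamma(t, shape = d1 / s1, scale = s1) -
    ratio * stats::dgamma(t, shape = d2 / s2, scale = s2)
}

#' HRF basis set: canonical, temporal derivative, dispersion derivative
#'
#' The three-function basis used to absorb subject- and age-related latency
#' and width variability of the hemodynamic response. The temporal derivative
#' is the finite difference of the canonical with respect to a 1 s onset
#' shift; the dispersion derivative is the finite difference with respect to
#' the response-dispersion parameter (increment 0.01). Both derivatives share
#' the canonical's peak normalization so that regression coefficients live on
#' a common scale.
#'
#' @inheritParams canonical_hrf
#' @param onset_shift onset increment (s) for the temporal derivative.
#' @param dispersion_increment increment of the response dispersion for the
#'   dispersion derivative.
#' @param ... further arguments passed to [canonical_hrf()].
#' @return object of class `hrf_basis`: list with `canonical`,
#'   `time_derivative`, `dispersion_derivative` (equal-length sampled curves),
#'   `step`, `duration`, `time`.
#' @export
hrf_basis_set <- function(step, duration = 32, onset_shift = 1,
                          dispersion_increment = 0.01,
                          response_delay = 6, undershoot_delay = 16,
                          response_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6) {
  canonical <- canonical_hrf(step, duration, response_delay, undershoot_delay,
                             response_dispersion, undershoot_dispersion,
                             undershoot_ratio)
  t <- attr(canonical, "time")
  peak <- max(double_gamma(t, response_delay, undershoot_delay,
                           response_dispersion, undershoot_dispersion,
                           undershoot_ratio))
  g0 <- peak * as.numeric(canonical)
  # onset shift delays the response: evaluate at t - shift, zero before onset
  g_shift <- double_gamma(pmax(t - onset_shift, 0), response_delay,
                          undershoot_delay, response_dispersion,
                          undershoot_dispersion, undershoot_ratio)
  g_disp <- double_gamma(t, response_delay, undershoot_delay,
                         response_dispersion + dispersion_increment,
                         undershoot_dispersion, undershoot_ratio)
  out <- list(canonical = as.numeric(canonical),
              time_derivative = (g0 - g_shift) / onset_shift / peak,
              dispersion_derivative = (g0 - g_disp) / dispersion_increment / peak,
              step = step, duration = duration, time = t)
  class(out) <- "hrf_basis"
  out
}

#' Build the GLM design matrix for one run
#'
#' Convolves the three condition event trains (boxcars of the scheduled
#' stimulus duration) with each of the three HRF basis functions, adds the
#' six motion parameters and their first derivatives (backward differences,
#' leading zero) — by default also convolved with each basis — and a constant
#' column. All columns except the constant are mean-centered. The default
#' regressor count is therefore 3 conditions x 3 bases + 12 motion series x 3
#' bases + 1 = 46.
#'
#' @param schedule a `task_schedule`.
#' @param motion numeric matrix of motion parameters, `n_scans` rows x 6
#'   columns.
#' @param basis an `hrf_basis`; its `step` must divide the TR.
#' @param convolve_motion logical; convolve motion regressors with the HRF
#'   bases (default `TRUE`). `FALSE` gives the conventional unconvolved
#'   alternative (22 columns).
#' @param condition_warn warn when the condition number of the (centered)
#'   design exceeds this (default `1e6`).
#' @return object of class `design_matrix`: list with `values`
#'   (scan x regressor matrix with informative column names), `labels`
#'   (data frame of regressor metadata), `tr_seconds`, `condition_number`.
#' @export
build_design <- function(schedule, motion, basis, convolve_motion = TRUE,
                         condition_warn = 1e6) {
  stopifnot(inherits(schedule, "task_schedule"), inherits(basis, "hrf_basis"))
  motion <- as.matrix(motion)
  n_scans <- schedule$n_scans
  tr <- schedule$tr_seconds
  if (nrow(motion) != n_scans || ncol(motion) != 6) {
    stop("motion must be an n_scans x 6 matrix (got ",
         nrow(motion), " x ", ncol(motion), ", expected ", n_scans, " x 6)")
  }
  dt <- basis$step
  if (abs(tr / dt - round(tr / dt)) > 1e-8) {
    stop("basis step (", dt, " s) must divide the TR (", tr, " s)")
  }
  run_end <- n_scans * tr
  ons <- condition_onsets(schedule)
  bad <- vapply(ons, function(o) any(o$onset >= run_end), logical(1))
  if (any(bad)) stop("event onset beyond run end in condition(s): ",
                     paste(names(ons)[bad], collapse = ", "))

  grid_n <- as.integer(round(run_end / dt))
  scan_idx <- as.integer(round((seq_len(n_scans) - 1) * tr / dt)) + 1L
  bases <- list(canonical = basis$canonical,
                time_derivative = basis$time_derivative,
                dispersion_derivative = basis$dispersion_derivative)

  cols <- list(); labels <- list()
  for (cond in names(ons)) {
    u <- numeric(grid_n)
    for (j in seq_len(nrow(ons[[cond]]))) {
      i0 <- as.integer(floor(ons[[cond]]$onset[j] / dt)) + 1L
      i1 <- min(grid_n, i0 + max(1L, as.integer(ceiling(ons[[cond]]$duration[j] / dt))) - 1L)
      u[i0:i1] <- 1
    }
    for (bn in names(bases)) {
      z <- convolve_causal(u, bases[[bn]])[scan_idx]
      cols[[length(cols) + 1L]] <- z
      labels[[length(labels) + 1L]] <-
        data.frame(name = paste(cond, bn, sep = "."), kind = "condition",
                   condition = cond, basis = bn, stringsAsFactors = FALSE)
    }
  }

  mot_all <- cbind(motion, rbind(0, diff(motion)))
  colnames(mot_all) <- c(paste0("motion", 1:6), paste0("dmotion", 1:6))
  if (convolve_motion) {
    tr_idx <- seq(1, length(basis$time), by = as.integer(round(tr / dt)))
    for (m in colnames(mot_all)) {
      for (bn in names(bases)) {
        z <- convolve_causal(mot_all[, m], bases[[bn]][tr_idx])
        cols[[length(cols) + 1L]] <- z
        labels[[length(labels) + 1L]] <-
          data.frame(name = paste(m, bn, sep = "."), kind = "motion",
                     condition = NA, basis = bn, stringsAsFactors = FALSE)
      }
    }
  } else {
    for (m in colnames(mot_all)) {
      cols[[length(cols) + 1L]] <- mot_all[, m]
      labels[[length(labels) + 1L]] <-
        data.frame(name = m, kind = "motion", condition = NA, basis = NA,
                   stringsAsFactors = FALSE)
    }
  }

  X <- do.call(cbind, cols)
  X <- scale(X, center = TRUE, scale = FALSE)  # center everything but the constant
  X <- cbind(X, 1)
  labels[[length(labels) + 1L]] <- data.frame(name = "constant", kind = "constant",
                                              condition = NA, basis = NA,
                                              stringsAsFactors = FALSE)
  lab <- do.call(rbind, labels)
  colnames(X) <- lab$name
  attr(X, "scaled:center") <- NULL

  sv <- svd(X, nu = 0, nv = 0)$d
  kappa <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  if (kappa > condition_warn) {
    warning("design matrix poorly conditioned (condition number ",
            format(kappa, digits = 3), ")")
  }
  out <- list(values = X, labels = lab, tr_seconds = tr,
              condition_number = kappa)
  class(out) <- "design_matrix"
  out
}

# causal convolution of a sampled input with a sampled kernel, truncated to
# the input's length (both on the same grid)
convolve_causal <- function(u, kernel) {
  n <- length(u)
  as.numeric(stats::convolve(u, rev(kernel), type = "open"))[seq_len(n)]
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("GLM design matrix:", nrow(x$values), "scans x", ncol(x$values),
      "regressors (TR", x$tr_seconds, "s)\n")
  cat("  condition number:", format(x$condition_number, digits = 4), "\n")
  invisible(x)
}
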