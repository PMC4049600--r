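#' Simulation configuration
#'
#' Bundles every parameter of the synthetic n-back fMRI + behavior generator.
#' Defaults reproduce the study conditions the analysis assumes: TR 2 s,
#' three load conditions of two 100-trial blocks each (about 200 task scans
#' per condition), block-design BOLD built from spatially sparse sources, and
#' behavioral distributions parameterized by group means/SDs of median RT and
#' accuracy per condition (see [behavior_parameters()] for the defaults).
#'
#' @param grid_dims integer vector of 3 voxel counts per axis.
#' @param n_sources number of spatial sources to plant.
#' @param n_subjects_per_group subjects per age group (young, old).
#' @param tr_seconds repetition time, seconds.
#' @param scans_per_condition nominal task scans per load condition (drives
#'   block length through the schedule).
#' @param noise_sd SD of additive Gaussian voxel noise.
#' @param drift_amplitude amplitude of the slow cosine drift terms.
#' @param hrf_delay_jitter_sd SD (s) of per-subject jitter on the two HRF
#'   gamma delays; the old group receives `old_jitter_multiplier` times this.
#' @param coupling_strength additive coupling (accuracy units per amplitude
#'   z-score) between the designated source's 2-back amplitude and old-group
#'   2-back accuracy.
#' @param seed master seed; all generator substreams derive from it.
#' @param amplitude_sd between-subject SD of source condition amplitudes.
#' @param old_jitter_multiplier HRF jitter inflation for the old group.
#' @param blob_sigma Gaussian blob width of the source maps, voxels.
#' @param designated_source index of the source whose 2-back amplitude is
#'   coupled to old-group accuracy.
#' @param rt_out_of_range_fraction fraction of *incorrect* trials whose RT is
#'   drawn out of the valid 200-1500 ms range (exercises trial filtering).
#' @param rt_log_sd within-subject lognormal sigma of trial RTs.
#' @param rest_duration rest period between task blocks, seconds.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(grid_dims = c(16L, 16L, 10L),
                              n_sources = 8L,
                              n_subjects_per_group = 38L,
                              tr_seconds = 2,
                              scans_per_condition = 200L,
                              noise_sd = 1,
                              drift_amplitude = 0.5,
                              hrf_delay_jitter_sd = 0.5,
                              coupling_strength = 0,
                              seed = 1L,
                              amplitude_sd = 0.2,
                              old_jitter_multiplier = 1.5,
                              blob_sigma = 1.5,
                              designated_source = 1L,
                              rt_out_of_range_fraction = 0.2,
                              rt_log_sd = 0.2,
                              rest_duration = 20) {
  cfg <- list(grid_dims = as.integer(grid_dims), n_sources = as.integer(n_sources),
              n_subjects_per_group = as.integer(n_subjects_per_group),
              tr_seconds = tr_seconds, scans_per_condition = as.integer(scans_per_condition),
              noise_sd = noise_sd, drift_amplitude = drift_amplitude,
              hrf_delay_jitter_sd = hrf_delay_jitter_sd,
              coupling_strength = coupling_strength, seed = as.integer(seed),
              amplitude_sd = amplitude_sd, old_jitter_multiplier = old_jitter_multiplier,
              blob_sigma = blob_sigma, designated_source = as.integer(designated_source),
              rt_out_of_range_fraction = rt_out_of_range_fraction,
              rt_log_sd = rt_log_sd, rest_duration = rest_duration)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
              n_sources >= 1, n_subjects_per_group >= 0,
              tr_seconds > 0, scans_per_condition >= 1,
              noise_sd >= 0, drift_amplitude >= 0, hrf_delay_jitter_sd >= 0,
              amplitude_sd >= 0, blob_sigma > 0,
              designated_source >= 1, designated_source <= n_sources,
              rt_out_of_range_fraction >= 0, rt_out_of_range_fraction <= 1,
              rt_log_sd > 0)
    if (prod(grid_dims) < n_sources * 20) {
      stop("grid too small: volume ", prod(grid_dims),
           " < n_sources * 20 = ", n_sources * 20)
    }
  })
  invisible(cfg)
}

#' Behavioral generating parameters (group means/SDs per condition)
#'
#' Group-level means and SDs of median RT (ms) and accuracy (proportion)
#' per load condition. The defaults are the published group values of the
#' n-back cohort the generator emulates (young: 473(51)/511(59)/617(98) ms,
#' .93(.03)/.90(.05)/.86(.04); old: 589(50)/668(84)/866(125) ms,
#' .94(.03)/.90(.04)/.73(.12)).
#'
#' @param rt_mean,rt_sd 2 x 3 matrices (group x condition) of RT means/SDs, ms.
#' @param acc_mean,acc_sd 2 x 3 matrices of accuracy means/SDs.
#' @return list with the four matrices, dimnames (young/old x 0back/1back/2back).
#' @export
behavior_parameters <- function(
    rt_mean = rbind(young = c(473, 511, 617), old = c(589, 668, 866)),
    rt_sd   = rbind(young = c(51, 59, 98),   old = c(50, 84, 125)),
    acc_mean = rbind(young = c(.93, .90, .86), old = c(.94, .90, .73)),
    acc_sd   = rbind(young = c(.03, .05, .04), old = c(.03, .04, .12))) {
  out <- list(rt_mean = rt_mean, rt_sd = rt_sd,
              acc_mean = acc_mean, acc_sd = acc_sd)
  for (nm in names(out)) {
    stopifnot(identical(dim(out[[nm]]), c(2L, 3L)))
    dimnames(out[[nm]]) <- list(c("young", "old"), NBACK_CONDITIONS)
  }
  stopifnot(all(out$acc_mean > 0 & out$acc_mean < 1),
            all(out$rt_mean > 0), all(out$rt_sd > 0), all(out$acc_sd >= 0))
  out
}

#' Generate sparse spatial source maps
#'
#' Plants `n_sources` Gaussian blobs at mutually separated centers on the
#' voxel grid. The resulting maps are sparse and spatially smooth with
#' super-Gaussian voxel histograms — the kind of source spatial ICA assumes —
#' and are scaled to unit Euclidean norm.
#'
#' @param config a `simulation_config`.
#' @return voxel x source matrix (unit-norm columns) with attributes
#'   `centers` (source x 3) and `grid_dims`.
#' @export
generate_source_maps <- function(config) {
  validate_simulation_config(config)
  dims <- config$grid_dims
  n <- config$n_sources
  sigma <- config$blob_sigma
  min_sep <- 3 * sigma

  with_substream(config$seed, "source_maps", expr = {
    centers <- matrix(NA_real_, n, 3)
    placed <- 0L; tries <- 0L
    margin <- pmin(sigma, (dims - 1) / 2)
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 2000L * n) {
        stop("infeasible source packing: could not place ", n,
             " blobs with separation ", round(min_sep, 2),
             " in a ", paste(dims, collapse = "x"), " grid")
      }
      cand <- c(stats::runif(1, 1 + margin[1], dims[1] - margin[1]),
                stats::runif(1, 1 + margin[2], dims[2] - margin[2]),
                stats::runif(1, 1 + margin[3], dims[3] - margin[3]))
      if (placed == 0L ||
          min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))) >= min_sep) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                    z = seq_len(dims[3])))
    maps <- matrix(0, nrow(coords), n)
    for (s in seq_len(n)) {
      d2 <- colSums((t(coords) - centers[s, ])^2)
      v <- exp(-d2 / (2 * sigma^2))
      v[v < 1e-4] <- 0  # hard sparsity outside the blob
      maps[, s] <- v / sqrt(sum(v^2))
    }
    attr(maps, "centers") <- centers
    attr(maps, "grid_dims") <- dims
    maps
  })
}

#' Generate the full ground truth of one simulated dataset
#'
#' Draws everything the BOLD and behavior generators condition on: the source
#' maps, per-subject condition amplitudes for every source (a load-modulated
#' group profile plus between-subject noise), per-subject HRF delay jitter
#' (larger in the old group), and the behavioral generating parameters. The
#' ground truth is retained alongside every simulated dataset and serves as
#' the oracle in recovery tests.
#'
#' @param config a `simulation_config`.
#' @param behavior list from [behavior_parameters()].
#' @return object of class `ground_truth`: list with `source_maps`,
#'   `amplitudes` (subject x source x condition), `hrf` (per-subject delays),
#'   `behavior`, `subjects` (id/group data frame), `config`.
#' @export
generate_ground_truth <- function(config, behavior = behavior_parameters()) {
  validate_simulation_config(config)
  maps <- generate_source_maps(config)
  npg <- config$n_subjects_per_group
  n_sub <- 2L * npg
  groups <- rep(c("young", "old"), each = npg)
  ids <- sprintf("sub%03d", seq_len(n_sub))

  with_substream(config$seed, "ground_truth", expr = {
    # group-level condition profile per source: positive baseline plus a
    # graded load effect (1-back halfway between 0-back and 2-back)
    base <- stats::runif(config$n_sources, 0.3, 0.7)
    load <- stats::runif(config$n_sources, 0.3, 1.0)
    mu <- cbind(`0back` = base, `1back` = base + 0.5 * load,
                `2back` = base + load)
    amps <- array(NA_real_, c(n_sub, config$n_sources, 3),
                  dimnames = list(ids, NULL, NBACK_CONDITIONS))
    for (i in seq_len(n_sub)) {
      amps[i, , ] <- mu + matrix(stats::rnorm(config$n_sources * 3,
                                              sd = config$amplitude_sd),
                                 config$n_sources, 3)
    }
    jit_sd <- ifelse(groups == "old",
                     config$old_jitter_multiplier * config$hrf_delay_jitter_sd,
                     config$hrf_delay_jitter_sd)
    hrf <- data.frame(subject = ids, group = groups,
                      response_delay = 6 + stats::rnorm(n_sub, sd = jit_sd),
                      undershoot_delay = 16 + stats::rnorm(n_sub, sd = jit_sd),
                      stringsAsFactors = FALSE)
    out <- list(source_maps = maps, amplitudes = amps,
                amplitude_profile = mu, hrf = hrf, behavior = behavior,
                subjects = data.frame(subject = ids, group = groups,
                                      stringsAsFactors = FALSE),
                config = config)
    class(out) <- "ground_truth"
    out
  })
}

#' Generate one subject's BOLD run and motion parameters
#'
#' Builds the voxel time series as the exact linear mixture of the ground-
#' truth source maps: each source's time course is the sum over conditions of
#' that subject's condition amplitude times the condition event train
#' convolved with the subject's (jittered) HRF, sampled at the TR. Slow
#' cosine drift and white Gaussian noise are added on top. Motion is six
#' smooth random-walk series.
#'
#' @param truth a `ground_truth`.
#' @param schedule a `task_schedule` consistent with the config's scan count.
#' @param subject_index integer subject index into `truth$subjects`.
#' @param config the `simulation_config` (defaults to `truth$config`).
#' @return list with `bold` (4D array x,y,z,time), `motion`
#'   (`n_scans` x 6 matrix), `signal` (noise- and drift-free voxel x scan
#'   matrix), `regressors` (condition x scan convolved regressors).
#' @export
generate_subject_bold <- function(truth, schedule, subject_index,
                                  config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(schedule, "task_schedule"))
  n_sub <- nrow(truth$subjects)
  if (subject_index < 1 || subject_index > n_sub) {
    stop("subject_index out of range 1..", n_sub)
  }
  task_scans <- sum(schedule$blocks$duration) / schedule$tr_seconds
  if (abs(task_scans - 3 * config$scans_per_condition) >
      0.15 * 3 * config$scans_per_condition) {
    stop("schedule length inconsistent with config: ", round(task_scans),
         " task scans vs scans_per_condition*3 = ", 3 * config$scans_per_condition)
  }
  dims <- config$grid_dims
  n_scans <- schedule$n_scans
  maps <- truth$source_maps

  regs <- condition_regressors(schedule,
                               response_delay = truth$hrf$response_delay[subject_index],
                               undershoot_delay = truth$hrf$undershoot_delay[subject_index])
  amp <- truth$amplitudes[subject_index, , , drop = FALSE]
  amp <- matrix(amp, config$n_sources, 3)          # source x condition
  source_tc <- amp %*% regs                        # source x scan
  signal <- maps %*% source_tc                     # voxel x scan

  with_substream(config$seed, "bold", subject_index, expr = {
    vox <- nrow(signal)
    data <- signal
    if (config$drift_amplitude > 0) {
      tt <- seq_len(n_scans) / n_scans
      basis <- sapply(1:3, function(k) cos(pi * k * tt))
      coefs <- matrix(stats::rnorm(vox * 3, sd = config$drift_amplitude / sqrt(3)),
                      vox, 3)
      data <- data + coefs %*% t(basis)
    }
    if (config$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(vox * n_scans, sd = config$noise_sd),
                            vox, n_scans)
    }
    steps <- matrix(stats::rnorm(n_scans * 6, sd = 0.02), n_scans, 6)
    motion <- apply(steps, 2, cumsum)
    motion <- apply(motion, 2, function(m) stats::filter(m, rep(1 / 5, 5),
                                                         sides = 2, circular = TRUE))
    motion <- matrix(as.numeric(motion), n_scans, 6)
    list(bold = array(data, c(dims, n_scans)), motion = motion,
         signal = signal, regressors = regs)
  })
}

# condition event trains convolved with a (possibly jittered) double-gamma
# HRF, sampled at the TR; rows = conditions
condition_regressors <- function(schedule, response_delay = 6,
                                 undershoot_delay = 16, dt = 0.5) {
  tr <- schedule$tr_seconds
  n_scans <- schedule$n_scans
  grid_n <- as.integer(round(n_scans * tr / dt))
  scan_idx <- as.integer(round((seq_len(n_scans) - 1) * tr / dt)) + 1L
  t <- seq(0, 32, by = dt)
  g <- double_gamma(t, response_delay, undershoot_delay, 1, 1, 1 / 6)
  g <- g / max(g)
  ons <- condition_onsets(schedule)
  out <- matrix(0, 3, n_scans, dimnames = list(NBACK_CONDITIONS, NULL))
  for (cond in NBACK_CONDITIONS) {
    u <- numeric(grid_n)
    oc <- ons[[cond]]
    for (j in seq_len(nrow(oc))) {
      i0 <- as.integer(floor(oc$onset[j] / dt)) + 1L
      i1 <- min(grid_n, i0 + max(1L, as.integer(ceiling(oc$duration[j] / dt))) - 1L)
      u[i0:i1] <- 1
    }
    out[cond, ] <- convolve_causal(u, g)[scan_idx]
  }
  out
}

#' Generate the behavioral trial table
#'
#' Draws, per subject and condition, trial RTs (lognormal around the
#' subject's median, truncated to the valid 200-1500 ms range for correct
#' responses) and trial correctness (Bernoulli at the subject's accuracy).
#' Old-group 2-back accuracy includes `coupling_strength` times the z-score
#' of the subject's designated-source 2-back amplitude; the residual
#' between-subject accuracy SD is shrunk so the total SD matches the group
#' parameter, making the planted amplitude-accuracy correlation equal to
#' `coupling_strength / acc_sd(old, 2back)`. A fraction of incorrect trials
#' receives an out-of-range RT (< 200 or > 1500 ms) to exercise filtering.
#'
#' @param config a `simulation_config`.
#' @param truth a `ground_truth` (for amplitudes and behavior parameters).
#' @param trials_per_condition trials per subject and condition (default 200:
#'   two blocks of 100).
#' @return data frame with columns `subject`, `group`, `condition`, `trial`,
#'   `rt_ms`, `correct` (0/1); attribute `subject_truth` holds the per-subject
#'   generating accuracy and median RT.
#' @export
generate_behavior <- function(config, truth, trials_per_condition = 200L) {
  stopifnot(inherits(truth, "ground_truth"))
  bp <- truth$behavior
  npg <- config$n_subjects_per_group
  if (npg == 0L) {
    return(data.frame(subject = character(0), group = character(0),
                      condition = character(0), trial = integer(0),
                      rt_ms = numeric(0), correct = integer(0),
                      stringsAsFactors = FALSE))
  }
  subs <- truth$subjects
  cp <- config$coupling_strength
  sd22 <- bp$acc_sd["old", "2back"]
  if (abs(cp) > sd22) {
    stop("coupling_strength (", cp, ") exceeds the old-group 2-back accuracy SD (",
         sd22, "); the planted correlation would exceed 1")
  }
  amp_des <- truth$amplitudes[, config$designated_source, "2back"]
  z_amp <- (amp_des - truth$amplitude_profile[config$designated_source, "2back"]) /
    config$amplitude_sd

  with_substream(config$seed, "behavior", expr = {
    n_cells <- nrow(subs) * 3L
    tpc <- trials_per_condition
    col_subject <- character(n_cells * tpc)
    col_group <- character(n_cells * tpc)
    col_condition <- character(n_cells * tpc)
    col_rt <- numeric(n_cells * tpc)
    col_correct <- integer(n_cells * tpc)
    truth_rows <- vector("list", n_cells)
    k <- 0L
    for (i in seq_len(nrow(subs))) {
      g <- subs$group[i]
      for (cond in NBACK_CONDITIONS) {
        k <- k + 1L
        m_acc <- bp$acc_mean[g, cond]; s_acc <- bp$acc_sd[g, cond]
        coupled_cell <- g == "old" && cond == "2back"
        couple <- if (coupled_cell) cp * z_amp[i] else 0
        resid_sd <- sqrt(max(s_acc^2 - (if (coupled_cell) cp^2 else 0), 0))
        acc_i <- m_acc + resid_sd * stats::rnorm(1) + couple
        if ((m_acc + couple) <= 0 || (m_acc + couple) >= 1) {
          stop("coupling pushes subject ", subs$subject[i],
               " accuracy outside (0, 1)")
        }
        acc_i <- min(max(acc_i, 0.01), 0.99)
        m_rt <- max(bp$rt_mean[g, cond] + bp$rt_sd[g, cond] * stats::rnorm(1), 250)
        correct <- stats::rbinom(trials_per_condition, 1L, acc_i)
        rt <- stats::rlnorm(trials_per_condition, meanlog = log(m_rt),
                            sdlog = config$rt_log_sd)
        rt <- pmin(pmax(rt, 200), 1500)
        n_bad <- sum(correct == 0L)
        if (n_bad > 0 && config$rt_out_of_range_fraction > 0) {
          out_of_range <- which(correct == 0L)[
            stats::runif(n_bad) < config$rt_out_of_range_fraction]
          if (length(out_of_range) > 0) {
            fast <- stats::runif(length(out_of_range)) < 0.5
            rt[out_of_range] <- ifelse(fast,
                                       stats::runif(length(out_of_range), 80, 199),
                                       stats::runif(length(out_of_range), 1501, 2600))
          }
        }
        ix <- (k - 1L) * tpc + seq_len(tpc)
        col_subject[ix] <- subs$subject[i]
        col_group[ix] <- g
        col_condition[ix] <- cond
        col_rt[ix] <- rt
        col_correct[ix] <- correct
        truth_rows[[k]] <- data.frame(subject = subs$subject[i], group = g,
                                      condition = cond, accuracy_true = acc_i,
                                      rt_median_true = m_rt,
                                      stringsAsFactors = FALSE)
      }
    }
    out <- data.frame(subject = col_subject, group = col_group,
                      condition = col_condition,
                      trial = rep.int(seq_len(tpc), n_cells),
                      rt_ms = col_rt, correct = col_correct,
                      stringsAsFactors = FALSE)
    attr(out, "subject_truth") <- do.call(rbind, truth_rows)
    out
  })
}
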