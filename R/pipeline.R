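#' @title Pipeline driver
#' @description Runs the analysis end to end — simulate, decompose, regress,
#'   behavior, stats, report — or any contiguous subset, with every stage
#'   reading its inputs from and writing its artifacts to a working
#'   directory. Outputs are deterministic functions of the configuration.
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "decompose", "regress", "behavior",
                     "stats", "report")

#' Run the analysis pipeline
#'
#' Stages and their artifacts (all tables tab-separated with a provenance
#' header):
#' \describe{
#'   \item{simulate}{`events.tsv`, `bold_subNNN.nii.gz`, `motion_subNNN.tsv`,
#'     `behavior.tsv`, `subjects.tsv`, `truth_source_maps.tsv`.}
#'   \item{decompose}{`group_maps.tsv`, `stability.tsv`,
#'     `subject_timecourses.tsv`.}
#'   \item{regress}{`activation.tsv`, `load_effects.tsv`.}
#'   \item{behavior}{`behavior_summary.tsv`, `behavior_subjects.tsv`,
#'     `exclusions.tsv`.}
#'   \item{stats}{`anova.tsv`, `ttests.tsv`, `interaction.tsv`,
#'     `per_condition.tsv`, `correlations.tsv`.}
#'   \item{report}{`report.txt`.}
#' }
#' A `MANIFEST` file records the completion state of every stage. Later
#' stages read the artifacts of earlier ones from `out_dir`; requesting a
#' stage whose prerequisites are missing raises a dependency error naming
#' the stage.
#'
#' @param config a `pipeline_config`.
#' @param out_dir working directory for artifacts.
#' @param stages contiguous subset of
#'   `c("simulate","decompose","regress","behavior","stats","report")`.
#' @param log_level `"INFO"` (stage transitions), `"DEBUG"` (per-subject
#'   detail) or `"QUIET"`.
#' @return named list of the in-memory results of the executed stages.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = PIPELINE_STAGES,
                         log_level = c("INFO", "DEBUG", "QUIET")) {
  stopifnot(inherits(config, "pipeline_config"))
  log_level <- match.arg(log_level)
  ix <- match(stages, PIPELINE_STAGES)
  if (any(is.na(ix)) || (length(ix) > 1 && any(diff(sort(ix)) != 1))) {
    stop("`stages` must be a contiguous subset of: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  }
  stages <- PIPELINE_STAGES[sort(ix)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_fn <- function(level, ...) {
    if (log_level == "QUIET") return(invisible())
    if (level == "DEBUG" && log_level != "DEBUG") return(invisible())
    message("[", level, "] ", ...)
  }
  results <- list()
  manifest <- file.path(out_dir, "MANIFEST")
  note <- function(stage, status) {
    cat(sprintf("%s\t%s\tconfig=%s\tseed=%d\n", stage, status, hash,
                config$seed),
        file = manifest, append = TRUE)
  }
  for (stage in stages) {
    log_fn("INFO", "stage ", stage, " starting (config ", hash,
           ", seed ", config$seed, ")")
    res <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, out_dir, hash, log_fn),
             decompose = stage_decompose(config, out_dir, hash, log_fn),
             regress = stage_regress(config, out_dir, hash, log_fn),
             behavior = stage_behavior(config, out_dir, hash),
             stats = stage_stats(config, out_dir, hash),
             report = stage_report(config, out_dir)),
      error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, "FAILED")
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(res),
           call. = FALSE)
    }
    note(stage, "DONE")
    results[[stage]] <- res
    log_fn("INFO", "stage ", stage, " done")
  }
  invisible(results)
}

need_artifact <- function(out_dir, file, stage, produced_by) {
  p <- file.path(out_dir, file)
  if (!file.exists(p)) {
    stop("stage `", stage, "` requires `", file,
         "` produced by stage `", produced_by, "`; run it first")
  }
  p
}

stage_simulate <- function(config, out_dir, hash, log_fn) {
  sim <- config$simulation
  schedule <- build_schedule(seed = substream_seed(sim$seed, "schedule"),
                             tr_seconds = sim$tr_seconds,
                             trials_per_block = 100L,
                             rest_duration = sim$rest_duration)
  truth <- generate_ground_truth(sim)
  write_events(schedule, file.path(out_dir, "events.tsv"),
               config_hash = hash, seed = config$seed)
  n_sub <- nrow(truth$subjects)
  for (i in seq_len(n_sub)) {
    log_fn("DEBUG", "simulating subject ", i, "/", n_sub)
    run <- generate_subject_bold(truth, schedule, i, sim)
    write_bold(run$bold, file.path(out_dir, sprintf("bold_sub%03d.nii.gz", i)),
               tr = sim$tr_seconds)
    write_tsv(as.data.frame(run$motion),
              file.path(out_dir, sprintf("motion_sub%03d.tsv", i)),
              config_hash = hash, seed = config$seed, col_names = FALSE)
  }
  beh <- generate_behavior(sim, truth)
  write_tsv(beh, file.path(out_dir, "behavior.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(truth$subjects, file.path(out_dir, "subjects.tsv"),
            config_hash = hash, seed = config$seed)
  maps <- as.data.frame(truth$source_maps)
  names(maps) <- paste0("source", seq_len(ncol(maps)))
  write_tsv(maps, file.path(out_dir, "truth_source_maps.tsv"),
            config_hash = hash, seed = config$seed)
  list(schedule = schedule, truth = truth)
}

load_subject_bold <- function(config, out_dir, stage) {
  subs <- utils::read.delim(
    need_artifact(out_dir, "subjects.tsv", stage, "simulate"),
    comment.char = "#", stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(subs)), function(i) {
    b <- read_bold(file.path(out_dir, sprintf("bold_sub%03d.nii.gz", i)))
    d <- dim(b$data)
    matrix(b$data, prod(d[1:3]), d[4])
  })
  list(subjects = subs, mats = mats)
}

stage_decompose <- function(config, out_dir, hash, log_fn) {
  loaded <- load_subject_bold(config, out_dir, "decompose")
  dataset <- group_dataset(loaded$mats, subjects = loaded$subjects$subject)
  k <- config$ica$n_components
  log_fn("DEBUG", "group ICA: ", k, " components, ",
         config$ica$n_runs, " runs")
  dec <- run_group_ica(dataset, n_components = k,
                       n_runs = config$ica$n_runs,
                       seed = substream_seed(config$seed, "ica"),
                       k_subject = config$ica$k_subject,
                       k_group = config$ica$k_group %||% k)
  gm <- as.data.frame(t(dec$maps))
  names(gm) <- paste0("IC", seq_len(ncol(gm)))
  write_tsv(gm, file.path(out_dir, "group_maps.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(data.frame(component = seq_len(k), stability = dec$stability),
            file.path(out_dir, "stability.tsv"),
            config_hash = hash, seed = config$seed)
  tc_rows <- list()
  for (i in seq_along(dec$subject_timecourses)) {
    tc <- dec$subject_timecourses[[i]]
    tc_rows[[i]] <- data.frame(subject = dec$subjects[i],
                               scan = rep(seq_len(nrow(tc)), times = ncol(tc)),
                               component = rep(seq_len(ncol(tc)),
                                               each = nrow(tc)),
                               value = as.vector(tc))
  }
  write_tsv(do.call(rbind, tc_rows),
            file.path(out_dir, "subject_timecourses.tsv"),
            config_hash = hash, seed = config$seed)
  dec
}

schedule_from_events <- function(events, tr, n_scans) {
  structure(list(blocks = NULL,
                 trials = data.frame(condition = events$trial_type,
                                     onset = events$onset,
                                     duration = events$duration,
                                     stringsAsFactors = FALSE),
                 tr_seconds = tr, n_scans = as.integer(n_scans)),
            class = "task_schedule")
}

stage_regress <- function(config, out_dir, hash, log_fn) {
  events <- read_events(need_artifact(out_dir, "events.tsv", "regress",
                                      "simulate"))
  tcs <- utils::read.delim(
    need_artifact(out_dir, "subject_timecourses.tsv", "regress", "decompose"),
    comment.char = "#", stringsAsFactors = FALSE)
  subs <- utils::read.delim(
    need_artifact(out_dir, "subjects.tsv", "regress", "simulate"),
    comment.char = "#", stringsAsFactors = FALSE)
  basis <- hrf_basis_set(config$hrf$step)
  k <- max(tcs$component)
  subjects <- unique(tcs$subject)
  n_scans <- max(tcs$scan)
  schedule <- schedule_from_events(events, config$simulation$tr_seconds,
                                   n_scans)
  sub_tcs <- vector("list", length(subjects))
  designs <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    log_fn("DEBUG", "design + fit for ", subjects[i])
    motion <- read_motion(file.path(out_dir,
                                    sprintf("motion_sub%03d.tsv", i)))
    designs[[i]] <- build_design(schedule, motion, basis,
                                 convolve_motion = config$hrf$convolve_motion)
    ti <- tcs[tcs$subject == subjects[i], ]
    sub_tcs[[i]] <- matrix(ti$value[order(ti$component, ti$scan)],
                           n_scans, k)
  }
  dec_stub <- structure(list(subject_timecourses = sub_tcs,
                             subjects = subjects, n_components = k),
                        class = "ica_decomposition")
  groups <- subs$group[match(subjects, subs$subject)]
  act <- compute_activation_table(dec_stub, designs, basis, groups = groups)
  write_tsv(act$activation, file.path(out_dir, "activation.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(act$load_effect, file.path(out_dir, "load_effects.tsv"),
            config_hash = hash, seed = config$seed)
  act
}

stage_behavior <- function(config, out_dir, hash) {
  trials <- read_behavior(need_artifact(out_dir, "behavior.tsv", "behavior",
                                        "simulate"))
  trials <- filter_trials(trials, config$behavior$rt_min,
                          config$behavior$rt_max)
  summ <- cost_indices(summarize_behavior(trials))
  excl <- apply_exclusions(summ, rule = config$behavior$exclusion_rule)
  write_tsv(summ$by_condition, file.path(out_dir, "behavior_summary.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(summ$by_subject, file.path(out_dir, "behavior_subjects.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(excl$log, file.path(out_dir, "exclusions.tsv"),
            config_hash = hash, seed = config$seed)
  list(summary = summ, exclusions = excl)
}

activation_table_from_df <- function(activation) {
  w0 <- activation[activation$condition == "0back", ]
  w2 <- activation[activation$condition == "2back", ]
  le <- merge(w0[, c("subject", "group", "component", "activation")],
              w2[, c("subject", "component", "activation")],
              by = c("subject", "component"), suffixes = c("_0", "_2"))
  le$load_effect <- le$activation_2 - le$activation_0
  structure(list(activation = activation,
                 load_effect = le[, c("subject", "group", "component",
                                      "load_effect")],
                 residual_variance = NULL),
            class = "activation_table")
}

stage_stats <- function(config, out_dir, hash) {
  act_df <- utils::read.delim(
    need_artifact(out_dir, "activation.tsv", "stats", "regress"),
    comment.char = "#", stringsAsFactors = FALSE)
  bc <- utils::read.delim(
    need_artifact(out_dir, "behavior_summary.tsv", "stats", "behavior"),
    comment.char = "#", stringsAsFactors = FALSE)
  bsub <- utils::read.delim(
    need_artifact(out_dir, "behavior_subjects.tsv", "stats", "behavior"),
    comment.char = "#", stringsAsFactors = FALSE)
  excl <- utils::read.delim(file.path(out_dir, "exclusions.tsv"),
                            comment.char = "#", stringsAsFactors = FALSE)
  keep <- setdiff(bsub$subject, excl$subject)
  summ <- structure(list(by_condition = bc[bc$subject %in% keep, ],
                         by_subject = bsub[bsub$subject %in% keep, ]),
                    class = "behavior_summary")
  act <- activation_table_from_df(act_df[act_df$subject %in% keep, ])
  comps <- config$stats$selected_components
  if (is.null(comps)) {
    truth_path <- file.path(out_dir, "truth_source_maps.tsv")
    if (file.exists(truth_path)) {
      # planted sources double as selection templates on synthetic data
      tmpl <- t(as.matrix(utils::read.delim(truth_path, comment.char = "#")))
      gm <- t(as.matrix(utils::read.delim(
        need_artifact(out_dir, "group_maps.tsv", "stats", "decompose"),
        comment.char = "#")))
      dec_stub <- structure(list(maps = gm, n_components = nrow(gm)),
                            class = "ica_decomposition")
      sel <- select_components(dec_stub, tmpl)
      comps <- sort(unname(sel[!is.na(sel)]))
    } else {
      comps <- sort(unique(act_df$component))
    }
  }
  rep <- analysis_report(act, summ, comps, alpha = config$stats$alpha)
  write_tsv(rep$anova, file.path(out_dir, "anova.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(rep$ttests, file.path(out_dir, "ttests.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(rep$interaction, file.path(out_dir, "interaction.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(rep$per_condition, file.path(out_dir, "per_condition.tsv"),
            config_hash = hash, seed = config$seed)
  write_tsv(rep$correlations, file.path(out_dir, "correlations.tsv"),
            config_hash = hash, seed = config$seed)
  rep
}

stage_report <- function(config, out_dir) {
  for (f in c("anova.tsv", "correlations.tsv")) {
    need_artifact(out_dir, f, "report", "stats")
  }
  path <- file.path(out_dir, "report.txt")
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("Working-memory network activation report")
  w("========================================")
  anova <- utils::read.delim(file.path(out_dir, "anova.tsv"),
                             comment.char = "#")
  ia <- anova[anova$effect == "group:component", ]
  w("")
  w(sprintf("Age x component interaction: F(%d,%d) = %.2f, p = %.4g",
            ia$df1, ia$df2, ia$F, ia$p))
  cors <- utils::read.delim(file.path(out_dir, "correlations.tsv"),
                            comment.char = "#")
  w("")
  w("Between-group comparison of accuracy-activation correlations:")
  for (i in seq_len(nrow(cors))) {
    w(sprintf("  IC%d %s: rho_young = %.3f (n=%d), rho_old = %.3f (n=%d), z = %.3f, p = %.3f",
              cors$component[i], cors$condition[i], cors$rho_young[i],
              cors$n_young[i], cors$rho_old[i], cors$n_old[i], cors$z[i],
              cors$p[i]))
  }
  path
}
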