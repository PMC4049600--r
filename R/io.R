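#' Read a 4D BOLD NIfTI volume
#'
#' @param path NIfTI file path.
#' @param tr optional TR override (seconds); otherwise taken from the header.
#' @return list with `data` (4D array, x/y/z/time), `affine` (4x4 matrix or
#'   `NULL`), `tr_seconds`.
#' @export
read_bold <- function(path, tr = NULL) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) {
    stop("not a 4D volume: ", path, " has ", length(d), " dimensions")
  }
  tr_hdr <- RNifti::pixdim(img)[4]
  tr_out <- tr %||% (if (is.finite(tr_hdr) && tr_hdr > 0) tr_hdr else
    stop("TR unavailable in header of ", path, " and no override given"))
  list(data = array(as.numeric(img), d),
       affine = tryCatch(RNifti::xform(img), error = function(e) NULL),
       tr_seconds = as.numeric(tr_out))
}

#' Write a 4D BOLD NIfTI volume
#'
#' @param data 4D array.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @param voxel_size numeric length 3, mm.
#' @param tr repetition time, seconds (stored in pixdim\[4\]).
#' @export
write_bold <- function(data, path, voxel_size = c(3, 3, 3), tr = 2) {
  stopifnot(length(dim(data)) == 4)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_table_checked <- function(path, required, what, numeric_cols = character(0)) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required_columns(tab, required, what)
  for (col in numeric_cols) {
    if (!is.numeric(tab[[col]])) {
      stop(what, ": column `", col, "` must be numeric")
    }
  }
  tab
}

#' Read an events table
#'
#' Tab-separated with header columns `onset`, `duration` (seconds) and
#' `trial_type` (0back/1back/2back).
#' @param path file path.
#' @return validated data frame.
#' @export
read_events <- function(path) {
  ev <- read_table_checked(path, c("onset", "duration", "trial_type"),
                           "events", c("onset", "duration"))
  if (any(ev$onset < 0)) stop("events: column `onset` contains negative values")
  bad <- setdiff(unique(ev$trial_type), NBACK_CONDITIONS)
  if (length(bad) > 0) {
    stop("events: unknown trial_type value(s): ", paste(bad, collapse = ", "))
  }
  ev
}

#' Read a motion-parameter table
#'
#' Whitespace- or tab-separated, 6 numeric columns, one row per scan.
#' @param path file path.
#' @return numeric matrix, `n_scans` x 6.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("motion file not found: ", path)
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  if (ncol(m) != 6) stop("motion: expected 6 columns, found ", ncol(m))
  if (!is.numeric(m)) stop("motion: non-numeric values")
  unname(m)
}

#' Read a behavioral trial table
#'
#' Tab-separated with columns `subject`, `group`, `condition`, `trial`,
#' `rt_ms`, `correct`.
#' @param path file path.
#' @return validated data frame.
#' @export
read_behavior <- function(path) {
  tab <- read_table_checked(path,
                            c("subject", "group", "condition", "trial",
                              "rt_ms", "correct"),
                            "behavior", c("rt_ms"))
  if (any(tab$rt_ms < 0, na.rm = TRUE)) {
    stop("behavior: column `rt_ms` contains negative values")
  }
  tab
}

#' Write a tab-separated table with a provenance header
#'
#' All pipeline tables carry the configuration hash and master seed in `#`
#' comment lines; readers skip them.
#'
#' @param tab data frame.
#' @param path destination.
#' @param config_hash,seed provenance fields (optional).
#' @param col_names write a header row (motion files conventionally have
#'   none).
#' @export
write_tsv <- function(tab, path, config_hash = NULL, seed = NULL,
                      col_names = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(paste0("# config_hash: ", config_hash), con, sep = "\n")
  }
  if (!is.null(seed)) {
    writeLines(paste0("# seed: ", seed), con, sep = "\n")
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col_names, eol = "\n")
  invisible(path)
}

#' Write the events of a schedule
#' @param schedule a `task_schedule`.
#' @param path destination.
#' @param ... passed to [write_tsv()].
#' @export
write_events <- function(schedule, path, ...) {
  tr <- schedule$trials
  write_tsv(data.frame(onset = tr$onset, duration = tr$duration,
                       trial_type = tr$condition), path, ...)
}

#' Pipeline configuration
#'
#' Validated nested configuration of the full analysis pipeline. Unknown
#' keys are rejected.
#'
#' @param simulation named list of [simulation_config()] overrides.
#' @param ica named list: `n_components`, `n_runs`, `k_subject`, `k_group`.
#' @param hrf named list: `step`, `convolve_motion`.
#' @param behavior named list: `rt_min`, `rt_max`, `exclusion_rule`.
#' @param stats named list: `alpha`, `selected_components` (optional).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), ica = list(), hrf = list(),
                            behavior = list(), stats = list(), seed = 1L) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in config section `", section, "`: ",
           paste(bad, collapse = ", "))
    }
    x
  }
  check_keys(simulation, names(formals(simulation_config)), "simulation")
  ica <- utils::modifyList(list(n_components = 8L, n_runs = 10L,
                                k_subject = NULL, k_group = NULL),
                           check_keys(ica, c("n_components", "n_runs",
                                             "k_subject", "k_group"), "ica"))
  hrf <- utils::modifyList(list(step = 0.5, convolve_motion = TRUE),
                           check_keys(hrf, c("step", "convolve_motion"), "hrf"))
  behavior <- utils::modifyList(list(rt_min = 200, rt_max = 1500,
                                     exclusion_rule = "either"),
                                check_keys(behavior,
                                           c("rt_min", "rt_max",
                                             "exclusion_rule"), "behavior"))
  stats <- utils::modifyList(list(alpha = 0.05, selected_components = NULL),
                             check_keys(stats, c("alpha",
                                                 "selected_components"),
                                        "stats"))
  simulation$seed <- simulation$seed %||% seed
  structure(list(simulation = do.call(simulation_config, simulation),
                 ica = ica, hrf = hrf, behavior = behavior, stats = stats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with sections `simulation`, `ica`, `hrf`,
#'   `behavior`, `stats` and a top-level `seed`.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("simulation", "ica", "hrf", "behavior", "stats", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  }
  pipeline_config(simulation = y$simulation %||% list(),
                  ica = y$ica %||% list(), hrf = y$hrf %||% list(),
                  behavior = y$behavior %||% list(),
                  stats = y$stats %||% list(),
                  seed = y$seed %||% 1L)
}

config_hash <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  s <- paste(names(flat), vapply(flat, function(v)
    format(v, digits = 15), character(1)), sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  sprintf("%08x", h)
}
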