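#' Temporal regression of a component time course on the GLM design
#'
#' Ordinary least squares of one subject-level component time course on the
#' full design matrix. The three per-condition basis coefficients (canonical,
#' temporal derivative, dispersion derivative) are returned grouped for the
#' activation statistic.
#'
#' @param timecourse numeric vector, one value per scan.
#' @param design a `design_matrix` (or plain matrix with condition/basis
#'   column names of the form `<cond>.<basis>`).
#' @return list with `coefficients` (named), `residual_variance`,
#'   `condition_betas` (3 x 3 matrix, conditions x bases), `df_residual`.
#' @export
fit_component <- function(timecourse, design) {
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  y <- as.numeric(timecourse)
  if (length(y) != nrow(X)) {
    stop("timecourse length (", length(y), ") must equal design rows (",
         nrow(X), ")")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  df <- length(y) - ncol(X)
  rv <- if (df > 0) sum(fit$residuals^2) / df else NA_real_
  bases <- c("canonical", "time_derivative", "dispersion_derivative")
  cb <- matrix(NA_real_, 3, 3, dimnames = list(NBACK_CONDITIONS, bases))
  for (cond in NBACK_CONDITIONS) {
    for (b in bases) {
      nm <- paste(cond, b, sep = ".")
      if (nm %in% names(beta)) cb[cond, b] <- beta[nm]
    }
  }
  list(coefficients = beta, residual_variance = rv, condition_betas = cb,
       df_residual = df)
}

#' Area-under-the-curve activation statistic
#'
#' Collapses the three basis coefficients of one condition into a single
#' activation value: the summed reconstructed BOLD response divided by the
#' summed canonical HRF,
#' `(b1*sum(canonical) + b2*sum(time_deriv) + b3*sum(disp_deriv)) / sum(canonical)`.
#' When the derivative curves sum to zero this is exactly the canonical
#' coefficient; the statistic is linear in all three coefficients.
#'
#' @param b numeric vector of the three basis coefficients (canonical,
#'   temporal derivative, dispersion derivative), or a single canonical
#'   coefficient with `b2`/`b3`.
#' @param basis an `hrf_basis`, or a list with elements `canonical`,
#'   `time_derivative`, `dispersion_derivative` sampled on a common grid.
#' @param b2,b3 alternative scalar interface.
#' @return scalar activation value on the canonical-coefficient scale.
#' @export
auc_activation <- function(b, basis, b2 = NULL, b3 = NULL) {
  if (!is.null(b2) || !is.null(b3)) b <- c(b, b2 %||% 0, b3 %||% 0)
  stopifnot(length(b) == 3)
  s1 <- sum(basis$canonical)
  if (s1 == 0) stop("canonical basis sums to zero; AUC undefined")
  if (s1 < 0) stop("canonical basis has negative sum; refusing to sign-flip")
  (b[1] * s1 + b[2] * sum(basis$time_derivative) +
      b[3] * sum(basis$dispersion_derivative)) / s1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject x component x condition activation table
#'
#' Applies [fit_component()] and [auc_activation()] to every subject-level
#' component time course and populates the BOLD load effect, the 2-back
#' minus 0-back activation difference per subject and component.
#'
#' @param decomposition an `ica_decomposition` (its z-scored subject time
#'   courses are regressed).
#' @param designs list of `design_matrix` objects, one per subject.
#' @param basis the `hrf_basis` the designs were built with.
#' @param components integer subset of components (default: all).
#' @param groups optional character vector of group labels per subject.
#' @return object of class `activation_table`: list with `activation` (tidy
#'   data frame: subject, group, component, condition, activation),
#'   `load_effect` (subject, group, component, load_effect),
#'   `residual_variance`.
#' @export
compute_activation_table <- function(decomposition, designs, basis,
                                     components = NULL, groups = NULL) {
  stopifnot(inherits(decomposition, "ica_decomposition"))
  m <- length(decomposition$subject_timecourses)
  if (length(designs) != m) {
    stop("need one design per subject (", m, " subjects, ",
         length(designs), " designs)")
  }
  if (is.null(components)) components <- seq_len(decomposition$n_components)
  if (is.null(groups)) groups <- rep(NA_character_, m)
  act <- list(); rv <- list()
  failures <- character(0)
  for (i in seq_len(m)) {
    tc_mat <- decomposition$subject_timecourses[[i]]
    for (comp in components) {
      fit <- tryCatch(fit_component(tc_mat[, comp], designs[[i]]),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- c(failures, paste0(decomposition$subjects[i], "/IC", comp,
                                       ": ", conditionMessage(fit)))
        next
      }
      for (cond in NBACK_CONDITIONS) {
        act[[length(act) + 1L]] <- data.frame(
          subject = decomposition$subjects[i], group = groups[i],
          component = comp, condition = cond,
          activation = auc_activation(fit$condition_betas[cond, ], basis),
          stringsAsFactors = FALSE)
      }
      rv[[length(rv) + 1L]] <- data.frame(
        subject = decomposition$subjects[i], component = comp,
        residual_variance = fit$residual_variance, stringsAsFactors = FALSE)
    }
  }
  if (length(failures) > 0) {
    stop("temporal regression failed for:\n  ",
         paste(failures, collapse = "\n  "))
  }
  activation <- do.call(rbind, act)
  if (any(!is.finite(activation$activation))) {
    stop("non-finite activation values produced")
  }
  w0 <- activation[activation$condition == "0back", ]
  w2 <- activation[activation$condition == "2back", ]
  le <- merge(w0[, c("subject", "group", "component", "activation")],
              w2[, c("subject", "component", "activation")],
              by = c("subject", "component"), suffixes = c("_0", "_2"))
  le$load_effect <- le$activation_2 - le$activation_0
  structure(list(activation = activation,
                 load_effect = le[, c("subject", "group", "component",
                                      "load_effect")],
                 residual_variance = do.call(rbind, rv)),
            class = "activation_table")
}

#' Reshape load effects to a subject x component matrix
#'
#' @param table an `activation_table`.
#' @param components optional component subset (in matrix column order).
#' @return numeric matrix with subject row names; `attr(, "groups")` carries
#'   the group label per row when available.
#' @export
load_effect_matrix <- function(table, components = NULL) {
  stopifnot(inherits(table, "activation_table"))
  le <- table$load_effect
  if (is.null(components)) components <- sort(unique(le$component))
  subs <- sort(unique(le$subject))
  M <- matrix(NA_real_, length(subs), length(components),
              dimnames = list(subs, paste0("IC", components)))
  for (j in seq_along(components)) {
    sel <- le[le$component == components[j], ]
    M[match(sel$subject, subs), j] <- sel$load_effect
  }
  g <- le$group[match(subs, le$subject)]
  attr(M, "groups") <- g
  M
}
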