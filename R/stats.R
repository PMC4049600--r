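#' @title Inferential chain over activation and behavior
#' @description Mixed repeated-measures ANOVA on component load effects,
#'   post-hoc t-tests, age x activation interaction regressions, Spearman
#'   correlations and the Fisher r-to-z comparison of independent
#'   correlations.
#' @name stats_chain
NULL

#' Mixed-design repeated-measures ANOVA on component load effects
#'
#' One within-subject factor (component) and one between-subjects factor
#' (age group). Returns the between, within and interaction effects with
#' uncorrected degrees of freedom — with k components and N subjects in two
#' groups the interaction has dfs (k-1, (N-2)(k-1)) — plus
#' Greenhouse-Geisser-corrected p-values computed from the sphericity
#' epsilon of the pooled within-group covariance.
#'
#' @param load_effects numeric subject x component matrix (complete cases).
#' @param groups character/factor of length `nrow(load_effects)` with two
#'   levels.
#' @return data frame with columns `effect`, `F`, `df1`, `df2`, `p`,
#'   `gg_epsilon`, `p_gg`.
#' @export
rm_anova <- function(load_effects, groups) {
  M <- as.matrix(load_effects)
  groups <- factor(groups)
  if (any(!is.finite(M))) stop("load_effects contains missing or non-finite cells")
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  n <- nrow(M); k <- ncol(M)
  long <- data.frame(
    y = as.vector(M),
    subject = factor(rep(seq_len(n), times = k)),
    component = factor(rep(seq_len(k), each = n)),
    group = rep(groups, times = k))
  fit <- stats::aov(y ~ group * component + Error(subject / component),
                    data = long)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: subject:component"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
      p = tab[i, "Pr(>F)"])
  }
  eff <- rbind(group = pick(between, "group"),
               component = pick(within, "component"),
               `group:component` = pick(within, "group:component"))

  eps <- gg_epsilon(M, groups)
  out <- data.frame(effect = rownames(eff), F = eff[, "F"],
                    df1 = eff[, "df1"], df2 = eff[, "df2"], p = eff[, "p"],
                    gg_epsilon = c(NA, eps, eps), row.names = NULL)
  out$p_gg <- ifelse(is.na(out$gg_epsilon), out$p,
                     stats::pf(out$F, out$gg_epsilon * out$df1,
                               out$gg_epsilon * out$df2, lower.tail = FALSE))
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# k repeated measures, via orthonormal contrasts.
gg_epsilon <- function(M, groups) {
  k <- ncol(M)
  S <- matrix(0, k, k); df <- 0
  for (g in levels(groups)) {
    Mg <- M[groups == g, , drop = FALSE]
    S <- S + stats::cov(Mg) * (nrow(Mg) - 1)
    df <- df + nrow(Mg) - 1
  }
  S <- S / df
  C <- contrast_basis(k)
  V <- C %*% S %*% t(C)
  sum(diag(V))^2 / ((k - 1) * sum(V^2))
}

contrast_basis <- function(k) {
  H <- stats::contr.helmert(k)
  t(apply(t(H), 1, function(v) v / sqrt(sum(v^2))))
}

#' Post-hoc t-tests on component load effects
#'
#' Per component: a pooled-variance two-sample t-test for the group
#' difference in load effect, and one-sample t-tests of the load effect
#' against zero within each group. Degenerate zero-variance cells are
#' flagged (`NA` statistic, note) rather than raising.
#'
#' @inheritParams rm_anova
#' @return data frame with one row per component x test (`two_sample`,
#'   `one_sample_<group>`): `statistic`, `df`, `p`, `estimate`, `note`.
#' @export
load_ttests <- function(load_effects, groups) {
  M <- as.matrix(load_effects)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2))
  comps <- colnames(M) %||% paste0("IC", seq_len(ncol(M)))
  rows <- list()
  for (j in seq_len(ncol(M))) {
    x <- M[groups == levels(groups)[1], j]
    y <- M[groups == levels(groups)[2], j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) != mean(y)) {
      stop("zero variance with nonzero mean difference in component ",
           comps[j], "; t statistic unbounded")
    }
    rows[[length(rows) + 1L]] <- safe_t(
      comps[j], "two_sample",
      function() stats::t.test(x, y, var.equal = TRUE),
      degenerate = stats::sd(x) == 0 && stats::sd(y) == 0)
    for (g in levels(groups)) {
      v <- M[groups == g, j]
      rows[[length(rows) + 1L]] <- safe_t(
        comps[j], paste0("one_sample_", g),
        function() stats::t.test(v, mu = 0),
        degenerate = stats::sd(v) == 0)
    }
  }
  do.call(rbind, rows)
}

safe_t <- function(component, test, thunk, degenerate = FALSE) {
  if (degenerate) {
    return(data.frame(component = component, test = test,
                      statistic = NA_real_, df = NA_real_, p = NA_real_,
                      estimate = NA_real_, note = "zero variance",
                      stringsAsFactors = FALSE))
  }
  res <- tryCatch(thunk(), error = function(e) e)
  if (inherits(res, "error")) {
    return(data.frame(component = component, test = test,
                      statistic = NA_real_, df = NA_real_, p = NA_real_,
                      estimate = NA_real_, note = conditionMessage(res),
                      stringsAsFactors = FALSE))
  }
  est <- if (length(res$estimate) == 2) diff(rev(res$estimate)) else res$estimate
  data.frame(component = component, test = test,
             statistic = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value, estimate = unname(est), note = "",
             stringsAsFactors = FALSE)
}

#' Age x activation interaction regression
#'
#' The behavioral outcome is regressed on effect-coded, centered age, the
#' within-group z-scored activation predictor, and their interaction. With
#' unbalanced groups the centered age codes are not exactly +/-1 (they are
#' +/-1 minus the unweighted mean code). Degrees of freedom follow the
#' conventional n - p - 1.
#'
#' @param outcome numeric vector (e.g. accuracy cost).
#' @param groups two-level factor; the second level is coded +1.
#' @param predictor numeric vector (e.g. BOLD load effect), z-scored within
#'   group before entering the model.
#' @return object of class `interaction_regression`: list with
#'   `coefficients` (data frame: term, estimate, t, df, p), `r_squared`,
#'   `F`, `df1`, `df2`, `p_model`, `n`.
#' @export
interaction_regression <- function(outcome, groups, predictor) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2,
            length(outcome) == length(groups),
            length(predictor) == length(groups))
  if (any(!is.finite(predictor)) || any(!is.finite(outcome))) {
    stop("outcome and predictor must be finite")
  }
  age_raw <- ifelse(groups == levels(groups)[2], 1, -1)
  age <- age_raw - mean(age_raw)
  z <- numeric(length(predictor))
  for (g in levels(groups)) {
    ix <- groups == g
    s <- stats::sd(predictor[ix])
    if (s == 0) stop("predictor is constant within group ", g,
                     "; cannot z-score")
    z[ix] <- (predictor[ix] - mean(predictor[ix])) / s
  }
  df <- data.frame(y = outcome, age = age, z = z)
  X <- stats::model.matrix(~ age * z, df)
  if (qr(X)$rank < ncol(X)) stop("collinear interaction design")
  if (stats::sd(outcome) == 0) {
    # a constant outcome carries no variance to explain
    co <- data.frame(term = c("(Intercept)", "age", "z", "age:z"),
                     estimate = c(outcome[1], 0, 0, 0), t = NA_real_,
                     df = length(outcome) - 4L, p = NA_real_)
    return(structure(list(coefficients = co, r_squared = 0, F = NA_real_,
                          df1 = 3, df2 = length(outcome) - 4L,
                          p_model = NA_real_, n = length(outcome)),
                     class = "interaction_regression"))
  }
  fit <- stats::lm(y ~ age * z, data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              t = co[, 3], df = fit$df.residual, p = co[, 4],
                              row.names = NULL),
    r_squared = sm$r.squared,
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    p_model = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                        lower.tail = FALSE),
    n = length(outcome)),
    class = "interaction_regression")
}

#' Simple within-group regression
#'
#' One-predictor least-squares regression, used for the per-condition
#' follow-up models (outcome on z-scored activation within one group).
#'
#' @param outcome,predictor numeric vectors.
#' @param zscore_predictor z-score the predictor first (default `TRUE`).
#' @return data frame with `estimate`, `t`, `df`, `p`, `r_squared`, `F`, `n`.
#' @export
simple_regression <- function(outcome, predictor, zscore_predictor = TRUE) {
  stopifnot(length(outcome) == length(predictor), length(outcome) >= 3)
  if (zscore_predictor) {
    s <- stats::sd(predictor)
    if (s == 0) stop("constant predictor")
    predictor <- (predictor - mean(predictor)) / s
  }
  fit <- stats::lm(outcome ~ predictor)
  sm <- summary(fit)
  co <- stats::coef(sm)
  data.frame(estimate = co["predictor", 1], t = co["predictor", 3],
             df = fit$df.residual, p = co["predictor", 4],
             r_squared = sm$r.squared, F = unname(sm$fstatistic[1]),
             n = length(outcome))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x,y numeric vectors, length >= 4.
#' @return the correlation coefficient rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y, method = "spearman")
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' Fisher-transforms both correlations and forms
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value. Swapping the two correlations negates z. The
#' transform is exact for Pearson correlations and a conventional
#' approximation when applied to Spearman rho.
#'
#' @param rho1,rho2 correlation coefficients, |rho| < 1.
#' @param n1,n2 sample sizes, >= 4.
#' @return list with `rho1`, `n1`, `rho2`, `n2`, `z`, `p` (two-sided).
#' @export
compare_correlations <- function(rho1, n1, rho2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(rho1) >= 1 || abs(rho2) >= 1) {
    stop("|rho| must be < 1 for the Fisher transform")
  }
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(rho1 = rho1, n1 = n1, rho2 = rho2, n2 = n2,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Run the full statistical chain
#'
#' Executes, in order: the mixed ANOVA on the selected components' load
#' effects, post-hoc two-sample and one-sample t-tests, per-component
#' interaction regressions with accuracy cost and speed cost as outcomes,
#' per-condition within-group regressions of accuracy (and median RT) on the
#' z-scored condition activation, Spearman accuracy-activation correlations
#' per group and condition, and the Fisher r-to-z comparison of those
#' correlations between groups.
#'
#' @param activation an `activation_table` with group labels.
#' @param behavior a `behavior_summary` with cost indices (see
#'   [cost_indices()]); only its included subjects should be passed.
#' @param components integer vector of selected component indices; empty
#'   selection returns an empty report with a warning.
#' @param alpha significance level gating the follow-up models (default .05).
#' @return object of class `wm_report`: list with elements `anova`,
#'   `ttests`, `interaction` (per component x outcome), `per_condition`
#'   (within-group condition regressions), `correlations` (Spearman +
#'   between-group z comparison per component x condition), `n_subjects`.
#' @export
analysis_report <- function(activation, behavior, components, alpha = 0.05) {
  stopifnot(inherits(activation, "activation_table"),
            inherits(behavior, "behavior_summary"))
  if (length(components) == 0) {
    warning("empty component selection; returning empty report")
    return(structure(list(anova = NULL, ttests = NULL, interaction = NULL,
                          per_condition = NULL, correlations = NULL,
                          n_subjects = 0), class = "wm_report"))
  }
  bs <- behavior$by_subject
  if (is.null(bs$speed_cost)) stop("behavior summary lacks cost indices; run cost_indices() first")
  M <- load_effect_matrix(activation, components)
  common <- intersect(rownames(M), bs$subject)
  if (length(common) < 4) stop("stage alignment: fewer than 4 subjects shared between activation and behavior tables")
  M <- M[common, , drop = FALSE]
  bs <- bs[match(common, bs$subject), ]
  groups <- factor(bs$group, levels = c("young", "old"))
  if (any(is.na(groups))) {
    stop("stage alignment: group labels must be young/old for all subjects")
  }

  anova_res <- rm_anova(M, groups)
  tt <- load_ttests(M, groups)

  inter <- list(); per_cond <- list(); cors <- list()
  act <- activation$activation[activation$activation$subject %in% common, ]
  for (j in seq_along(components)) {
    comp <- components[j]
    le <- M[, j]
    for (outcome_name in c("accuracy_cost", "speed_cost")) {
      reg <- interaction_regression(bs[[outcome_name]], groups, le)
      inter[[length(inter) + 1L]] <- cbind(
        data.frame(component = comp, outcome = outcome_name),
        reg$coefficients,
        r_squared = reg$r_squared, F_model = reg$F, df1 = reg$df1,
        df2 = reg$df2)
    }
    for (cond in NBACK_CONDITIONS) {
      a <- act[act$component == comp & act$condition == cond, ]
      a <- a[match(common, a$subject), ]
      acc <- behavior$by_condition
      acc <- acc[acc$condition == cond, ]
      acc <- acc[match(common, acc$subject), ]
      grp_cors <- list()
      for (g in levels(groups)) {
        ix <- groups == g
        per_cond[[length(per_cond) + 1L]] <- cbind(
          data.frame(component = comp, condition = cond, group = g,
                     outcome = "accuracy"),
          simple_regression(acc$accuracy[ix], a$activation[ix]))
        per_cond[[length(per_cond) + 1L]] <- cbind(
          data.frame(component = comp, condition = cond, group = g,
                     outcome = "median_rt"),
          simple_regression(acc$median_rt[ix], a$activation[ix]))
        grp_cors[[g]] <- list(rho = spearman_rho(a$activation[ix],
                                                 acc$accuracy[ix]),
                              n = sum(ix))
      }
      cc <- compare_correlations(grp_cors$young$rho, grp_cors$young$n,
                                 grp_cors$old$rho, grp_cors$old$n)
      cors[[length(cors) + 1L]] <- data.frame(
        component = comp, condition = cond,
        rho_young = cc$rho1, n_young = cc$n1,
        rho_old = cc$rho2, n_old = cc$n2, z = cc$z, p = cc$p)
    }
  }
  structure(list(anova = anova_res, ttests = tt,
                 interaction = do.call(rbind, inter),
                 per_condition = do.call(rbind, per_cond),
                 correlations = do.call(rbind, cors),
                 alpha = alpha, n_subjects = length(common)),
            class = "wm_report")
}

#' @export
print.wm_report <- function(x, ...) {
  if (is.null(x$anova)) {
    cat("working-memory report: empty (no components selected)\n")
    return(invisible(x))
  }
  cat("working-memory activation report over", x$n_subjects, "subjects\n\n")
  cat("Mixed ANOVA (component within, age between):\n")
  print(x$anova, digits = 3)
  ia <- x$anova[x$anova$effect == "group:component", ]
  cat(sprintf("\n  interaction: F(%d,%d) = %.2f, p = %.4g\n",
              ia$df1, ia$df2, ia$F, ia$p))
  cat("\nBetween-group correlation comparisons (accuracy vs activation):\n")
  print(x$correlations, digits = 3)
  invisible(x)
}
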