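#' Yeo-Johnson transform followed by z-scoring
#'
#' Normality correction used before every model fit: the Yeo-Johnson power
#' transform with lambda chosen by maximum likelihood
#' ([car::powerTransform()]), followed by standardization to mean 0 / SD 1
#' so the power transform's scale change does not bias coefficients across
#' variables.
#'
#' @param values Numeric vector (>= 3 finite values, non-constant).
#' @return Transformed, z-scored numeric vector with attribute `"lambda"`.
#' @export
yeo_johnson_z <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3L) {
    rlang::abort("Need at least 3 finite values.",
                 class = "ripsync_validation_error")
  }
  if (stats::sd(v) == 0) {
    rlang::abort("Constant input cannot be normalized.",
                 class = "ripsync_validation_error")
  }
  lambda <- tryCatch(
    as.numeric(car::powerTransform(v, family = "yjPower")$lambda),
    error = function(e) 1)
  tv <- car::yjPower(values, lambda)
  out <- (tv - mean(tv, na.rm = TRUE)) / stats::sd(tv, na.rm = TRUE)
  attr(out, "lambda") <- lambda
  out
}

#' Mixed-effects trial/division model on a decile table
#'
#' Fits the study's core model: a linear mixed model for one metric of the
#' long decile table, with categorical fixed effects for trial (reference
#' Baseline, i.e. the first trial level) and division (reference 1), an
#' optional set of metric covariates (the second modelling approach, e.g.
#' EMG amplitude/median frequency predicting RIP synchrony), and a random
#' intercept per subject capturing inter-participant variability. The
#' dependent variable and all covariates are Yeo-Johnson + z transformed
#' across the pooled sample before fitting. Estimation is by REML
#' ([lme4::lmer()]); per-term Wald z statistics and normal p-values are
#' reported together with the random-intercept variance.
#'
#' @param table Long decile table: tibble with columns `subject_id`,
#'   `trial`, `division`, `metric`, `value`.
#' @param dependent Metric name to model.
#' @param covariates Character vector of metric names entered as fixed
#'   covariates (default none).
#' @param reml Fit by REML (default) or ML.
#' @param transform Apply [yeo_johnson_z()] to dependent and covariates
#'   (default `TRUE`).
#' @return An object of class `tdm_fit` with `terms` (tibble `term`, `beta`,
#'   `z`, `p`), `random_intercept_variance`, `residual_variance`,
#'   `converged`, the fitted `lme4` model and the model frame.
#' @export
fit_trial_division_model <- function(table, dependent, covariates = character(),
                                     reml = TRUE, transform = TRUE) {
  wide <- decile_table_wide(table, c(dependent, covariates))
  if (length(unique(wide$subject_id)) < 2L) {
    rlang::abort("Mixed model needs at least 2 subjects.",
                 class = "ripsync_validation_error")
  }
  if (transform) {
    for (m in c(dependent, covariates)) wide[[m]] <- strip_attr(yeo_johnson_z(wide[[m]]))
  }
  # reference = first trial in protocol order (Baseline first by convention)
  lv <- unique(as.character(wide$trial))
  if ("Baseline" %in% lv) lv <- c("Baseline", setdiff(lv, "Baseline"))
  wide$trial <- factor(as.character(wide$trial), levels = lv)
  wide$division <- factor(wide$division, levels = sort(unique(wide$division)))
  rhs <- paste(c("trial", "division", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("`", dependent, "` ~ ", rhs, " + (1 | subject_id)"))
  fit <- lme4::lmer(fml, data = wide, REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  if (!conv) rlang::warn("Mixed model did not converge cleanly; partial result.")
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- co / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri <- vc$vcov[vc$grp == "subject_id"][1]
  structure(list(
    terms = tibble::tibble(term = names(co), beta = unname(co),
                           z = unname(z), p = unname(p)),
    random_intercept_variance = ri,
    residual_variance = vc$vcov[vc$grp == "Residual"][1],
    converged = conv, dependent = dependent, covariates = covariates,
    model = fit, data = wide),
    class = "tdm_fit")
}

strip_attr <- function(x) { attributes(x) <- NULL; x }

# Pivot the long decile table to one row per (subject, trial, division) with
# one column per requested metric, checking uniqueness.
decile_table_wide <- function(table, metrics) {
  need <- c("subject_id", "trial", "division", "metric", "value")
  if (!all(need %in% names(table))) {
    rlang::abort("Decile table needs columns subject_id, trial, division, metric, value.",
                 class = "ripsync_format_error")
  }
  miss <- setdiff(metrics, unique(table$metric))
  if (length(miss) > 0) {
    rlang::abort(sprintf("Metric(s) not in table: %s", paste(miss, collapse = ", ")),
                 class = "ripsync_format_error")
  }
  sub <- dplyr::filter(table, .data$metric %in% metrics)
  dup <- dplyr::count(sub, .data$subject_id, .data$trial, .data$division,
                      .data$metric) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort("Decile table has duplicate (subject, trial, division, metric) rows.",
                 class = "ripsync_validation_error")
  }
  tidyr::pivot_wider(sub, names_from = "metric", values_from = "value")
}

#' @export
print.tdm_fit <- function(x, ...) {
  cat(sprintf("<tdm_fit> %s ~ trial + division%s + (1 | subject)\n",
              x$dependent,
              if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = " + ")) else ""))
  print(x$terms, n = nrow(x$terms))
  cat(sprintf("Subject variation (random-intercept variance): %.4f\n",
              x$random_intercept_variance))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trial/division mixed-model fit
#'
#' @param x A `tdm_fit` from [fit_trial_division_model()].
#' @param ... Unused.
#' @return Tibble with `term`, `beta`, `z`, `p`.
#' @export
tidy.tdm_fit <- function(x, ...) x$terms

#' One-row summary of a trial/division mixed-model fit
#'
#' @param x A `tdm_fit`.
#' @param ... Unused.
#' @return Tibble with the dependent name, variances, convergence flag and
#'   number of observations.
#' @export
glance.tdm_fit <- function(x, ...) {
  tibble::tibble(dependent = x$dependent,
                 random_intercept_variance = x$random_intercept_variance,
                 residual_variance = x$residual_variance,
                 converged = x$converged,
                 nobs = nrow(x$data))
}

#' Residual assumption checks for a mixed-model fit
#'
#' Runs the three residual diagnostics used for model validation:
#' \describe{
#'   \item{independence}{Wald test on the lag-1 autocorrelation of the
#'     residuals (z = r1 * sqrt(n)).}
#'   \item{normality}{Shapiro–Wilk test.}
#'   \item{homoscedasticity}{White's Lagrange-multiplier test: squared
#'     residuals regressed on the model's fitted values and their squares,
#'     LM = n R^2 ~ chi^2(2).}
#' }
#'
#' @param fit A `tdm_fit`, or `NULL` when `residuals`/`fitted` are given
#'   directly.
#' @param residuals,fitted Optional numeric vectors overriding the fit's own.
#' @return Tibble with columns `check`, `statistic`, `p`, `computable`.
#' @export
residual_diagnostics <- function(fit = NULL, residuals = NULL, fitted = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "tdm_fit"))
    if (is.null(residuals)) residuals <- stats::residuals(fit$model)
    if (is.null(fitted)) fitted <- stats::fitted(fit$model)
  }
  r <- as.numeric(residuals)
  n <- length(r)
  row <- function(check, statistic, p, computable = TRUE) {
    tibble::tibble(check = check, statistic = statistic, p = p,
                   computable = computable)
  }
  # independence: Wald z on lag-1 autocorrelation
  indep <- if (n >= 10) {
    r1 <- stats::cor(r[-n], r[-1])
    z <- r1 * sqrt(n)
    row("independence_wald", z, 2 * stats::pnorm(-abs(z)))
  } else row("independence_wald", NA_real_, NA_real_, FALSE)
  norm <- if (n >= 3 && n <= 5000) {
    sw <- stats::shapiro.test(r)
    row("normality_shapiro", unname(sw$statistic), sw$p.value)
  } else if (n > 5000) {
    sw <- stats::shapiro.test(sample(r, 5000))
    row("normality_shapiro", unname(sw$statistic), sw$p.value)
  } else row("normality_shapiro", NA_real_, NA_real_, FALSE)
  het <- if (!is.null(fitted) && n >= 10 && stats::sd(fitted) > 0) {
    aux <- stats::lm(I(r^2) ~ fitted + I(fitted^2))
    lm_stat <- n * summary(aux)$r.squared
    row("homoscedasticity_white", lm_stat, stats::pchisq(lm_stat, 2, lower.tail = FALSE))
  } else row("homoscedasticity_white", NA_real_, NA_real_, FALSE)
  dplyr::bind_rows(indep, norm, het)
}

#' Pearson product-moment correlation
#'
#' @param a,b Numeric vectors of equal length (>= 3), non-constant.
#' @return Tibble with columns `r`, `p`, `n`.
#' @export
pearson_r <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) {
    rlang::abort("Need at least 3 paired finite values.",
                 class = "ripsync_validation_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("Zero-variance input to correlation.",
                 class = "ripsync_validation_error")
  }
  ct <- stats::cor.test(a, b)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' One-way repeated-measures ANOVA across trials
#'
#' One within-subject factor (trial) ANOVA on per-subject per-trial values,
#' with Mauchly's sphericity test, Greenhouse-Geisser-corrected degrees of
#' freedom and p-value when sphericity is rejected (at the 5% level),
#' partial eta squared, and Bonferroni-corrected paired t-tests for the
#' trial pairs (reported p = min(1, n_pairs * raw p)).
#'
#' @param per_subject_trial Tibble with columns `subject_id`, `trial`,
#'   `value` — one value per subject and trial, complete.
#' @param alpha Significance level for the sphericity decision (default
#'   0.05).
#' @return An object of class `rm_anova` with fields `F`, `df`, `p`,
#'   `partial_eta_sq`, `sphericity_ok`, `mauchly_p`, `gg_epsilon`,
#'   `correction`, and `pairwise` (tibble `pair`, `t`, `p_raw`,
#'   `p_bonferroni`).
#' @export
rm_anova <- function(per_subject_trial, alpha = 0.05) {
  need <- c("subject_id", "trial", "value")
  if (!all(need %in% names(per_subject_trial))) {
    rlang::abort("Need columns subject_id, trial, value.",
                 class = "ripsync_format_error")
  }
  wide <- tidyr::pivot_wider(per_subject_trial, names_from = "trial",
                             values_from = "value")
  if (anyNA(wide)) {
    rlang::abort("Incomplete subject x trial table.",
                 class = "ripsync_validation_error")
  }
  trials <- setdiff(names(wide), "subject_id")
  k <- length(trials)
  n <- nrow(wide)
  Y <- as.matrix(wide[trials])
  # sums of squares of the one-way within-subject decomposition
  grand <- mean(Y)
  ss_trial <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_trial - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  degenerate <- ss_trial <= 1e-12 * max(ss_tot, 1)
  if (degenerate && ss_err <= 1e-12 * max(ss_tot, 1)) {
    Fv <- 0; p <- 1
  } else {
    Fv <- (ss_trial / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  peta <- if (ss_trial + ss_err <= 0) 0 else ss_trial / (ss_trial + ss_err)
  # sphericity via Mauchly / GG epsilon on the covariance of the trials
  mauchly_p <- NA_real_; eps <- 1
  if (k > 2 && ss_err > 1e-12 * max(ss_tot, 1)) {
    mlm <- stats::lm(Y ~ 1)
    idata <- data.frame(trial = factor(trials, levels = trials))
    av <- car::Anova(mlm, idata = idata, idesign = ~trial, type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    sph <- s$sphericity.tests
    mauchly_p <- unname(sph[1, "p-value"])
    eps <- unname(s$pval.adjustments[1, "GG eps"])
  }
  sphericity_ok <- is.na(mauchly_p) || mauchly_p >= alpha
  correction <- "none"
  df <- c(df1, df2)
  if (!sphericity_ok) {
    correction <- "greenhouse_geisser"
    df <- c(df1 * eps, df2 * eps)
    p <- stats::pf(Fv, df[1], df[2], lower.tail = FALSE)
  }
  pairs <- utils::combn(trials, 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    d <- Y[, pr[1]] - Y[, pr[2]]
    if (stats::sd(d) == 0) {
      tibble::tibble(pair = paste(pr, collapse = " vs "), t = 0, p_raw = 1,
                     p_bonferroni = 1)
    } else {
      tt <- stats::t.test(Y[, pr[1]], Y[, pr[2]], paired = TRUE)
      tibble::tibble(pair = paste(pr, collapse = " vs "),
                     t = unname(tt$statistic), p_raw = tt$p.value,
                     p_bonferroni = min(1, length(pairs) * tt$p.value))
    }
  })
  structure(list(F = Fv, df = df, p = p, partial_eta_sq = peta,
                 sphericity_ok = sphericity_ok, mauchly_p = mauchly_p,
                 gg_epsilon = eps, correction = correction, pairwise = pw,
                 n_subjects = n, trials = trials),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%.3f, %.3f) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$partial_eta_sq))
  cat(sprintf("Sphericity %s (Mauchly p = %s); correction: %s\n",
              if (x$sphericity_ok) "ok" else "violated",
              format(x$mauchly_p, digits = 3), x$correction))
  print(x$pairwise)
  invisible(x)
}

#' @rdname tidy.tdm_fit
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(term = "trial", F = x$F, df1 = x$df[1], df2 = x$df[2],
                 p = x$p, partial_eta_sq = x$partial_eta_sq,
                 correction = x$correction)
}

#' @rdname glance.tdm_fit
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_trials = length(x$trials),
                 sphericity_ok = x$sphericity_ok, mauchly_p = x$mauchly_p,
                 gg_epsilon = x$gg_epsilon)
}
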