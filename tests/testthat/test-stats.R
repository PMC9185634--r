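test_that("Yeo-Johnson + z-scoring standardizes and de-skews", {
  set.seed(51)
  v <- rlnorm(300)
  z <- yeo_johnson_z(v)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  sk <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_lt(abs(sk(z)), abs(sk(v)))
  # near-normal input: transform is essentially an affine rescale
  vn <- rnorm(400)
  zn <- yeo_johnson_z(vn)
  expect_gt(stats::cor(zn, scale(vn)[, 1]), 0.999)
  expect_error(yeo_johnson_z(rep(1, 10)), class = "ripsync_validation_error")
  expect_error(yeo_johnson_z(c(1, 2)), class = "ripsync_validation_error")
})

test_that("mixed model recovers imposed trial effects with Table-1-like variances", {
  set.seed(52)
  hits <- replicate(20, {
    tbl <- simulate_decile_table(
      22, c(Baseline = 0, `Fatigue 1` = -0.36, `Fatigue 2` = -0.35),
      subject_sd = 0.8, sigma = 0.55)
    f <- fit_trial_division_model(tbl, "metric", transform = FALSE)
    tt <- f$terms[grepl("^trial", f$terms$term), ]
    all(abs(tt$beta - c(-0.36, -0.35)) < 0.1) && all(tt$p < 0.05)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("with zero between-subject variance the mixed fit matches OLS", {
  set.seed(53)
  tbl <- simulate_decile_table(12, c(A = 0, B = 0.4, C = 0.1),
                               subject_sd = 0, sigma = 1)
  f <- fit_trial_division_model(tbl, "metric", transform = FALSE, reml = FALSE)
  wide <- tidyr::pivot_wider(tbl, names_from = "metric", values_from = "value")
  wide$trial <- factor(wide$trial)
  wide$division <- factor(wide$division)
  ols <- stats::lm(metric ~ trial + division, data = wide)
  expect_equal(unname(f$terms$beta), unname(stats::coef(ols)), tolerance = 1e-4)
})

test_that("fixed effects transform exactly under affine rescaling of the dependent", {
  set.seed(54)
  tbl <- simulate_decile_table(8, c(A = 0, B = 0.5, C = 0.2))
  f1 <- fit_trial_division_model(tbl, "metric", transform = FALSE)
  tbl2 <- dplyr::mutate(tbl, value = 3 * .data$value + 10)
  f2 <- fit_trial_division_model(tbl2, "metric", transform = FALSE)
  expect_equal(f2$terms$beta[-1], 3 * f1$terms$beta[-1], tolerance = 1e-6)
  expect_equal(f2$terms$z[-1], f1$terms$z[-1], tolerance = 1e-6)
})

test_that("a covariate built to mediate the trial effect attenuates it", {
  set.seed(55)
  base <- simulate_decile_table(16, c(A = 0, B = 0, C = 0), sigma = 0.3,
                                metric = "mediator")
  med <- dplyr::mutate(base, value = .data$value +
                         c(A = 0, B = 1, C = 1)[.data$trial])
  dep <- dplyr::mutate(med, metric = "dep",
                       value = 0.8 * .data$value + rnorm(dplyr::n(), 0, 0.3))
  tbl <- dplyr::bind_rows(med, dep)
  f_plain <- fit_trial_division_model(tbl, "dep", transform = FALSE)
  f_med <- fit_trial_division_model(tbl, "dep", covariates = "mediator",
                                    transform = FALSE)
  b_plain <- f_plain$terms$beta[f_plain$terms$term == "trialB"]
  b_med <- f_med$terms$beta[f_med$terms$term == "trialB"]
  expect_lt(abs(b_med), abs(b_plain))
})

test_that("mixed modelling refuses single-subject tables and duplicate cells", {
  tbl <- simulate_decile_table(1)
  expect_error(fit_trial_division_model(tbl, "metric"),
               class = "ripsync_validation_error")
  tbl2 <- simulate_decile_table(3)
  expect_error(fit_trial_division_model(dplyr::bind_rows(tbl2, tbl2[1, ]),
                                        "metric"),
               class = "ripsync_validation_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(56)
  tbl <- simulate_decile_table(6)
  f <- fit_trial_division_model(tbl, "metric", transform = FALSE)
  td <- tidy(f)
  expect_named(td, c("term", "beta", "z", "p"))
  expect_identical(nrow(td), 12L)        # intercept + 2 trials + 9 divisions
  gl <- glance(f)
  expect_true(gl$random_intercept_variance >= 0)
  expect_identical(gl$nobs, 180L)
})

test_that("residual diagnostics detect heteroscedasticity and pass clean residuals", {
  set.seed(57)
  n <- 600
  x <- rnorm(n)
  het_hits <- replicate(20, {
    e <- rnorm(n, 0, sqrt(exp(1 + 1.2 * x)))
    d <- residual_diagnostics(residuals = e, fitted = x)
    d$p[d$check == "homoscedasticity_white"] < 0.05
  })
  expect_gte(mean(het_hits), 0.8)
  clean <- residual_diagnostics(residuals = rnorm(500), fitted = rnorm(500))
  expect_identical(nrow(clean), 3L)
  expect_true(all(clean$computable))
  tiny <- residual_diagnostics(residuals = rnorm(5), fitted = rnorm(5))
  expect_false(all(tiny$computable))
})

test_that("Shapiro-Wilk p-values are uniform under normal residuals", {
  set.seed(58)
  ps <- replicate(200, {
    d <- residual_diagnostics(residuals = rnorm(120), fitted = rnorm(120))
    d$p[d$check == "normality_shapiro"]
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Pearson correlation matches closed forms and sampling bounds", {
  a <- rnorm(50)
  expect_equal(pearson_r(a, 2 * a + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(a, -a)$r, -1, tolerance = 1e-12)
  set.seed(59)
  ind <- pearson_r(rnorm(10000), rnorm(10000))
  expect_lt(abs(ind$r), 0.03)
  expect_error(pearson_r(a, rep(1, 50)), class = "ripsync_validation_error")
  expect_error(pearson_r(1:2, 1:2), class = "ripsync_validation_error")
})

test_that("repeated-measures ANOVA handles degenerate and two-trial designs", {
  # identical values across trials: F = 0, p = 1
  t1 <- tidyr::expand_grid(subject_id = letters[1:10], trial = c("A", "B", "C"))
  t1$value <- rep(rnorm(10), each = 3)
  a <- rm_anova(t1)
  expect_identical(a$F, 0)
  expect_identical(a$p, 1)
  # two trials: F equals the squared paired t statistic
  set.seed(60)
  t2 <- tidyr::expand_grid(subject_id = letters[1:12], trial = c("A", "B"))
  t2$value <- rnorm(24)
  a2 <- rm_anova(t2)
  w <- tidyr::pivot_wider(t2, names_from = "trial", values_from = "value")
  tt <- stats::t.test(w$A, w$B, paired = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_error(rm_anova(t2[-1, ]), class = "ripsync_validation_error")
})

test_that("RM-ANOVA applies Greenhouse-Geisser when sphericity fails and Bonferroni pairwise", {
  set.seed(61)
  n <- 18
  # strongly non-spherical covariance: third condition much noisier
  vals <- cbind(rnorm(n, 0, 0.1), rnorm(n, 0.1, 0.1), rnorm(n, 0.6, 1.5))
  tb <- tibble::tibble(subject_id = rep(sprintf("s%02d", 1:n), 3),
                       trial = rep(c("A", "B", "C"), each = n),
                       value = c(vals))
  a <- rm_anova(tb)
  expect_identical(nrow(a$pairwise), 3L)
  expect_equal(a$pairwise$p_bonferroni,
               pmin(1, 3 * a$pairwise$p_raw), tolerance = 1e-12)
  expect_true(a$partial_eta_sq >= 0 && a$partial_eta_sq <= 1)
  if (!a$sphericity_ok) {
    expect_identical(a$correction, "greenhouse_geisser")
    expect_lte(a$df[1], 2)
    expect_lt(a$gg_epsilon, 1)
  }
  td <- tidy(a)
  expect_named(td, c("term", "F", "df1", "df2", "p", "partial_eta_sq",
                     "correction"))
})

test_that("RM-ANOVA empirical power matches the noncentral-F closed form", {
  set.seed(62)
  n <- 12; k <- 3
  eff <- c(0, 0.5, 0.5)                 # trial means, compound symmetry
  sigma <- 1
  # closed-form: lambda = n * sum((mu - mean(mu))^2) / sigma^2
  lambda <- n * sum((eff - mean(eff))^2) / sigma^2
  fcrit <- stats::qf(0.95, k - 1, (k - 1) * (n - 1))
  power_cf <- 1 - stats::pf(fcrit, k - 1, (k - 1) * (n - 1), ncp = lambda)
  hits <- replicate(150, {
    subj <- rnorm(n, 0, 0.8)
    Y <- outer(subj, rep(1, k)) + outer(rep(1, n), eff) +
      matrix(rnorm(n * k, 0, sigma), n, k)
    tb <- tibble::tibble(subject_id = rep(sprintf("s%02d", 1:n), k),
                         trial = rep(c("A", "B", "C"), each = n),
                         value = c(Y))
    a <- rm_anova(tb)
    a$p < 0.05
  })
  se <- sqrt(power_cf * (1 - power_cf) / 150)
  expect_lt(abs(mean(hits) - power_cf), 3 * se + 0.02)
})
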