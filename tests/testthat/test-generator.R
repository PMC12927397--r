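test_that("confounder sampling honours the configured marginals", {
  cfg <- generator_config(n = 100000)
  set.seed(71)
  C <- sample_confounders(cfg)
  # female share: 3 binomial SEs around the configured 65.3%
  se <- sqrt(0.653 * 0.347 / nrow(C))
  expect_lt(abs(mean(C$sex == 0) - 0.653), 3 * se)
  expect_true(all(C$age >= 23 & C$age <= 64))
  expect_true(all(C$social_support_quality %in% 1:3))
  expect_lt(abs(mean(C$social_support_quality) - 2.10), 0.02)
  # degenerate proportion -> constant column; n = 0 -> empty table
  cfg1 <- generator_config(n = 50, confounders = list(education = 1.0))
  set.seed(72)
  expect_true(all(sample_confounders(cfg1)$education == 1))
  expect_identical(nrow(sample_confounders(cfg, n = 0)), 0L)
  expect_error(generator_config(confounders = list(sex_male = 1.2)),
               "outside \\[0, 1\\]")
})

test_that("exposure assignment reduces to uniform under null coefficients", {
  cfg <- generator_config(
    n = 40000,
    exposure = list(intercepts = c(0, 0, 0),
                    coefficients = matrix(0, 3, 8))
  )
  set.seed(73)
  C <- sample_confounders(cfg)
  z <- assign_exposure(C, cfg)
  se <- sqrt(0.25 * 0.75 / cfg$n)
  for (lev in 0:3) expect_lt(abs(mean(z == lev) - 0.25), 3 * se)
})

test_that("exposure prevalence is monotone in a strongly weighted confounder", {
  cfg <- generator_config(n = 30000)
  set.seed(74)
  C <- sample_confounders(cfg)
  z <- assign_exposure(C, cfg)
  # education has a large positive weight for weekly telework
  expect_gt(mean(z[C$education == 1] == 2), mean(z[C$education == 0] == 2))
  # single respondent, fixed seed -> reproducible level
  set.seed(75); z1 <- assign_exposure(C[1, , drop = FALSE], cfg)
  set.seed(75); z2 <- assign_exposure(C[1, , drop = FALSE], cfg)
  expect_identical(z1, z2)
})

test_that("the mediator model run forward is recovered by regression", {
  cfg <- generator_config(n = 5000)
  set.seed(76)
  C <- sample_confounders(cfg)
  z <- assign_exposure(C, cfg)
  M <- generate_mediators(z, C, cfg)
  d <- cbind(data.frame(z = z, A1 = as.integer(z == 1), A2 = as.integer(z == 2),
                        A3 = as.integer(z == 3)), M, C)
  f <- stats::as.formula(paste("emotional_load ~ A1 + A2 + A3 +",
                               paste(confounder_names(), collapse = " + ")))
  fit <- summary(stats::lm(f, data = d))$coefficients
  truth <- cfg$mediators$theta1[, "emotional_load"]
  for (zi in 1:3) {
    a <- c("A1", "A2", "A3")[zi]
    expect_lt(abs(fit[a, "Estimate"] - truth[zi]), 3 * fit[a, "Std. Error"])
  }
})

test_that("zero-noise mediators are the exact linear predictor", {
  cfg <- generator_config(
    n = 200,
    mediators = list(theta2 = matrix(0, 8, 6),
                     sigma = rep(0, 6))
  )
  set.seed(77)
  C <- sample_confounders(cfg)
  z <- assign_exposure(C, cfg)
  M <- generate_mediators(z, C, cfg)
  for (zi in 0:3) {
    expected <- cfg$mediators$theta0["autonomy"] +
      if (zi == 0) 0 else cfg$mediators$theta1[zi, "autonomy"]
    expect_equal(unique(M$autonomy[z == zi]), unname(expected),
                 tolerance = 1e-12)
  }
  # all-null structural model -> all-zero mediators
  cfg0 <- generator_config(
    n = 50,
    mediators = list(theta0 = rep(0, 6), theta1 = matrix(0, 3, 6),
                     theta2 = matrix(0, 8, 6), sigma = rep(0, 6))
  )
  set.seed(78)
  C0 <- sample_confounders(cfg0)
  M0 <- generate_mediators(assign_exposure(C0, cfg0), C0, cfg0)
  expect_true(all(as.matrix(M0) == 0))
})

test_that("binary outcomes follow the clipped linear probability model", {
  # intercept-only model: prevalence matches the intercept
  cfg <- generator_config(
    n = 50000,
    mediators = list(theta1 = matrix(0, 3, 6)),
    outcomes = list(anxiety = list(beta0 = 0.10, beta1 = c(0, 0, 0),
                                   beta2 = rep(0, 6), beta3 = rep(0, 8)))
  )
  set.seed(79)
  C <- sample_confounders(cfg)
  z <- assign_exposure(C, cfg)
  M <- generate_mediators(z, C, cfg)
  Y <- generate_outcomes(z, M, C, cfg)
  se <- sqrt(0.1 * 0.9 / cfg$n)
  expect_lt(abs(mean(Y$anxiety) - 0.10), 3 * se)

  # a predictor beyond the bounds is clipped and counted
  cfg_clip <- generator_config(
    n = 1,
    outcomes = list(anxiety = list(beta0 = 1.5, beta1 = c(0, 0, 0),
                                   beta2 = rep(0, 6), beta3 = rep(0, 8)),
                    depression = list(beta0 = 0.5, beta1 = c(0, 0, 0),
                                      beta2 = rep(0, 6), beta3 = rep(0, 8))),
    clip_ceiling = 0.9
  )
  set.seed(80)
  C1 <- sample_confounders(cfg_clip)
  z1 <- assign_exposure(C1, cfg_clip)
  M1 <- generate_mediators(z1, C1, cfg_clip)
  Y1 <- generate_outcomes(z1, M1, C1, cfg_clip)
  expect_identical(unname(attr(Y1, "clip_counts")["anxiety"]), 1L)
  expect_identical(unname(attr(Y1, "clip_counts")["depression"]), 0L)
  # with the default ceiling the same configuration is an error
  cfg_bad <- generator_config(
    n = 100,
    outcomes = list(anxiety = list(beta0 = 1.5, beta1 = c(0, 0, 0),
                                   beta2 = rep(0, 6), beta3 = rep(0, 8)))
  )
  set.seed(81)
  C2 <- sample_confounders(cfg_bad)
  z2 <- assign_exposure(C2, cfg_bad)
  M2 <- generate_mediators(z2, C2, cfg_bad)
  expect_error(generate_outcomes(z2, M2, C2, cfg_bad), "clipping rate")
})

test_that("a noiseless continuous outcome reproduces beta exactly on refit", {
  cfg <- generator_config(
    n = 400,
    outcomes = list(burnout = list(sigma = 0))
  )
  rows <- simulate_analysis_rows(cfg, seed = 82)
  fits <- fit_path_models(rows, outcomes = "burnout")
  oc <- cfg$outcomes$burnout
  expect_equal(unname(fits$beta$burnout[c("A1", "A2", "A3")]),
               unname(oc$beta1), tolerance = 1e-8)
  expect_equal(unname(fits$beta$burnout[mediator_names()]),
               unname(oc$beta2), tolerance = 1e-8)
  expect_equal(unname(fits$beta$burnout[confounder_names()]),
               unname(oc$beta3), tolerance = 1e-8)
})

test_that("the closed-form truth table obeys the product and sum rules", {
  th1 <- matrix(0, 3, 6); th1[1, 1] <- 0.3
  cfg <- generator_config(
    n = 10,
    mediators = list(theta1 = th1),
    outcomes = list(burnout = list(beta1 = c(0.2, 0, 0),
                                   beta2 = c(0.5, 0, 0, 0, 0, 0)))
  )
  tr <- true_effect_table(cfg)
  mb <- tr[tr$outcome == "burnout" & tr$contrast == "monthly", ]
  expect_equal(mb$truth[mb$effect_type == "indirect:workload"], 0.15)
  expect_equal(mb$truth[mb$effect_type == "joint_indirect"], 0.15)
  expect_equal(mb$truth[mb$effect_type == "direct"], 0.2)
  expect_equal(mb$truth[mb$effect_type == "total"], 0.35)
  expect_false(attr(tr, "approximate"))
  expect_true(attr(true_effect_table(cfg, clip_rate = 0.01), "approximate"))
  # all-null configuration -> all effects zero
  cfg0 <- generator_config(
    n = 10,
    mediators = list(theta1 = matrix(0, 3, 6)),
    outcomes = list(
      anxiety = list(beta1 = c(0, 0, 0), beta2 = rep(0, 6)),
      depression = list(beta1 = c(0, 0, 0), beta2 = rep(0, 6)),
      burnout = list(beta1 = c(0, 0, 0), beta2 = rep(0, 6)),
      work_engagement = list(beta1 = c(0, 0, 0), beta2 = rep(0, 6))
    )
  )
  expect_true(all(true_effect_table(cfg0)$truth == 0))
})

test_that("emitted item responses reproduce the generated scores exactly", {
  cfg <- generator_config(n = 250)
  path <- withr::local_tempfile(fileext = ".csv")
  simulate_survey(cfg, path, seed = 83)
  rows <- build_analysis_rows(read_survey_table(path), sensitivity = TRUE)
  scales <- default_scale_definitions()
  # mediator scores: regenerate the structural draws and snap to the grid
  set.seed(83)
  C <- sample_confounders(cfg)
  z <- assign_exposure(C, cfg)
  M <- generate_mediators(z, C, cfg)
  for (m in mediator_names()) {
    k <- scales[[m]]$item_count
    snapped <- pmin(pmax(round(M[[m]] * k), k), 5 * k) / k
    expect_identical(rows[[m]], snapped)
  }
  # scale means live on the attainable grid and within the response range
  expect_true(all(rows$burnout >= 1 & rows$burnout <= 5))
  expect_true(all(abs(rows$burnout * 12 - round(rows$burnout * 12)) < 1e-9))
  # binary outcomes match the dichotomisation of the emitted items
  expect_identical(rows$anxiety, as.integer(rows$anxiety_score >= 10))
  expect_identical(rows$depression, as.integer(rows$depression_score >= 10))
})

test_that("a uniform missingness rate feeds the complete-case filter", {
  cfg <- generator_config(n = 300, missing_rate = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  simulate_survey(cfg, path, seed = 84)
  rows <- build_analysis_rows(read_survey_table(path))
  kept <- complete_case_filter(rows)
  expect_lt(nrow(kept), 300L)
  expect_identical(nrow(kept) + attr(kept, "n_dropped"), 300L)
  expect_false(anyNA(kept[, c("z", mediator_names(), "burnout")]))
})

test_that("generator configs reject structural nonsense", {
  expect_error(generator_config(n = -5), "nonnegative")
  expect_error(generator_config(mediators = list(sigma = rep(-1, 6))), "sigma")
  expect_error(generator_config(clip = c(0.5, 0.4)), "clip")
  expect_error(generator_config(mediators = list(theta1 = matrix(0, 2, 6))),
               "3 x 6")
  expect_error(generator_config(frobnicate = 1), "unknown component")
})

test_that("generator configs round-trip through a YAML document", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n: 42",
    "missing_rate: 0.05",
    "confounders:",
    "  sex_male: 0.5",
    "mediators:",
    "  theta1:",
    paste0("    - [", paste(rep("0.1", 6), collapse = ", "), "]"),
    paste0("    - [", paste(rep("0.2", 6), collapse = ", "), "]"),
    paste0("    - [", paste(rep("0.0", 6), collapse = ", "), "]")
  ), path)
  cfg <- read_generator_config(path)
  expect_identical(cfg$n, 42L)
  expect_equal(cfg$confounders$sex_male, 0.5)
  expect_equal(unname(cfg$mediators$theta1["weekly", ]), rep(0.2, 6))
  expect_equal(cfg$missing_rate, 0.05)
})
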