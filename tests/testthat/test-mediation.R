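test_that("indirect effects are the product of the two path coefficients", {
  th1 <- matrix(0, 3, 1, dimnames = list(NULL, "m1"))
  th1[2, 1] <- 0.5   # weekly exposure -> mediator coefficient
  fits <- fake_fits(delta1 = c(0, 0.5 * 0.4, 0), direct = c(0, 0, 0),
                    theta1 = th1, beta2 = c(m1 = 0.4))
  eff <- decompose_effects(fits)
  weekly <- eff[eff$contrast == "weekly", ]
  expect_equal(weekly$estimate[weekly$effect_type == "indirect:m1"], 0.20)
  expect_equal(weekly$estimate[weekly$effect_type == "joint_indirect"], 0.20)
})

test_that("the printed direct and joint indirect compose to the printed total", {
  # weekly telework on burnout: direct 0.1339, joint indirect -0.1241,
  # total 0.0098 by the decomposition identity
  th1 <- matrix(c(0, -0.1241, 0), 3, 1, dimnames = list(NULL, "m1"))
  fits <- fake_fits(delta1 = c(0, 0.0098, 0), direct = c(0, 0.1339, 0),
                    theta1 = th1, beta2 = c(m1 = 1))
  eff <- decompose_effects(fits)
  weekly <- eff[eff$contrast == "weekly", ]
  total <- weekly$estimate[weekly$effect_type == "total"]
  expect_equal(weekly$estimate[weekly$effect_type == "direct"] +
                 weekly$estimate[weekly$effect_type == "joint_indirect"],
               total, tolerance = 1e-12)
  expect_equal(total, 0.0098)
  expect_lt(max(abs(weekly$identity_gap)), 1e-12)
})

test_that("null mediation collapses the total onto the direct effect", {
  th1 <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("m1", "m2")))
  fits <- fake_fits(delta1 = c(0.1, 0.2, 0.3), direct = c(0.1, 0.2, 0.3),
                    theta1 = th1, beta2 = c(m1 = 0, m2 = 0))
  eff <- decompose_effects(fits)
  expect_true(all(eff$estimate[eff$effect_type == "joint_indirect"] == 0))
  expect_equal(eff$estimate[eff$effect_type == "total"],
               eff$estimate[eff$effect_type == "direct"])
})

test_that("fitted decompositions satisfy the OVB identity on generated data", {
  for (seed in c(1, 2, 3)) {
    rows <- small_rows(n = 400, seed = seed)
    fits <- fit_path_models(rows)
    chk <- verify_decomposition_identity(fits, tolerance = 1e-8)
    expect_true(chk$pass)
    expect_lt(chk$max_gap, 1e-10)
  }
})

test_that("the identity check fails for fits computed on different rows", {
  rows <- small_rows(n = 600, seed = 7)
  f1 <- fit_path_models(rows[1:300, ], outcomes = "burnout")
  f2 <- fit_path_models(rows[301:600, ], outcomes = "burnout")
  mixed <- f1
  mixed$delta <- f2$delta   # total model from a different row subset
  expect_error(verify_decomposition_identity(mixed, tolerance = 1e-8),
               "identity violated")
})

test_that("a saturated outcome fit (n = p) passes with zero gap", {
  # 7 rows, 7 columns in the outcome design (intercept, 3 dummies, 1
  # mediator, 2 confounders): exact interpolation, identity still holds
  set.seed(31)
  z <- c(0L, 0L, 1L, 1L, 2L, 2L, 3L)
  sub <- data.frame(z = z, A1 = as.integer(z == 1), A2 = as.integer(z == 2),
                    A3 = as.integer(z == 3),
                    workload = rnorm(7, 3), burnout = rnorm(7, 2),
                    sex = c(0, 1, 0, 1, 0, 1, 0), age = c(25, 40, 33, 51, 47, 29, 60))
  fits <- fit_path_models(sub, outcomes = "burnout", mediators = "workload",
                          confounders = c("sex", "age"))
  chk <- verify_decomposition_identity(fits, tolerance = 1e-8)
  expect_true(chk$pass)
})

test_that("mediator relabeling permutes indirects and fixes the aggregates", {
  rows <- small_rows(n = 500, seed = 19)
  perm <- c("autonomy", "workload", "skills_use", "emotional_load",
            "social_support", "role_conflict")
  e1 <- decompose_effects(fit_path_models(rows, outcomes = "work_engagement"))
  e2 <- decompose_effects(fit_path_models(rows, outcomes = "work_engagement",
                                          mediators = perm))
  for (eff_type in c("total", "direct", "joint_indirect")) {
    expect_equal(e1$estimate[e1$effect_type == eff_type],
                 e2$estimate[e2$effect_type == eff_type], tolerance = 1e-10)
  }
  for (m in perm) {
    key <- paste0("indirect:", m)
    expect_equal(e1$estimate[e1$effect_type == key & e1$contrast == "weekly"],
                 e2$estimate[e2$effect_type == key & e2$contrast == "weekly"],
                 tolerance = 1e-12)
  }
})

test_that("confounder location shifts change intercepts only", {
  rows <- small_rows(n = 500, seed = 23)
  shifted <- rows
  shifted$age <- shifted$age + 100
  shifted$social_support_quality <- shifted$social_support_quality - 7
  e1 <- decompose_effects(fit_path_models(rows))
  e2 <- decompose_effects(fit_path_models(shifted))
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
})

test_that("risk differences scale exactly with the 0/1 outcome coding", {
  rows <- small_rows(n = 500, seed = 29)
  pct <- rows
  pct$anxiety <- 100 * pct$anxiety
  e1 <- decompose_effects(fit_path_models(rows, outcomes = "anxiety"))
  e2 <- decompose_effects(fit_path_models(pct, outcomes = "anxiety"))
  expect_equal(100 * e1$estimate, e2$estimate, tolerance = 1e-9)
})

test_that("an empty exposure level is an estimability error naming the level", {
  rows <- small_rows(n = 400, seed = 37)
  nodaily <- rows[rows$z != 3L, ]
  expect_error(fit_path_models(nodaily), "level 3")
  expect_error(fit_path_models(rows[0, ]), "no rows")
})

test_that("null exposure coefficients are recovered as null within 3 SE", {
  cfg <- generator_config(
    n = 5000,
    mediators = list(theta1 = matrix(0, 3, 6)),
    outcomes = list(burnout = list(beta1 = c(0, 0, 0)))
  )
  rows <- simulate_analysis_rows(cfg, seed = 41)
  fits <- fit_path_models(rows, outcomes = "burnout")
  # model-based SEs from the same regressions, fitted independently via lm
  confs <- paste(confounder_names(), collapse = " + ")
  lm_tot <- stats::lm(stats::as.formula(
    paste("burnout ~ A1 + A2 + A3 +", confs)), data = rows)
  se <- summary(lm_tot)$coefficients[c("A1", "A2", "A3"), "Std. Error"]
  expect_true(all(abs(fits$delta$burnout[c("A1", "A2", "A3")]) < 3 * se))
  lm_med <- stats::lm(stats::as.formula(
    paste("workload ~ A1 + A2 + A3 +", confs)), data = rows)
  se_m <- summary(lm_med)$coefficients[c("A1", "A2", "A3"), "Std. Error"]
  expect_true(all(abs(fits$theta$workload[c("A1", "A2", "A3")]) < 3 * se_m))
})

test_that("fitted coefficients agree with lm on the same specification", {
  rows <- small_rows(n = 400, seed = 43)
  fits <- fit_path_models(rows, outcomes = "work_engagement")
  f <- stats::as.formula(paste(
    "work_engagement ~ A1 + A2 + A3 +",
    paste(mediator_names(), collapse = " + "), "+",
    paste(confounder_names(), collapse = " + ")))
  ref <- stats::coef(stats::lm(f, data = rows))
  got <- fits$beta$work_engagement
  expect_equal(unname(got[-1]), unname(ref[-1]), tolerance = 1e-10)
})
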