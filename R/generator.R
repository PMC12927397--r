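# Synthetic-data generator: survey-like populations with known structural
# parameters, so every interventional estimand has a closed-form ground
# truth. Confounders are drawn from configured marginals, exposure from a
# multinomial logit on the confounders (inducing confounding), mediators
# from the linear mediator model run forward, and outcomes from the linear
# (probability) outcome model run forward.

.gc_mediators <- function() mediator_names()
.gc_confounders <- function() confounder_names()

.named_vec <- function(x, nms, what) {
  x <- unlist(x)
  if (length(x) != length(nms)) {
    stop(sprintf("generator config: %s must have length %d", what, length(nms)))
  }
  stats::setNames(as.numeric(x), nms)
}

.named_mat <- function(x, rnms, cnms, what) {
  m <- as.matrix(x)
  if (nrow(m) != length(rnms) || ncol(m) != length(cnms)) {
    stop(sprintf("generator config: %s must be %d x %d", what,
                 length(rnms), length(cnms)))
  }
  dimnames(m) <- list(rnms, cnms)
  apply(m, c(1, 2), as.numeric)
}

#' Synthetic-population configuration
#'
#' Assembles and validates the structural parameters of a synthetic survey
#' population. Defaults reproduce the analysed sample's marginals (65.3%
#' female, 83.6% bachelor+, 94.4% permanent contract, 66.4% chronic illness,
#' 79.6% functional limitation, 39.3% high work skill, social-support
#' quality with mean 2.10 / SD 0.70, age uniform on 23-64), a multinomial
#' logit exposure model calibrated to the observed telework shares
#' (~37/10/50/3%), and effect magnitudes of the order reported for this
#' design (direct effects ~0.1-0.2 on the continuous outcomes, per-mediator
#' indirect effects ~0.01-0.05). Binary outcomes follow a linear probability
#' model with clipping to `clip`; default coefficients keep the expected
#' clipping rate well below `clip_ceiling`. The defaults describe the
#' analysed complete-case sample, not the source population.
#'
#' @param n number of respondents.
#' @param ... overrides for any top-level component (`confounders`,
#'   `exposure`, `mediators`, `outcomes`, `clip`, `clip_ceiling`,
#'   `emit_items`, `missing_rate`); supplied sub-lists are merged over the
#'   defaults.
#' @return A validated object of class `"generator_config"`.
#' @export
generator_config <- function(n = 2323, ...) {
  med <- .gc_mediators(); conf <- .gc_confounders()
  defaults <- list(
    confounders = list(
      sex_male = 0.347, education = 0.836, contract = 0.944,
      chronic_illness = 0.664, functional_limitation = 0.796,
      work_skill_high = 0.393,
      social_support_quality_probs = c(0.20, 0.50, 0.30),
      age_range = c(23L, 64L)
    ),
    exposure = list(
      intercepts = c(monthly = -2.64, weekly = -1.38, daily = -4.17),
      coefficients = rbind(
        monthly = c(sex = 0.1, age = 0.000, education = 1.0, contract = 0,
                    chronic_illness = 0, functional_limitation = 0,
                    social_support_quality = 0.1, work_skill = 0.8),
        weekly  = c(0.2, 0.005, 1.2, 0, 0, 0, 0.0, 1.0),
        daily   = c(0.3, 0.020, 1.0, 0, 0, 0, -0.2, 0.8)
      )
    ),
    mediators = list(
      theta0 = c(workload = 3.1, emotional_load = 2.6, role_conflict = 2.3,
                 autonomy = 3.4, social_support = 3.6, skills_use = 3.5),
      theta1 = rbind(
        monthly = c(-0.05, -0.10, -0.05, 0.10, -0.05, 0.02),
        weekly  = c(-0.08, -0.20, -0.15, 0.18, -0.12, 0.05),
        daily   = c(-0.05, -0.25, -0.15, 0.25, -0.20, 0.05)
      ),
      theta2 = rbind(
        sex                    = c(0.05, -0.08, 0.04, 0.03, 0.00, 0.02),
        age                    = c(-0.003, 0.002, -0.002, 0.003, -0.002, -0.003),
        education              = c(0.10, 0.12, 0.05, 0.08, 0.02, 0.15),
        contract               = c(0.05, 0.00, 0.03, 0.05, 0.02, 0.05),
        chronic_illness        = c(0.04, 0.05, 0.05, -0.03, -0.02, -0.02),
        functional_limitation  = c(0.05, 0.04, 0.04, -0.04, -0.03, -0.02),
        social_support_quality = c(-0.05, -0.03, -0.08, 0.10, 0.25, 0.08),
        work_skill             = c(0.15, 0.10, 0.08, 0.12, 0.03, 0.10)
      ),
      sigma = c(0.80, 0.85, 0.70, 0.70, 0.65, 0.70)
    ),
    outcomes = list(
      anxiety = list(
        type = "binary", beta0 = 0.148,
        beta1 = c(0.00, 0.01, 0.05),
        beta2 = c(0.010, 0.008, 0.010, -0.010, -0.012, -0.006),
        beta3 = c(-0.010, 0.0002, 0, 0, 0.020, 0.020, -0.010, 0)
      ),
      depression = list(
        type = "binary", beta0 = 0.111,
        beta1 = c(0.00, 0.01, 0.08),
        beta2 = c(0.008, 0.006, 0.008, -0.008, -0.010, -0.005),
        beta3 = c(-0.008, 0.0002, 0, 0, 0.015, 0.015, -0.008, 0)
      ),
      burnout = list(
        type = "continuous", beta0 = 2.26, sigma = 0.45,
        beta1 = c(0.02, 0.13, 0.06),
        beta2 = c(0.15, 0.20, 0.18, -0.15, -0.12, -0.10),
        beta3 = c(-0.05, -0.002, 0.02, -0.03, 0.08, 0.06, -0.10, 0.02)
      ),
      work_engagement = list(
        type = "continuous", beta0 = 2.11, sigma = 0.60,
        beta1 = c(-0.10, -0.21, -0.06),
        beta2 = c(-0.05, -0.05, -0.10, 0.20, 0.15, 0.12),
        beta3 = c(0.03, 0.002, -0.02, 0.02, -0.05, -0.04, 0.12, 0.03)
      )
    ),
    clip = c(0.01, 0.99),
    clip_ceiling = 0.001,
    emit_items = FALSE,
    missing_rate = 0
  )

  overrides <- list(...)
  unknown <- setdiff(names(overrides), c(names(defaults)))
  if (length(unknown)) {
    stop(sprintf("generator config: unknown component(s) %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg$n <- as.integer(n)

  # validation ---------------------------------------------------------------
  if (cfg$n < 0L) stop("generator config: n must be nonnegative")
  cc <- cfg$confounders
  props <- c(cc$sex_male, cc$education, cc$contract, cc$chronic_illness,
             cc$functional_limitation, cc$work_skill_high,
             cc$social_support_quality_probs)
  if (any(props < 0 | props > 1)) {
    stop("generator config: a marginal proportion lies outside [0, 1]")
  }
  if (abs(sum(cc$social_support_quality_probs) - 1) > 1e-8) {
    stop("generator config: social_support_quality_probs must sum to 1")
  }
  if (length(cc$age_range) != 2L || cc$age_range[1] > cc$age_range[2] ||
      cc$age_range[1] < 0) {
    stop("generator config: invalid age_range")
  }
  cfg$exposure$intercepts <- .named_vec(cfg$exposure$intercepts,
                                        contrast_names(), "exposure intercepts")
  cfg$exposure$coefficients <- .named_mat(cfg$exposure$coefficients,
                                          contrast_names(), conf,
                                          "exposure coefficients")
  mm <- cfg$mediators
  cfg$mediators$theta0 <- .named_vec(mm$theta0, med, "theta0")
  cfg$mediators$theta1 <- .named_mat(mm$theta1, contrast_names(), med, "theta1")
  cfg$mediators$theta2 <- .named_mat(mm$theta2, conf, med, "theta2")
  cfg$mediators$sigma <- .named_vec(mm$sigma, med, "mediator sigma")
  if (any(cfg$mediators$sigma < 0)) stop("generator config: mediator sigma must be >= 0")
  for (q in names(cfg$outcomes)) {
    oc <- cfg$outcomes[[q]]
    if (!oc$type %in% c("binary", "continuous")) {
      stop(sprintf("generator config: outcome '%s' type must be binary or continuous", q))
    }
    cfg$outcomes[[q]]$beta1 <- .named_vec(oc$beta1, contrast_names(),
                                          sprintf("%s beta1", q))
    cfg$outcomes[[q]]$beta2 <- .named_vec(oc$beta2, med, sprintf("%s beta2", q))
    cfg$outcomes[[q]]$beta3 <- .named_vec(oc$beta3, conf, sprintf("%s beta3", q))
    if (oc$type == "continuous") {
      if (is.null(oc$sigma) || oc$sigma < 0) {
        stop(sprintf("generator config: outcome '%s' needs sigma >= 0", q))
      }
    }
  }
  if (length(cfg$clip) != 2L || cfg$clip[1] <= 0 || cfg$clip[2] >= 1 ||
      cfg$clip[1] >= cfg$clip[2]) {
    stop("generator config: clip bounds must satisfy 0 < eps < 1 - eps < 1")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("generator config: missing_rate must lie in [0, 1)")
  }
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n = %d, %d mediators, %d outcomes (%s), emit_items = %s\n",
              x$n, ncol(x$mediators$theta1), length(x$outcomes),
              paste(names(x$outcomes), collapse = ", "),
              x$emit_items))
  invisible(x)
}

#' Read a generator configuration document
#'
#' Reads a YAML document whose top-level keys override [generator_config()]
#' components (matrices given as lists of rows).
#'
#' @param path YAML file path.
#' @return A `"generator_config"`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key "n" as boolean FALSE; take it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  n <- if (is.null(raw$n)) 2323 else raw$n
  raw$n <- NULL
  for (part in c("exposure", "mediators")) {
    for (fld in c("coefficients", "theta1", "theta2")) {
      if (!is.null(raw[[part]][[fld]])) {
        raw[[part]][[fld]] <- do.call(rbind, lapply(raw[[part]][[fld]], unlist))
      }
    }
  }
  do.call(generator_config, c(list(n = n), raw))
}

#' Sample confounders from the configured marginals
#'
#' Independent draws per respondent: Bernoulli for the binary covariates,
#' uniform over the configured integer range for age, and the configured
#' 3-point distribution for social-support quality. Uses the current RNG
#' state; seed at the caller (see [simulate_analysis_rows()]).
#'
#' @param config a `"generator_config"`.
#' @param n number of respondents (defaults to `config$n`).
#' @return data.frame with the eight confounder columns.
#' @export
sample_confounders <- function(config, n = config$n) {
  cc <- config$confounders
  data.frame(
    sex = stats::rbinom(n, 1, cc$sex_male),
    age = if (n > 0) sample(seq(cc$age_range[1], cc$age_range[2]), n, replace = TRUE)
          else integer(0),
    education = stats::rbinom(n, 1, cc$education),
    contract = stats::rbinom(n, 1, cc$contract),
    chronic_illness = stats::rbinom(n, 1, cc$chronic_illness),
    functional_limitation = stats::rbinom(n, 1, cc$functional_limitation),
    social_support_quality = if (n > 0) sample(1:3, n, replace = TRUE,
                                               prob = cc$social_support_quality_probs)
                             else integer(0),
    work_skill = stats::rbinom(n, 1, cc$work_skill_high)
  )
}

#' Assign telework exposure by multinomial logit
#'
#' Per respondent, the probability of exposure level z in 1-3 (vs reference
#' level 0, whose linear predictor is 0) follows the softmax of
#' `intercept_z + coefficients_z . C`. All-zero intercepts and coefficients
#' give equal 1/4 probabilities.
#'
#' @param confounders confounder data.frame from [sample_confounders()].
#' @param config a `"generator_config"`.
#' @return Integer vector of exposure levels 0-3.
#' @export
assign_exposure <- function(confounders, config) {
  C <- as.matrix(confounders[, .gc_confounders(), drop = FALSE])
  co <- config$exposure$coefficients
  if (ncol(C) != ncol(co)) {
    stop("generator config: exposure coefficient dimension does not match confounders")
  }
  lp <- sweep(C %*% t(co), 2L, config$exposure$intercepts, `+`)
  expo <- cbind(1, exp(lp))              # reference level has lp = 0
  pr <- expo / rowSums(expo)
  u <- stats::runif(nrow(C))
  c1 <- pr[, 1]; c2 <- c1 + pr[, 2]; c3 <- c2 + pr[, 3]
  as.integer((u > c1) + (u > c2) + (u > c3))
}

.dummies <- function(z) {
  cbind(A1 = as.integer(z == 1L), A2 = as.integer(z == 2L),
        A3 = as.integer(z == 3L))
}

#' Generate mediators from the structural mediator model
#'
#' `M_s = theta0_s + sum_z theta1_zs A_z + sum_j theta2_js C_j + e`,
#' `e ~ N(0, sigma_s^2)`.
#'
#' @param exposure integer exposure levels 0-3.
#' @param confounders confounder data.frame.
#' @param config a `"generator_config"`.
#' @return data.frame with the six mediator columns.
#' @export
generate_mediators <- function(exposure, confounders, config) {
  mm <- config$mediators
  A <- .dummies(exposure)
  C <- as.matrix(confounders[, .gc_confounders(), drop = FALSE])
  n <- nrow(A)
  mu <- matrix(mm$theta0, n, length(mm$theta0), byrow = TRUE) +
    A %*% mm$theta1 + C %*% mm$theta2
  eps <- matrix(stats::rnorm(n * ncol(mu)), n) %*% diag(mm$sigma, ncol(mu))
  out <- as.data.frame(mu + eps)
  names(out) <- .gc_mediators()
  out
}

#' Generate outcomes from the structural outcome model
#'
#' Continuous outcomes are the linear predictor plus Gaussian noise; binary
#' outcomes are Bernoulli draws with probability equal to the linear
#' predictor clipped to the configured bounds (clipping events are counted
#' in the `clip_counts` attribute and an overall rate above
#' `config$clip_ceiling` is an error, since heavy clipping would distort the
#' configured ground truth).
#'
#' @param exposure integer exposure levels 0-3.
#' @param mediators mediator data.frame.
#' @param confounders confounder data.frame.
#' @param config a `"generator_config"`.
#' @return data.frame of outcome columns with attributes `clip_counts`
#'   (per binary outcome) and `clip_rate`.
#' @export
generate_outcomes <- function(exposure, mediators, confounders, config) {
  A <- .dummies(exposure)
  M <- as.matrix(mediators[, .gc_mediators(), drop = FALSE])
  C <- as.matrix(confounders[, .gc_confounders(), drop = FALSE])
  n <- nrow(A)
  out <- list()
  clip_counts <- integer(0)
  n_binary_cells <- 0L
  for (q in names(config$outcomes)) {
    oc <- config$outcomes[[q]]
    lp <- oc$beta0 + drop(A %*% oc$beta1 + M %*% oc$beta2 + C %*% oc$beta3)
    if (oc$type == "continuous") {
      out[[q]] <- lp + stats::rnorm(n, sd = oc$sigma)
    } else {
      p <- pmin(pmax(lp, config$clip[1]), config$clip[2])
      clip_counts[q] <- sum(lp < config$clip[1] | lp > config$clip[2])
      n_binary_cells <- n_binary_cells + n
      out[[q]] <- stats::rbinom(n, 1, p)
    }
  }
  rate <- if (n_binary_cells > 0L) sum(clip_counts) / n_binary_cells else 0
  if (rate > config$clip_ceiling) {
    stop(sprintf("linear-probability clipping rate %.4f exceeds ceiling %.4f; the configured truth would be distorted",
                 rate, config$clip_ceiling))
  }
  res <- as.data.frame(out)
  attr(res, "clip_counts") <- clip_counts
  attr(res, "clip_rate") <- rate
  res
}

#' Closed-form true effects of a configuration
#'
#' Direct = `beta1_zq`, per-mediator indirect = `theta1_zs * beta2_sq`, joint
#' indirect = their sum, total = direct + joint indirect; all computed
#' directly from the configured coefficients (exact when binary-outcome
#' clipping is absent).
#'
#' @param config a `"generator_config"`.
#' @param clip_rate observed clipping rate for the generated data (if any);
#'   a nonzero value flags the truth as approximate.
#' @return data.frame with columns `outcome`, `contrast`, `effect_type`,
#'   `truth`, and attribute `approximate`.
#' @export
true_effect_table <- function(config, clip_rate = 0) {
  med <- .gc_mediators()
  th1 <- config$mediators$theta1
  rows <- list(); k <- 0L
  for (q in names(config$outcomes)) {
    oc <- config$outcomes[[q]]
    for (zi in 1:3) {
      ind <- th1[zi, ] * oc$beta2
      joint <- sum(ind)
      direct <- unname(oc$beta1[zi])
      k <- k + 1L
      rows[[k]] <- data.frame(
        outcome = q, contrast = contrast_names()[zi],
        effect_type = c("total", "direct", paste0("indirect:", med),
                        "joint_indirect"),
        truth = c(direct + joint, direct, unname(ind), joint),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "approximate") <- clip_rate > 0
  out
}

#' Simulate analysis-ready rows
#'
#' Runs the full structural model forward (confounders, exposure, mediators,
#' outcomes) and assembles the canonical analysis layout, bypassing the
#' survey-file round trip. This is the mode used for parameter-recovery and
#' coverage validation: mediators are the exact Gaussian draws of the
#' structural model.
#'
#' @param config a `"generator_config"`.
#' @param seed integer seed.
#' @return Analysis data.frame (attribute `confounders` set; also
#'   `clip_rate` from outcome generation).
#' @export
simulate_analysis_rows <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  C <- sample_confounders(config)
  z <- assign_exposure(C, config)
  M <- generate_mediators(z, C, config)
  Y <- generate_outcomes(z, M, C, config)
  out <- cbind(
    data.frame(respondent_id = sprintf("R%05d", seq_len(config$n)),
               z = z, .dummies(z)),
    M, Y, C
  )
  attr(out, "confounders") <- .gc_confounders()
  attr(out, "clip_rate") <- attr(Y, "clip_rate")
  out
}

# --- item-level emission ----------------------------------------------------

# Snap a continuous scale mean onto the attainable grid (multiples of 1/k
# within the response range), so the emitted items reproduce it exactly.
.snap_mean <- function(x, k, rng) {
  s <- round(x * k)
  s <- pmin(pmax(s, k * rng[1]), k * rng[2])
  s / k
}

# Distribute an integer recoded sum over k items with per-item range; the
# remainder goes to the leading items (deterministic).
.items_from_sum <- function(s, k, lo) {
  base <- s %/% k
  r <- s - base * k
  items <- matrix(base, nrow = length(s), ncol = k)
  add <- outer(r, seq_len(k), ">=")
  items + add * 1L + lo
}

#' Simulate a raw survey file
#'
#' Generates a synthetic population and writes it in the survey dialect —
#' telework answer strings, item-level responses for every instrument,
#' covariates (including the raw 1-6 work-skill category), age and
#' employment — so the whole pipeline (read, code, score, include, fit) is
#' exercised with no shortcut. Scale scores are snapped to the attainable
#' item grid before outcome generation, so scoring the emitted items
#' reproduces the generated scores exactly; the binary anxiety/depression
#' draws determine whether the emitted GAD-7/PHQ-9 sums fall above or below
#' the dichotomisation threshold. An optional uniform missingness rate
#' blanks item cells for testing the complete-case filter.
#'
#' @param config a `"generator_config"`.
#' @param path output file path.
#' @param seed integer seed.
#' @param dialect a [survey_dialect()] controlling headers and separator.
#' @param scales scale definitions used for item emission.
#' @return The path, invisibly; attribute `truth` carries the
#'   [true_effect_table()] (flagged approximate, since snapping perturbs the
#'   mediator scale).
#' @export
simulate_survey <- function(config, path, seed = 1L,
                            dialect = survey_dialect(),
                            scales = default_scale_definitions()) {
  set.seed(as.integer(seed))
  n <- config$n
  C <- sample_confounders(config)
  z <- assign_exposure(C, config)
  M <- generate_mediators(z, C, config)
  for (m in .gc_mediators()) {
    M[[m]] <- .snap_mean(M[[m]], scales[[m]]$item_count, scales[[m]]$response_range)
  }
  Y <- generate_outcomes(z, M, C, config)

  out <- data.frame(respondent_id = sprintf("R%05d", seq_len(n)))
  # telework answer string: draw uniformly among the strings coding to z
  level_strings <- split(names(.telework_map), unname(.telework_map))
  out$telework <- vapply(z, function(zz) {
    opts <- level_strings[[as.character(zz)]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))

  for (m in .gc_mediators()) {
    def <- scales[[m]]
    s <- as.integer(round(M[[m]] * def$item_count)) - def$item_count * def$response_range[1]
    items <- .items_from_sum(s, def$item_count, def$response_range[1])
    colnames(items) <- def$items
    out <- cbind(out, items)
  }
  for (q in c("burnout", "work_engagement")) {
    def <- if (q == "burnout") scales$bat12 else scales$uwes3
    snapped <- .snap_mean(Y[[q]], def$item_count, def$response_range)
    Y[[q]] <- snapped
    s <- as.integer(round(snapped * def$item_count)) - def$item_count * def$response_range[1]
    items <- .items_from_sum(s, def$item_count, def$response_range[1])
    colnames(items) <- def$items
    out <- cbind(out, items)
  }
  for (q in c("anxiety", "depression")) {
    def <- if (q == "anxiety") scales$gad7 else scales$phq9
    thr <- def$dichotomize_at
    below <- sample.int(thr, n, replace = TRUE) - 1L          # 0 .. thr-1
    above_max <- def$item_count * 3L - thr                     # recoded max is 3/item
    above <- thr + sample.int(above_max + 1L, n, replace = TRUE) - 1L
    s <- ifelse(Y[[q]] == 1L, above, below)
    items <- .items_from_sum(s, def$item_count, def$response_range[1])
    colnames(items) <- def$items
    out <- cbind(out, items)
  }

  out$sex <- C$sex
  out$age <- C$age
  out$education <- C$education
  out$contract <- C$contract
  out$chronic_illness <- C$chronic_illness
  out$functional_limitation <- C$functional_limitation
  out$social_support_quality <- C$social_support_quality
  out$work_skill_raw <- ifelse(C$work_skill == 1L,
                               sample(5:6, n, replace = TRUE),
                               sample(1:4, n, replace = TRUE))
  out$employed <- 1L

  if (config$missing_rate > 0) {
    item_cols <- dialect$item_columns
    for (col in item_cols) {
      blank <- stats::runif(n) < config$missing_rate
      out[[col]][blank] <- NA
    }
  }

  names(out) <- unname(dialect$columns[names(out)])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = TRUE, na = "NA")
  res <- invisible(path)
  attr(res, "truth") <- true_effect_table(config, clip_rate = attr(Y, "clip_rate"))
  invisible(res)
}
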