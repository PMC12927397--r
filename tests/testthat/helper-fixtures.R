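# Fixtures built in code: a tiny hand-written survey file and a fake
# path-model-fits constructor for arithmetic checks on the decomposition.

# Writes a deterministic 5-row survey file with valid codes and returns the
# data.frame that was written.
write_survey_fixture <- function(path, sep = ",") {
  scales <- default_scale_definitions()
  n <- 5L
  df <- data.frame(respondent_id = paste0("P", 1:n))
  df$telework <- c("Never, because this is not possible in my job",
                   "About one day a month",
                   "About one day a week",
                   "daily",
                   "Several days a week")
  set.seed(42)
  for (def in scales) {
    rng <- def$response_range
    items <- matrix(sample(rng[1]:rng[2], n * def$item_count, replace = TRUE),
                    nrow = n)
    colnames(items) <- def$items
    df <- cbind(df, items)
  }
  df$sex <- c(1, 0, 0, 1, 0)
  df$age <- c(30, 45, 50, 64, 23)
  df$education <- c(1, 1, 0, 1, 1)
  df$contract <- c(1, 1, 1, 0, 1)
  df$chronic_illness <- c(0, 1, 1, 0, 1)
  df$functional_limitation <- c(1, 1, 0, 0, 1)
  df$social_support_quality <- c(2, 3, 1, 2, 2)
  df$work_skill_raw <- c(2, 6, 3, 5, 4)
  df$employed <- c(1, 1, 1, 1, 1)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  df
}

# A minimal path_model_fits object from explicit coefficient values, for
# arithmetic checks on decompose_effects without any fitting.
fake_fits <- function(delta1, direct, theta1, beta2,
                      outcome = "burnout", mediators = names(beta2)) {
  dummies <- c("A1", "A2", "A3")
  delta <- stats::setNames(list(stats::setNames(delta1, dummies)), outcome)
  beta_vec <- c(stats::setNames(direct, dummies), beta2)
  beta <- stats::setNames(list(beta_vec), outcome)
  theta <- lapply(mediators, function(m) stats::setNames(theta1[, m], dummies))
  names(theta) <- mediators
  structure(list(n = 0L, outcomes = outcome, mediators = mediators,
                 confounders = character(), delta = delta, beta = beta,
                 theta = theta),
            class = "path_model_fits")
}

# Small non-null generator dataset shared across tests.
small_rows <- function(n = 500, seed = 101, ...) {
  simulate_analysis_rows(generator_config(n = n, ...), seed = seed)
}
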