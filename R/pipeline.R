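# Orchestration and reporting: descriptive summaries by exposure level,
# publication-style effect tables, and the end-to-end pipeline
# (read/generate -> code -> score -> include -> fit -> bootstrap -> Holm ->
# render) with structured per-stage logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Descriptive sample summary by exposure level
#'
#' Per exposure level and overall: respondent count, mean/SD and
#' median/min/max for continuous variables, count and percent for binary
#' variables — the layout of a standard sample-characteristics table.
#'
#' @param rows analysis data.frame (nonempty).
#' @return Long data.frame with columns `group`, `variable`, `statistic`,
#'   `value`.
#' @export
summarize_sample <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) stop("cannot summarise an empty sample")
  groups <- list(
    non_teleworker = rows$z == 0L, monthly = rows$z == 1L,
    weekly = rows$z == 2L, daily = rows$z == 3L,
    overall = rep(TRUE, nrow(rows))
  )
  binary_vars <- intersect(
    c("sex", "education", "contract", "chronic_illness",
      "functional_limitation", "work_skill", "anxiety", "depression"),
    names(rows)
  )
  continuous_vars <- intersect(
    c("age", "social_support_quality", mediator_names(),
      "burnout", "work_engagement", "anxiety_score", "depression_score"),
    names(rows)
  )
  recs <- list(); k <- 0L
  add <- function(group, variable, statistic, value) {
    k <<- k + 1L
    recs[[k]] <<- data.frame(group = group, variable = variable,
                             statistic = statistic, value = value,
                             stringsAsFactors = FALSE)
  }
  for (g in names(groups)) {
    sub <- rows[groups[[g]], , drop = FALSE]
    add(g, "n", "count", nrow(sub))
    for (v in binary_vars) {
      x <- sub[[v]]
      add(g, v, "count", sum(x == 1, na.rm = TRUE))
      add(g, v, "percent",
          if (nrow(sub)) 100 * mean(x == 1, na.rm = TRUE) else NA_real_)
    }
    for (v in continuous_vars) {
      x <- sub[[v]]
      if (!nrow(sub)) {
        for (s in c("mean", "sd", "median", "min", "max")) add(g, v, s, NA_real_)
      } else {
        add(g, v, "mean", mean(x, na.rm = TRUE))
        add(g, v, "sd", stats::sd(x, na.rm = TRUE))
        add(g, v, "median", stats::median(x, na.rm = TRUE))
        add(g, v, "min", min(x, na.rm = TRUE))
        add(g, v, "max", max(x, na.rm = TRUE))
      }
    }
  }
  do.call(rbind, recs)
}

#' Render a publication-style effect table
#'
#' Rounds effects and confidence limits to 4 decimals (percentages in the
#' descriptive output use 2), adds the x100 percentage rendering of every
#' binary-outcome effect (a risk difference in percent), and a significance
#' marker at the adjusted alpha. Machine-readable output should use the
#' unrounded summary table instead.
#'
#' @param effects summary data.frame from [summarize_bootstrap()].
#' @param outcome_type named vector from [outcome_types()]; rows of binary
#'   outcomes get the percentage column.
#' @param digits decimals for effects and confidence limits.
#' @return The rendered data.frame: rounded `estimate`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_holm`, `estimate_pct` (100 x estimate for binary outcomes,
#'   `NA` otherwise) and `sig` (`"*"` when significant).
#' @export
render_effect_table <- function(effects, outcome_type = outcome_types(sensitivity = TRUE),
                                digits = 4) {
  out <- effects
  for (col in c("estimate", "se", "ci_low", "ci_high", "p_raw", "p_holm")) {
    out[[col]] <- round(out[[col]], digits)
  }
  is_binary <- !is.na(outcome_type[out$outcome]) &
    outcome_type[out$outcome] == "binary"
  out$estimate_pct <- ifelse(is_binary, 100 * out$estimate, NA_real_)
  out$sig <- ifelse(out$significant, "*", "")
  out
}

.stage <- function(name, log_env, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes read (or generate) -> code -> score -> include -> complete-case
#' -> fit -> decompose -> bootstrap -> Holm -> render, writes the effect
#' table, descriptive table, exclusion tally and run metadata when an output
#' directory is given, and returns everything invisibly. Identical
#' configurations and seeds produce byte-identical output files.
#'
#' @param config a configuration list or the path to a YAML document. Keys:
#'   `input` (survey file path) or `generator` (overrides for
#'   [generator_config()], incl. `n`); `seed`; `B`; `ci_method`; `p_method`;
#'   `holm_family`; `alpha`; `sensitivity` (logical, adds the continuous
#'   anxiety/depression sum-score outcomes); `work_skill_mode`;
#'   `age_bounds`; `dialect` (list with `columns`, `sep`).
#' @param output_dir optional directory for `effects.csv` (full precision),
#'   `effects_rendered.csv`, `descriptives.csv`, `exclusions.json` and
#'   `metadata.json`.
#' @return (Invisibly) a list: `effects`, `rendered`, `descriptives`,
#'   `tally`, `metadata`, `log`, `rows`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  B <- as.integer(config$B %||% 1000L)
  ci_method <- config$ci_method %||% "percentile"
  p_method <- config$p_method %||% "normal"
  holm_family <- config$holm_family %||% "outcome"
  alpha <- config$alpha %||% 0.05
  sensitivity <- isTRUE(config$sensitivity)
  work_skill_mode <- config$work_skill_mode %||% "binary"
  age_bounds <- unlist(config$age_bounds %||% c(18, 64))
  scales <- default_scale_definitions()
  dialect <- survey_dialect(
    columns = unlist(config$dialect$columns %||% character()),
    sep = config$dialect$sep %||% ",", scales = scales
  )
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  if (!is.null(config$input)) {
    path <- config$input
    note("input", source = "file", path = path)
  } else {
    path <- .stage("generate", NULL, {
      gen <- config$generator %||% list()
      # YAML 1.1 reads the bare key "n" as boolean FALSE; take it back
      names(gen)[names(gen) == "FALSE"] <- "n"
      n <- gen$n %||% 2323; gen$n <- NULL
      gen$emit_items <- NULL  # survey emission always writes items
      gcfg <- do.call(generator_config, c(list(n = n), gen))
      dir <- output_dir %||% tempdir()
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, "synthetic_survey.csv")
      simulate_survey(gcfg, p, seed = seed, dialect = dialect, scales = scales)
      p
    })
    note("generate", source = "synthetic", path = path)
  }

  records <- .stage("read", NULL, read_survey_table(path, dialect, scales))
  note("read", n_out = nrow(records), out_of_range = attr(records, "out_of_range"))

  incl <- .stage("include", NULL, apply_inclusion(records, age_bounds))
  note("include", n_in = incl$tally$input, n_out = incl$tally$retained,
       excluded_employment = incl$tally$excluded_employment,
       excluded_age = incl$tally$excluded_age)

  rows <- .stage("score", NULL,
                 build_analysis_rows(incl$included, scales,
                                     sensitivity = sensitivity,
                                     work_skill_mode = work_skill_mode))
  rows <- .stage("complete_case", NULL, complete_case_filter(rows))
  note("complete_case", n_dropped = attr(rows, "n_dropped"), n_out = nrow(rows))

  boot <- .stage("bootstrap", NULL,
                 bootstrap_effects(rows, B = B, seed = seed))
  effects <- .stage("summarize", NULL,
                    summarize_bootstrap(boot, ci_method = ci_method,
                                        p_method = p_method,
                                        holm_family = holm_family,
                                        alpha = alpha))
  descriptives <- .stage("describe", NULL, summarize_sample(rows))
  rendered <- render_effect_table(effects)
  note("summarize", n_estimands = nrow(effects))

  metadata <- list(
    n_analyzed = nrow(rows), B = B, seed = seed,
    ci_method = ci_method, p_method = p_method, holm_family = holm_family,
    alpha = alpha, sensitivity = sensitivity,
    n_failed_replicates = boot$n_failed,
    exclusion_tally = incl$tally,
    n_dropped_incomplete = attr(rows, "n_dropped"),
    software_version = as.character(utils::packageVersion("telemediate"))
  )

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(effects, file.path(output_dir, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(rendered, file.path(output_dir, "effects_rendered.csv"),
                     row.names = FALSE)
    utils::write.csv(descriptives, file.path(output_dir, "descriptives.csv"),
                     row.names = FALSE)
    jsonlite::write_json(incl$tally, file.path(output_dir, "exclusions.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(metadata, file.path(output_dir, "metadata.json"),
                         auto_unbox = TRUE)
  }

  invisible(list(effects = effects, rendered = rendered,
                 descriptives = descriptives, tally = incl$tally,
                 metadata = metadata, log = log, rows = rows))
}
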