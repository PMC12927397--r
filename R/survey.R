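# Survey schema: read raw survey tables, apply the variable coding rules
# (telework frequency, work-skill collapse), the inclusion flow (employed,
# aged 18-64) and the complete-case filter, producing analysis-ready rows.

.telework_map <- c(
  "never, because this is not possible in my job" = 0L,
  "never, because i choose not to work from home" = 0L,
  "about one day a month" = 1L,
  "more than one day a month but less than one day a week" = 1L,
  "about one day a week" = 2L,
  "several days a week" = 2L,
  "daily" = 3L
)

#' Telework answer strings by exposure level
#'
#' The seven questionnaire answers to "Do you work from home?", grouped by
#' the exposure level they code to (0 non-teleworker, 1 monthly, 2 weekly,
#' 3 daily).
#'
#' @return Named integer vector mapping the (case-folded) answer string to
#'   its exposure level.
#' @export
telework_levels <- function() .telework_map

#' Code the telework answer string to an exposure level
#'
#' Exact matching after trimming and case-folding; no fuzzy matching.
#' Missing responses stay missing (they are removed by the complete-case
#' filter); any other unrecognised string is a coding error.
#'
#' @param telework_response character vector of questionnaire answers.
#' @return Integer vector of exposure levels in 0-3.
#' @export
encode_telework <- function(telework_response) {
  key <- tolower(trimws(as.character(telework_response)))
  z <- unname(.telework_map[key])
  bad <- is.na(z) & !is.na(telework_response)
  if (any(bad)) {
    stop(sprintf("unrecognised telework response: '%s'",
                 telework_response[bad][1]))
  }
  z
}

#' Code the raw work-skill category
#'
#' The six job categories are collapsed into three levels (1-2, 3-4, 5-6).
#' The default binary coding contrasts level 3 ("high level") against levels
#' 1-2 ("lower/mid level"), giving the single confounder column the path
#' models expect; `mode = "three_level"` returns the collapsed level (1-3)
#' for sensitivity analyses with level dummies.
#'
#' @param work_skill_raw integer vector in 1-6 (missing allowed).
#' @param mode `"binary"` (default) or `"three_level"`.
#' @return Integer vector: 0/1 in binary mode, 1-3 in three-level mode.
#' @export
encode_work_skill <- function(work_skill_raw, mode = c("binary", "three_level")) {
  mode <- match.arg(mode)
  x <- as.integer(work_skill_raw)
  bad <- !is.na(x) & (x < 1L | x > 6L)
  if (any(bad)) {
    stop(sprintf("work skill category %d outside 1-6", x[bad][1]))
  }
  lev <- as.integer(ceiling(x / 2))
  if (mode == "binary") as.integer(lev == 3L) else lev
}

#' Column dictionary for a survey file
#'
#' Maps the logical variable names the pipeline uses (telework, item columns
#' per instrument, covariates) onto the headers of a source file, and records
#' the field separator. The default is the identity mapping over the
#' canonical column names with comma separation.
#'
#' @param columns named character vector, logical name -> source header;
#'   entries given here override the identity default.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param scales scale definitions supplying the item column names.
#' @return An object of class `"survey_dialect"`.
#' @export
survey_dialect <- function(columns = character(), sep = ",",
                           scales = default_scale_definitions()) {
  item_cols <- unlist(lapply(scales, `[[`, "items"), use.names = FALSE)
  logical_names <- c("respondent_id", "telework", item_cols,
                     "sex", "age", "education", "contract", "chronic_illness",
                     "functional_limitation", "social_support_quality",
                     "work_skill_raw", "employed")
  map <- stats::setNames(logical_names, logical_names)
  if (length(columns)) {
    unknown <- setdiff(names(columns), logical_names)
    if (length(unknown)) {
      stop(sprintf("unknown logical column name(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    map[names(columns)] <- columns
  }
  structure(list(columns = map, sep = sep, item_columns = item_cols),
            class = "survey_dialect")
}

#' Read a raw survey table
#'
#' Reads a delimited text file (UTF-8, header row) and maps its columns onto
#' the logical survey-record layout via the dialect's column dictionary.
#' Item responses outside their documented response range are turned into
#' missing-markers; the number of such replacements is recorded in the
#' `"out_of_range"` attribute and raised as a single warning.
#'
#' @param path path to the delimited file.
#' @param dialect a [survey_dialect()].
#' @param scales scale definitions used to range-check item columns.
#' @return A data.frame of survey records with canonical column names, with
#'   attribute `out_of_range` (count of item responses blanked).
#' @export
read_survey_table <- function(path, dialect = survey_dialect(),
                              scales = default_scale_definitions()) {
  if (!file.exists(path)) stop(sprintf("cannot read survey file '%s'", path))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_cols)) {
    logical_missing <- names(dialect$columns)[dialect$columns %in% missing_cols]
    stop(sprintf("survey file lacks mandatory column(s): %s",
                 paste(logical_missing, collapse = ", ")))
  }
  out <- raw[, unname(dialect$columns), drop = FALSE]
  names(out) <- names(dialect$columns)

  n_blanked <- 0L
  for (def in scales) {
    rng <- def$response_range
    for (col in def$items) {
      v <- suppressWarnings(as.numeric(out[[col]]))
      bad <- !is.na(v) & (v < rng[1] | v > rng[2])
      n_blanked <- n_blanked + sum(bad)
      v[bad] <- NA
      out[[col]] <- v
    }
  }
  for (col in c("sex", "age", "education", "contract", "chronic_illness",
                "functional_limitation", "social_support_quality",
                "work_skill_raw", "employed")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  if (n_blanked > 0L) {
    warning(sprintf("%d item response(s) outside their documented range were set to missing",
                    n_blanked))
  }
  attr(out, "out_of_range") <- n_blanked
  out
}

#' Apply the inclusion flow
#'
#' Keeps respondents who were employed and aged within the (inclusive)
#' bounds. Exclusions are tallied sequentially and mutually exclusively:
#' first employment (missing counts as excluded), then age among the
#' remainder.
#'
#' @param records survey-record data.frame (needs `employed` and `age`).
#' @param age_bounds inclusive age bounds, default `c(18, 64)`.
#' @return List with `included` (data.frame) and `tally` (named list:
#'   `input`, `excluded_employment`, `excluded_age`, `retained`).
#' @export
apply_inclusion <- function(records, age_bounds = c(18, 64)) {
  n <- nrow(records)
  employed_ok <- !is.na(records$employed) & records$employed == 1
  age_ok <- !is.na(records$age) &
    records$age >= age_bounds[1] & records$age <= age_bounds[2]
  keep <- employed_ok & age_ok
  tally <- list(
    input = n,
    excluded_employment = sum(!employed_ok),
    excluded_age = sum(employed_ok & !age_ok),
    retained = sum(keep)
  )
  list(included = records[keep, , drop = FALSE], tally = tally)
}

#' Build analysis rows from coded survey records
#'
#' Codes the exposure (telework level and dummies), scores every instrument,
#' and assembles the canonical analysis layout: exposure level `z`, dummies
#' `A1`-`A3`, six mediator means, the four outcomes (binary anxiety and
#' depression, continuous burnout and work engagement; plus the continuous
#' sum scores when `sensitivity = TRUE`) and the eight confounders. Rows may
#' still contain missing values; apply [complete_case_filter()] before
#' fitting.
#'
#' @param records survey-record data.frame from [read_survey_table()].
#' @param scales scale definitions.
#' @param sensitivity logical; also emit `anxiety_score` / `depression_score`.
#' @param work_skill_mode passed to [encode_work_skill()]; in three-level
#'   mode the confounder set replaces `work_skill` by level dummies
#'   `work_skill_l2`, `work_skill_l3`.
#' @return Analysis data.frame with attribute `confounders` naming the
#'   confounder columns to adjust for.
#' @export
build_analysis_rows <- function(records, scales = default_scale_definitions(),
                                sensitivity = FALSE,
                                work_skill_mode = c("binary", "three_level")) {
  work_skill_mode <- match.arg(work_skill_mode)
  z <- encode_telework(records$telework)
  out <- data.frame(respondent_id = records$respondent_id, z = z,
                    A1 = as.integer(z == 1L), A2 = as.integer(z == 2L),
                    A3 = as.integer(z == 3L))

  gad <- score_scale_matrix(records[, scales$gad7$items, drop = FALSE], scales$gad7)
  phq <- score_scale_matrix(records[, scales$phq9$items, drop = FALSE], scales$phq9)
  for (m in mediator_names()) {
    out[[m]] <- score_scale_matrix(records[, scales[[m]]$items, drop = FALSE],
                                   scales[[m]])$score
  }
  out$anxiety <- gad$indicator
  out$depression <- phq$indicator
  out$burnout <- score_scale_matrix(records[, scales$bat12$items, drop = FALSE],
                                    scales$bat12)$score
  out$work_engagement <- score_scale_matrix(records[, scales$uwes3$items, drop = FALSE],
                                            scales$uwes3)$score
  if (sensitivity) {
    out$anxiety_score <- gad$score
    out$depression_score <- phq$score
  }

  out$sex <- records$sex
  out$age <- records$age
  out$education <- records$education
  out$contract <- records$contract
  out$chronic_illness <- records$chronic_illness
  out$functional_limitation <- records$functional_limitation
  out$social_support_quality <- records$social_support_quality
  if (work_skill_mode == "binary") {
    out$work_skill <- encode_work_skill(records$work_skill_raw)
    confs <- confounder_names()
  } else {
    lev <- encode_work_skill(records$work_skill_raw, mode = "three_level")
    out$work_skill_l2 <- as.integer(lev == 2L)
    out$work_skill_l3 <- as.integer(lev == 3L)
    confs <- c(setdiff(confounder_names(), "work_skill"),
               "work_skill_l2", "work_skill_l3")
  }
  attr(out, "confounders") <- confs
  attr(out, "sensitivity") <- sensitivity
  out
}

#' Complete-case filter
#'
#' Drops every row with a missing value in any analysis variable: exposure,
#' any mediator, any outcome, any confounder. No imputation is performed.
#'
#' @param rows analysis data.frame from [build_analysis_rows()].
#' @param variables columns to scan; defaults to every analysis column
#'   present (exposure, mediators, outcomes, confounders).
#' @return The complete rows, with attribute `n_dropped`.
#' @export
complete_case_filter <- function(rows, variables = NULL) {
  if (is.null(variables)) {
    confs <- attr(rows, "confounders")
    if (is.null(confs)) confs <- intersect(confounder_names(), names(rows))
    sens <- isTRUE(attr(rows, "sensitivity"))
    variables <- intersect(
      c("z", mediator_names(), names(outcome_types(sensitivity = sens)), confs),
      names(rows)
    )
  }
  keep <- stats::complete.cases(rows[, variables, drop = FALSE])
  out <- rows[keep, , drop = FALSE]
  attr(out, "confounders") <- attr(rows, "confounders")
  attr(out, "sensitivity") <- attr(rows, "sensitivity")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write an analysis table
#'
#' Writes analysis rows as delimited text with canonical column names.
#'
#' @param rows analysis data.frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_analysis_table <- function(rows, path, sep = ",") {
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
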