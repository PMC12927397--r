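# Psychometric scale scoring: sum scores with optional dichotomisation
# (GAD-7, PHQ-9), item-mean scores (BAT-12, UWES-3, SIMPH subscales), and
# standardised Cronbach's alpha for reliability reporting.

#' Define a psychometric scale
#'
#' A scale definition describes how a bank of ordinal item responses is turned
#' into a score: how many items, their legal response range on file, whether
#' the score is the item sum or the item mean, an optional recode offset
#' applied to every item before summing (e.g. `-1` to map 1-4 responses onto
#' 0-3), and an optional dichotomisation threshold on the recoded sum.
#'
#' @param name label for the instrument.
#' @param items character vector of item column names (length >= 2).
#' @param response_range integer vector `c(min, max)` of legal on-file item
#'   responses.
#' @param scoring `"sum"` or `"mean"`.
#' @param recode_offset integer added to each item before a sum score is
#'   formed; ignored for mean scales.
#' @param dichotomize_at optional integer threshold on the recoded sum; the
#'   binary indicator is 1 iff sum >= threshold. Must lie within the
#'   attainable sum range.
#' @return An object of class `"scale_definition"`.
#' @export
scale_definition <- function(name, items, response_range, scoring = c("sum", "mean"),
                             recode_offset = 0L, dichotomize_at = NULL) {
  scoring <- match.arg(scoring)
  items <- as.character(items)
  if (length(items) < 2L) {
    stop(sprintf("scale '%s': a scale needs at least 2 items", name))
  }
  response_range <- as.integer(response_range)
  if (length(response_range) != 2L || response_range[1] >= response_range[2]) {
    stop(sprintf("scale '%s': response_range must be c(min, max) with min < max", name))
  }
  k <- length(items)
  if (!is.null(dichotomize_at)) {
    lo <- k * (response_range[1] + recode_offset)
    hi <- k * (response_range[2] + recode_offset)
    if (dichotomize_at < lo || dichotomize_at > hi) {
      stop(sprintf("scale '%s': dichotomize_at %s outside attainable sum range [%d, %d]",
                   name, dichotomize_at, lo, hi))
    }
  }
  structure(
    list(name = name, items = items, item_count = k,
         response_range = response_range, scoring = scoring,
         recode_offset = as.integer(recode_offset),
         dichotomize_at = if (is.null(dichotomize_at)) NULL else as.integer(dichotomize_at)),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s: %d items in [%d, %d], scoring = %s%s\n",
              x$name, x$item_count, x$response_range[1], x$response_range[2],
              x$scoring,
              if (is.null(x$dichotomize_at)) ""
              else sprintf(", dichotomised at sum >= %d (offset %d)",
                           x$dichotomize_at, x$recode_offset)))
  invisible(x)
}

#' Load scale definitions from a configuration document
#'
#' Instruments are shipped as data: a YAML document with one entry per
#' instrument (item columns, response range, scoring rule, optional recode
#' offset and dichotomisation threshold). The default document defines GAD-7,
#' PHQ-9, BAT-12, UWES-3 and the six SIMPH subscales.
#'
#' @param path path to a YAML scale document; defaults to the document shipped
#'   with the package.
#' @return Named list of [scale_definition()] objects.
#' @export
default_scale_definitions <- function(path = system.file("extdata", "scales.yaml",
                                                         package = "telemediate")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    scale_definition(
      name = nm, items = d$items, response_range = unlist(d$response_range),
      scoring = d$scoring,
      recode_offset = if (is.null(d$recode_offset)) 0L else d$recode_offset,
      dichotomize_at = d$dichotomize_at
    )
  })
  names(out) <- names(raw)
  out
}

.check_items <- function(items, definition) {
  if (length(items) != definition$item_count) {
    stop(sprintf("scale '%s': expected %d items, got %d",
                 definition$name, definition$item_count, length(items)))
  }
  rng <- definition$response_range
  bad <- !is.na(items) & (items < rng[1] | items > rng[2])
  if (any(bad)) {
    stop(sprintf("scale '%s': item response %s outside [%d, %d]",
                 definition$name, items[bad][1], rng[1], rng[2]))
  }
  if (anyNA(items)) {
    stop(sprintf("scale '%s': missing item response (complete cases only)",
                 definition$name))
  }
  invisible(TRUE)
}

#' Score a sum scale with optional dichotomisation
#'
#' Recodes each item by the definition's offset, sums, and (if a threshold is
#' configured) sets a binary indicator to 1 iff the sum reaches the threshold.
#' For GAD-7 this is the 0-21 sum of seven items recoded 0-3, dichotomised at
#' 10+ to flag likely generalised anxiety disorder.
#'
#' @param items numeric vector of one respondent's item responses.
#' @param definition a [scale_definition()] with `scoring = "sum"`.
#' @return List with `sum` (recoded sum score) and `indicator` (0/1, or `NULL`
#'   when the scale has no threshold).
#' @export
score_sum_scale <- function(items, definition) {
  if (definition$scoring != "sum") {
    stop(sprintf("scale '%s' is not a sum scale", definition$name))
  }
  .check_items(items, definition)
  s <- sum(items + definition$recode_offset)
  ind <- if (is.null(definition$dichotomize_at)) NULL
         else as.integer(s >= definition$dichotomize_at)
  list(sum = s, indicator = ind)
}

#' Score a mean scale
#'
#' Arithmetic mean of the raw item responses, as used for BAT-12, UWES-3 and
#' the SIMPH mediator subscales.
#'
#' @inheritParams score_sum_scale
#' @param definition a [scale_definition()] with `scoring = "mean"`.
#' @return The mean score (numeric scalar).
#' @export
score_mean_scale <- function(items, definition) {
  if (definition$scoring != "mean") {
    stop(sprintf("scale '%s' is not a mean scale", definition$name))
  }
  .check_items(items, definition)
  mean(items)
}

#' Score a scale over a respondents x items matrix
#'
#' Vectorised scorer used by the pipeline: out-of-range responses and
#' missing items propagate `NA` scores rather than erroring (missingness is
#' resolved downstream by the complete-case filter).
#'
#' @param mat numeric matrix or data.frame, respondents in rows, the scale's
#'   items in columns.
#' @param definition a [scale_definition()].
#' @return List with `score` (sum or mean per respondent) and `indicator`
#'   (0/1 vector, or `NULL` for scales without a threshold).
#' @export
score_scale_matrix <- function(mat, definition) {
  mat <- as.matrix(mat)
  if (ncol(mat) != definition$item_count) {
    stop(sprintf("scale '%s': expected %d item columns, got %d",
                 definition$name, definition$item_count, ncol(mat)))
  }
  rng <- definition$response_range
  mat[!is.na(mat) & (mat < rng[1] | mat > rng[2])] <- NA
  if (definition$scoring == "sum") {
    s <- rowSums(mat + definition$recode_offset)
    ind <- if (is.null(definition$dichotomize_at)) NULL
           else as.integer(s >= definition$dichotomize_at)
    list(score = s, indicator = ind)
  } else {
    list(score = rowMeans(mat), indicator = NULL)
  }
}

#' Standardised Cronbach's alpha
#'
#' Reliability from the mean pairwise inter-item Pearson correlation:
#' `alpha_std = k * rbar / (1 + (k - 1) * rbar)` with `k` items. The
#' standardised form depends on correlations only, so it is invariant to
#' separate linear rescaling of individual items.
#'
#' @param item_matrix numeric matrix, respondents in rows, items in columns
#'   (>= 3 respondents, >= 2 items, every item with nonzero variance).
#' @return Standardised alpha (numeric scalar).
#' @export
cronbach_alpha_standardized <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 3L) stop("reliability needs at least 3 respondents")
  if (ncol(m) < 2L) stop("reliability needs at least 2 items")
  v <- apply(m, 2L, stats::var)
  if (any(v == 0 | is.na(v))) {
    nm <- colnames(m)
    if (is.null(nm)) nm <- paste0("item", seq_len(ncol(m)))
    stop(sprintf("reliability undefined: zero-variance item '%s'",
                 nm[which(v == 0 | is.na(v))[1]]))
  }
  k <- ncol(m)
  r <- stats::cor(m)
  rbar <- mean(r[upper.tri(r)])
  k * rbar / (1 + (k - 1) * rbar)
}
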