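# Mediation engine: OLS fits for the three model sets (total-effect model,
# outcome model with mediators, one model per mediator) and the interventional
# effect decomposition by the product of coefficients.
#
# With all three sets fitted by OLS on the same rows and regressor sets, the
# total exposure coefficient decomposes exactly (omitted-variable algebra):
#   delta_1zq = beta_1zq + sum_s theta_1zs * beta_2sq
# so total = direct + joint indirect holds to numerical precision.

#' Ordinary least squares with rank checking
#'
#' QR-based least squares. A rank-deficient design is an error naming the
#' collinear columns (via the pivoted QR), rather than a silent NA fill.
#'
#' @param response numeric response vector.
#' @param design numeric design matrix including the intercept column;
#'   `nrow >= ncol` required.
#' @return List with `coefficients` (named by design columns), `residuals`,
#'   `fitted`, `rank`, `sigma2` (residual variance, denominator `n - p`, or
#'   `NA` when `n == p`).
#' @export
fit_ols <- function(response, design) {
  design <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(design); p <- ncol(design)
  if (length(y) != n) stop("response length does not match design rows")
  if (n < p) stop(sprintf("underdetermined system: %d rows < %d columns", n, p))
  qrx <- qr(design)
  if (qrx$rank < p) {
    cols <- colnames(design)
    if (is.null(cols)) cols <- paste0("x", seq_len(p))
    dropped <- cols[qrx$pivot[(qrx$rank + 1L):p]]
    stop(sprintf("singular design: collinear column(s) %s",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(design %*% beta)
  res <- y - fitted
  names(beta) <- colnames(design)
  list(coefficients = beta, residuals = res, fitted = fitted,
       rank = qrx$rank, sigma2 = if (n > p) sum(res^2) / (n - p) else NA_real_)
}

# Lean coefficient solver for the bootstrap loop; returns NULL on rank
# deficiency instead of erroring (the replicate is then redrawn).
.fast_coefs <- function(y, x) {
  fit <- .lm.fit(x, y)
  if (fit$rank < ncol(x)) return(NULL)
  co <- fit$coefficients
  names(co) <- colnames(x)
  co
}

# Design matrices shared by the three model sets.
.path_designs <- function(data, mediators, confounders) {
  need <- c("A1", "A2", "A3", mediators, confounders)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop(sprintf("analysis rows lack column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  X_te <- cbind("(Intercept)" = rep(1, n),
                as.matrix(data[, c("A1", "A2", "A3", confounders)]))
  X_out <- cbind("(Intercept)" = rep(1, n),
                 as.matrix(data[, c("A1", "A2", "A3", mediators, confounders)]))
  list(total = X_te, outcome = X_out)
}

.check_levels <- function(z) {
  present <- tabulate(z + 1L, nbins = 4L) > 0L
  if (!all(present)) {
    lvl <- which(!present)[1] - 1L
    stop(sprintf("exposure level %d has no respondents; effects for it are not estimable", lvl))
  }
  invisible(TRUE)
}

#' Fit the three path-model sets
#'
#' Fits, on the identical row set, (1) the total-effect model regressing each
#' outcome on the exposure dummies and confounders, (2) the outcome model
#' adding the six mediators, and (3) one model per mediator regressing it on
#' the exposure dummies and confounders. Binary outcomes are fitted
#' identically by OLS (linear probability model), so their coefficients are
#' risk differences.
#'
#' @param data complete analysis rows (see [build_analysis_rows()] and
#'   [complete_case_filter()]).
#' @param outcomes character vector of outcome columns; defaults to the four
#'   study outcomes (plus the sum-score outcomes when the rows carry them).
#' @param mediators mediator columns (default the canonical six).
#' @param confounders confounder columns (default the canonical eight, or the
#'   rows' `confounders` attribute when present).
#' @return An object of class `"path_model_fits"`: per-outcome coefficient
#'   sets `delta` (total model) and `beta` (outcome model), per-mediator set
#'   `theta`, residual variances, and the fitted row count `n`.
#' @export
fit_path_models <- function(data, outcomes = NULL,
                            mediators = mediator_names(),
                            confounders = NULL) {
  if (is.null(confounders)) {
    confounders <- attr(data, "confounders")
    if (is.null(confounders)) confounders <- confounder_names()
  }
  if (is.null(outcomes)) {
    sens <- isTRUE(attr(data, "sensitivity"))
    outcomes <- intersect(names(outcome_types(sensitivity = sens)), names(data))
  }
  if (nrow(data) == 0L) stop("no rows to fit")
  .check_levels(data$z)
  d <- .path_designs(data, mediators, confounders)

  theta <- lapply(mediators, function(m) fit_ols(data[[m]], d$total))
  names(theta) <- mediators
  delta <- lapply(outcomes, function(q) fit_ols(data[[q]], d$total))
  beta <- lapply(outcomes, function(q) fit_ols(data[[q]], d$outcome))
  names(delta) <- names(beta) <- outcomes

  structure(
    list(n = nrow(data), outcomes = outcomes, mediators = mediators,
         confounders = confounders,
         delta = lapply(delta, `[[`, "coefficients"),
         beta = lapply(beta, `[[`, "coefficients"),
         theta = lapply(theta, `[[`, "coefficients"),
         sigma2 = list(total = vapply(delta, `[[`, numeric(1), "sigma2"),
                       outcome = vapply(beta, `[[`, numeric(1), "sigma2"),
                       mediator = vapply(theta, `[[`, numeric(1), "sigma2"))),
    class = "path_model_fits"
  )
}

#' @export
print.path_model_fits <- function(x, ...) {
  cat(sprintf("<path_model_fits> n = %d; outcomes: %s; mediators: %s\n",
              x$n, paste(x$outcomes, collapse = ", "),
              paste(x$mediators, collapse = ", ")))
  invisible(x)
}

# Effect decomposition from coefficient sets (shared by the full fit and the
# bootstrap replicates). Returns a data.frame in canonical estimand order.
.decompose <- function(delta, beta, theta, outcomes, mediators) {
  dummies <- c("A1", "A2", "A3")
  contrasts <- contrast_names()
  rows <- vector("list", length(outcomes) * 3L)
  k <- 0L
  for (q in outcomes) {
    b <- beta[[q]]
    for (zi in 1:3) {
      direct <- unname(b[dummies[zi]])
      indirect <- vapply(mediators,
                         function(m) unname(theta[[m]][dummies[zi]] * b[m]),
                         numeric(1))
      joint <- sum(indirect)
      total <- unname(delta[[q]][dummies[zi]])
      k <- k + 1L
      rows[[k]] <- data.frame(
        outcome = q, contrast = contrasts[zi],
        effect_type = c("total", "direct", paste0("indirect:", mediators),
                        "joint_indirect"),
        estimate = c(total, direct, indirect, joint),
        identity_gap = total - direct - joint,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Decompose fitted path models into interventional effects
#'
#' For every outcome and exposure contrast (monthly, weekly, daily vs none):
#' the direct effect is the outcome-model exposure coefficient, each
#' per-mediator indirect effect is the product of that mediator's exposure
#' coefficient and its outcome-model coefficient, the joint indirect effect
#' is their sum, and the total effect is the total-model exposure
#' coefficient. The `identity_gap` column reports
#' `total - direct - joint_indirect`, which is zero (to numerical precision)
#' for OLS fits on common rows.
#'
#' @param fits a `"path_model_fits"` object.
#' @return A tidy data.frame with columns `outcome`, `contrast`,
#'   `effect_type` (`total`, `direct`, `indirect:<mediator>`,
#'   `joint_indirect`), `estimate` and `identity_gap`.
#' @export
decompose_effects <- function(fits) {
  stopifnot(inherits(fits, "path_model_fits"))
  .decompose(fits$delta, fits$beta, fits$theta, fits$outcomes, fits$mediators)
}

#' Check the effect-decomposition identity
#'
#' Asserts that `total = direct + joint_indirect` holds for every outcome and
#' contrast up to a numerical tolerance. The identity is algebraically exact
#' for nested OLS fits on identical rows, so a violation signals a fitting
#' bug (e.g. models fitted on different row subsets).
#'
#' @param fits a `"path_model_fits"` object.
#' @param tolerance maximum absolute gap allowed (default `1e-8`).
#' @return List with `pass` (logical) and `max_gap`.
#' @export
verify_decomposition_identity <- function(fits, tolerance = 1e-8) {
  eff <- decompose_effects(fits)
  max_gap <- max(abs(eff$identity_gap))
  if (max_gap > tolerance) {
    stop(sprintf("decomposition identity violated: max |gap| = %.3e exceeds %.1e (models must be OLS fits on identical rows)",
                 max_gap, tolerance))
  }
  list(pass = TRUE, max_gap = max_gap)
}
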