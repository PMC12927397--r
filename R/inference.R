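# Nonparametric bootstrap inference for every interventional estimand, and
# Bonferroni-Holm multiplicity adjustment per outcome.
#
# The resampling unit is the individual respondent row. Replicates that lose
# an exposure level or hit a singular design are redrawn from a deterministic
# per-replicate seed pool, so B stays fixed and results do not depend on
# execution order.

# Estimand values from the three coefficient matrices of one (re)fit.
# thc: p_t x S mediator-model coefficients; dc: p_t x Q total-model;
# bc: p_o x Q outcome-model. Columns ordered as in .path_designs, so the
# exposure dummies sit in rows 2:4 and the mediators in rows 5:(4+S) of bc.
# Output order matches .decompose: outcome-major, then contrast, then
# (total, direct, indirect x S, joint).
.estimates_from_coefs <- function(thc, dc, bc, S) {
  theta1 <- thc[2:4, , drop = FALSE]
  delta1 <- dc[2:4, , drop = FALSE]
  b1 <- bc[2:4, , drop = FALSE]
  bm <- bc[5:(4 + S), , drop = FALSE]
  Q <- ncol(dc)
  out <- numeric(Q * 3L * (S + 3L))
  k <- 0L
  for (q in seq_len(Q)) {
    for (zi in 1:3) {
      ind <- theta1[zi, ] * bm[, q]
      out[k + seq_len(S + 3L)] <- c(delta1[zi, q], b1[zi, q], ind, sum(ind))
      k <- k + S + 3L
    }
  }
  out
}

#' Bootstrap the interventional effect estimates
#'
#' Draws `B` nonparametric bootstrap samples (respondents resampled with
#' replacement), refits all three model sets on each, and recomputes every
#' estimand. A replicate whose resample misses an exposure level or yields a
#' singular design is redrawn from the next seed in that replicate's
#' deterministic seed chunk (budget `retry_budget` draws per replicate), so
#' `B` stays fixed; redraws are counted in `n_failed`. Identical seeds give
#' bit-identical replicate matrices.
#'
#' @param data complete analysis rows.
#' @param B number of bootstrap replicates (study default 1000).
#' @param seed integer root seed.
#' @param outcomes,mediators,confounders as in [fit_path_models()].
#' @param retry_budget maximum draws per replicate slot (default 50).
#' @return An object of class `"bootstrap_effects"`: `estimates` (the
#'   full-sample effect table), `replicates` (`B` x estimand matrix),
#'   `B`, `n_failed`, `seed`, `n`.
#' @export
bootstrap_effects <- function(data, B = 1000L, seed = 1L, outcomes = NULL,
                              mediators = mediator_names(), confounders = NULL,
                              retry_budget = 50L) {
  if (B < 1L) stop("B must be >= 1")
  fits <- fit_path_models(data, outcomes = outcomes, mediators = mediators,
                          confounders = confounders)
  outcomes <- fits$outcomes
  confounders <- fits$confounders
  point <- decompose_effects(fits)

  d <- .path_designs(data, mediators, confounders)
  n <- nrow(data)
  z <- data$z
  M <- as.matrix(data[, mediators, drop = FALSE])
  Y <- as.matrix(data[, outcomes, drop = FALSE])
  S <- length(mediators)
  K <- nrow(point)

  set.seed(as.integer(seed))
  pool <- sample.int(2147483646L, B * retry_budget, replace = TRUE)

  reps <- matrix(NA_real_, nrow = B, ncol = K)
  n_failed <- 0L
  for (b in seq_len(B)) {
    est <- NULL
    for (a in seq_len(retry_budget)) {
      set.seed(pool[(b - 1L) * retry_budget + a])
      idx <- sample.int(n, n, replace = TRUE)
      if (any(tabulate(z[idx] + 1L, nbins = 4L) == 0L)) { n_failed <- n_failed + 1L; next }
      Xt <- d$total[idx, , drop = FALSE]
      Xo <- d$outcome[idx, , drop = FALSE]
      th_fit <- .lm.fit(Xt, M[idx, , drop = FALSE])
      if (th_fit$rank < ncol(Xt)) { n_failed <- n_failed + 1L; next }
      de_fit <- .lm.fit(Xt, Y[idx, , drop = FALSE])
      be_fit <- .lm.fit(Xo, Y[idx, , drop = FALSE])
      if (be_fit$rank < ncol(Xo)) { n_failed <- n_failed + 1L; next }
      est <- .estimates_from_coefs(as.matrix(th_fit$coefficients),
                                   as.matrix(de_fit$coefficients),
                                   as.matrix(be_fit$coefficients), S)
      break
    }
    if (is.null(est)) {
      stop(sprintf("bootstrap retry budget exhausted at replicate %d (%d failed draws); data too sparse to resample",
                   b, n_failed))
    }
    reps[b, ] <- est
  }
  colnames(reps) <- paste(point$outcome, point$contrast, point$effect_type, sep = "|")

  structure(list(estimates = point, replicates = reps, B = as.integer(B),
                 n_failed = n_failed, seed = as.integer(seed), n = n),
            class = "bootstrap_effects")
}

#' @export
print.bootstrap_effects <- function(x, ...) {
  cat(sprintf("<bootstrap_effects> %d estimands, B = %d (n_failed = %d), n = %d, seed = %d\n",
              ncol(x$replicates), x$B, x$n_failed, x$n, x$seed))
  invisible(x)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down familywise-error adjustment: with the raw p-values sorted
#' ascending, `adjusted_(i) = max_(j<=i) min(1, (m - j + 1) * p_(j))`,
#' reported in the original order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Summarise bootstrap replicates
#'
#' Per estimand: bootstrap standard error (sample SD over replicates), 95%
#' confidence interval (percentile method by default: 2.5th/97.5th replicate
#' percentiles with linear interpolation; or normal approximation
#' `estimate +/- z * se`), a two-sided p-value (normal approximation from
#' `z = estimate / se` by default, or percentile-based), and the
#' Bonferroni-Holm adjusted p-value within the configured family.
#'
#' @param boot a `"bootstrap_effects"` object.
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @param p_method `"normal"` (default) or `"percentile"`.
#' @param conf confidence level (default 0.95).
#' @param holm_family `"outcome"` (default: all estimands sharing an outcome,
#'   pooled across contrasts, form one family) or `"outcome_contrast"`.
#' @param alpha significance threshold applied to the adjusted p-values.
#' @return A data.frame (one row per estimand): `outcome`, `contrast`,
#'   `effect_type`, `estimate`, `se`, `ci_low`, `ci_high`, `p_raw`, `p_holm`,
#'   `significant`, `B`, `n_failed`, `seed`; methods recorded in attributes
#'   `ci_method` / `p_method` / `holm_family`.
#' @export
summarize_bootstrap <- function(boot, ci_method = c("percentile", "normal"),
                                p_method = c("normal", "percentile"),
                                conf = 0.95,
                                holm_family = c("outcome", "outcome_contrast"),
                                alpha = 0.05) {
  stopifnot(inherits(boot, "bootstrap_effects"))
  ci_method <- match.arg(ci_method)
  p_method <- match.arg(p_method)
  holm_family <- match.arg(holm_family)
  if (nrow(boot$replicates) < 2L) stop("need at least 2 bootstrap replicates")

  reps <- boot$replicates
  out <- boot$estimates[, c("outcome", "contrast", "effect_type", "estimate")]
  est <- out$estimate
  se <- apply(reps, 2L, stats::sd)
  lo <- (1 - conf) / 2

  if (ci_method == "percentile") {
    qs <- apply(reps, 2L, stats::quantile, probs = c(lo, 1 - lo),
                names = FALSE, type = 7)
    out$ci_low <- qs[1, ]; out$ci_high <- qs[2, ]
  } else {
    zc <- stats::qnorm(1 - lo)
    out$ci_low <- est - zc * se; out$ci_high <- est + zc * se
  }
  out$se <- se

  if (p_method == "normal") {
    p <- ifelse(se > 0, 2 * stats::pnorm(-abs(est / se)),
                ifelse(est == 0, 1, 0))
    if (any(se == 0 & est != 0)) {
      warning("degenerate bootstrap distribution (se = 0) with nonzero estimate; p set to 0")
    }
  } else {
    p <- apply(rbind(est, reps), 2L, function(v) {
      min(1, 2 * min(mean(v[-1] <= 0), mean(v[-1] >= 0)))
    })
  }
  out$p_raw <- p

  fam <- if (holm_family == "outcome") out$outcome
         else paste(out$outcome, out$contrast)
  out$p_holm <- stats::ave(out$p_raw, fam, FUN = holm_adjust)
  out$significant <- out$p_holm < alpha
  out$B <- boot$B
  out$n_failed <- boot$n_failed
  out$seed <- boot$seed
  out <- out[, c("outcome", "contrast", "effect_type", "estimate", "se",
                 "ci_low", "ci_high", "p_raw", "p_holm", "significant",
                 "B", "n_failed", "seed")]
  attr(out, "ci_method") <- ci_method
  attr(out, "p_method") <- p_method
  attr(out, "holm_family") <- holm_family
  attr(out, "alpha") <- alpha
  out
}
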