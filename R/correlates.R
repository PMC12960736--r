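## Weighted logistic fit with design-based (sandwich) covariance.
## Weights are treated as fixed survey weights: bread is the weighted
## expected information, meat the outer product of weighted scores.
wglm_fit <- function(y, X, w) {
  ## quasibinomial: identical IRLS solution, no non-integer-count warnings
  fit <- glm.fit(X, y, weights = w, family = stats::quasibinomial(),
                 control = list(epsilon = 1e-12, maxit = 100))
  if (!fit$converged)
    stop("weighted logistic fit did not converge", call. = FALSE)
  mu <- fit$fitted.values
  W <- w * mu * (1 - mu)
  bread <- solve(crossprod(X, X * W))
  meat <- crossprod(X * (w * (y - mu)))
  list(coef = fit$coefficients, vcov = bread %*% meat %*% bread,
       fitted = mu, converged = fit$converged)
}

## Weighted 2x2 cells of outcome x predictor: a = (1,1), b = (1,0),
## c = (0,1), d = (0,0), in outcome-first notation used below.
weighted_2x2 <- function(y, x, w) {
  c(a = sum(w[y == 1 & x == 1]), b = sum(w[y == 1 & x == 0]),
    c = sum(w[y == 0 & x == 1]), d = sum(w[y == 0 & x == 0]))
}

#' Survey-weighted logistic odds ratio with robust CI
#'
#' Fits the unadjusted weighted logistic regression of a binary outcome on
#' an intercept and a single binary predictor, reporting
#' `OR = exp(coefficient)` with a sandwich (robust) standard error and a
#' Wald interval at `level`. For a binary predictor the weighted MLE
#' coefficient equals the log of the weighted cross-product ratio
#' `ad/bc`, so model-based and table-based estimates coincide. Separation
#' (a zero weighted cell) falls back to a 0.5 continuity correction on the
#' weighted table, with `method = "table+0.5"` flagged in the output.
#'
#' @param outcome binary vector.
#' @param predictor binary vector.
#' @param design a [survey_design()].
#' @param level confidence level (default 0.99).
#' @param outcome_label,predictor_label labels used in the output row.
#' @return One-row data frame: outcome, predictor, or_point, ci_low,
#'   ci_high, log_or_se, p_value, method.
#' @export
weighted_logistic_or <- function(outcome, predictor, design, level = 0.99,
                                 outcome_label = "outcome",
                                 predictor_label = "predictor") {
  y <- check_binary(outcome, "outcome")
  x <- check_binary(predictor, "predictor")
  w <- design$weights
  stopifnot(length(y) == length(w), length(x) == length(w))
  z <- qnorm(1 - (1 - level) / 2)
  cells <- weighted_2x2(y, x, w)
  if (any(cells == 0)) {
    warning("separation (zero weighted cell): using 0.5 continuity correction",
            call. = FALSE)
    cc <- cells + 0.5
    log_or <- log(cc["a"] * cc["d"] / (cc["b"] * cc["c"]))
    se <- sqrt(sum(1 / cc))
    method <- "table+0.5"
  } else {
    fit <- wglm_fit(y, cbind(1, x), w)
    log_or <- fit$coef[2]
    se <- sqrt(fit$vcov[2, 2])
    method <- "mle"
  }
  log_or <- unname(log_or); se <- unname(se)
  data.frame(outcome = outcome_label, predictor = predictor_label,
             or_point = exp(log_or),
             ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
             log_or_se = se,
             p_value = 2 * stats::pnorm(-abs(log_or / se)),
             method = method, stringsAsFactors = FALSE)
}

#' Grid of unadjusted odds ratios: items by demographic indicators
#'
#' Runs [weighted_logistic_or()] for every item/predictor pair, one
#' bivariable model per cell (no mutual adjustment, no multiple-testing
#' correction by default — the wide confidence level is the only guard).
#' Failed cells are recorded with `NA` estimates rather than aborting the
#' grid.
#'
#' @param items 0/1 item matrix.
#' @param predictors data frame (or matrix) of binary indicators.
#' @param design a [survey_design()].
#' @param level confidence level (default 0.99).
#' @param holm if `TRUE`, adds a Holm-adjusted significance column.
#' @return Data frame, one row per item/predictor pair, with a
#'   `significant` flag (CI excludes 1 at `level`).
#' @export
correlate_grid <- function(items, predictors, design, level = 0.99,
                           holm = FALSE) {
  predictors <- as.data.frame(predictors)
  rows <- list()
  for (it in colnames(items)) {
    for (pv in names(predictors)) {
      res <- tryCatch(
        suppressWarnings(
          weighted_logistic_or(items[, it], predictors[[pv]], design,
                               level, it, pv)),
        error = function(e) data.frame(
          outcome = it, predictor = pv, or_point = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, log_or_se = NA_real_,
          p_value = NA_real_, method = paste("failed:", conditionMessage(e)),
          stringsAsFactors = FALSE))
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$ci_low) & (out$ci_low > 1 | out$ci_high < 1)
  if (holm)
    out$significant_holm <- stats::p.adjust(out$p_value, "holm") < 1 - level
  rownames(out) <- NULL
  out
}
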