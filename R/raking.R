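#' Survey design: per-respondent weights with metadata
#'
#' Lightweight container used by every downstream estimator. Weights are
#' strictly positive; `normalization` records the convention (`"sum-to-n"`
#' scales weights to sum to the sample size, `"mean-1"` is the equivalent
#' mean-one scaling). All estimators in the package are ratio estimators,
#' so results are invariant to the convention.
#'
#' @param weights positive numeric vector.
#' @param normalization `"sum-to-n"` (default) or `"mean-1"`.
#' @param convergence optional list of raking metadata.
#' @param trimmed cap applied, if any.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(weights, normalization = c("sum-to-n", "mean-1"),
                          convergence = NULL, trimmed = NULL) {
  normalization <- match.arg(normalization)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive and finite", call. = FALSE)
  n <- length(weights)
  weights <- weights / sum(weights) * n   # both conventions coincide here
  structure(list(weights = weights, normalization = normalization,
                 convergence = convergence, trimmed = trimmed),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("Survey design: n = %d, weight range [%.3f, %.3f]",
              length(x$weights), min(x$weights), max(x$weights)))
  if (!is.null(x$convergence))
    cat(sprintf(", raking converged in %d cycle(s) (max error %.2e)",
                x$convergence$iterations, x$convergence$max_error))
  cat("\n")
  invisible(x)
}

## Normalize/validate a margin table: variable, level, target columns.
validate_margins <- function(margins) {
  stopifnot(is.data.frame(margins),
            all(c("variable", "level", "target") %in% names(margins)))
  margins$level <- as.character(margins$level)
  if (any(margins$target < 0))
    stop("margin targets must be non-negative", call. = FALSE)
  for (v in unique(margins$variable)) {
    s <- sum(margins$target[margins$variable == v])
    if (abs(s - 1) > 1e-6)
      stop(sprintf("targets for '%s' sum to %.6f, not 1", v, s),
           call. = FALSE)
  }
  margins
}

weighted_margin <- function(x, w, levels) {
  tab <- vapply(levels, function(l) sum(w[x == l]), numeric(1))
  tab / sum(w)
}

rake_once <- function(demographics, margins, w, tol, max_iter) {
  vars <- unique(margins$variable)
  cols <- lapply(setNames(vars, vars),
                 function(v) as.character(demographics[[v]]))
  levs <- lapply(setNames(vars, vars),
                 function(v) margins$level[margins$variable == v])
  targ <- lapply(setNames(vars, vars),
                 function(v) margins$target[margins$variable == v])
  for (v in vars) {
    miss <- levs[[v]][targ[[v]] > 0 & !(levs[[v]] %in% unique(cols[[v]]))]
    if (length(miss))
      stop(sprintf("level '%s' of '%s' has positive target but no sample cases",
                   miss[1], v), call. = FALSE)
  }
  max_err <- Inf
  for (it in seq_len(max_iter)) {
    for (v in vars) {
      cur <- weighted_margin(cols[[v]], w, levs[[v]])
      ratio <- ifelse(cur > 0, targ[[v]] / cur, 1)
      w <- w * unname(ratio)[match(cols[[v]], levs[[v]])]
    }
    max_err <- max(vapply(vars, function(v)
      max(abs(weighted_margin(cols[[v]], w, levs[[v]]) - targ[[v]])),
      numeric(1)))
    if (max_err < tol) break
  }
  list(w = w, iterations = it, max_error = max_err)
}

#' Rake weights to population margins (iterative proportional fitting)
#'
#' Cycles through the margin variables, multiplying each respondent's
#' weight by the ratio of the target to the current weighted proportion of
#' their level, until the largest absolute margin error falls below `tol`.
#' With `by` set (typically the country stratum), raking is carried out
#' independently within each stratum and the weights pooled, matching a
#' quota design of separate national samples; stratum weights then sum to
#' the stratum sample sizes.
#'
#' @param demographics data frame holding the margin variables (and `by`).
#' @param margins data frame with columns `variable`, `level`, `target`;
#'   targets are proportions summing to 1 within each variable.
#' @param tol convergence tolerance on margin proportions.
#' @param max_iter maximum number of full cycles.
#' @param trim_cap if finite, weights above `trim_cap` times the median
#'   are capped and the margins re-raked once.
#' @param by optional name of a stratum column raked within.
#' @param base_weights optional starting weights.
#' @return A [survey_design()] carrying convergence metadata.
#' @export
rake <- function(demographics, margins, tol = 1e-6, max_iter = 200,
                 trim_cap = Inf, by = NULL, base_weights = NULL) {
  stopifnot(tol > 0, max_iter >= 1)
  margins <- validate_margins(margins)
  n <- nrow(demographics)
  w <- base_weights %||% rep(1, n)
  run <- function(idx) {
    res <- rake_once(demographics[idx, , drop = FALSE], margins,
                     w[idx], tol, max_iter)
    if (res$max_error >= tol)
      stop(sprintf("raking did not converge in %d cycles (max margin error %.3e)",
                   max_iter, res$max_error), call. = FALSE)
    if (is.finite(trim_cap)) {
      cap <- trim_cap * stats::median(res$w)
      if (any(res$w > cap)) {
        res2 <- rake_once(demographics[idx, , drop = FALSE], margins,
                          pmin(res$w, cap), tol, 1)
        res$w <- res2$w
        res$max_error <- res2$max_error
        res$trimmed <- cap
      }
    }
    res
  }
  if (is.null(by)) {
    res <- run(seq_len(n))
    w <- res$w
    meta <- list(iterations = res$iterations, max_error = res$max_error,
                 tol = tol)
  } else {
    strata <- demographics[[by]]
    iters <- 0; err <- 0
    for (s in unique(strata)) {
      idx <- which(strata == s)
      res <- run(idx)
      w[idx] <- res$w / sum(res$w) * length(idx)
      iters <- max(iters, res$iterations)
      err <- max(err, res$max_error)
    }
    meta <- list(iterations = iters, max_error = err, tol = tol, by = by)
  }
  survey_design(w, convergence = meta,
                trimmed = if (is.finite(trim_cap)) trim_cap else NULL)
}

#' Compare weighted sample margins against targets
#'
#' @param design a [survey_design()].
#' @param demographics data frame with the margin variables.
#' @param margins margin table as for [rake()].
#' @return Data frame: variable, level, unweighted, weighted, target,
#'   absolute error.
#' @export
margin_report <- function(design, demographics, margins) {
  margins <- validate_margins(margins)
  if (length(design$weights) != nrow(demographics))
    stop("design and demographics are not conformable", call. = FALSE)
  w <- design$weights
  out <- lapply(unique(margins$variable), function(v) {
    lv <- margins$level[margins$variable == v]
    tg <- margins$target[margins$variable == v]
    x <- as.character(demographics[[v]])
    uw <- weighted_margin(x, rep(1, length(x)), lv)
    ww <- weighted_margin(x, w, lv)
    data.frame(variable = v, level = lv, unweighted = uw, weighted = ww,
               target = tg, abs_error = abs(ww - tg), row.names = NULL)
  })
  do.call(rbind, out)
}
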