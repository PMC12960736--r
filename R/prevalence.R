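#' Dichotomize the raw item battery
#'
#' Behaviour and feeling items are coded 1 for "yes" and 0 for "no",
#' "maybe" or "unsure". The likely-contact composite is 1 if the response
#' to any of its three age brackets is "very likely" or "definitely"
#' (versus "never", "unlikely" or "maybe").
#'
#' @param raw data frame of raw responses.
#' @param item_cols named character vector mapping the nine single-item
#'   labels to raw column names; defaults to identical names.
#' @param bracket_cols raw column names of the three likely-contact age
#'   brackets (14 and under, 12 and under, under 10).
#' @return Integer 0/1 matrix with the ten canonical item labels,
#'   class `item_battery`.
#' @export
encode_items <- function(raw,
                         item_cols = NULL,
                         bracket_cols = c("likely_12_14", "likely_10_12",
                                          "likely_u10")) {
  singles <- setdiff(item_labels(), "likely_contact_u14")
  item_cols <- item_cols %||% setNames(singles, singles)
  yesno_levels <- c("no", "maybe", "unsure", "yes")
  likely_levels <- c("never", "unlikely", "maybe", "very likely",
                     "definitely")
  need <- c(unname(item_cols), bracket_cols)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing raw columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  check_levels <- function(x, levels, col) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad))
      stop(sprintf("unknown response level(s) in '%s': %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- matrix(0L, nrow(raw), 10, dimnames = list(NULL, item_labels()))
  for (lab in names(item_cols)) {
    col <- item_cols[[lab]]
    check_levels(raw[[col]], yesno_levels, col)
    out[, lab] <- as.integer(raw[[col]] == "yes")
  }
  hit <- rep(FALSE, nrow(raw))
  for (col in bracket_cols) {
    check_levels(raw[[col]], likely_levels, col)
    hit <- hit | raw[[col]] %in% c("very likely", "definitely")
  }
  out[, "likely_contact_u14"] <- as.integer(hit)
  class(out) <- c("item_battery", class(out))
  out
}

#' Design-based prevalence with linearized confidence intervals
#'
#' Point estimate is the weighted proportion (a ratio estimator); its
#' variance comes from Taylor linearization with an `n/(n-1)` small-sample
#' factor. The default interval is Wald on the logit scale,
#' back-transformed, which respects the \[0,1\] bounds and reproduces the
#' asymmetry typical of rare items; `ci_method = "wald"` gives the plain
#' linear interval. Degenerate estimates (all 0s or all 1s) get a
#' one-sided exact-binomial-style bound on the effective sample size and
#' are flagged.
#'
#' @param items binary vector, or a 0/1 matrix of items (one estimate per
#'   column).
#' @param design a [survey_design()].
#' @param level confidence level (default 0.99).
#' @param by optional grouping factor (one estimate per item and group).
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @return Data frame: item, group, point, ci_low, ci_high, n_eff,
#'   degenerate.
#' @export
weighted_prevalence <- function(items, design, level = 0.99, by = NULL,
                                ci_method = c("logit", "wald")) {
  ci_method <- match.arg(ci_method)
  if (is.null(dim(items)))
    items <- matrix(items, ncol = 1, dimnames = list(NULL, "item"))
  w <- design$weights
  stopifnot(nrow(items) == length(w), level > 0, level < 1)
  groups <- if (is.null(by)) factor(rep("all", nrow(items))) else
    factor(by)
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (j in seq_len(ncol(items))) {
    y <- check_binary(items[, j], colnames(items)[j])
    for (g in levels(groups)) {
      idx <- groups == g
      wg <- w[idx]; yg <- y[idx]
      if (sum(wg) <= 0)
        stop("zero total weight in group '", g, "'", call. = FALSE)
      ng <- length(wg)
      pt <- wmean(yg, wg)
      ne <- n_eff(wg)
      if (pt %in% c(0, 1)) {
        alpha <- (1 - level) / 2
        bound <- 1 - alpha^(1 / ne)
        ci <- if (pt == 0) c(0, bound) else c(1 - bound, 1)
        rows[[length(rows) + 1]] <- data.frame(
          item = colnames(items)[j], group = g, point = pt,
          ci_low = ci[1], ci_high = ci[2], n_eff = ne, degenerate = TRUE)
        next
      }
      infl <- wg * (yg - pt) / sum(wg)
      v <- ng / (ng - 1) * sum(infl^2)
      if (ci_method == "logit") {
        se_logit <- sqrt(v) / (pt * (1 - pt))
        ci <- plogis(qlogis(pt) + c(-1, 1) * z * se_logit)
      } else {
        ci <- pmin(pmax(pt + c(-1, 1) * z * sqrt(v), 0), 1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        item = colnames(items)[j], group = g, point = pt,
        ci_low = ci[1], ci_high = ci[2], n_eff = ne, degenerate = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rao-Scott second-order adjusted-F test of independence
#'
#' Computes the Pearson chi-square on the weighted cell proportions of the
#' item-by-group table, estimates the design-based covariance of the
#' independence residuals by Taylor linearization, and corrects the
#' reference distribution with the generalized design effects (the
#' eigenvalues \eqn{\lambda_k} of the product of the inverse multinomial
#' covariance and the design covariance). The reported statistic is
#' \deqn{F = X^2 / \sum_k \lambda_k,} referred to an F distribution with
#' Satterthwaite degrees of freedom
#' \eqn{df_1 = (\sum\lambda)^2/\sum\lambda^2} and
#' \eqn{df_2 = df_1 (n - 1)}. With equal weights every \eqn{\lambda_k = 1}
#' and the test reduces to the classical Pearson-based F approximation
#' \eqn{X^2/d} on \eqn{(d, d(n-1))} degrees of freedom.
#'
#' @param item binary vector (or any factor-like variable).
#' @param group grouping variable with at least two levels.
#' @param design a [survey_design()].
#' @return An object of class `rao_scott`: list with `F_stat`, `df1`,
#'   `df2`, `p_value`, `X2`, `lambda` and the mean generalized design
#'   effect `first_order_deff`.
#' @export
rao_scott_test <- function(item, group, design) {
  y <- factor(item)
  g <- factor(group)
  w <- design$weights
  n <- length(w)
  stopifnot(length(y) == n, length(g) == n)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  for (lv in levels(g))
    if (sum(w[g == lv]) <= 0)
      stop("zero weighted count in group '", lv, "'", call. = FALSE)
  R <- nlevels(y); C <- nlevels(g)
  wt <- w / sum(w)
  ## joint, row and column weighted proportions
  P <- matrix(0, R, C)
  for (r in seq_len(R)) for (c in seq_len(C))
    P[r, c] <- sum(wt[y == levels(y)[r] & g == levels(g)[c]])
  pr <- rowSums(P); pc <- colSums(P)
  E <- outer(pr, pc)
  X2 <- n * sum((P - E)^2 / E)
  d <- (R - 1) * (C - 1)
  ## linearized covariance of the independence residuals h_rc over the
  ## free cells (drop last row and column)
  free <- expand.grid(r = seq_len(R - 1), c = seq_len(C - 1))
  U <- matrix(0, n, d)
  yi <- as.integer(y); gi <- as.integer(g)
  for (k in seq_len(d)) {
    r <- free$r[k]; c <- free$c[k]
    drc <- as.numeric(yi == r & gi == c)
    dr <- as.numeric(yi == r)
    dc <- as.numeric(gi == c)
    U[, k] <- wt * ((drc - P[r, c]) - pc[c] * (dr - pr[r]) -
                      pr[r] * (dc - pc[c]))
  }
  Vh <- crossprod(U)
  ## multinomial (SRS) covariance of the same residuals, via the
  ## Jacobian applied to (diag(p) - p p')/n
  ## Jacobian dh_rc / dp_{r'c'} = [r'=r][c'=c] - pc_c [r'=r] - pr_r [c'=c]
  A <- matrix(0, d, R * C)
  cell <- function(r, c) (c - 1) * R + r
  for (k in seq_len(d)) {
    r <- free$r[k]; c <- free$c[k]
    for (rr in seq_len(R)) for (cc in seq_len(C)) {
      A[k, cell(rr, cc)] <- (rr == r && cc == c) - pc[c] * (rr == r) -
        pr[r] * (cc == c)
    }
  }
  pvec <- as.numeric(P)           # column-major: cell(r,c) indexing
  Cmat <- (diag(pvec) - tcrossprod(pvec)) / n
  V0 <- A %*% Cmat %*% t(A)
  lambda <- Re(eigen(solve(V0, Vh), only.values = TRUE)$values)
  F_stat <- X2 / sum(lambda)
  df1 <- sum(lambda)^2 / sum(lambda^2)
  df2 <- df1 * (n - 1)
  structure(list(F_stat = F_stat, df1 = df1, df2 = df2,
                 p_value = pf(F_stat, df1, df2, lower.tail = FALSE),
                 X2 = X2, lambda = lambda,
                 first_order_deff = mean(lambda)),
            class = "rao_scott")
}

#' @export
print.rao_scott <- function(x, ...) {
  cat(sprintf("Rao-Scott adjusted F(%.2f, %.2f) = %.3f, p = %.4g (mean deff %.3f)\n",
              x$df1, x$df2, x$F_stat, x$p_value, x$first_order_deff))
  invisible(x)
}
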