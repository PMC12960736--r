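#' Weighted co-endorsement overlap and odds-ratio matrices
#'
#' For every pair of items builds the weighted 2x2 table and reports the
#' row-proportion overlap matrix (entry (i, j) is the weighted share of
#' i-endorsers who also endorse j) and the pairwise odds-ratio matrix on
#' the weighted cells, with Wald significance flags on the log OR. Pairs
#' with an empty weighted cell get a 0.5 continuity correction and are
#' flagged.
#'
#' @param items 0/1 item matrix with column labels.
#' @param design a [survey_design()].
#' @param alpha significance threshold for the per-pair Wald flag
#'   (default 0.01).
#' @return An object of class `coendorsement_table`: list with `n_vec`
#'   (weighted endorsement count per item), `N` (weighted total),
#'   `rowprop`, `or_mat`, `se_mat`, `significant`, `corrected`.
#' @export
coendorsement_table <- function(items, design, alpha = 0.01) {
  p <- ncol(items)
  if (p < 2) stop("need at least two items", call. = FALSE)
  w <- design$weights
  stopifnot(nrow(items) == length(w))
  for (j in seq_len(p)) check_binary(items[, j], colnames(items)[j])
  labels <- colnames(items)
  N <- sum(w)
  n_vec <- setNames(as.numeric(crossprod(items, w)), labels)
  joint <- crossprod(items, items * w)        # weighted a-cells
  rowprop <- sweep(joint, 1, n_vec, "/")
  diag(rowprop) <- NA_real_
  or_mat <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  se_mat <- or_mat
  sig <- matrix(NA, p, p, dimnames = list(labels, labels))
  corrected <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  zcrit <- qnorm(1 - alpha / 2)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    a <- joint[i, j]
    b <- n_vec[i] - a
    cc <- n_vec[j] - a
    d <- N - n_vec[i] - n_vec[j] + a
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) {
      cells <- cells + 0.5
      corrected[i, j] <- corrected[j, i] <- TRUE
    }
    lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
    se <- sqrt(sum(1 / cells))
    or_mat[i, j] <- or_mat[j, i] <- exp(lor)
    se_mat[i, j] <- se_mat[j, i] <- se
    sig[i, j] <- sig[j, i] <- abs(lor / se) > zcrit
  }
  structure(list(labels = labels, n_vec = n_vec, N = N,
                 rowprop = rowprop, or_mat = or_mat, se_mat = se_mat,
                 significant = sig, corrected = corrected, alpha = alpha),
            class = "coendorsement_table")
}

#' @export
print.coendorsement_table <- function(x, digits = 2, ...) {
  cat(sprintf("Co-endorsement table: %d items, weighted N = %.1f\n",
              length(x$labels), x$N))
  cat("Pairwise ORs (weighted cells):\n")
  print(round(x$or_mat, digits))
  invisible(x)
}

#' Tidy one-row-per-pair view of a co-endorsement table
#'
#' @param x a [coendorsement_table()] result.
#' @param ... unused.
#' @return Data frame: item_i, item_j, n_i, n_j, rowprop_ij, rowprop_ji,
#'   odds_ratio, significant, corrected.
#' @export
as.data.frame.coendorsement_table <- function(x, ...) {
  p <- length(x$labels)
  idx <- which(upper.tri(x$or_mat), arr.ind = TRUE)
  data.frame(
    item_i = x$labels[idx[, 1]], item_j = x$labels[idx[, 2]],
    n_i = x$n_vec[idx[, 1]], n_j = x$n_vec[idx[, 2]],
    rowprop_ij = x$rowprop[idx], rowprop_ji = x$rowprop[idx[, c(2, 1)]],
    odds_ratio = x$or_mat[idx], significant = x$significant[idx],
    corrected = x$corrected[idx], row.names = NULL)
}

#' Reconstruct a pairwise odds ratio from printed margins
#'
#' Given a total `N`, two endorsement counts and the row-proportion
#' overlap `rowprop_ij` (share of i-endorsers who endorse j), recovers the
#' implied joint count `a = rowprop_ij * n_i` and the 2x2 odds ratio
#' \deqn{OR = \frac{a\,(N - n_i - n_j + a)}{(n_i - a)(n_j - a)}.}
#' This is the identity used to audit published overlap tables whose
#' underlying microdata are unavailable: the printed margins fully
#' determine the OR up to rounding of the printed proportions.
#'
#' @param N total (weighted) sample size.
#' @param n_i,n_j (weighted) endorsement counts of the two items.
#' @param rowprop_ij overlap proportion in (0, 1].
#' @return The implied odds ratio (scalar).
#' @export
or_from_margins <- function(N, n_i, n_j, rowprop_ij) {
  stopifnot(n_i > 0, n_j > 0, n_i < N, n_j < N,
            rowprop_ij > 0, rowprop_ij <= 1)
  a <- rowprop_ij * n_i
  if (a > min(n_i, n_j) + 1e-9)
    stop("inconsistent margins: implied joint count exceeds a margin",
         call. = FALSE)
  d <- N - n_i - n_j + a
  if (d < 0)
    stop("inconsistent margins: implied negative (0,0) cell", call. = FALSE)
  a * d / ((n_i - a) * (n_j - a))
}
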