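#' Ground-truth Ising model for binary co-endorsement items
#'
#' Defines a pairwise binary Markov random field on \{0,1\}-coded items:
#' \deqn{P(x) \propto \exp(\tau^\top x + \sum_{i<j} \omega_{ij} x_i x_j).}
#' On this coding \eqn{\tau_i} is the log-odds of item \eqn{i} when all
#' other items are 0, and \eqn{\omega_{ij}} is the conditional log
#' odds-ratio of the pair given the rest — the quantity the network
#' estimator reports as an edge OR.
#'
#' @param tau numeric threshold vector (baseline log-odds per item).
#' @param omega symmetric numeric matrix of pairwise interactions with a
#'   zero diagonal, in conditional log-OR units.
#' @param beta optional item-by-covariate matrix of threshold shifts; row
#'   names must match `labels`, column names name covariates.
#' @param labels item names; defaults to `v1..vp`.
#' @return An object of class `ising_truth` with elements `p`, `tau`,
#'   `omega`, `beta`, `labels` and the recorded off-diagonal `sparsity`
#'   (fraction of zero upper-triangle entries).
#' @export
ising_truth <- function(tau, omega, beta = NULL, labels = NULL) {
  p <- length(tau)
  omega <- as.matrix(omega)
  if (!all(dim(omega) == p))
    stop("omega must be a ", p, "x", p, " matrix", call. = FALSE)
  if (!isTRUE(all.equal(omega, t(omega), tolerance = 1e-12)))
    stop("omega must be symmetric", call. = FALSE)
  if (any(diag(omega) != 0))
    stop("omega must have a zero diagonal", call. = FALSE)
  if (!all(is.finite(tau)) || !all(is.finite(omega)))
    stop("tau and omega must be finite", call. = FALSE)
  labels <- labels %||% paste0("v", seq_len(p))
  stopifnot(length(labels) == p, !anyDuplicated(labels))
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (nrow(beta) != p)
      stop("beta must have one row per item", call. = FALSE)
    rownames(beta) <- rownames(beta) %||% labels
  }
  ut <- omega[upper.tri(omega)]
  structure(
    list(p = p, tau = as.numeric(tau), omega = omega, beta = beta,
         labels = labels, sparsity = mean(ut == 0)),
    class = "ising_truth")
}

#' @export
print.ising_truth <- function(x, ...) {
  cat(sprintf("Ising ground truth: %d items, %d nonzero edges (sparsity %.2f)\n",
              x$p, sum(x$omega[upper.tri(x$omega)] != 0), x$sparsity))
  invisible(x)
}

#' Enumerate all states of a binary Ising model
#'
#' @param p number of items (at most 20; the state space is `2^p`).
#' @return Integer matrix with `2^p` rows, one 0/1 state per row.
#' @export
ising_states <- function(p) {
  if (p > 20) stop("exact enumeration limited to p <= 20", call. = FALSE)
  k <- seq_len(2^p) - 1L
  m <- sapply(seq_len(p), function(j) bitwAnd(bitwShiftR(k, j - 1L), 1L))
  matrix(as.integer(m), ncol = p)
}

## Unnormalized log-weights of all states for thresholds tau (vector, or a
## matrix with one column per threshold profile).
ising_log_weights <- function(states, tau, omega) {
  pair <- rowSums((states %*% omega) * states) / 2
  if (is.matrix(tau)) states %*% tau + pair else
    as.numeric(states %*% tau + pair)
}

#' Exact state probabilities of an Ising model
#'
#' @param truth an [ising_truth()] object (or a list with `tau`, `omega`).
#' @param tau optional replacement threshold vector.
#' @return Numeric vector of length `2^p`, ordered as [ising_states()].
#' @export
ising_state_probs <- function(truth, tau = NULL) {
  tau <- tau %||% truth$tau
  st <- ising_states(length(tau))
  lw <- ising_log_weights(st, tau, truth$omega)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Exact marginal item prevalences by enumeration
#' @inheritParams ising_state_probs
#' @return Named numeric vector of `P(x_i = 1)` per item.
#' @export
ising_marginals <- function(truth, tau = NULL) {
  pr <- ising_state_probs(truth, tau)
  st <- ising_states(length(tau %||% truth$tau))
  setNames(as.numeric(crossprod(st, pr)), truth$labels)
}

#' Calibrate Ising thresholds to target marginal prevalences
#'
#' Fixed-point iteration on the log-odds scale: each threshold is shifted
#' by the gap between the target and current marginal logit, with the
#' marginals recomputed by exact enumeration at each step.
#'
#' @param omega symmetric interaction matrix.
#' @param target_prev target marginal prevalences in (0, 1).
#' @param tol convergence tolerance on marginal prevalences.
#' @param max_iter iteration cap.
#' @return Threshold vector `tau` such that the model marginals match
#'   `target_prev` within `tol`.
#' @export
calibrate_thresholds <- function(omega, target_prev, tol = 1e-8,
                                 max_iter = 500) {
  p <- length(target_prev)
  stopifnot(all(target_prev > 0), all(target_prev < 1))
  truth <- ising_truth(rep(0, p), omega)
  tau <- qlogis(target_prev)
  for (it in seq_len(max_iter)) {
    m <- ising_marginals(truth, tau)
    if (max(abs(m - target_prev)) < tol) return(tau)
    tau <- tau + (qlogis(target_prev) - qlogis(m))
  }
  stop("threshold calibration did not converge", call. = FALSE)
}

#' Simulate respondents from an Ising model
#'
#' `method = "exact"` enumerates all `2^p` states and samples rows i.i.d.
#' from the normalized distribution (requires `p <= 20`). `method =
#' "gibbs"` runs a single-site Gibbs sampler (one chain; `burnin` full
#' sweeps discarded, every `thin`-th sweep kept), for models too large to
#' enumerate. Defaults (1000 burn-in sweeps, thinning 10) keep the
#' empirical state distribution within total-variation distance 0.02 of
#' the exact one at moderate p; see the package vignette.
#'
#' @param truth an [ising_truth()] object.
#' @param n number of respondents to draw.
#' @param method `"exact"` or `"gibbs"`.
#' @param seed optional integer seed (R RNG).
#' @param burnin,thin Gibbs controls, ignored for `method = "exact"`.
#' @return `n` by `p` integer 0/1 matrix with item labels as column names.
#' @export
simulate_ising <- function(truth, n, method = c("exact", "gibbs"),
                           seed = NULL, burnin = 1000, thin = 10) {
  method <- match.arg(method)
  stopifnot(inherits(truth, "ising_truth"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- truth$p
  if (method == "exact") {
    if (p > 20)
      stop("p > 20: exact enumeration infeasible, use method = 'gibbs'",
           call. = FALSE)
    pr <- ising_state_probs(truth)
    idx <- sample.int(length(pr), n, replace = TRUE, prob = pr)
    x <- ising_states(p)[idx, , drop = FALSE]
  } else {
    x <- gibbs_sample_cpp(truth$tau, truth$omega, as.integer(n),
                          as.integer(burnin), as.integer(thin))
  }
  colnames(x) <- truth$labels
  x
}

## Exact sampling where each respondent has their own threshold profile.
## Profiles are grouped so each distinct threshold vector is enumerated
## once; used by attach_demographics().
simulate_ising_profiles <- function(tau_mat, omega, labels) {
  p <- ncol(tau_mat)
  if (p > 14)
    stop("profile-wise enumeration limited to p <= 14", call. = FALSE)
  key <- apply(tau_mat, 1, paste, collapse = ",")
  uk <- unique(key)
  grp <- match(key, uk)
  st <- ising_states(p)
  utau <- t(tau_mat[match(uk, key), , drop = FALSE])   # p x U
  lw <- ising_log_weights(st, utau, omega)             # 2^p x U
  lw <- sweep(lw, 2, apply(lw, 2, max))
  w <- exp(lw)
  pru <- sweep(w, 2, colSums(w), "/")
  n <- nrow(tau_mat)
  out <- matrix(0L, n, p, dimnames = list(NULL, labels))
  for (u in seq_along(uk)) {
    rows <- which(grp == u)
    idx <- sample.int(nrow(st), length(rows), replace = TRUE, prob = pru[, u])
    out[rows, ] <- st[idx, , drop = FALSE]
  }
  out
}

#' Built-in ground-truth presets
#'
#' `"sparse10"` is the default stated world: 10 items carrying the
#' canonical co-endorsement battery labels, 12 nonzero edges with weights
#' spread over \[0.5, 1.5\] (conditional log-OR scale), and thresholds
#' calibrated by exact enumeration so the marginal prevalences equal the
#' pooled prevalence profile of rare survey items (2.4\%–8.0\%).
#' `"independence10"` keeps the same marginals with all edges zero.
#'
#' @param name preset name.
#' @return An [ising_truth()] object.
#' @export
ising_preset <- function(name = c("sparse10", "independence10")) {
  name <- match.arg(name)
  labels <- item_labels()
  target <- item_target_prevalence()
  p <- 10
  omega <- matrix(0, p, p, dimnames = list(labels, labels))
  if (name == "sparse10") {
    edges <- list(
      c("flirted_online", "webcam_child", 1.50),
      c("webcam_child", "purchased_csam", 1.40),
      c("purchased_csam", "likely_contact_u14", 1.30),
      c("viewed_csam", "contact_child", 1.20),
      c("viewed_csam", "likely_contact_u14", 1.10),
      c("viewed_csam", "concerned", 1.00),
      c("would_view_csam", "would_watch_webcam", 0.90),
      c("would_watch_webcam", "feelings", 0.80),
      c("viewed_csam", "would_view_csam", 0.70),
      c("feelings", "likely_contact_u14", 0.60),
      c("concerned", "likely_contact_u14", 0.55),
      c("contact_child", "likely_contact_u14", 0.50))
    for (e in edges) {
      omega[e[1], e[2]] <- omega[e[2], e[1]] <- as.numeric(e[3])
    }
  }
  tau <- calibrate_thresholds(omega, target)
  ising_truth(tau, omega, labels = labels)
}

## Canonical short labels of the 10-item battery, in reporting order.
item_labels <- function() {
  c("viewed_csam", "contact_child", "flirted_online", "webcam_child",
    "purchased_csam", "would_view_csam", "would_watch_webcam",
    "feelings", "concerned", "likely_contact_u14")
}

## Pooled prevalence profile the presets are calibrated to (proportions).
item_target_prevalence <- function() {
  setNames(c(0.035, 0.046, 0.047, 0.024, 0.027,
             0.055, 0.057, 0.080, 0.057, 0.074), item_labels())
}
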