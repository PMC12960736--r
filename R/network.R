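#' L1-penalised weighted logistic coefficient path
#'
#' Solves, over a decreasing penalty grid, the weighted lasso logistic
#' problem
#' \deqn{\min_{\beta_0,\beta}\; -\tfrac1n \sum_i w_i \ell_i(\beta_0,\beta)
#'   + \lambda \lVert\beta\rVert_1}
#' with the intercept unpenalised (weights are normalized to mean 1, so
#' \eqn{\lambda} is on the per-observation scale). The grid defaults to
#' 100 log-spaced values from the KKT critical penalty
#' \eqn{\lambda_{max} = \max_j |\tfrac1n\sum_i w_i x_{ij}(y_i-\bar
#' y_w)|} — the smallest penalty with an all-zero slope vector — down to
#' \eqn{10^{-3}\lambda_{max}}. Fitting is delegated to coordinate descent
#' (glmnet) with warm starts; solutions are deterministic given inputs.
#'
#' @param y binary outcome vector.
#' @param X 0/1 matrix of the remaining items (predictors).
#' @param weights observation weights (survey weights).
#' @param lambda optional strictly decreasing penalty grid; computed from
#'   the KKT bound when `NULL`.
#' @param nlambda,lambda_min_ratio grid size and lower endpoint ratio.
#' @param standardize standardize predictors before penalisation
#'   (default `TRUE`; coefficients are always reported on the original
#'   0/1 scale). Standardization changes which edges are selected and is
#'   therefore surfaced as a first-class argument.
#' @return List of class `penalized_path`: `lambda`, `a0` (intercepts),
#'   `beta` (p x nlambda coefficient matrix), `fit` (the glmnet object).
#' @export
penalized_logistic_path <- function(y, X, weights = rep(1, length(y)),
                                    lambda = NULL, nlambda = 100,
                                    lambda_min_ratio = 1e-3,
                                    standardize = TRUE) {
  y <- check_binary(y, "y")
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) check_binary(X[, j], "X columns")
  stopifnot(length(weights) == length(y), all(weights > 0))
  w <- weights / mean(weights)
  if (!is.null(lambda)) {
    if (any(diff(lambda) >= 0))
      stop("lambda grid must be strictly decreasing", call. = FALSE)
  } else {
    n <- length(y)
    ybar <- wmean(y, w)
    xs <- if (standardize) {
      mu <- colSums(w * X) / n
      s <- sqrt(colSums(w * sweep(X, 2, mu)^2) / n)
      sweep(sweep(X, 2, mu), 2, pmax(s, 1e-12), "/")
    } else X
    lambda_max <- max(abs(crossprod(xs, w * (y - ybar)))) / n
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  }
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", weights = w,
                   lambda = lambda, standardize = standardize,
                   thresh = 1e-10))
  if (fit$jerr != 0)
    stop("penalised path did not converge (glmnet error ", fit$jerr, ")",
         call. = FALSE)
  beta <- as.matrix(fit$beta)
  structure(list(lambda = fit$lambda, a0 = as.numeric(fit$a0),
                 beta = beta, fit = fit),
            class = "penalized_path")
}

## Response-scale predictions from a fitted glmnet path at the requested
## penalties. glmnet can stop a path early on degenerate folds (rare
## outcomes), so each requested penalty maps to the nearest fitted one
## and the last converged solution covers the truncated tail.
predict_path <- function(fit, X, lambda) {
  a0 <- as.numeric(fit$a0)
  beta <- as.matrix(fit$beta)
  idx <- vapply(lambda, function(l) which.min(abs(fit$lambda - l)),
                integer(1))
  eta <- sweep(X %*% beta[, idx, drop = FALSE], 2, a0[idx], "+")
  plogis(eta)
}

## Stratified K-fold assignment: permutes within each outcome class so
## every fold sees both classes whenever the rare class has >= K cases.
stratified_folds <- function(y, K) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
    stop("a fold has a single-class outcome even under stratification; ",
         "reduce K or pool items", call. = FALSE)
  fold
}

#' Cross-validated one-standard-error penalty selection
#'
#' K-fold cross-validation (folds stratified by the outcome to protect
#' rare items) of the penalised path under the binomial deviance loss.
#' `lambda_min` minimises the mean CV deviance; `lambda_1se` is the
#' largest penalty whose mean CV deviance is within one standard error of
#' that minimum — the sparser model the estimator reports. Out-of-fold
#' predictions at `lambda_1se` yield the reported CV AUC and deviance.
#'
#' @inheritParams penalized_logistic_path
#' @param K number of folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @return List: `lambda`, `cvm`, `cvse`, `lambda_min`, `lambda_1se`,
#'   `cv_auc`, `cv_deviance`, `fold`, plus the full-data `path`.
#' @export
cv_one_se <- function(y, X, weights = rep(1, length(y)), K = 10,
                      seed = 1L, standardize = TRUE) {
  stopifnot(K >= 2, length(y) >= K)
  w <- weights / mean(weights)
  path <- penalized_logistic_path(y, X, w, standardize = standardize)
  lam <- path$lambda
  set.seed(seed)
  fold <- stratified_folds(y, K)
  loss <- matrix(NA_real_, K, length(lam))
  oof <- rep(NA_real_, length(y))
  for (k in seq_len(K)) {
    tr <- fold != k; te <- !tr
    fit <- suppressWarnings(
      glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                     family = "binomial", weights = w[tr],
                     lambda = lam, standardize = standardize,
                     thresh = 1e-10))
    pred <- predict_path(fit, X[te, , drop = FALSE], lam)
    loss[k, ] <- vapply(seq_along(lam), function(l)
      binomial_deviance(y[te], pred[, l], w[te]), numeric(1))
  }
  cvm <- colMeans(loss)
  cvse <- apply(loss, 2, sd) / sqrt(K)
  i_min <- which.min(cvm)
  lambda_min <- lam[i_min]
  ok <- cvm <= cvm[i_min] + cvse[i_min]
  lambda_1se <- max(lam[ok])
  i_1se <- which(lam == lambda_1se)
  for (k in seq_len(K)) {
    te <- fold == k
    fit <- suppressWarnings(
      glmnet::glmnet(X[!te, , drop = FALSE], y[!te],
                     family = "binomial", weights = w[!te],
                     lambda = lam, standardize = standardize,
                     thresh = 1e-10))
    oof[te] <- predict_path(fit, X[te, , drop = FALSE], lambda_1se)
  }
  list(lambda = lam, cvm = cvm, cvse = cvse,
       lambda_min = lambda_min, lambda_1se = lambda_1se,
       cv_auc = weighted_auc(y, oof, w),
       cv_deviance = binomial_deviance(y, oof, w),
       fold = fold, path = path)
}

#' Nodewise penalised fits for all items
#'
#' For each item fits the penalised logistic regression of that item on
#' the remaining items with [cv_one_se()]; the support at `lambda_1se`
#' feeds the AND-rule edge selection.
#'
#' @param items 0/1 item matrix with column labels.
#' @param design a [survey_design()].
#' @param K CV folds.
#' @param seed master seed; each node gets a derived sub-seed.
#' @param standardize passed through to the penalised fits.
#' @param penalty_scale multiplier applied to each node's `lambda_1se`
#'   before reading off the support (support is taken at the smallest
#'   grid penalty at or above the scaled value); 1 is the plain
#'   one-standard-error rule, larger values give sparser graphs.
#' @return Named list of per-node fits, each carrying `support`,
#'   `lambda_min`, `lambda_1se`, `cv_auc`, `cv_deviance`, `n_selected`.
#' @export
nodewise_fits <- function(items, design, K = 10, seed = 1L,
                          standardize = TRUE, penalty_scale = 1) {
  stopifnot(penalty_scale > 0)
  labels <- colnames(items)
  fits <- list()
  for (j in seq_along(labels)) {
    y <- items[, j]
    X <- items[, -j, drop = FALSE]
    cv <- cv_one_se(y, X, design$weights, K = K,
                    seed = derive_seed(seed, j), standardize = standardize)
    lam_sel <- cv$lambda_1se * penalty_scale
    at <- which(cv$path$lambda >= lam_sel)
    at <- if (length(at)) max(at) else 1L
    b <- cv$path$beta[, at]
    b_min <- cv$path$beta[, which(cv$path$lambda == cv$lambda_min)]
    support <- colnames(X)[b != 0]
    fits[[labels[j]]] <- list(
      node = labels[j], support = support, n_selected = length(support),
      lambda_min = cv$lambda_min, lambda_1se = cv$lambda_1se,
      cv_auc = cv$cv_auc, cv_deviance = cv$cv_deviance,
      cvm = cv$cvm, cvse = cv$cvse, lambda = cv$lambda,
      coef_1se = b, coef_min = b_min)
  }
  fits
}

#' AND-rule edge selection from nodewise supports
#'
#' An undirected edge (i, j) is retained only when item j is in the
#' support of item i's model *and* item i is in the support of item j's
#' model; one-sided selections are discarded.
#'
#' @param node_fits result of [nodewise_fits()].
#' @return Symmetric logical adjacency matrix with a zero diagonal.
#' @export
select_edges <- function(node_fits) {
  labels <- names(node_fits)
  p <- length(labels)
  adj <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  for (i in labels) for (j in node_fits[[i]]$support)
    adj[i, j] <- j %in% labels && i %in% node_fits[[j]]$support
  adj & t(adj)
}

#' Post-selection refits and symmetrised conditional odds ratios
#'
#' Fits, per node, one unpenalised weighted logistic regression of that
#' node on all other items (sandwich covariance). For each retained edge
#' the two directional conditional ORs are `exp` of the partner
#' coefficient in each model; the reported undirected edge weight is
#' their arithmetic mean, and the CI bounds are averaged the same way
#' (`ci_symmetrize = "geometric"` averages on the log scale instead).
#' Refits hit by separation fall back to a flagged continuity-corrected
#' estimate of the directional OR.
#'
#' @param items 0/1 item matrix.
#' @param adjacency symmetric logical matrix from [select_edges()].
#' @param design a [survey_design()].
#' @param level confidence level (default 0.99).
#' @param ci_symmetrize `"arithmetic"` (default) or `"geometric"`.
#' @return Data frame, one row per retained edge: item_i, item_j,
#'   or_sym, ci_low, ci_high, or_ij, or_ji, flagged.
#' @export
refit_edges <- function(items, adjacency, design, level = 0.99,
                        ci_symmetrize = c("arithmetic", "geometric")) {
  ci_symmetrize <- match.arg(ci_symmetrize)
  labels <- colnames(items)
  stopifnot(identical(dim(adjacency), c(length(labels), length(labels))),
            isTRUE(all(adjacency == t(adjacency))))
  w <- design$weights
  z <- qnorm(1 - (1 - level) / 2)
  ## one unpenalised model per node, on all other items
  models <- list()
  for (j in seq_along(labels)) {
    X <- cbind(`(Intercept)` = 1, items[, -j, drop = FALSE])
    models[[labels[j]]] <- tryCatch(
      wglm_fit(items[, j], X, w),
      error = function(e) NULL)
  }
  dir_or <- function(node, partner) {
    m <- models[[node]]
    if (!is.null(m) && all(abs(m$coef) < 15)) {
      k <- which(colnames(items)[-match(node, labels)] == partner) + 1L
      est <- m$coef[k]; se <- sqrt(m$vcov[k, k])
      list(est = unname(est), se = unname(se), flagged = FALSE)
    } else {
      ## separation fallback: continuity-corrected marginal table OR
      cells <- weighted_2x2(items[, node], items[, partner], w) + 0.5
      list(est = log(cells["a"] * cells["d"] / (cells["b"] * cells["c"])),
           se = sqrt(sum(1 / cells)), flagged = TRUE)
    }
  }
  rows <- list()
  idx <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- labels[idx[r, 1]]; j <- labels[idx[r, 2]]
    dij <- dir_or(i, j)   # coefficient of j in model for i
    dji <- dir_or(j, i)
    ci_ij <- exp(dij$est + c(-1, 1) * z * dij$se)
    ci_ji <- exp(dji$est + c(-1, 1) * z * dji$se)
    if (ci_symmetrize == "arithmetic") {
      ci <- (ci_ij + ci_ji) / 2
    } else {
      ci <- exp((log(ci_ij) + log(ci_ji)) / 2)
    }
    rows[[r]] <- data.frame(
      item_i = i, item_j = j,
      or_sym = mean(c(exp(dij$est), exp(dji$est))),
      ci_low = ci[1], ci_high = ci[2],
      or_ij = exp(dij$est), or_ji = exp(dji$est),
      flagged = dij$flagged || dji$flagged,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(item_i = character(), item_j = character(),
                      or_sym = numeric(), ci_low = numeric(),
                      ci_high = numeric(), or_ij = numeric(),
                      or_ji = numeric(), flagged = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate the conditional-dependence (Ising) network
#'
#' Full nodewise-lasso pipeline: per-item penalised logistic regressions
#' with 10-fold cross-validated one-standard-error penalties, AND-rule
#' edge selection, unpenalised refits for the retained edges, and
#' symmetrised conditional odds ratios with CIs. Per-node diagnostics
#' (out-of-fold AUC, binomial deviance, number of predictors selected)
#' summarise predictive performance.
#'
#' @inheritParams nodewise_fits
#' @param level confidence level for edge CIs.
#' @param ci_symmetrize passed to [refit_edges()].
#' @return Object of class `ising_network`: `adjacency`, `edges` (refit
#'   table), `nodes` (diagnostics data frame), `node_fits`, `edge_count`,
#'   `mean_support`, `seed`.
#' @export
estimate_network <- function(items, design, K = 10, seed = 1L,
                             standardize = TRUE, level = 0.99,
                             ci_symmetrize = "arithmetic",
                             penalty_scale = 1) {
  fits <- nodewise_fits(items, design, K = K, seed = seed,
                        standardize = standardize,
                        penalty_scale = penalty_scale)
  adj <- select_edges(fits)
  edges <- refit_edges(items, adj, design, level = level,
                       ci_symmetrize = ci_symmetrize)
  nodes <- do.call(rbind, lapply(fits, function(f) data.frame(
    node = f$node, cv_auc = f$cv_auc, cv_deviance = f$cv_deviance,
    n_selected = f$n_selected, lambda_min = f$lambda_min,
    lambda_1se = f$lambda_1se, stringsAsFactors = FALSE)))
  rownames(nodes) <- NULL
  structure(list(adjacency = adj, edges = edges, nodes = nodes,
                 node_fits = fits,
                 edge_count = sum(adj[upper.tri(adj)]),
                 max_edges = ncol(items) * (ncol(items) - 1) / 2,
                 mean_support = mean(nodes$n_selected),
                 seed = seed, K = K, standardize = standardize),
            class = "ising_network")
}

#' @export
print.ising_network <- function(x, ...) {
  cat(sprintf("Ising network: %d of %d possible edges (AND-rule)\n",
              x$edge_count, x$max_edges))
  cat(sprintf("mean support size %.1f, mean CV AUC %.2f\n",
              x$mean_support, mean(x$nodes$cv_auc, na.rm = TRUE)))
  invisible(x)
}

#' Score an estimated network against a known truth
#'
#' `method = "coef"` (default, requires a full `ising_network`) ranks all
#' p(p-1)/2 item pairs by a continuous edge-confidence score — the
#' smaller of the two directional penalised-coefficient magnitudes at
#' each node's CV-optimal penalty (an AND-rule-consistent relaxation of
#' the selected graph) — and reports the ROC AUC of that ranking against
#' the true edge set, the standard recovery metric in the
#' structure-learning literature. `method = "binary"` scores the final
#' AND-rule adjacency itself; a binary classifier has a single operating
#' point, so the AUC then equals the balanced accuracy (mean of
#' sensitivity and specificity). Counts `tp`/`fp`/`fn`/`tn` always refer
#' to the binary AND-rule adjacency.
#'
#' @param network an `ising_network` (or, with `method = "binary"`, a
#'   plain logical adjacency matrix).
#' @param truth an [ising_truth()] (edges are `omega != 0`).
#' @param method `"coef"` or `"binary"`.
#' @return List: `auc`, `tp`, `fp`, `fn`, `tn`.
#' @export
edge_recovery <- function(network, truth, method = c("coef", "binary")) {
  method <- match.arg(method)
  adjacency <- if (inherits(network, "ising_network"))
    network$adjacency else network
  est <- adjacency[upper.tri(adjacency)]
  tru <- truth$omega[upper.tri(truth$omega)] != 0
  tp <- sum(est & tru); fp <- sum(est & !tru)
  fn <- sum(!est & tru); tn <- sum(!est & !tru)
  if (method == "binary") {
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    auc <- mean(c(sens, spec), na.rm = TRUE)
  } else {
    if (!inherits(network, "ising_network"))
      stop("method = 'coef' needs a full ising_network", call. = FALSE)
    labels <- colnames(adjacency)
    S <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (i in labels) {
      b <- abs(network$node_fits[[i]]$coef_min)
      S[i, names(b)] <- b
    }
    score <- pmin(S, t(S))[upper.tri(S)]
    auc <- weighted_auc(as.numeric(tru), score)
  }
  list(auc = auc, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Export an estimated network as edge list and JSON
#'
#' @param network an `ising_network`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(network$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  write.csv(network$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(nodes = colnames(network$adjacency),
         edges = network$edges,
         edge_count = network$edge_count,
         mean_support = network$mean_support),
    file.path(dir, "network.json"), digits = NA, pretty = TRUE)
  invisible(dir)
}
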