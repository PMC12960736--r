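make_toy <- function(n = 400, p = 4, seed = 33, strength = 1.2) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  eta <- -1 + strength * X[, 1] - 0.4 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  w <- runif(n, 0.5, 2)
  list(y = y, X = X, w = w / mean(w))
}

test_that("penalties above lambda_max shrink every slope to zero", {
  d <- make_toy()
  ybar <- sum(d$w * d$y) / sum(d$w)
  lam_max <- max(abs(crossprod(d$X, d$w * (d$y - ybar)))) / length(d$y)
  path <- penalized_logistic_path(d$y, d$X, d$w,
                                  lambda = c(lam_max * 1.05, lam_max * 1.01),
                                  standardize = FALSE)
  expect_true(all(path$beta == 0))
  ## intercept at full shrinkage is the weighted logit of the mean
  expect_equal(path$a0[1], qlogis(ybar), tolerance = 1e-6)
  ## just below lambda_max the first coefficient enters (KKT breakpoint)
  path2 <- penalized_logistic_path(d$y, d$X, d$w,
                                   lambda = c(lam_max * 1.01, lam_max * 0.97),
                                   standardize = FALSE)
  expect_true(any(path2$beta[, 2] != 0))
})

test_that("the penalised path matches the slow proximal-gradient oracle", {
  d <- make_toy(n = 250, p = 3)
  for (lam in c(0.05, 0.02, 0.005)) {
    path <- penalized_logistic_path(d$y, d$X, d$w, lambda = c(lam * 2, lam),
                                    standardize = FALSE)
    ref <- ista_logistic_lasso(d$y, d$X, d$w, lam)
    expect_equal(unname(c(path$a0[2], path$beta[, 2])), ref,
                 tolerance = 1e-4)
  }
})

test_that("lambda -> 0 recovers the unpenalised weighted MLE", {
  d <- make_toy(n = 300, p = 3)
  path <- penalized_logistic_path(d$y, d$X, d$w,
                                  lambda = c(0.01, 1e-6),
                                  standardize = FALSE)
  ref <- suppressWarnings(
    glm.fit(cbind(1, d$X), d$y, weights = d$w,
            family = binomial())$coefficients)
  expect_equal(unname(c(path$a0[2], path$beta[, 2])), unname(ref),
               tolerance = 1e-4)
})

test_that("path rejects malformed inputs", {
  d <- make_toy()
  expect_error(penalized_logistic_path(d$y, d$X + 0.5, d$w), "0/1")
  expect_error(penalized_logistic_path(d$y, d$X, d$w,
                                       lambda = c(0.1, 0.2)),
               "decreasing")
})

test_that("one-SE selection: definitional ordering and null behaviour", {
  set.seed(55)
  for (k in 1:4) {
    n <- 300
    X <- matrix(rbinom(n * 5, 1, 0.4), n, 5)   # pure noise
    y <- rbinom(n, 1, 0.25)
    cv <- cv_one_se(y, X, K = 5, seed = k)
    expect_gte(cv$lambda_1se, cv$lambda_min)
    b <- cv$path$beta[, which(cv$path$lambda == cv$lambda_1se)]
    expect_lte(sum(b != 0), 1)   # null data: support empty or near-empty
  }
})

test_that("a planted strong predictor survives the one-SE rule", {
  set.seed(77)
  for (k in 1:3) {
    n <- 5000
    X <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
    y <- rbinom(n, 1, plogis(-2.5 + 1.5 * X[, 1]))
    cv <- cv_one_se(y, X, K = 10, seed = k)
    b <- cv$path$beta[, which(cv$path$lambda == cv$lambda_1se)]
    expect_true(b[1] != 0)
  }
})

test_that("single-class folds are impossible or raise a clear error", {
  y <- c(rep(1, 3), rep(0, 97))
  X <- matrix(rbinom(100 * 2, 1, 0.5), 100, 2)
  set.seed(1)
  expect_error(cv_one_se(y, X, K = 10, seed = 1), "single-class")
})

test_that("AND-rule edge selection discards one-sided links", {
  fits <- list(
    a = list(node = "a", support = c("b", "c")),
    b = list(node = "b", support = "a"),
    c = list(node = "c", support = character(0)))
  adj <- select_edges(fits)
  expect_true(adj["a", "b"] && adj["b", "a"])   # mutual
  expect_false(adj["a", "c"])                   # one-sided
  expect_false(any(diag(adj)))
  ## AND-rule graph is a subset of the OR-rule graph
  or_adj <- matrix(FALSE, 3, 3, dimnames = dimnames(adj))
  for (i in names(fits)) for (j in fits[[i]]$support)
    or_adj[i, j] <- or_adj[j, i] <- TRUE
  expect_true(all(!adj | or_adj))
  ## empty supports give the empty graph
  none <- lapply(fits, function(f) { f$support <- character(0); f })
  expect_false(any(select_edges(none)))
})

test_that("refits on enumerated pseudo-data recover omega exactly", {
  ## feed the exact p = 3 Ising distribution in as weighted pseudo-data:
  ## conditional log-ORs from the refit must equal the generating omega
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- 0.9
  om[2, 3] <- om[3, 2] <- -0.6
  tr <- ising_truth(c(-0.5, 0.2, -1), om, labels = c("a", "b", "c"))
  st <- ising_states(3)
  colnames(st) <- tr$labels
  w <- ising_state_probs(tr) * 1e4
  adj <- om != 0
  edges <- refit_edges(st, adj, survey_design(w))
  expect_equal(nrow(edges), 2)
  ab <- edges[edges$item_i == "a" & edges$item_j == "b", ]
  bc <- edges[edges$item_i == "b" & edges$item_j == "c", ]
  expect_equal(log(ab$or_ij), 0.9, tolerance = 1e-6)
  expect_equal(log(ab$or_ji), 0.9, tolerance = 1e-6)
  expect_equal(log(bc$or_sym), log((exp(-0.6) + exp(-0.6)) / 2),
               tolerance = 1e-6)
})

test_that("symmetrised OR is the arithmetic mean of the directional ORs", {
  set.seed(61)
  x <- simulate_ising(ising_preset("sparse10"), 3000, seed = 61)
  adj <- matrix(FALSE, 10, 10,
                dimnames = list(colnames(x), colnames(x)))
  adj["flirted_online", "webcam_child"] <-
    adj["webcam_child", "flirted_online"] <- TRUE
  edges <- refit_edges(x, adj, equal_design(3000))
  expect_equal(edges$or_sym, (edges$or_ij + edges$or_ji) / 2)
  geo <- refit_edges(x, adj, equal_design(3000),
                     ci_symmetrize = "geometric")
  expect_lte(geo$ci_low, edges$ci_low + 1e-9)
})

test_that("estimate_network is deterministic and reports capacity", {
  x <- simulate_ising(ising_preset("sparse10"), 1200, seed = 71)
  d <- equal_design(1200)
  n1 <- estimate_network(x, d, K = 5, seed = 9)
  n2 <- estimate_network(x, d, K = 5, seed = 9)
  expect_identical(n1$adjacency, n2$adjacency)
  expect_equal(n1$edges$or_sym, n2$edges$or_sym)
  expect_equal(n1$max_edges, 45)
  expect_lte(n1$edge_count, 45)
  ## every retained edge has both directional supports
  fits <- n1$node_fits
  for (r in seq_len(nrow(n1$edges))) {
    i <- n1$edges$item_i[r]; j <- n1$edges$item_j[r]
    expect_true(j %in% fits[[i]]$support && i %in% fits[[j]]$support)
  }
})

test_that("edge count is non-increasing under a global penalty multiplier", {
  x <- simulate_ising(ising_preset("sparse10"), 2000, seed = 81)
  d <- equal_design(2000)
  counts <- sapply(c(1, 1.5, 2.5), function(mult) {
    fits <- nodewise_fits(x, d, K = 5, seed = 3, penalty_scale = mult)
    adj <- select_edges(fits)
    sum(adj[upper.tri(adj)])
  })
  expect_true(all(diff(counts) <= 0))
})
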