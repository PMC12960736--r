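# Independent reference implementations used as oracles. These are
# deliberately slow and simple, and share no code with the package.

## Proximal-gradient (ISTA) solver for the weighted lasso logistic
## objective  -(1/n) sum_i w_i [y_i eta_i - log(1 + exp(eta_i))] +
## lambda * ||beta||_1  with unpenalised intercept, run to a tight
## tolerance. Matches the objective of penalized_logistic_path() when
## weights have mean 1 and standardize = FALSE.
ista_logistic_lasso <- function(y, X, w, lambda, max_iter = 200000,
                                tol = 1e-11) {
  n <- length(y)
  w <- w / mean(w)
  Xa <- cbind(1, X)
  theta <- rep(0, ncol(Xa))
  ## Lipschitz bound for the logistic gradient: (1/4n) * ||sqrt(w) Xa||^2
  L <- max(eigen(crossprod(Xa * sqrt(w)) / (4 * n),
                 only.values = TRUE)$values)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  obj <- function(theta) {
    eta <- as.numeric(Xa %*% theta)
    -sum(w * (y * eta - log1p(exp(eta)))) / n +
      lambda * sum(abs(theta[-1]))
  }
  last <- obj(theta)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xa %*% theta)
    mu <- plogis(eta)
    grad <- -crossprod(Xa, w * (y - mu)) / n
    theta_new <- theta - grad / L
    theta_new[-1] <- soft(theta_new[-1], lambda / L)
    theta <- as.numeric(theta_new)
    if (it %% 200 == 0) {
      cur <- obj(theta)
      if (abs(last - cur) < tol) break
      last <- cur
    }
  }
  theta
}

## Exact conditional log-odds of item i given the rest, from an
## enumerated Ising distribution (independent of the package's
## ising_log_weights): P computed state by state.
enumerate_conditional_logit <- function(tau, omega, i, x_rest) {
  p <- length(tau)
  x1 <- x0 <- numeric(p)
  x1[-i] <- x0[-i] <- x_rest
  x1[i] <- 1
  energy <- function(x) sum(tau * x) + sum(omega[upper.tri(omega)] *
    (outer(x, x)[upper.tri(omega)]))
  energy(x1) - energy(x0)
}

## Brute-force Pearson chi-square of independence on an unweighted
## two-way table of vectors.
pearson_x2 <- function(y, g) {
  tab <- table(y, g)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}
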