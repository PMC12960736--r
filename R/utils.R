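# Internal numeric helpers shared across modules.

#' @importFrom stats plogis qlogis rbinom runif pf pchisq qnorm glm.fit
#'   binomial sd setNames complete.cases
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

wmean <- function(x, w) sum(w * x) / sum(w)

## Effective sample size under unequal weighting (Kish).
n_eff <- function(w) sum(w)^2 / sum(w^2)

## Weighted mean binomial deviance, -2 * loglik per unit weight.
binomial_deviance <- function(y, p, w = rep(1, length(y))) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

## Weighted AUC (probability of concordance, ties counted half).
weighted_auc <- function(y, score, w = rep(1, length(y))) {
  stopifnot(length(y) == length(score), length(w) == length(y))
  if (all(y == y[1])) return(NA_real_)
  o <- order(score)
  y <- y[o]; w <- w[o]; score <- score[o]
  w0 <- w * (y == 0)
  ## cumulative negative weight strictly below each score value
  grp <- cumsum(!duplicated(score))
  tot0_by_grp <- tapply(w0, grp, sum)
  below <- c(0, cumsum(tot0_by_grp))[grp]
  conc <- sum((w * (y == 1)) * (below + 0.5 * tot0_by_grp[grp]))
  conc / (sum(w[y == 1]) * sum(w0))
}

check_binary <- function(x, what = "input") {
  x <- as.numeric(x)
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop(sprintf("%s must be coded 0/1 with no missing values", what),
         call. = FALSE)
  x
}

## Draw a sub-seed deterministically from a master seed; keeps values
## well inside 32-bit integer range.
derive_seed <- function(seed, k) {
  ((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483563) + 1
}
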