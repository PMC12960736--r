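#' Specification of a synthetic survey cohort
#'
#' Bundles everything the generator needs: cohort size, country strata
#' (labels, mixing proportions, per-stratum threshold offsets), marginal
#' distributions for the demographic covariates, an item-by-covariate
#' effect matrix, and a selection-bias vector that makes the achieved
#' sample deviate from the population so that raking is non-trivial.
#'
#' Covariates follow the standard battery: `age` with six ordered bands
#' (1 = 18-24 ... 6 = 65+), and binary `partnered`, `university`,
#' `high_income`, `employed`, `child_household`, `works_children`.
#'
#' @param n number of respondents.
#' @param countries list with `labels`, `props` (mixing proportions
#'   summing to 1) and `tau_offset` (per-stratum threshold shift).
#' @param covariates named list of marginal distributions: `age` is a
#'   length-6 probability vector, each binary covariate a single
#'   probability of being 1.
#' @param beta item-by-covariate matrix of threshold shifts (log-odds);
#'   column names must be covariate names. `NULL` means no effects.
#' @param selection_bias named numeric vector of log-odds coefficients
#'   on the covariates governing inclusion (see [biased_subsample()]).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        countries = list(
                          labels = c("AUS", "GBR", "USA"),
                          props = c(1939, 1506, 1473) / 4918,
                          tau_offset = c(0, 0, 0.4)),
                        covariates = default_covariate_marginals(),
                        beta = NULL,
                        selection_bias = NULL,
                        seed = 1L) {
  stopifnot(n >= 1)
  if (abs(sum(countries$props) - 1) > 1e-8)
    stop("country mixing proportions must sum to 1", call. = FALSE)
  stopifnot(length(countries$labels) == length(countries$props),
            length(countries$tau_offset) == length(countries$props))
  if (abs(sum(covariates$age) - 1) > 1e-8)
    stop("age band probabilities must sum to 1", call. = FALSE)
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    bad <- setdiff(colnames(beta), names(covariates))
    if (length(bad))
      stop("unknown covariate(s) in beta: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(selection_bias)) {
    bad <- setdiff(names(selection_bias), names(covariates))
    if (length(bad))
      stop("unknown covariate(s) in selection_bias: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n = as.integer(n), countries = countries,
                 covariates = covariates, beta = beta,
                 selection_bias = selection_bias, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default covariate marginal distributions
#'
#' Age-band shares approximate an adult male population pyramid; the
#' binary covariate rates are round figures typical of the national adult
#' male populations the quota samples emulate.
#' @return Named list of marginal distributions.
#' @export
default_covariate_marginals <- function() {
  list(age = c(0.14, 0.18, 0.17, 0.16, 0.15, 0.20),
       partnered = 0.60, university = 0.35, high_income = 0.25,
       employed = 0.75, child_household = 0.35, works_children = 0.12)
}

## Numeric design row per covariate used for threshold shifts and
## selection: age enters centred and scaled to roughly unit range.
covariate_design <- function(demographics, covariate_names) {
  z <- sapply(covariate_names, function(v) {
    if (v == "age") (demographics$age - 3.5) / 2.5 else demographics[[v]]
  })
  matrix(z, nrow = nrow(demographics),
         dimnames = list(NULL, covariate_names))
}

draw_demographics <- function(n, spec) {
  cv <- spec$covariates
  country <- sample(spec$countries$labels, n, replace = TRUE,
                    prob = spec$countries$props)
  out <- data.frame(
    id = seq_len(n),
    country = country,
    age = sample.int(6L, n, replace = TRUE, prob = cv$age),
    stringsAsFactors = FALSE)
  for (v in setdiff(names(cv), "age"))
    out[[v]] <- rbinom(n, 1L, cv[[v]])
  out
}

## Population margin targets implied by the generating marginals.
population_margins_from_spec <- function(spec) {
  cv <- spec$covariates
  rows <- list(data.frame(variable = "age", level = as.character(1:6),
                          target = as.numeric(cv$age)))
  for (v in setdiff(names(cv), "age"))
    rows[[v]] <- data.frame(variable = v, level = c("0", "1"),
                            target = c(1 - cv[[v]], cv[[v]]))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Attach demographics to simulated responses
#'
#' Draws demographic covariates from the spec marginals, then re-simulates
#' the items with respondent-specific thresholds
#' \eqn{\tau + \text{country offset} + \beta z}, grouping respondents by
#' distinct threshold profile so every profile is sampled from its exact
#' enumerated distribution.
#'
#' @param responses matrix from [simulate_ising()] (fixes `n` and labels;
#'   its values are replaced by the covariate-shifted re-simulation).
#' @param spec a [cohort_spec()].
#' @param truth the [ising_truth()] used to generate `responses`.
#' @param seed integer seed.
#' @return An object of class `synthetic_cohort`: list with `responses`,
#'   `demographics`, `truth`, `population_margins`.
#' @export
attach_demographics <- function(responses, spec, truth, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ising_truth"))
  n <- nrow(responses)
  set.seed(seed)
  demo <- draw_demographics(n, spec)
  tau_mat <- matrix(truth$tau, n, truth$p, byrow = TRUE)
  off <- spec$countries$tau_offset[match(demo$country,
                                         spec$countries$labels)]
  tau_mat <- tau_mat + off   # recycled per column: same shift on all items
  beta <- spec$beta %||% truth$beta
  if (!is.null(beta)) {
    z <- covariate_design(demo, colnames(beta))
    tau_mat <- tau_mat + z %*% t(beta)
  }
  resp <- simulate_ising_profiles(tau_mat, truth$omega, truth$labels)
  structure(list(responses = resp, demographics = demo, truth = truth,
                 population_margins = population_margins_from_spec(spec)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d respondents, %d items, %d covariates\n",
              nrow(x$responses), ncol(x$responses),
              ncol(x$demographics) - 2L))
  invisible(x)
}

#' Draw a demographically biased subsample
#'
#' Retains respondents with probability proportional to
#' `plogis(z %*% selection_bias)`, inducing the sample/population mismatch
#' that raking later corrects. The attached population margins are left
#' unchanged: they describe the pre-selection population.
#'
#' @param cohort a `synthetic_cohort`.
#' @param selection_bias named log-odds vector over covariates; `NULL`
#'   falls back to the uniform (unbiased) case.
#' @param n_keep subsample size, at most the cohort size.
#' @param seed integer seed.
#' @return A `synthetic_cohort` of `n_keep` respondents.
#' @export
biased_subsample <- function(cohort, selection_bias, n_keep, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$responses)
  if (n_keep > n) stop("n_keep exceeds cohort size", call. = FALSE)
  set.seed(seed)
  if (is.null(selection_bias) || all(selection_bias == 0)) {
    keep <- if (n_keep == n) seq_len(n) else sample.int(n, n_keep)
  } else {
    z <- covariate_design(cohort$demographics, names(selection_bias))
    pr <- plogis(as.numeric(z %*% selection_bias))
    if (sum(pr) < 1e-8)
      stop("selection probabilities are numerically zero", call. = FALSE)
    keep <- sample.int(n, n_keep, prob = pr)
  }
  keep <- sort(keep)
  out <- cohort
  out$responses <- cohort$responses[keep, , drop = FALSE]
  out$demographics <- cohort$demographics[keep, , drop = FALSE]
  out$demographics$id <- seq_len(n_keep)
  out
}

#' Generate a complete synthetic cohort in one call
#'
#' Convenience wrapper: simulate from `truth`, attach demographics, and
#' (optionally) pass through biased selection. This is the generator the
#' pipeline's `simulate` stage runs.
#'
#' @param spec a [cohort_spec()].
#' @param truth an [ising_truth()]; defaults to `ising_preset("sparse10")`.
#' @param oversample factor by which the pre-selection population exceeds
#'   `spec$n` when selection bias is active.
#' @return A `synthetic_cohort` with `spec$n` respondents.
#' @export
generate_cohort <- function(spec, truth = ising_preset("sparse10"),
                            oversample = 4) {
  biased <- !is.null(spec$selection_bias) && any(spec$selection_bias != 0)
  n0 <- if (biased) ceiling(spec$n * oversample) else spec$n
  resp <- simulate_ising(truth, n0, method = "exact", seed = spec$seed)
  cohort <- attach_demographics(resp, spec, truth,
                                seed = derive_seed(spec$seed, 1))
  if (biased || n0 > spec$n)
    cohort <- biased_subsample(cohort, spec$selection_bias, spec$n,
                               seed = derive_seed(spec$seed, 2))
  cohort
}

#' Write a cohort to plain-text files
#'
#' Writes `responses.csv`, `demographics.csv` and a `truth.json` sidecar
#' carrying the generating parameters and the population margins.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  resp <- data.frame(id = cohort$demographics$id, cohort$responses,
                     check.names = FALSE)
  write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE)
  write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
            row.names = FALSE)
  sidecar <- list(
    truth = list(tau = cohort$truth$tau,
                 omega = cohort$truth$omega,
                 labels = cohort$truth$labels),
    population_margins = cohort$population_margins)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       digits = NA, pretty = TRUE, matrix = "rowmajor")
  invisible(dir)
}
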