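test_that("raking is the identity when margins already match", {
  demo <- data.frame(z = rep(c("0", "1"), each = 50))
  d <- rake(demo, binary_margins(target1 = 0.5))
  expect_equal(d$weights, rep(1, 100))
})

test_that("single binary margin gives the closed-form ratio weights", {
  demo <- data.frame(z = rep(c("0", "1"), times = c(70, 30)))
  d <- rake(demo, binary_margins(target1 = 0.5))
  ## 30/70 split raked to 50/50: weights 5/3 on the 30%-cell, 5/7 on the
  ## 70%-cell (one IPF iteration, exact)
  expect_equal(unique(d$weights[demo$z == "1"]), 5 / 3, tolerance = 1e-12)
  expect_equal(unique(d$weights[demo$z == "0"]), 5 / 7, tolerance = 1e-12)
  expect_equal(d$convergence$iterations, 1)
})

test_that("two compatible binary margins converge below 1e-8", {
  set.seed(31)
  demo <- data.frame(a = as.character(rbinom(500, 1, 0.3)),
                     b = as.character(rbinom(500, 1, 0.7)))
  margins <- rbind(binary_margins("a", 0.5), binary_margins("b", 0.5))
  d <- rake(demo, margins, tol = 1e-9)
  rep_ <- margin_report(d, demo, margins)
  expect_lt(max(rep_$abs_error), 1e-8)
  ## fixed-point oracle: direct IPF in the test
  w <- rep(1, 500)
  for (k in 1:100) for (v in c("a", "b")) {
    cur <- tapply(w, demo[[v]], sum) / sum(w)
    w <- w * as.numeric((0.5 / cur)[demo[[v]]])
  }
  w <- w / sum(w) * 500
  expect_equal(d$weights, unname(w), tolerance = 1e-7)
})

test_that("raking errors are informative", {
  demo <- data.frame(z = rep("0", 20))
  expect_error(rake(demo, binary_margins(target1 = 0.5)),
               "level '1' of 'z'")
  set.seed(1)
  demo2 <- data.frame(a = as.character(rbinom(200, 1, 0.3)),
                      b = as.character(rbinom(200, 1, 0.7)))
  margins <- rbind(binary_margins("a", 0.5), binary_margins("b", 0.5))
  expect_error(rake(demo2, margins, tol = 1e-12, max_iter = 1),
               "did not converge")
  bad <- binary_margins(); bad$target <- c(0.6, 0.6)
  expect_error(rake(demo2, bad), "sum to")
})

test_that("margin order does not change the converged margins", {
  set.seed(5)
  demo <- data.frame(a = as.character(rbinom(400, 1, 0.25)),
                     b = as.character(rbinom(400, 1, 0.6)),
                     c = as.character(rbinom(400, 1, 0.5)))
  m1 <- rbind(binary_margins("a", 0.4), binary_margins("b", 0.5),
              binary_margins("c", 0.45))
  m2 <- m1[c(5, 6, 1, 2, 3, 4), ]
  d1 <- rake(demo, m1, tol = 1e-10)
  d2 <- rake(demo, m2, tol = 1e-10)
  expect_equal(margin_report(d1, demo, m1)$weighted,
               margin_report(d2, demo, m1)$weighted, tolerance = 1e-8)
})

test_that("weights stay positive and trimming is applied and recorded", {
  set.seed(17)
  demo <- data.frame(z = as.character(rbinom(300, 1, 0.05)),
                     u = as.character(rbinom(300, 1, 0.5)))
  margins <- rbind(binary_margins("z", 0.4), binary_margins("u", 0.5))
  d <- rake(demo, margins)
  expect_true(all(d$weights > 0))
  ## trim then single re-rake: extremes cannot grow, cap is recorded
  dt <- rake(demo, margins, trim_cap = 2)
  expect_lte(max(dt$weights), max(d$weights) + 1e-9)
  expect_false(is.null(dt$trimmed))
})

test_that("stratified raking matches targets within every stratum", {
  set.seed(23)
  n <- 600
  demo <- data.frame(country = sample(c("A", "B"), n, TRUE),
                     z = as.character(rbinom(n, 1, 0.3)))
  d <- rake(demo, binary_margins(target1 = 0.5), by = "country")
  for (s in c("A", "B")) {
    idx <- demo$country == s
    expect_equal(sum(d$weights[idx]), sum(idx))
    expect_equal(sum(d$weights[idx & demo$z == "1"]) / sum(d$weights[idx]),
                 0.5, tolerance = 1e-6)
  }
})

test_that("pre-rake report on a biased subsample shows the bias", {
  tr <- ising_preset("independence10")
  spec <- cohort_spec(3000, seed = 13)
  co <- attach_demographics(simulate_ising(tr, 3000, seed = 13), spec, tr)
  sub <- biased_subsample(co, c(age = -1.0), 1200, seed = 13)
  pre <- margin_report(survey_design(rep(1, 1200)), sub$demographics,
                       sub$population_margins)
  age_err <- pre$abs_error[pre$variable == "age"]
  expect_gt(max(age_err), 0.02)
  post <- margin_report(rake(sub$demographics, sub$population_margins),
                        sub$demographics, sub$population_margins)
  expect_lt(max(post$abs_error), 1e-6)
})
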