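test_that("encode_items applies the dichotomization rules", {
  raw <- raw_battery_fixture()
  items <- encode_items(raw)
  expect_equal(unname(items[, "viewed_csam"]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(items[, "feelings"]), c(0L, 1L, 0L, 0L))
  ## composite: any bracket "very likely"/"definitely" triggers
  expect_equal(unname(items[, "likely_contact_u14"]), c(0L, 0L, 1L, 1L))
  ## "unsure"/"maybe" count as 0 for behaviours; composite invariant
  agg <- (raw$likely_12_14 %in% c("very likely", "definitely")) |
    (raw$likely_10_12 %in% c("very likely", "definitely")) |
    (raw$likely_u10 %in% c("very likely", "definitely"))
  expect_equal(items[, "likely_contact_u14"], as.integer(agg))
})

test_that("encode_items rejects unknown response levels by name", {
  raw <- raw_battery_fixture()
  raw$viewed_csam[2] <- "dunno"
  expect_error(encode_items(raw), "dunno")
  raw <- raw_battery_fixture()
  raw$likely_u10[1] <- "certainly"
  expect_error(encode_items(raw), "certainly")
})

test_that("equal-weight prevalence matches the linearized-logit oracle", {
  y <- c(rep(1, 8), rep(0, 92))
  est <- weighted_prevalence(y, equal_design(100), level = 0.99)
  expect_equal(est$point, 0.08)
  ## hand oracle: v = p(1-p)/(n-1), CI on logit scale
  p <- 0.08; n <- 100
  v <- p * (1 - p) / (n - 1)
  se_logit <- sqrt(v) / (p * (1 - p))
  z <- qnorm(0.995)
  expect_equal(est$ci_low, plogis(qlogis(p) - z * se_logit),
               tolerance = 1e-12)
  expect_equal(est$ci_high, plogis(qlogis(p) + z * se_logit),
               tolerance = 1e-12)
  expect_true(est$ci_high - est$point > est$point - est$ci_low)
})

test_that("prevalence is invariant to weight rescaling and degenerate-safe", {
  set.seed(3)
  y <- rbinom(250, 1, 0.1)
  w <- runif(250, 0.5, 3)
  e1 <- weighted_prevalence(y, survey_design(w))
  e2 <- weighted_prevalence(y, survey_design(w * 17))
  expect_equal(e1$point, e2$point)
  expect_equal(e1$ci_low, e2$ci_low)
  z <- rep(0, 50)
  ez <- weighted_prevalence(z, equal_design(50))
  expect_equal(ez$point, 0)
  expect_true(ez$degenerate)
  expect_gt(ez$ci_high, 0)
})

test_that("grouped prevalences weight-average to the pooled estimate", {
  set.seed(9)
  y <- rbinom(400, 1, 0.2)
  w <- runif(400, 0.2, 2)
  g <- sample(c("A", "B", "C"), 400, TRUE)
  d <- survey_design(w)
  pooled <- weighted_prevalence(y, d)$point
  per <- weighted_prevalence(y, d, by = g)
  shares <- tapply(d$weights, g, sum) / sum(d$weights)
  expect_equal(sum(per$point * shares[per$group]), pooled,
               tolerance = 1e-12)
})

test_that("weighted count 391 of N 4918 prints as 8.0% prevalence", {
  ## construct a design whose weighted totals reproduce the printed
  ## margin: 391 weighted endorsements among weighted N = 4918
  y <- c(rep(1, 200), rep(0, 800))
  w <- c(rep(391 / 200, 200), rep((4918 - 391) / 800, 800))
  est <- weighted_prevalence(y, survey_design(w))
  expect_equal(round(100 * est$point, 1), 8.0)
})

test_that("Rao-Scott: null tables give F near 0, p near 1", {
  ## identical weighted proportions in both groups
  y <- rep(c(1, 0, 1, 0), times = c(10, 90, 20, 180))
  g <- rep(c("a", "b"), times = c(100, 200))
  rs <- rao_scott_test(y, g, equal_design(300))
  expect_lt(rs$F_stat, 1e-20)
  expect_gt(rs$p_value, 0.999)
})

test_that("equal weights reduce Rao-Scott to the classical Pearson F", {
  set.seed(12)
  y <- rbinom(240, 1, 0.25)
  g <- sample(c("x", "y", "z"), 240, TRUE)
  rs <- rao_scott_test(y, g, equal_design(240))
  x2 <- pearson_x2(y, g)   # brute-force oracle
  n <- 240; d <- 2
  expect_equal(rs$X2, x2, tolerance = 1e-9)
  expect_equal(rs$F_stat, x2 / d, tolerance = 1e-9)
  expect_equal(rs$df1, d, tolerance = 1e-9)
  expect_equal(rs$df2, d * (n - 1), tolerance = 1e-9)
  expect_equal(rs$p_value, pf(x2 / d, d, d * (n - 1), lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(rs$first_order_deff, 1, tolerance = 1e-9)
})

test_that("Rao-Scott eigenvalue steps verified long-hand on a 2x2 table", {
  ## unequal weights, 2x2: d = 1 so the single lambda is Vh / V0 and
  ## F = X2 / lambda on (1, n-1) df — checked against a from-scratch
  ## computation that shares nothing with the implementation
  set.seed(8)
  n <- 150
  y <- rbinom(n, 1, 0.3)
  g <- rbinom(n, 1, 0.5)
  w <- runif(n, 0.5, 2)
  d <- survey_design(w)
  rs <- rao_scott_test(y, g, d)
  wt <- d$weights / sum(d$weights)
  p11 <- sum(wt[y == 1 & g == 1]); pr <- sum(wt[y == 1]); pc <- sum(wt[g == 1])
  h <- p11 - pr * pc
  u <- wt * ((y == 1 & g == 1) - p11 - pc * ((y == 1) - pr) -
               pr * ((g == 1) - pc))
  Vh <- sum(u^2)
  ## multinomial covariance of h via the delta method on the 4 cells
  pv <- c(sum(wt[y == 0 & g == 0]), sum(wt[y == 1 & g == 0]),
          sum(wt[y == 0 & g == 1]), p11)
  ## gradient of h = p11 - pr*pc wrt cells (00, 10, 01, 11)
  a <- c(0, -pc, -pr, 1 - pc - pr)
  V0 <- as.numeric(t(a) %*% (diag(pv) - tcrossprod(pv)) %*% a) / n
  lambda <- Vh / V0
  X2 <- n * sum((p11 - pr * pc)^2 *
                  c(1 / (pr * pc), 1 / (pr * (1 - pc)),
                    1 / ((1 - pr) * pc), 1 / ((1 - pr) * (1 - pc))))
  expect_equal(rs$lambda, lambda, tolerance = 1e-8)
  expect_equal(rs$F_stat, X2 / lambda, tolerance = 1e-8)
  expect_equal(rs$df1, 1, tolerance = 1e-8)
})

test_that("Rao-Scott rejects degenerate groups", {
  y <- rbinom(50, 1, 0.5)
  expect_error(rao_scott_test(y, rep("a", 50), equal_design(50)),
               "two groups")
})
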