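# Spline basis, per-code logistic fits, BH selection, signed Manhattan
# values, winner's-curse correction, and the age-risk curve.

test_that("spline knots sit at the 5/35/65/95th percentiles and tails are linear", {
  ages <- seq(20, 40, length.out = 500)
  b <- rcs_basis(ages, n_knots = 4)
  expect_equal(b$knots, unname(quantile(ages, c(0.05, 0.35, 0.65, 0.95))))
  expect_equal(ncol(b$design), 3)  # dimension = knots - 1
  # far below the boundary knot the basis is linear: second differences ~ 0
  grid <- seq(5, 15, by = 0.5)
  m <- predict(b, grid)
  d2 <- diff(diff(m[, 1]))
  expect_lt(max(abs(d2)), 1e-9)
  # continuity of value and first derivative at an interior knot
  k <- b$knots[2]
  eps <- 1e-6
  left <- predict(b, c(k - 2 * eps, k - eps))
  right <- predict(b, c(k + eps, k + 2 * eps))
  at <- predict(b, k)
  expect_lt(max(abs(left[2, ] - at)), 1e-5)
  expect_lt(max(abs(right[1, ] - at)), 1e-5)
  d_left <- (left[2, ] - left[1, ]) / eps
  d_right <- (right[2, ] - right[1, ]) / eps
  expect_lt(max(abs(d_left - d_right)), 1e-3)
  expect_error(rcs_basis(rep(c(20, 30, 40), 10), n_knots = 4), "n_knots")
})

test_that("the screening log-OR equals the closed-form 2x2 value under constant age", {
  # exposed: 100 cases / 1,000; unexposed: 50 cases / 1,000
  y <- c(rep(1, 100), rep(0, 900), rep(1, 50), rep(0, 950))
  x <- c(rep(1, 1000), rep(0, 1000))
  fit <- fit_code_model(y, x)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$log_or - logor_2x2(100, 900, 50, 950)), 1e-6)
  expect_true(fit$ci_low < fit$log_or && fit$log_or < fit$ci_high)
})

test_that("per-code fits agree with stats::glm including the spline adjustment", {
  set.seed(31)
  sim <- simulate_screen_data(4000, 0.2, 0.5, 0.08, age_effect = 0.03)
  b <- rcs_basis(sim$ages)
  fit <- fit_code_model(sim$y, sim$X[, 1], b$design)
  ref <- glm(sim$y ~ sim$X[, 1] + b$design, family = binomial)
  ref0 <- glm(sim$y ~ b$design, family = binomial)
  expect_lt(abs(fit$log_or - coef(ref)[2]), 1e-6)
  lrt_ref <- ref0$deviance - ref$deviance
  expect_lt(abs(fit$lrt - lrt_ref), 1e-6)
  expect_lt(abs(fit$p_value - pchisq(lrt_ref, 1, lower.tail = FALSE)), 1e-8)
})

test_that("separation and empty cells are reported non-estimable with p = 1", {
  y <- rep(c(0, 1), each = 50)
  fit <- fit_code_model(y, y)          # x identical to y: separation
  expect_equal(fit$status, "non-estimable")
  expect_equal(fit$p_value, 1)
  expect_true(is.na(fit$log_or))
  fit0 <- fit_code_model(y, rep(0, 100))  # zero exposed
  expect_equal(fit0$status, "non-estimable")
})

test_that("BH adjustment matches the hand step-up computation and nests across levels", {
  p <- c(0.001, 0.011, 0.02, 0.8)
  res <- bh_select(p, 0.05)
  expect_equal(res$adjusted, c(0.004, 0.022, 4 * 0.02 / 3, 0.8))
  expect_equal(res$selected, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(res$adjusted >= p))
  # all p = 1: nothing selected at any level
  expect_false(any(bh_select(rep(1, 10), 0.10)$selected))
  # nesting: selections at 1% within 5% within 10% on random inputs
  set.seed(7)
  for (i in 1:20) {
    pv <- runif(50)^3
    s1 <- bh_select(pv, 0.01)$selected
    s5 <- bh_select(pv, 0.05)$selected
    s10 <- bh_select(pv, 0.10)$selected
    expect_true(all(!s1 | s5))
    expect_true(all(!s5 | s10))
  }
  expect_length(bh_select(numeric(0), 0.05)$adjusted, 0)
})

test_that("null-code p-values are uniform (type-I calibration)", {
  set.seed(12)
  pvals <- replicate(500, {
    y <- rbinom(5000, 1, 0.05)
    x <- rbinom(5000, 1, 0.10)
    fit_code_model(y, x)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signed -log10 p carries the association sign and caps at 20", {
  s <- signed_log10(c(0.01, 0.01, 1e-25, 0), c(0.5, -0.5, 1, -1))
  expect_equal(s$signed_mlog10p, c(2, -2, 20, -20))
  expect_equal(s$capped, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(signed_log10(0.01, 0)$signed_mlog10p, 0)
})

test_that("screen_codes orders selections consistently and flags degenerate codes", {
  set.seed(44)
  sim <- simulate_screen_data(20000, c(0.05, rep(0.1, 9)),
                              c(log(3), rep(0, 9)), 0.05)
  scr <- screen_codes(sim$X, sim$y, ages = sim$ages)
  tab <- scr$table
  expect_true(tab$selected_fdr05[1])     # strong planted signal found
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_true(all(!tab$selected_fdr01 | tab$selected_fdr05))
  expect_true(all(!tab$selected_fdr05 | tab$selected_fdr10))
  expect_equal(coef(scr)[["c001"]], tab$log_or[1])
})

test_that("winner's-curse correction is near zero without multiplicity and deterministic", {
  set.seed(9)
  sim <- simulate_screen_data(15000, 0.1, 0.5, 0.05)
  scr <- screen_codes(sim$X, sim$y, ages = NULL)
  expect_error(correct_winners_curse(scr, B = 10), "B")
  cor1 <- correct_winners_curse(scr, fdr = 0.05, B = 80, seed = 5)
  # a single strongly significant code tested alone: no selection pressure,
  # bias within Monte-Carlo error of zero
  expect_true(cor1$table$selected_fdr05[1])
  expect_lt(abs(cor1$table$bias[1]), 0.08)
  cor2 <- correct_winners_curse(scr, fdr = 0.05, B = 80, seed = 5)
  expect_identical(cor1$table, cor2$table)
})

test_that("the age-risk curve is flat for a null age effect and monotone for a planted one", {
  set.seed(17)
  ages <- pmin(55, pmax(12, round(rnorm(20000, 31, 4.5))))
  y0 <- rbinom(20000, 1, 0.05)
  curve0 <- age_risk_curve(y0, ages)
  # zeroing the age coefficients collapses the curve to a constant rate
  flat <- plogis(cbind(1, predict(curve0$basis, 20:40)) %*%
                   c(curve0$coefficients[1], 0, 0, 0))
  expect_lt(diff(range(flat)), 1e-12)
  # monotone planted effect recovered over the central age range
  y1 <- rbinom(20000, 1, plogis(-4 + 0.06 * (ages - 31)))
  curve1 <- age_risk_curve(y1, ages)
  central <- curve1$curve[curve1$curve$age >= 25 & curve1$curve$age <= 38, ]
  expect_true(all(diff(central$risk) > 0))
  # small bins are absent; bins must exceed the minimum count
  expect_true(all(curve1$bins$n > 100))
  expect_true(any(table(2 * floor(ages / 2)) <= 100))  # fixture has small bins
  # grid beyond the observed range is flagged as extrapolated
  curve2 <- age_risk_curve(y1, ages, grid = c(5, 30, 70))
  expect_equal(curve2$curve$extrapolated, c(TRUE, FALSE, TRUE))
})
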