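# Subgroup discovery: balancing, Apriori mining vs a brute-force oracle,
# Westfall-Young selection, and full-data risk metrics.

test_that("downsampling balances classes, keeps all cases, and is deterministic", {
  set.seed(3)
  X <- matrix(rbinom(10100 * 3, 1, 0.3), ncol = 3)
  y <- c(rep(1, 100), rep(0, 10000))
  bal <- downsample_balance(X, y, seed = 4)
  expect_equal(length(bal$y), 200)
  expect_equal(mean(bal$y), 0.5)
  bal2 <- downsample_balance(X, y, seed = 4)
  expect_identical(bal$X, bal2$X)
  # already balanced input: identity up to row order
  yb <- rep(c(1, 0), 50)
  balb <- downsample_balance(X[1:100, ], yb, seed = 1)
  expect_equal(sort(rowSums(balb$X)), sort(rowSums(X[1:100, ])))
  expect_error(downsample_balance(X[1:3, ], c(1, 1, 0)), "down-sampling")
})

test_that("mined rules match brute-force enumeration on small feature sets", {
  cfg <- apriori_config(min_support = 0.02, min_confidence = 0.55,
                        max_length = 8)
  for (s in 1:5) {
    set.seed(500 + s)
    n <- 400
    X <- matrix(rbinom(n * 7, 1, runif(7, 0.1, 0.5)), n, 7)
    colnames(X) <- letters[1:7]
    y <- rbinom(n, 1, plogis(-0.5 + X %*% rnorm(7, 0.4, 0.5)))
    mined <- apriori_rules(X, y, cfg)
    oracle <- brute_force_rules(X, y, cfg)
    mined <- mined[order(mined$antecedent), , drop = FALSE]
    expect_equal(mined$antecedent, oracle$antecedent)
    expect_equal(mined$n_antecedent, oracle$n_antecedent)
    expect_equal(mined$n_with_outcome, oracle$n_with_outcome)
    expect_equal(mined$support, oracle$support)
    expect_equal(mined$confidence, oracle$confidence)
  }
})

test_that("max antecedent length is honoured against the oracle", {
  set.seed(88)
  X <- matrix(rbinom(300 * 6, 1, 0.5), 300, 6)
  colnames(X) <- letters[1:6]
  y <- rbinom(300, 1, 0.6)
  cfg <- apriori_config(min_support = 0.05, min_confidence = 0.5, max_length = 2)
  mined <- apriori_rules(X, y, cfg)
  expect_true(all(mined$length <= 2))
  oracle <- brute_force_rules(X, y, cfg)
  expect_setequal(mined$antecedent, oracle$antecedent)
})

test_that("a perfect predictor yields a confidence-1 rule and anti-monotonicity holds", {
  set.seed(10)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  X <- cbind(perf = y, r1 = rbinom(n, 1, 0.4), rare = rbinom(n, 1, 0.005))
  cfg <- apriori_config(min_support = 0.05, min_confidence = 0.55, max_length = 3)
  rules <- apriori_rules(X, y, cfg)
  perf <- rules[rules$antecedent == "perf", ]
  expect_equal(perf$confidence, 1)
  expect_equal(perf$support, mean(y))
  # below-support feature absent, and no antecedent contains it
  expect_false(any(grepl("rare", rules$antecedent)))
  # every subset of a frequent antecedent is itself frequent (anti-monotone;
  # support is checked directly since confidence filtering is not monotone)
  for (i in which(rules$length > 1)) {
    its <- rules$items[[i]]
    for (j in seq_along(its)) {
      sub_mask <- rowSums(X[, its[-j], drop = FALSE]) == length(its) - 1
      expect_gte(sum(sub_mask & y == 1) / n, cfg$min_support)
    }
  }
  expect_error(apriori_rules(cbind(x = c(0, 2, 1)), c(0, 1, 1), cfg), "binary")
})

test_that("Westfall-Young adjusted p dominates the per-rule permutation p", {
  set.seed(23)
  n <- 400
  X <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
  colnames(X) <- letters[1:5]
  y <- rbinom(n, 1, plogis(-0.2 + 0.8 * X[, 1]))
  cfg <- apriori_config(min_support = 0.05, min_confidence = 0.5, max_length = 2)
  rules <- apriori_rules(X, y, cfg)
  wy <- westfall_young(rules, X, y, n_perm = 150, alpha = 0.05, seed = 2)
  expect_true(all(wy$p_wy >= wy$p_unadjusted))
  expect_true(all(wy$p_wy >= 0 & wy$p_wy <= 1))
  # alpha = 0 selects nothing
  wy0 <- westfall_young(rules, X, y, n_perm = 150, alpha = 0, seed = 2)
  expect_false(any(wy0$selected))
  # zero rules: empty selection without error
  empty <- apriori_rules(X, 1 - y, apriori_config(min_support = 0.9))
  wye <- westfall_young(empty, X, 1 - y, n_perm = 150, seed = 1)
  expect_equal(nrow(wye), 0)
  expect_error(westfall_young(rules, X, y, n_perm = 50), "n_perm")
})

test_that("full-data risk ratios match the closed-form Katz interval", {
  X <- matrix(c(rep(1, 1000), rep(0, 1000)), ncol = 1)
  y <- c(rep(1, 30), rep(0, 970), rep(1, 10), rep(0, 990))
  m <- subgroup_metrics(1, X, y)
  expect_lt(abs(m$rr - 3), 1e-12)
  se <- sqrt(1 / 30 - 1 / 1000 + 1 / 10 - 1 / 1000)
  expect_lt(abs(m$rr_low - 3 * exp(-qnorm(0.975) * se)), 1e-6)
  expect_lt(abs(m$rr_high - 3 * exp(qnorm(0.975) * se)), 1e-6)
  expect_false(m$continuity_corrected)
  # in-group = everyone: undefined and flagged
  me <- subgroup_metrics(1, matrix(1, 100, 1), rbinom(100, 1, 0.3))
  expect_true(me$undefined)
  expect_true(is.na(me$rr))
  # zero cell: continuity corrected and flagged
  y0 <- c(rep(0, 1000), rep(1, 10), rep(0, 990))
  mz <- subgroup_metrics(1, X, y0)
  expect_true(mz$continuity_corrected)
  expect_gt(mz$rr, 0)
})

test_that("a planted carrier subgroup is recovered at its true prevalence and risk", {
  n <- 100000
  gen <- generate_cohort(sim_config(
    n, factors = list(latent_factor(
      "diabetes",
      codes = data.frame(code = "250", vocabulary = "dx-section",
                         emission_prob = 1),
      carrier_prevalence = 0.014, outcome_log_or = log(2.2))),
    age_log_or_per_year = 0, multiple_gestation_rate = 0, seed = 77))
  carr <- gen$truth$carriers[, 1]
  m <- subgroup_metrics(1, matrix(as.numeric(carr), ncol = 1), gen$truth$outcome)
  expect_lt(abs(m$prevalence - 0.014), 3 * sqrt(0.014 * 0.986 / n))
  # risk ratio near the planted odds ratio (rare outcome: RR ~ OR)
  expect_true(m$rr_low < 2.2 && 2.2 < m$rr_high)
})
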