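# Synthetic claims-cohort generator: determinism, calibration, planted
# structure, and configuration validation.

one_factor_config <- function(n, seed = 1, log_or = log(2.2), prev = 0.014) {
  sim_config(
    n_pregnancies = n,
    factors = list(latent_factor(
      "diabetes",
      codes = data.frame(code = c("250", "TD001"),
                         vocabulary = c("dx-section", "tdc"),
                         emission_prob = c(0.9, 0.6)),
      carrier_prevalence = prev, outcome_log_or = log_or)),
    age_log_or_per_year = 0,
    multiple_gestation_rate = 0,
    seed = seed)
}

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(2000, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tab in c("persons", "enroll", "dx_events", "rx_events",
                "pregnancies", "links")) {
    expect_identical(a$cohort[[tab]], b$cohort[[tab]])
  }
  expect_identical(a$truth$carriers, b$truth$carriers)
  expect_identical(a$truth$outcome, b$truth$outcome)
})

test_that("zero factors with baseline rate zero give a cohort with no outcome events", {
  cfg <- sim_config(500, factors = list(), baseline_outcome_rate = 0, seed = 3)
  gen <- generate_cohort(cfg)
  expect_equal(sum(gen$truth$outcome), 0)
  oc <- flag_outcomes(gen$cohort, gen$cohort$pregnancies$pregnancy_id,
                      default_outcome_codes())
  expect_equal(sum(oc$primary), 0)
})

test_that("carrier prevalence and carrier-outcome odds ratio match the planted values", {
  n <- 200000
  gen <- generate_cohort(one_factor_config(n, seed = 11))
  carr <- gen$truth$carriers[, 1]
  # empirical carrier prevalence within 3 binomial SDs of 1.4%
  expect_lt(abs(mean(carr) - 0.014), 3 * sqrt(0.014 * 0.986 / n))
  # closed-form 2x2 OR within simulation error of 2.2
  y <- gen$truth$outcome
  a <- sum(carr & y); b <- sum(carr & !y)
  cc <- sum(!carr & y); d <- sum(!carr & !y)
  lor <- logor_2x2(a, b, cc, d)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  expect_lt(abs(lor - log(2.2)), 3 * se)
})

test_that("marginal outcome rate matches the logistic model's implied rate", {
  n <- 100000
  gen <- generate_cohort(sim_config(n, seed = 5))
  rate <- mean(gen$truth$outcome)
  expect_lt(abs(rate - 0.013), 3 * sqrt(0.013 * 0.987 / n))
})

test_that("codes of a common factor are positively phi-correlated, noise codes are not", {
  gen <- generate_cohort(sim_config(10000, seed = 9))
  ids <- gen$cohort$pregnancies$pregnancy_id
  panel <- derive_panel(gen$cohort, ids, window_spec("maternal-dx"))
  rxp <- derive_panel(gen$cohort, ids, window_spec("maternal-rx"))
  ind <- cbind(panel$indicator, rxp$indicator)
  phi <- function(u, v) suppressWarnings(cor(as.numeric(u), as.numeric(v)))
  # same factor (diabetes): dx 250 with insulin-like TDCs
  expect_gt(phi(ind[, "250"], ind[, "TD001"]), 0.2)
  expect_gt(phi(ind[, "401"], ind[, "TD005"]), 0.2)
  # across factors and for noise, phi is near zero
  expect_lt(abs(phi(ind[, "250"], ind[, "401"])), 0.05)
  noise <- setdiff(colnames(ind), c("250", "401", "628", "655", "796", "758",
                                    paste0("TD00", 1:9)))
  expect_lt(abs(phi(ind[, noise[1]], ind[, noise[2]])), 0.05)
})

test_that("eligibility violations occur at the configured rate", {
  n <- 50000
  rate <- 0.08
  gen <- generate_cohort(sim_config(n, enrollment_gap_rate = rate, seed = 2))
  viol <- mean(gen$truth$violation != "none")
  expect_lt(abs(viol - rate), 3 * sqrt(rate * (1 - rate) / n))
  # and the violating pregnancies are exactly the ineligible ones
  el <- apply_eligibility(gen$cohort)
  flagged <- gen$truth$pregnancy_id[gen$truth$violation != "none"]
  expect_setequal(setdiff(gen$truth$pregnancy_id, el$eligible), flagged)
})

test_that("planted truth report covers every code with the right status", {
  f <- function(nm, code1, code2, lor) latent_factor(
    nm, data.frame(code = c(code1, code2),
                   vocabulary = c("dx-section", "tdc"),
                   emission_prob = c(0.8, 0.5)),
    carrier_prevalence = 0.05, outcome_log_or = lor)
  cfg <- sim_config(200,
                    factors = list(f("f1", "250", "TD001", log(2)),
                                   f("f2", "401", "TD002", 0),
                                   f("f3", "493", "TD003", log(1.5))),
                    n_noise_dx = 50, n_noise_rx = 50, seed = 1)
  gen <- generate_cohort(cfg)
  rep <- planted_truth_report(gen$truth)
  # 3 factors x 2 codes + 100 noise codes + chromosomal marker
  expect_equal(nrow(rep), 6 + 100 + 1)
  expect_false(any(duplicated(rep$code)))
  # zero-log-OR factor: OR 1 but factor linkage retained
  f2 <- rep[rep$factor %in% "f2", ]
  expect_equal(f2$true_or, c(1, 1))
  expect_equal(f2$true_status, c("factor", "factor"))
  expect_true(all(rep$true_or[rep$true_status == "null"] == 1))
})

test_that("all-noise configurations report every code as null with OR 1", {
  gen <- generate_cohort(sim_config(100, factors = list(), seed = 1))
  rep <- planted_truth_report(gen$truth)
  expect_true(all(rep$true_status == "null"))
  expect_true(all(rep$true_or == 1))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(0), "n_pregnancies")
  expect_error(sim_config(10, father_link_rate = 1.2), "father_link_rate")
  expect_error(latent_factor("x", data.frame(code = "250", vocabulary = "dx-section",
                                             emission_prob = 1.5),
                             0.1, 0), "emission_prob")
  expect_error(latent_factor("x", data.frame(code = c("250", "250"),
                                             vocabulary = "dx-section",
                                             emission_prob = 0.5),
                             0.1, 0), "unique")
})

test_that("a cohort round-trips through the TSV directory format", {
  gen <- generate_cohort(sim_config(300, seed = 8))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(gen$cohort, dir)
  back <- read_cohort(dir)
  for (tab in c("persons", "enroll", "dx_events", "rx_events",
                "pregnancies", "links")) {
    a <- gen$cohort[[tab]]; rownames(a) <- NULL
    b <- back[[tab]]; rownames(b) <- NULL
    expect_equal(a, b, ignore_attr = TRUE)
  }
  expect_equal(gen$cohort$gem$source, back$gem$source)
  unlink(dir, recursive = TRUE)
})
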