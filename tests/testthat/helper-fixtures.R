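# Fixtures and independent oracles shared across the suite.

# Hand-built cohort exercising every eligibility rule and window boundary.
# All pregnancies: LMP day 0, end day 270 (so end+30 = 300, end+90 = 360).
boundary_cohort <- function() {
  preg <- function(id, mother, age = 30, nf = 1) {
    data.frame(pregnancy_id = id, mother_id = mother, lmp_day = 0L,
               end_day = 270L, delivery_year = 2018L, n_fetuses = nf,
               age = age, stringsAsFactors = FALSE)
  }
  pregnancies <- rbind(
    preg("P1", "M1"),            # fully eligible
    preg("P2", "M2"),            # infant followup only to end+60 -> excluded
    preg("P3", "M3"),            # infant death at end+10 -> retained
    preg("P4", "M4"),            # maternal enrollment gap -> excluded
    preg("P5", "M5"),            # no rx benefit -> excluded
    preg("P6", "M6", age = 56),  # age out of bounds -> excluded
    preg("P7", "M7"),            # no linked infant -> excluded
    preg("P8", "M8", nf = 2))    # eligible twin

  persons <- data.frame(
    person_id = c(paste0("M", 1:8), "I1", "I2", "I3", "I4", "I5", "I6",
                  "I8a", "I8b", "FA1", "FB2", "FC8", "FD8"),
    sex = c(rep("F", 8), rep("F", 8), rep("M", 4)),
    birth_year = c(2018L - pregnancies$age, rep(2018L, 8),
                   1988L, 1988L, 1985L, 1960L),
    family_key = c(paste0("FAM", 1:8), "FAM1", "FAM2", "FAM3", "FAM4",
                   "FAM5", "FAM6", "FAM8", "FAM8",
                   "FAM1", "FAM2", "FAM8", "FAM8"),
    stringsAsFactors = FALSE)

  mom_span <- function(id, rx = TRUE) {
    data.frame(person_id = id, start_day = -200L, end_day = 310L,
               rx_benefit = rx, stringsAsFactors = FALSE)
  }
  enroll <- rbind(
    mom_span("M1"), mom_span("M2"), mom_span("M3"),
    # M4: gap -99..-91 inside [-180, 300]
    data.frame(person_id = "M4", start_day = c(-200L, -90L),
               end_day = c(-100L, 310L), rx_benefit = TRUE),
    mom_span("M5", rx = FALSE),
    mom_span("M6"), mom_span("M7"), mom_span("M8"),
    data.frame(person_id = "I1", start_day = 270L, end_day = 360L, rx_benefit = FALSE),
    data.frame(person_id = "I2", start_day = 270L, end_day = 330L, rx_benefit = FALSE),
    data.frame(person_id = "I3", start_day = 270L, end_day = 280L, rx_benefit = FALSE),
    data.frame(person_id = c("I4", "I5", "I6"), start_day = 270L,
               end_day = 360L, rx_benefit = FALSE),
    data.frame(person_id = "I8a", start_day = 270L, end_day = 370L, rx_benefit = FALSE),
    data.frame(person_id = "I8b", start_day = 270L, end_day = 370L, rx_benefit = FALSE),
    # FA1 qualifies for P1; FB2 has a 15-day gap inside [-180, 0]
    data.frame(person_id = "FA1", start_day = -200L, end_day = 10L, rx_benefit = TRUE),
    data.frame(person_id = "FB2", start_day = c(-200L, -35L),
               end_day = c(-50L, 10L), rx_benefit = TRUE),
    # FAM8 has two qualifying males (FC8 younger, FD8 older)
    data.frame(person_id = "FC8", start_day = -200L, end_day = 10L, rx_benefit = TRUE),
    data.frame(person_id = "FD8", start_day = -200L, end_day = 10L, rx_benefit = TRUE))

  dx_events <- data.frame(
    person_id = c("M1", "M1", "I1", "I8a"),
    day = c(-181L, -180L, 360L, 361L),
    code = c("4010", "4010", "7454", "7454"),
    vocabulary = "ICD9", stringsAsFactors = FALSE)
  rx_events <- data.frame(
    person_id = c("M1", "M1"), day = c(90L, 91L), tdc = "TD001",
    stringsAsFactors = FALSE)
  links <- data.frame(
    pregnancy_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P8", "P8"),
    infant_id = c("I1", "I2", "I3", "I4", "I5", "I6", "I8a", "I8b"),
    death_day = c(NA, NA, 280L, NA, NA, NA, NA, NA), stringsAsFactors = FALSE)
  claims_cohort(persons = persons, enroll = enroll, dx_events = dx_events,
                rx_events = rx_events, pregnancies = pregnancies, links = links)
}

# Direct Bernoulli simulator for the screening calibration experiments:
# binary codes with given prevalences, outcome from a logistic model with
# the given per-code log odds-ratios (no claims machinery involved).
simulate_screen_data <- function(n, prevalences, log_ors, base_rate,
                                 age_effect = 0) {
  m <- length(prevalences)
  X <- matrix(rbinom(n * m, 1L, rep(prevalences, each = n)), n, m)
  colnames(X) <- sprintf("c%03d", seq_len(m))
  ages <- pmin(55, pmax(12, round(rnorm(n, 31, 4.5))))
  lp <- qlogis(base_rate) + as.numeric(X %*% log_ors) + age_effect * (ages - 31)
  y <- rbinom(n, 1L, plogis(lp))
  list(X = X, y = y, ages = ages)
}

# Closed-form 2x2 log odds ratio.
logor_2x2 <- function(a, b, c, d) log((a * d) / (b * c))

# Brute-force oracle for outcome-consequent rule mining: enumerate every
# non-empty antecedent over <= 8 features and apply the same support /
# confidence / length thresholds.
brute_force_rules <- function(X, y, config) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(m <= 8)
  feats <- colnames(X)
  min_cnt <- ceiling(config$min_support * n)
  out <- list()
  for (bits in 1:(2^m - 1)) {
    items <- which(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0)
    if (length(items) > config$max_length) next
    mask <- rowSums(X[, items, drop = FALSE]) == length(items)
    cnt_a <- sum(mask)
    cnt_y <- sum(mask & y == 1)
    if (cnt_y < min_cnt) next
    conf <- cnt_y / cnt_a
    if (conf < config$min_confidence) next
    out[[length(out) + 1L]] <- data.frame(
      antecedent = paste(feats[items], collapse = "; "),
      n_antecedent = cnt_a, n_with_outcome = cnt_y,
      support = cnt_y / n, confidence = conf, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(antecedent = character(0), n_antecedent = numeric(0),
                      n_with_outcome = numeric(0), support = numeric(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$antecedent), , drop = FALSE]
}

# Adjusted Rand index between two labelings (used for cluster recovery).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nt <- comb2(sum(tab))
  expected <- si * sj / nt
  (sij - expected) / ((si + sj) / 2 - expected)
}
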