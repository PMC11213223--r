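# Synthetic claims-cohort generator.
#
# Emulates a commercial-claims pregnancy cohort with latent clinical factors:
# each factor has carriers who emit correlated diagnosis and medication codes
# inside the exposure-assessment windows, and contributes a planted log
# odds-ratio to the pregnancy-level outcome.  Everything downstream
# (eligibility, panels, screening, LSA, subgroup discovery) is testable
# against the generator's ground truth.

#' Specify a latent clinical factor
#'
#' A latent factor represents an unobserved clinical state (for example,
#' diabetes) whose carriers emit a correlated set of diagnosis and medication
#' codes and whose carrier status shifts the outcome odds by a planted
#' log odds-ratio.
#'
#' @param name Factor label.
#' @param codes Data frame with columns `code`, `vocabulary`
#'   (`"dx-section"` or `"tdc"`), and `emission_prob` in `[0, 1]`: the
#'   probability that a carrier emits at least one event with the code inside
#'   the relevant exposure window.
#' @param carrier_prevalence Carrier probability per pregnancy, strictly in
#'   `(0, 1)`.
#' @param outcome_log_or Log odds-ratio contribution of carrier status on the
#'   pregnancy-level outcome.
#' @param multiple_gestation_rate Optional carrier-specific multiple-gestation
#'   probability overriding the cohort-wide rate (used to emulate
#'   fertility-treatment factors whose apparent risk is a twin artifact).
#' @return An object of class `latent_factor`.
#' @export
#' @examples
#' latent_factor("diabetes",
#'   codes = data.frame(code = c("250", "TD001"),
#'                      vocabulary = c("dx-section", "tdc"),
#'                      emission_prob = c(0.9, 0.7)),
#'   carrier_prevalence = 0.014, outcome_log_or = log(2.2))
latent_factor <- function(name, codes, carrier_prevalence, outcome_log_or,
                          multiple_gestation_rate = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.data.frame(codes) ||
      !all(c("code", "vocabulary", "emission_prob") %in% names(codes))) {
    stop_config("codes", "must be a data frame with columns code, vocabulary, emission_prob")
  }
  if (!all(codes$vocabulary %in% c("dx-section", "tdc"))) {
    stop_config("codes$vocabulary", "must be 'dx-section' or 'tdc'")
  }
  if (anyDuplicated(codes$code)) {
    stop_config("codes$code", "must be unique within a factor")
  }
  check_prob(codes$emission_prob, "codes$emission_prob")
  check_prob(carrier_prevalence, "carrier_prevalence", open = TRUE)
  if (!is.numeric(outcome_log_or) || length(outcome_log_or) != 1L || is.na(outcome_log_or)) {
    stop_config("outcome_log_or", "must be a single real number")
  }
  if (!is.null(multiple_gestation_rate)) {
    check_prob(multiple_gestation_rate, "multiple_gestation_rate")
  }
  structure(list(name = name,
                 codes = data.frame(code = as.character(codes$code),
                                    vocabulary = as.character(codes$vocabulary),
                                    emission_prob = as.numeric(codes$emission_prob),
                                    stringsAsFactors = FALSE),
                 carrier_prevalence = carrier_prevalence,
                 outcome_log_or = outcome_log_or,
                 multiple_gestation_rate = multiple_gestation_rate),
            class = "latent_factor")
}

#' Default planted latent factors
#'
#' Four factors whose prevalences and effect sizes echo well-established
#' maternal risk patterns: a diabetes-like factor (prevalence 1.4%, OR 2.2,
#' diagnosis section plus insulin-like therapeutic detail codes), a chronic
#' hypertension-like factor (2.8%, OR 1.52), a fertility-treatment proxy with
#' no direct effect but an elevated multiple-gestation rate among carriers
#' (the twin-counting artifact), and a rare fetal-abnormality factor
#' (0.3%, OR 2.82).
#'
#' @return List of [latent_factor()] objects.
#' @export
default_factors <- function() {
  list(
    latent_factor("diabetes",
      codes = data.frame(
        code = c("250", "TD001", "TD002", "TD003"),
        vocabulary = c("dx-section", "tdc", "tdc", "tdc"),
        emission_prob = c(0.90, 0.60, 0.35, 0.25)),
      carrier_prevalence = 0.014, outcome_log_or = log(2.2)),
    latent_factor("hypertension",
      codes = data.frame(
        code = c("401", "TD005"),
        vocabulary = c("dx-section", "tdc"),
        emission_prob = c(0.85, 0.55)),
      carrier_prevalence = 0.028, outcome_log_or = log(1.52)),
    latent_factor("fertility_treatment",
      codes = data.frame(
        code = c("628", "TD006", "TD007"),
        vocabulary = c("dx-section", "tdc", "tdc"),
        emission_prob = c(0.70, 0.60, 0.45)),
      carrier_prevalence = 0.020, outcome_log_or = 0,
      multiple_gestation_rate = 0.30),
    latent_factor("fetal_abnormality",
      codes = data.frame(
        code = c("655", "796"),
        vocabulary = c("dx-section", "dx-section"),
        emission_prob = c(0.80, 0.50)),
      carrier_prevalence = 0.003, outcome_log_or = log(2.82))
  )
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study conditions of a large US commercial-claims
#' pregnancy cohort: baseline pregnancy-level outcome rate about 1.3%,
#' father linkage 70.4%, multiple gestation 3.4%, and maternal age with
#' median 31 and interquartile range 28-34 years.
#'
#' @param n_pregnancies Number of pregnancies (>= 1).
#' @param factors List of [latent_factor()] objects (may be empty).
#' @param n_noise_dx,n_noise_rx Numbers of null diagnosis-section and
#'   therapeutic-detail codes; marginal frequencies follow a power law so
#'   top-k code selection is non-trivial.
#' @param baseline_outcome_rate Target marginal pregnancy-level outcome rate;
#'   the model intercept is solved so the realized logistic model implies
#'   this rate.
#' @param father_link_rate Fraction of pregnancies with a linkable,
#'   fully-enrolled father.
#' @param multiple_gestation_rate Cohort-wide twin probability.
#' @param age_median,age_iqr Maternal age summary used to parameterize a
#'   discretized normal truncated to 12-55 years.
#' @param age_log_or_per_year Planted log odds-ratio per year of maternal age
#'   (centred at the median); gives the monotone age-risk curve.
#' @param enrollment_gap_rate Fraction of pregnancies assigned one random
#'   eligibility violation (maternal enrollment gap, missing drug benefit, or
#'   short infant follow-up).
#' @param infant_death_rate Rate of early infant death (the follow-up
#'   exception path).
#' @param icd10_fraction Probability that a diagnosis event is coded in
#'   ICD-10 (and so must pass through the GEM crosswalk).
#' @param distractor_rate Probability that a non-carrier emits a factor code
#'   outside the exposure window (exercises window boundaries).
#' @param chromosomal_rate Rate of a chromosomal-anomaly marker code
#'   (section 758) used by the no-chromosomal restriction.
#' @param extra_male_rate Rate of families with a non-qualifying male
#'   (enrollment gap in the paternal window).
#' @param tie_male_rate Rate of families with two qualifying males
#'   (exercises the oldest-male tie-break).
#' @param seed Integer seed; identical config and seed reproduce the cohort
#'   byte-identically.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_pregnancies,
                       factors = default_factors(),
                       n_noise_dx = 40, n_noise_rx = 30,
                       baseline_outcome_rate = 0.013,
                       father_link_rate = 0.704,
                       multiple_gestation_rate = 0.034,
                       age_median = 31, age_iqr = c(28, 34),
                       age_log_or_per_year = 0.03,
                       enrollment_gap_rate = 0.05,
                       infant_death_rate = 0.002,
                       icd10_fraction = 0.5,
                       distractor_rate = 0.02,
                       chromosomal_rate = 0.004,
                       extra_male_rate = 0.03,
                       tie_male_rate = 0.002,
                       seed = 1L) {
  if (!is.numeric(n_pregnancies) || length(n_pregnancies) != 1L ||
      is.na(n_pregnancies) || n_pregnancies < 1) {
    stop_config("n_pregnancies", "must be a positive count")
  }
  for (f in factors) {
    if (!inherits(f, "latent_factor")) stop_config("factors", "must be latent_factor objects")
  }
  all_codes <- unlist(lapply(factors, function(f) f$codes$code))
  if (anyDuplicated(all_codes)) {
    stop_config("factors", "share a code id; every non-noise code must map to exactly one factor")
  }
  check_prob(baseline_outcome_rate, "baseline_outcome_rate")
  check_prob(father_link_rate, "father_link_rate")
  check_prob(multiple_gestation_rate, "multiple_gestation_rate")
  check_prob(enrollment_gap_rate, "enrollment_gap_rate")
  check_prob(infant_death_rate, "infant_death_rate")
  check_prob(icd10_fraction, "icd10_fraction")
  check_prob(distractor_rate, "distractor_rate")
  check_prob(chromosomal_rate, "chromosomal_rate")
  check_prob(extra_male_rate, "extra_male_rate")
  check_prob(tie_male_rate, "tie_male_rate")
  structure(list(n_pregnancies = as.integer(n_pregnancies),
                 factors = factors,
                 n_noise_dx = as.integer(n_noise_dx),
                 n_noise_rx = as.integer(n_noise_rx),
                 baseline_outcome_rate = baseline_outcome_rate,
                 father_link_rate = father_link_rate,
                 multiple_gestation_rate = multiple_gestation_rate,
                 age_median = age_median, age_iqr = age_iqr,
                 age_log_or_per_year = age_log_or_per_year,
                 enrollment_gap_rate = enrollment_gap_rate,
                 infant_death_rate = infant_death_rate,
                 icd10_fraction = icd10_fraction,
                 distractor_rate = distractor_rate,
                 chromosomal_rate = chromosomal_rate,
                 extra_male_rate = extra_male_rate,
                 tie_male_rate = tie_male_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Noise-code power-law marginal prevalences (heavy-tailed, as in claims data).
noise_prevalences <- function(n) {
  if (n == 0L) return(numeric(0))
  pmax(0.002, pmin(0.30, 0.35 * seq_len(n)^-0.8))
}

# Synthetic stand-in cardiac-malformation code list (primary + 11 subtypes).
# Codes follow the ICD-9 745-747 / ICD-10 Q2x congenital-anomaly shape but
# are synthetic; real analyses supply validated lists via read_code_list().
#' Synthetic cardiac-malformation outcome code list
#'
#' @return Data frame with columns `code`, `vocabulary`, `subtype`.
#' @export
default_outcome_codes <- function() {
  sub <- c("conotruncal", "single_ventricle", "ventricular_septal",
           "atrial_septal", "atrioventricular_septal", "right_sided",
           "left_sided", "pda", "pphn", "great_veins", "other")
  icd9 <- c("7451", "7453", "7454", "7455", "7456", "7460",
            "7467", "7470", "7478", "7474", "7468")
  icd10 <- c("Q200", "Q204", "Q210", "Q211", "Q212", "Q220",
             "Q234", "Q250", "Q253", "Q262", "Q248")
  data.frame(code = c(icd9, icd10),
             vocabulary = rep(c("ICD9", "ICD10"), each = length(sub)),
             subtype = rep(sub, 2L),
             stringsAsFactors = FALSE)
}

# Relative frequencies of cardiac-malformation subtypes (ventricular septal
# defects dominate, then left-sided and atrial septal defects).
subtype_weights <- function() {
  w <- c(conotruncal = 0.02, single_ventricle = 0.01, ventricular_septal = 0.59,
         atrial_septal = 0.10, atrioventricular_septal = 0.01,
         right_sided = 0.02, left_sided = 0.14, pda = 0.03, pphn = 0.02,
         great_veins = 0.02, other = 0.04)
  w / sum(w)
}

#' Generate a synthetic claims cohort with known ground truth
#'
#' Draws pregnancies, mothers, linked fathers and infants, enrollment spans
#' (with planted eligibility violations), latent-factor carrier states,
#' correlated diagnosis/dispensing events inside the exposure windows, and a
#' pregnancy-level outcome from a logistic model with the planted log
#' odds-ratios.  All days are integer offsets from each pregnancy's last
#' menstrual period (LMP = day 0).
#'
#' @param config A [sim_config()].
#' @return List with elements `cohort` (a [claims_cohort()]) and `truth`
#'   (a `ground_truth` object; see [planted_truth_report()]).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config", "must be a sim_config")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_pregnancies
  nf_factors <- length(config$factors)

  preg_id <- sprintf("P%07d", seq_len(n))
  mother_id <- sprintf("M%07d", seq_len(n))
  family <- sprintf("FAM%07d", seq_len(n))
  delivery_year <- sample(2011:2021, n, replace = TRUE)

  # maternal age: discretized normal matched to median/IQR, truncated 12-55
  age_sd <- diff(config$age_iqr) / (2 * stats::qnorm(0.75))
  age <- round(rnorm(n, config$age_median, age_sd))
  age <- pmin(55, pmax(12, age))

  # latent-factor carriers
  carriers <- matrix(FALSE, n, nf_factors)
  colnames(carriers) <- vapply(config$factors, `[[`, character(1), "name")
  for (j in seq_len(nf_factors)) {
    carriers[, j] <- runif(n) < config$factors[[j]]$carrier_prevalence
  }

  # multiple gestation; factor-specific overrides apply to carriers
  mg_rate <- rep(config$multiple_gestation_rate, n)
  for (j in seq_len(nf_factors)) {
    r <- config$factors[[j]]$multiple_gestation_rate
    if (!is.null(r)) mg_rate[carriers[, j]] <- r
  }
  n_fetuses <- 1L + as.integer(runif(n) < mg_rate)

  end_day <- as.integer(pmin(300, pmax(200, round(rnorm(n, 273, 10)))) -
                          14L * (n_fetuses > 1L))

  # outcome: per-fetus logistic risk; intercept solved for the target
  # marginal pregnancy-level rate
  log_ors <- vapply(config$factors, `[[`, numeric(1), "outcome_log_or")
  lp <- as.numeric(carriers %*% log_ors) +
    config$age_log_or_per_year * (age - config$age_median)
  if (config$baseline_outcome_rate == 0) {
    b0 <- -Inf
    affected <- integer(n)
  } else {
    b0 <- uniroot(function(b) {
      mean(1 - (1 - plogis(b + lp))^n_fetuses) - config$baseline_outcome_rate
    }, c(-25, 5), tol = 1e-10)$root
    affected <- rbinom(n, n_fetuses, plogis(b0 + lp))
  }
  outcome <- affected > 0L

  # eligibility violations: one random violation type per flagged pregnancy
  viol <- rep("none", n)
  flagged <- runif(n) < config$enrollment_gap_rate
  viol[flagged] <- sample(c("maternal_gap", "no_rx_benefit", "infant_followup"),
                          sum(flagged), replace = TRUE)
  death <- !flagged & runif(n) < config$infant_death_rate

  # fathers
  has_father <- runif(n) < config$father_link_rate
  gap_father <- !has_father & runif(n) < config$extra_male_rate
  tie_father <- has_father & runif(n) < config$tie_male_rate
  father_age <- round(rnorm(n, 33, diff(c(30, 37)) / (2 * stats::qnorm(0.75))))
  father_age <- pmin(70, pmax(18, father_age))

  # ---- persons -------------------------------------------------------------
  persons <- list(data.frame(
    person_id = mother_id, sex = "F",
    birth_year = delivery_year - age, family_key = family,
    stringsAsFactors = FALSE))
  father_id <- ifelse(has_father | gap_father, sprintf("F%07d", seq_len(n)), NA_character_)
  fi <- which(!is.na(father_id))
  persons[[2]] <- data.frame(
    person_id = father_id[fi], sex = "M",
    birth_year = delivery_year[fi] - father_age[fi], family_key = family[fi],
    stringsAsFactors = FALSE)
  ti <- which(tie_father)
  tie_id <- sprintf("G%07d", ti)
  if (length(ti)) {
    persons[[3]] <- data.frame(
      person_id = tie_id, sex = "M",
      birth_year = delivery_year[ti] - father_age[ti] - 25L, family_key = family[ti],
      stringsAsFactors = FALSE)
  }

  # infants (one row per fetus)
  inf_n <- n_fetuses
  inf_preg <- rep(seq_len(n), inf_n)
  inf_ord <- sequence(inf_n)
  infant_id <- sprintf("I%07d_%d", inf_preg, inf_ord)
  persons[[length(persons) + 1L]] <- data.frame(
    person_id = infant_id, sex = sample(c("F", "M"), length(infant_id), replace = TRUE),
    birth_year = delivery_year[inf_preg], family_key = family[inf_preg],
    stringsAsFactors = FALSE)
  persons <- do.call(rbind, persons)

  # ---- enrollment spans ----------------------------------------------------
  spans <- list()
  # mothers
  mg_idx <- viol == "maternal_gap"
  rx_idx <- viol == "no_rx_benefit"
  ok_idx <- !mg_idx
  spans[[1]] <- data.frame(
    person_id = mother_id[ok_idx], start_day = -220L,
    end_day = end_day[ok_idx] + 40L, rx_benefit = !rx_idx[ok_idx],
    stringsAsFactors = FALSE)
  if (any(mg_idx)) {
    spans[[2]] <- data.frame(
      person_id = rep(mother_id[mg_idx], 2L),
      start_day = c(rep(-220L, sum(mg_idx)), rep(-45L, sum(mg_idx))),
      end_day = c(rep(-60L, sum(mg_idx)), end_day[mg_idx] + 40L),
      rx_benefit = TRUE, stringsAsFactors = FALSE)
  }
  # fathers: qualifying cover [-220, 10]; gap fathers have a hole pre-LMP
  qual <- which(has_father)
  spans[[length(spans) + 1L]] <- data.frame(
    person_id = father_id[qual], start_day = -220L, end_day = 10L,
    rx_benefit = TRUE, stringsAsFactors = FALSE)
  gapq <- which(gap_father)
  if (length(gapq)) {
    spans[[length(spans) + 1L]] <- data.frame(
      person_id = rep(father_id[gapq], 2L),
      start_day = c(rep(-220L, length(gapq)), rep(-80L, length(gapq))),
      end_day = c(rep(-100L, length(gapq)), rep(10L, length(gapq))),
      rx_benefit = TRUE, stringsAsFactors = FALSE)
  }
  if (length(ti)) {
    spans[[length(spans) + 1L]] <- data.frame(
      person_id = tie_id, start_day = -220L, end_day = 10L,
      rx_benefit = TRUE, stringsAsFactors = FALSE)
  }
  # infants: full follow-up unless short-follow-up violation or early death
  inf_viol <- viol[inf_preg] == "infant_followup"
  inf_death <- death[inf_preg] & inf_ord == 1L
  inf_end <- end_day[inf_preg] + ifelse(inf_death, 10L, ifelse(inf_viol, 60L, 100L))
  spans[[length(spans) + 1L]] <- data.frame(
    person_id = infant_id, start_day = end_day[inf_preg], end_day = inf_end,
    rx_benefit = FALSE, stringsAsFactors = FALSE)
  enroll <- do.call(rbind, spans)

  # ---- code events ---------------------------------------------------------
  # code universe: factor codes + power-law noise codes
  factor_code_tab <- do.call(rbind, lapply(config$factors, function(f) {
    data.frame(code = f$codes$code, vocabulary = f$codes$vocabulary,
               emission_prob = f$codes$emission_prob, factor = f$name,
               log_or = f$outcome_log_or, stringsAsFactors = FALSE)
  }))
  used_sections <- c("745", "746", "747", "758",
                     if (!is.null(factor_code_tab))
                       factor_code_tab$code[factor_code_tab$vocabulary == "dx-section"])
  pool <- setdiff(sprintf("%03d", 100:599), used_sections)
  noise_dx <- pool[seq_len(config$n_noise_dx)]
  noise_rx <- sprintf("TD1%02d", seq_len(config$n_noise_rx))
  prev_dx <- noise_prevalences(config$n_noise_dx)
  prev_rx <- noise_prevalences(config$n_noise_rx)

  dxl <- list(); rxl <- list()
  emit_dx <- function(person, section, day) {
    m <- length(person)
    if (m == 0L) return(NULL)
    is10 <- runif(m) < config$icd10_fraction
    data.frame(person_id = person,
               day = as.integer(day),
               code = ifelse(is10, paste0("X", section), paste0(section, "0")),
               vocabulary = ifelse(is10, "ICD10", "ICD9"),
               stringsAsFactors = FALSE)
  }
  rand_days <- function(k, lo, hi) as.integer(floor(runif(k, lo, hi + 1)))
  emit_rx <- function(person, day, tdc) {
    if (length(person) == 0L) return(NULL)
    data.frame(person_id = person, day = as.integer(day), tdc = tdc,
               stringsAsFactors = FALSE)
  }

  # factor-code emissions: carriers inside windows, distractors outside
  if (nf_factors > 0L) {
    for (j in seq_len(nf_factors)) {
      f <- config$factors[[j]]
      cj <- which(carriers[, j])
      nc <- which(!carriers[, j])
      for (r in seq_len(nrow(f$codes))) {
        emit <- cj[runif(length(cj)) < f$codes$emission_prob[r]]
        distract <- nc[runif(length(nc)) < config$distractor_rate]
        cnt <- 1L + rpois(length(emit), 0.5)
        who <- rep(emit, cnt)
        if (f$codes$vocabulary[r] == "dx-section") {
          dxl[[length(dxl) + 1L]] <- emit_dx(mother_id[who], f$codes$code[r],
                                             rand_days(length(who), -180, 90))
          dxl[[length(dxl) + 1L]] <- emit_dx(mother_id[distract], f$codes$code[r],
                                             rand_days(length(distract), 120, 250))
        } else {
          rxl[[length(rxl) + 1L]] <- emit_rx(mother_id[who],
            rand_days(length(who), 0, 90), f$codes$code[r])
          rxl[[length(rxl) + 1L]] <- emit_rx(mother_id[distract],
            rand_days(length(distract), 120, 250), f$codes$code[r])
        }
      }
    }
  }

  # noise emissions: mothers (inside maternal windows) and fathers (paternal)
  fathers_linked <- father_id[has_father]
  for (j in seq_along(noise_dx)) {
    emit <- which(runif(n) < prev_dx[j])
    cnt <- 1L + rpois(length(emit), 0.5)
    who <- rep(emit, cnt)
    dxl[[length(dxl) + 1L]] <- emit_dx(mother_id[who], noise_dx[j],
                                       rand_days(length(who), -180, 90))
    femit <- fathers_linked[runif(length(fathers_linked)) < prev_dx[j]]
    dxl[[length(dxl) + 1L]] <- emit_dx(femit, noise_dx[j],
                                       rand_days(length(femit), -180, 0))
  }
  for (j in seq_along(noise_rx)) {
    emit <- which(runif(n) < prev_rx[j])
    rxl[[length(rxl) + 1L]] <- emit_rx(mother_id[emit],
      rand_days(length(emit), 0, 90), noise_rx[j])
    femit <- fathers_linked[runif(length(fathers_linked)) < prev_rx[j]]
    rxl[[length(rxl) + 1L]] <- emit_rx(femit,
      rand_days(length(femit), -90, 0), noise_rx[j])
  }

  # chromosomal-anomaly marker (section 758) for the restriction filters
  chrom <- which(runif(n) < config$chromosomal_rate)
  dxl[[length(dxl) + 1L]] <- emit_dx(mother_id[chrom], "758",
                                     rand_days(length(chrom), 0, 90))

  # infant outcome codes: affected fetuses get a subtype-specific cardiac code
  oc <- default_outcome_codes()
  wts <- subtype_weights()
  aff_rows <- which(inf_ord <= affected[inf_preg])
  if (length(aff_rows)) {
    st <- sample(names(wts), length(aff_rows), replace = TRUE, prob = wts)
    is10 <- runif(length(aff_rows)) < config$icd10_fraction
    voc <- ifelse(is10, "ICD10", "ICD9")
    key <- paste(st, voc)
    lut <- stats::setNames(oc$code, paste(oc$subtype, oc$vocabulary))
    dxl[[length(dxl) + 1L]] <- data.frame(
      person_id = infant_id[aff_rows],
      day = end_day[inf_preg[aff_rows]] + rand_days(length(aff_rows), 5, 60),
      code = unname(lut[key]), vocabulary = voc, stringsAsFactors = FALSE)
  }

  dx_events <- do.call(rbind, dxl[!vapply(dxl, is.null, logical(1))])
  rx_events <- do.call(rbind, rxl[!vapply(rxl, is.null, logical(1))])
  if (is.null(dx_events)) dx_events <- data.frame(
    person_id = character(), day = integer(), code = character(),
    vocabulary = character(), stringsAsFactors = FALSE)
  if (is.null(rx_events)) rx_events <- data.frame(
    person_id = character(), day = integer(), tdc = character(),
    stringsAsFactors = FALSE)

  # GEM crosswalk for every synthetic ICD-10 leaf: "X<section>" -> "<section>0"
  sections <- sort(unique(c(noise_dx, "758",
                            if (!is.null(factor_code_tab))
                              factor_code_tab$code[factor_code_tab$vocabulary == "dx-section"])))
  gem <- data.frame(source = paste0("X", sections),
                    target = paste0(sections, "0"),
                    flags = 0L, stringsAsFactors = FALSE)

  pregnancies <- data.frame(
    pregnancy_id = preg_id, mother_id = mother_id, lmp_day = 0L,
    end_day = end_day, delivery_year = delivery_year,
    n_fetuses = n_fetuses, age = age, stringsAsFactors = FALSE)
  links <- data.frame(
    pregnancy_id = preg_id[inf_preg], infant_id = infant_id,
    death_day = ifelse(inf_death, end_day[inf_preg] + 10L, NA_integer_),
    stringsAsFactors = FALSE)

  cohort <- claims_cohort(persons = persons, enroll = enroll,
                          dx_events = dx_events, rx_events = rx_events,
                          pregnancies = pregnancies, links = links, gem = gem)

  code_truth <- rbind(
    if (!is.null(factor_code_tab))
      data.frame(code = factor_code_tab$code,
                 vocabulary = factor_code_tab$vocabulary,
                 factor = factor_code_tab$factor,
                 true_log_or = factor_code_tab$log_or,
                 stringsAsFactors = FALSE),
    data.frame(code = c(noise_dx, "758", noise_rx),
               vocabulary = c(rep("dx-section", length(noise_dx) + 1L),
                              rep("tdc", length(noise_rx))),
               factor = NA_character_, true_log_or = 0,
               stringsAsFactors = FALSE))
  truth <- structure(list(
    codes = code_truth,
    carriers = carriers,
    pregnancy_id = preg_id,
    outcome = outcome,
    violation = viol,
    intercept = b0,
    age_log_or_per_year = config$age_log_or_per_year,
    config = config), class = "ground_truth")

  list(cohort = cohort, truth = truth)
}

#' Report the planted per-code truth
#'
#' One row per code in the generator's code universe: its true status
#' (`"null"` for noise codes, `"factor"` for factor-emitted codes) and true
#' odds ratio (1 for noise codes and for factor codes whose factor has log
#' odds-ratio zero; factor linkage is retained either way).
#'
#' @param truth A `ground_truth` object from [generate_cohort()].
#' @return Data frame with columns `code`, `vocabulary`, `true_status`,
#'   `factor`, `true_or`.
#' @export
planted_truth_report <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  codes <- truth$codes
  data.frame(code = codes$code,
             vocabulary = codes$vocabulary,
             true_status = ifelse(is.na(codes$factor), "null", "factor"),
             factor = codes$factor,
             true_or = exp(codes$true_log_or),
             stringsAsFactors = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", nrow(x$codes), "codes,",
      ncol(x$carriers), "latent factors,",
      length(x$pregnancy_id), "pregnancies\n")
  cat("  planted outcome rate:", format(mean(x$outcome), digits = 3), "\n")
  invisible(x)
}
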