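# Cohort construction: eligibility rules, father linkage, ICD crosswalking,
# exposure-window covariate panels, top-k code selection, outcome flagging,
# and sensitivity-analysis restrictions.

#' Eligibility configuration
#'
#' @param pre_lmp_days Required continuous maternal enrollment before LMP
#'   (default 180).
#' @param post_end_days Required maternal enrollment after the pregnancy end
#'   (default 30).
#' @param infant_followup_days Required infant enrollment after the pregnancy
#'   end, waived on infant death (default 90).
#' @param paternal_window Paternal continuous-enrollment window in days
#'   relative to LMP (default `c(-180, 0)`, the spermatogenesis window).
#' @param age_bounds Maternal age bounds in years (default 12-55).
#' @return Object of class `eligibility_config`.
#' @export
eligibility_config <- function(pre_lmp_days = 180L, post_end_days = 30L,
                               infant_followup_days = 90L,
                               paternal_window = c(-180L, 0L),
                               age_bounds = c(12L, 55L)) {
  if (any(c(pre_lmp_days, post_end_days, infant_followup_days) < 0)) {
    stop_config("day counts", "must be >= 0")
  }
  structure(list(pre_lmp_days = as.integer(pre_lmp_days),
                 post_end_days = as.integer(post_end_days),
                 infant_followup_days = as.integer(infant_followup_days),
                 paternal_window = as.integer(paternal_window),
                 age_bounds = age_bounds),
            class = "eligibility_config")
}

#' Apply the study eligibility rules
#'
#' A pregnancy is retained iff (in application order): it has at least one
#' linked infant; the mother is continuously enrolled from `pre_lmp_days`
#' before LMP through `post_end_days` after the pregnancy end; the mother
#' holds full medication benefits from `pre_lmp_days` before LMP through the
#' pregnancy end; every linked infant is enrolled through
#' `infant_followup_days` after the end of pregnancy or died earlier; and
#' maternal age lies inside `age_bounds`.
#'
#' @param cohort A [claims_cohort()].
#' @param cfg An [eligibility_config()].
#' @return List with `eligible` (character vector of pregnancy ids) and
#'   `tally` (data frame of exclusions per rule, in application order; each
#'   rule counts only pregnancies surviving the previous rules).
#' @export
apply_eligibility <- function(cohort, cfg = eligibility_config()) {
  pg <- cohort$pregnancies
  rules <- c("no_linked_infant", "maternal_enrollment", "rx_benefit",
             "infant_followup", "maternal_age")
  tally <- stats::setNames(integer(length(rules)), rules)
  if (nrow(pg) == 0L) {
    return(list(eligible = character(0),
                tally = data.frame(rule = rules, excluded = unname(tally),
                                   stringsAsFactors = FALSE)))
  }
  alive <- rep(TRUE, nrow(pg))

  # (0) upstream linkage failure: no linked infant at all
  has_infant <- pg$pregnancy_id %in% cohort$links$pregnancy_id
  tally["no_linked_infant"] <- sum(alive & !has_infant)
  alive <- alive & has_infant

  # (a) maternal continuous enrollment over [LMP - pre, end + post]
  cov_a <- spans_cover(cohort$enroll, pg$mother_id,
                       pg$lmp_day - cfg$pre_lmp_days,
                       pg$end_day + cfg$post_end_days)
  tally["maternal_enrollment"] <- sum(alive & !cov_a)
  alive <- alive & cov_a

  # (b) medication benefits over [LMP - pre, end]
  rx_spans <- cohort$enroll[cohort$enroll$rx_benefit, , drop = FALSE]
  cov_b <- spans_cover(rx_spans, pg$mother_id,
                       pg$lmp_day - cfg$pre_lmp_days, pg$end_day)
  tally["rx_benefit"] <- sum(alive & !cov_b)
  alive <- alive & cov_b

  # (c) every linked infant enrolled through end + followup, or died earlier
  lk <- cohort$links
  lk <- lk[lk$pregnancy_id %in% pg$pregnancy_id, , drop = FALSE]
  pi <- match(lk$pregnancy_id, pg$pregnancy_id)
  need_to <- pg$end_day[pi] + cfg$infant_followup_days
  died_first <- !is.na(lk$death_day) & lk$death_day <= need_to
  inf_cov <- spans_cover(cohort$enroll, lk$infant_id, pg$end_day[pi], need_to)
  inf_ok <- inf_cov | died_first
  bad_preg <- unique(lk$pregnancy_id[!inf_ok])
  cov_c <- !(pg$pregnancy_id %in% bad_preg)
  tally["infant_followup"] <- sum(alive & !cov_c)
  alive <- alive & cov_c

  # (d) maternal age bounds
  cov_d <- pg$age >= cfg$age_bounds[1] & pg$age <= cfg$age_bounds[2]
  tally["maternal_age"] <- sum(alive & !cov_d)
  alive <- alive & cov_d

  list(eligible = pg$pregnancy_id[alive],
       tally = data.frame(rule = rules, excluded = unname(tally),
                          stringsAsFactors = FALSE))
}

#' Link fathers to eligible pregnancies
#'
#' The father is the adult male sharing the mother's family key, continuously
#' enrolled with medication benefits over the paternal window (LMP - 180 days
#' to LMP by default).  When several males qualify the oldest is chosen
#' (ties broken by lexicographic person id); tied pregnancies are recorded in
#' the `ties` attribute.
#'
#' @param cohort A [claims_cohort()].
#' @param eligible Character vector of pregnancy ids (subset of the cohort).
#' @param cfg An [eligibility_config()].
#' @return Named character vector mapping pregnancy id to father person id;
#'   unlinked pregnancies are absent.
#' @export
link_fathers <- function(cohort, eligible, cfg = eligibility_config()) {
  pg <- cohort$pregnancies
  if (!all(eligible %in% pg$pregnancy_id)) {
    stop_config("eligible", "contains pregnancy ids absent from the cohort")
  }
  pg <- pg[match(eligible, pg$pregnancy_id), , drop = FALSE]
  if (nrow(pg) == 0L) return(stats::setNames(character(0), character(0)))
  ps <- cohort$persons
  males <- ps[ps$sex == "M", , drop = FALSE]
  mother_fam <- ps$family_key[match(pg$mother_id, ps$person_id)]
  cand <- merge(
    data.frame(pregnancy_id = pg$pregnancy_id, family_key = mother_fam,
               lmp_day = pg$lmp_day, delivery_year = pg$delivery_year,
               stringsAsFactors = FALSE),
    males[, c("person_id", "birth_year", "family_key")],
    by = "family_key")
  if (nrow(cand) == 0L) return(stats::setNames(character(0), character(0)))
  # adult at delivery
  cand <- cand[cand$delivery_year - cand$birth_year >= 18L, , drop = FALSE]
  # continuous enrollment + medication benefits over the paternal window
  rx_spans <- cohort$enroll[cohort$enroll$rx_benefit, , drop = FALSE]
  ok <- spans_cover(rx_spans, cand$person_id,
                    cand$lmp_day + cfg$paternal_window[1],
                    cand$lmp_day + cfg$paternal_window[2])
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(stats::setNames(character(0), character(0)))
  # oldest first, then lexicographic id; first row per pregnancy wins
  cand <- cand[order(cand$pregnancy_id, cand$birth_year, cand$person_id), ,
               drop = FALSE]
  dup <- duplicated(cand$pregnancy_id)
  ties <- unique(cand$pregnancy_id[dup])
  picked <- cand[!dup, , drop = FALSE]
  out <- stats::setNames(picked$person_id, picked$pregnancy_id)
  attr(out, "ties") <- ties
  out
}

#' Read a General Equivalence Mapping file
#'
#' Whitespace-delimited rows of `source target flags` (the CMS GEM dialect);
#' rows with fewer than two fields raise a parse error naming the line.
#'
#' @param path File path.
#' @return Data frame with columns `source`, `target`, `flags`.
#' @export
read_gem <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed GEM row at line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  }
  data.frame(source = vapply(parts, `[`, character(1), 1L),
             target = vapply(parts, `[`, character(1), 2L),
             flags = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "0",
                            character(1)),
             stringsAsFactors = FALSE)
}

#' Map ICD-10 codes to ICD-9 3-digit sections
#'
#' Returns the 3-digit section (first three characters) of the GEM target
#' ICD-9 code.  Codes absent from the GEM return the sentinel `"UNMAPPED"`.
#' When a source has several targets, the first listed is used; the code is
#' flagged ambiguous only if its targets disagree at the 3-digit section
#' level.
#'
#' @param codes Character vector of ICD-10 codes.
#' @param gem GEM table from [read_gem()] (columns `source`, `target`).
#' @return Character vector of sections with attributes `n_unmapped` and
#'   `ambiguous` (the distinct ambiguous source codes).
#' @export
map_icd10_to_icd9_section <- function(codes, gem) {
  sec <- substr(gem$target, 1L, 3L)
  first <- !duplicated(gem$source)
  lut <- stats::setNames(sec[first], gem$source[first])
  out <- unname(lut[codes])
  out[is.na(out)] <- "UNMAPPED"
  # ambiguity: same source, disagreeing 3-digit sections
  amb_src <- unique(gem$source[stats::ave(as.integer(factor(sec)), gem$source,
                                          FUN = function(v) length(unique(v))) > 1L])
  attr(out, "n_unmapped") <- sum(out == "UNMAPPED")
  attr(out, "ambiguous") <- intersect(unique(codes), amb_src)
  out
}

#' Exposure-window specification
#'
#' Closed integer-day intervals relative to LMP.  The main-analysis presets
#' are: maternal diagnoses `[-180, 90]`, maternal medications `[0, 90]`
#' (first trimester), paternal diagnoses `[-180, 0]`, paternal medications
#' `[-90, 0]` (spermatogenesis).  The acute preset narrows diagnosis windows
#' to `[0, 90]` (maternal) and `[-90, 0]` (paternal).
#'
#' @param role One of `"maternal-dx"`, `"maternal-rx"`, `"paternal-dx"`,
#'   `"paternal-rx"`.
#' @param start,end Day offsets relative to LMP (start <= end); defaults are
#'   the main-analysis preset for the role.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(role = c("maternal-dx", "maternal-rx",
                                 "paternal-dx", "paternal-rx"),
                        start = NULL, end = NULL) {
  role <- match.arg(role)
  preset <- switch(role,
    "maternal-dx" = c(-180L, 90L), "maternal-rx" = c(0L, 90L),
    "paternal-dx" = c(-180L, 0L), "paternal-rx" = c(-90L, 0L))
  if (is.null(start)) start <- preset[1]
  if (is.null(end)) end <- preset[2]
  if (start > end) stop_config("window", "must have start <= end")
  structure(list(role = role, start = as.integer(start), end = as.integer(end)),
            class = "window_spec")
}

#' @rdname window_spec
#' @param preset `"main"` or `"acute"`.
#' @export
window_preset <- function(role, preset = c("main", "acute")) {
  preset <- match.arg(preset)
  w <- window_spec(role)
  if (preset == "acute") {
    if (role == "maternal-dx") w <- window_spec(role, 0L, 90L)
    if (role == "paternal-dx") w <- window_spec(role, -90L, 0L)
  }
  w
}

#' Derive an exposure-window covariate panel
#'
#' Counts, per pregnancy and code, the events of the relevant parent within
#' the closed window `[LMP + start, LMP + end]`.  Diagnosis codes are
#' collapsed to ICD-9 3-digit sections first (ICD-9 by prefix, ICD-10 through
#' the GEM crosswalk); dispensings are kept at the therapeutic-detail-code
#' level.  The indicator matrix is `count >= threshold`.
#'
#' @param cohort A [claims_cohort()].
#' @param pregnancies Character vector of pregnancy ids to include.
#' @param window A [window_spec()].
#' @param threshold Occurrence threshold for the indicator (default 1; the
#'   two-or-more sensitivity analysis uses 2).
#' @param fathers Named pregnancy-to-father map from [link_fathers()]
#'   (required for paternal roles; pregnancies without a linked father are
#'   dropped and tallied in the `dropped_no_father` attribute).
#' @param gem GEM table; defaults to the cohort's own.
#' @return Object of class `covariate_panel`: pregnancy index, code index,
#'   sparse indicator and count matrices, threshold and window used.
#' @export
derive_panel <- function(cohort, pregnancies, window, threshold = 1L,
                         fathers = NULL, gem = cohort$gem) {
  stopifnot(inherits(window, "window_spec"))
  if (threshold < 1L) stop_config("threshold", "must be >= 1")
  paternal <- grepl("^paternal", window$role)
  use_dx <- grepl("dx$", window$role)

  pg <- cohort$pregnancies
  pg <- pg[match(pregnancies, pg$pregnancy_id), , drop = FALSE]
  dropped <- character(0)
  if (paternal) {
    if (is.null(fathers)) stop_config("fathers", "is required for paternal windows")
    linked <- pg$pregnancy_id %in% names(fathers)
    dropped <- pg$pregnancy_id[!linked]
    pg <- pg[linked, , drop = FALSE]
    person <- unname(fathers[pg$pregnancy_id])
  } else {
    person <- pg$mother_id
  }

  ev <- if (use_dx) cohort$dx_events else cohort$rx_events
  # join events onto pregnancies via the relevant parent
  key <- data.frame(person_id = person, pregnancy_id = pg$pregnancy_id,
                    lmp_day = pg$lmp_day, stringsAsFactors = FALSE)
  ev <- merge(ev, key, by = "person_id")
  ev <- ev[ev$day >= ev$lmp_day + window$start &
             ev$day <= ev$lmp_day + window$end, , drop = FALSE]

  n_unmapped <- 0L
  if (use_dx) {
    code <- character(nrow(ev))
    is9 <- ev$vocabulary == "ICD9"
    code[is9] <- substr(ev$code[is9], 1L, 3L)
    if (any(!is9)) {
      if (is.null(gem)) stop_config("gem", "is required to map ICD-10 codes")
      mapped <- map_icd10_to_icd9_section(ev$code[!is9], gem)
      code[!is9] <- mapped
      n_unmapped <- attr(mapped, "n_unmapped")
    }
    ev$panel_code <- code
    ev <- ev[ev$panel_code != "UNMAPPED", , drop = FALSE]
    voc <- "dx-section"
  } else {
    ev$panel_code <- ev$tdc
    voc <- "tdc"
  }

  codes <- sort(unique(ev$panel_code))
  if (length(codes)) {
    i <- match(ev$pregnancy_id, pg$pregnancy_id)
    j <- match(ev$panel_code, codes)
    counts <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, nrow(ev)),
                                   dims = c(nrow(pg), length(codes)),
                                   dimnames = list(pg$pregnancy_id, codes))
  } else {
    counts <- Matrix::Matrix(0, nrow(pg), 0, sparse = TRUE,
                             dimnames = list(pg$pregnancy_id, NULL))
  }
  indicator <- counts >= threshold
  structure(list(
    pregnancies = pg$pregnancy_id,
    codes = data.frame(code = codes,
                       vocabulary = rep(voc, length(codes)),
                       role = rep(window$role, length(codes)),
                       label = codes,
                       stringsAsFactors = FALSE),
    indicator = methods::as(indicator, "CsparseMatrix"),
    counts = counts,
    threshold = as.integer(threshold),
    window = window,
    dropped_no_father = dropped,
    n_unmapped = n_unmapped), class = "covariate_panel")
}

#' @export
print.covariate_panel <- function(x, ...) {
  cat(sprintf("Covariate panel [%s, days %d..%d, threshold %d]: %d pregnancies x %d codes\n",
              x$window$role, x$window$start, x$window$end, x$threshold,
              length(x$pregnancies), nrow(x$codes)))
  invisible(x)
}

#' Retain the k most prevalent codes of a panel
#'
#' Prevalence is the number of pregnancies with indicator 1.  Codes are
#' ranked by descending prevalence with ties broken by lexicographically
#' smaller code id; if fewer than `k` codes exist all are retained.
#'
#' @param panel A [derive_panel()] result.
#' @param k Number of codes to keep (default 500).
#' @return A reduced `covariate_panel`.
#' @export
select_top_codes <- function(panel, k = 500L) {
  stopifnot(inherits(panel, "covariate_panel"))
  if (k < 1L) stop_config("k", "must be >= 1")
  prev <- Matrix::colSums(panel$indicator)
  ord <- order(-prev, panel$codes$code)
  keep <- sort(ord[seq_len(min(k, length(ord)))])
  panel$codes <- panel$codes[keep, , drop = FALSE]
  panel$indicator <- panel$indicator[, keep, drop = FALSE]
  panel$counts <- panel$counts[, keep, drop = FALSE]
  panel
}

#' Read an outcome code list
#'
#' Delimited file with columns `code`, `vocabulary` and optionally `subtype`.
#'
#' @param path File path (tab-separated with header).
#' @return Data frame.
#' @export
read_code_list <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("code", "vocabulary") %in% names(df))) {
    stop_config("code list", "must have columns code and vocabulary")
  }
  if (is.null(df$subtype)) df$subtype <- "primary"
  df
}

#' Flag pregnancy-level outcomes from infant codes
#'
#' A pregnancy is flagged iff any linked infant has a qualifying code within
#' the infant follow-up window (`[end, end + followup_days]`, closed);
#' multiple infants' records are unioned (pregnancy-level presence).  Subtype
#' flags are independent and non-exclusive.
#'
#' @param cohort A [claims_cohort()].
#' @param pregnancies Character vector of pregnancy ids.
#' @param code_lists Data frame with columns `code`, `vocabulary`, `subtype`
#'   (see [default_outcome_codes()]); the primary outcome is any subtype.
#' @param followup_days Follow-up length in days (default 90).
#' @return Data frame: `pregnancy_id`, `primary`, and one logical column per
#'   subtype.
#' @export
flag_outcomes <- function(cohort, pregnancies, code_lists,
                          followup_days = 90L) {
  if (is.null(code_lists) || nrow(code_lists) == 0L) {
    stop_config("code_lists", "must be a non-empty code list")
  }
  if (is.null(code_lists$subtype)) code_lists$subtype <- "primary"
  pg <- cohort$pregnancies
  pg <- pg[match(pregnancies, pg$pregnancy_id), , drop = FALSE]
  lk <- cohort$links[cohort$links$pregnancy_id %in% pg$pregnancy_id, , drop = FALSE]
  ev <- merge(cohort$dx_events,
              lk[, c("pregnancy_id", "infant_id")],
              by.x = "person_id", by.y = "infant_id")
  pi <- match(ev$pregnancy_id, pg$pregnancy_id)
  ev <- ev[ev$day >= pg$end_day[pi] &
             ev$day <= pg$end_day[pi] + followup_days, , drop = FALSE]
  key <- paste(ev$code, ev$vocabulary)
  list_key <- paste(code_lists$code, code_lists$vocabulary)
  hit <- match(key, list_key)
  ev <- ev[!is.na(hit), , drop = FALSE]
  ev$subtype <- code_lists$subtype[hit[!is.na(hit)]]

  subtypes <- unique(code_lists$subtype)
  out <- data.frame(pregnancy_id = pg$pregnancy_id, stringsAsFactors = FALSE)
  out$primary <- out$pregnancy_id %in% ev$pregnancy_id
  for (s in subtypes) {
    out[[s]] <- out$pregnancy_id %in% ev$pregnancy_id[ev$subtype == s]
  }
  out
}

#' Apply a sensitivity-analysis cohort restriction
#'
#' Set-theoretic filters, composable by chaining: `"singleton"` keeps
#' single-fetus pregnancies; `"no-chromosomal"` drops pregnancies with a
#' chromosomal-anomaly marker (infant code in follow-up or maternal code
#' during pregnancy); `"no-diabetes"` drops pregnancies whose mother carries
#' a diabetes marker in the covariate window; `"no-parental-malformation"`
#' drops pregnancies with a congenital-malformation code recorded for either
#' parent in the 6 months before LMP.
#'
#' @param cohort A [claims_cohort()].
#' @param pregnancies Character vector of pregnancy ids to filter.
#' @param restriction One of `"singleton"`, `"no-chromosomal"`,
#'   `"no-diabetes"`, `"no-parental-malformation"`.
#' @param markers List of marker code sets (ICD-9 sections / therapeutic
#'   detail codes): `chromosomal`, `diabetes_dx`, `diabetes_rx`,
#'   `malformation`.
#' @param fathers Optional pregnancy-to-father map (used by
#'   `"no-parental-malformation"`).
#' @return Character vector of retained pregnancy ids.
#' @export
apply_restriction <- function(cohort, pregnancies, restriction,
                              markers = default_restriction_markers(),
                              fathers = NULL) {
  known <- c("singleton", "no-chromosomal", "no-diabetes",
             "no-parental-malformation")
  if (!restriction %in% known) {
    stop_config("restriction", paste("must be one of:", paste(known, collapse = ", ")))
  }
  pg <- cohort$pregnancies
  pg <- pg[match(pregnancies, pg$pregnancy_id), , drop = FALSE]

  section_of <- function(ev, gem = cohort$gem) {
    out <- character(nrow(ev))
    is9 <- ev$vocabulary == "ICD9"
    out[is9] <- substr(ev$code[is9], 1L, 3L)
    if (any(!is9) && !is.null(gem)) {
      out[!is9] <- map_icd10_to_icd9_section(ev$code[!is9], gem)
    }
    out
  }
  mother_dx_in <- function(sections, from_off, to_off) {
    key <- data.frame(person_id = pg$mother_id, pregnancy_id = pg$pregnancy_id,
                      lmp_day = pg$lmp_day, end_day = pg$end_day,
                      stringsAsFactors = FALSE)
    ev <- merge(cohort$dx_events, key, by = "person_id")
    ev <- ev[section_of(ev) %in% sections, , drop = FALSE]
    lo <- ev$lmp_day + from_off(ev)
    hi <- ev$lmp_day + to_off(ev)
    unique(ev$pregnancy_id[ev$day >= lo & ev$day <= hi])
  }

  keep <- switch(restriction,
    "singleton" = pg$pregnancy_id[pg$n_fetuses == 1L],
    "no-chromosomal" = {
      # infant marker in follow-up
      lk <- cohort$links[cohort$links$pregnancy_id %in% pg$pregnancy_id, , drop = FALSE]
      iev <- merge(cohort$dx_events, lk[, c("pregnancy_id", "infant_id")],
                   by.x = "person_id", by.y = "infant_id")
      isec <- section_of(iev)
      flagged_inf <- unique(iev$pregnancy_id[isec %in% markers$chromosomal])
      # maternal marker during pregnancy
      flagged_mat <- mother_dx_in(markers$chromosomal,
                                  function(ev) 0L,
                                  function(ev) ev$end_day - ev$lmp_day)
      setdiff(pg$pregnancy_id, union(flagged_inf, flagged_mat))
    },
    "no-diabetes" = {
      flagged_dx <- mother_dx_in(markers$diabetes_dx,
                                 function(ev) -180L,
                                 function(ev) ev$end_day - ev$lmp_day)
      key <- data.frame(person_id = pg$mother_id, pregnancy_id = pg$pregnancy_id,
                        lmp_day = pg$lmp_day, end_day = pg$end_day,
                        stringsAsFactors = FALSE)
      rx <- merge(cohort$rx_events, key, by = "person_id")
      rx <- rx[rx$tdc %in% markers$diabetes_rx &
                 rx$day >= rx$lmp_day - 180L & rx$day <= rx$end_day, , drop = FALSE]
      setdiff(pg$pregnancy_id, union(flagged_dx, unique(rx$pregnancy_id)))
    },
    "no-parental-malformation" = {
      flagged_mat <- mother_dx_in(markers$malformation,
                                  function(ev) -180L, function(ev) -1L)
      flagged_pat <- character(0)
      if (!is.null(fathers) && length(fathers)) {
        key <- data.frame(person_id = unname(fathers),
                          pregnancy_id = names(fathers),
                          stringsAsFactors = FALSE)
        key <- key[key$pregnancy_id %in% pg$pregnancy_id, , drop = FALSE]
        key$lmp_day <- pg$lmp_day[match(key$pregnancy_id, pg$pregnancy_id)]
        fev <- merge(cohort$dx_events, key, by = "person_id")
        fsec <- section_of(fev)
        fev <- fev[fsec %in% markers$malformation &
                     fev$day >= fev$lmp_day - 180L & fev$day <= fev$lmp_day - 1L, ,
                   drop = FALSE]
        flagged_pat <- unique(fev$pregnancy_id)
      }
      setdiff(pg$pregnancy_id, union(flagged_mat, flagged_pat))
    })
  intersect(pregnancies, keep)
}

#' Default marker code sets for the cohort restrictions
#'
#' Synthetic stand-ins aligned with the generator's code universe:
#' chromosomal anomalies (section 758), diabetes (section 250 and the
#' insulin-like therapeutic detail codes), congenital malformations
#' (sections 745-747).
#'
#' @return Named list of character vectors.
#' @export
default_restriction_markers <- function() {
  list(chromosomal = "758",
       diabetes_dx = "250",
       diabetes_rx = c("TD001", "TD002", "TD003"),
       malformation = c("745", "746", "747"))
}
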