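# Relational claims-cohort container and its delimited-table serialization.

#' Construct a claims cohort
#'
#' Bundles the six relational tables of a pregnancy claims cohort and
#' validates their referential invariants.  All days are integer offsets
#' anchored at each pregnancy's last menstrual period (LMP = day 0).
#'
#' @param persons Data frame: `person_id`, `sex` (`"F"`/`"M"`), `birth_year`,
#'   `family_key`.
#' @param enroll Data frame of enrollment spans: `person_id`, `start_day`,
#'   `end_day`, `rx_benefit` (logical; full medication benefits).
#' @param dx_events Data frame: `person_id`, `day`, `code`, `vocabulary`
#'   (`"ICD9"`/`"ICD10"`).
#' @param rx_events Data frame of outpatient dispensings: `person_id`, `day`,
#'   `tdc` (therapeutic detail code).
#' @param pregnancies Data frame: `pregnancy_id`, `mother_id`, `lmp_day`,
#'   `end_day`, `delivery_year`, `n_fetuses`, `age` (maternal age in years).
#' @param links Data frame: `pregnancy_id`, `infant_id`, `death_day`
#'   (NA if alive).
#' @param gem Optional General Equivalence Mapping table (`source`, `target`,
#'   `flags`) for ICD-10 to ICD-9 crosswalking.
#' @return Object of class `claims_cohort`.
#' @export
claims_cohort <- function(persons, enroll, dx_events, rx_events,
                          pregnancies, links, gem = NULL) {
  need <- function(df, cols, what) {
    if (!is.data.frame(df) || !all(cols %in% names(df))) {
      stop_config(what, paste("must contain columns:", paste(cols, collapse = ", ")))
    }
  }
  need(persons, c("person_id", "sex", "birth_year", "family_key"), "persons")
  need(enroll, c("person_id", "start_day", "end_day", "rx_benefit"), "enroll")
  need(dx_events, c("person_id", "day", "code", "vocabulary"), "dx_events")
  need(rx_events, c("person_id", "day", "tdc"), "rx_events")
  need(pregnancies, c("pregnancy_id", "mother_id", "lmp_day", "end_day",
                      "delivery_year", "n_fetuses", "age"), "pregnancies")
  need(links, c("pregnancy_id", "infant_id"), "links")
  if (any(enroll$start_day > enroll$end_day)) {
    stop_config("enroll", "has spans with start_day > end_day")
  }
  if (any(pregnancies$lmp_day >= pregnancies$end_day)) {
    stop_config("pregnancies", "must have lmp_day < end_day")
  }
  if (any(pregnancies$n_fetuses < 1L)) {
    stop_config("pregnancies", "must have n_fetuses >= 1")
  }
  ids <- persons$person_id
  for (tab in c("enroll", "dx_events", "rx_events")) {
    df <- list(enroll = enroll, dx_events = dx_events, rx_events = rx_events)[[tab]]
    if (nrow(df) && !all(df$person_id %in% ids)) {
      stop_config(tab, "refers to person_id values absent from persons")
    }
  }
  if (nrow(pregnancies) && !all(pregnancies$mother_id %in% ids)) {
    stop_config("pregnancies", "refers to mother_id values absent from persons")
  }
  if (!("death_day" %in% names(links))) links$death_day <- NA_integer_
  structure(list(persons = persons, enroll = enroll, dx_events = dx_events,
                 rx_events = rx_events, pregnancies = pregnancies,
                 links = links, gem = gem),
            class = "claims_cohort")
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat("Claims cohort\n")
  cat("  pregnancies:", nrow(x$pregnancies),
      sprintf("(%.1f%% multiple gestation)",
              100 * mean(x$pregnancies$n_fetuses > 1L)), "\n")
  cat("  persons:    ", nrow(x$persons), "\n")
  cat("  dx events:  ", nrow(x$dx_events), "\n")
  cat("  rx events:  ", nrow(x$rx_events), "\n")
  cat("  infant links:", nrow(x$links), "\n")
  if (!is.null(x$gem)) cat("  GEM rows:   ", nrow(x$gem), "\n")
  invisible(x)
}

cohort_files <- c(persons = "persons.tsv", enroll = "enroll.tsv",
                  dx_events = "dx_events.tsv", rx_events = "rx_events.tsv",
                  pregnancies = "pregnancies.tsv", links = "links.tsv")

#' Write / read a claims cohort as a directory of TSV tables
#'
#' The on-disk layout is one tab-separated file per table (`persons.tsv`,
#' `enroll.tsv`, `dx_events.tsv`, `rx_events.tsv`, `pregnancies.tsv`,
#' `links.tsv`, plus `gem.tsv` when a crosswalk is attached).
#'
#' @param cohort A [claims_cohort()].
#' @param dir Directory path (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   [claims_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "claims_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort_files)) {
    write.table(cohort[[nm]], file.path(dir, cohort_files[[nm]]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$gem)) {
    write.table(cohort$gem, file.path(dir, "gem.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  classes <- list(
    persons = c(person_id = "character", sex = "character",
                birth_year = "integer", family_key = "character"),
    enroll = c(person_id = "character", start_day = "integer",
               end_day = "integer", rx_benefit = "logical"),
    dx_events = c(person_id = "character", day = "integer",
                  code = "character", vocabulary = "character"),
    rx_events = c(person_id = "character", day = "integer", tdc = "character"),
    pregnancies = c(pregnancy_id = "character", mother_id = "character",
                    lmp_day = "integer", end_day = "integer",
                    delivery_year = "integer", n_fetuses = "integer",
                    age = "integer"),
    links = c(pregnancy_id = "character", infant_id = "character",
              death_day = "integer"))
  tabs <- lapply(names(cohort_files), function(nm) {
    read.table(file.path(dir, cohort_files[[nm]]), sep = "\t", header = TRUE,
               colClasses = classes[[nm]], stringsAsFactors = FALSE)
  })
  names(tabs) <- names(cohort_files)
  gem_path <- file.path(dir, "gem.tsv")
  gem <- if (file.exists(gem_path)) {
    read.table(gem_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               colClasses = "character")
  }
  claims_cohort(persons = tabs$persons, enroll = tabs$enroll,
                dx_events = tabs$dx_events, rx_events = tabs$rx_events,
                pregnancies = tabs$pregnancies, links = tabs$links, gem = gem)
}
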