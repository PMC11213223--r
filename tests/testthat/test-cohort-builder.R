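# Eligibility rules, father linkage, GEM mapping, panels, top-k selection,
# outcome flagging and restrictions on hand-built boundary fixtures.

test_that("each eligibility rule excludes exactly the intended boundary case", {
  ch <- boundary_cohort()
  el <- apply_eligibility(ch)
  expect_setequal(el$eligible, c("P1", "P3", "P8"))
  tl <- setNames(el$tally$excluded, el$tally$rule)
  expect_equal(tl[["no_linked_infant"]], 1)    # P7
  expect_equal(tl[["maternal_enrollment"]], 1) # P4 (gap inside the window)
  expect_equal(tl[["rx_benefit"]], 1)          # P5
  expect_equal(tl[["infant_followup"]], 1)     # P2 (enrolled to end+60 only)
  expect_equal(tl[["maternal_age"]], 1)        # P6
  # infant death before end+90 with enrollment to death is retained
  expect_true("P3" %in% el$eligible)
})

test_that("an empty cohort yields an empty set and all-zero tallies", {
  ch <- boundary_cohort()
  ch$pregnancies <- ch$pregnancies[0, ]
  el <- apply_eligibility(ch)
  expect_length(el$eligible, 0)
  expect_true(all(el$tally$excluded == 0))
})

test_that("father linkage requires gap-free enrollment and ties go to the oldest male", {
  ch <- boundary_cohort()
  el <- apply_eligibility(ch)
  fa <- link_fathers(ch, el$eligible)
  expect_equal(unname(fa["P1"]), "FA1")
  # FB2 has a 15-day gap inside [LMP-180, LMP]: P2 would not link even if eligible
  fa_all <- link_fathers(ch, ch$pregnancies$pregnancy_id)
  expect_false("P2" %in% names(fa_all))
  # two qualifying males in FAM8: the older (FD8, born 1960) wins, tie logged
  expect_equal(unname(fa["P8"]), "FD8")
  expect_true("P8" %in% attr(fa, "ties"))
})

test_that("GEM mapping extracts 3-digit sections, tallies unmapped, flags true ambiguity", {
  gem_file <- tempfile(fileext = ".txt")
  writeLines(c("X2501  25000  0",
               "X4011  4010   0",
               "X4011  4011   0",     # second target, same section: no flag
               "X9999  1234   0",
               "X9999  9990   0"),    # targets disagree at 3-digit level
             gem_file)
  gem <- read_gem(gem_file)
  out <- map_icd10_to_icd9_section(c("X2501", "X4011", "X9999", "ZZZZ"), gem)
  expect_equal(as.vector(out), c("250", "401", "123", "UNMAPPED"))
  expect_equal(attr(out, "n_unmapped"), 1)
  expect_equal(attr(out, "ambiguous"), "X9999")
  # malformed row raises a parse error with the line number
  writeLines(c("A10 100 0", "BADROW"), gem_file)
  expect_error(read_gem(gem_file), "line 2")
})

test_that("panel windows are closed intervals and thresholds dominate", {
  ch <- boundary_cohort()
  ids <- c("P1", "P3", "P8")
  dxp <- derive_panel(ch, ids, window_spec("maternal-dx"))   # [-180, 90]
  # M1 has dx at day -181 (out) and -180 (in): count 1, indicator 1
  expect_equal(as.numeric(dxp$counts["P1", "401"]), 1)
  expect_equal(as.numeric(dxp$indicator["P1", "401"]), 1)
  rxp <- derive_panel(ch, ids, window_spec("maternal-rx"))   # [0, 90]
  # dispensing at day 90 inside, day 91 outside
  expect_equal(as.numeric(rxp$counts["P1", "TD001"]), 1)
  # threshold 2 with a single event gives indicator 0
  rxp2 <- derive_panel(ch, ids, window_spec("maternal-rx"), threshold = 2)
  expect_equal(as.numeric(rxp2$indicator["P1", "TD001"]), 0)
  # two events at threshold 2 give indicator 1
  ch2 <- ch
  ch2$rx_events <- rbind(ch2$rx_events,
                         data.frame(person_id = "M1", day = 45L, tdc = "TD001"))
  rxp3 <- derive_panel(ch2, ids, window_spec("maternal-rx"), threshold = 2)
  expect_equal(as.numeric(rxp3$indicator["P1", "TD001"]), 1)
  # elementwise dominance on a generated cohort
  gen <- generate_cohort(sim_config(2000, seed = 4))
  gids <- gen$cohort$pregnancies$pregnancy_id
  p1 <- derive_panel(gen$cohort, gids, window_spec("maternal-dx"), threshold = 1)
  p2 <- derive_panel(gen$cohort, gids, window_spec("maternal-dx"), threshold = 2)
  expect_true(all(p2$indicator@x <= 1))
  expect_true(all((p1$indicator - p2$indicator)@x >= 0))
})

test_that("shrinking a window never increases counts", {
  gen <- generate_cohort(sim_config(2000, seed = 14))
  ids <- gen$cohort$pregnancies$pregnancy_id
  wide <- derive_panel(gen$cohort, ids, window_spec("maternal-dx", -180, 90))
  narrow <- derive_panel(gen$cohort, ids, window_spec("maternal-dx", 0, 90))
  shared <- intersect(colnames(wide$counts), colnames(narrow$counts))
  diff <- wide$counts[, shared] - narrow$counts[, shared]
  expect_true(all(diff@x >= 0))
})

test_that("paternal panels drop pregnancies without a linked father and tally them", {
  ch <- boundary_cohort()
  el <- apply_eligibility(ch)
  fa <- link_fathers(ch, el$eligible)
  pp <- derive_panel(ch, el$eligible, window_spec("paternal-dx"), fathers = fa)
  expect_setequal(pp$pregnancies, c("P1", "P8"))
  expect_setequal(pp$dropped_no_father, "P3")
  expect_error(derive_panel(ch, el$eligible, window_spec("paternal-dx")),
               "fathers")
})

test_that("top-k code selection ranks by prevalence with lexicographic tie-break", {
  ind <- Matrix::Matrix(0, 20, 3, sparse = TRUE,
                        dimnames = list(sprintf("P%02d", 1:20), c("b", "a", "c")))
  ind[1:10, "b"] <- 1; ind[1:5, "a"] <- 1; ind[1, "c"] <- 1
  panel <- structure(list(
    pregnancies = rownames(ind),
    codes = data.frame(code = colnames(ind), vocabulary = "dx-section",
                       role = "maternal-dx", label = colnames(ind),
                       stringsAsFactors = FALSE),
    indicator = methods::as(ind, "CsparseMatrix"), counts = ind,
    threshold = 1L, window = window_spec("maternal-dx")),
    class = "covariate_panel")
  top2 <- select_top_codes(panel, 2)
  expect_setequal(top2$codes$code, c("b", "a"))
  # k larger than the code count is the identity
  expect_equal(select_top_codes(panel, 10)$codes$code, panel$codes$code)
  # tie at rank k: lexicographically smaller id retained
  ind2 <- ind; ind2[1:5, "c"] <- 1   # a and c now tie at prevalence 5
  panel$indicator <- methods::as(ind2, "CsparseMatrix"); panel$counts <- ind2
  top2 <- select_top_codes(panel, 2)
  expect_setequal(top2$codes$code, c("b", "a"))
  # dropped codes never out-rank retained ones
  prevs <- Matrix::colSums(ind2)
  kept <- select_top_codes(panel, 2)$codes$code
  expect_gte(min(prevs[kept]), max(prevs[setdiff(names(prevs), kept)]))
})

test_that("outcome flagging is pregnancy-level with a closed follow-up window", {
  ch <- boundary_cohort()
  oc <- flag_outcomes(ch, c("P1", "P3", "P8"), default_outcome_codes())
  # twin P8: one affected infant (I8a) but its code is on day end+91 -> not flagged
  expect_false(oc$primary[oc$pregnancy_id == "P8"])
  # P1's infant code on day end+90 exactly -> flagged
  expect_true(oc$primary[oc$pregnancy_id == "P1"])
  expect_true(oc$ventricular_septal[oc$pregnancy_id == "P1"])
  expect_false(oc$primary[oc$pregnancy_id == "P3"])
  # twin with one affected infant inside follow-up -> flagged
  ch2 <- ch
  ch2$dx_events <- rbind(ch2$dx_events,
                         data.frame(person_id = "I8b", day = 300L,
                                    code = "Q210", vocabulary = "ICD10"))
  oc2 <- flag_outcomes(ch2, "P8", default_outcome_codes())
  expect_true(oc2$primary)
  expect_error(flag_outcomes(ch, "P1", data.frame()), "code_lists")
})

test_that("restrictions filter set-theoretically and compose by chaining", {
  gen <- generate_cohort(sim_config(5000, seed = 21))
  ids <- gen$cohort$pregnancies$pregnancy_id
  # singleton restriction keeps exactly the single-fetus pregnancies
  s <- apply_restriction(gen$cohort, ids, "singleton")
  expect_setequal(s, ids[gen$cohort$pregnancies$n_fetuses == 1L])
  # all-singleton input: identity
  sub <- ids[gen$cohort$pregnancies$n_fetuses == 1L]
  expect_setequal(apply_restriction(gen$cohort, sub, "singleton"), sub)
  # chained restrictions equal the intersection of the individual filters
  d <- apply_restriction(gen$cohort, ids, "no-diabetes")
  chain <- apply_restriction(gen$cohort, s, "no-diabetes")
  expect_setequal(chain, intersect(s, d))
  # no-diabetes removes the pregnancies with diabetes marker codes
  pan <- derive_panel(gen$cohort, ids, window_spec("maternal-dx"))
  with_dx <- pan$pregnancies[as.numeric(pan$indicator[, "250"]) > 0]
  expect_length(intersect(d, with_dx), 0)
  expect_error(apply_restriction(gen$cohort, ids, "no-such"), "restriction")
})
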