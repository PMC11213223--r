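# cardioscreen

Hypothesis-free screening of insurance-claims codes for associations with
cardiac malformations in live-born infants.

Cardiac malformations are among the most common congenital malformations,
and most of their non-genetic etiology is unknown. Rather than testing a
handful of pre-specified exposures, `cardioscreen` implements a screening
pipeline that tests *every* diagnosis and medication code observed in a
pregnancy cohort — maternal and paternal — against the outcome, with
principled multiplicity control, and then helps interpret what was found.
It is aimed at pharmacoepidemiologists and perinatal researchers working
with claims-shaped data (persons, enrollment spans, coded diagnoses,
outpatient dispensings, pregnancy episodes, infant links).

The pipeline has five stages:

1. **Cohort construction** — eligibility rules (continuous maternal
   enrollment from 180 days before the last menstrual period (LMP) to 30
   days after the end of pregnancy, full medication benefits, 90-day infant
   follow-up with an infant-death exception, maternal age 12–55), father
   linkage through the family key with an oldest-male tie-break, and
   ICD-10 → ICD-9 3-digit-section mapping via CMS General Equivalence
   Mappings.
2. **Covariate derivation** (hdPS-style) — indicator and count matrices per
   exposure window (maternal diagnoses LMP−180..LMP+90; first-trimester
   medications LMP..LMP+90; paternal spermatogenesis windows LMP−180..LMP
   and LMP−90..LMP; all windows closed), with the 500 most prevalent codes
   retained per role.
3. **Screening** — for each code *j* a separate logistic model

   logit P(Y = 1) = β₀ + β₁ xⱼ + f(age),

   where f is a restricted cubic spline (4 knots at the 5/35/65/95th age
   percentiles), tested by a 1-df likelihood-ratio test; Benjamini–Hochberg
   selection at 1%, 5% and 10% FDR; a conditional-bootstrap winner's-curse
   correction of the selected odds ratios; signed Manhattan output
   (−log₁₀ p × sign of log OR, capped at 20 for display).
4. **Characterization** — latent semantic analysis: truncated SVD of the
   log(1+count) matrix over all mapped codes, cosine similarity between the
   selected codes' vectors, and average-linkage agglomerative clustering on
   angular distance arccos(cos)/π.
5. **Subgroup discovery** — Apriori mining of outcome-consequent rules on
   class-balanced data (non-cases downsampled 1:1; minimum support 0.1%,
   minimum confidence 55%, antecedents of ≤10 codes, age dichotomized at
   35), Westfall–Young max-statistic permutation selection at 5% FWER, and
   prevalence/risk-ratio reporting (Katz CI) in the full data.

Because real claims data of this kind are proprietary, the package ships a
**synthetic cohort generator** with known ground truth: latent clinical
factors (e.g. a diabetes-like state) whose carriers emit correlated
diagnosis and medication codes inside the exposure windows and shift the
outcome odds by planted log odds-ratios, plus multiple-gestation pregnancies,
~70% father linkage, enrollment-gap eligibility violations, and an
ICD-9/ICD-10 vocabulary mix that exercises the GEM crosswalk. Every stage is
tested against this generator's truth.

## Worked example

```r
library(cardioscreen)

gen <- generate_cohort(sim_config(150000, seed = 42))
el  <- apply_eligibility(gen$cohort)
ids <- el$eligible
dxp <- derive_panel(gen$cohort, ids, window_spec("maternal-dx"))
rxp <- derive_panel(gen$cohort, ids, window_spec("maternal-rx"))
out <- flag_outcomes(gen$cohort, ids, default_outcome_codes())
ages <- gen$cohort$pregnancies$age[match(ids, gen$cohort$pregnancies$pregnancy_id)]

scr <- screen_codes(cbind(dxp$indicator, rxp$indicator), out$primary, ages = ages)
summary(scr)
#> 6 of 82 codes selected at 5% FDR
#>   code n_exposed_cases               or  p_value p_adjusted
#>    250              56 2.52 (1.92-3.30) 4.10e-09   3.36e-07
#>  TD003              19 3.20 (2.02-5.07) 2.72e-05   1.12e-03
#>  TD001              32 2.17 (1.52-3.10) 1.26e-04   3.43e-03
#>  TD002              20 2.39 (1.53-3.74) 7.68e-04   1.57e-02
#>    401              65 1.53 (1.19-1.96) 1.78e-03   2.92e-02
#>  TD007              29 1.84 (1.27-2.67) 3.16e-03   4.31e-02

sp <- build_latent_space(cbind(dxp$counts, rxp$counts), k = 50)
sel <- scr$table$code[scr$table$selected_fdr05]
cluster_codes(code_cosines(sp, sel), cut = 0.4)
#> Code clustering (average linkage, cut 0.40): 3 groups over 6 codes
#>  group               code_terms size
#>      1 250; TD001; TD002; TD003    4
#>      2                      401    1
#>      3                    TD007    1
```

Reading the output: the screen recovers the planted diabetes-like factor —
the diagnosis section `250` (adjusted OR 2.52, planted OR 2.2) and its
three insulin-like therapeutic detail codes — plus the hypertension-like
section `401` (OR 1.53, planted 1.52) and one fertility-treatment
medication whose apparent risk is purely the twin-counting artifact
(carriers have more multiple gestations, and outcomes are counted at the
pregnancy level; restricting to singletons removes it). The clustering then
groups the four diabetes-related codes into a single latent-state group,
which is exactly how the embedding is meant to aid interpretation:
medications, diagnoses and sequelae of one clinical state land close
together.

`run_all(run_config(...))` chains all five stages, writes every artifact as
delimited text (screening tables per outcome subtype, Manhattan data,
singular values, similarity matrix, groupings, a newick linkage tree,
subgroup rules, age-risk curve, exclusion tally) plus a JSON manifest, and
is byte-identical under a fixed seed. A thin command-line wrapper lives at
`inst/cli/cardioscreen.R`.

## Limitations

The generator emulates the *structure* of claims data, not its semantics:
code frequencies are power-law but codes carry no real ICD meaning, and
maternal/paternal exposures are independent given family linkage. Screening
adjusts for maternal age only (by design — the goal is signal generation,
not causal estimation); selected associations are subject to confounding,
selection and measurement bias and are hypotheses, not effects.
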