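---
title: "Methods: high-dimensional claims-code screening for cardiac malformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-dimensional claims-code screening for cardiac malformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models it fits, the defaults it chooses where a choice had to be made,
what the synthetic-data generator does and does not emulate, and the
numerical conventions a maintainer should know about. Nothing here reports
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The screening model

For a pregnancy cohort with binary outcome $Y$ (any live-born infant with a
cardiac malformation) and a panel of binary code indicators $x_1, \dots,
x_m$, the screen fits one logistic model per code,

$$\operatorname{logit} P(Y_i = 1) = \beta_0 + \beta_1 x_{ij} + f(\text{age}_i),$$

and tests $\beta_1 = 0$ with a 1-df likelihood-ratio test against the
reduced model omitting $x_j$. Screening is deliberately *marginal*: no
joint model across codes, and no confounder adjustment beyond maternal age.
The target is signal generation — a ranked list of associations for
downstream scrutiny — not causal effect estimation, and maternal age is
adjusted because it is an established risk factor whose footprint would
otherwise dominate the list.

$f$ is a restricted cubic spline: a natural cubic spline, linear beyond its
boundary knots, with continuous first and second derivatives. The default
is 4 knots at the 5/35/65/95th percentiles of observed age — the standard
quantile placement for restricted cubic splines — giving a 3-dimensional
basis (knots − 1, including the linear term). The number of knots is a
tunable (`n_knots`) with the usual bias/flexibility trade-off; with ages
concentrated between 25 and 38 years, 4 knots is plenty.

All codes submitted in one `screen_codes()` call form one
Benjamini–Hochberg family. Maternal and paternal analyses, run separately,
therefore have separate BH families by default; callers who prefer one
pooled family over all ~2,000 tests can concatenate the panels into a
single call. Adjusted p-values are the standard step-up quantities
(`stats::p.adjust`, method `"BH"`), and selection flags are reported at 1%,
5% and 10% FDR, which are nested by construction.

### Degenerate codes

A code whose exposure–outcome 2×2 table has an empty cell (no exposed
pregnancies, no exposed cases, no unexposed cases, …) has no finite maximum
likelihood estimate. Such codes are reported with status
`"non-estimable"` and p-value 1 — they stay visible in the table, never
enter selection, and are excluded from the bias correction. The same
treatment applies to fits that fail to converge or run away
($|\hat\beta_1| > 15$). Separation is a property of the data, not an
error, so no exception is thrown.

### Winner's-curse correction

Estimates that survive multiplicity-corrected selection are biased away
from the null, because selection favors estimates inflated by noise. The
package implements a conditional bootstrap correction: resample pregnancies
with replacement; in each resample refit every code and rerun BH selection
at the analysis FDR; for each originally selected code, average (bootstrap
estimate − full-data estimate) over the resamples *in which the code was
selected again*; subtract that average from the full-data estimate. The
cited literature names a bootstrap correction without formulas, so this
standard realization is documented here and labelled in the output
(`winners_curse$scheme`). Codes never re-selected in any resample carry a
missing correction and a flag rather than a fabricated value. The default
`B = 200` resamples (minimum 50; below that the bias estimate is too noisy
to subtract).

What the correction targets is *bias* — the systematic component of the
error of selected estimates. In the package's mixed null/non-null
simulations it shrinks the signed bias of the selected set and the bias of
selected null codes; the per-realization absolute error of strongly
estimated codes can tick up slightly, since subtracting a noisy bias
estimate adds variance. The acceptance suite measures the bias metric.

### Manhattan output

The signed Manhattan value is $-\log_{10}(p) \cdot \operatorname{sign}
(\hat\beta_1)$, capping magnitudes at 20 with a flag. The cap is a display
convention only (p-values below $10^{-20}$ are plotted at the rim); the
screening table always retains the raw p-value.

## Synthetic cohorts and what passing tests mean

Real data of this shape (MarketScan-like commercial claims) are
proprietary, so the generator is a first-class module, not a fixture. Its
premise mirrors how correlated codes arise in claims: an unobserved
clinical state (for example diabetes) emits a bundle of codes — diagnosis
sections, medications, sequelae — among its carriers. Each
`latent_factor()` has a carrier prevalence, per-code emission
probabilities, and a planted log odds-ratio on the outcome. Defaults are
the study conditions the package is calibrated to:

* baseline pregnancy-level outcome rate 1.3% (the model intercept is solved
  by `uniroot` so the realized cohort's marginal rate matches);
* father linkage 70.4%; baseline twin rate 3.4%; maternal age discretized
  normal matched to median 31, IQR 28–34, truncated to 12–55;
* a diabetes-like factor (prevalence 1.4%, OR 2.2), a chronic
  hypertension-like factor (2.8%, OR 1.52), a rare fetal-abnormality factor
  (0.3%, OR 2.82), and a fertility-treatment proxy with *no* direct effect
  but an elevated twin rate among carriers.

The last factor exists to reproduce a known artifact: outcomes are counted
at the pregnancy level (any affected infant flags the pregnancy), so twin
pregnancies mechanically carry up to twice the apparent risk, and exposure
proxies for fertility treatment inherit that risk. The generator draws one
outcome per fetus and flags the pregnancy if any is affected; the
singleton-restriction sensitivity analysis then attenuates the proxy's OR
toward the null, which the test suite checks. Because the fertility factor
raises twin rates among its carriers, the marginal twin fraction of a
default cohort is ~3.9% against the 3.4% baseline parameter.

Further structural choices:

* **Days are LMP-relative integers** (LMP = day 0). Every window in the
  analysis is LMP-anchored, so calendar dates add nothing.
* **One pregnancy per mother.** The real cohort has ~1.1 pregnancies per
  mother; modelling repeat pregnancies would complicate the person/event
  model without exercising any additional pipeline path.
* **Noise codes have power-law prevalences**, so top-k code selection is a
  real ranking problem, as in heavy-tailed claims frequencies.
* **Vocabulary mix:** each diagnosis event is ICD-10 with probability
  `icd10_fraction`, and the generator emits a matching GEM table, so the
  crosswalk path is always exercised.
* **Eligibility violations** are planted at a configured rate, split
  uniformly across the three violation types (maternal enrollment gap,
  missing drug benefit, short infant follow-up), plus a separate
  infant-death path that the follow-up rule must *retain*.

What the generator does **not** emulate: real ICD semantics or billing
behavior, calendar-time coding transitions, dependence between maternal and
paternal exposures (they are independent given family linkage; the
literature gives no joint distribution to copy), and repeat pregnancies.
Passing tests therefore demonstrate that the machinery is correct and
calibrated under a faithful structural model — not that any particular
clinical signal in real data is true.

## Cohort-building conventions

* **All exposure windows are closed** on both endpoints, on integer days.
  The sources write windows like "LMP to LMP plus 90 days" without an
  interval convention; inclusive endpoints match common claims-epidemiology
  practice, and both boundaries are unit-tested (day −181 out, −180 in;
  day 90 in, 91 out).
* **Eligibility order**: no-linked-infant, maternal enrollment, medication
  benefit, infant follow-up, maternal age. The exclusion tally is
  order-dependent (each rule counts survivors of the previous ones); the
  final eligible set is not.
* **Father tie-break**: when several family males qualify, the oldest wins,
  then lexicographic id; ties are logged in an attribute. Deterministic by
  construction.
* **Top-500 ranking** uses pregnancy-level prevalence (number of
  pregnancies with the indicator set), not raw event counts — prevalence is
  what the indicator matrix measures — with ties broken toward the
  lexicographically smaller code id.
* **GEM dialect**: whitespace-delimited `source target flags` rows. When a
  source has several targets the first listed is used; the code is counted
  ambiguous only when targets disagree at the 3-digit-section level.
  Unmappable codes map to a sentinel and are tallied, never silently
  dropped.

## Latent semantic analysis

Counts (not indicators) over *all* mapped codes — not just the top-500
screen set — are transformed $x \mapsto \log(1+x)$; the offset is forced by
zero counts and is the usual choice. The matrix is **not** centered
(classical LSA convention; `center = TRUE` gives the PCA-style variant).
Truncated SVD retains the `k` largest singular values (default 500, capped
at the matrix rank, which desk-scale cohorts always hit); code vectors are
right singular vectors scaled by their singular values, so cosine
similarity between codes reflects co-occurrence structure across
pregnancies. Angular distance $\arccos(\text{cos})/\pi$ normalizes to
$[0,1]$; clustering is agglomerative with average linkage by default
(configurable to single/complete — the sources do not name a linkage), cut
at a configurable height (pipeline default 0.4, which cleanly separates the
planted factors in the recovery experiments). Zero-norm code vectors have
undefined cosines: flagged and excluded rather than imputed.

## Subgroup discovery

Apriori is run on class-balanced data (all cases, non-cases downsampled 1:1
without replacement, seeded) because confidence thresholds are
uninterpretable at a 1.3% base rate. Support is the proportion of rows with
the antecedent *and* the outcome — the definition that makes support
anti-monotone for outcome-consequent rules — and confidence is the outcome
rate given the antecedent. Defaults: support ≥ 0.1%, confidence ≥ 55%,
antecedent length ≤ 10, age dichotomized at 35 with both sides offered as
features. The miner is a hand-written level-wise implementation (checked
against brute-force enumeration on ≤8-feature fixtures, exactly).

The "SD" post-processing beyond frequent-rule mining is under-specified in
the source literature, so each step here is explicit and independently
switchable: outcome-consequent filtering (always), an optional
closed-itemset reduction (drop a rule when a strict superset antecedent has
identical support; off by default so the oracle equivalence is over pure
Apriori), and ranking by the rule's 2×2 chi-square statistic on balanced
data (configurable in principle to confidence ranking; chi-square is the
permutation statistic).

Westfall–Young selection permutes the balanced outcome, re-mines the rule
family under identical thresholds per permutation (the strict
construction; a fixed-family mode is offered and labelled approximate), and
compares each observed statistic to the permutation distribution of the
family maximum. One deliberate refinement: the family maximum also covers
the observed antecedents' own permuted statistics, so a rule whose
antecedent falls below the mining support under a permuted outcome still
contributes, and adjusted p-values provably dominate per-rule permutation
p-values. Adjusted p is the plain fraction of permutations whose maximum
reaches the observed statistic; `alpha = 0` therefore selects nothing by
explicit convention. Prevalence, risk ratios and Katz log-normal intervals
are computed on the full (un-downsampled) data; zero cells get a 0.5
continuity correction on all four cells, flagged.

## Numerical choices

* Per-code fits use an IRLS Newton solver (RcppArmadillo) warm-started from
  the shared reduced model, converging on the relative deviance change
  (tolerance $10^{-9}$, ≤30 iterations); it matches `stats::glm` to
  $10^{-6}$ on the test fixtures and makes the bootstrap and simulation
  suites tractable (tens of thousands of fits).
* The LRT statistic is clamped at 0 (floating-point can make the full
  model's deviance infinitesimally larger).
* Cosines are clamped to $[-1, 1]$ before $\arccos$.
* Stage seeds derive from one master seed by a fixed integer recurrence
  modulo $2^{31}-1$, so stages rerun independently and the whole pipeline
  is byte-identical under a fixed seed (tested against output trees).

## Problem sizes in the test and acceptance suites

Chosen to make simulation-based checks statistically meaningful on a single
CPU: FDR calibration uses 200 global-null cohorts of n = 20,000 with 200
codes; planted-signal power uses n = 200,000 (at which the planted OR-2.2 /
1.4%-prevalence code is detected essentially always — the power criterion
is recomputed by the simulation itself rather than assumed from the
original cohort size); winner's-curse simulations use 10 cohorts of
n = 20,000 with 50 codes and 60 bootstrap resamples; LSA recovery uses 20
cohorts of n = 4,000; Westfall–Young calibration uses 200 null scenarios of
600 balanced rows with 120 permutations (500 for the power scenario). The
acceptance script scales a few of these down (its sizes are recorded in its
JSON output).

## Known limitations

Screening adjusts for maternal age only; everything else is left to the
reader of the signal list, by design. The BH family composition (per-run
vs. pooled) changes which codes clear a given FDR level; both are
available. Whether paternal models should adjust for maternal age, paternal
age, or neither is genuinely open; the default adjusts all runs for
maternal age, matching the stated analysis. The subgroup miner's
chi-square ranking is one defensible choice among several; rules should be
read as descriptions of high-risk strata, not effects.
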