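---
title: "Estimating respirable from inhalable dust: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respirable from inhalable dust: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustconv)
```

## The problem

Occupational dust exposure is measured in size-selective fractions. The
*inhalable* fraction `c_I` covers everything that enters nose and mouth
(aerodynamic diameter up to ~100 µm, sampled per the EN 481 / ISO 7708
conventions; see `inhalable_convention()`); the *respirable* fraction
`c_R` is the subset small enough to reach the alveolar region (roughly
below 10–15 µm). Historical measurement campaigns often recorded only
`c_I`, while modern limit values and disease investigations need `c_R`.
Retrospective exposure assessment therefore needs a defensible way to
estimate `c_R` from `c_I` — not a single factor, but a function with a
quantified uncertainty, conditioned on what was being done and with what
material.

dustconv implements that workflow end to end: reading raw single-fraction
records, filtering and pairing them, assigning pairs to a group taxonomy,
fitting per-group conversion functions, and applying a registry of
published conversion functions derived from parallel measurements in the
German MEGA exposure database (German industry, 1998–2016).

## The model

Workplace concentrations are approximately lognormal, so the relation is
modeled in log space:

$$\ln(c_R) = k \cdot \ln(c_I) + C_0 + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

fitted by ordinary least squares per group (`fit_loglog()`).
Back-transforming gives the power-law conversion function

$$c_R = c_I^{\,k} \cdot e^{C_0}.$$

Two limiting cases anchor the interpretation: `k = 1, C0 = 0` is the
worst case `c_R = c_I`; `k = 1, C0 < 0` is a constant conversion factor.
All published entries have `k < 1` and `C0 < 0`: the ratio
`c_R / c_I = c_I^{k-1} e^{C_0}` declines with concentration
(`dust_ratio()`), plausibly because agglomeration grows with
concentration and because coarse process mixtures are pooled within
groups.

A consequence worth stating explicitly: a power law with `k < 1` and
`C0 < 0` crosses the identity line at `c_I* = exp(C0 / (1 - k))` and
predicts `c_R > c_I` below it. For the shipped registry entries this
crossing lies between ~3·10⁻⁵ and ~0.12 mg m⁻³ — far below
occupationally relevant levels, but it means the physical constraint
`c_R ≤ c_I` is guaranteed by the functional form only *above* the
crossing, not over an arbitrary range. The test suite asserts the
constraint on a log grid over [0.15, 100] mg m⁻³ and separately asserts
that every crossing point is below 0.15 mg m⁻³.

### Fit statistics carried along

* Classical standard errors of `k` and `C0`.
* Pearson `R`, `R²`, and the sample-size-adjusted
  `R² − (m/(n−m−1))(1−R²)` with `m = 1` predictor (`adjusted_r2()`).
* The standard error of the fitted mean,
  `s_fit(x) = s_resid · sqrt(1/n + (x − x̄)²/Sxx)`, reported as a range
  over the observed `ln(c_I)` (minimum `s_resid/sqrt(n)` at the
  predictor mean, maximum at the observed extremes). The range is
  evaluated over observed predictor values, not a trimmed grid.
* Diagnostics: the Durbin–Watson statistic on residuals ordered by
  measurement start time (ties broken by record id — the natural
  autocorrelation axis; no ordering is inherent in the model), and a
  Lilliefors-corrected Kolmogorov–Smirnov normality test.

Confidence bands (`confidence_band()`, `convert_dust()`) use
`± z · s_fit` with `z = 1.96` at the 95% level — a normal rather than a
t-quantile, appropriate for the group sizes involved and matching how
the published bands are defined. Published registry entries carry only
the `s_fit` *range*, not `x̄` and `Sxx`, so intervals computed from them
use the minimum `s_fit` and are flagged `"minimum-width"`: correct near
the predictor mean, optimistic toward the extremes. Functions created
from a fresh fit via `as_conversion_fn()` carry the full design
summaries and give exact bands.

### The Lilliefors test

Testing residual normality with mean and variance estimated from the
same sample invalidates the plain Kolmogorov–Smirnov null. Instead of
tabulated corrections (which differ between sources), the p-value is
Monte Carlo: `n_mc` standard-normal samples of the same size are pushed
through the same estimation step, and
`p = (1 + #{D_null ≥ D}) / (n_mc + 1)`. A seed is mandatory; the null
distribution for a given sample size can be precomputed once with
`lilliefors_null_stats()` when testing many samples. The suite checks
type-I calibration (rejection rate 5% ± 2 points over 1000 replicates at
n = 500) and agreement with the tabulated implementation in the nortest
package.

## Data selection and pairing

Records are excluded (with auditable per-record reasons,
`apply_exclusion_filters()`) when the duration is below 2 h (strict:
2.0 h is kept), the value is below the limit of quantification, or the
concentration exceeds 100 mg m⁻³ (inhalable) / 10 mg m⁻³ (respirable),
both strict as printed. Below-LOQ records are read and carried with a
flag, then excluded and counted at the filter stage, so exclusion
tallies remain auditable; LOQ values are inputs, never computed —
samplers' LOQs are not published.

Pairing (`form_pairs()`) matches an inhalable and a respirable record
when they share factory, location within the factory, calendar day (of
the start time), industrial sector, report number, sampling type and
working activity; when start and end times each differ by at most 5
minutes (inclusive); and when `c_R ≤ c_I`. The original pairing
procedure used 12 variables but enumerates only examples; the
implemented set is a documented approximation. Where several candidates
remain, the resolution is deterministic: inhalable records are processed
in (start, id) order and take the candidate with the smallest total
|start offset| + |end offset|, ties broken by record id. This makes
pairing invariant under row shuffling, which the suite verifies, along
with equivalence to a brute-force all-candidates matcher on instances of
~2000 records. The `c_R ≤ c_I` check runs after metadata/time matching
so its rejection count is reported separately.

## Grouping

The taxonomy (`load_taxonomy()`, an editable YAML file) has four levels:

1. **Working activity**, six mutually exclusive groups: 1 surface
   treatment, 2 high-temperature processing, 3
   filling/transport/storage, 4 machining/abrasive techniques, 5
   forming, 6 others. Unknown activity strings fall back to group 6.
2. **Material**, ten printed subcategories pooled into A
   (mineral-dominated), B (metal-dominated), C (fiber-dominated).
   Wood is deliberately left unclassified: wood dust is predominantly
   inhalable and not comparable to mineral dust, so no conversion is
   offered for it.
3. **Combined** activity × material groups — only 1-A, 2-B, 4-A and 6-B
   have published functions.
4. **Heuristic** groups α–η (soldering, casting, welding,
   high-temperature cutting, blasting, chiseling/embossing, wire
   drawing): activity subsets with the best fit quality. Membership
   requires the matching material group (metal for α, β, γ, δ, η;
   mineral for ζ; any classified material for ε). The source table
   lists ζ as originating from 4-A while the accompanying text says
   5-A; the taxonomy records the table value and flags the
   contradiction in a comment.

`resolve_conversion_group()` walks heuristic → combined → activity →
material and returns the most specific available group, mirroring the
recommended usage order. One policy decision was genuinely open:
activity group 6 ("others") is also the fallback bucket for unknown
codes, so it is treated as uninformative at the activity level and
resolution falls through to the material group; a pair with activity 6
and unclassified material resolves to nothing. The whole-dataset
function ("0") is only ever returned on explicit request
(`allow_whole_dataset = TRUE`, with a warning): grouped functions should
always be preferred.

## The conversion registry

`load_registry()` ships all 21 published entries (whole data set, groups
1–6, A–C, the four combined groups, α–η) with coefficients exactly as
printed, guarded by an MD5 digest over a canonical serialization that is
verified on every load. The abstract of the source reports exponents
from 0.454, while the smallest tabulated `k` is 0.500 (group 1); the
registry transcribes the table. Default validity range for conversions
is 0.01–100 mg m⁻³ of `c_I`, with loud warnings outside; the functions
describe German industry 1998–2016 and extrapolate beyond comparable
conditions. User-facing examples round concentrations to two significant
figures; full precision is kept internally.

## The synthetic generator

The original paired data are not public. `group_scenario()` +
`generate_pairs()` + `generate_records()` emulate their statistical
structure so the whole pipeline is testable against known ground truth:

* `ln(c_I) ~ N(mu_lnI, sigma_lnI)` with defaults `mu_lnI = 0`,
  `sigma_lnI = 1` (median 1 mg m⁻³, spanning roughly 0.05–20 mg m⁻³) —
  a convention chosen once as a realistic workplace range, not a value
  from data.
* `ln(c_R)` from the conversion model with residual sd `sigma_res`.
* Draws violating `c_R ≤ c_I` or the concentration cutoffs are
  resampled, with counts reported (`n_resampled`), so truncation is
  never silent. A scenario where more than half of the draws violate
  `c_R ≤ c_I` is refused as inconsistent.
* Timestamps are 2-h shifts (most published values came from 2-h
  measurements), metadata are synthesized consistently, and each duo
  carries its own report number, so decoys cannot cross-pair and
  pairing precision/recall against the manifest are exact.
* `generate_records()` adds decoy duos that each violate exactly one
  rule (time offset beyond tolerance, mismatched report number,
  `c_R > c_I`, below LOQ, short duration, above-cutoff concentrations),
  then shuffles rows deterministically.
* One master seed expands into per-scenario seeds by a fixed rule, so
  adding a scenario never perturbs the others; the caller's RNG state
  is saved and restored.

When a simulation should mirror a published group,
`scenario_from_registry()` back-derives the residual sd from the printed
minimum fit standard error (`sigma_res = s_fit_min · sqrt(n)`, since the
minimum of `s_fit` is `s_resid/sqrt(n)`), and optionally the predictor
spread from the printed slope standard error
(`sigma_lnI = s_fit_min / se_k`), making the printed `se_k` the true
sampling sd of the simulated design.

### What the generator does and does not show

Passing recovery tests on this generator demonstrates that the
estimator, the pairing logic and the bookkeeping are correct under the
model's own assumptions. It does not validate the published coefficients
against real workplaces: the generator has no sampler-specific
measurement error, no secular trend, no within-group activity mixture,
and exact lognormality.

Two caveats discovered while building the recovery suites are worth
recording. First, conditioning on `c_R ≤ c_I` truncates the residual at
a bound that grows with `ln(c_I)`; when `sigma_res` is large (the
whole-dataset value is ≈1.13 on the log scale) this biases a refit of
the slope upward substantially. Estimator-recovery checks therefore draw
from the untruncated model (`enforce_cr_le_ci = FALSE,
apply_cutoffs = FALSE`); the same conditioning affects any real data set
selected with a `c_R ≤ c_I` rule, and the published coefficients
describe the selected population. Second, the printed standard errors of
`C0` lie *below* the theoretical floor `s_resid·sqrt(1/n)` (the printed
minimum `s_fit`) for part of the groups — mathematically,
`se(C0) = s·sqrt(1/n + x̄²/Sxx) ≥ s·sqrt(1/n)` — so a ±3·se(C0) coverage
check against the printed values cannot reach nominal coverage for
those groups under any simulated design. The acceptance suite asserts
it anyway and the affected assertions fail, documenting the
inconsistency rather than hiding it; the slope coverage checks pass for
all 21 groups.

## Numerical choices and problem sizes

* Natural logarithms throughout.
* OLS via `stats::lm`; the suite verifies equality with the closed-form
  normal-equation solution to 10 significant digits up to n = 10⁵.
* A numerically perfect fit (residuals at rounding-noise level) reports
  `s_resid = 0`-like values and an undefined (`NA`) Durbin–Watson
  statistic rather than a noise-driven one.
* Degenerate inputs error loudly: fewer than 3 pairs, zero predictor
  variance, all-zero residuals for the Durbin–Watson statistic,
  fewer than 5 observations for the Lilliefors test.
* Recovery suites use 200 replicates per registry group at the printed
  group sizes (34–15 120 pairs); the slope-recovery average uses 50
  replicates at n = 15 120; Lilliefors calibration uses 1000 replicates
  of n = 500 against a 4000-sample precomputed null. These sizes give
  Monte-Carlo error comfortably inside the asserted margins.
* Timestamps carry minute precision (ISO-8601, UTC); the duration field
  must agree with the timestamps within one minute.

## A worked example

```{r example, eval = FALSE}
reg <- load_registry()
tax <- load_taxonomy()

# simulate a welding campaign, run the full pipeline
cfg <- simulation_config(
  list(group_scenario("gamma", k_true = 0.803, C0_true = -0.601,
                      sigma_res = 0.3, n_pairs = 500)),
  seed = 1, decoy_time_frac = 0.05
)
sim <- generate_records(cfg)
flt <- apply_exclusion_filters(sim$records)
prs <- form_pairs(flt$records)
pairs <- assign_groups(prs$pairs, tax)
fit_by_group(pairs, level = "heuristic")

# retrospective estimate for a welding workplace measured at 10 mg/m^3
convert_dust(10, registry_fn(reg, "gamma"))
```

## Limitations

* The activity lists in the taxonomy are seeded from the published
  group definitions; real exports use local coding systems and need the
  YAML extended.
* No thoracic-fraction conversion, no wood-dust conversion, no
  probabilistic record linkage, no weighted or robust regression, and
  no multi-predictor regression — activity and material influence
  `c_I` itself, so they enter through grouping, not as covariates.
* Published-entry intervals are minimum-width by necessity (the full
  design summaries were not published).
* The conversion functions describe average relations over many
  workplaces in German industry 1998–2016; individual workplaces within
  a group can differ substantially, and choosing the right group
  matters more than the statistical error terms.
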