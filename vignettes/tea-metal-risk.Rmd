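---
title: "Methods: deterministic heavy-metal risk assessment for brewed tea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic heavy-metal risk assessment for brewed tea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brewrisk)
```

## The problem and the model

Surveys of trace metals in tea report concentrations in the dried leaves
("made tea", mg/kg), but a drinker ingests only what leaches into the cup.
`brewrisk` chains three deterministic models:

**Brewing transfer.** For a brew of $M_t$ grams of tea in $V_i$ litres of
water, the transfer rate of an element is

$$T = \frac{C_i \, V_i}{C_t \, M_t},$$

with $C_i$ the infusion concentration (µg/L) and $C_t$ the made-tea
concentration (mg/kg, numerically µg/g, so the units cancel). $T$ is the
fraction of the element's brewed mass that reaches the liquid. Values above
1 are physically impossible but can arise from measurement noise on paired
samples; the pipeline permits and flags them rather than truncating, so the
flag count is itself a QC signal. The default protocol is 7 g / 150 mL /
10 min; steep time is metadata only — no leaching kinetics are modelled, so
the package cannot extrapolate to other brew times.

**Exposure.** A subpopulation drinking $D$ grams of tea per day at body
weight $B_w$ kg has an estimated daily intake (µg per kg body weight per
day)

$$\mathrm{EDI} = \frac{C_t \, T \, D}{B_w} = C_t \, T \, r,$$

where $r = D/B_w$ (g/kg bw/day) is the canonical internal representation of
a consumption profile. $C_t T$ — the made-tea concentration with transfer
applied — is used rather than the infusion concentration directly; this is
both the standard formulation and the one that reproduces the published
hazard tables from a single $r$ per subpopulation (checked below).

**Risk.** Non-carcinogenic: $\mathrm{HQ} = \mathrm{EDI}/\mathrm{RfD}$
(both µg/kg bw/day) and $\mathrm{HI} = \sum_e \mathrm{HQ}_e$, with 1 the
conventional acceptability line. Some typeset renderings of the index
divide the sum by the number of elements; the quantity actually used and
tabulated in this literature is the plain sum, and the published HI rows
that `tests/testthat/test-acceptance.R` reproduces confirm it, so `hi()`
sums. Bioavailability-adjusted variants multiply each HQ by the element's
oral absorption fraction (defaults 40/60/1/50/10 % for Cu/Pb/Cr/Cd/Ni).
Carcinogenic: $\mathrm{TR} = \mathrm{EDI} \times S_f$ with $S_f$ in
(mg/kg bw/day)$^{-1}$; the EDI is converted µg→mg in exactly one audited
place (`tr()`), and `tr_total()` sums TRs against the $10^{-4}$ threshold.
The "adjusted TR" column (`tr_adjusted`) is TR scaled by the same oral
bioavailability; the source survey plotted such a starred series without
stating its formula, so this column is explicitly the package's
interpretation.

## Units

| Quantity | Unit | Where fixed |
|---|---|---|
| made-tea concentration | mg/kg ≡ µg/g | matrix tag `made_tea` |
| infusion / blank / spike | µg/L | matrix tags |
| RfD, EDI | µg/kg bw/day | toxref, `edi()` |
| $S_f$ | per mg/kg bw/day | toxref; µg→mg inside `tr()` only |
| consumption ratio $r$ | g/kg bw/day | profiles |
| HQ, HI, TR | dimensionless | report layer prints HQ/HI ×100 (%) |

The matrix tag carries the unit, so mixing mg/kg with µg/L without an
explicit conversion is impossible by construction. HQ is stored as a
dimensionless fraction; the percent scale seen in published tables is a
formatting concern handled only by `format_sci_percent()` (2-significant-
figure scientific notation), never inside the arithmetic.

## Analytical quality control

LOD and LOQ are 3× and 10× the SD of the reagent blanks, computed with the
sample SD ($n-1$ denominator — the survey did not specify; $n-1$ is the
standard choice for ten blanks and is what reproduces the published limits
from the published SDs). `loq/lod = 10/3` exactly, and both are
scale-equivariant in the blanks; both facts are property-tested.

Below-detection ("ND") measurements are carried as censored flags with no
value until `substitute_censored()` applies a policy. The default policy
assigns the LOQ — the source survey's own rule and the most conservative of
the three; `half_loq` and `zero` are offered for sensitivity analysis, and
the policy used is recorded in the output's provenance attribute. The
policies order every per-element mean monotonically (LOQ ≥ ½LOQ ≥ zero),
which is property-tested rather than assumed.

Spike recovery is `(measured − base)/spiked × 100` with `base = 0` by
default (the reference recoveries imply negligible base signal). The CRM
check passes when `|detected − certified| ≤ k·sqrt(sd_c² + sd_d²)` with
coverage `k = 2`.

## Reconstructing the consumption profiles

The survey behind the default numbers never published $D$ or $B_w$ for its
six subpopulations (male/female, urban/rural, two age bands) — only the
resulting HQ table. Because HQ is linear in $r$, the ratio is recoverable
by inversion:

$$r = \frac{\mathrm{HQ} \cdot \mathrm{RfD}}{C_t \, T}.$$

`default_profiles()` performs this inversion at run time from the published
Cu HQ cells. The inversion is well-posed: back-solving $r$ from each of the
five elements of a column must agree if the published table came from one
ratio per subpopulation, and the test suite checks that the coefficient of
variation across elements is below 3 % for the male and female columns.
Cu anchors the convention; any other element changes the ratios by at most
a few percent. The resulting defaults are approximately 2.25, 1.49, 1.92,
1.77, 1.77 and 2.40 ×10⁻³ g/kg bw/day for male, female, urban, rural,
age 18–40 and age ≥ 41 — derived values, not survey measurements.

## The synthetic-data generator

Only summary statistics of the 91-sample survey were published, so the
generator emulates their structure:

* **Concentrations** — per element, a lognormal truncated to the published
  range, with `(meanlog, sdlog)` fitted so the *truncated* mean and SD
  match the published mean ± SD (closed-form truncated-lognormal moments,
  Nelder–Mead on `(meanlog, log sdlog)` with the mean error weighted 200:1
  so the mean is matched exactly whenever the SD is not attainable).
  Lognormal because concentrations are positive and right-skewed and the
  published ranges are wide. One published combination is infeasible for
  this family: a mean of 1.90 with SD 0.70 on the range 1.02–2.93 (Ni)
  exceeds the supremum SD (~0.55) of any truncated lognormal with that
  mean — an SD that large on that range requires a U-shaped/bimodal sample.
  The generator therefore matches the Ni mean exactly and attains the
  closest feasible SD; tests consequently check sample moments against the
  generator's own analytic truncated moments (1 % at n = 200,000) plus
  sample means against the published means (3 SE at the survey's n = 91).
* **Sampling** is inverse-CDF (uniform on the CDF interval, then
  `qlnorm`): distributionally identical to rejection sampling from the
  range, but with exact sample counts and no retry loop. `sdlog` is kept
  inside [0.02, 2.5]; beyond that the family degenerates toward power laws
  and the tail-probability arithmetic in the moment formulas loses all
  precision.
* **Censoring** — elements with a nonzero `nd_fraction` (default: Cd at
  0.05, since the survey reported its Cd minimum only as "below detection"
  and several infusion values under the limit; the exact count was not
  published, so 5 % of 91 ≈ 4–5 censored samples is the package's one-time
  realism choice) treat the `nd_fraction` quantile of the fitted
  distribution as the reporting limit: draws below it are emitted censored.
  `made_tea_nd_limits()` exposes that limit so the substitution step is
  reproducible.
* **Transfer rates** — logit-normal per element, moment-matched by
  quadrature to the published mean with SD defaulting to 0.3 × mean (no
  dispersion was published; 0.3 gives coefficient-of-variation dispersion
  comparable to the concentration data while keeping essentially all mass
  away from the 0/1 boundaries). Logit-normal guarantees $T \in (0, 1)$; a
  configured SD of zero degenerates to the constant mean. Infusion
  concentrations are then derived through the exact brewing identity, so
  `mean_transfer_rates()` on a generated dataset recovers the configured
  means by construction plus sampling noise only.
* **QC batches** — ten blanks per element, drawn then affinely
  standardised so the sample SD is exactly LOD/3 (making
  `detection_limits()` reproduce the published LOD/LOQ bit-for-bit — a
  fixture-calibration device, not a claim about real blank behaviour),
  with the blank mean at 3×SD so all values stay nonnegative (standardised
  deviates of n = 10 are bounded by 3). Spike recoveries are drawn within
  1.5 percentage points of the published values.
* **Seeding** — one master seed; each element × stage gets a deterministic
  substream seed, so regenerating with the same seed is byte-identical and
  the whole pipeline (generation → censoring → transfer → risk report) is
  reproducible end to end.

What the generator does *not* emulate: inter-element correlation (none was
published), spatial/plantation covariates, analytical triplicates, or the
apparent bimodality implied by the Ni summary. Passing tests on synthetic
data therefore demonstrate that the pipeline's arithmetic, censoring
handling and summaries are correct under the published marginal structure —
not that real Tieguanyin samples follow these distributions.

## Known inconsistencies in the reference numbers

Three published values cannot be reproduced by any consistent application
of the model, and the package deliberately does not chase them:

* The reported Cd target risk (1.6 × 10⁻⁵ for age ≥ 41) is ~50× larger
  than $\mathrm{EDI}_{Cd} \times S_{f,Cd}$ computed from the same source's
  own HQ table (~3 × 10⁻⁷); consequently the "~97 % Cd contribution" to
  total cancer risk is also not reproducible. `brewrisk` computes TR
  uniformly for every carcinogen.
* The claim that adjusted HI fell "by approximately 20 %" conflicts with
  the published adjusted values (the decrease is ~72 %); the package simply
  computes both indices.
* The reported TR minimum ("Cr for females") is not the minimum of the
  model's TRs — Pb TRs are ~30× smaller. The package reproduces the
  Cr-female value itself and leaves the ranking to the data.

One further rounding artefact is worth knowing: adjusted-HQ cells published
at 2 significant figures were computed from unrounded HQs, so multiplying
the *printed* HQ by the bioavailability occasionally lands a unit or two
off in the last digit (Cu male: 4.7e-3 × 0.4 = 1.88e-3 vs a printed
2.0e-3). The acceptance tests propagate the input rounding instead of
pretending the printed cells are exact.

## Numerical choices and degenerate inputs

* Full double precision everywhere; rounding only at the report layer
  (2-significant-figure scientific notation on the percent scale).
* `transfer_rate()` treats $C_t = 0$ as an undefined-transfer error, never
  infinity; `tr()` on an element without a slope factor is an error, not 0.
* Zero-variance blanks give LOD = LOQ = 0; equal certified/detected CRM
  values with zero SDs pass with score 0 (0/0 defined as 0).
* `hi()` and `tr_total()` reject empty input; `assess()` with zero
  profiles returns empty tibbles without error.
* Mean transfer summarises the per-sample ratio mean (samples are the
  replication unit), not the ratio of element totals; unpaired samples are
  skipped with a logged count, elements with no pairs omitted with a
  warning.

## Problem sizes

The test suite works at the survey's own scale: n = 91 for
moment-recovery checks (3 SE bands), n = 200,000 for the sampler-vs-
analytic-moment battery (1 % bands), 20-case property loops for
scale-equivariance and censoring monotonicity, all under fixed seeds. The
whole suite runs in well under a minute; `scripts/acceptance.R` is
deterministic desk arithmetic plus one seeded synthetic smoke run.

## Limitations

Deterministic point estimates only: no Monte-Carlo exposure distributions,
no multi-pathway aggregation (water, rice, vegetables), no speciation
(total Cr, not Cr(VI)), no leaching-kinetics dependence on steep time, and
consumption ratios inherited from a survey whose raw data are unavailable.
The defaults describe one oolong tea from one region; for other teas or
brewing habits, supply your own concentration data, transfer rates,
brewing spec and profiles — every default is an argument.
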