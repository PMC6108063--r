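---
title: "Methods: composite livelihood vulnerability indices at agroecosystem scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite livelihood vulnerability indices at agroecosystem scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lviaes)
```

## The model

`lviaes` implements the Livelihood Vulnerability Index family for stratified
household surveys aggregated to agroecosystem (AES) units. The chain is:

1. **Aggregation.** Each indicator is reduced to one raw value per unit:
   categorical fields as `100 × matches / non-missing responses` (missing
   responses leave the denominator — they are "no response", not "no"),
   numeric fields as means or sums. Unit-level quantities that no household
   question measures (land suitability scores, irrigation potential in
   hectares, production totals) enter as *precomputed* cells; every cell
   records its provenance.
2. **Standardization.** Min-max across units,
   $I_v = (I_a - I_{min})/(I_{max} - I_{min})$, so each non-constant
   indicator attains 0 and 1 at some unit. The bounds come from the units
   being compared, which makes every score *relative to the compared
   population* — the central interpretive caveat of this index family.
3. **Orientation.** Indicators hypothesized to *lower* their contributing
   factor are flipped ($1 - I_v$) after standardization. Orientation is data
   (a per-indicator field in the framework config), not convention, because a
   silent sign error in, say, walking distances would invert adaptive
   capacity. The flip after (rather than inside) min-max is algebraically
   equivalent to swapping the bounds and keeps the bounds reportable.
4. **Profiles and factors.** Profile scores are unweighted means of their
   indicators; the composite LVI and the IPCC contributing factors
   (exposure $E$, sensitivity $S$, adaptive capacity $A$) weight profile
   scores by indicator count $N_p$. This "balanced weighted average" makes
   the composite identical to the flat mean of all standardized indicators —
   an identity the test suite checks to $10^{-12}$ against a brute-force
   oracle on random tables, and the reason missing cells are handled by
   *reducing* $N_p$ for that unit rather than imputing.
5. **Index.** $\mathrm{LVI\text{-}IPCC} = (E - A)\,S$, in $[-1, 1]$ when all
   factors are in $[0,1]$: sensitivity multiplies the exposure/capacity
   imbalance rather than adding to it, so a highly sensitive unit with
   balanced $E$ and $A$ still scores near zero.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Classification thresholds | (0, 0.45) | Negative = capacity exceeds exposure = `low`. The split of positive scores at 0.45 reproduces the canonical published class pattern (scores ≈ 0.7 "high", ≈ 0.18 "positive but close to zero" = `moderate`); intervals are left-closed. Fully configurable. |
| TLU factors | camel 1.0, cattle 0.7, horse 0.8, mule 0.7, donkey 0.5, sheep 0.1, goat 0.1, pig 0.2, chicken 0.01 | The standard tropical-livestock-unit table (1 TLU = 250 kg animal); overridable per call. |
| "All households" summary | both conventions reported | Published survey tables demonstrably mix the unweighted unit mean and the sample-size-weighted mean row by row, so `all_units_summary()` exposes `mode = "unweighted"`/`"weighted"` and reports never guess a single convention. |
| Significance level α | 0.05, no multiplicity correction | Published pairwise "significantly different (95% level)" flags are uncorrected; Holm/Bonferroni available via `adjust`. |
| Anomaly baseline | full period of record | Standard when no reference climatology is stated; configurable as a year range. |
| Monthly → annual missing tolerance | 2 months | A year missing more than this is dropped with a warning; configurable. |
| Trend test df | points used − 2 | Matches the classical Student's-t-for-linear-trend convention (a 31-point record gives df = 29). |

## Statistical tests

Proportions are compared with the pooled two-sample $z$ (identical to the
2×2 Pearson chi-square without continuity correction, an identity tested
against `prop.test`); at survey-scale $n$ this is indistinguishable from the
$t$-of-proportions wording some reports use, and it reproduces the published
temperature-perception significance pattern from the printed percentages and
sample sizes. Means use Welch's $t$ (unequal variances,
Welch–Satterthwaite df), computable from published summary statistics alone;
correlation is Pearson's $r$ with the $t$-based two-tailed p on $n-2$ df.
Trend tests are OLS slope / standard error with two-tailed $t$ p-values; an
exact fit is flagged rather than reported as $p = 0$ from a division by zero.

## What the synthetic generator emulates — and what it does not

`default_choke_spec()` encodes a five-unit stratified survey with the
published per-unit sample sizes (87/183/148/284/91, total 793). Categorical
probabilities and the land-holding and herd-size (TLU) means are the
published per-unit summary values; herd composition fixes cattle at 70% of
expected TLU with sheep/goats/donkeys/chickens making up the rest, at
per-species Poisson head counts. Where the source tables publish no
dispersion or no per-unit value, the spec uses conventions chosen once:
lognormal with coefficient of variation 0.5 for positive continuous
quantities (land, money, walking hours), and *identical* parameters across
units for infrastructure/community/social fields reported as not
significantly different between units. Printed categorical rows that do not
sum to 100% keep their analysis-relevant categories exactly and absorb the
residual into the catch-all level.

The generator draws responses independently within a household (no
response correlations are published), samples each unit from its own
deterministic RNG substream (adding a unit never perturbs the others), and
does not model: spatial structure within units, enumerator effects,
item-nonresponse patterns, or the ecosystem/agriculture unit-level cells,
which ship as a clearly-labelled synthetic fixture
(`precomputed_choke_synthetic.csv`).

Consequently a green test establishes that the *pipeline* — aggregation,
standardization, weighting, testing — is correct and that parameters fed in
are recovered (proportions within 3 binomial SE at inflated $n$; trend-slope
CI coverage ≈ 95%); it does **not** establish that the synthetic world
reproduces the published per-unit factor scores, which depend on undeposited
raw data and are excluded as targets.

## Numerical choices and degenerate inputs

- Constant indicators across units standardize to 0 with a warning (a
  no-information indicator should not inject spread); a single-unit table is
  an error since min = max everywhere.
- A degenerate pooled proportion (0 or 100%) has zero variance; it can only
  arise with equal group proportions and returns $p = 1$.
- Missing indicator cells reduce the profile's $N$ for that unit and drop
  out of the composite weights, preserving the flat-mean identity over the
  non-missing indicators.
- Report tables round half away from zero (0.545 → 0.55) at 2 decimals for
  indices and 1 for percentages, matching printed-table precision;
  everything upstream carries full precision.
- Classification at a threshold takes the upper class (left-closed
  intervals), so a score of exactly 0 is `moderate`.

## Design choices where the method description is open

- **Duplicated "irrigation potential".** The canonical indicator table lists
  irrigation under both ecosystem (hectares suitable) and technology (% of
  households practicing). Both are kept as distinct indicators with distinct
  sources and both count in $N_p$; dropping either would silently change
  every downstream weight.
- **Published index tables as inputs, not truths.** The published
  sensitivity values > 1 cannot arise from the equations as written (factors
  are convex combinations of [0,1] values), and the published LVI-IPCC
  column does not equal $(E-A)S$ of its own columns. The package implements
  the equations exactly; `format_table(style = "paper")` carries a footnote
  noting the identity it enforces, and nothing is reconciled silently.
- **Exposure from perceptions.** The default framework feeds the climate
  profile from perception proportions (temperature increasing, precipitation
  decreasing, extreme events experienced), the three climate quantities the
  household survey actually measures per unit.

## Known limitations

- Min-max standardization makes all scores relative: adding or removing a
  unit changes every bound and hence every score. Cross-study comparisons of
  absolute values are not meaningful.
- The classification thresholds above 0 are a reporting convention, not an
  estimated quantity.
- No survey design weights beyond per-unit $n$, no imputation, and no
  alternative aggregation families (geometric, PCA-weighted) — the balanced
  weighted average is the method's defining choice.
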