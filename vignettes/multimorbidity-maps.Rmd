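---
title: "Multimorbidity relationship maps: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity relationship maps: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbimap)
```

This vignette documents the models behind morbimap, the parameters that
matter, and the design decisions taken where more than one reasonable
choice existed.

## The impairment model

Twenty test domains from four instruments are reduced to one binary scale:
*impaired* means performance more than 1 SD below test norms on the
instrument's native scale.

- **Touwen / MND.** The examination scores eight functional domains as
  dysfunctional or not. One or two dysfunctional domains is *simple* minor
  neurological dysfunction, more than two *complex*; the MND column of the
  impairment matrix pools both as impaired. A missing domain flag makes
  the whole classification indeterminate — we do not classify on partial
  counts, because a child with 2 observed dysfunctions and a missing flag
  could be either simple or complex.
- **MABC-2 and NEPSY-II.** Integer standard/scaled scores 1–19 with mean
  10, SD 3; impaired when ≤ 7, i.e. below the 16th percentile.
- **SIPT.** z-scores in [−3, 3]; impaired below −1.0. The boundary itself
  is ambiguous in the source conventions (the band "−1.0 to −2.0" denotes
  mild dysfunction, but the cutoff is stated as *below* 1 SD); we take the
  strict inequality as default and expose `siptStrict = FALSE` for the
  inclusive reading. For continuously distributed scores the choice is
  immaterial in expectation; for archival data with scores recorded at
  exactly −1.0 it is not, hence the flag.

Missing scores propagate to an *observed* mask. An unobserved cell is
never an impairment call, so per-domain denominators follow the observed
data (matching reference tables in which denominators vary by domain),
burden counts are bounded by each child's observed domains, and a child
missing either member of a domain pair contributes nothing to that pair.
The alternative — counting missing as unimpaired — silently deflates
rates and was rejected.

Two imputation utilities implement the rules used for sparse,
non-systematic missingness in this literature: the group median for a
skewed score domain, and the mean of observed composite members for an IQ
subtest. Both log their imputations and are idempotent. They are never
applied automatically.

## The synthetic-cohort generator

The generator exists so the whole pipeline — classification, maps,
statistics — can be exercised and tested without clinical data. It
emulates a two-group design (defaults 56 EPT, 37 term-born) with a
single-factor latent liability:

$$L \sim N(\mu_g, 1), \qquad \mu_{EPT} = -s,\; \mu_{TERM} = 0,$$
$$z_d = \delta_d + \lambda_d L + \sqrt{1 - \lambda_d^2}\,\varepsilon,
  \qquad \varepsilon \sim N(0, 1),$$

with the native score \(= \text{mean} + \text{SD} \cdot z_d\), rounded to
1–19 for MABC-2/NEPSY-II and clipped to [−3, 3] for SIPT. Each Touwen
domain is dysfunctional when its own liability-linked draw falls below a
probit threshold set by `touwen_base_rate`. The single factor is the
minimal structure that produces *correlated* impairments across
instruments — the phenomenon relationship maps display — while leaving
every marginal rate free; with a common loading \(\lambda\), the implied
inter-domain score correlation is \(\lambda^2\) (a tested invariant).
Multi-factor structure (e.g. a separate motor factor) is deliberately out
of scope.

**Calibration.** The marginal impairment probability is closed-form,
\(\Phi(c_d - \delta_d - \lambda_d \mu_g)\), so matching a target
(EPT, term) rate pair per domain is two equations in two unknowns:
\(\delta_d = c_d - \Phi^{-1}(\text{term}_d)\) and \(\lambda_d =
(\Phi^{-1}(\text{ept}_d) - \Phi^{-1}(\text{term}_d)) / s\). The
per-domain difficulty offset \(\delta_d\) is essential: without it the
term-group rate is pinned at \(\Phi(c_d)\) by the scale's own cutoff and
most published term rates are unreachable. For MND the two parameters
(base rate, Touwen loading) are solved numerically against the
closed-form integral `mndRate()` (801-point Gaussian quadrature grid over
±8 SD; Nelder–Mead from three starts; residual above 1e−6 is flagged as
infeasible, never silently accepted).

Choices a user can override, with the defaults' rationale:

- `latent_shift` — default is the largest probit gap across domains
  (≈ 1.37 for the reference rates, set by SIPT motor accuracy), the
  smallest shift for which every loading stays in [0, 1].
- target rates — default `referenceImpairmentRates()`, the published
  prevalence table for a 56/37 EPT cohort at 6 years. Zero term-group
  rates are unreachable on a probit scale and are floored at \(1/(2N)\),
  flagged in the calibration's feasibility table. Infeasible pairs (term
  rate above EPT rate, or a loading above 1 under a user-fixed shift) are
  reported per domain, not clamped. With zero shift and equal targets any
  loading fits; the tie-break returns the smallest (0).
- `missing_rate` — default 0.08, MCAR, applied per score and to the
  Touwen block as a whole. The reference denominators imply roughly 4–12
  missing children per domain out of 56/37, i.e. high single-digit
  percentages; MCAR operationalizes "non-systematic" missingness. The
  generator does not model informative missingness.
- covariate marginals — sex, mother's education (3 ordinal levels),
  severe neonatal brain injury (IVH III–IV) and a combined morbidity flag
  (sepsis/BPD/NEC) are drawn from the published group characteristics,
  independent of liability. The combined morbidity probability is not
  published; 0.6 sits between the largest single component (0.51) and the
  independence union (~0.71), reflecting the positive correlation of
  neonatal morbidities. Covariates independent of liability make the
  adjusted and unadjusted group coefficients agree in expectation — a
  useful test property, and the reason passing covariate-adjustment tests
  says nothing about confounding control on real data.

What the generator does *not* emulate: item-level test content, age
norms, dropout, informative missingness, multi-factor impairment
structure, and covariate–outcome confounding. Tests passing on synthetic
cohorts validate the pipeline's arithmetic and calibration, not these
aspects of real data.

## Co-occurrence counting

"Impaired test pairs" is read as the number of *distinct* domain pairs
with at least one (more generally \(k\)) co-occurring impaired children —
consistent with published totals that respect the \(\binom{20}{2} = 190\)
ceiling. The alternative reading, summing incidences over pairs, is
exposed as `incidenceSum()`. Triple relationships are per-child
conjunctions (impaired in *all* listed domains), reported as per-group
counts, as conditional proportions among children impaired in the first
listed domain, and as a whole-group 2×2 odds ratio — published phrasings
mix the conditional and whole-group denominators, so both are provided.

Map layout is fixed by the registry: upper semicircle clockwise
MND → BMC, lower semicircle anti-clockwise AuAttn → GeoP, so motor/
sensorimotor instruments face neuropsychological ones. Edge thickness is
linear in the pair count with a 0.5 pt minimum visible width (the source
convention specifies proportionality only); node annotations are the
impaired-child counts and the distinct-pair total is printed bottom left.
Rendering is pure base graphics and deterministic; the returned layout
and edge table (not device bytes) are the tested surface.

## The statistical layer

- **2×2 odds ratios** are cross-products with Woolf log-scale intervals;
  for a 2×2 table this equals the binomial-logistic MLE, which we verify
  against the cumulative-logit fit reduced to two levels. Any zero cell
  yields NA (matching how such tables are published) unless the
  Haldane–Anscombe +0.5 correction is explicitly requested.
- **Cumulative-logit OR** (3-level outcomes such as normal/simple/complex
  MND): proportional-odds likelihood maximised by Newton iteration on
  sufficient statistics — analytic score, numerically differentiated
  Hessian (central differences, h = 1e−5), step-halving, convergence at
  gradient or step below 1e−10. |β| > 15 (OR beyond e¹⁵) is declared
  separation and reported as non-convergent, never as an estimate.
- **Wild bootstrap regression** (default B = 2000): resamples
  \(y^* = \hat y + w\hat e\) with i.i.d. Rademacher signs, preserving
  each observation's residual scale and hence heteroscedasticity. The
  weight law is not pinned by the sources; Rademacher is the standard
  default and Mammen's two-point law is available. With all weights +1
  the original fit is reproduced exactly (a tested invariant). A
  noiseless response short-circuits to point intervals rather than
  degenerate BCa input. Coefficients per resample are obtained by one
  precomputed projection matrix, so B resamples cost one matrix product.
- **BCa intervals**: bias correction from the fraction of resamples
  strictly below the estimate (clamped to \(1/(2B)\) with a warning when
  all resamples fall on one side), acceleration from the jackknife
  skewness formula, endpoints as type-6 empirical quantiles (the common
  bootstrap convention; at B ≥ 500 the quantile type is immaterial at the
  tested tolerances). Identical resamples give the degenerate point
  interval with a warning. Jackknife refits that lose their contrast
  (e.g. deleting the only brain-injured child) produce undefined
  statistics; the acceleration uses the finite ones.
- **Bootstrap t-test** (default B = 1000): BCa interval for the mean
  difference; the p-value studentizes the null-shifted resample
  distribution (both groups recentred to the grand mean) with the +1/(B+1)
  finite-sample correction.
- **Standard tests** — Fisher's exact, Pearson χ², Mann–Whitney (midranks,
  continuity-corrected normal approximation), Welch t, BH adjustment —
  delegate to base R's implementations behind the package's interfaces,
  and the test suite checks them against independent brute-force oracles
  (full hypergeometric enumeration, exhaustive pair counting, hand
  step-up). The likelihood-ratio G test, which base R lacks, is
  implemented directly: zero observed cells contribute nothing, all-zero
  margins are dropped with a warning and the df adjusted.
- **FDR families**: the rate table adjusts across the 20 domains with a
  computable test; the regression table adjusts across the 19 score
  domains within each model family (unadjusted, adjusted). Family
  boundaries are not canonical in the sources; these are the package's
  documented choices.

Group comparisons code EPT = 1, so score coefficients are negative when
EPT children perform worse; Cohen's d is oriented positive for worse EPT
performance. The MND row of the comparison table is the unadjusted
cumulative-logit OR only — covariate-adjusted ordinal regression is out
of scope.

## Problem sizes used in the tests

The suite checks calibration at n = 5000/group (Monte-Carlo rate error
within ±0.03 of target), group separation across 200 seeded study-scale
cohorts (56/37), wild-bootstrap null coverage over 200 simulations at
n = 100 with B = 500, and BCa coverage for a Normal mean over 500
replications at B = 1000 — sizes at which binomial noise sits well inside
the asserted tolerances while the suite stays fast. Oracle-equivalence
checks run on random instances up to 100 children × 20 domains, where
exhaustive enumeration is exact.

## Known limitations

- The single-factor liability cannot represent domain clusters with
  distinct aetiologies; calibration constrains only marginal rates, so
  pair-count *totals* on synthetic data are model outputs, not targets.
- Adjusted-model coefficients on synthetic cohorts do not reproduce any
  published regression table: that would require the original raw data.
- The cumulative-logit fit supports one binary predictor, matching its
  use here; it is not a general ordinal-regression replacement.
- PNG output requires a capable graphics device; PDF is always written.
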