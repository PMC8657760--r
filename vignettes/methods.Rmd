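---
title: "Acquiescence correction and target-rotated factor structure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acquiescence correction and target-rotated factor structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: the measurement
model and its assumptions, the estimator conventions, what the synthetic
data generator does and does not emulate, and the numerical choices behind
the implementation.

## The instrument design

Everything is indexed against a *blueprint*: five domains (O, C, E, A, N
in the socio-emotional reading of the Big Five), 18 facets allocated
3/5/3/4/3 across them, and nine items per facet — three positively keyed
identity items, three negatively keyed identity items paired one-to-one
with the positive ones as antonym pairs, and three always positively keyed
self-efficacy items. The default blueprint therefore has 162 items, 108
identity items, and 54 antonym pairs. Facet codes follow the order in
which facets are conventionally tabulated for this design (within Amity:
Empathy, Respect, Trust, Gratitude); published tables occasionally swap
labels within a domain, so the package fixes one canonical order and keeps
it everywhere, giving byte-comparable loading tables across runs. Item
identifiers are synthetic tokens (`A2_idneg_1`); item wording is out of
scope.

## Acquiescence: definition and correction order

The acquiescence index of a respondent is the plain mean of their raw
identity-item responses, *before any reversal*. On a balanced set this is
an estimate of the respondent's content-blind scale shift: trait content
cancels between the two members of each antonym pair, so a respondent who
answers symmetrically scores exactly 3 (the midpoint of the 1–5 scale),
regardless of trait level. Self-efficacy items are excluded from the index
— all positively keyed, they confound content with agreement — but they
*are* corrected: the index is subtracted from every item response.

The order of operations matters and is a deliberate contract of the
package:

1. center: `corrected = raw − ACQ` (all 162 items);
2. orient: multiply by the keying sign (`identity_neg` columns × −1).

Reversing on the raw scale first (`6 − x`) and centering afterwards leaves
`−2·(ACQ − 3)` of bias in every negatively keyed item — acquiescence
doubled rather than removed. The test suite demonstrates this failure mode
explicitly. Raw-score (uncorrected) pipelines use the `6 − x` reversal,
which is the appropriate convention on the bounded scale.

Missing data: the index is the mean over *answered* identity items. The
balance argument needs pair-complete data, so respondents with fewer than
half the identity items answered, or with any answered pair missing its
partner, carry `balanced_flag = FALSE`; a warning reports how many
respondents fall below the (configurable) thresholds. A respondent with no
answered identity item gets a missing index and is dropped — with a
logged count — at the centering stage. The analysis this package
re-implements was collected on a forced-choice web platform, so no
authoritative missing-data rule exists for the index; this one is the
package's own documented choice, preferring transparency over imputation
machinery.

Corrected scores are centered reals and are *not* re-clipped to any range.

## Indicator scales

Factor analyses run on cluster scales: per facet, the mean of each item
triplet (positive identity, negative identity after orientation,
self-efficacy) gives the 54-indicator set; collapsing the six identity
items gives 18 six-item scales; the self-efficacy triplets alone give 18;
identity and self-efficacy scales together give 36. A cluster mean
tolerates one missing item in three (two in six); below that the
indicator is missing. Correlation matrices use listwise-complete rows by
default, with a pairwise option — the published analysis does not state
its choice, and at the sample sizes involved the difference is immaterial.

One algebraic consequence of within-person centering deserves note: the
corrected identity items of a complete-data respondent sum to exactly
zero, which induces one exact linear dependency among the oriented
identity indicators. The 54-indicator correlation matrix of corrected
scores is therefore singular by construction. This is a property of
ipsatized data, not a bug; the factor code handles it (see Numerical
choices).

## The factor model

The published analysis fitted a five-factor exploratory structural
equation model with target rotation in a commercial SEM program. This
package implements the same point-estimate structure as exploratory
factor analysis with oblique target rotation — the central methodological
substitution of the artifact, stated openly: estimates of loadings and
factor correlations correspond, while robust standard errors and
estimator-specific corrections are out of scope.

* **Extraction.** Maximum likelihood (via the standard ML discrepancy, the
  default), minimum residual (direct minimization of squared off-diagonal
  residuals over the uniquenesses), or principal components (for the
  separate identity / self-efficacy analyses, which were published as PCA
  "to place no constraints on loadings"). Uniquenesses below 0.005 are
  Heywood cases: clamped, flagged, and warned about (common-factor
  methods only; a PCA communality of 1 is legitimate).
* **Target.** The standard partially specified target: every loading cell
  outside an indicator's intended domain is targeted at zero; intended
  cells are free. The criterion is the sum of squared loadings over the
  zero-targeted cells.
* **Rotation.** Gradient projection on the orthogonal or oblique rotation
  manifold, minimizing the target criterion; oblique is the default (the
  published rotation's obliqueness is not stated; correlated domains are
  the substantively defensible assumption). Convergence when the
  projected-gradient norm falls below 1e−6, capped at 1000 iterations;
  non-convergence is a warning, never an error. Ten seeded random
  orthonormal starts plus the identity start guard against local minima;
  the best criterion wins.
* **Alignment.** Factor order and sign leaving the rotation are arbitrary,
  so solutions are aligned to the blueprint by exhaustive search over all
  column permutations and sign patterns (5! · 2⁵ candidates for five
  factors), maximizing the summed diagonal congruence against the one-hot
  target. The factor correlation matrix is permuted and sign-flipped
  consistently.

### Fit statistics

Conventions, fixed and labelled rather than configurable:
`χ² = (n − 1)·F_ML` with no Bartlett correction;
`df = k(k+1)/2 − (km + k − m(m−1)/2)` (1171 for 54 indicators and five
factors); `RMSEA = √(max(χ²−df, 0)/(df(n−1)))`; CFI/TLI against the
independence baseline (`F₀ = −log|R|`); SRMR as the root mean square
residual over the lower triangle including the diagonal; and the
χ²-based `BIC = χ² − df·ln(n)`. BIC conventions differ across programs
(−2logL-based values are on an entirely different scale), so the
package's BIC is labelled as the χ²-based variant and is not comparable
to values reported from SEM software.

## Congruence against an idealized target

Structure recovery is summarized by comparing each empirical factor's
54-vector of loadings with an idealized target vector per domain: 1 on
indicators intended for that domain, 0 elsewhere — deliberately ignoring
known secondary loadings, so the summary is conservative. All 5 × 5
empirical-by-theoretical pairs are computed.

Two coefficients are offered. **Tucker's congruence coefficient** (the
normalized inner product, no centering) is the default: recomputing the
published congruence tables from the published loading matrices reproduces
every printed cell only under Tucker's definition, so that is evidently
the coefficient behind them, and the package follows suit. The **Pearson
correlation** over the indicator rows is available as an option; it is
invariant to affine (not just scale) transformations of a loading column,
which can be preferable when solutions differ in loading variance. The
reproduction suite pins the published summaries: corrected diagonal mean
0.85 (minimum 0.78), raw diagonal mean 0.62 with the Amity diagonal entry
at −0.06 — the raw solution's fourth factor is an acquiescence factor
(negative items loading positively against positive items loading
negatively), and the package keeps the published raw columns exactly as
printed, since the published summaries were evidently computed without
re-alignment. Prose and table disagree by 0.01 on one raw-half entry
(0.25 vs 0.24 for theoretical A against empirical N); the tests use the
prose value with a ±0.02 tolerance, which covers both.

## The synthetic data generator

The generator exists so that every stage has a truth-known test bed (the
motivating data set, 50,209 students, is not publicly deposited). The
response process, content first:

1. domain scores `θ ~ MVN(0, Φ)`, default `Φ` with 0.25 off-diagonal;
2. facet scores `f = γ·θ_domain + √(1−γ²)·u`, `u` standard normal shared
   by the facet's nine items, default `γ = 0.8`;
3. latent item value `y = key·(λ·f + secondary terms) + ε`, default
   `λ = 0.7`, `ε` scaled so `var(y) = 1`; default secondary loadings put
   0.25 cross-loadings on facets that repeatedly show them in large
   samples (Responsibility→A, Self-confidence→E, Frustration
   tolerance→A, Enthusiasm-SE→N, Respect-SE→N);
4. acquiescence enters *pre-reversal and content-blind* as an additive
   shift on the latent response: `z = y + (a − 3)`, `a ~ N(2.95, 0.37)`
   on the response scale — the mean and spread observed in the motivating
   sample;
5. discretization onto 1..5 at thresholds {1.5, 2.5, 3.5, 4.5}
   (equally spaced around the midpoint; a value exactly at a cut falls in
   the upper category);
6. 5% of respondents are overwritten with uniform random responses
   (insufficient-effort responding); missingness, when requested, is
   completely at random.

The additive-shift-then-threshold model is the package's stated
assumption — no response-process model is published for these data — and
it is chosen because it reproduces the bounded-scale asymmetries the
correction has to tolerate: an acquiescent respondent saturates the top
category, so the estimated index is a shrunken version of the latent
shift. The attenuation is visible in the defaults: with `a` at SD 0.37,
the computed index has SD ≈ 0.35, and the recovery correlation with truth
is ≈ 0.98 for attentive respondents. Tests bound these quantities
empirically rather than assuming them away.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: graded-response (IRT) measurement with
item-specific thresholds, non-normal or skewed trait distributions,
school- or class-level clustering, content-dependent missingness,
extreme-response style, and any developmental trend in acquiescence.
Conclusions about the *estimators* (recovery, correction gain, the
acquiescence-factor signature) transfer; population values of fit indices
do not.

## Numerical choices

* Correlation matrices that are indefinite beyond −1e−8 are
  ridge-repaired with a warning; numerical dust above that is fixed
  silently. Exactly singular matrices (the ipsatization dependency) get a
  minimal 1e−6 ridge before ML so the discrepancy stays finite; the
  perturbation to correlations is below 1e−6.
* The ML path uses `stats::factanal`; its default starting values
  occasionally fail on large matrices, so the package retries from
  squared-multiple-correlation starts and then from flat uniquenesses of
  0.5.
* Minres optimizes uniquenesses with L-BFGS-B bounded to [0.005, 1] from
  SMC-based starts; the closed-form equicorrelation case is recovered to
  1e−6 (pinned by test).
* Rotation ties (e.g., column permutations with equal criterion) are
  broken deterministically by the seeded start sequence; alignment ties
  cannot occur on real data and resolve to the first maximum in the
  exhaustive scan.
* `discretize` uses the half-open convention via `findInterval`, making
  the map monotone and exactly reproducible.
* Determinism: one seed drives the generator stream; the rotation's
  random starts take their own seed argument; reports hash their inputs
  (MD5 of a version-pinned serialization) so identical runs produce
  byte-identical file sets.

## Problem sizes in the test suite

The suite validates stochastic properties at sizes chosen to make the
quantities stable while keeping a full run around half a minute: index
recovery at n = 2000, structure recovery and the corrected-vs-raw
congruence gap at n = 5000 (20 replicate seeds for the gap), index
mean/SD calibration at n = 10000. The desk-scale reproduction of the
published congruence tables is exact-input and runs in milliseconds.

## Known limitations

* No standard errors or confidence intervals for loadings, factor
  correlations, or congruence coefficients; the package reports point
  structure.
* The ESEM-by-EFA substitution reproduces loading structure, not the
  commercial estimator's fit statistics; χ² and BIC are on different
  conventions than published values and are not targeted.
* Model-based acquiescence estimators (random-intercept item factor
  analysis) are out of scope; the mean-based index is exactly the
  published procedure.
* The congruence analysis assumes the indicator set matches the blueprint
  labels; bring-your-own indicator labels must parse as
  `<facet>_<suffix>`.
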