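# acqstruct

Acquiescence correction and five-factor structure recovery for balanced
Likert-type socio-emotional skill inventories.

## The problem

Self-report inventories administered to young or heterogeneous respondents
suffer from *acquiescence*: a content-blind tendency to agree (yea-saying)
or disagree (nay-saying) with items regardless of what they say. Because
the tendency varies across respondents, it inflates correlations between
items keyed in the same direction and suppresses correlations between items
of opposite poles, to the point where factor analyses of raw scores produce
spurious "method" factors and fail to recover real trait structure.

A balanced item design makes the bias estimable. The inventory analysed
here measures 18 socio-emotional facets nested under five broad domains
(Open-mindedness **O**, Self-management **C**, Engaging with others **E**,
Amity **A**, Negative-emotion regulation **N**), with nine items per facet:
three positively keyed identity items, three negatively keyed identity
items arranged as antonym pairs with the positive ones, and three
(always positively keyed) self-efficacy items — 162 items, of which 108
identity items form 54 antonym pairs.

For respondent $i$ with raw responses $x_{ij} \in \{1,\dots,5\}$, the
acquiescence index is the mean over the $J$ balanced identity items
*before* reversing anything:

$$\mathrm{ACQ}_i = \frac{1}{J}\sum_{j \in \text{identity}} x_{ij}, \qquad J = 108 .$$

A respondent answering every antonym pair symmetrically (1–5, 2–4, 3–3,
4–2, 5–1) gets exactly 3, the scale midpoint; yea-sayers get more,
nay-sayers less. The corrected score for **every** item — including the
self-efficacy items, which cannot carry their own balance — is
$x_{ij} - \mathrm{ACQ}_i$, and negatively keyed content is re-oriented
*after* centering by multiplying by the keying sign. (Reversing first and
centering afterwards doubles the bias in negative items instead of removing
it; the package tests demonstrate this failure mode.)

Items are then aggregated into 54 triplet cluster scales (facet ×
framing), and a five-factor exploratory model with oblique **target
rotation** is fitted to their correlation matrix: all loadings outside an
indicator's intended domain are rotated toward zero (gradient projection
on the rotation manifold), intended loadings stay free. Structure recovery
is quantified by **congruence coefficients** between each empirical factor
and an idealized one-hot target (1 on the intended domain's indicators, 0
elsewhere); Tucker's coefficient
$\phi(x,y)=\sum x y/\sqrt{\sum x^2 \sum y^2}$ is the default, with the
Pearson correlation over indicator rows as an option.

The package also ships a synthetic response generator (correlated domain
scores, facet hierarchy, balanced keying, additive latent acquiescence
shifts, threshold discretization, careless responders) so every estimator
can be validated against known truth, and the published 54 × 5 reference
loading matrices (raw and corrected, from an administration to 50,209
students) as a desk-scale worked example.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`results/` is created on the fly):

```sh
Rscript analysis/01_simulate.R            # 5000 x 162 responses + truth
Rscript analysis/02_acquiescence.R        # ACQ estimation and recovery
Rscript analysis/03_structure.R           # raw vs corrected factor models
Rscript analysis/04_published_congruence.R# published loadings -> congruence
```

Step 2 prints

```
acquiescence index: mean 2.962, sd 0.348 (generator: 2.95 / 0.37)
recovery of true levels: r = 0.946 (r = 0.980 excluding careless)
```

— the mean-over-identity-items index recovers the generating acquiescence
levels almost perfectly for attentive respondents (the remaining gap is
threshold-discretization noise plus the 5% careless responders). Step 3
prints

```
  corrected branch: congruence diag mean 0.978 (min 0.955)
  raw branch:       congruence diag mean 0.786 (min 0.490)
correction gain in diagonal-mean congruence: 0.192
```

— on raw scores the five-factor solution loses part of the structure to an
acquiescence factor (loading signs follow item pole), while the corrected
branch recovers all five domains. Step 4 reproduces the published
congruence tables from the packaged reference loadings:

```
corrected solution: diagonal mean 0.836, min 0.777
raw solution:       diagonal mean 0.616, min -0.065
```

matching the reported summaries (0.85 and 0.78 after rounding for the
corrected solution, 0.62 for the raw one, where the Amity factor is not
recovered at all).

In code, the same pipeline is three calls:

```r
library(acqstruct)
bp  <- build_default_blueprint()
sim <- simulate_responses(sim_config(n = 5000, seed = 1))
rep <- run_full_analysis(sim$responses, bp)
rep$corrected$congruence   # 5 x 5 congruence with the one-hot target
```

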