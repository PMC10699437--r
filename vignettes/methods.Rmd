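---
title: "Measuring regional healthcare-resource allocation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring regional healthcare-resource allocation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hralloc)
```

This vignette is the package's own account of the measurement chain it
implements — the models, their assumptions, the parameters that matter,
and the design decisions taken where the methodology literature leaves
the choice open.

## The measurement chain

The object of study is a tidy panel of provincial units observed yearly
on a set of per-capita resource indicators (hospitals, primary-care
institutions, physicians, nurses, beds, and so on). The chain has five
stages, each usable on its own.

### 1. AHP weights and the consistency test

Indicator weights come from pairwise-comparison judgment matrices on
Saaty's 1–9 scale. A matrix $X$ with entries $x_{ij}$ (how much more
important element $i$ is than $j$) must have unit diagonal and
reciprocal structure $x_{ij} x_{ji} = 1$. `derive_weights()` implements
the **sum-product method**: normalize each column to sum one, average
across rows, renormalize. The principal eigenvalue is estimated as
$$\lambda_{\max} = \frac{1}{n}\sum_i \frac{(Xw)_i}{w_i},$$
the mean of the componentwise Rayleigh ratios — the standard AHP
convention when weights come from the sum-product rather than an
eigen-solver. A true dominant-eigenpair route (`power_iteration`, to
1e-12) is provided as an independent cross-check; for matrices that pass
the consistency test the two agree in $\lambda_{\max}$ to about 1e-3
(property-tested over random near-consistent matrices).

Consistency is tested with $CI = (\lambda_{\max} - n)/(n - 1)$ and
$CR = CI/RI$, using Saaty's classical random-index table
(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49 for $n = 1..10$);
$CR < 0.1$ accepts. Two conventions deserve note:

* **Orders 1 and 2** are always consistent; since $RI = 0$ makes the
  ratio undefined, $CI$ and $CR$ are defined as 0 there.
* **Reciprocity tolerance.** Published judgment matrices are typically
  printed to 4 decimal places, so their reciprocal pairs multiply to 1
  only within about $3\times10^{-5}$. The validator therefore accepts
  relative deviations up to 1e-3 by default (configurable); demanding
  machine-exact reciprocity would reject essentially every transcribed
  matrix. The packaged secondary matrix fixture goes one step further:
  its printed lower-triangle entries (1.0526, 0.9524, 0.8333) are
  recognizably 4-d.p. roundings of the exact reciprocals of
  (0.95, 1.05, 1.2), and the fixture carries the exact-reciprocal form,
  which is the form that reproduces the published $\lambda_{\max}$ and
  $CI$ at their printed precision.

`build_weight_tree()` composes a secondary-level matrix (over indicator
groups) with one tertiary matrix per group; any $CR \ge 0.1$ is a hard
refusal naming the offending matrix — an inconsistent elicitation must
be revised by the analysts, not repaired by software. Global weights are
secondary × local; the group sums and the overall sum are exact by
construction. Only the secondary matrix of the reference system is
published; the packaged weight tree therefore back-computes the local
tertiary weights as global/secondary ratios and treats them as given.

### 2. Orientation-aware min-max scoring

Positive indicators map as $d = (x - x_{\min})/(x_{\max} - x_{\min})$,
negative ones as $d = (x_{\max} - x)/(x_{\max} - x_{\min})$, so larger
$d$ always means better provision. The composite score is
$Z = \sum_i w_i d_i \in [0, 1]$, and group sub-scores partition $Z$
exactly.

**Normalization scope** is the one genuinely open choice here. The
default is `pooled`: extrema taken over the whole panel, so a unit's
score is comparable across years and trend statements are meaningful.
Per-year extrema (`per_year`) are available but largely flatten temporal
trends, since every cross-section is rescaled to its own range; the
scope used is recorded in the result. Scoring requires a rectangular
panel and refuses constant indicators (zero denominator) by name rather
than producing NaN.

Regional summaries report both the mean of the region means ("the
average score of the four zones") and the plain 31-unit mean; the two
differ whenever region sizes differ, and published narratives do not
always say which is meant.

### 3. Theil decomposition

Inequality of the composite score uses the generalized-entropy family;
$c = 1$ (the Theil T index) is the default because it decomposes exactly:
$$T = \underbrace{\sum_g S_g T_g}_{TWR} +
      \underbrace{\sum_g S_g \ln\frac{S_g}{n_g/n}}_{TBR},$$
with $S_g$ group $g$'s share of the total score and $T_g$ its internal
Theil index. Unit weights are equal ($1/n$) by default — the
decomposition is over provincial units, not populations — with an
optional weight vector for extensions. The identity $T = TWR + TBR$ is
enforced to 1e-12 in tests, alongside scale invariance, replication
invariance, and the agreement of the share form
$\sum_i s_i \ln(n s_i)$ with the mean-ratio form.

Min-max scores can be exactly 0 for the pooled-minimum unit, where the
logarithm is undefined. The default is a hard error naming the year and
units; an explicit `epsilon_shift = TRUE` adds $10^{-6}\bar{y}$ to the
affected cross-section and reports it. A silent shift would be
untraceable in published tables.

Percent changes between the first and last year are computed from
full-precision values; tables are displayed at 4 d.p. The two can
disagree noticeably — changes recomputed from rounded components of a
printed table routinely miss the printed change figures, which is a
property of rounding, not of the decomposition.

### 4. Moran's I, inference conventions, LISA

Global Moran's I uses centered values; local Moran's I standardizes with
the $n$-divisor variance so that, under row-standardized weights,
$\sum_i I_i = n I$ (verified against a brute-force double-loop oracle).
The spatial weights matrix is **user input**: binary symmetric from a
GAL file or edge list, optionally row-standardized. The package does not
derive contiguity from geometry (out of scope), and analyses of the same
data under different weight constructions are not comparable — published
global statistics cannot be pinned without knowing the matrix used.

Inference conventions, fixed once and recorded in every result:

* Analytic variance under both **randomization** (kurtosis-corrected
  permutation moments, the default) and **normality** is always
  reported, since published tables often print a variance without naming
  the assumption.
* The **global permutation test** reassigns values over units; the
  directional count $(1 + \#\{I^{perm} \text{ at least as extreme}\}) /
  (n_{perm} + 1)$ is doubled (capped at 1) to a two-sided pseudo-p. The
  two-sided form is what holds the empirical type-I error at the nominal
  5% level (acceptance-tested at n = 25, 199 permutations, 1,000
  replicates).
* The **local test** holds unit $i$'s value fixed and permutes the rest
  onto its neighbor positions. The pseudo-p folds the two tail counts,
  with ties counted as extreme in both directions — on tiny graphs the
  conditional null support is discrete and heavily tied, and the naive
  strict-complement count would report spurious significance.
* Labels HH/HL/LH/LL follow the sign pattern of $(z_i, \text{lag}_i)$,
  gated at `alpha = 0.05`; insignificant units are NS. No
  multiple-testing correction is applied across units by default (the
  conventional LISA map is uncorrected); a Benjamini–Hochberg option
  exists behind `fdr = TRUE`.
* **Isolated units** (no neighbors) keep their place in the global
  statistic ($n$ and $S_0$ unchanged) but have undefined spatial lag, so
  their local label is `undefined` — never a silent zero.
* Seeds are mandatory whenever permutations are requested, and all
  seeded routines restore the caller's RNG state.

Small neighborhoods bound the attainable local significance: with $k$
neighbors drawn from $n - 1$ values, the probability that a permuted lag
matches an extreme observed configuration cannot fall below roughly
$\prod_{j<k}(m - j)/(n - 1 - j)$ for an $m$-unit high block, which for
$k \in \{3, 4\}$ on a 24-unit map sits near 0.06–0.12. A cluster can
therefore be visible in every sign pattern yet partly NS — expected
behavior of the statistic, not a power defect.

### 5. Quadrant classification

Units are classified against the unweighted cross-unit mean composite
score at two timepoints. Ties at a mean count as above-average (the
`>=` convention) and are flagged in the output; some closed convention
is needed for deterministic counts, and ties are measure-zero for
continuous scores anyway. Swapping the timepoints maps II ↔ IV and fixes
I and III, and the classification is invariant to per-year affine
rescaling — both property-tested.

## The synthetic generator

`generate_panel()` draws unit–year–indicator values as
$$x = \text{baseline} + s\,(\text{region effect} + \text{trend}\cdot t +
      u), \qquad u = (I - \rho W)^{-1}\varepsilon,$$
with $\varepsilon \sim N(0, \sigma^2)$ i.i.d., $W$ the row-standardized
adjacency, and $s = \pm 1$ the orientation sign (negative-orientation
indicators worsen as the latent level improves). The SAR form is the
minimal structure under which Moran/LISA power and null behavior can be
tested: $\rho = 0$ gives i.i.d. noise, and with all effects and noise at
zero every unit is identical — exactly the degenerate input the
downstream statistics must refuse. Values are floored to strict
positivity by a recorded affine shift so the entropy measures stay
defined.

Defaults mirror the provincial study design this package serves: 31
units in four zones of sizes 3/10/6/12, nine positive-orientation
indicators in three groups, twelve years from 2010, zone effects
(NE +0.05, E −0.10, C −0.03, W +0.08 on a unit baseline) reproducing the
west > northeast > central > east ordering of zone means, a +0.02/year
common trend, noise sd 0.1, and $\rho = 0.3$ — moderate positive spatial
autocorrelation of the kind national provincial panels show. Geometries
are deliberately schematic: ring, rook grid, or two grid blocks joined
by one bridge. The generator emulates the *statistical* structure the
analysis assumes — mean shifts, trends, spatial correlation,
orientation — not real provincial geography, real contiguity, or
yearbook indicator magnitudes; tests passing on synthetic panels
validate the machinery, not any empirical claim about real allocation.

## Numerical conventions and test scale

* Weight-sum identities at 1e-9 (validator) and 1e-12 (tests); Theil
  decomposition identity at 1e-12; exact $E(I) = -1/(n-1)$.
* Display rounding is 4 d.p. throughout; computation and CSV output are
  full precision. Pipeline outputs are byte-identical under a fixed seed
  (timings are logged to the console, not the manifest, to keep outputs
  reproducible).
* Judgment-matrix entries must lie on the 1/9..9 scale (tolerance 1e-6);
  the reciprocity tolerance is 1e-3 relative, as discussed above.
* Property tests run at deliberately small problem sizes — random graphs
  up to n = 15 against brute-force oracles, the permutation-size study
  at n = 25 with 199 permutations and 1,000 replicates, the power study
  at $\rho = 0.8$ on a 6×6 grid with 200 replicates — sizes chosen so
  the full suite stays fast while the binomial error of the estimated
  rates remains well inside the asserted bands.

## Known limitations

* The AHP stage implements the sum-product and power-iteration routes
  only; geometric-mean and fuzzy variants are out of scope, as is any
  aggregation of raw expert scores into judgment matrices (Delphi is a
  human procedure; matrices are inputs here).
* Spatial weights are consumed, never derived from geometry; no
  shapefile/GeoJSON support and no map rendering.
* Inequality measures beyond the GE family (Gini, concentration index)
  and bootstrap confidence intervals for Theil components are not
  provided.
* The epsilon-shift for zero scores is a pragmatic device; analysts who
  anticipate exact-zero composites should reconsider the indicator set
  or the normalization scope instead of relying on it.
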