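# hralloc

Measurement toolkit for studies of **regional healthcare-resource
allocation**: how evenly hospitals, health personnel and beds are
distributed across the provinces of a country, how that distribution
changes over time, and whether it clusters in space.

The package is written for health-services researchers and regional
scientists who work with provincial panel data (unit × year × indicator)
and want the full measurement chain of this literature as tested,
reusable functions rather than spreadsheet steps:

1. **AHP indicator weighting.** Pairwise-comparison judgment matrices on
   Saaty's 1–9 scale are turned into priority weights by the sum-product
   method, with the consistency test
   λmax → CI = (λmax − n)/(n − 1) → CR = CI/RI, accepting a matrix only
   when CR < 0.1. Secondary (group) and tertiary (indicator) weights
   combine into a global weight tree whose group sums and total are exact.
2. **Composite scoring.** Indicators are min-max normalized with
   orientation awareness — positive: d = (x − min)/(max − min); negative:
   d = (max − x)/(max − min) — and aggregated as Z = Σᵢ wᵢ dᵢ, which
   splits into per-group sub-scores (facilities / personnel / beds).
3. **Theil inequality decomposition.** The Theil index (generalized
   entropy at c = 1) of the composite score decomposes exactly per year
   into within-region and between-region parts,
   T = TWR + TBR, TWR = Σ_g S_g T_g, TBR = Σ_g S_g ln(S_g/(n_g/n)),
   with contribution rates in percent.
4. **Spatial autocorrelation.** Global Moran's
   I = (n/S₀) ΣᵢΣⱼ wᵢⱼ zᵢ zⱼ / Σᵢ zᵢ², with E(I) = −1/(n − 1), analytic
   variance under randomization or normality, and a seeded permutation
   test; local Moran's Iᵢ = zᵢ Σⱼ wᵢⱼ zⱼ with conditional permutation and
   LISA cluster typing (HH/HL/LH/LL, NS below the significance gate,
   undefined for isolated units).
5. **Quadrant dynamics.** Two-timepoint classification of every unit
   against the cross-unit mean scores (I above–above, II below–above,
   III below–below, IV above–below).

A synthetic panel generator (`synthetic_config()` / `generate_panel()`)
produces 31-unit, four-zone, nine-indicator, twelve-year panels with
tunable region effects, trends and spatial-autoregressive noise, so the
whole chain can be exercised and tested without external data. Packaged
fixtures provide the published 3×3 secondary judgment matrix, the
nine-indicator weight scheme and the four-zone partition of China's 31
provincial units.

## Worked example

```r
library(hralloc)

derive_weights(secondary_judgment_matrix())
#> ahp_result (sum_product): n = 3
#>     HF     HP     HB
#> 0.3324 0.3596 0.3080
#> lambda_max = 3.000752, CI = 0.000376, CR = 0.000648 -> consistent (CR < 0.1)
```

The three weights say the personnel dimension (HP, 0.3596) carries
slightly more importance than facilities (HF) and beds (HB); CR far
below 0.1 means the expert judgments are internally consistent.

The full pipeline on the packaged synthetic configuration:

```r
cfg <- system.file("extdata", "synthetic_config.yaml", package = "hralloc")
res <- run_pipeline(cfg, out_dir = "demo_out")

round(head(res$theil$table, 3), 4)
#>   year     NE      E      C      W    TWR    TBR      T
#> 1 2010 0.0000 0.0029 0.0029 0.0017 0.0075 0.0320 0.0395
#> 2 2011 0.0001 0.0029 0.0006 0.0009 0.0045 0.0304 0.0349
#> 3 2012 0.0011 0.0017 0.0004 0.0015 0.0047 0.0248 0.0295

round(head(res$moran[, c("year", "I", "z", "pseudo_p")], 3), 4)
#>   year      I      z pseudo_p
#> 1 2010 0.5683 4.2890     0.01
#> 2 2011 0.6953 5.1957     0.01
#> 3 2012 0.6725 5.0314     0.01

attr(res$quadrant, "counts")
#>   I  II III  IV
#>  15   0  12   4
```

Each Theil row shows total score inequality (T) split into the four
within-zone components plus the between-zone part (TWR + TBR = T
exactly). Moran's I near 0.6 with a permutation pseudo-p of 0.01 (the
floor at 199 permutations) reflects the positive spatial autocorrelation
planted in the generator (rho = 0.3 plus zone-level mean differences);
the quadrant counts say 15 units were above the national mean score at
both endpoints and 12 below at both. `demo_out/` holds every stage's CSV
(full precision, seed and config hash in the header) and a `manifest.json`
that suffices to re-run the analysis identically.

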