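# End-to-end demo configuration: a synthetic 31-unit, 9-indicator,
# 12-year panel with four zones, a mild trend and positive spatial
# autocorrelation, analyzed with the packaged reference weight scheme
# replaced by equal weights (the synthetic indicators are generic).
synthetic:
  n_units: 31
  n_indicators: 9
  n_years: 12
  rho: 0.3
  noise_sd: 0.1
seed: 20260922
permutations: 199
alpha: 0.05
scope: pooled
weights: equal
quadrant_years: [2010, 2021]
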