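name: Guelph, Ontario
# 2011 census inputs
latitude: 43.55
dwellings: 52620
area_ha: 7885
# Unowned densities adjusted to the local field estimates (cats/ha, both
# sexes); the continental defaults are exp(-0.752664) and exp(-2.536883).
freeroaming_density: 0.787
feral_density: 0.246
# The per-hectare survival forms best reproduce the published
# case-study abundances for this city.
density_dependence:
  variant: per_hectare
  juvenile_rule: sqrt_adult
  sterilization_preset: table
solver:
  max_iter: 1200
  tol: 1.0e-9
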