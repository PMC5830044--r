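name: Compact tropical city (synthetic)
# A hypothetical dense near-equatorial city used to demonstrate the
# non-convergence failure mode: nearly year-round breeding plus the
# composite published survival forms drive diverging oscillations.
latitude: 21.3
dwellings: 52620
area_ha: 2590
density_dependence:
  variant: composite
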