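name: Toy city
# A small synthetic town for smoke tests: no real-world counterpart.
latitude: 45
dwellings: 5000
area_ha: 800
shelter_capacity: 20
solver:
  max_iter: 1200
  tol: 1.0e-8
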