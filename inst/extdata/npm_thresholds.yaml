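# UK 2004/05 Nutrient Profile Model threshold tables.
# Points = number of thresholds the per-100 g amount STRICTLY exceeds.
a:
  energy_kj:  [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
  satfat_g:   [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  sugar_g:    [4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45]
  sodium_mg:  [90, 180, 270, 360, 450, 540, 630, 720, 810, 900]
c:
  # fruit/veg/nut fraction (percent); 3 and 4 points are unattainable
  fvn_pct:    [40, 60, 80]
  fvn_points: [1, 2, 5]
  fibre_nsp_g:  [0.7, 1.4, 2.1, 2.8, 3.5]
  fibre_aoac_g: [0.9, 1.9, 2.8, 3.7, 4.7]
  protein_g:    [1.6, 3.2, 4.8, 6.4, 8.0]
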