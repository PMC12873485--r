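# Independent brute-force oracle for the 2004/05 scoring model. The
# threshold tables are restated literally here, and points are found by
# scanning from the top bin down for the first strictly-exceeded
# threshold, independent of the package's lookup implementation.

oracle_tables <- list(
  energy = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350),
  satfat = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
  sugar  = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
  sodium = c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900),
  fibre_nsp  = c(0.7, 1.4, 2.1, 2.8, 3.5),
  fibre_aoac = c(0.9, 1.9, 2.8, 3.7, 4.7),
  protein = c(1.6, 3.2, 4.8, 6.4, 8.0)
)

oracle_scan <- function(amount, thresholds) {
  for (n in rev(seq_along(thresholds))) {
    if (amount > thresholds[n]) return(n)
  }
  0L
}

oracle_fvn <- function(pct) {
  if (pct > 80) 5L else if (pct > 60) 2L else if (pct > 40) 1L else 0L
}

# full model by brute force: A-sum minus credits, protein withheld when
# A >= 11 without maximum fruit/veg/nut credit
oracle_npm <- function(energy, satfat, sugar, sodium, fvn, fibre, protein,
                       fibre_basis = "AOAC") {
  a <- oracle_scan(energy, oracle_tables$energy) +
    oracle_scan(satfat, oracle_tables$satfat) +
    oracle_scan(sugar, oracle_tables$sugar) +
    oracle_scan(sodium, oracle_tables$sodium)
  cf <- oracle_fvn(fvn)
  cfi <- oracle_scan(fibre, if (toupper(fibre_basis) == "AOAC") {
    oracle_tables$fibre_aoac
  } else {
    oracle_tables$fibre_nsp
  })
  cp <- oracle_scan(protein, oracle_tables$protein)
  if (a >= 11 && cf < 5) cp <- 0L
  a - cf - cfi - cp
}

make_profile <- function(energy = 0, satfat = 0, sugar = 0, sodium = 0,
                         fvn = 0, fibre = 0, protein = 0,
                         fibre_basis = "AOAC", ...) {
  nutrient_profile(energy_kj = energy, satfat_g = satfat, sugar_g = sugar,
                   sodium_mg = sodium, fvn_pct = fvn, fibre_g = fibre,
                   protein_g = protein, fibre_basis = fibre_basis, ...)
}
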