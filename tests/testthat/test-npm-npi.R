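thr <- npm_thresholds()

test_that("A-point lookups honour strict inequality at every boundary", {
  expect_identical(a_points("energy", 0), 0L)
  expect_identical(a_points("energy", 335), 0L)
  expect_identical(a_points("energy", 335.1), 1L)
  expect_identical(a_points("sugar", 20), 4L)
  # every nutrient, every threshold, both sides
  for (nutrient in c("energy", "satfat", "sugar", "sodium")) {
    key <- switch(nutrient, energy = "energy_kj", satfat = "satfat_g",
                  sugar = "sugar_g", sodium = "sodium_mg")
    tab <- thr$a[[key]]
    for (amt in c(tab, tab - 1e-6, tab + 1e-6)) {
      expect_identical(a_points(nutrient, amt),
                       oracle_scan(amt, oracle_tables[[nutrient]]))
    }
  }
  expect_error(a_points("energy", -1), "non-negative")
  expect_error(a_points("transfat", 1), "unknown nutrient")
})

test_that("C-point lookups match the credit tables, both fibre bases", {
  expect_identical(c_points("fvn", 0), 0L)
  expect_identical(c_points("fvn", 50), 1L)
  expect_identical(c_points("protein", 8.1), 5L)
  for (pct in c(0, 39, 40, 41, 60, 61, 80, 81, 100)) {
    expect_identical(c_points("fvn", pct), oracle_fvn(pct))
  }
  # 3 and 4 fruit/veg/nut points are unattainable by construction
  expect_false(any(vapply(seq(0, 100, by = 0.5),
                          function(p) c_points("fvn", p) %in% c(3L, 4L),
                          logical(1))))
  for (basis in c("AOAC", "NSP")) {
    tab <- oracle_tables[[if (basis == "AOAC") "fibre_aoac" else "fibre_nsp"]]
    for (amt in c(tab - 0.01, tab, tab + 0.01)) {
      expect_identical(c_points("fibre", amt, fibre_basis = basis),
                       oracle_scan(amt, tab))
    }
  }
  expect_error(c_points("protein", -0.1), "non-negative")
})

test_that("compute_npm reproduces worked component breakdowns", {
  zero <- make_profile()
  s0 <- compute_npm(zero)
  expect_identical(s0$total, 0L)
  expect_false(s0$protein_capped)

  s <- compute_npm(make_profile(energy = 2000, satfat = 5, sugar = 20,
                                sodium = 300, fibre = 2,
                                fibre_basis = "NSP", protein = 10))
  expect_identical(c(s$a_energy, s$a_satfat, s$a_sugar, s$a_sodium),
                   c(5L, 4L, 4L, 3L))
  expect_true(s$protein_capped)
  expect_identical(s$c_fibre, 2L)
  expect_identical(s$total, 14L)

  top <- compute_npm(make_profile(energy = 3400, satfat = 11, sugar = 46,
                                  sodium = 1000, protein = 20))
  expect_identical(top$total, 40L)
  expect_true(top$protein_capped)
})

test_that("missing A-nutrients are unscorable; missing credits warn to 0", {
  p <- nutrient_profile(energy_kj = 100, satfat_g = 1, sugar_g = NA,
                        sodium_mg = 10, fvn_pct = 0, fibre_g = 0,
                        protein_g = 0)
  err <- tryCatch(compute_npm(p), condition = identity)
  expect_s3_class(err, "npiscore_unscorable")
  expect_match(conditionMessage(err), "sugar")

  q <- nutrient_profile(energy_kj = 100, satfat_g = 1, sugar_g = 1,
                        sodium_mg = 10, fvn_pct = 0, protein_g = 0)
  expect_warning(sq <- compute_npm(q), "fibre")
  expect_identical(sq$c_fibre, 0L)
})

test_that("protein cap engages exactly when A >= 11 without max fvn credit", {
  set.seed(42)
  for (i in 1:300) {
    p <- make_profile(
      energy = runif(1, 0, 3500), satfat = runif(1, 0, 12),
      sugar = runif(1, 0, 50), sodium = runif(1, 0, 1000),
      fvn = sample(c(0, 50, 70, 90), 1), fibre = runif(1, 0, 6),
      protein = runif(1, 0, 10)
    )
    s <- compute_npm(p)
    a_sum <- s$a_energy + s$a_satfat + s$a_sugar + s$a_sodium
    expect_identical(s$protein_capped, a_sum >= 11 && s$c_fvn < 5)
    applied <- if (s$protein_capped) 0L else s$c_protein
    expect_identical(s$total,
                     a_sum - s$c_fvn - s$c_fibre - applied)
    expect_true(s$total >= -15 && s$total <= 40)
  }
})

test_that("NPM total is monotone in penalties and credits", {
  set.seed(7)
  base <- list(energy = 800, satfat = 3, sugar = 12, sodium = 200,
               fvn = 0, fibre = 1, protein = 3)
  total_of <- function(args) do.call(make_profile, args) |>
    compute_npm() |> getElement("total")
  t0 <- total_of(base)
  for (field in c("energy", "satfat", "sugar", "sodium")) {
    for (bump in c(1, 5, 50)) {
      args <- base
      args[[field]] <- args[[field]] + bump *
        (if (field == "energy") 100 else 1)
      expect_gte(total_of(args), t0)
    }
  }
  for (field in c("fvn", "fibre")) {
    args <- base
    args[[field]] <- args[[field]] + (if (field == "fvn") 60 else 3)
    expect_lte(total_of(args), t0)
  }
})

test_that("NPM-to-NPI conversion is the stated linear map with clamping", {
  r3 <- npm_to_npi(3)
  expect_equal(r3$npi, 64)
  expect_true(r3$healthy)
  r0 <- npm_to_npi(0)
  expect_equal(r0$npi, 70)
  r40 <- npm_to_npi(40)
  expect_equal(r40$npi_raw, -10)
  expect_equal(r40$npi, 1)
  expect_false(r40$healthy)
  rmin <- npm_to_npi(-15)
  expect_equal(rmin$npi, 100)

  # bijection on the unclamped scale; healthy <=> NPM <= 3 <=> raw >= 64
  for (k in -15:40) {
    r <- npm_to_npi(k)
    expect_equal((70 - r$npi_raw) / 2, k)
    expect_identical(r$healthy, k <= 3)
    expect_identical(r$healthy, r$npi_raw >= 64)
  }
  expect_error(npm_to_npi(41), "\\[-15, 40\\]")
})

test_that("healthfulness labels split exactly at unclamped NPI 64", {
  expect_identical(as.character(classify_healthfulness(64)), "healthy")
  expect_identical(as.character(classify_healthfulness(63.9)), "unhealthy")
  expect_identical(as.character(classify_healthfulness(100)), "healthy")
  expect_identical(as.character(classify_healthfulness(npm_to_npi(4))),
                   "unhealthy")
})

test_that("per-serving amounts rescale to 100 g; kcal converts at 4.184", {
  p <- nutrient_profile(energy_kj = 200, satfat_g = 2, sugar_g = 10,
                        sodium_mg = 50, fibre_g = 1, protein_g = 5,
                        fvn_pct = 30, serving_weight_g = 50)
  n <- normalize_to_100g(p)
  expect_equal(n$sugar_g, 20)
  expect_equal(n$energy_kj, 400)
  expect_equal(n$fvn_pct, 30)  # a fraction of the food: never rescaled

  kcal <- nutrient_profile(energy_kcal = 100, satfat_g = 0, sugar_g = 0,
                           sodium_mg = 0, serving_weight_g = 100)
  expect_equal(normalize_to_100g(kcal)$energy_kj, 418.4)

  # identity when already per 100 g
  p100 <- nutrient_profile(energy_kj = 337, satfat_g = 1.5, sugar_g = 9.1,
                           sodium_mg = 91, fibre_g = 2, protein_g = 3,
                           fvn_pct = 10, serving_weight_g = 100)
  n100 <- normalize_to_100g(p100)
  for (f in c("energy_kj", "satfat_g", "sugar_g", "sodium_mg", "fibre_g",
              "protein_g")) {
    expect_equal(n100[[f]], p100[[f]])
  }

  zeros <- nutrient_profile(energy_kj = 0, satfat_g = 0, sugar_g = 0,
                            sodium_mg = 0, serving_weight_g = 30)
  expect_equal(normalize_to_100g(zeros)$energy_kj, 0)

  expect_error(normalize_to_100g(p, serving_weight_g = 0), "positive")
  err <- tryCatch(normalize_to_100g(p, serving_weight_g = NA),
                  condition = identity)
  expect_s3_class(err, "npiscore_unscorable")
})

test_that("salt converts to sodium at 400 mg/g when sodium is absent", {
  p <- nutrient_profile(energy_kj = 0, satfat_g = 0, sugar_g = 0,
                        salt_g = 1.5)
  expect_equal(p$sodium_mg, 600)
})

test_that("first-five-ingredients rule assigns 50% fvn, never overwrites", {
  jam <- nutrient_profile(energy_kj = 500, satfat_g = 0, sugar_g = 30,
                          sodium_mg = 10,
                          ingredients = c("strawberries", "sugar", "pectin"))
  expect_equal(apply_fvn_ingredient_rule(jam)$fvn_pct, 50)

  biscuit <- nutrient_profile(
    energy_kj = 2000, satfat_g = 8, sugar_g = 25, sodium_mg = 300,
    ingredients = c("wheat flour", "sugar", "palm oil", "cocoa", "salt"))
  expect_equal(apply_fvn_ingredient_rule(biscuit)$fvn_pct, 0)

  # a match beyond the first five ingredients does not count
  late <- nutrient_profile(
    energy_kj = 100, satfat_g = 0, sugar_g = 0, sodium_mg = 0,
    ingredients = c("water", "wheat flour", "sugar", "salt", "yeast",
                    "almonds"))
  expect_equal(apply_fvn_ingredient_rule(late)$fvn_pct, 0)

  set_already <- nutrient_profile(energy_kj = 100, satfat_g = 0,
                                  sugar_g = 0, sodium_mg = 0, fvn_pct = 85,
                                  ingredients = "sugar")
  expect_equal(apply_fvn_ingredient_rule(set_already)$fvn_pct, 85)

  empty <- nutrient_profile(energy_kj = 100, satfat_g = 0, sugar_g = 0,
                            sodium_mg = 0)
  expect_warning(out <- apply_fvn_ingredient_rule(empty), "no ingredient")
  expect_equal(out$fvn_pct, 0)
})

test_that("profile construction rejects invalid amounts", {
  expect_error(nutrient_profile(energy_kj = 100, sugar_g = -1), "negative")
  expect_error(nutrient_profile(fvn_pct = 101), "\\[0, 100\\]")
  expect_error(nutrient_profile(serving_weight_g = 0), "positive")
})

test_that("threshold tables load from YAML identically to the defaults", {
  yaml_path <- system.file("extdata", "npm_thresholds.yaml",
                           package = "npiscore")
  expect_identical(npm_thresholds(yaml_path)$a, npm_thresholds()$a)
  expect_equal(npm_thresholds(yaml_path)$c$fibre_aoac_g,
               npm_thresholds()$c$fibre_aoac_g)
})
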