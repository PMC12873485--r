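#' Construct a per-100 g nutrient profile
#'
#' Bundles the nutrition facts the Nutrient Profile Model needs, expressed
#' per 100 g of food. Energy may be given in kJ or kcal (converted at
#' 4.184 kJ/kcal); sodium may be given directly in mg or derived from salt
#' at 400 mg sodium per g salt. Unknown values are `NA`: the four "A"
#' nutrients (energy, saturated fat, sugar, sodium) are mandatory for
#' scoring, while missing "C" components (fruit/veg/nut fraction, fibre,
#' protein) are treated as zero with a warning by [compute_npm()].
#'
#' @param energy_kj Energy per 100 g in kJ.
#' @param satfat_g Saturated fat per 100 g in g.
#' @param sugar_g Total sugar per 100 g in g.
#' @param sodium_mg Sodium per 100 g in mg.
#' @param fibre_g Dietary fibre per 100 g in g.
#' @param fibre_basis Fibre assay basis, `"AOAC"` (US labels) or `"NSP"`.
#' @param protein_g Protein per 100 g in g.
#' @param fvn_pct Fruit/vegetable/nut fraction of the food, percent (0-100).
#' @param serving_weight_g Serving size in g, if known.
#' @param ingredients Character vector of ingredient names in label order.
#' @param energy_kcal Energy per 100 g in kcal; used when `energy_kj` is
#'   missing.
#' @param salt_g Salt per 100 g in g; used when `sodium_mg` is missing.
#' @return An object of class `nutrient_profile`.
#' @export
#' @examples
#' nutrient_profile(energy_kj = 2000, satfat_g = 5, sugar_g = 20,
#'                  sodium_mg = 300, fibre_g = 2, fibre_basis = "NSP",
#'                  protein_g = 10, fvn_pct = 0)
nutrient_profile <- function(energy_kj = NA_real_, satfat_g = NA_real_,
                             sugar_g = NA_real_, sodium_mg = NA_real_,
                             fibre_g = NA_real_, fibre_basis = "AOAC",
                             protein_g = NA_real_, fvn_pct = NA_real_,
                             serving_weight_g = NA_real_, ingredients = NULL,
                             energy_kcal = NA_real_, salt_g = NA_real_) {
  if (is.na(energy_kj) && !is.na(energy_kcal)) {
    energy_kj <- energy_kcal * 4.184
  }
  if (is.na(sodium_mg) && !is.na(salt_g)) {
    sodium_mg <- salt_g * 400
  }
  fibre_basis <- match.arg(toupper(fibre_basis), c("AOAC", "NSP"))
  amounts <- c(energy_kj = energy_kj, satfat_g = satfat_g, sugar_g = sugar_g,
               sodium_mg = sodium_mg, fibre_g = fibre_g,
               protein_g = protein_g)
  bad <- names(amounts)[!is.na(amounts) & amounts < 0]
  if (length(bad)) {
    stop("nutrient_profile: negative amount(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.na(fvn_pct) && (fvn_pct < 0 || fvn_pct > 100)) {
    stop("nutrient_profile: fvn_pct must lie in [0, 100]", call. = FALSE)
  }
  if (!is.na(serving_weight_g) && serving_weight_g <= 0) {
    stop("nutrient_profile: serving_weight_g must be positive",
         call. = FALSE)
  }
  structure(
    list(energy_kj = as.numeric(energy_kj), satfat_g = as.numeric(satfat_g),
         sugar_g = as.numeric(sugar_g), sodium_mg = as.numeric(sodium_mg),
         fibre_g = as.numeric(fibre_g), fibre_basis = fibre_basis,
         protein_g = as.numeric(protein_g), fvn_pct = as.numeric(fvn_pct),
         serving_weight_g = as.numeric(serving_weight_g),
         ingredients = ingredients),
    class = "nutrient_profile"
  )
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat("<nutrient_profile> per 100 g\n")
  cat(sprintf("  energy %s kJ | satfat %s g | sugar %s g | sodium %s mg\n",
              format(x$energy_kj), format(x$satfat_g), format(x$sugar_g),
              format(x$sodium_mg)))
  cat(sprintf("  fibre %s g (%s) | protein %s g | fvn %s%%\n",
              format(x$fibre_g), x$fibre_basis, format(x$protein_g),
              format(x$fvn_pct)))
  if (!is.na(x$serving_weight_g)) {
    cat(sprintf("  serving weight %s g\n", format(x$serving_weight_g)))
  }
  if (!is.null(x$ingredients)) {
    cat("  ingredients:", paste(utils::head(x$ingredients, 5),
                                collapse = "; "),
        if (length(x$ingredients) > 5) "..." else "", "\n")
  }
  invisible(x)
}

# strict-inequality table lookup: points = #(thresholds strictly exceeded)
points_from_table <- function(amount, thresholds) {
  vapply(amount, function(a) sum(a > thresholds), integer(1))
}

#' A-component (penalty) points
#'
#' Scores one of the four penalty nutrients against its threshold table:
#' the points are the number of thresholds the per-100 g amount strictly
#' exceeds (0--10).
#'
#' @param nutrient One of `"energy"`, `"satfat"`, `"sugar"`, `"sodium"`.
#' @param amount Amount per 100 g, in the nutrient's unit (kJ, g, g, mg
#'   respectively). Vectorised.
#' @param thresholds Threshold tables from [npm_thresholds()].
#' @return Integer points, 0--10, same length as `amount`.
#' @export
#' @examples
#' a_points("sugar", 20)    # 4: exceeds 18 but not 22.5
#' a_points("energy", 335)  # 0: strict inequality at the boundary
a_points <- function(nutrient, amount, thresholds = npm_thresholds()) {
  key <- switch(nutrient,
                energy = "energy_kj", satfat = "satfat_g",
                sugar = "sugar_g", sodium = "sodium_mg",
                stop("a_points: unknown nutrient '", nutrient, "'",
                     call. = FALSE))
  if (any(is.na(amount))) {
    stop("a_points: amount must not be NA", call. = FALSE)
  }
  if (any(amount < 0)) {
    stop("a_points: amount must be non-negative", call. = FALSE)
  }
  points_from_table(amount, thresholds$a[[key]])
}

#' C-component (credit) points
#'
#' Scores one of the three credit components. Fruit/veg/nut uses the 3-bin
#' table (>40\% = 1, >60\% = 2, >80\% = 5); fibre and protein use their
#' 5-bin tables with strict inequalities. Fibre thresholds depend on the
#' assay basis (`"AOAC"` as on US labels, or `"NSP"`).
#'
#' @param component One of `"fvn"`, `"fibre"`, `"protein"`.
#' @param amount Percent for fvn, g per 100 g otherwise. Vectorised.
#' @param fibre_basis `"AOAC"` or `"NSP"`; only consulted for fibre.
#' @param thresholds Threshold tables from [npm_thresholds()].
#' @return Integer points, 0--5, same length as `amount`.
#' @export
#' @examples
#' c_points("fvn", 50)       # 1
#' c_points("protein", 8.1)  # 5
c_points <- function(component, amount, fibre_basis = "AOAC",
                     thresholds = npm_thresholds()) {
  if (any(is.na(amount))) {
    stop("c_points: amount must not be NA", call. = FALSE)
  }
  if (any(amount < 0)) {
    stop("c_points: amount must be non-negative", call. = FALSE)
  }
  switch(component,
    fvn = {
      idx <- points_from_table(amount, thresholds$c$fvn_pct)
      c(0L, thresholds$c$fvn_points)[idx + 1L]
    },
    fibre = {
      basis <- match.arg(toupper(fibre_basis), c("AOAC", "NSP"))
      tab <- if (basis == "AOAC") thresholds$c$fibre_aoac_g
             else thresholds$c$fibre_nsp_g
      points_from_table(amount, tab)
    },
    protein = points_from_table(amount, thresholds$c$protein_g),
    stop("c_points: unknown component '", component, "'", call. = FALSE)
  )
}

#' Compute the NPM score of a nutrient profile
#'
#' Applies the full 2004/05 model: the four A-component points are summed;
#' C-points for fruit/veg/nut, fibre and protein are subtracted, except
#' that protein points are withheld (the "protein cap") when the A-sum
#' reaches 11 or more and the food does not earn the maximum 5 fruit/veg/nut
#' points. Missing A-nutrients make the profile unscorable; missing
#' C-components count as zero with a warning, since credits can only lower
#' the score.
#'
#' @param profile A [nutrient_profile()].
#' @param thresholds Threshold tables from [npm_thresholds()].
#' @return An object of class `npm_score`: integer component points
#'   (`a_energy`, `a_satfat`, `a_sugar`, `a_sodium`, `c_fvn`, `c_fibre`,
#'   `c_protein`), logical `protein_capped`, and integer `total` in
#'   [-15, 40].
#' @export
#' @examples
#' p <- nutrient_profile(energy_kj = 2000, satfat_g = 5, sugar_g = 20,
#'                       sodium_mg = 300, fibre_g = 2, fibre_basis = "NSP",
#'                       protein_g = 10, fvn_pct = 0)
#' compute_npm(p)$total  # 14
compute_npm <- function(profile, thresholds = npm_thresholds()) {
  stopifnot(inherits(profile, "nutrient_profile"))
  a_fields <- c(energy = "energy_kj", satfat = "satfat_g", sugar = "sugar_g",
                sodium = "sodium_mg")
  missing_a <- a_fields[vapply(a_fields,
                               function(f) is.na(profile[[f]]), logical(1))]
  if (length(missing_a)) {
    stop(unscorable_error(paste0(
      "missing A-nutrient(s): ", paste(missing_a, collapse = ", "))))
  }
  a <- c(
    energy = a_points("energy", profile$energy_kj, thresholds),
    satfat = a_points("satfat", profile$satfat_g, thresholds),
    sugar  = a_points("sugar",  profile$sugar_g,  thresholds),
    sodium = a_points("sodium", profile$sodium_mg, thresholds)
  )
  c_amount <- function(field, component) {
    x <- profile[[field]]
    if (is.na(x)) {
      warning("compute_npm: missing ", component, "; scored as 0 points",
              call. = FALSE)
      0
    } else {
      x
    }
  }
  c_fvn <- c_points("fvn", c_amount("fvn_pct", "fruit/veg/nut fraction"),
                    thresholds = thresholds)
  c_fibre <- c_points("fibre", c_amount("fibre_g", "fibre"),
                      fibre_basis = profile$fibre_basis,
                      thresholds = thresholds)
  c_protein <- c_points("protein", c_amount("protein_g", "protein"),
                        thresholds = thresholds)
  a_sum <- sum(a)
  capped <- a_sum >= 11 && c_fvn < max(thresholds$c$fvn_points)
  total <- a_sum - c_fvn - c_fibre - (if (capped) 0L else c_protein)
  structure(
    list(a_energy = a[["energy"]], a_satfat = a[["satfat"]],
         a_sugar = a[["sugar"]], a_sodium = a[["sodium"]],
         c_fvn = c_fvn, c_fibre = c_fibre, c_protein = c_protein,
         protein_capped = capped, total = as.integer(total)),
    class = "npm_score"
  )
}

#' @export
print.npm_score <- function(x, ...) {
  cat("<npm_score> total", x$total, "\n")
  cat(sprintf("  A: energy %d + satfat %d + sugar %d + sodium %d = %d\n",
              x$a_energy, x$a_satfat, x$a_sugar, x$a_sodium,
              x$a_energy + x$a_satfat + x$a_sugar + x$a_sodium))
  cat(sprintf("  C: fvn %d, fibre %d, protein %d%s\n",
              x$c_fvn, x$c_fibre, x$c_protein,
              if (x$protein_capped) " (protein capped)" else ""))
  invisible(x)
}

#' Convert an NPM score to the Nutrient Profile Index
#'
#' The NPI is a linear rescaling of the NPM score, `-2 * NPM + 70`, onto a
#' nominal 1 (least healthy) to 100 (most healthy) scale. A food is
#' classified healthy when the unclamped index reaches 64, which is exactly
#' the NPM <= 3 cut-off used to regulate food advertising to children in
#' the UK.
#'
#' @param npm_total Integer NPM total(s) in [-15, 40], or an `npm_score`.
#' @param clamp Clamp the reported index to [1, 100] (default). The raw
#'   value is always retained for the healthy test.
#' @return An object of class `npi_result` with numeric vectors `npi`
#'   (clamped), `npi_raw`, and logical `healthy`.
#' @export
#' @examples
#' npm_to_npi(3)   # npi 64, healthy
#' npm_to_npi(40)  # npi_raw -10, clamped to 1, unhealthy
npm_to_npi <- function(npm_total, clamp = TRUE) {
  if (inherits(npm_total, "npm_score")) npm_total <- npm_total$total
  if (any(is.na(npm_total)) ||
      any(npm_total < -15) || any(npm_total > 40)) {
    stop("npm_to_npi: npm_total must lie in [-15, 40]", call. = FALSE)
  }
  raw <- -2 * npm_total + 70
  npi <- if (clamp) pmin(pmax(raw, 1), 100) else raw
  structure(list(npi = npi, npi_raw = raw, healthy = raw >= 64),
            class = "npi_result")
}

#' @export
print.npi_result <- function(x, ...) {
  cat("<npi_result>\n")
  print(tibble::tibble(npi = round(x$npi, 2), npi_raw = x$npi_raw,
                       healthy = x$healthy))
  invisible(x)
}

#' Healthfulness label from an NPI result
#'
#' @param result An `npi_result` from [npm_to_npi()], or a numeric vector of
#'   unclamped NPI values.
#' @return Factor with levels `healthy`, `unhealthy`; healthy iff the
#'   unclamped NPI is at least 64.
#' @export
#' @examples
#' classify_healthfulness(npm_to_npi(3))  # healthy
classify_healthfulness <- function(result) {
  raw <- if (inherits(result, "npi_result")) result$npi_raw
         else as.numeric(result)
  factor(ifelse(raw >= 64, "healthy", "unhealthy"),
         levels = c("healthy", "unhealthy"))
}

#' Rescale a per-serving profile to per 100 g
#'
#' The NPM scores amounts per 100 g; label data are often per serving. Each
#' nutrient amount is multiplied by `100 / serving_weight_g`. The
#' fruit/veg/nut fraction is a percentage of the food and is left unchanged,
#' as is the fibre basis. Energy given in kcal should be converted before or
#' at profile construction (4.184 kJ/kcal, see [nutrient_profile()]).
#'
#' @param profile A [nutrient_profile()] whose amounts are per serving.
#' @param serving_weight_g Serving size in g; defaults to the profile's own.
#' @return A `nutrient_profile` per 100 g, with `serving_weight_g` retained.
#' @export
#' @examples
#' p <- nutrient_profile(energy_kj = 418.4, satfat_g = 1, sugar_g = 10,
#'                       sodium_mg = 50, serving_weight_g = 50)
#' normalize_to_100g(p)$sugar_g  # 20
normalize_to_100g <- function(profile,
                              serving_weight_g = profile$serving_weight_g) {
  stopifnot(inherits(profile, "nutrient_profile"))
  if (is.na(serving_weight_g)) {
    stop(unscorable_error("missing serving weight"))
  }
  if (serving_weight_g <= 0) {
    stop("normalize_to_100g: serving_weight_g must be positive",
         call. = FALSE)
  }
  f <- 100 / serving_weight_g
  out <- profile
  for (field in c("energy_kj", "satfat_g", "sugar_g", "sodium_mg",
                  "fibre_g", "protein_g")) {
    out[[field]] <- profile[[field]] * f
  }
  out
}

#' Apply the first-five-ingredients fruit/veg/nut assumption
#'
#' When the fruit/vegetable/nut fraction of a food is unknown, it is assumed
#' to be at least 50\% if a fruit, vegetable or nut appears among the first
#' five ingredients on the label. The rule assigns exactly 50\% (the stated
#' lower bound, worth 1 C-point); otherwise 0\%. An explicitly supplied
#' `fvn_pct` is never overwritten.
#'
#' @param profile A [nutrient_profile()].
#' @param lexicon Character vector of fruit/veg/nut terms, see
#'   [fvn_lexicon()].
#' @return The profile with `fvn_pct` filled in.
#' @export
#' @examples
#' p <- nutrient_profile(energy_kj = 500, satfat_g = 0, sugar_g = 30,
#'                       sodium_mg = 10,
#'                       ingredients = c("strawberries", "sugar", "pectin"))
#' apply_fvn_ingredient_rule(p)$fvn_pct  # 50
apply_fvn_ingredient_rule <- function(profile, lexicon = fvn_lexicon()) {
  stopifnot(inherits(profile, "nutrient_profile"))
  if (!is.na(profile$fvn_pct)) {
    return(profile)
  }
  out <- profile
  if (is.null(profile$ingredients) || !length(profile$ingredients)) {
    warning("apply_fvn_ingredient_rule: no ingredient list; ",
            "fruit/veg/nut fraction set to 0", call. = FALSE)
    out$fvn_pct <- 0
    return(out)
  }
  first5 <- tolower(utils::head(profile$ingredients, 5))
  hit <- any(vapply(first5, ingredient_matches_lexicon, logical(1),
                    lexicon = lexicon))
  out$fvn_pct <- if (hit) 50 else 0
  out
}

# whole-word match with simple plural handling: term "strawberry" matches
# "strawberries", "almond" matches "almonds"
ingredient_matches_lexicon <- function(ingredient, lexicon) {
  patterns <- vapply(lexicon, function(t) {
    stem <- if (grepl("y$", t)) paste0(sub("y$", "", t), "(y|ies)")
            else paste0(t, "(s|es)?")
    paste0("\\b", stem, "\\b")
  }, character(1))
  any(vapply(patterns, function(p) grepl(p, ingredient), logical(1)))
}

# classed condition for items that cannot be scored (missing A-nutrients,
# missing serving weight, ...); the pipeline converts it to omission_reason
unscorable_error <- function(reason) {
  structure(
    class = c("npiscore_unscorable", "error", "condition"),
    list(message = paste0("unscorable: ", reason), call = NULL,
         reason = reason)
  )
}

#' @export
format.npiscore_unscorable <- function(x, ...) x$message
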