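#' Product category taxonomy
#'
#' The taxonomy assigns every featured product a category appropriate to
#' its type. Food categories combine food groups with processed/packaged
#' categories (breakfast cereals, packaged snacks, condiments and cooking
#' staples), prepared-food categories (mixed dishes, desserts), a dedicated
#' restaurant category, fruits and vegetables, protein, and a residual
#' bucket. Beverage categories follow a children's-drinks style taxonomy
#' extended with alcoholic beverages and plain water, with sweetened and
#' unsweetened coffee/tea combined into one category.
#'
#' @param file Optional YAML file overriding the shipped taxonomy (a copy
#'   lives at `system.file("extdata", "taxonomy.yaml", package =
#'   "npiscore")`). Top-level keys `food`, `beverage`, `supplement`, each a
#'   list of unique labels.
#' @return A named list of character vectors, class `category_taxonomy`.
#' @export
default_taxonomy <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "taxonomy.yaml", package = "npiscore")
  }
  tax <- yaml::read_yaml(file)
  tax <- lapply(tax, function(x) as.character(unlist(x)))
  if (!all(c("food", "beverage") %in% names(tax)) ||
      !length(tax$food) || !length(tax$beverage)) {
    stop("taxonomy: 'food' and 'beverage' label sets are required",
         call. = FALSE)
  }
  if (anyDuplicated(unlist(tax))) {
    stop("taxonomy: category labels must be unique", call. = FALSE)
  }
  if (is.null(tax$supplement)) tax$supplement <- "supplement"
  structure(tax, class = "category_taxonomy")
}

#' Keyword rules for categorisation
#'
#' @param file Optional YAML rules file (default ships at
#'   `system.file("extdata", "category_rules.yaml", package = "npiscore")`):
#'   per product type, an ordered list of `category` + `keywords` entries.
#' @return Nested list of ordered rules per product type.
#' @export
category_rules <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "category_rules.yaml",
                        package = "npiscore")
  }
  yaml::read_yaml(file)
}

#' Validate a product-records table
#'
#' Checks the schema of a products table before it enters the pipeline:
#' required columns, non-missing identifiers, known product types, logical
#' flags, and the one-product-per-video rule (the analysis keeps only the
#' most prominent product per video, so a duplicated `video_id` is a data
#' error, not something to deduplicate silently).
#'
#' @param products Data frame with columns `product_id`, `video_id`,
#'   `name`, `product_type` (`food`/`beverage`/`supplement`), `branded`
#'   (logical), `restaurant` (logical); optional `category`.
#' @return The validated tibble, invisibly classed for downstream use.
#' @export
validate_products <- function(products) {
  products <- tibble::as_tibble(products)
  required <- c("product_id", "video_id", "name", "product_type",
                "branded", "restaurant")
  missing_cols <- setdiff(required, names(products))
  if (length(missing_cols)) {
    stop("products: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail_rows <- function(ok, what) {
    if (!all(ok)) {
      stop("products: ", what, " in row(s) ",
           paste(utils::head(which(!ok), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  fail_rows(!is.na(products$product_id) & products$product_id != "",
            "missing product_id")
  fail_rows(!is.na(products$video_id) & products$video_id != "",
            "missing video_id")
  fail_rows(products$product_type %in% c("food", "beverage", "supplement"),
            "unknown product_type")
  fail_rows(!is.na(as.logical(products$branded)), "non-logical branded flag")
  fail_rows(!is.na(as.logical(products$restaurant)),
            "non-logical restaurant flag")
  dup <- duplicated(products$video_id)
  if (any(dup)) {
    stop("products: more than one product for video_id(s) ",
         paste(utils::head(unique(products$video_id[dup]), 10),
               collapse = ", "),
         " (one product per video)", call. = FALSE)
  }
  products$branded <- as.logical(products$branded)
  products$restaurant <- as.logical(products$restaurant)
  products
}

#' Categorise products into the taxonomy
#'
#' Deterministic, ordered rule matching. Restaurant-flagged foods always
#' map to the restaurant category before any keyword rule fires. An
#' explicit `category` already present and valid for the product's type is
#' kept. Products no rule matches fall into the type's "other" bucket with
#' a warning.
#'
#' @param products Validated products tibble (see [validate_products()]).
#' @param taxonomy A [default_taxonomy()].
#' @param rules Keyword rules, see [category_rules()].
#' @return The tibble with a `category` column; every row has one.
#' @export
categorize_products <- function(products, taxonomy = default_taxonomy(),
                                rules = category_rules()) {
  if (!length(unlist(taxonomy))) {
    stop("categorize_products: empty taxonomy", call. = FALSE)
  }
  restaurant_cat <- grep("restaurant", taxonomy$food, value = TRUE)[1]
  other_of <- function(type) {
    labels <- taxonomy[[type]]
    hit <- grep("^other", labels, value = TRUE)
    if (length(hit)) hit[1] else labels[length(labels)]
  }
  assign_one <- function(name, type, restaurant, explicit) {
    if (!is.na(explicit) && explicit %in% taxonomy[[type]]) {
      return(explicit)
    }
    if (type == "supplement") {
      return(taxonomy$supplement[1])
    }
    if (type == "food" && isTRUE(restaurant) && !is.na(restaurant_cat)) {
      return(restaurant_cat)
    }
    name_l <- tolower(name)
    for (rule in rules[[type]]) {
      if (any(vapply(tolower(rule$keywords),
                     function(k) grepl(k, name_l, fixed = TRUE),
                     logical(1)))) {
        return(rule$category)
      }
    }
    warning("categorize_products: no rule matched '", name,
            "' (", type, "); assigned '", other_of(type), "'",
            call. = FALSE)
    other_of(type)
  }
  explicit <- if ("category" %in% names(products)) products$category
              else rep(NA_character_, nrow(products))
  products$category <- purrr::pmap_chr(
    list(products$name, products$product_type, products$restaurant,
         explicit),
    assign_one
  )
  products
}

#' Resolve each food's nutrition-data pathway
#'
#' Mirrors the data-resolution hierarchy of the analysis: branded/packaged
#' foods are looked up in the branded-label table (official label data);
#' restaurant foods are looked up in the pre-extracted restaurant report
#' (NPI values), falling back to averaging the brand's top five items; any
#' remaining food is looked up in the generic reference table (typical
#' recipes); foods found nowhere are omitted from the NPI analysis with an
#' explicit reason. Beverages and supplements are never scored and resolve
#' to source `none` without an omission reason.
#'
#' @param products Categorised products tibble.
#' @param tables Named list of lookup tables: `branded_label` and
#'   `generic_reference` in the nutrition CSV dialect (see
#'   [read_nutrition_table()]; multiple rows per `product_id` are allowed
#'   for top-five items), and `restaurant_report` with columns
#'   `product_id`, `npi`.
#' @return The tibble with a `nutrition_source` column (one of
#'   `branded_label`, `restaurant_report`, `restaurant_top5`,
#'   `generic_reference`, `none`) and an `omission_reason` column set for
#'   unresolvable foods.
#' @export
resolve_nutrition_source <- function(products, tables) {
  for (nm in c("branded_label", "restaurant_report", "generic_reference")) {
    if (is.null(tables[[nm]])) {
      tables[[nm]] <- tibble::tibble(product_id = character(0))
    }
    if (!"product_id" %in% names(tables[[nm]])) {
      stop("resolve_nutrition_source: table '", nm,
           "' lacks a product_id column", call. = FALSE)
    }
  }
  branded_ids <- unique(tables$branded_label$product_id)
  report_ids  <- unique(tables$restaurant_report$product_id)
  generic_ids <- unique(tables$generic_reference$product_id)

  resolve_one <- function(product_id, product_type, branded, restaurant) {
    if (product_type != "food") return("none")
    if (restaurant) {
      if (product_id %in% report_ids) return("restaurant_report")
      if (product_id %in% branded_ids) return("restaurant_top5")
    }
    if (branded && product_id %in% branded_ids) return("branded_label")
    if (product_id %in% generic_ids) return("generic_reference")
    if (product_id %in% branded_ids) return("branded_label")
    "none"
  }
  products$nutrition_source <- purrr::pmap_chr(
    list(products$product_id, products$product_type, products$branded,
         products$restaurant),
    resolve_one
  )
  products$omission_reason <- ifelse(
    products$product_type == "food" & products$nutrition_source == "none",
    "no nutrition information", NA_character_
  )
  products
}

#' Average NPI over a restaurant's top five items
#'
#' When a restaurant food has no pre-extracted index, the top five items
#' from the brand's menu are scored individually and their NPI values
#' averaged; the healthfulness verdict is taken from the mean against the
#' 64-point cut-off. Fewer than five items are averaged with a warning;
#' zero scorable items is an error.
#'
#' @param items A list of [nutrient_profile()]s, or a numeric vector of
#'   already-computed NPI values.
#' @param thresholds Threshold tables, used when profiles are supplied.
#' @return An `npi_result` of length 1 (the aggregate).
#' @export
#' @examples
#' restaurant_top5_score(c(40, 50, 60, 70, 80))  # npi 60, unhealthy
restaurant_top5_score <- function(items, thresholds = npm_thresholds()) {
  npis <- if (is.numeric(items)) {
    items
  } else {
    vapply(items, function(p) npm_to_npi(compute_npm(p, thresholds))$npi,
           numeric(1))
  }
  npis <- npis[!is.na(npis)]
  if (!length(npis)) {
    stop(unscorable_error("no scorable top-five items"))
  }
  if (length(npis) < 5) {
    warning("restaurant_top5_score: averaging over ", length(npis),
            " item(s), not 5", call. = FALSE)
  }
  m <- mean(npis)
  structure(list(npi = m, npi_raw = m, healthy = m >= 64),
            class = "npi_result")
}

# build a nutrient_profile from one row of the nutrition CSV dialect,
# normalising to per 100 g and applying the ingredient rule as needed
profile_from_row <- function(row, lexicon = fvn_lexicon()) {
  ingredients <- if (!is.null(row$ingredients) &&
                     !is.na(row$ingredients) && nzchar(row$ingredients)) {
    trimws(strsplit(row$ingredients, ";", fixed = TRUE)[[1]])
  }
  unit <- if (!is.null(row$energy_unit) && !is.na(row$energy_unit)) {
    tolower(row$energy_unit)
  } else {
    "kj"
  }
  num <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))
  p <- nutrient_profile(
    energy_kj   = if (unit == "kj") num(row$energy) else NA_real_,
    energy_kcal = if (unit == "kcal") num(row$energy) else NA_real_,
    satfat_g = num(row$satfat_g), sugar_g = num(row$sugar_g),
    sodium_mg = num(row$sodium_mg), salt_g = num(row$salt_g),
    fibre_g = num(row$fibre_g),
    fibre_basis = if (!is.null(row$fibre_basis) && !is.na(row$fibre_basis)) {
      row$fibre_basis
    } else {
      "AOAC"
    },
    protein_g = num(row$protein_g), fvn_pct = num(row$fvn_pct),
    serving_weight_g = num(row$serving_weight_g),
    ingredients = ingredients
  )
  basis <- if (!is.null(row$per_basis) && !is.na(row$per_basis)) {
    row$per_basis
  } else {
    "100g"
  }
  if (identical(basis, "serving")) {
    p <- normalize_to_100g(p)
  }
  if (is.na(p$fvn_pct)) {
    if (is.null(p$ingredients)) {
      p$fvn_pct <- 0
    } else {
      p <- apply_fvn_ingredient_rule(p, lexicon)
    }
  }
  p
}

#' Score a product table end to end
#'
#' Runs categorisation, nutrition-source resolution and NPM/NPI scoring
#' over a validated products table. Foods leave either scored (NPM
#' components, NPI, healthy/unhealthy) or with an explicit
#' `omission_reason`; beverages and supplements keep their category and are
#' never scored, matching the analysis design (the NPM is not considered
#' reliable for beverages).
#'
#' @param products Products tibble (validated, or raw — validation is
#'   applied).
#' @param tables Lookup tables, see [resolve_nutrition_source()].
#' @param taxonomy,rules Passed to [categorize_products()].
#' @param thresholds Threshold tables from [npm_thresholds()].
#' @param lexicon Fruit/veg/nut lexicon for the ingredient rule.
#' @return A tibble with one row per product: identity columns, `category`,
#'   `nutrition_source`, NPM component points and total (where a label or
#'   reference profile was scored), `npi` (2 dp), `npi_raw`, `healthy`,
#'   `omission_reason`.
#' @export
score_products <- function(products, tables,
                           taxonomy = default_taxonomy(),
                           rules = category_rules(),
                           thresholds = npm_thresholds(),
                           lexicon = fvn_lexicon()) {
  products <- validate_products(products)
  if (!"category" %in% names(products) ||
      anyNA(products$category)) {
    products <- categorize_products(products, taxonomy, rules)
  }
  products <- resolve_nutrition_source(products, tables)

  blank <- list(a_energy = NA_integer_, a_satfat = NA_integer_,
                a_sugar = NA_integer_, a_sodium = NA_integer_,
                c_fvn = NA_integer_, c_fibre = NA_integer_,
                c_protein = NA_integer_, protein_capped = NA,
                npm_total = NA_integer_, npi = NA_real_,
                npi_raw = NA_real_, healthy = NA,
                omission_reason = NA_character_)

  score_one <- function(product_id, source, omission_reason) {
    out <- blank
    out$omission_reason <- omission_reason
    if (source %in% c("branded_label", "generic_reference")) {
      rows <- nutrition[nutrition_rows[[product_id]], , drop = FALSE]
      res <- tryCatch({
        p <- profile_from_row(as.list(rows[1, ]), lexicon)
        s <- compute_npm(p, thresholds)
        r <- npm_to_npi(s)
        out[names(s)[names(s) %in% names(out)]] <-
          s[names(s) %in% names(out)]
        out$npm_total <- s$total
        out$npi <- round(r$npi, 2)
        out$npi_raw <- r$npi_raw
        out$healthy <- r$healthy
        out
      }, npiscore_unscorable = function(e) {
        out$omission_reason <- conditionMessage(e)
        out
      })
      return(res)
    }
    if (source == "restaurant_report") {
      npi <- report$npi[match(product_id, report$product_id)]
      out$npi <- round(npi, 2)
      out$npi_raw <- npi
      out$healthy <- npi >= 64
      return(out)
    }
    if (source == "restaurant_top5") {
      rows <- nutrition[utils::head(nutrition_rows[[product_id]], 5),
                        , drop = FALSE]
      res <- tryCatch({
        profiles <- lapply(seq_len(nrow(rows)), function(i) {
          profile_from_row(as.list(rows[i, ]), lexicon)
        })
        r <- suppressWarnings(restaurant_top5_score(profiles, thresholds))
        out$npi <- round(r$npi, 2)
        out$npi_raw <- r$npi_raw
        out$healthy <- r$healthy
        out
      }, npiscore_unscorable = function(e) {
        out$omission_reason <- conditionMessage(e)
        out
      })
      return(res)
    }
    out
  }

  if (nrow(products) == 0) {
    return(dplyr::bind_cols(
      products[setdiff(names(products), "omission_reason")],
      tibble::as_tibble(blank)[0, ]
    ))
  }
  nutrition <- dplyr::bind_rows(
    tables$branded_label, tables$generic_reference
  )
  nutrition_rows <- split(seq_len(nrow(nutrition)), nutrition$product_id)
  report <- tables$restaurant_report

  scored <- purrr::pmap(
    list(products$product_id, products$nutrition_source,
         products$omission_reason),
    function(product_id, source, omission_reason) {
      tryCatch(
        score_one(product_id, source, omission_reason),
        npiscore_unscorable = function(e) {
          out <- blank
          out$omission_reason <- conditionMessage(e)
          out
        },
        error = function(e) {
          stop("score_products: product '", product_id, "': ",
               conditionMessage(e), call. = FALSE)
        }
      )
    }
  )
  scored <- dplyr::bind_rows(lapply(scored, tibble::as_tibble))
  out <- dplyr::bind_cols(
    products[setdiff(names(products), "omission_reason")], scored
  )
  stopifnot(nrow(out) == nrow(products))
  out
}
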