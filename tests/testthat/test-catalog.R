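products_fixture <- function() {
  tibble::tibble(
    product_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    video_id = paste0("v", 1:6),
    name = c("homemade lasagna", "cold-brew with oat milk, unsweetened",
             "chocolate chips cookies", "burger combo", "mystery thing",
             "whey protein powder"),
    product_type = c("food", "beverage", "food", "food", "food",
                     "supplement"),
    branded = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    restaurant = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

nutrition_row <- function(product_id, sugar = 10, energy = 400,
                          per_basis = "100g", serving = NA_real_, ...) {
  tibble::tibble(product_id = product_id, energy = energy,
                 energy_unit = "kJ", satfat_g = 1, sugar_g = sugar,
                 sodium_mg = 100, fibre_g = 1, fibre_basis = "AOAC",
                 protein_g = 2, fvn_pct = 0, serving_weight_g = serving,
                 per_basis = per_basis, ingredients = NA_character_, ...)
}

test_that("product validation rejects schema violations with row context", {
  p <- products_fixture()
  expect_s3_class(validate_products(p), "tbl_df")
  expect_error(validate_products(p[, -1]), "missing column")
  bad_type <- p
  bad_type$product_type[3] <- "gadget"
  expect_error(validate_products(bad_type), "row\\(s\\) 3")
  dup <- p
  dup$video_id[2] <- "v1"
  expect_error(validate_products(dup), "one product per video")
})

test_that("categorisation is total, deterministic, and respects precedence", {
  cat_tbl <- suppressWarnings(categorize_products(products_fixture()))
  expect_false(anyNA(cat_tbl$category))
  by_id <- stats::setNames(cat_tbl$category, cat_tbl$product_id)
  expect_identical(unname(by_id["p1"]), "mixed dishes")
  expect_identical(unname(by_id["p2"]), "coffee/tea")
  expect_identical(unname(by_id["p3"]), "packaged snacks")
  # restaurant flag wins over any keyword
  expect_identical(unname(by_id["p4"]), "fast food/restaurant")
  expect_identical(unname(by_id["p6"]), "supplement")

  expect_warning(
    fallback <- categorize_products(products_fixture()),
    "no rule matched"
  )
  expect_identical(
    fallback$category[fallback$product_id == "p5"], "other food")

  # explicit valid category is preserved
  explicit <- products_fixture()
  explicit$category <- NA_character_
  explicit$category[1] <- "desserts"
  out <- suppressWarnings(categorize_products(explicit))
  expect_identical(out$category[1], "desserts")

  expect_error(
    categorize_products(products_fixture(),
                        taxonomy = structure(list(), class = "category_taxonomy")),
    "empty taxonomy")
})

test_that("nutrition-source resolution follows the pathway hierarchy", {
  p <- suppressWarnings(categorize_products(products_fixture()))
  tables <- list(
    branded_label = nutrition_row("p3"),
    restaurant_report = tibble::tibble(product_id = "p4", npi = 45),
    generic_reference = nutrition_row("p1")
  )
  r <- resolve_nutrition_source(p, tables)
  src <- stats::setNames(r$nutrition_source, r$product_id)
  expect_identical(unname(src["p3"]), "branded_label")
  expect_identical(unname(src["p4"]), "restaurant_report")
  expect_identical(unname(src["p1"]), "generic_reference")
  expect_identical(unname(src["p5"]), "none")
  expect_identical(
    r$omission_reason[r$product_id == "p5"], "no nutrition information")
  # beverages and supplements resolve to none without omission reasons
  expect_identical(unname(src["p2"]), "none")
  expect_true(is.na(r$omission_reason[r$product_id == "p2"]))

  # restaurant without report entry but with menu rows -> top-five path
  tables2 <- tables
  tables2$restaurant_report <- tibble::tibble(product_id = character(0),
                                              npi = numeric(0))
  tables2$branded_label <- dplyr::bind_rows(
    nutrition_row("p3"),
    dplyr::bind_rows(lapply(1:5, function(i) nutrition_row("p4"))))
  r2 <- resolve_nutrition_source(p, tables2)
  expect_identical(
    r2$nutrition_source[r2$product_id == "p4"], "restaurant_top5")
})

test_that("top-five averaging works on the NPI scale with mean cut-off", {
  r <- restaurant_top5_score(c(40, 50, 60, 70, 80))
  expect_equal(r$npi, 60)
  expect_false(r$healthy)
  expect_true(restaurant_top5_score(rep(64, 5))$healthy)
  r2 <- restaurant_top5_score(c(70, 70, 70, 50, 50))
  expect_equal(r2$npi, 62)
  expect_false(r2$healthy)
  expect_warning(restaurant_top5_score(c(64, 64)), "not 5")
  err <- tryCatch(restaurant_top5_score(numeric(0)), condition = identity)
  expect_s3_class(err, "npiscore_unscorable")

  # profiles route: five all-zero profiles score NPM 0 -> NPI 70
  profiles <- replicate(5, make_profile(), simplify = FALSE)
  expect_equal(restaurant_top5_score(profiles)$npi, 70)
})

test_that("scoring leaves every food scored or excused, others unscored", {
  p <- products_fixture()
  tables <- list(
    branded_label = nutrition_row("p3", sugar = 30, energy = 2200),
    restaurant_report = tibble::tibble(product_id = "p4", npi = 45),
    generic_reference = nutrition_row("p1")
  )
  scored <- suppressWarnings(score_products(p, tables))
  expect_identical(nrow(scored), nrow(p))
  foods <- scored[scored$product_type == "food", ]
  expect_true(all(xor(!is.na(foods$npi), !is.na(foods$omission_reason))))
  others <- scored[scored$product_type != "food", ]
  expect_true(all(is.na(others$npi)))
  # report-sourced NPI passes straight through
  expect_equal(scored$npi[scored$product_id == "p4"], 45)
  # label-sourced foods carry their component breakdown
  p3 <- scored[scored$product_id == "p3", ]
  expect_false(is.na(p3$npm_total))
  expect_equal(p3$npi_raw, -2 * p3$npm_total + 70)

  # per-serving rows without serving weight become omissions, not errors
  tables$branded_label <- nutrition_row("p3", per_basis = "serving")
  scored2 <- suppressWarnings(score_products(p, tables))
  expect_match(scored2$omission_reason[scored2$product_id == "p3"],
               "serving weight")
})

test_that("scoring a zero-row product table yields a zero-row result", {
  empty <- products_fixture()[0, ]
  scored <- score_products(empty, list())
  expect_identical(nrow(scored), 0L)
  expect_true(all(c("npi", "omission_reason", "category") %in%
                    names(scored)))
})
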