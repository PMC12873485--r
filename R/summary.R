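#' Round half away from zero
#'
#' Descriptive tables in this field conventionally round 0.5 up (so
#' 1360/8871 prints as 15.3\%), whereas base R's `round()` rounds half to
#' even. Used for every printed percentage and summary statistic.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

percent1 <- function(n, denom) {
  if (denom == 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / denom, 1)
}

#' Frequency table of product categories
#'
#' Counts and percentages per category, optionally stratified by brand
#' status. Rows are sorted by descending count with alphabetical
#' tie-breaks; percentages use the stratum's own record count as the
#' denominator (carried in the `denominator` attribute and printed in the
#' header).
#'
#' @param records Products tibble with `category` (and `branded` when
#'   stratifying).
#' @param stratify_by_brand Add per-stratum count/percent columns.
#' @return A tibble with `category`, `n`, `pct` (1 dp, half-up), plus
#'   `n_branded`/`pct_branded`/`n_unbranded`/`pct_unbranded` when
#'   stratified. Empty input gives an empty table.
#' @export
category_frequency_table <- function(records, stratify_by_brand = FALSE) {
  if (nrow(records) == 0) {
    out <- tibble::tibble(category = character(0), n = integer(0),
                          pct = numeric(0))
    attr(out, "denominator") <- 0L
    return(out)
  }
  total <- nrow(records)
  tab <- records |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(pct = percent1(.data$n, total)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
  if (stratify_by_brand) {
    add_stratum <- function(tab, flag, label) {
      sub <- records[records$branded == flag, , drop = FALSE]
      denom <- nrow(sub)
      counts <- table(sub$category)
      n_s <- as.integer(counts[tab$category])
      n_s[is.na(n_s)] <- 0L
      tab[[paste0("n_", label)]] <- n_s
      tab[[paste0("pct_", label)]] <- percent1(n_s, denom)
      attr(tab, paste0("denominator_", label)) <- denom
      tab
    }
    tab <- add_stratum(tab, TRUE, "branded")
    tab <- add_stratum(tab, FALSE, "unbranded")
  }
  attr(tab, "denominator") <- total
  tab
}

#' Brand-stratified NPI statistics
#'
#' Mean and sample (n-1) standard deviation of NPI over scored foods,
#' overall and by brand status, rounded to 2 decimal places. Emits an
#' internal consistency check: the pooled mean must equal the
#' count-weighted mean of the stratum means.
#'
#' @param scored Scored foods tibble with `npi` (non-missing) and
#'   `branded`.
#' @return A tibble with rows `overall`, `branded`, `unbranded` and
#'   columns `stratum`, `n`, `mean`, `sd`; empty strata are dropped with a
#'   message. Attribute `pooled_consistent` records the check.
#' @export
stratified_npi <- function(scored) {
  scored <- scored[!is.na(scored$npi), , drop = FALSE]
  one <- function(x, label) {
    if (!length(x)) return(NULL)
    tibble::tibble(
      stratum = label, n = length(x),
      mean = round_half_up(mean(x), 2),
      sd = if (length(x) >= 2) round_half_up(stats::sd(x), 2) else NA_real_
    )
  }
  strata <- list(
    one(scored$npi, "overall"),
    one(scored$npi[scored$branded], "branded"),
    one(scored$npi[!scored$branded], "unbranded")
  )
  dropped <- c("overall", "branded", "unbranded")[
    vapply(strata, is.null, logical(1))]
  if (length(dropped)) {
    message("stratified_npi: empty stratum(s) omitted: ",
            paste(dropped, collapse = ", "))
  }
  out <- dplyr::bind_rows(strata)
  if (all(c("branded", "unbranded") %in% out$stratum) &&
      "overall" %in% out$stratum) {
    sub <- out[out$stratum != "overall", ]
    pooled <- sum(sub$n * sub$mean) / sum(sub$n)
    out_mean <- out$mean[out$stratum == "overall"]
    attr(out, "pooled_consistent") <- abs(pooled - out_mean) < 0.02
  }
  out
}

#' Study-level descriptive summary
#'
#' Builds the full descriptive layer of the analysis from a scored product
#' table: prevalence of product-featuring videos, the
#' food/beverage/supplement split, the branded share, per-category
#' frequency tables stratified by brand status, brand-stratified NPI means
#' and standard deviations, the proportion of foods classified unhealthy
#' (unclamped NPI < 64), and the scored/omitted accounting. All
#' percentages are computed from the module's own denominators and rounded
#' half-up to 1 decimal place; means/SDs to 2.
#'
#' @param scored Scored products tibble from [score_products()] (or any
#'   table with the same columns).
#' @param n_videos Total number of videos screened; must be at least the
#'   number of distinct `video_id`s.
#' @return An object of class `study_summary` (a named list; see the
#'   fields in the implementation) with a print method mirroring the usual
#'   count (percent) table layout.
#' @export
summarize_study <- function(scored, n_videos) {
  scored <- tibble::as_tibble(scored)
  n_products <- nrow(scored)
  if (n_videos < length(unique(scored$video_id))) {
    stop("summarize_study: n_videos is smaller than the number of ",
         "distinct video_ids", call. = FALSE)
  }
  foods <- scored[scored$product_type == "food", , drop = FALSE]
  bevs  <- scored[scored$product_type == "beverage", , drop = FALSE]
  type_counts <- tibble::tibble(
    product_type = c("food", "beverage", "supplement"),
    n = vapply(c("food", "beverage", "supplement"),
               function(t) sum(scored$product_type == t), integer(1),
               USE.NAMES = FALSE)
  )
  type_counts$pct <- percent1(type_counts$n, n_products)

  scored_foods <- foods[!is.na(foods$npi), , drop = FALSE]
  n_scored <- nrow(scored_foods)
  n_omitted <- sum(!is.na(foods$omission_reason))

  npi_stats <- if (n_scored > 0) stratified_npi(foods) else NULL

  unhealthy_row <- function(sub, label) {
    if (!nrow(sub)) return(NULL)
    n_un <- sum(sub$npi_raw < 64)
    tibble::tibble(stratum = label, n = nrow(sub), n_unhealthy = n_un,
                   pct_unhealthy = percent1(n_un, nrow(sub)))
  }
  unhealthy <- dplyr::bind_rows(
    unhealthy_row(scored_foods, "overall"),
    unhealthy_row(scored_foods[scored_foods$branded, ], "branded"),
    unhealthy_row(scored_foods[!scored_foods$branded, ], "unbranded")
  )

  structure(list(
    n_videos = n_videos,
    n_product_videos = n_products,
    pct_product_videos = percent1(n_products, n_videos),
    type_counts = type_counts,
    branded_share = percent1(sum(scored$branded), n_products),
    food_category_table = category_frequency_table(foods, TRUE),
    beverage_category_table = category_frequency_table(bevs, TRUE),
    npi_stats = npi_stats,
    unhealthy = unhealthy,
    n_foods = nrow(foods),
    n_scored = n_scored,
    pct_scored = percent1(n_scored, nrow(foods)),
    n_omitted = n_omitted,
    pct_omitted = percent1(n_omitted, nrow(foods))
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("== Study summary ==\n")
  cat(sprintf("Videos screened: %d; featuring a product: %d (%.1f%%)\n",
              x$n_videos, x$n_product_videos, x$pct_product_videos))
  cat(sprintf("Branded products: %.1f%%\n", x$branded_share))
  cat("\nProduct types (n, % of products):\n")
  print(as.data.frame(x$type_counts), row.names = FALSE)
  cat(sprintf("\nFood categories (n = %d):\n",
              attr(x$food_category_table, "denominator")))
  print(as.data.frame(x$food_category_table), row.names = FALSE)
  cat(sprintf("\nBeverage categories (n = %d):\n",
              attr(x$beverage_category_table, "denominator")))
  print(as.data.frame(x$beverage_category_table), row.names = FALSE)
  cat(sprintf("\nFoods scored: %d of %d (%.1f%%); omitted: %d (%.1f%%)\n",
              x$n_scored, x$n_foods, x$pct_scored, x$n_omitted,
              x$pct_omitted))
  if (!is.null(x$npi_stats)) {
    cat("\nNPI among scored foods (mean, sd):\n")
    print(as.data.frame(x$npi_stats), row.names = FALSE)
    cat("\nClassified unhealthy (unclamped NPI < 64):\n")
    print(as.data.frame(x$unhealthy), row.names = FALSE)
  } else {
    cat("\nNPI statistics unavailable (no scored foods)\n")
  }
  invisible(x)
}

#' Write summary artifacts
#'
#' Emits the machine-readable and human-readable forms of a
#' [summarize_study()] result: a JSON file with every field, a plain-text
#' rendering of the print method, and one CSV per table.
#'
#' @param summary A `study_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "study_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(dir, "summary.json"),
    text = file.path(dir, "summary.txt"),
    food = file.path(dir, "food_categories.csv"),
    beverage = file.path(dir, "beverage_categories.csv"),
    types = file.path(dir, "type_counts.csv")
  )
  jsonlite::write_json(unclass(summary), paths["json"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  writeLines(utils::capture.output(print(summary)), paths["text"])
  readr::write_csv(summary$food_category_table, paths["food"])
  readr::write_csv(summary$beverage_category_table, paths["beverage"])
  readr::write_csv(summary$type_counts, paths["types"])
  if (!is.null(summary$npi_stats)) {
    paths["npi"] <- file.path(dir, "npi_stats.csv")
    readr::write_csv(summary$npi_stats, paths["npi"])
    paths["unhealthy"] <- file.path(dir, "unhealthy.csv")
    readr::write_csv(summary$unhealthy, paths["unhealthy"])
  }
  invisible(paths)
}
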