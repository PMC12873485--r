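#' Read a products CSV
#'
#' Dialect: UTF-8, comma-separated, header required, `.` decimal separator.
#' Columns: `product_id`, `video_id`, `name`, `product_type`, `branded`,
#' `restaurant`, optional `category`.
#'
#' @param path File path.
#' @return Validated products tibble.
#' @export
read_products <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  known <- c("product_id", "video_id", "name", "product_type", "branded",
             "restaurant", "category")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("read_products: ignoring unknown column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  validate_products(df)
}

#' Read a nutrition table CSV
#'
#' Dialect columns: `product_id`, `energy`, `energy_unit` (`kJ`/`kcal`),
#' `satfat_g`, `sugar_g`, `sodium_mg` (or `salt_g`), `fibre_g`,
#' `fibre_basis` (`AOAC`/`NSP`), `protein_g`, `fvn_pct`,
#' `serving_weight_g`, `per_basis` (`100g`/`serving`), `ingredients`
#' (semicolon-joined). Multiple rows per `product_id` represent a
#' restaurant's top items.
#'
#' @param path File path.
#' @return Tibble in the nutrition dialect.
#' @export
read_nutrition_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"product_id" %in% names(df)) {
    stop("nutrition table ", path, ": missing product_id column",
         call. = FALSE)
  }
  df
}

#' Read a restaurant report CSV (pre-extracted NPI values)
#'
#' @param path File path; columns `product_id`, `npi`.
#' @return Tibble with `product_id` and numeric `npi`.
#' @export
read_restaurant_report <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("product_id", "npi") %in% names(df))) {
    stop("restaurant report ", path,
         ": requires product_id and npi columns", call. = FALSE)
  }
  df
}

#' Simulate a corpus and write its CSV files
#'
#' Runs [generate_study()] and writes `videos.csv`, `products.csv`,
#' `branded_label.csv`, `restaurant_report.csv` and
#' `generic_reference.csv` to `out_dir` — the exact dialects the scoring
#' stage reads back. Deterministic for a fixed config seed.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
run_simulate <- function(config = generator_config(), out_dir) {
  study <- generate_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    videos = file.path(out_dir, "videos.csv"),
    products = file.path(out_dir, "products.csv"),
    branded_label = file.path(out_dir, "branded_label.csv"),
    restaurant_report = file.path(out_dir, "restaurant_report.csv"),
    generic_reference = file.path(out_dir, "generic_reference.csv")
  )
  readr::write_csv(study$videos, paths["videos"], progress = FALSE)
  readr::write_csv(study$products, paths["products"], progress = FALSE)
  readr::write_csv(study$tables$branded_label, paths["branded_label"],
                   progress = FALSE)
  readr::write_csv(study$tables$restaurant_report,
                   paths["restaurant_report"], progress = FALSE)
  readr::write_csv(study$tables$generic_reference,
                   paths["generic_reference"], progress = FALSE)
  invisible(paths)
}

#' Score a products CSV against nutrition tables
#'
#' File-level wrapper around [score_products()]: reads the products table
#' and the three lookup tables, scores every product, and (optionally)
#' writes the scored CSV.
#'
#' @param products_csv Products CSV path.
#' @param branded_label_csv,generic_reference_csv Nutrition table paths
#'   (`NULL` for none).
#' @param restaurant_report_csv Restaurant report path (`NULL` for none).
#' @param out_csv Output path for the scored table, or `NULL` to skip
#'   writing.
#' @param fibre_basis Default fibre basis for rows that do not state one.
#' @param thresholds_yaml Optional YAML overriding [npm_thresholds()].
#' @return The scored tibble, invisibly when `out_csv` is written.
#' @export
run_score <- function(products_csv, branded_label_csv = NULL,
                      restaurant_report_csv = NULL,
                      generic_reference_csv = NULL, out_csv = NULL,
                      fibre_basis = "AOAC", thresholds_yaml = NULL) {
  products <- read_products(products_csv)
  tables <- list(
    branded_label = if (!is.null(branded_label_csv)) {
      read_nutrition_table(branded_label_csv)
    },
    restaurant_report = if (!is.null(restaurant_report_csv)) {
      read_restaurant_report(restaurant_report_csv)
    },
    generic_reference = if (!is.null(generic_reference_csv)) {
      read_nutrition_table(generic_reference_csv)
    }
  )
  thresholds <- npm_thresholds(thresholds_yaml)
  scored <- score_products(products, tables, thresholds = thresholds)
  if (!is.null(out_csv)) {
    dir.create(dirname(out_csv), showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(scored, out_csv, progress = FALSE)
    return(invisible(scored))
  }
  scored
}

#' Summarise a scored CSV
#'
#' Reads a scored table written by [run_score()] and produces the
#' descriptive summary artifacts of [summarize_study()] /
#' [write_summary()].
#'
#' @param scored_csv Scored CSV path.
#' @param n_videos Total videos screened.
#' @param out_dir Output directory for summary artifacts, or `NULL` to
#'   only return the summary object.
#' @return The `study_summary`.
#' @export
run_summarize <- function(scored_csv, n_videos, out_dir = NULL) {
  scored <- readr::read_csv(scored_csv, show_col_types = FALSE,
                            progress = FALSE)
  s <- summarize_study(scored, n_videos)
  if (!is.null(out_dir)) write_summary(s, out_dir)
  s
}
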