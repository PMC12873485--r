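#' Nutrient Profile Model threshold tables
#'
#' The UK 2004/05 Nutrient Profile Model reads each scoring component off a
#' threshold table with strict-inequality bins: a component scores the
#' largest number of points `n` such that the amount per 100 g strictly
#' exceeds the `n`-th threshold. "A" (penalty) components score 0--10 points
#' each; "C" (credit) components score 0--5.
#'
#' The defaults encode the published guidance tables:
#' \itemize{
#'   \item energy: 335 kJ steps (335, 670, ..., 3350 kJ)
#'   \item saturated fat: 1 g steps (1--10 g)
#'   \item total sugar: 4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45 g
#'   \item sodium: 90 mg steps (90--900 mg)
#'   \item fruit/vegetable/nut fraction: >40\% = 1, >60\% = 2, >80\% = 5
#'     points (3 and 4 are unattainable by design)
#'   \item fibre (NSP basis): 0.7 g steps; fibre (AOAC basis, as on US
#'     labels): 0.9, 1.9, 2.8, 3.7, 4.7 g
#'   \item protein: 1.6 g steps (1.6--8 g)
#' }
#'
#' @param file Optional path to a YAML file overriding the defaults. The file
#'   must carry the same structure as the returned list; a copy of the
#'   defaults ships at
#'   `system.file("extdata", "npm_thresholds.yaml", package = "npiscore")`.
#' @return A named list with elements `a` (lists `energy_kj`, `satfat_g`,
#'   `sugar_g`, `sodium_mg`, each a length-10 ascending numeric vector) and
#'   `c` (`fvn_pct` thresholds with their point values, `fibre_nsp_g`,
#'   `fibre_aoac_g`, `protein_g`, each length 5 except the 3-bin FVN table).
#' @export
#' @examples
#' thr <- npm_thresholds()
#' thr$a$sugar_g
npm_thresholds <- function(file = NULL) {
  if (!is.null(file)) {
    raw <- yaml::read_yaml(file)
    thr <- list(
      a = lapply(raw$a, as.numeric),
      c = list(
        fvn_pct    = as.numeric(raw$c$fvn_pct),
        fvn_points = as.integer(raw$c$fvn_points),
        fibre_nsp_g  = as.numeric(raw$c$fibre_nsp_g),
        fibre_aoac_g = as.numeric(raw$c$fibre_aoac_g),
        protein_g    = as.numeric(raw$c$protein_g)
      )
    )
  } else {
    # literal constants, not multiples: 0.7 * 3 is 2.0999... in binary
    # floating point, which would flip the strict inequality at 2.1 g
    thr <- list(
      a = list(
        energy_kj = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015,
                      3350),
        satfat_g  = as.numeric(1:10),
        sugar_g   = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
        sodium_mg = c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900)
      ),
      c = list(
        fvn_pct    = c(40, 60, 80),
        fvn_points = c(1L, 2L, 5L),
        fibre_nsp_g  = c(0.7, 1.4, 2.1, 2.8, 3.5),
        fibre_aoac_g = c(0.9, 1.9, 2.8, 3.7, 4.7),
        protein_g    = c(1.6, 3.2, 4.8, 6.4, 8.0)
      )
    )
  }
  validate_thresholds(thr)
  thr
}

validate_thresholds <- function(thr) {
  a_keys <- c("energy_kj", "satfat_g", "sugar_g", "sodium_mg")
  if (!all(a_keys %in% names(thr$a))) {
    stop("threshold config: missing A-component table(s): ",
         paste(setdiff(a_keys, names(thr$a)), collapse = ", "), call. = FALSE)
  }
  for (k in a_keys) {
    v <- thr$a[[k]]
    if (length(v) != 10 || is.unsorted(v, strictly = TRUE) || any(v <= 0)) {
      stop("threshold config: A table '", k,
           "' must be 10 strictly increasing positive values", call. = FALSE)
    }
  }
  for (k in c("fibre_nsp_g", "fibre_aoac_g", "protein_g")) {
    v <- thr$c[[k]]
    if (length(v) != 5 || is.unsorted(v, strictly = TRUE) || any(v <= 0)) {
      stop("threshold config: C table '", k,
           "' must be 5 strictly increasing positive values", call. = FALSE)
    }
  }
  if (length(thr$c$fvn_pct) != length(thr$c$fvn_points)) {
    stop("threshold config: fvn_pct and fvn_points lengths differ",
         call. = FALSE)
  }
  invisible(thr)
}

#' Fruit, vegetable and nut ingredient lexicon
#'
#' Terms used by [apply_fvn_ingredient_rule()] to decide whether an
#' ingredient names a fruit, vegetable or nut. Matching is case-insensitive
#' on whole words with simple plural handling ("strawberry" matches
#' "strawberries").
#'
#' @param file Optional path to a YAML file with a top-level `terms` list
#'   replacing the shipped lexicon (a copy lives at
#'   `system.file("extdata", "fvn_lexicon.yaml", package = "npiscore")`).
#' @return Character vector of lowercase lexicon terms.
#' @export
fvn_lexicon <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "fvn_lexicon.yaml", package = "npiscore")
  }
  terms <- yaml::read_yaml(file)$terms
  if (is.null(terms) || !length(terms)) {
    stop("fvn lexicon: no 'terms' entry in ", file, call. = FALSE)
  }
  tolower(unlist(terms))
}
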