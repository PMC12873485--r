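#' Generator configuration for synthetic study corpora
#'
#' Defines the statistical structure of a synthetic influencer-video
#' corpus: how many videos are screened, how often a video features a
#' product, the food/beverage/supplement split, the branded share,
#' per-stratum category mixes, the distribution of NPM totals per brand
#' stratum, and per-stratum probabilities that a food's nutrition
#' information cannot be found. Defaults reproduce the study conditions of
#' the source corpus: 8871 videos with a 15.3\% product share (1360/8871),
#' a 55.5/42.6/1.8 type split (755/580/25), a 47.6\% branded share, NPM
#' distributions targeting branded/unbranded NPI moments of (49.58, 17.80)
#' and (57.61, 20.52) via the linear map NPM = (70 - NPI)/2, and omission
#' probabilities scaled so that 11.4\% of foods (81 unbranded, 5 branded of
#' an expected 755) lack nutrition information.
#'
#' @param n_videos Number of videos screened.
#' @param p_product Probability a video features a product.
#' @param type_probs Named simplex over `food`, `beverage`, `supplement`.
#' @param p_branded Probability a product is branded.
#' @param food_category_mix,beverage_category_mix Named list with `branded`
#'   and `unbranded` simplexes over the taxonomy's category labels.
#' @param npm_dist Named list with `branded` and `unbranded` entries, each
#'   `c(mean = , sd = )` on the NPM scale; totals are drawn from a
#'   discretized normal truncated to [-15, 40].
#' @param p_unscorable_branded,p_unscorable_unbranded Probability a food in
#'   the stratum has no findable nutrition information.
#' @param seed Integer seed governing every draw.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_videos = 8871,
    p_product = 1360 / 8871,
    type_probs = c(food = 755, beverage = 580, supplement = 25) / 1360,
    p_branded = 0.476,
    food_category_mix = list(
      branded = c("packaged snacks" = 0.389, "fast food/restaurant" = 0.332,
                  "condiments and cooking staples" = 0.070,
                  "breakfast cereals" = 0.050, "mixed dishes" = 0.040,
                  "desserts" = 0.025, "fruits and vegetables" = 0.020,
                  "protein" = 0.030, "other food" = 0.044),
      unbranded = c("desserts" = 0.203, "fruits and vegetables" = 0.181,
                    "protein" = 0.139, "packaged snacks" = 0.131,
                    "mixed dishes" = 0.090, "fast food/restaurant" = 0.068,
                    "condiments and cooking staples" = 0.040,
                    "breakfast cereals" = 0.030, "other food" = 0.118)
    ),
    beverage_category_mix = list(
      branded = c("energy drinks" = 0.389, "alcoholic beverages" = 0.213,
                  "coffee/tea" = 0.110, "soda" = 0.070,
                  "fruit drinks" = 0.050, "sweetened dairy drinks" = 0.040,
                  "100% juice" = 0.030, "sports drinks" = 0.030,
                  "plain water" = 0.030, "other beverage" = 0.038),
      unbranded = c("alcoholic beverages" = 0.365, "other beverage" = 0.255,
                    "coffee/tea" = 0.125, "plain water" = 0.095,
                    "sweetened dairy drinks" = 0.050,
                    "fruit drinks" = 0.040, "100% juice" = 0.030,
                    "soda" = 0.020, "sports drinks" = 0.015,
                    "energy drinks" = 0.005)
    ),
    npm_dist = list(
      branded = c(mean = (70 - 49.58) / 2, sd = 17.80 / 2),
      unbranded = c(mean = (70 - 57.61) / 2, sd = 20.52 / 2)
    ),
    p_unscorable_branded = 5 / (755 * 0.476),
    p_unscorable_unbranded = 81 / (755 * 0.524),
    seed = 1L) {
  probs <- c(p_product = p_product, p_branded = p_branded,
             p_unscorable_branded = p_unscorable_branded,
             p_unscorable_unbranded = p_unscorable_unbranded)
  if (any(probs < 0 | probs > 1)) {
    stop("generator_config: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  check_simplex <- function(x, what) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop("generator_config: ", what,
           " must be a simplex (non-negative, summing to 1)",
           call. = FALSE)
    }
  }
  check_simplex(type_probs, "type_probs")
  for (s in c("branded", "unbranded")) {
    check_simplex(food_category_mix[[s]], paste0("food_category_mix$", s))
    check_simplex(beverage_category_mix[[s]],
                  paste0("beverage_category_mix$", s))
    if (npm_dist[[s]][["sd"]] <= 0) {
      stop("generator_config: npm_dist sd must be positive", call. = FALSE)
    }
  }
  if (n_videos < 0) stop("generator_config: n_videos must be >= 0",
                         call. = FALSE)
  structure(list(
    n_videos = as.integer(n_videos), p_product = p_product,
    type_probs = type_probs, p_branded = p_branded,
    food_category_mix = food_category_mix,
    beverage_category_mix = beverage_category_mix,
    npm_dist = npm_dist,
    p_unscorable_branded = p_unscorable_branded,
    p_unscorable_unbranded = p_unscorable_unbranded,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# draw integer NPM totals from a discretized normal truncated to [-15, 40]
draw_npm_totals <- function(n, mean, sd) {
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(stats::rnorm(max(n - length(out), 1), mean, sd)))
    out <- c(out, x[x >= -15 & x <= 40])
  }
  out[seq_len(n)]
}

# pick an amount strictly inside the bin that yields `points` against a
# 10- or 5-threshold table; jittered variants stay strictly inside
amount_for_points <- function(points, thresholds, jitter = FALSE) {
  k <- length(thresholds)
  if (points == 0) {
    if (jitter) stats::runif(1, 0, 0.9) * thresholds[1] else 0
  } else if (points < k) {
    lo <- thresholds[points]
    hi <- thresholds[points + 1]
    u <- if (jitter) stats::runif(1, 0.02, 0.98) else 0.5
    lo + u * (hi - lo)
  } else {
    thresholds[k] * (if (jitter) stats::runif(1, 1.02, 1.3) else 1.05)
  }
}

#' Construct a nutrient profile with a prescribed NPM total
#'
#' Constructive inverse of [compute_npm()]: for any integer NPM total in
#' [-15, 40] it builds a profile scoring exactly that total. Non-negative
#' targets are reached through A-points alone (credits zero); negative
#' targets through C-points with all A-nutrients at zero, using the
#' maximum fruit/veg/nut credit only when fibre and protein cannot supply
#' the deficit — the protein cap never bites because the A-sum is then 0.
#' Amounts are placed strictly inside the required threshold bins
#' (midpoints, or uniformly jittered within the bin).
#'
#' @param target_npm Integer in [-15, 40].
#' @param thresholds Threshold tables from [npm_thresholds()].
#' @param fibre_basis Fibre basis for the constructed profile.
#' @param jitter Randomise amounts within their bins (draws from the
#'   current RNG stream).
#' @return A [nutrient_profile()] with
#'   `compute_npm(profile)$total == target_npm`.
#' @export
#' @examples
#' compute_npm(npm_to_profile(17))$total  # 17
npm_to_profile <- function(target_npm, thresholds = npm_thresholds(),
                           fibre_basis = "AOAC", jitter = FALSE) {
  k <- as.integer(target_npm)
  if (is.na(k) || k < -15 || k > 40) {
    stop("npm_to_profile: target_npm must be an integer in [-15, 40]",
         call. = FALSE)
  }
  a_pts <- c(energy = 0L, satfat = 0L, sugar = 0L, sodium = 0L)
  c_pts <- c(fvn = 0L, fibre = 0L, protein = 0L)
  if (k >= 0) {
    rem <- k
    for (nm in names(a_pts)) {
      a_pts[nm] <- min(rem, 10L)
      rem <- rem - a_pts[nm]
    }
    stopifnot(rem == 0)
  } else {
    need <- -k
    if (need <= 10) {
      c_pts["fibre"] <- min(need, 5L)
      c_pts["protein"] <- need - c_pts["fibre"]
    } else {
      c_pts["fvn"] <- 5L
      c_pts["fibre"] <- 5L
      c_pts["protein"] <- need - 10L
    }
  }
  fvn_pct <- switch(as.character(c_pts["fvn"]),
    "0" = if (jitter) stats::runif(1, 0, 39) else 0,
    "1" = if (jitter) stats::runif(1, 41, 59) else 50,
    "2" = if (jitter) stats::runif(1, 61, 79) else 70,
    "5" = if (jitter) stats::runif(1, 81, 100) else 90
  )
  fibre_tab <- if (toupper(fibre_basis) == "AOAC") {
    thresholds$c$fibre_aoac_g
  } else {
    thresholds$c$fibre_nsp_g
  }
  nutrient_profile(
    energy_kj = amount_for_points(a_pts[["energy"]],
                                  thresholds$a$energy_kj, jitter),
    satfat_g = amount_for_points(a_pts[["satfat"]],
                                 thresholds$a$satfat_g, jitter),
    sugar_g = amount_for_points(a_pts[["sugar"]],
                                thresholds$a$sugar_g, jitter),
    sodium_mg = amount_for_points(a_pts[["sodium"]],
                                  thresholds$a$sodium_mg, jitter),
    fibre_g = amount_for_points(c_pts[["fibre"]], fibre_tab, jitter),
    fibre_basis = fibre_basis,
    protein_g = amount_for_points(c_pts[["protein"]],
                                  thresholds$c$protein_g, jitter),
    fvn_pct = fvn_pct
  )
}

profile_to_nutrition_row <- function(product_id, profile) {
  tibble::tibble(
    product_id = product_id,
    energy = profile$energy_kj, energy_unit = "kJ",
    satfat_g = profile$satfat_g, sugar_g = profile$sugar_g,
    sodium_mg = profile$sodium_mg, fibre_g = profile$fibre_g,
    fibre_basis = profile$fibre_basis, protein_g = profile$protein_g,
    fvn_pct = profile$fvn_pct, serving_weight_g = profile$serving_weight_g,
    per_basis = "100g", ingredients = NA_character_
  )
}

empty_nutrition_table <- function() {
  tibble::tibble(
    product_id = character(0), energy = numeric(0),
    energy_unit = character(0), satfat_g = numeric(0), sugar_g = numeric(0),
    sodium_mg = numeric(0), fibre_g = numeric(0), fibre_basis = character(0),
    protein_g = numeric(0), fvn_pct = numeric(0),
    serving_weight_g = numeric(0), per_basis = character(0),
    ingredients = character(0)
  )
}

#' Generate a synthetic study corpus
#'
#' Draws a full corpus under a [generator_config()]: per video a product
#' indicator, then for product videos a product type, brand status and
#' category; foods additionally receive either an NPM total drawn from the
#' stratum's distribution — inverted to a consistent nutrient profile with
#' [npm_to_profile()] — or are marked unscorable and carry no nutrition
#' row. Unbranded restaurant foods are given pre-extracted index entries in
#' the restaurant report table, exercising that resolution pathway.
#' Everything is reproducible from the config's seed.
#'
#' @param config A [generator_config()].
#' @return A list with `videos` (video_id, has_product), `products` (the
#'   products CSV dialect), and `tables` (named list `branded_label`,
#'   `restaurant_report`, `generic_reference` in the nutrition CSV
#'   dialect / report dialect).
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_videos
  has_product <- stats::runif(n) < config$p_product
  videos <- tibble::tibble(
    video_id = sprintf("v%07d", seq_len(n)),
    has_product = has_product
  )
  idx <- which(has_product)
  m <- length(idx)
  if (m == 0) {
    return(list(
      videos = videos,
      products = tibble::tibble(
        product_id = character(0), video_id = character(0),
        name = character(0), product_type = character(0),
        branded = logical(0), restaurant = logical(0),
        category = character(0)
      ),
      tables = list(branded_label = empty_nutrition_table(),
                    restaurant_report = tibble::tibble(
                      product_id = character(0), npi = numeric(0)),
                    generic_reference = empty_nutrition_table())
    ))
  }
  type <- sample(names(config$type_probs), m, replace = TRUE,
                 prob = config$type_probs)
  branded <- stats::runif(m) < config$p_branded
  category <- character(m)
  for (t in c("food", "beverage")) {
    mix_set <- if (t == "food") config$food_category_mix
               else config$beverage_category_mix
    for (b in c(TRUE, FALSE)) {
      sel <- type == t & branded == b
      mix <- mix_set[[if (b) "branded" else "unbranded"]]
      if (any(sel)) {
        category[sel] <- sample(names(mix), sum(sel), replace = TRUE,
                                prob = mix)
      }
    }
  }
  category[type == "supplement"] <- "supplement"
  restaurant <- type == "food" & category == "fast food/restaurant"
  products <- tibble::tibble(
    product_id = sprintf("p%07d", seq_len(m)),
    video_id = videos$video_id[idx],
    name = paste("synthetic", category),
    product_type = type,
    branded = branded,
    restaurant = restaurant,
    category = category
  )

  is_food <- type == "food"
  p_miss <- ifelse(branded, config$p_unscorable_branded,
                   config$p_unscorable_unbranded)
  unscorable <- is_food & stats::runif(m) < p_miss
  scorable <- is_food & !unscorable

  npm_total <- rep(NA_integer_, m)
  for (b in c(TRUE, FALSE)) {
    sel <- scorable & branded == b
    par <- config$npm_dist[[if (b) "branded" else "unbranded"]]
    if (any(sel)) {
      npm_total[sel] <- draw_npm_totals(sum(sel), par[["mean"]],
                                        par[["sd"]])
    }
  }

  thresholds <- npm_thresholds()
  # unbranded restaurant foods resolve via the pre-extracted report
  to_report <- scorable & restaurant & !branded
  to_label  <- scorable & !to_report & branded
  to_generic <- scorable & !to_report & !branded

  make_rows <- function(sel) {
    if (!any(sel)) return(empty_nutrition_table())
    rows <- lapply(which(sel), function(i) {
      profile_to_nutrition_row(
        products$product_id[i],
        npm_to_profile(npm_total[i], thresholds, jitter = TRUE)
      )
    })
    dplyr::bind_rows(rows)
  }
  branded_label <- make_rows(to_label)
  generic_reference <- make_rows(to_generic)
  restaurant_report <- tibble::tibble(
    product_id = products$product_id[to_report],
    npi = pmin(pmax(-2 * npm_total[to_report] + 70, 1), 100)
  )

  list(videos = videos, products = products,
       tables = list(branded_label = branded_label,
                     restaurant_report = restaurant_report,
                     generic_reference = generic_reference))
}
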