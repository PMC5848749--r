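#' Identifiers of the eight SACN recommendations
#'
#' Order is fixed and used throughout: fruit and vegetables, oily fish,
#' red and processed meat, non-milk extrinsic sugars, total fat, saturated
#' fat, fibre, salt.
#'
#' @export
sacn_ids <- function() {
  c("fruit_veg", "oily_fish", "red_processed_meat", "nmes",
    "fat", "satfat", "fibre", "salt")
}

#' Simulation configuration for the synthetic NDNS/price world
#'
#' Builds and validates the configuration driving all three generators
#' ([gen_food_universe()], [gen_price_panel()],
#' [gen_population_and_diaries()]). Defaults emulate the study conditions of
#' the source surveys: ~2083 adults keeping 4-day unweighed diaries, a
#' scanner panel with many transactions per generic product ("sub mark"),
#' a positive association between a food's healthiness and its price, and
#' observational cost premiums attached to meeting each dietary
#' recommendation.
#'
#' @param n_people Number of adults to simulate.
#' @param n_foods Number of distinct diary foods in the food universe.
#' @param n_days Diary days per person.
#' @param submarks_per_food Integer range `c(min, max)`: sub marks matched
#'   to each food (uniform).
#' @param transactions_per_submark Integer range `c(min, max)`: scanner
#'   transactions recorded per sub mark (uniform).
#' @param healthiness_price_slope Pence per 100 g (as consumed) added per
#'   unit of latent healthiness (centred at 0.5).
#' @param sacn_premiums Named numeric (names [sacn_ids()]): true cost
#'   premium, pence per 2000 kcal, carried by meeting each recommendation.
#' @param sacn_prevalence Named numeric in `[0, 1]`: probability a person
#'   is generated to meet each recommendation.
#' @param price_noise_sd Transaction-level price noise, pence per unit sold.
#' @param promo_fraction Proportion of transactions at a discounted
#'   (promotional) price.
#' @param promo_discount Relative discount applied to promotional prices.
#' @param food_price_cv Coefficient of variation of food-level price
#'   around the group baseline (multiplicative, log-normal); this
#'   within-group spread is what the premium tilt acts on.
#' @param base_price_per_kcal Baseline as-consumed price, pence per kcal,
#'   shared by all food groups so that group mix alone does not move the
#'   isoenergetic diet cost.
#' @param weight_dispersion Coefficient of variation of the log-normal
#'   survey weights (renormalised to mean 1).
#' @param energy_mean,energy_cv,energy_range Mean, coefficient of
#'   variation and truncation bounds (kcal/day) of person-level energy
#'   intake.
#' @param prop_missing_covariate Probability a person's occupational class
#'   is missing (drives covariate exclusions).
#' @param prop_short_diary Probability a person completes only
#'   `min(2, n_days - 1)` diary days (drives diary-length exclusions).
#' @param seed Integer master seed; all generator randomness flows from it
#'   via named substreams.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_people = 2083L,
                       n_foods = 72L,
                       n_days = 4L,
                       submarks_per_food = c(2L, 6L),
                       transactions_per_submark = c(20L, 80L),
                       healthiness_price_slope = 30,
                       sacn_premiums = c(fruit_veg = 87, oily_fish = 80,
                                         red_processed_meat = -20, nmes = 25,
                                         fat = 35, satfat = 60, fibre = 0,
                                         salt = 15),
                       sacn_prevalence = c(fruit_veg = 0.30, oily_fish = 0.25,
                                           red_processed_meat = 0.55,
                                           nmes = 0.45, fat = 0.45,
                                           satfat = 0.20, fibre = 0.20,
                                           salt = 0.40),
                       price_noise_sd = 6,
                       promo_fraction = 0.20,
                       promo_discount = 0.25,
                       food_price_cv = 0.40,
                       base_price_per_kcal = 0.26,
                       weight_dispersion = 0.5,
                       energy_mean = 1840,
                       energy_cv = 0.20,
                       energy_range = c(1250, 3000),
                       prop_missing_covariate = 0,
                       prop_short_diary = 0,
                       seed = 1L) {
  cfg <- list(
    n_people = as.integer(n_people), n_foods = as.integer(n_foods),
    n_days = as.integer(n_days),
    submarks_per_food = as.integer(submarks_per_food),
    transactions_per_submark = as.integer(transactions_per_submark),
    healthiness_price_slope = healthiness_price_slope,
    sacn_premiums = sacn_premiums, sacn_prevalence = sacn_prevalence,
    price_noise_sd = price_noise_sd, promo_fraction = promo_fraction,
    promo_discount = promo_discount, food_price_cv = food_price_cv,
    base_price_per_kcal = base_price_per_kcal,
    weight_dispersion = weight_dispersion,
    energy_mean = energy_mean, energy_cv = energy_cv,
    energy_range = energy_range,
    prop_missing_covariate = prop_missing_covariate,
    prop_short_diary = prop_short_diary,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` list.
#' @return `cfg`, invisibly, if valid; otherwise a configuration error
#'   naming the offending field.
#' @export
validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop_dietcost(sprintf("invalid sim_config field '%s': %s", field, why),
                  "dietcost_config_error")
  }
  for (f in c("n_people", "n_foods", "n_days")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) bad(f, "must be a count >= 1")
  }
  for (f in c("submarks_per_food", "transactions_per_submark")) {
    v <- cfg[[f]]
    if (length(v) != 2L || any(is.na(v)) || any(v < 1L) || v[1] > v[2])
      bad(f, "must be an integer range c(min, max) with min >= 1")
  }
  for (f in c("promo_fraction", "prop_missing_covariate", "prop_short_diary")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad(f, "must be a probability in [0, 1]")
  }
  if (cfg$promo_discount < 0 || cfg$promo_discount >= 1)
    bad("promo_discount", "must be in [0, 1)")
  for (f in c("price_noise_sd", "food_price_cv", "weight_dispersion"))
    if (cfg[[f]] < 0) bad(f, "must be non-negative")
  if (cfg$base_price_per_kcal <= 0)
    bad("base_price_per_kcal", "must be positive")
  ids <- sacn_ids()
  for (f in c("sacn_premiums", "sacn_prevalence")) {
    v <- cfg[[f]]
    if (!all(ids %in% names(v)))
      bad(f, paste("must be named with all of:", paste(ids, collapse = ", ")))
  }
  if (any(cfg$sacn_prevalence < 0 | cfg$sacn_prevalence > 1))
    bad("sacn_prevalence", "probabilities must lie in [0, 1]")
  if (cfg$energy_mean <= 0 || cfg$energy_cv < 0)
    bad("energy_mean", "energy_mean > 0 and energy_cv >= 0 required")
  if (length(cfg$energy_range) != 2L || cfg$energy_range[1] <= 0 ||
      cfg$energy_range[1] >= cfg$energy_range[2])
    bad("energy_range", "must be c(lo, hi) with 0 < lo < hi")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    bad("seed", "must be a single integer")
  invisible(cfg)
}

# Food-group reference table for the synthetic universe. Composition is per
# 100 g *as consumed*; cooking/edible fractions only convert purchase prices
# to as-consumed prices. `share` controls how many of n_foods land in each
# group (at least one each).
food_group_params <- function() {
  tibble::tribble(
    ~group,               ~share, ~energy, ~fat, ~satfat, ~nmes, ~fibre, ~salt, ~health, ~cf_lo, ~cf_hi, ~ef_lo, ~ef_hi,
    "fruit",                 1.6,     55,   0.3,    0.1,   0.5,    1.8,  0.01,    0.85,    1.0,    1.0,   0.70,   0.95,
    "vegetables",            1.6,     40,   0.4,    0.1,   0.2,    2.2,  0.05,    0.85,    0.90,   1.10,  0.75,   0.95,
    "nuts_legumes",          0.8,    420,  28.0,    4.5,   0.5,    6.0,  0.15,    0.80,    1.0,    1.0,   0.95,   1.0,
    "whole_grains",          1.0,    220,   2.0,    0.4,   0.5,    7.5,  0.45,    0.75,    1.0,    2.8,   1.0,    1.0,
    "lowfat_dairy",          0.8,     55,   1.6,    1.0,   0.0,    0.0,  0.13,    0.70,    1.0,    1.0,   1.0,    1.0,
    "oily_fish",             0.8,    190,  12.0,    2.8,   0.0,    0.0,  0.40,    0.80,    0.80,   1.0,   0.85,   1.0,
    "red_processed_meat",    1.2,    240,  15.0,    5.5,   0.0,    0.0,  1.30,    0.15,    0.70,   0.95,  0.85,   1.0,
    "confectionery",         1.0,    400,   9.0,    4.0,  52.0,    1.0,  0.30,    0.05,    1.0,    1.0,   1.0,    1.0,
    "staples",               1.6,    230,   1.8,    0.4,   1.5,    0.9,  0.50,    0.50,    1.0,    2.6,   1.0,    1.0,
    "butter_spreads",        0.5,    730,  80.0,   52.0,   0.0,    0.0,  1.60,    0.15,    1.0,    1.0,   1.0,    1.0,
    "oils",                  0.5,    880,  99.0,    6.0,   0.0,    0.0,  0.00,    0.50,    1.0,    1.0,   1.0,    1.0,
    "sauces_condiments",     0.6,     90,   3.0,    0.6,   5.0,    0.5,  5.50,    0.20,    1.0,    1.0,   1.0,    1.0)
}
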