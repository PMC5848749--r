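#' Generate the synthetic food universe
#'
#' Creates `n_foods` diary foods spread over twelve food groups, each with a
#' per-100 g (as consumed) composition for the nutrients the recommendations
#' score (energy, fat, saturated fat, NMES, fibre, salt), exactly one primary
#' food-group tag, DASH-component membership, a latent healthiness score in
#' `[0, 1]`, a mean as-consumed price, and the cooking/edible fractions used
#' to convert purchase prices to as-consumed prices.
#'
#' Baseline prices are proportional to energy density (a common pence/kcal
#' rate for every group), so that with `healthiness_price_slope = 0` diet
#' composition alone carries no isoenergetic cost signal; the healthiness
#' gradient and food-level price noise create the price structure the
#' analysis studies.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per food: `food_id`, `group`,
#'   `energy_kcal`, `fat_g`, `satfat_g`, `nmes_g`, `fibre_g`, `salt_g` (per
#'   100 g consumed), `dash_component` (or `NA`), `healthiness`,
#'   `cooking_fraction`, `edible_fraction`, `mean_price_consumed_p100g`,
#'   `mean_price_purchase_p100g`.
#' @export
gen_food_universe <- function(config) {
  validate_sim_config(config)
  gp <- food_group_params()
  n <- config$n_foods

  # allocate foods to groups: >= 1 each, remainder by share
  n_groups <- nrow(gp)
  if (n < n_groups)
    stop_dietcost(sprintf(
      "invalid sim_config field 'n_foods': need at least %d (one per food group)",
      n_groups), "dietcost_config_error")
  alloc <- rep(1L, n_groups)
  extra <- n - n_groups
  if (extra > 0) {
    pr <- gp$share / sum(gp$share)
    add <- floor(extra * pr)
    rem <- extra - sum(add)
    if (rem > 0) {
      ord <- order(extra * pr - add, decreasing = TRUE)
      add[ord[seq_len(rem)]] <- add[ord[seq_len(rem)]] + 1L
    }
    alloc <- alloc + as.integer(add)
  }

  with_substream(config$seed, "foods", {
    rows <- gp[rep(seq_len(n_groups), alloc), ]
    m <- nrow(rows)
    jit <- function(mu, cv) mu * exp(rnorm(m, 0, cv) - cv^2 / 2)
    foods <- tibble::tibble(
      food_id = sprintf("F%03d", seq_len(m)),
      group = rows$group,
      energy_kcal = jit(rows$energy, 0.04),
      fat_g = jit(rows$fat, 0.04),
      satfat_g = jit(rows$satfat, 0.04),
      nmes_g = jit(rows$nmes, 0.04),
      fibre_g = jit(rows$fibre, 0.04),
      salt_g = jit(rows$salt, 0.04),
      healthiness = pmin(1, pmax(0, rows$health + rnorm(m, 0, 0.08))),
      cooking_fraction = runif(m, rows$cf_lo, rows$cf_hi),
      edible_fraction = runif(m, rows$ef_lo, rows$ef_hi))
    foods$satfat_g <- pmin(foods$satfat_g, foods$fat_g)
    dash_map <- c(fruit = "fruit", vegetables = "vegetables",
                  nuts_legumes = "nuts_legumes", whole_grains = "whole_grains",
                  lowfat_dairy = "lowfat_dairy",
                  red_processed_meat = "red_processed_meat")
    foods$dash_component <- unname(dash_map[foods$group])
    # within-group price ladder: evenly spaced log-normal quantiles (plus a
    # little noise), so every group reliably offers cheap and premium
    # variants for the tilt mechanism to act on
    cv <- config$food_price_cv
    logq <- numeric(m)
    for (ix in split(seq_len(m), foods$group))
      logq[ix] <- sample(qnorm(ppoints(length(ix))))
    qual <- exp(cv * logq + rnorm(m, 0, cv / 8))
    # centre the ladder with energy weights so every group's untilted
    # (uniform-choice) price per kcal sits exactly on the baseline,
    # keeping isoenergetic diet cost flat across group mixes
    ew <- stats::ave(foods$energy_kcal * qual, foods$group) /
      stats::ave(foods$energy_kcal, foods$group)
    qual <- qual / ew
    price <- (foods$energy_kcal * config$base_price_per_kcal +
                config$healthiness_price_slope * (foods$healthiness - 0.5)) *
      qual
    foods$mean_price_consumed_p100g <- pmax(price, 4)
    foods$mean_price_purchase_p100g <- foods$mean_price_consumed_p100g *
      foods$cooking_fraction * foods$edible_fraction
    foods
  })
}
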