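# Shared fixtures, built in code at test time.

# tiny transaction table: prices chosen so per-100g prices are easy to
# verify by hand (unit weight 100 g => price_pence == pence per 100 g)
toy_transactions <- function(prices_by_submark) {
  dplyr::bind_rows(lapply(names(prices_by_submark), function(s)
    tibble::tibble(submark_id = s,
                   price_pence = prices_by_submark[[s]],
                   unit_weight_g = 100)))
}

toy_linkage <- function(food_id, submarks, cf = 1, ef = 1) {
  tibble::tibble(food_id = food_id,
                 submark_ids = paste(submarks, collapse = ";"),
                 cooking_fraction = cf, edible_fraction = ef)
}

# minimal composition table covering the columns the aggregator needs
toy_foods <- function(df) {
  defaults <- tibble::tibble(group = "staples", energy_kcal = 100,
                             fat_g = 0, satfat_g = 0, nmes_g = 0,
                             fibre_g = 0, salt_g = 0)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df
}

toy_prices <- function(food_id, price_consumed) {
  tibble::tibble(food_id = food_id,
                 price_per_100g_consumed = price_consumed,
                 price_per_100g_purchased = price_consumed)
}

# a complete person-totals row with every field at its SACN bound
totals_at_bounds <- function(n = 1) {
  tibble::tibble(
    person_id = sprintf("P%03d", seq_len(n)), n_diary_days = 4,
    energy_kcal = 2000, fat_g = 77.8, satfat_g = 24.4, nmes_g = 58.7,
    fibre_g = 18, salt_g = 6,
    fat_pct_energy = 35, satfat_pct_energy = 11, nmes_pct_energy = 11,
    fv_portions = 5, oily_fish_g = 20, red_processed_meat_g = 70,
    fruit_g = 200, veg_g = 200, nuts_legumes_g = 20, whole_grains_g = 100,
    lowfat_dairy_g = 150)
}

# small cached simulated world shared by read-only tests
.world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.world_cache$w)) {
    cfg <- sim_config(n_people = 150, seed = 42)
    .world_cache$w <- list(cfg = cfg, dat = simulate_dataset(cfg))
  }
  .world_cache$w
}
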