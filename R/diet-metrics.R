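#' Default SACN recommendation thresholds
#'
#' The eight food- and nutrient-based targets scored here, with standard UK
#' bounds: fruit and vegetables >= 5 portions/day (80 g/portion); oily fish
#' >= 20 g/day (one 140 g portion per week averaged over days); red and
#' processed meat <= 70 g/day; NMES <= 11 % of food energy; total fat
#' <= 35 % of food energy; saturated fat <= 11 % of food energy; fibre
#' >= 18 g/day; salt <= 6 g/day. Bounds are inclusive: an intake exactly at
#' the bound meets the target. A YAML copy ships in
#' `inst/extdata/sacn_thresholds.yaml` and can be edited and re-loaded.
#'
#' @param path Optional YAML file overriding the defaults (same fields).
#' @return Tibble: `id`, `field` (column of the person-totals table),
#'   `direction` (`"ge"` or `"le"`), `bound`, `unit`.
#' @export
sacn_thresholds <- function(path = NULL) {
  defaults <- tibble::tribble(
    ~id,                   ~field,                  ~direction, ~bound, ~unit,
    "fruit_veg",           "fv_portions",           "ge",        5,     "portions/day",
    "oily_fish",           "oily_fish_g",           "ge",        20,    "g/day",
    "red_processed_meat",  "red_processed_meat_g",  "le",        70,    "g/day",
    "nmes",                "nmes_pct_energy",       "le",        11,    "% food energy",
    "fat",                 "fat_pct_energy",        "le",        35,    "% food energy",
    "satfat",              "satfat_pct_energy",     "le",        11,    "% food energy",
    "fibre",               "fibre_g",               "ge",        18,    "g/day",
    "salt",                "salt_g",                "le",        6,     "g/day")
  if (is.null(path)) return(defaults)
  y <- yaml::read_yaml(path)
  for (nm in names(y)) {
    i <- match(nm, defaults$id)
    if (is.na(i))
      stop_dietcost(sprintf("unknown recommendation id in thresholds: %s", nm),
                    "dietcost_validation_error")
    if (!is.null(y[[nm]]$bound)) defaults$bound[i] <- y[[nm]]$bound
    if (!is.null(y[[nm]]$direction)) defaults$direction[i] <- y[[nm]]$direction
  }
  if (!all(defaults$direction %in% c("ge", "le")))
    stop_dietcost("threshold direction must be 'ge' or 'le'",
                  "dietcost_validation_error")
  defaults
}

#' Aggregate diaries into per-person intakes and diet cost
#'
#' Total diet cost is the sum over diary entries of grams eaten times the
#' food's as-consumed price per gram; dividing by diary days gives cost per
#' day, and `total cost / total kcal * 2000` gives the isoenergetic cost
#' per 2000 kcal. Nutrient intakes come from the composition table
#' (per 100 g as consumed). Persons with fewer than `min_days` diary days
#' are excluded, with the count reported via `attr(, "n_excluded_days")`
#' and a message.
#'
#' @param diaries Tibble `person_id`, `day`, `food_id`, `grams`.
#' @param foods Composition table (see [gen_food_universe()] for columns).
#' @param food_prices Tibble from [link_food_prices()].
#' @param min_days Minimum diary days for inclusion (default 3).
#' @return Person-totals tibble: diary days, daily energy and nutrients,
#'   percent-energy shares (food energy denominators), SACN food-group
#'   intakes, DASH component intakes, `cost_per_day` and
#'   `cost_per_2000kcal` (pence).
#' @export
aggregate_diary <- function(diaries, foods, food_prices, min_days = 3L) {
  miss_comp <- setdiff(unique(diaries$food_id), foods$food_id)
  if (length(miss_comp))
    stop_dietcost(sprintf("diary food(s) lacking composition: %s",
                          paste(miss_comp, collapse = ", ")),
                  "dietcost_linkage_error")
  miss_price <- setdiff(unique(diaries$food_id), food_prices$food_id)
  if (length(miss_price))
    stop_dietcost(sprintf("diary food(s) lacking a linked price: %s",
                          paste(miss_price, collapse = ", ")),
                  "dietcost_linkage_error")

  totals <- diary_nutrient_totals(diaries, foods)

  cost <- dplyr::left_join(
    diaries, food_prices[, c("food_id", "price_per_100g_consumed")],
    by = "food_id")
  percost <- dplyr::summarise(
    dplyr::group_by(cost, .data$person_id),
    cost_total = sum(.data$grams * .data$price_per_100g_consumed / 100),
    .groups = "drop")
  totals <- dplyr::left_join(totals, percost, by = "person_id")
  totals$cost_per_day <- totals$cost_total / totals$n_diary_days
  totals$cost_per_2000kcal <- totals$cost_total /
    (totals$energy_kcal * totals$n_diary_days) * 2000
  totals$cost_total <- NULL

  drop <- totals$n_diary_days < min_days
  if (any(drop))
    rlang::inform(sprintf(
      "aggregate_diary: excluded %d person(s) with fewer than %d diary days",
      sum(drop), min_days))
  out <- totals[!drop, ]
  attr(out, "n_excluded_days") <- sum(drop)
  out
}

#' Evaluate the eight SACN recommendations for each person
#'
#' Each recommendation is met when the person's intake satisfies the bound
#' in the stated direction; bounds are inclusive. The accordance count is
#' the number met (0-8) and the banded count collapses 6-8 as in the
#' reporting convention.
#'
#' @param totals Person-totals tibble from [aggregate_diary()].
#' @param thresholds Tibble from [sacn_thresholds()].
#' @return Tibble: `person_id`, eight `met_*` logicals,
#'   `accordance_count`, `banded_count` (factor `0,...,5,6-8`).
#' @export
evaluate_sacn <- function(totals, thresholds = sacn_thresholds()) {
  missing <- setdiff(thresholds$field, names(totals))
  if (length(missing))
    stop_dietcost(sprintf("totals lack required field(s): %s",
                          paste(missing, collapse = ", ")),
                  "dietcost_validation_error")
  out <- tibble::tibble(person_id = totals$person_id)
  for (i in seq_len(nrow(thresholds))) {
    v <- totals[[thresholds$field[i]]]
    if (anyNA(v))
      stop_dietcost(sprintf("missing values in field '%s'",
                            thresholds$field[i]),
                    "dietcost_validation_error")
    met <- if (thresholds$direction[i] == "ge") v >= thresholds$bound[i]
           else v <= thresholds$bound[i]
    out[[paste0("met_", thresholds$id[i])]] <- met
  }
  out$accordance_count <- rowSums(as.matrix(out[, paste0("met_",
                                                         thresholds$id)]))
  out$banded_count <- band_accordance(out$accordance_count)
  out
}

#' Collapse an accordance count into reporting bands
#'
#' Bands `0, 1, 2, 3, 4, 5, 6-8` partition the 0-8 range exactly.
#'
#' @param count Integer vector of accordance counts.
#' @param collapse_from First count absorbed into the top band (default 6).
#' @return Factor with one level per band.
#' @export
band_accordance <- function(count, collapse_from = 6L) {
  top <- paste0(collapse_from, "-8")
  lv <- c(as.character(seq(0L, collapse_from - 1L)), top)
  factor(ifelse(count >= collapse_from, top, as.character(count)),
         levels = lv)
}

#' Residual-method energy adjustment
#'
#' Regresses an intake on total energy by least squares and returns the
#' residual plus the predicted intake at the sample mean energy. The
#' adjusted intake has zero sample correlation with energy and the same
#' mean as the input, isolating diet composition from diet quantity.
#'
#' @param values Intake vector.
#' @param energies Energy vector (kcal), same length, not all equal.
#' @return Adjusted intake vector.
#' @export
residual_energy_adjust <- function(values, energies) {
  if (length(values) != length(energies) || length(values) < 3)
    stop_dietcost("need aligned vectors of length >= 3",
                  "dietcost_validation_error")
  ve <- stats::var(energies)
  if (ve == 0)
    stop_dietcost("energy vector is constant; adjustment is degenerate",
                  "dietcost_degenerate_fit_error")
  slope <- stats::cov(values, energies) / ve
  values - slope * (energies - mean(energies))
}

#' Rank-based quintile assignment
#'
#' Assigns fifths 1 (lowest) to 5 (highest). A tie group shares the
#' quintile determined by the proportion of strictly smaller observations
#' (`floor(5 * frac_below) + 1`), so all-equal input is assigned quintile 1
#' and group sizes differ by at most 1 when no ties straddle a boundary.
#'
#' @param values Numeric vector, length >= 5.
#' @return Integer vector of scores 1-5.
#' @export
assign_quintiles <- function(values) {
  n <- length(values)
  if (n < 5)
    stop_dietcost("need at least 5 observations to form quintiles",
                  "dietcost_validation_error")
  if (anyNA(values))
    stop_dietcost("missing values in quintile input",
                  "dietcost_validation_error")
  frac_below <- (rank(values, ties.method = "min") - 1) / n
  pmin(floor(5 * frac_below) + 1, 5)
}

#' DASH accordance score (Fung-style, NMES for sugary drinks)
#'
#' For each of eight components — five encouraged (fruit, vegetables, nuts
#' and legumes, whole grains, low-fat dairy) and three discouraged (red and
#' processed meat, salt, NMES) — intake is energy-adjusted by the residual
#' method, the population is cut into quintiles, and the quintile (1-5) is
#' the component score; discouraged components are reverse-scored
#' (`6 - quintile`). The DASH score is the sum, range 8-40; the population
#' is then classed into quintiles of the score itself (or fixed cuts).
#'
#' @param totals Person-totals tibble from [aggregate_diary()].
#' @param fixed_cuts Optional increasing numeric cut points (length 4)
#'   classing scores into the five accordance groups instead of realised
#'   population quintiles.
#' @return Tibble: `person_id`, eight `score_*` columns, `dash_score`,
#'   `dash_quintile`.
#' @export
dash_score <- function(totals, fixed_cuts = NULL) {
  if (nrow(totals) < 5)
    stop_dietcost("need at least 5 persons to score DASH accordance",
                  "dietcost_validation_error")
  comps <- dash_components()
  out <- tibble::tibble(person_id = totals$person_id)
  score_mat <- matrix(0L, nrow(totals), nrow(comps))
  for (i in seq_len(nrow(comps))) {
    adj <- residual_energy_adjust(totals[[comps$field[i]]],
                                  totals$energy_kcal)
    q <- assign_quintiles(adj)
    s <- if (comps$encouraged[i]) q else 6L - q
    score_mat[, i] <- s
    out[[paste0("score_", comps$component[i])]] <- s
  }
  out$dash_score <- rowSums(score_mat)
  out$dash_quintile <- if (is.null(fixed_cuts))
    assign_quintiles(out$dash_score)
  else {
    if (length(fixed_cuts) != 4 || is.unsorted(fixed_cuts))
      stop_dietcost("fixed_cuts must be 4 increasing cut points",
                    "dietcost_validation_error")
    as.integer(findInterval(out$dash_score, fixed_cuts) + 1L)
  }
  out
}

#' DASH component definitions
#'
#' @return Tibble: `component`, `field` (person-totals column),
#'   `encouraged` (logical; discouraged components are reverse-scored).
#' @export
dash_components <- function() {
  tibble::tribble(
    ~component,            ~field,                  ~encouraged,
    "fruit",               "fruit_g",               TRUE,
    "vegetables",          "veg_g",                 TRUE,
    "nuts_legumes",        "nuts_legumes_g",        TRUE,
    "whole_grains",        "whole_grains_g",        TRUE,
    "lowfat_dairy",        "lowfat_dairy_g",        TRUE,
    "red_processed_meat",  "red_processed_meat_g",  FALSE,
    "salt",                "salt_g",                FALSE,
    "nmes",                "nmes_g",                FALSE)
}
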