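#' Generate the synthetic price-transaction panel and linkage key
#'
#' Each food is matched one-to-many to several generic products ("sub
#' marks"); each sub mark accrues many scanner transactions over the year.
#' A transaction records the price paid (pence) for one unit and the unit
#' weight (g). Prices vary between sub marks of a food (multiplicative
#' offset), between transactions (additive noise of sd `price_noise_sd`),
#' and a `promo_fraction` of transactions are recorded at a promotional
#' discount, mirroring a till-scanner panel that keeps every occurrence of
#' every price paid.
#'
#' @param foods Food universe from [gen_food_universe()].
#' @param config The same [sim_config()].
#' @return A list with `transactions` (tibble: `submark_id`, `price_pence`,
#'   `unit_weight_g`) and `linkage` (tibble: `food_id`, `submark_ids`
#'   semicolon-joined, `cooking_fraction`, `edible_fraction`).
#' @export
gen_price_panel <- function(foods, config) {
  validate_sim_config(config)
  if (nrow(foods) == 0)
    stop_dietcost("foods table is empty", "dietcost_generation_error")

  with_substream(config$seed, "prices", {
    smf <- config$submarks_per_food
    n_sub <- if (smf[1] == smf[2]) rep(smf[1], nrow(foods)) else
      sample(seq(smf[1], smf[2]), nrow(foods), replace = TRUE)
    sub <- tibble::tibble(
      food_id = rep(foods$food_id, n_sub),
      submark_id = sprintf("S%05d", seq_len(sum(n_sub))),
      base_purchase_p100g = rep(foods$mean_price_purchase_p100g, n_sub) *
        exp(rnorm(sum(n_sub), 0, 0.015)),
      unit_weight_g = round(runif(sum(n_sub), 100, 1000)))

    tps <- config$transactions_per_submark
    n_tr <- if (tps[1] == tps[2]) rep(tps[1], nrow(sub)) else
      sample(seq(tps[1], tps[2]), nrow(sub), replace = TRUE)
    idx <- rep(seq_len(nrow(sub)), n_tr)
    base_price <- sub$base_purchase_p100g[idx] * sub$unit_weight_g[idx] / 100
    # promotional transactions sit well below the regular price, so the
    # median of all recorded prices is the (0.5 - pf)/(1 - pf) quantile of
    # the regular-price branch; offset the regular price so the measured
    # median reproduces the assigned price
    pf <- config$promo_fraction
    comp <- if (pf < 0.5) -qnorm((0.5 - pf) / (1 - pf)) * config$price_noise_sd
            else 0
    price <- base_price + comp + rnorm(length(idx), 0, config$price_noise_sd)
    promo <- runif(length(idx)) < config$promo_fraction
    price[promo] <- price[promo] * (1 - config$promo_discount)
    transactions <- tibble::tibble(
      submark_id = sub$submark_id[idx],
      price_pence = pmax(1, round(price)),
      unit_weight_g = sub$unit_weight_g[idx])

    linkage <- dplyr::summarise(
      dplyr::group_by(sub, .data$food_id),
      submark_ids = paste(.data$submark_id, collapse = ";"),
      .groups = "drop")
    linkage <- dplyr::left_join(
      linkage,
      foods[, c("food_id", "cooking_fraction", "edible_fraction")],
      by = "food_id")
    list(transactions = transactions, linkage = linkage)
  })
}
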