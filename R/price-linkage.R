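#' Price per 100 g of a transaction
#'
#' @param price_paid Price paid for the unit, pence.
#' @param unit_weight Unit weight, grams.
#' @return Pence per 100 g: `price_paid / unit_weight * 100`. Vectorised.
#' @export
price_per_100g <- function(price_paid, unit_weight) {
  bad <- which(!(price_paid > 0) | !(unit_weight > 0))
  if (length(bad))
    stop_dietcost(sprintf(
      "non-positive price or unit weight in transaction(s): %s",
      paste(utils::head(bad, 10), collapse = ", ")),
      "dietcost_validation_error")
  price_paid / unit_weight * 100
}

#' Median price per 100 g for each product sub mark
#'
#' Converts every transaction to a per-100 g price and takes, per sub mark,
#' the median over the full distribution of recorded prices — duplicates
#' retained, so the same price paid many times counts many times. Even
#' counts use the midpoint of the two central order statistics.
#'
#' @param transactions Tibble with `submark_id`, `price_pence`,
#'   `unit_weight_g` (one row per transaction).
#' @return Named numeric vector: sub mark id -> median pence per 100 g.
#' @export
submark_median_prices <- function(transactions) {
  if (nrow(transactions) == 0)
    stop_dietcost("no transactions supplied", "dietcost_linkage_error")
  p100 <- price_per_100g(transactions$price_pence,
                         transactions$unit_weight_g)
  out <- tapply(p100, transactions$submark_id, stats::median)
  setNames(as.numeric(out), names(out))
}

#' Link sub-mark prices to diary foods (median of medians)
#'
#' Each diary food is matched one-to-many to product sub marks; its
#' purchased price per 100 g is the median of the matched sub-mark medians.
#' The as-consumed price divides by `cooking_fraction * edible_fraction`
#' (cooking fraction = cooked/raw weight), so foods that lose weight in
#' preparation or have inedible portions cost more per 100 g eaten.
#'
#' @param linkage Tibble with `food_id`, `submark_ids` (semicolon-joined
#'   or a list-column of character vectors), `cooking_fraction`,
#'   `edible_fraction`.
#' @param submark_prices Named vector from [submark_median_prices()].
#' @return Tibble: `food_id`, `price_per_100g_purchased`,
#'   `price_per_100g_consumed` (pence).
#' @export
link_food_prices <- function(linkage, submark_prices) {
  subs <- linkage$submark_ids
  if (!is.list(subs)) subs <- strsplit(as.character(subs), ";", fixed = TRUE)
  empty <- lengths(subs) == 0 | vapply(subs, function(s)
    all(!nzchar(s)), logical(1))
  if (any(empty))
    stop_dietcost(sprintf("food(s) with no matched sub marks: %s",
                          paste(linkage$food_id[empty], collapse = ", ")),
                  "dietcost_validation_error")
  missing <- setdiff(unique(unlist(subs)), names(submark_prices))
  if (length(missing))
    stop_dietcost(sprintf("sub mark(s) missing from price table: %s",
                          paste(missing, collapse = ", ")),
                  "dietcost_linkage_error")
  cf <- linkage$cooking_fraction
  ef <- linkage$edible_fraction
  if (any(!(cf > 0)) || any(!(ef > 0 & ef <= 1)))
    stop_dietcost(
      "cooking_fraction must be > 0 and edible_fraction in (0, 1]",
      "dietcost_validation_error")
  purchased <- vapply(subs, function(s) stats::median(submark_prices[s]),
                      numeric(1))
  tibble::tibble(
    food_id = linkage$food_id,
    price_per_100g_purchased = purchased,
    price_per_100g_consumed = purchased / (cf * ef))
}
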