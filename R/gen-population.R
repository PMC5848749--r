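# Lever groups used to hit per-person nutrient targets (one dominant
# nutrient each; staples fill the energy budget), and fixed groups whose
# grams are drawn directly from the adherence targets.
.lever_groups <- c("confectionery", "butter_spreads", "oils",
                   "whole_grains", "sauces_condiments", "staples")
.fixed_groups <- c("fruit", "vegetables", "nuts_legumes", "lowfat_dairy",
                   "oily_fish", "red_processed_meat")

# kcal per gram of nutrient (UK convention); NMES as carbohydrate
.kcal_per_g <- c(fat = 9, satfat = 9, nmes = 3.75)

#' Generate the synthetic population, diaries and ground truth
#'
#' Draws covariates (age, sex, occupational class), log-normal survey
#' weights renormalised to mean 1, a latent Bernoulli adherence indicator
#' per person per recommendation, and a 4-day food diary whose intakes put
#' each person on the intended side of each recommendation threshold.
#'
#' Cost premiums are injected by exponentially tilting each person's food
#' choice within food groups toward higher-priced foods: the tilt is
#' calibrated (by inverting the person's expected-cost curve on a grid) so
#' that meeting a set of recommendations carries the sum of the configured
#' premiums, in pence per 2000 kcal, in expectation. Because baseline
#' prices are proportional to energy density, no premium flows through
#' group mix itself.
#'
#' @param foods Food universe from [gen_food_universe()].
#' @param config The same [sim_config()].
#' @param food_prices Optional linked prices (tibble with `food_id`,
#'   `price_per_100g_consumed`, as from [link_food_prices()]); when given,
#'   the premium tilt is calibrated against these measured prices rather
#'   than the generator's assigned means, so premiums are carried on the
#'   cost scale the analysis will actually observe.
#' @return A list: `covariates` (tibble with `person_id`, `age`, `sex`,
#'   `nssec`, `weight`), `weights` (numeric vector, mean 1), `diaries`
#'   (tibble `person_id`, `day`, `food_id`, `grams`), and `ground_truth`
#'   (tibble with intended and realized adherence per recommendation, the
#'   tilt parameter and expected cost; premiums attached as attribute
#'   `premiums`).
#' @export
gen_population_and_diaries <- function(foods, config, food_prices = NULL) {
  validate_sim_config(config)
  if (!all(c(.lever_groups, .fixed_groups) %in% foods$group))
    stop_dietcost(
      "food universe lacks one or more required food groups; cannot realise premiums",
      "dietcost_generation_error")
  foods$price_basis <- foods$mean_price_consumed_p100g
  if (!is.null(food_prices)) {
    i <- match(foods$food_id, food_prices$food_id)
    if (anyNA(i))
      stop_dietcost("food_prices must cover every food in the universe",
                    "dietcost_generation_error")
    foods$price_basis <- food_prices$price_per_100g_consumed[i]
  }
  n <- config$n_people
  ids <- sacn_ids()

  cov <- with_substream(config$seed, "population", {
    w <- rlnorm(n, 0, sqrt(log(1 + config$weight_dispersion^2)))
    w <- w / mean(w)
    nssec_levels <- c("higher_managerial", "intermediate", "routine_manual",
                      "never_worked")
    tibble::tibble(
      person_id = sprintf("P%05d", seq_len(n)),
      age = floor(runif(n, 19, 97)),
      sex = ifelse(runif(n) < 0.435, "male", "female"),
      nssec = sample(nssec_levels, n, replace = TRUE,
                     prob = c(0.34, 0.22, 0.36, 0.08)),
      weight = w,
      short_diary = runif(n) < config$prop_short_diary,
      missing_cov = runif(n) < config$prop_missing_covariate)
  })
  cov$nssec[cov$missing_cov] <- NA_character_

  adhere <- with_substream(config$seed, "adherence", {
    m <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
    for (id in ids) m[, id] <- rbinom(n, 1L, config$sacn_prevalence[[id]])
    m
  })

  sim <- with_substream(config$seed, "diaries",
                        build_diaries(foods, config, adhere))

  # realized per-person intakes and adherence, from the diary itself
  totals <- diary_nutrient_totals(sim$diaries, foods)
  realized <- evaluate_sacn(totals, sacn_thresholds())
  realized <- realized[match(cov$person_id, realized$person_id), ]

  if (config$prop_short_diary > 0) {
    keep_days <- ifelse(cov$short_diary[match(sim$diaries$person_id,
                                              cov$person_id)],
                        min(2L, config$n_days), config$n_days)
    sim$diaries <- sim$diaries[sim$diaries$day <= keep_days, ]
  }

  gt <- tibble::tibble(person_id = cov$person_id)
  for (id in ids) gt[[paste0("intended_", id)]] <- adhere[, id]
  for (id in ids) gt[[paste0("realized_", id)]] <-
    as.integer(realized[[paste0("met_", id)]])
  gt$theta <- sim$theta
  gt$expected_cost_per_2000kcal <- sim$expected_cost
  attr(gt, "premiums") <- config$sacn_premiums

  list(covariates = cov[, c("person_id", "age", "sex", "nssec", "weight")],
       weights = cov$weight, diaries = sim$diaries, ground_truth = gt)
}

# Draw per-person intake targets, solve lever grams, calibrate the price
# tilt and expand to diary entries. Runs inside the "diaries" substream.
build_diaries <- function(foods, config, adhere) {
  n <- nrow(adhere)
  A <- function(id) adhere[, id] == 1L

  sdlog <- sqrt(log(1 + config$energy_cv^2))
  energy <- rlnorm(n, log(config$energy_mean) - sdlog^2 / 2, sdlog)
  energy <- pmin(pmax(energy, config$energy_range[1]), config$energy_range[2])
  esc <- pmin(1.3, energy / 1840)  # scale bulky meats/fish with appetite

  fv_port <- ifelse(A("fruit_veg"), runif(n, 5.15, 8.5), runif(n, 1.2, 4.8))
  fruit_frac <- runif(n, 0.35, 0.55)
  fish <- ifelse(A("oily_fish"), runif(n, 20.5, 55),
                 ifelse(runif(n) < 0.65, 0, runif(n, 0, 18)))
  rpm <- ifelse(A("red_processed_meat"), runif(n, 5, 67),
                74 + runif(n, 0, 96) * esc)
  nuts <- ifelse(runif(n) < 0.30, 0, runif(n, 2, 35))
  dairy <- runif(n, 40, 280)

  s_nmes <- ifelse(A("nmes"), runif(n, 0.055, 0.104), runif(n, 0.122, 0.19))
  s_sat <- ifelse(A("satfat"), runif(n, 0.075, 0.101), runif(n, 0.121, 0.155))
  s_fat <- ifelse(A("fat"), runif(n, 0.27, 0.34), runif(n, 0.37, 0.45))
  # keep the saturated/total fat ratio where a butter/oil mix can realise
  # it; the clamp never leaves the adherence band of either share
  s_fat <- pmin(pmax(s_fat, s_sat / 0.48), s_sat / 0.13)
  fibre_t <- ifelse(A("fibre"), runif(n, 18.3, 30), runif(n, 9.5, 17.5))
  salt_t <- ifelse(A("salt"), runif(n, 3.2, 5.8), runif(n, 6.3, 9.5))

  # group-mean composition (per gram) for the lever solve
  comp_cols <- c("energy_kcal", "fat_g", "satfat_g", "nmes_g", "fibre_g",
                 "salt_g")
  gm <- dplyr::summarise(dplyr::group_by(foods, .data$group),
                         dplyr::across(dplyr::all_of(comp_cols), mean),
                         .groups = "drop")
  gmat <- as.matrix(gm[, comp_cols]) / 100  # per-gram
  rownames(gmat) <- gm$group

  fixed_g <- cbind(fruit = 80 * fv_port * fruit_frac,
                   vegetables = 80 * fv_port * (1 - fruit_frac),
                   nuts_legumes = nuts, lowfat_dairy = dairy,
                   oily_fish = fish, red_processed_meat = rpm)
  # keep fixed foods within ~60 % of the energy budget by shrinking the
  # unconstrained bulky items (dairy, nuts), so the lever solve stays
  # feasible for small eaters
  e_g <- gmat[colnames(fixed_g), "energy_kcal"]
  fixed_e <- as.numeric(fixed_g %*% e_g)
  flex_e <- fixed_g[, "lowfat_dairy"] * e_g[["lowfat_dairy"]] +
    fixed_g[, "nuts_legumes"] * e_g[["nuts_legumes"]]
  over <- fixed_e - 0.60 * energy
  shrink <- pmax(0.1, pmin(1, 1 - over / pmax(flex_e, 1e-9)))
  fixed_g[, "lowfat_dairy"] <- fixed_g[, "lowfat_dairy"] * shrink
  fixed_g[, "nuts_legumes"] <- fixed_g[, "nuts_legumes"] * shrink
  fixed_nutr <- fixed_g %*% gmat[colnames(fixed_g), ]  # n x 6

  # solve lever grams for the nutrient targets; when a small eater's fixed
  # foods force the energy above target (staples lever at zero), raise the
  # person's energy to the realised floor and re-derive the share-based
  # gram targets, so percent-energy intakes stay on the intended side of
  # their thresholds
  lever_mat <- t(gmat[.lever_groups,
                      c("energy_kcal", "fat_g", "satfat_g", "nmes_g",
                        "fibre_g", "salt_g")])  # 6 nutrients x 6 levers
  for (pass in 1:4) {
    targets <- cbind(
      energy_kcal = energy,
      fat_g = s_fat * energy / .kcal_per_g[["fat"]],
      satfat_g = s_sat * energy / .kcal_per_g[["satfat"]],
      nmes_g = s_nmes * energy / .kcal_per_g[["nmes"]],
      fibre_g = fibre_t,
      salt_g = salt_t)
    b <- targets - fixed_nutr[, colnames(targets)]
    x <- solve_levers(lever_mat, b)  # n x 6 levers
    e_real <- fixed_nutr[, "energy_kcal"] +
      as.numeric(x %*% lever_mat["energy_kcal", ])
    over <- e_real > energy * 1.005
    if (!any(over)) break
    energy[over] <- e_real[over]
  }

  grams <- matrix(0, n, length(c(.fixed_groups, .lever_groups)),
                  dimnames = list(NULL, c(.fixed_groups, .lever_groups)))
  grams[, colnames(fixed_g)] <- fixed_g
  grams[, .lever_groups] <- x

  tilt <- calibrate_tilt(foods, grams, energy,
                         as.numeric(adhere %*%
                                      config$sacn_premiums[colnames(adhere)]))

  # expand to diary entries: per group, a tilted food choice per person-day
  groups <- colnames(grams)
  n_days <- config$n_days
  fac <- matrix(rgamma(n * n_days, 25, 25), n, n_days)
  fac <- fac / rowMeans(fac)
  entries <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    sel <- which(grams[, g] > 0.05)
    if (!length(sel)) next
    fg <- foods[foods$group == g, ]
    z <- scale_or_zero(fg$price_basis / fg$energy_kcal)
    pw <- exp(outer(tilt$theta[sel], z))
    pw <- pw / rowSums(pw)
    cum <- pw %*% upper.tri(diag(ncol(pw)), diag = TRUE)
    picks <- matrix(0L, length(sel), n_days)
    for (d in seq_len(n_days)) {
      u <- runif(length(sel))
      picks[, d] <- 1L + as.integer(rowSums(cum < u))
    }
    entries[[gi]] <- tibble::tibble(
      person_id = rep(sprintf("P%05d", sel), n_days),
      day = rep(seq_len(n_days), each = length(sel)),
      food_id = fg$food_id[as.vector(picks)],
      grams = round(as.vector(grams[sel, g] * fac[sel, ]), 1))
  }
  diaries <- dplyr::arrange(dplyr::bind_rows(entries), .data$person_id,
                            .data$day, .data$food_id)
  diaries <- diaries[diaries$grams > 0, ]

  list(diaries = diaries, theta = tilt$theta,
       expected_cost = tilt$expected_cost)
}

# Solve lever grams against nutrient targets with non-negativity. Each
# lever owns one equation (confectionery-NMES, butter-satfat, oils-fat,
# whole grains-fibre, sauces-salt, staples-energy); when a lever would go
# negative it is removed together with its equation (that nutrient then
# floats at its feasible boundary) and the reduced system is re-solved.
solve_levers <- function(lever_mat, b) {
  pair <- c(confectionery = "nmes_g", butter_spreads = "satfat_g",
            oils = "fat_g", whole_grains = "fibre_g",
            sauces_condiments = "salt_g", staples = "energy_kcal")
  levers <- colnames(lever_mat)
  x <- t(solve(lever_mat, t(b)))
  colnames(x) <- levers
  dropped <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  for (iter in seq_len(length(levers))) {
    new_neg <- x < -1e-9 & !dropped
    if (!any(new_neg)) break
    dropped <- dropped | new_neg
    pat <- apply(dropped, 1, function(r) paste(which(r), collapse = ","))
    for (p in setdiff(unique(pat), "")) {
      rows <- which(pat == p)
      drop_ix <- as.integer(strsplit(p, ",")[[1]])
      x[rows, ] <- 0
      if (length(drop_ix) == length(levers)) next
      keep_lv <- levers[-drop_ix]
      keep_eq <- setdiff(colnames(b), pair[levers[drop_ix]])
      sub <- lever_mat[keep_eq, keep_lv, drop = FALSE]
      x[rows, keep_lv] <- t(solve(sub, t(b[rows, keep_eq, drop = FALSE])))
    }
  }
  x[x < 0] <- 0
  x
}

scale_or_zero <- function(x) {
  if (length(x) < 2 || stats::sd(x) == 0) return(rep(0, length(x)))
  as.numeric(scale(x))
}

# Invert each person's expected cost-per-2000kcal curve in the tilt
# parameter so the configured total premium is carried in expectation.
# The curve is the ratio of expected diary cost to expected diary energy
# under tilted within-group food choice, so selecting pricier (per kcal)
# foods does not distort the energy denominator.
calibrate_tilt <- function(foods, grams, energy, premium_total) {
  theta_grid <- seq(-8, 8, by = 0.02)
  groups <- colnames(grams)
  Mp <- Me <- matrix(0, length(groups), length(theta_grid),
                     dimnames = list(groups, NULL))
  for (g in groups) {
    fg <- foods[foods$group == g, ]
    z <- scale_or_zero(fg$price_basis / fg$energy_kcal)
    wgt <- exp(outer(z, theta_grid))
    Mp[g, ] <- colSums(wgt * fg$price_basis) / colSums(wgt)
    Me[g, ] <- colSums(wgt * fg$energy_kcal) / colSums(wgt)
  }
  G <- grams[, groups, drop = FALSE]
  c2k <- 2000 * (G %*% Mp) / (G %*% Me)
  i0 <- which(theta_grid == 0)
  d <- c2k - c2k[, i0]
  n <- nrow(grams)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    p <- premium_total[i]
    if (p == 0) next
    di <- d[i, ]
    if (p < di[1] || p > di[length(di)])
      stop_dietcost(sprintf(
        "infeasible premium combination: person %d needs %+.1f p/2000 kcal, attainable range [%.1f, %.1f]",
        i, p, di[1], di[length(di)]), "dietcost_generation_error")
    j <- findInterval(p, di)
    j <- min(max(j, 1L), length(di) - 1L)
    frac <- if (di[j + 1] > di[j]) (p - di[j]) / (di[j + 1] - di[j]) else 0
    theta[i] <- theta_grid[j] + frac * 0.02
  }
  # expected cost at the calibrated tilt (linear interpolation on the grid)
  j <- findInterval(theta, theta_grid)
  j <- pmin(pmax(j, 1L), length(theta_grid) - 1L)
  frac <- (theta - theta_grid[j]) / 0.02
  ec <- c2k[cbind(seq_len(n), j)] * (1 - frac) +
    c2k[cbind(seq_len(n), j + 1L)] * frac
  list(theta = theta, expected_cost = ec)
}

# Per-person nutrient totals straight from a diary (no prices); used by the
# generator to record realized adherence and by aggregate_diary().
diary_nutrient_totals <- function(diaries, foods) {
  d <- dplyr::left_join(diaries, foods, by = "food_id")
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$person_id),
    n_diary_days = dplyr::n_distinct(.data$day),
    energy_total = sum(.data$grams * .data$energy_kcal / 100),
    fat_total = sum(.data$grams * .data$fat_g / 100),
    satfat_total = sum(.data$grams * .data$satfat_g / 100),
    nmes_total = sum(.data$grams * .data$nmes_g / 100),
    fibre_total = sum(.data$grams * .data$fibre_g / 100),
    salt_total = sum(.data$grams * .data$salt_g / 100),
    fruit_total = sum(.data$grams[.data$group == "fruit"]),
    veg_total = sum(.data$grams[.data$group == "vegetables"]),
    nuts_total = sum(.data$grams[.data$group == "nuts_legumes"]),
    wgrain_total = sum(.data$grams[.data$group == "whole_grains"]),
    dairy_total = sum(.data$grams[.data$group == "lowfat_dairy"]),
    fish_total = sum(.data$grams[.data$group == "oily_fish"]),
    rpm_total = sum(.data$grams[.data$group == "red_processed_meat"]),
    .groups = "drop")
  nd <- per$n_diary_days
  tibble::tibble(
    person_id = per$person_id,
    n_diary_days = nd,
    energy_kcal = per$energy_total / nd,
    fat_g = per$fat_total / nd,
    satfat_g = per$satfat_total / nd,
    nmes_g = per$nmes_total / nd,
    fibre_g = per$fibre_total / nd,
    salt_g = per$salt_total / nd,
    fat_pct_energy = 100 * .kcal_per_g[["fat"]] * per$fat_total /
      per$energy_total,
    satfat_pct_energy = 100 * .kcal_per_g[["satfat"]] * per$satfat_total /
      per$energy_total,
    nmes_pct_energy = 100 * .kcal_per_g[["nmes"]] * per$nmes_total /
      per$energy_total,
    fv_portions = (per$fruit_total + per$veg_total) / 80 / nd,
    oily_fish_g = per$fish_total / nd,
    red_processed_meat_g = per$rpm_total / nd,
    fruit_g = per$fruit_total / nd,
    veg_g = per$veg_total / nd,
    nuts_legumes_g = per$nuts_total / nd,
    whole_grains_g = per$wgrain_total / nd,
    lowfat_dairy_g = per$dairy_total / nd)
}
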