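test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_foods = 0), "n_foods",
               class = "dietcost_config_error")
  expect_error(sim_config(promo_fraction = 1.5), "promo_fraction",
               class = "dietcost_config_error")
  expect_error(sim_config(sacn_premiums = c(fat = 10)), "sacn_premiums",
               class = "dietcost_config_error")
  expect_error(sim_config(submarks_per_food = c(4, 2)), "submarks_per_food",
               class = "dietcost_config_error")
})

test_that("the food universe honours its contract and is deterministic", {
  cfg <- sim_config(n_foods = 50, seed = 1)
  foods <- gen_food_universe(cfg)
  expect_equal(nrow(foods), 50)
  expect_true(all(foods$energy_kcal > 0))
  expect_true(all(foods$fat_g >= 0 & foods$fibre_g >= 0 & foods$salt_g >= 0))
  expect_true(all(table(foods$food_id) == 1))
  expect_true(all(foods$healthiness >= 0 & foods$healthiness <= 1))
  expect_true(all(foods$cooking_fraction > 0))
  expect_true(all(foods$edible_fraction > 0 & foods$edible_fraction <= 1))
  expect_identical(foods, gen_food_universe(cfg))
})

test_that("with a zero price slope healthiness carries no price signal", {
  cfg <- sim_config(n_foods = 500, seed = 2, healthiness_price_slope = 0)
  foods <- gen_food_universe(cfg)
  # prices are proportional to energy density by design, so the relevant
  # null is on the isoenergetic (per kcal) scale
  r <- stats::cor(foods$healthiness,
                  foods$mean_price_consumed_p100g / foods$energy_kcal)
  expect_lt(abs(r), 0.1)
})

test_that("the price panel respects its degenerate and fixed-count contracts", {
  cfg <- sim_config(n_people = 10, n_foods = 24, seed = 3,
                    promo_fraction = 0, price_noise_sd = 0,
                    submarks_per_food = c(3, 3))
  foods <- gen_food_universe(cfg)
  panel <- gen_price_panel(foods, cfg)
  expect_true(all(panel$transactions$price_pence > 0))
  expect_true(all(panel$transactions$unit_weight_g > 0))
  # every sub mark trades at a single price when noise and promos are off
  spread <- tapply(panel$transactions$price_pence,
                   panel$transactions$submark_id,
                   function(p) diff(range(p)))
  expect_true(all(spread == 0))
  # fixed 3 sub marks per food
  expect_true(all(lengths(strsplit(panel$linkage$submark_ids, ";")) == 3))
  # every linked sub mark has transactions
  expect_true(all(unlist(strsplit(panel$linkage$submark_ids, ";")) %in%
                    panel$transactions$submark_id))
  expect_identical(panel, gen_price_panel(foods, cfg))
})

test_that("population, weights and diaries honour their contracts", {
  w <- small_world()
  cov <- w$dat$covariates
  expect_equal(nrow(cov), w$cfg$n_people)
  expect_true(all(cov$age >= 19 & cov$age <= 96))
  expect_true(all(cov$sex %in% c("male", "female")))
  expect_equal(sort(unique(cov$nssec)),
               sort(c("higher_managerial", "intermediate", "never_worked",
                      "routine_manual")))
  expect_true(all(cov$weight > 0))
  expect_equal(mean(cov$weight), 1, tolerance = 1e-12)
  days <- tapply(w$dat$diaries$day, w$dat$diaries$person_id,
                 function(d) length(unique(d)))
  expect_true(all(days == w$cfg$n_days))
  expect_true(all(w$dat$diaries$grams > 0))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_people = 60, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  for (nm in c("foods", "transactions", "linkage", "covariates", "diaries"))
    expect_identical(d1[[nm]], d2[[nm]])
  expect_equal(d1$ground_truth, d2$ground_truth)
})

test_that("zero prevalence yields diaries meeting no recommendation", {
  prev <- setNames(rep(0, 8), sacn_ids())
  cfg <- sim_config(n_people = 200, seed = 5, sacn_prevalence = prev)
  dat <- simulate_dataset(cfg)
  fp <- link_food_prices(dat$linkage,
                         submark_median_prices(dat$transactions))
  tot <- aggregate_diary(dat$diaries, dat$foods, fp)
  prof <- evaluate_sacn(tot)
  expect_true(all(prof$accordance_count == 0))
})

test_that("the analytic sample size of the emulated survey is reproduced", {
  cfg <- sim_config(n_people = 2045, seed = 12)
  foods <- gen_food_universe(cfg)
  pop <- gen_population_and_diaries(foods, cfg)
  days <- tapply(pop$diaries$day, pop$diaries$person_id,
                 function(d) length(unique(d)))
  expect_equal(length(days), 2045)
  expect_true(all(days >= 3))
})

test_that("zero premiums produce a met-vs-not difference compatible with zero", {
  prem <- setNames(rep(0, 8), sacn_ids())
  cfg <- sim_config(n_people = 2000, seed = 6, sacn_premiums = prem,
                    healthiness_price_slope = 0)
  dat <- simulate_dataset(cfg)
  fp <- link_food_prices(dat$linkage,
                         submark_median_prices(dat$transactions))
  tot <- aggregate_diary(dat$diaries, dat$foods, fp)
  tot <- dplyr::inner_join(tot, dat$covariates, by = "person_id")
  prof <- evaluate_sacn(tot)
  d <- group_difference(tot$cost_per_2000kcal, prof$met_fruit_veg,
                        tot$weight)
  expect_true(d$ci_low <= 0 && 0 <= d$ci_high)
})

test_that("an unattainable premium is a generation error", {
  prem <- setNames(rep(0, 8), sacn_ids())
  prem["fruit_veg"] <- 5000
  cfg <- sim_config(n_people = 50, seed = 7, sacn_premiums = prem)
  foods <- gen_food_universe(cfg)
  expect_error(gen_population_and_diaries(foods, cfg),
               "infeasible premium", class = "dietcost_generation_error")
})

test_that("a positive healthiness-price slope makes DASH accordance costlier", {
  signs <- vapply(1:20, function(r) {
    cfg <- sim_config(n_people = 2000, seed = 900 + r,
                      healthiness_price_slope = 30)
    foods <- gen_food_universe(cfg)
    pop <- gen_population_and_diaries(foods, cfg)
    fp <- tibble::tibble(
      food_id = foods$food_id,
      price_per_100g_consumed = foods$mean_price_consumed_p100g)
    tot <- aggregate_diary(pop$diaries, foods, fp)
    sc <- dash_score(tot)
    sign(stats::cor(sc$dash_score, tot$cost_per_2000kcal))
  }, numeric(1))
  expect_gte(sum(signs > 0), 18)
})

test_that("per-person energy spans the configured realistic range", {
  w <- small_world()
  fp <- link_food_prices(w$dat$linkage,
                         submark_median_prices(w$dat$transactions))
  tot <- aggregate_diary(w$dat$diaries, w$dat$foods, fp)
  expect_true(all(tot$energy_kcal > 0.85 * w$cfg$energy_range[1]))
  expect_true(all(tot$energy_kcal < 1.15 * w$cfg$energy_range[2]))
  expect_gt(diff(range(tot$energy_kcal)), 500)
})
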