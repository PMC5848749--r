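test_that("diary aggregation reproduces hand-computed cost and energy", {
  foods <- toy_foods(tibble::tibble(food_id = c("A", "B"),
                                    energy_kcal = c(100, 120)))
  prices <- toy_prices(c("A", "B"), c(50, 100))  # 0.5 and 1.0 pence/gram
  diary <- tibble::tibble(person_id = "P1", day = c(1, 2),
                          food_id = c("A", "B"), grams = c(200, 300))
  tot <- aggregate_diary(diary, foods, prices, min_days = 2)
  expect_equal(tot$cost_per_day, (200 * 0.5 + 300 * 1.0) / 2)  # 200 p/day
  # total cost 400 p over 200*1 + 300*1.2 = 560 kcal
  expect_equal(tot$cost_per_2000kcal, 400 / 560 * 2000)
  expect_equal(tot$energy_kcal, 560 / 2)
})

test_that("a three-food diary matches an independent spreadsheet-style oracle", {
  foods <- toy_foods(tibble::tibble(
    food_id = c("apple", "bread", "cheese"),
    group = c("fruit", "staples", "lowfat_dairy"),
    energy_kcal = c(52, 240, 410),
    fat_g = c(0.2, 2.1, 34.5), satfat_g = c(0.05, 0.5, 21.5),
    nmes_g = c(0, 2.5, 0), fibre_g = c(2.4, 2.8, 0),
    salt_g = c(0.01, 1.0, 1.8)))
  prices <- toy_prices(c("apple", "bread", "cheese"), c(30, 15, 80))
  diary <- tibble::tibble(
    person_id = "P1", day = c(1, 1, 2, 3, 3, 3),
    food_id = c("apple", "bread", "cheese", "apple", "bread", "cheese"),
    grams = c(150, 80, 40, 120, 100, 25))
  tot <- aggregate_diary(diary, foods, prices)

  # independent oracle: explicit sums, written before the implementation
  g <- c(apple = 150 + 120, bread = 80 + 100, cheese = 40 + 25)
  cost <- (g[["apple"]] * 30 + g[["bread"]] * 15 + g[["cheese"]] * 80) / 100
  kcal <- (g[["apple"]] * 52 + g[["bread"]] * 240 + g[["cheese"]] * 410) / 100
  fat <- (g[["apple"]] * 0.2 + g[["bread"]] * 2.1 + g[["cheese"]] * 34.5) / 100
  expect_equal(tot$n_diary_days, 3)
  expect_equal(tot$cost_per_day, cost / 3, tolerance = 1e-12)
  expect_equal(tot$cost_per_2000kcal, cost / kcal * 2000, tolerance = 1e-12)
  expect_equal(tot$fat_pct_energy, 100 * 9 * fat / kcal, tolerance = 1e-12)
  expect_equal(tot$fruit_g, g[["apple"]] / 3)
  expect_equal(tot$fv_portions, g[["apple"]] / 80 / 3)
})

test_that("persons below the diary-day minimum are excluded and counted", {
  foods <- toy_foods(tibble::tibble(food_id = "A"))
  prices <- toy_prices("A", 50)
  diary <- tibble::tibble(person_id = c("P1", "P1", "P1", "P2"),
                          day = c(1, 2, 3, 1), food_id = "A", grams = 100)
  expect_message(tot <- aggregate_diary(diary, foods, prices, min_days = 3),
                 "excluded 1")
  expect_equal(tot$person_id, "P1")
  expect_equal(attr(tot, "n_excluded_days"), 1L)
})

test_that("missing composition or price is a linkage error naming the food", {
  foods <- toy_foods(tibble::tibble(food_id = "A"))
  diary <- tibble::tibble(person_id = "P1", day = 1, food_id = "B",
                          grams = 10)
  expect_error(aggregate_diary(diary, foods, toy_prices("B", 10)),
               "B", class = "dietcost_linkage_error")
  diary$food_id <- "A"
  expect_error(aggregate_diary(diary, foods, toy_prices("Z", 10)),
               "A", class = "dietcost_linkage_error")
})

test_that("SACN bounds are inclusive and counted correctly", {
  tot <- totals_at_bounds()
  prof <- evaluate_sacn(tot)
  expect_true(all(as.logical(prof[, paste0("met_", sacn_ids())])))
  expect_equal(prof$accordance_count, 8)
  expect_equal(as.character(prof$banded_count), "6-8")

  tot$fat_pct_energy <- 36
  prof <- evaluate_sacn(tot)
  expect_false(prof$met_fat)
  expect_equal(prof$accordance_count, 7)
})

test_that("accordance counts match an independent per-row re-check", {
  set.seed(9)
  n <- 20
  tot <- totals_at_bounds(n)
  tot$fv_portions <- runif(n, 2, 8)
  tot$oily_fish_g <- runif(n, 0, 40)
  tot$red_processed_meat_g <- runif(n, 20, 150)
  tot$nmes_pct_energy <- runif(n, 5, 20)
  tot$fat_pct_energy <- runif(n, 25, 45)
  tot$satfat_pct_energy <- runif(n, 7, 16)
  tot$fibre_g <- runif(n, 8, 30)
  tot$salt_g <- runif(n, 3, 10)
  prof <- evaluate_sacn(tot)
  # brute-force oracle, one person and rule at a time
  for (i in seq_len(n)) {
    expected <- (tot$fv_portions[i] >= 5) + (tot$oily_fish_g[i] >= 20) +
      (tot$red_processed_meat_g[i] <= 70) + (tot$nmes_pct_energy[i] <= 11) +
      (tot$fat_pct_energy[i] <= 35) + (tot$satfat_pct_energy[i] <= 11) +
      (tot$fibre_g[i] >= 18) + (tot$salt_g[i] <= 6)
    expect_equal(prof$accordance_count[i], expected)
  }
})

test_that("raising fat intake can only switch the fat target from met to unmet", {
  tot <- totals_at_bounds()
  fat_seq <- seq(20, 50, by = 1)
  met <- vapply(fat_seq, function(f) {
    tot$fat_pct_energy <- f
    evaluate_sacn(tot)$met_fat
  }, logical(1))
  expect_true(all(diff(met) <= 0))
})

test_that("residual energy adjustment has the documented closed form", {
  # zero slope: adjustment returns the input
  v <- c(3, 5, 4, 6, 2)
  e <- rep(c(1800, 2200), length.out = 5)
  e <- e - mean(e) + 2000
  v0 <- v - (stats::cov(v, e) / stats::var(e)) * (e - mean(e))
  expect_equal(residual_energy_adjust(v0, e), v0, tolerance = 1e-12)

  # intake proportional to energy: everyone lands on the mean intake
  e <- c(1500, 1800, 2000, 2400, 2800)
  expect_equal(residual_energy_adjust(0.01 * e, e),
               rep(mean(0.01 * e), 5), tolerance = 1e-12)

  # 10-point toy against an explicit least-squares oracle
  set.seed(4)
  e <- runif(10, 1400, 2900)
  v <- 2 + 0.003 * e + rnorm(10)
  slope <- sum((v - mean(v)) * (e - mean(e))) / sum((e - mean(e))^2)
  intercept <- mean(v) - slope * mean(e)
  oracle <- (v - (intercept + slope * e)) + (intercept + slope * mean(e))
  adj <- residual_energy_adjust(v, e)
  expect_equal(adj, oracle, tolerance = 1e-10)
  expect_lt(abs(stats::cor(adj, e)), 1e-10)
  expect_equal(mean(adj), mean(v), tolerance = 1e-12)

  expect_error(residual_energy_adjust(v, rep(2000, 10)),
               class = "dietcost_degenerate_fit_error")
})

test_that("quintile assignment follows the tie rule and matches a sort oracle", {
  expect_equal(assign_quintiles(1:10), rep(1:5, each = 2))
  expect_equal(assign_quintiles(rep(7, 9)), rep(1, 9))
  expect_error(assign_quintiles(1:4), class = "dietcost_validation_error")

  set.seed(11)
  x <- rnorm(1000)
  q <- assign_quintiles(x)
  # sort-based brute-force oracle
  oracle <- integer(1000)
  for (i in seq_len(1000))
    oracle[i] <- min(floor(5 * sum(x < x[i]) / 1000) + 1, 5)
  expect_equal(q, oracle)
  expect_true(all(abs(table(q) - 200) <= 1))
})

test_that("DASH scoring spans 8-40 and reverse-scores discouraged components", {
  set.seed(3)
  n <- 30
  tot <- totals_at_bounds(n)
  tot$energy_kcal <- runif(n, 1500, 2500)
  for (f in dash_components()$field) tot[[f]] <- runif(n, 10, 200)
  # person 1: extreme high on encouraged, extreme low on discouraged
  enc <- dash_components()$field[dash_components()$encouraged]
  dis <- dash_components()$field[!dash_components()$encouraged]
  tot$energy_kcal[1:2] <- mean(tot$energy_kcal)
  for (f in enc) { tot[[f]][1] <- 5000; tot[[f]][2] <- -5000 }
  for (f in dis) { tot[[f]][1] <- -5000; tot[[f]][2] <- 5000 }
  sc <- dash_score(tot)
  expect_equal(sc$dash_score[1], 40)
  expect_equal(sc$dash_score[2], 8)
  expect_true(all(sc$dash_score >= 8 & sc$dash_score <= 40))

  # reverse scoring: stored score is 6 - raw quintile for every person
  for (f in dis) {
    adj <- residual_energy_adjust(tot[[f]], tot$energy_kcal)
    q <- assign_quintiles(adj)
    comp <- dash_components()$component[dash_components()$field == f]
    expect_equal(sc[[paste0("score_", comp)]], 6L - q)
  }
})

test_that("DASH scores equal an independent step-by-step recomputation", {
  set.seed(21)
  n <- 25
  tot <- totals_at_bounds(n)
  tot$energy_kcal <- runif(n, 1400, 2800)
  for (f in dash_components()$field)
    tot[[f]] <- runif(n, 0, 300) + 0.05 * tot$energy_kcal
  sc <- dash_score(tot)
  comps <- dash_components()
  oracle_total <- numeric(n)
  for (i in seq_len(nrow(comps))) {
    v <- tot[[comps$field[i]]]
    e <- tot$energy_kcal
    b <- sum((v - mean(v)) * (e - mean(e))) / sum((e - mean(e))^2)
    adj <- v - b * (e - mean(e))
    q <- vapply(seq_len(n), function(j)
      min(floor(5 * sum(adj < adj[j]) / n) + 1, 5), numeric(1))
    oracle_total <- oracle_total + if (comps$encouraged[i]) q else 6 - q
  }
  expect_equal(sc$dash_score, oracle_total)

  # permutation invariance: relabelling persons permutes scores with them
  perm <- sample(n)
  sc2 <- dash_score(tot[perm, ])
  expect_equal(sc2$dash_score, sc$dash_score[perm])

  # fixed cuts option
  sc3 <- dash_score(tot, fixed_cuts = c(20, 24, 27, 30))
  expect_equal(sc3$dash_quintile,
               as.integer(findInterval(sc3$dash_score, c(20, 24, 27, 30)) + 1))
})

test_that("cost per 2000 kcal is invariant to doubling every diary quantity", {
  foods <- toy_foods(tibble::tibble(food_id = c("A", "B"),
                                    energy_kcal = c(90, 250)))
  prices <- toy_prices(c("A", "B"), c(40, 120))
  diary <- tibble::tibble(person_id = "P1", day = c(1, 1, 2, 3),
                          food_id = c("A", "B", "A", "B"),
                          grams = c(100, 60, 150, 90))
  t1 <- aggregate_diary(diary, foods, prices)
  t2 <- aggregate_diary(dplyr::mutate(diary, grams = grams * 2),
                        foods, prices)
  expect_equal(t2$cost_per_2000kcal, t1$cost_per_2000kcal, tolerance = 1e-12)
  expect_equal(t2$cost_per_day, 2 * t1$cost_per_day, tolerance = 1e-12)
})

test_that("threshold overrides load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("salt: {bound: 5}\nfibre: {bound: 30, direction: ge}", f)
  thr <- sacn_thresholds(f)
  expect_equal(thr$bound[thr$id == "salt"], 5)
  expect_equal(thr$bound[thr$id == "fibre"], 30)
  expect_equal(thr$bound[thr$id == "fat"], 35)
})
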