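#' Run configuration for an end-to-end pipeline run
#'
#' Either `sim` (a [sim_config()]) or `inputs` (named paths to diaries,
#' foods, transactions, linkage and covariates CSVs) must be supplied.
#'
#' @param sim Optional [sim_config()] to simulate inputs.
#' @param inputs Optional named list of CSV paths: `diaries`, `foods`,
#'   `transactions`, `linkage`, `covariates`.
#' @param thresholds SACN thresholds tibble (see [sacn_thresholds()]).
#' @param min_diary_days Minimum diary days for inclusion (default 3).
#' @param dash_cuts Optional fixed DASH-score cut points (length 4).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Seed recorded in the manifest; defaults to `sim$seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       thresholds = sacn_thresholds(), min_diary_days = 3L,
                       dash_cuts = NULL, out_dir = NULL, seed = NULL) {
  if (is.null(sim) && is.null(inputs))
    stop_dietcost("run_config needs either 'sim' or 'inputs'",
                  "dietcost_config_error")
  if (!is.null(sim)) validate_sim_config(sim)
  if (!is.null(inputs)) {
    need <- c("diaries", "foods", "transactions", "linkage", "covariates")
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      stop_dietcost(sprintf("inputs missing path(s): %s",
                            paste(missing, collapse = ", ")),
                    "dietcost_config_error")
  }
  structure(list(sim = sim, inputs = inputs, thresholds = thresholds,
                 min_diary_days = as.integer(min_diary_days),
                 dash_cuts = dash_cuts, out_dir = out_dir,
                 seed = seed %||% (if (!is.null(sim)) sim$seed else NA)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `sim` (fields of [sim_config()]), `inputs`,
#' `min_diary_days`, `dash_cuts`, `out_dir`, `seed`; `thresholds` may map
#' recommendation ids to `bound`/`direction` overrides.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, lapply(y$sim, unlist))
  thr <- sacn_thresholds()
  if (!is.null(y$thresholds)) {
    for (nm in names(y$thresholds)) {
      i <- match(nm, thr$id)
      if (is.na(i))
        stop_dietcost(sprintf("unknown recommendation id '%s'", nm),
                      "dietcost_config_error")
      if (!is.null(y$thresholds[[nm]]$bound))
        thr$bound[i] <- y$thresholds[[nm]]$bound
      if (!is.null(y$thresholds[[nm]]$direction))
        thr$direction[i] <- y$thresholds[[nm]]$direction
    }
  }
  run_config(sim = sim, inputs = y$inputs, thresholds = thr,
             min_diary_days = y$min_diary_days %||% 3L,
             dash_cuts = unlist(y$dash_cuts),
             out_dir = y$out_dir, seed = y$seed)
}

#' Apply the analytic exclusions
#'
#' Drops, in order, persons with fewer than `min_days` diary days and then
#' persons with any missing covariate, and returns the balanced exclusion
#' accounting.
#'
#' @param persons Tibble with `person_id`, `n_diary_days` and the
#'   covariate columns.
#' @param min_days Minimum diary days.
#' @param covariate_cols Covariate columns checked for missingness.
#' @return List: `analytic` (tibble) and `log` (tibble `n_initial`,
#'   `n_excluded_days`, `n_excluded_covariates`, `n_analytic`).
#' @export
apply_exclusions <- function(persons, min_days = 3L,
                             covariate_cols = c("age", "sex", "nssec")) {
  n0 <- nrow(persons)
  keep_days <- persons$n_diary_days >= min_days
  after_days <- persons[keep_days, ]
  cc <- complete.cases(after_days[, covariate_cols, drop = FALSE])
  analytic <- after_days[cc, ]
  log <- tibble::tibble(n_initial = n0,
                        n_excluded_days = sum(!keep_days),
                        n_excluded_covariates = sum(!cc),
                        n_analytic = nrow(analytic))
  stopifnot(log$n_analytic ==
              log$n_initial - log$n_excluded_days - log$n_excluded_covariates)
  if (log$n_analytic == 0)
    rlang::warn("analytic sample is empty after exclusions")
  list(analytic = analytic, log = log)
}

age_bands <- function(age) {
  cut(age, breaks = c(18, 34, 49, 64, Inf),
      labels = c("19-34", "35-49", "50-64", "65+"))
}

#' Run the full diet-cost pipeline
#'
#' Simulates (or reads) diaries, composition, price transactions, linkage
#' and covariates; links prices (median per sub mark, then median of
#' matched sub-mark medians, adjusted for cooking and edible fractions);
#' aggregates diaries into per-person intakes and costs; applies the
#' exclusion rules; scores SACN and DASH accordance; and estimates
#' survey-weighted crude and covariate-adjusted mean costs with 95 % CI
#' for demographic strata, each recommendation (met vs not), accordance
#' bands and DASH quintiles, plus the cost-energy regression. Reruns with
#' the same configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return List: `person_metrics`, `table_strata`, `table_sacn`,
#'   `table_dash`, `table_bands`, `fig_cost_energy`, `exclusion_log`,
#'   `manifest`, and (simulate mode) `ground_truth`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_dietcost("config must be a run_config object",
                  "dietcost_config_error")
  stage <- function(name, expr) {
    tryCatch(expr, dietcost_error = function(e) {
      stop_dietcost(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)), class(e)[1])
    })
  }

  if (!is.null(config$sim)) {
    dat <- stage("simulate", simulate_dataset(config$sim))
  } else {
    dat <- stage("read_inputs", read_dataset(config$inputs))
  }

  prices <- stage("price_linkage", {
    sm <- submark_median_prices(dat$transactions)
    link_food_prices(dat$linkage, sm)
  })

  totals_all <- stage("aggregate", suppressMessages(
    aggregate_diary(dat$diaries, dat$foods, prices,
                    min_days = config$min_diary_days)))
  n_excluded_days <- attr(totals_all, "n_excluded_days")

  # day counts for everyone, for the exclusion accounting
  day_counts <- dplyr::summarise(
    dplyr::group_by(dat$diaries, .data$person_id),
    n_diary_days = dplyr::n_distinct(.data$day), .groups = "drop")
  persons <- dplyr::left_join(dat$covariates, day_counts, by = "person_id")
  persons$n_diary_days[is.na(persons$n_diary_days)] <- 0L
  excl <- stage("exclusions",
                apply_exclusions(persons, config$min_diary_days))

  analytic <- dplyr::inner_join(totals_all, excl$analytic, by = "person_id")
  sacn <- stage("sacn", evaluate_sacn(analytic, config$thresholds))
  dash <- stage("dash", dash_score(analytic, fixed_cuts = config$dash_cuts))
  metrics <- dplyr::left_join(dplyr::left_join(analytic, sacn,
                                               by = "person_id"),
                              dash, by = "person_id")

  w <- metrics$weight
  covs <- metrics[, c("age", "sex", "nssec")]
  est <- function(y, g, model) {
    if (model == "crude") group_means(y, g, w, model = "crude")
    else group_means(y, g, w, covariates = covs, model = "adjusted")
  }

  # Table 1: demographic and socio-economic strata; daily cost and
  # energy-adjusted (per 2000 kcal) cost, both as weighted means
  strata <- list(sex = metrics$sex, age_band = age_bands(metrics$age),
                 nssec = metrics$nssec)
  table_strata <- dplyr::bind_rows(lapply(names(strata), function(s)
    dplyr::bind_rows(lapply(c("cost_per_day", "cost_per_2000kcal"),
                            function(oc)
      dplyr::mutate(est(metrics[[oc]], strata[[s]], "crude"),
                    stratum = s, outcome = oc, .before = 1)))))

  # Table 2: each recommendation, met vs not, crude and adjusted
  table_sacn <- dplyr::bind_rows(lapply(sacn_ids(), function(id) {
    met <- factor(ifelse(metrics[[paste0("met_", id)]], "met", "not_met"),
                  levels = c("not_met", "met"))
    dplyr::bind_rows(lapply(c("crude", "adjusted"), function(m) {
      gm <- est(metrics$cost_per_2000kcal, met, m)
      dif <- group_difference(metrics$cost_per_2000kcal,
                              metrics[[paste0("met_", id)]], w,
                              if (m == "adjusted") covs else NULL)
      gm$pct_diff <- percent_difference(gm$mean[gm$group == "met"],
                                        gm$mean[gm$group == "not_met"])
      gm$diff <- dif$diff
      gm$diff_ci_low <- dif$ci_low
      gm$diff_ci_high <- dif$ci_high
      gm$diff_p <- dif$p_value
      dplyr::mutate(gm, recommendation = id, .before = 1)
    }))
  }))

  # Table 3: DASH accordance quintiles with linear trend
  table_dash <- dplyr::bind_rows(lapply(c("crude", "adjusted"), function(m) {
    gm <- est(metrics$cost_per_2000kcal,
              factor(paste0("Q", metrics$dash_quintile)), m)
    tr <- linear_trend(metrics$cost_per_2000kcal, metrics$dash_quintile, w,
                       if (m == "adjusted") covs else NULL)
    gm$trend_p <- tr$p_value
    gm
  }))

  # Accordance-count bands (0..5, 6-8)
  table_bands <- dplyr::bind_rows(lapply(c("crude", "adjusted"), function(m)
    est(metrics$cost_per_2000kcal, metrics$banded_count, m)))

  fig_cost_energy <- cost_energy_regression(metrics$cost_per_day,
                                            metrics$energy_kcal)

  stopifnot(excl$log$n_excluded_days == n_excluded_days)
  manifest <- list(
    package = "dietcost",
    version = as.character(utils::packageVersion("dietcost")),
    seed = config$seed,
    mode = if (!is.null(config$sim)) "simulate" else "files",
    config_hash = rlang::hash(config[c("sim", "inputs", "min_diary_days",
                                       "dash_cuts", "thresholds")]),
    n_analytic = excl$log$n_analytic)

  out <- list(person_metrics = metrics, table_strata = table_strata,
              table_sacn = table_sacn, table_dash = table_dash,
              table_bands = table_bands, fig_cost_energy = fig_cost_energy,
              exclusion_log = excl$log, manifest = manifest)
  if (!is.null(dat$ground_truth)) out$ground_truth <- dat$ground_truth
  if (!is.null(config$out_dir)) write_report_bundle(out, config$out_dir)
  out
}

#' Simulate a complete linked data set
#'
#' Convenience wrapper running all three generators from one
#' [sim_config()].
#'
#' @param cfg A [sim_config()].
#' @return List: `foods`, `transactions`, `linkage`, `covariates`,
#'   `weights`, `diaries`, `ground_truth`.
#' @export
simulate_dataset <- function(cfg) {
  foods <- gen_food_universe(cfg)
  panel <- gen_price_panel(foods, cfg)
  fp <- link_food_prices(panel$linkage,
                         submark_median_prices(panel$transactions))
  pop <- gen_population_and_diaries(foods, cfg, food_prices = fp)
  list(foods = foods, transactions = panel$transactions,
       linkage = panel$linkage, covariates = pop$covariates,
       weights = pop$weights, diaries = pop$diaries,
       ground_truth = pop$ground_truth)
}

read_dataset <- function(inputs) {
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                    progress = FALSE)
  list(diaries = rd(inputs$diaries), foods = rd(inputs$foods),
       transactions = rd(inputs$transactions),
       linkage = rd(inputs$linkage), covariates = rd(inputs$covariates))
}

#' Write a simulated data set as the five input CSVs plus ground truth
#'
#' @param dat From [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dat$diaries, file.path(dir, "diaries.csv"))
  readr::write_csv(dat$foods, file.path(dir, "foods.csv"))
  readr::write_csv(dat$transactions, file.path(dir, "transactions.csv"))
  readr::write_csv(dat$linkage, file.path(dir, "linkage.csv"))
  readr::write_csv(dat$covariates, file.path(dir, "covariates.csv"))
  gt <- dat$ground_truth
  jsonlite::write_json(
    list(premiums = as.list(attr(gt, "premiums")),
         persons = gt),
    file.path(dir, "ground_truth.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_report_bundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out$person_metrics, file.path(dir, "person_metrics.csv"))
  readr::write_csv(out$table_strata, file.path(dir, "table1_strata.csv"))
  readr::write_csv(out$table_sacn, file.path(dir, "table2_sacn.csv"))
  readr::write_csv(out$table_dash, file.path(dir, "table3_dash.csv"))
  readr::write_csv(out$table_bands, file.path(dir, "fig2_bands.csv"))
  readr::write_csv(out$exclusion_log, file.path(dir, "exclusion_log.csv"))
  jsonlite::write_json(out$fig_cost_energy,
                       file.path(dir, "fig1_cost_energy.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
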