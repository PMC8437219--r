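# Scenario runner -----------------------------------------------------------

#' Describe one simulation scenario
#'
#' @param sex `"male"` or `"female"`.
#' @param strategy a `crc_strategy`, or `NULL` for a no-screening run.
#' @param pattern a `crc_pattern`, or `NULL` for full adherence to the
#'   strategy.
#' @param start_age age at model start (50 in the reference analyses; 45 in
#'   the early-start sensitivity analysis).
#' @param horizon number of simulated years; `start_age + horizon <= 100`.
#' @param cohort_size starting population the counts are reported per
#'   (default 100,000).
#' @param variant parameter variant expected by the run (recorded and
#'   checked against the parameter set's tag).
#' @return An object of class `crc_config`.
#' @export
scenario_config <- function(sex = c("male", "female"), strategy = NULL,
                            pattern = NULL, start_age = 50L, horizon = 50L,
                            cohort_size = 1e5,
                            variant = c("point", "ci-lower", "ci-upper")) {
  sex <- match.arg(sex)
  variant <- match.arg(variant)
  start_age <- as.integer(start_age)
  horizon <- as.integer(horizon)
  if (start_age + horizon > 100)
    stop("start_age + horizon must not exceed 100", call. = FALSE)
  if (!is.null(strategy)) stopifnot(inherits(strategy, "crc_strategy"))
  if (!is.null(pattern)) {
    stopifnot(inherits(pattern, "crc_pattern"))
    if (is.null(strategy))
      stop("an adherence pattern requires a strategy", call. = FALSE)
  }
  if (!is.null(strategy) && is.null(pattern)) pattern <- selective_adherence(1)
  structure(list(sex = sex, strategy = strategy, pattern = pattern,
                 start_age = start_age, horizon = horizon,
                 cohort_size = cohort_size, variant = variant),
            class = "crc_config")
}

# Run the weighted sub-cohorts of a plan and aggregate their annual flows.
# Events scheduled at an age are applied before that year's natural-history
# step; offers outside [start_age, start_age + horizon) are ignored.
simulate_plan <- function(params, sex, start_age, horizon, plan) {
  ages <- seq(start_age, start_age + horizon - 1L)
  agg <- data.frame(age = ages, new_screen_dx = 0, new_symptom_dx = 0,
                    crc_deaths = 0, other_deaths = 0, n_fit = 0,
                    n_colonoscopy = 0)
  if (!length(plan)) plan <- list(list(weight = 1, ages = integer(0),
                                       modality = "fit"))
  for (cohort in plan) {
    w <- cohort$weight
    if (w == 0) next
    dist <- initial_distribution(params, sex, start_age)
    for (i in seq_along(ages)) {
      a <- ages[i]
      if (a %in% cohort$ages) {
        ev <- apply_screen(dist, params, cohort$modality)
        dist <- ev$dist
        agg$new_screen_dx[i] <- agg$new_screen_dx[i] + w * ev$result$detected_preclin
        agg$n_fit[i] <- agg$n_fit[i] + w * ev$result$n_fit
        agg$n_colonoscopy[i] <- agg$n_colonoscopy[i] + w * ev$result$n_colonoscopy
      }
      step <- advance_year(dist, params)
      dist <- step$dist
      agg$new_symptom_dx[i] <- agg$new_symptom_dx[i] + w * step$flows$new_symptom_dx
      agg$crc_deaths[i] <- agg$crc_deaths[i] + w * step$flows$crc_deaths
      agg$other_deaths[i] <- agg$other_deaths[i] + w * step$flows$other_deaths
    }
  }
  agg
}

summarize_flows <- function(flows, params, sex, cohort_size) {
  le <- params$life_expectancy
  deaths <- data.frame(age = flows$age, deaths = flows$crc_deaths * cohort_size)
  traj <- data.frame(
    age = flows$age + 1L,
    cum_cases = cumsum(flows$new_screen_dx + flows$new_symptom_dx) * cohort_size,
    cum_deaths = cumsum(flows$crc_deaths) * cohort_size,
    cum_ypll = cumsum(flows$crc_deaths * cohort_size *
                        le$value[match(paste(sex, flows$age),
                                       paste(le$sex, le$age))]))
  list(cases = utils::tail(traj$cum_cases, 1),
       deaths = utils::tail(traj$cum_deaths, 1),
       ypll = ypll(deaths, le, sex),
       n_fit = sum(flows$n_fit) * cohort_size,
       n_colonoscopy = sum(flows$n_colonoscopy) * cohort_size,
       trajectory = traj, flows = flows)
}

#' Run a screening scenario with its matched no-screening baseline
#'
#' Expands the scenario's adherence pattern into weighted fully-adherent and
#' non-attending (or sporadically attending) sub-cohorts, propagates each
#' deterministically over the horizon, aggregates annual flows, and also
#' runs the matched no-screening baseline so percentage reductions and
#' prevented counts are always available. All counts are per `cohort_size`
#' starting population.
#'
#' @param config a `crc_config` from [scenario_config()].
#' @param params a `crc_params` object; its variant tag must match the
#'   config's.
#' @return An object of class `crc_outcome`: cumulative CRC cases, CRC
#'   deaths and YPLL, test counts, the by-year cumulative trajectories, the
#'   embedded baseline outcome, and the percentage reductions.
#' @export
run_scenario <- function(config, params) {
  stopifnot(inherits(config, "crc_config"), inherits(params, "crc_params"))
  if (!identical(config$variant, params$meta$variant))
    stop(sprintf("config expects variant '%s' but parameter set is '%s'",
                 config$variant, params$meta$variant), call. = FALSE)

  mk <- function(plan, level, label) {
    flows <- simulate_plan(params, config$sex, config$start_age,
                           config$horizon, plan)
    s <- summarize_flows(flows, params, config$sex, config$cohort_size)
    structure(c(s, list(sex = config$sex, start_age = config$start_age,
                        horizon = config$horizon, variant = config$variant,
                        cohort_size = config$cohort_size,
                        modality = if (is.null(config$strategy)) NA_character_
                                   else config$strategy$modality,
                        level = level, pattern = label)),
              class = "crc_outcome")
  }

  baseline <- mk(list(), level = 0, label = "no screening")
  if (is.null(config$strategy)) {
    out <- baseline
    out$baseline <- baseline
    out$reductions <- stats::setNames(rep(0, 3), c("cases", "deaths", "ypll"))
    return(out)
  }

  plan <- build_cohort_plan(config$pattern, config$strategy)
  level <- adherence_level(config$pattern, config$strategy)
  label <- if (config$pattern$variant == "selective")
    sprintf("selective %.0f%%", 100 * config$pattern$p)
  else
    sprintf("sporadic at ages %s", paste(config$pattern$ages, collapse = ","))
  out <- mk(plan, level, label)
  out$baseline <- baseline
  out$reductions <- reduction_vs_baseline(out, baseline)
  out
}

#' @export
print.crc_outcome <- function(x, ...) {
  cat(sprintf("<crc_outcome> %s, start age %d, horizon %d y (%s)\n",
              x$sex, x$start_age, x$horizon, x$pattern))
  cat(sprintf("  per %s: %.0f CRC cases, %.0f CRC deaths, %.0f YPLL\n",
              format(x$cohort_size, big.mark = ",", scientific = FALSE),
              x$cases, x$deaths, x$ypll))
  if (!is.null(x$reductions))
    cat(sprintf("  reduction vs no screening: %.0f%% / %.0f%% / %.0f%% (cases/deaths/YPLL)\n",
                x$reductions["cases"], x$reductions["deaths"], x$reductions["ypll"]))
  invisible(x)
}

pct_label <- function(x) sprintf("%d%%", floor(100 * x + 0.5))

#' Reproduce the matched selective-vs-sporadic comparison tables
#'
#' Runs the full grid of matched adherence scenarios for both strategies:
#' for annual FIT, selective fractions 1, 1/2, ..., 1/10 against sporadic
#' attendance every 1, 2, ..., 10 years; for colonoscopy at three offered
#' ages, selective fractions 1, 2/3, 1/3 against sporadic attendance at
#' every two-age and one-age subset of the offers. Each row carries the
#' incidence, mortality and YPLL reductions for both patterns and the
#' sporadic/selective ratios of prevented outcomes.
#'
#' @param params a `crc_params` object (point variant).
#' @param sexes which sexes to run (default both).
#' @param start_age,horizon simulation window (defaults 50 and 50 years).
#' @param fit_strategy,colo_strategy the two strategies; defaults are annual
#'   FIT at ages 50-75 and colonoscopy at ages 50, 60 and 70.
#' @return A list of two data frames, `fit` and `colonoscopy`, one row per
#'   sex and matched scenario pair. Reductions are percentages (unrounded),
#'   ratios are unrounded; use [format_outcome_table()] for display
#'   rounding.
#' @export
reproduce_tables <- function(params, sexes = c("male", "female"),
                             start_age = 50L, horizon = 50L,
                             fit_strategy = strategy_fit_annual(),
                             colo_strategy = strategy_colonoscopy()) {
  run_pair <- function(sex, strategy, sel_p, spo_ages) {
    sel <- run_scenario(scenario_config(sex, strategy, selective_adherence(sel_p),
                                        start_age, horizon,
                                        variant = params$meta$variant),
                        params)
    spo <- run_scenario(scenario_config(sex, strategy, sporadic_adherence(spo_ages),
                                        start_age, horizon,
                                        variant = params$meta$variant),
                        params)
    cmp <- suppressWarnings(compare_patterns(sel, spo))
    data.frame(sex = sex,
               level = sel$level,
               scheme_selective = pct_label(sel_p),
               sel_red_cases = sel$reductions["cases"],
               sel_red_deaths = sel$reductions["deaths"],
               sel_red_ypll = sel$reductions["ypll"],
               scheme_sporadic = paste(spo_ages, collapse = ","),
               spo_red_cases = spo$reductions["cases"],
               spo_red_deaths = spo$reductions["deaths"],
               spo_red_ypll = spo$reductions["ypll"],
               ratio_cases = cmp$ratios["cases"],
               ratio_deaths = cmp$ratios["deaths"],
               ratio_ypll = cmp$ratios["ypll"],
               row.names = NULL)
  }

  fit_rows <- list()
  for (sex in sexes) {
    for (k in 1:10) {
      spo <- sporadic_every(fit_strategy, k)
      fit_rows[[length(fit_rows) + 1]] <-
        run_pair(sex, fit_strategy, 1 / k, spo$ages)
    }
  }

  colo_sets <- list(colo_strategy$ages)
  n <- length(colo_strategy$ages)
  if (n >= 2)
    colo_sets <- c(colo_sets, utils::combn(colo_strategy$ages, n - 1, simplify = FALSE),
                   as.list(colo_strategy$ages))
  colo_rows <- list()
  for (sex in sexes) {
    for (ages in colo_sets) {
      colo_rows[[length(colo_rows) + 1]] <-
        run_pair(sex, colo_strategy, length(ages) / n, ages)
    }
  }

  list(fit = do.call(rbind, fit_rows), colonoscopy = do.call(rbind, colo_rows))
}

#' Round a comparison table for display
#'
#' Reductions are shown as whole percentages and ratios to one decimal,
#' the conventional presentation for this kind of comparison.
#'
#' @param tab one of the data frames returned by [reproduce_tables()].
#' @return The table with rounded display columns.
#' @export
format_outcome_table <- function(tab) {
  for (col in grep("_red_", names(tab), value = TRUE))
    tab[[col]] <- floor(tab[[col]] + 0.5)
  for (col in grep("^ratio_", names(tab), value = TRUE))
    tab[[col]] <- round(tab[[col]], 1)
  tab
}

#' Run the sensitivity-analysis suite for one scenario
#'
#' Re-runs a base scenario with (i) every prevalence and transition rate at
#' its lower 95% limit, (ii) every such rate at its upper limit, and (iii)
#' the point estimates with screening starting at age 45 (horizon extended
#' so the end age is unchanged). Parameter variants are re-loaded from a
#' parameter-set directory so the CI columns of the stored tables are the
#' single source of truth. If the stored tables carry no usable CI bounds
#' the corresponding variant is skipped with a warning.
#'
#' @param config a `crc_config` describing the base scenario (point
#'   variant).
#' @param params_dir directory readable by [load_param_set()].
#' @return Named list of `crc_outcome` objects: `point`, and where
#'   available `ci-lower`, `ci-upper`, `start-45`.
#' @export
run_sensitivity_suite <- function(config, params_dir) {
  stopifnot(inherits(config, "crc_config"))
  out <- list()
  base_params <- load_param_set(params_dir, "point")
  out$point <- run_scenario(config, base_params)

  has_ci <- function(df) all(c("ci_lower", "ci_upper") %in% names(df)) &&
    any(!is.na(df$ci_lower))
  ci_available <- has_ci(base_params$transitions) || has_ci(base_params$prevalence)

  for (v in c("ci-lower", "ci-upper")) {
    if (!ci_available) {
      warning(sprintf("no CI bounds in '%s'; skipping %s variant", params_dir, v),
              call. = FALSE)
      next
    }
    p <- load_param_set(params_dir, v)
    cfg <- config
    cfg$variant <- v
    out[[v]] <- run_scenario(cfg, p)
  }

  cfg45 <- config
  shift <- config$start_age - 45L
  cfg45$start_age <- 45L
  cfg45$horizon <- config$horizon + shift
  if (!is.null(cfg45$strategy)) {
    if (cfg45$strategy$modality == "fit") {
      # annual FIT shifts its whole offer window earlier
      cfg45$strategy <- screening_strategy("fit",
        seq(45, max(config$strategy$ages) - shift))
    } else {
      cfg45$strategy <- screening_strategy(cfg45$strategy$modality,
                                           pmax(config$strategy$ages - shift, 45))
    }
    if (!is.null(cfg45$pattern) && cfg45$pattern$variant == "sporadic")
      cfg45$pattern <- sporadic_adherence(pmax(cfg45$pattern$ages - shift, 45))
  }
  out[["start-45"]] <- run_scenario(cfg45, base_params)
  out
}
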