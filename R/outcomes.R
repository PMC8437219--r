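# Outcome aggregation -------------------------------------------------------

#' Years of potential life lost
#'
#' Weights every premature death by the average remaining life expectancy at
#' the (integer) age of death, so deaths at younger ages contribute more
#' than deaths at older ages.
#'
#' @param deaths data frame with columns `age` and `deaths` (CRC deaths at
#'   each age, in whatever population unit the caller uses).
#' @param life_expectancy remaining life-expectancy table: columns `age`,
#'   `value`, and optionally `sex` (in which case `sex` must be given).
#' @param sex which sex's expectancies to use when the table carries both.
#' @return Total years of potential life lost (same population unit as
#'   `deaths`).
#' @examples
#' le <- data.frame(age = c(60, 80), value = c(22, 8))
#' ypll(data.frame(age = c(60, 80), deaths = c(2, 1)), le)  # 52
#' @export
ypll <- function(deaths, life_expectancy, sex = NULL) {
  stopifnot(all(c("age", "deaths") %in% names(deaths)))
  le <- life_expectancy
  if ("sex" %in% names(le)) {
    if (is.null(sex)) stop("life-expectancy table is sex-specific; supply `sex`",
                           call. = FALSE)
    le <- le[le$sex == sex, , drop = FALSE]
  }
  idx <- match(deaths$age, le$age)
  bad <- is.na(idx) & deaths$deaths > 0
  if (any(bad))
    stop(sprintf("no life expectancy for age(s) %s",
                 paste(unique(deaths$age[bad]), collapse = ", ")), call. = FALSE)
  sum(deaths$deaths * le$value[idx], na.rm = TRUE)
}

outcome_counts <- function(x) {
  c(cases = x$cases, deaths = x$deaths, ypll = x$ypll)
}

#' Percentage reduction of a scenario against its no-screening baseline
#'
#' For each cumulative outcome (CRC cases, CRC deaths, YPLL) returns
#' `100 * (baseline - scenario) / baseline`. A baseline of zero (nothing to
#' prevent) yields a reduction of 0 by convention.
#'
#' @param scenario,baseline `crc_outcome` objects (see [run_scenario()])
#'   sharing sex, starting age, horizon and parameter variant.
#' @return Named vector of percentages (`cases`, `deaths`, `ypll`).
#' @export
reduction_vs_baseline <- function(scenario, baseline) {
  stopifnot(inherits(scenario, "crc_outcome"), inherits(baseline, "crc_outcome"))
  same <- identical(scenario$sex, baseline$sex) &&
    identical(scenario$start_age, baseline$start_age) &&
    identical(scenario$horizon, baseline$horizon) &&
    identical(scenario$variant, baseline$variant)
  if (!same)
    stop("scenario and baseline configurations do not match", call. = FALSE)
  s <- outcome_counts(scenario)
  b <- outcome_counts(baseline)
  ifelse(b > 0, 100 * (b - s) / b, 0)
}

#' Compare a matched selective/sporadic scenario pair
#'
#' Computes the sporadic-to-selective ratios of prevented CRC cases,
#' prevented CRC deaths and prevented YPLL for two scenarios run at the
#' same overall adherence level. Ratios are computed on unrounded prevented
#' counts (baseline minus scenario), never on rounded percentages.
#'
#' @param selective,sporadic `crc_outcome` objects from [run_scenario()],
#'   sharing strategy, sex, parameters and horizon.
#' @return An object of class `crc_comparison` with the two summaries, the
#'   adherence levels, and the three ratios. If the selective scenario
#'   prevents nothing the ratios are undefined and returned as `NA` with a
#'   warning.
#' @export
compare_patterns <- function(selective, sporadic) {
  stopifnot(inherits(selective, "crc_outcome"), inherits(sporadic, "crc_outcome"))
  if (!identical(selective$sex, sporadic$sex) ||
      !identical(selective$start_age, sporadic$start_age) ||
      !identical(selective$horizon, sporadic$horizon) ||
      !identical(selective$modality, sporadic$modality))
    stop("selective and sporadic scenarios do not share a configuration",
         call. = FALSE)
  prev_sel <- outcome_counts(selective$baseline) - outcome_counts(selective)
  prev_spo <- outcome_counts(sporadic$baseline) - outcome_counts(sporadic)
  if (any(prev_sel <= 0)) {
    warning("selective scenario prevents nothing; ratios undefined", call. = FALSE)
    ratios <- stats::setNames(rep(NA_real_, 3), names(prev_sel))
  } else {
    ratios <- prev_spo / prev_sel
  }
  structure(list(level_selective = selective$level,
                 level_sporadic = sporadic$level,
                 selective = selective, sporadic = sporadic,
                 prevented_selective = prev_sel,
                 prevented_sporadic = prev_spo,
                 ratios = ratios),
            class = "crc_comparison")
}

#' @export
print.crc_comparison <- function(x, ...) {
  cat("<crc_comparison> sporadic vs selective adherence\n")
  cat(sprintf("  adherence level: selective %.0f%%, sporadic %.0f%%\n",
              100 * x$level_selective, 100 * x$level_sporadic))
  cat(sprintf("  prevented (selective): %.0f cases, %.0f deaths, %.0f YPLL\n",
              x$prevented_selective["cases"], x$prevented_selective["deaths"],
              x$prevented_selective["ypll"]))
  cat(sprintf("  prevented (sporadic):  %.0f cases, %.0f deaths, %.0f YPLL\n",
              x$prevented_sporadic["cases"], x$prevented_sporadic["deaths"],
              x$prevented_sporadic["ypll"]))
  cat(sprintf("  ratios sporadic/selective: %.1f / %.1f / %.1f\n",
              x$ratios["cases"], x$ratios["deaths"], x$ratios["ypll"]))
  invisible(x)
}
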