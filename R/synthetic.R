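# Synthetic parameter sets --------------------------------------------------
#
# The generator emulates the statistical structure of registry-derived
# inputs for this kind of model: adenoma and preclinical-cancer prevalence
# rising with age, sex-specific onset and progression rates, screening-test
# sensitivity increasing along the lesion sequence (adenomas hardest to
# detect by stool testing), Gompertz-shaped all-cause mortality with a
# consistent life table, and diagnosed-cancer excess mortality that is lower
# for screen-detected than for symptom-detected disease and fades with time
# since diagnosis. Values are structurally realistic, not transcriptions of
# any registry.

#' Specification for a synthetic parameter set
#'
#' All defaults describe a previously unscreened average-risk population of
#' the kind colorectal screening programs target; they are chosen so that
#' the simulated lifetime CRC risk without screening falls in the
#' commonly cited 3-7% band (`target_lifetime_risk`), and so that screening
#' effects are large enough for monotonicity properties to be tested far
#' from numerical noise.
#'
#' @param seed integer seed; everything downstream is deterministic given it.
#' @param prevalence_50,prevalence_75 named vectors (`nonadv_adenoma`,
#'   `adv_adenoma`, `preclin_crc`): male starting prevalences at ages 50 and
#'   75. Prevalence at 75 must be >= prevalence at 50.
#' @param transition_50,transition_75 named vectors (`no_nonadv`,
#'   `nonadv_adv`, `adv_preclin`, `preclin_clin`): male annual transition
#'   probabilities at ages 50 and 75. The preclinical-to-clinical rate is
#'   the reciprocal of the mean preclinical sojourn time (default 0.22/yr,
#'   i.e. about 4.5 years).
#' @param female_factor multiplier applied to female prevalences and lesion
#'   onset/progression rates (women develop colorectal neoplasms later and
#'   less often).
#' @param fit_sens,colo_sens per-lesion-state sensitivities
#'   (`nonadv_adenoma`, `adv_adenoma`, `preclin_crc`) for FIT and
#'   colonoscopy.
#' @param fit_spec,colo_spec specificities.
#' @param gompertz list with `male`/`female` vectors `c(rate, shape)`:
#'   all-cause annual death probability `rate * exp(shape * (age - 50))`,
#'   capped at 0.6.
#' @param crc_mort_year0 symptom-detected CRC excess annual death
#'   probability in the year of diagnosis.
#' @param crc_mort_decay exponential decay of that probability per year
#'   since diagnosis.
#' @param screen_mortality_ratio relative excess mortality of
#'   screen-detected vs symptom-detected CRC (< 1: earlier detection is
#'   less lethal).
#' @param jitter relative half-width of the uniform noise applied per age
#'   band (monotone age trends are re-imposed afterwards).
#' @param ci_width relative half-width of the synthetic 95% confidence
#'   intervals attached to prevalences and transition rates.
#' @param ysd_cap years since diagnosis after which CRC excess mortality is
#'   zero.
#' @param target_lifetime_risk plausibility band for the no-screening
#'   lifetime CRC risk implied by the set (checked by tests, not enforced
#'   here).
#' @return An object of class `crc_synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       prevalence_50 = c(nonadv_adenoma = 0.17,
                                         adv_adenoma = 0.03,
                                         preclin_crc = 0.002),
                       prevalence_75 = c(nonadv_adenoma = 0.32,
                                         adv_adenoma = 0.07,
                                         preclin_crc = 0.007),
                       transition_50 = c(no_nonadv = 0.013, nonadv_adv = 0.013,
                                         adv_preclin = 0.022, preclin_clin = 0.22),
                       transition_75 = c(no_nonadv = 0.022, nonadv_adv = 0.020,
                                         adv_preclin = 0.032, preclin_clin = 0.22),
                       female_factor = 0.72,
                       fit_sens = c(nonadv_adenoma = 0.10, adv_adenoma = 0.25,
                                    preclin_crc = 0.75),
                       fit_spec = 0.96,
                       colo_sens = c(nonadv_adenoma = 0.75, adv_adenoma = 0.95,
                                     preclin_crc = 0.98),
                       colo_spec = 1,
                       gompertz = list(male = c(rate = 0.004, shape = 0.088),
                                       female = c(rate = 0.0025, shape = 0.092)),
                       crc_mort_year0 = 0.16,
                       crc_mort_decay = 0.25,
                       screen_mortality_ratio = 0.45,
                       jitter = 0.05,
                       ci_width = 0.15,
                       ysd_cap = 14L,
                       target_lifetime_risk = c(0.03, 0.07)) {
  spec <- structure(as.list(environment()), class = "crc_synth_spec")
  frac <- c(prevalence_50, prevalence_75, transition_50, transition_75,
            fit_sens, fit_spec, colo_sens, colo_spec, crc_mort_year0,
            screen_mortality_ratio)
  if (any(frac < 0 | frac > 1))
    stop("all probabilities and fractions must lie in [0, 1]", call. = FALSE)
  if (any(prevalence_75 < prevalence_50))
    stop("lesion prevalence at 75 must be >= prevalence at 50", call. = FALSE)
  spec
}

# interpolate a male age trend between the age-50 and age-75 anchors,
# jitter per band, and re-impose the monotone trend
band_values <- function(v50, v75, mids, jitter, monotone = TRUE) {
  v <- v50 + (v75 - v50) * (mids - 50) / 25
  v <- pmax(v, 0)
  if (jitter > 0)
    v <- v * (1 + stats::runif(length(v), -jitter, jitter))
  if (monotone && v75 >= v50) v <- cummax(v)
  pmin(pmax(v, 0), 1)
}

#' Generate a full parameter set from a synthetic specification
#'
#' Deterministic given the spec's seed: the same spec always yields the
#' identical `crc_params` object. The output uses 5-year age bands from 45
#' to 80 (older ages extrapolate the last band), carries symmetric relative
#' confidence bounds on every prevalence and transition rate, and always
#' passes [validate_param_set()].
#'
#' @param spec a `crc_synth_spec`.
#' @return A validated `crc_params` object.
#' @export
generate_param_set <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "crc_synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  lo <- as.integer(seq(45, 75, by = 5))
  hi <- lo + 5L
  mids <- lo + 2.5
  ages <- 45:100

  ci <- function(v) list(lower = pmax(v * (1 - spec$ci_width), 0),
                         upper = pmin(v * (1 + spec$ci_width), 1))

  prev_rows <- list()
  trans_rows <- list()
  edge_key <- c(no_nonadv = 1, nonadv_adv = 2, adv_preclin = 3, preclin_clin = 4)
  for (sex in SEXES) {
    f <- if (sex == "male") 1 else spec$female_factor
    for (st in LESION_STATES) {
      v <- band_values(f * spec$prevalence_50[[st]], f * spec$prevalence_75[[st]],
                       mids, spec$jitter)
      b <- ci(v)
      prev_rows[[paste(sex, st)]] <- data.frame(
        sex = sex, age_lo = lo, age_hi = hi, state = st, value = v,
        ci_lower = b$lower, ci_upper = b$upper)
    }
    for (ed in names(edge_key)) {
      i <- edge_key[[ed]]
      ff <- if (ed == "preclin_clin") 1 else f   # sojourn is not sex-scaled
      v <- band_values(ff * spec$transition_50[[ed]], ff * spec$transition_75[[ed]],
                       mids, spec$jitter)
      b <- ci(v)
      trans_rows[[paste(sex, ed)]] <- data.frame(
        sex = sex, age_lo = lo, age_hi = hi,
        from = TRANSITION_EDGES$from[i], to = TRANSITION_EDGES$to[i],
        value = v, ci_lower = b$lower, ci_upper = b$upper)
    }
  }

  tests <- rbind(
    data.frame(modality = "fit",
               measure = TEST_MEASURES,
               value = c(spec$fit_sens[["nonadv_adenoma"]],
                         spec$fit_sens[["adv_adenoma"]],
                         spec$fit_sens[["preclin_crc"]], spec$fit_spec)),
    data.frame(modality = "colonoscopy",
               measure = TEST_MEASURES,
               value = c(spec$colo_sens[["nonadv_adenoma"]],
                         spec$colo_sens[["adv_adenoma"]],
                         spec$colo_sens[["preclin_crc"]], spec$colo_spec)))

  mort_rows <- list()
  le_rows <- list()
  for (sex in SEXES) {
    g <- spec$gompertz[[sex]]
    q <- pmin(g[["rate"]] * exp(g[["shape"]] * (ages - 50)), 0.6)
    mort_rows[[sex]] <- data.frame(sex = sex, age = ages, value = q)
    # life table consistent with the mortality curve (tail held at the cap)
    q_ext <- c(q, rep(0.6, 40))
    le <- vapply(seq_along(ages), function(i) {
      s <- cumprod(1 - q_ext[i:(i + 39)])
      sum(s) + 0.5
    }, 0)
    le_rows[[sex]] <- data.frame(sex = sex, age = ages, value = le)
  }

  ysd <- 0:(spec$ysd_cap - 1)
  q_sym <- pmin(spec$crc_mort_year0 * exp(-spec$crc_mort_decay * ysd), 1)
  crc_mort <- rbind(
    data.frame(mode = "symptom", years_since_dx = ysd, value = q_sym),
    data.frame(mode = "screen", years_since_dx = ysd,
               value = spec$screen_mortality_ratio * q_sym))

  param_set(
    prevalence = do.call(rbind, c(prev_rows, list(make.row.names = FALSE))),
    transitions = do.call(rbind, c(trans_rows, list(make.row.names = FALSE))),
    tests = tests,
    mortality = do.call(rbind, c(mort_rows, list(make.row.names = FALSE))),
    crc_mortality = crc_mort,
    life_expectancy = do.call(rbind, c(le_rows, list(make.row.names = FALSE))),
    source = sprintf("synthetic (seed %d)", spec$seed),
    variant = "point",
    ysd_cap = spec$ysd_cap
  )
}

#' Degenerate parameter sets for analytic checks
#'
#' Four limiting cases with known exact behaviour:
#' * `null` — no lesions at start and zero progression everywhere: no CRC
#'   ever, whatever the scenario.
#' * `deterministic-chain` — every transition probability 1 and no death
#'   from any cause: a cohort placed in a lesion state marches one state
#'   per year, so timing of diagnoses is forced exactly.
#' * `perfect-test` — both tests detect every lesion and never produce
#'   false positives.
#' * `useless-test` — both tests detect nothing (specificity 1), making
#'   every screening scenario identical to no screening.
#'
#' @param base parameter set to derive the test-performance variants from
#'   (default: `generate_param_set(synth_spec())`).
#' @return Named list of `crc_params` objects.
#' @export
degenerate_sets <- function(base = generate_param_set(synth_spec())) {
  zero_tab <- function(df) {
    df$value <- 0
    if ("ci_lower" %in% names(df)) df$ci_lower <- 0
    if ("ci_upper" %in% names(df)) df$ci_upper <- 0
    df
  }
  set_tests <- function(p, sens, specificity) {
    te <- p$tests
    te$value[te$measure != "specificity"] <- sens
    te$value[te$measure == "specificity"] <- specificity
    p$tests <- te
    validate_param_set(p)
    p
  }

  null <- base
  null$prevalence <- zero_tab(null$prevalence)
  null$transitions <- zero_tab(null$transitions)
  null$meta$source <- "degenerate: null"
  validate_param_set(null)

  det <- base
  det$prevalence <- zero_tab(det$prevalence)
  det$transitions$value <- 1
  det$transitions$ci_lower <- NA_real_
  det$transitions$ci_upper <- NA_real_
  det$mortality$value <- 0
  det$crc_mortality$value <- 0
  det$life_expectancy$value <- 105 - det$life_expectancy$age
  det$meta$source <- "degenerate: deterministic-chain"
  validate_param_set(det)

  perfect <- set_tests(base, sens = 1, specificity = 1)
  perfect$meta$source <- "degenerate: perfect-test"

  useless <- suppressWarnings(set_tests(base, sens = 0, specificity = 1))
  useless$meta$source <- "degenerate: useless-test"

  list("null" = null, "deterministic-chain" = det,
       "perfect-test" = perfect, "useless-test" = useless)
}
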