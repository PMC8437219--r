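# Fixture builders used across the suite. Everything is constructed in code;
# no stored data files are required.

# Age-independent parameter set: one band [45, 100) per edge, constant
# all-cause mortality, optional constant CRC excess mortality. Handy for
# closed-form and matrix-power oracles.
flat_params <- function(r = c(no_nonadv = 0, nonadv_adv = 0,
                              adv_preclin = 0, preclin_clin = 0),
                        prev = c(nonadv_adenoma = 0, adv_adenoma = 0,
                                 preclin_crc = 0),
                        q_all = 0,
                        crc_q_symptom = 0, crc_q_screen = 0,
                        fit_sens = c(0.1, 0.25, 0.75), fit_spec = 0.96,
                        colo_sens = c(0.75, 0.95, 0.98), colo_spec = 1,
                        ysd_cap = 14L) {
  both <- function(df) rbind(transform(df, sex = "male"),
                             transform(df, sex = "female"))
  prevalence <- both(data.frame(age_lo = 45, age_hi = 100,
                                state = names(prev), value = unname(prev),
                                ci_lower = NA_real_, ci_upper = NA_real_))
  edges <- data.frame(from = c("no_lesion", "nonadv_adenoma", "adv_adenoma",
                               "preclin_crc"),
                      to = c("nonadv_adenoma", "adv_adenoma", "preclin_crc",
                             "clin_crc"))
  transitions <- both(data.frame(age_lo = 45, age_hi = 100,
                                 from = edges$from, to = edges$to,
                                 value = unname(r),
                                 ci_lower = NA_real_, ci_upper = NA_real_))
  tests <- data.frame(
    modality = rep(c("fit", "colonoscopy"), each = 4),
    measure = rep(c("sens_nonadv_adenoma", "sens_adv_adenoma",
                    "sens_preclin_crc", "specificity"), 2),
    value = c(fit_sens, fit_spec, colo_sens, colo_spec))
  mortality <- both(data.frame(age = 45:100, value = q_all))
  ysd <- 0:(ysd_cap - 1)
  crc_mortality <- rbind(
    data.frame(mode = "symptom", years_since_dx = ysd, value = crc_q_symptom),
    data.frame(mode = "screen", years_since_dx = ysd, value = crc_q_screen))
  life_expectancy <- both(data.frame(age = 45:100,
                                     value = 60 - 0.5 * (45:100 - 45)))
  param_set(prevalence, transitions, tests, mortality, crc_mortality,
            life_expectancy, source = "test fixture", ysd_cap = ysd_cap)
}

# Explicit one-year transition matrix for the 6-state aggregate chain
# (no lesion, non-advanced adenoma, advanced adenoma, preclinical CRC,
# clinical CRC, dead of other causes) matching the engine's within-year
# order: progression first, then other-cause death on every alive state.
# Assumes no CRC-specific mortality.
one_year_matrix <- function(r, q) {
  nm <- c("no", "nonadv", "adv", "preclin", "clin", "dead_other")
  P <- matrix(0, 6, 6, dimnames = list(nm, nm))
  P["no", "no"] <- (1 - r[1]) * (1 - q)
  P["no", "nonadv"] <- r[1] * (1 - q)
  P["nonadv", "nonadv"] <- (1 - r[2]) * (1 - q)
  P["nonadv", "adv"] <- r[2] * (1 - q)
  P["adv", "adv"] <- (1 - r[3]) * (1 - q)
  P["adv", "preclin"] <- r[3] * (1 - q)
  P["preclin", "preclin"] <- (1 - r[4]) * (1 - q)
  P["preclin", "clin"] <- r[4] * (1 - q)
  P["clin", "clin"] <- 1 - q
  P[1:5, "dead_other"] <- q
  P["dead_other", "dead_other"] <- 1
  P
}

# collapse an engine distribution onto the 6 aggregate states above
aggregate_mass <- function(dist) {
  m <- dist$mass
  c(m[["no_lesion"]], m[["nonadv_adenoma"]], m[["adv_adenoma"]],
    m[["preclin_crc"]], sum(m[grep("^clin_", names(m))]), m[["dead_other"]])
}

# place all cohort mass in one named state
dist_in_state <- function(state, sex = "male", age = 50L, ysd_cap = 14L) {
  nm <- crcscreen:::state_names(ysd_cap)
  mass <- stats::setNames(numeric(length(nm)), nm)
  mass[state] <- 1
  state_distribution(sex, age, mass, ysd_cap)
}

default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_param_set(synth_spec())
    cache
  }
})
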