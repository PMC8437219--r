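# Cohort state space --------------------------------------------------------
#
# The cohort is propagated as expected state-occupancy fractions (a
# deterministic Markov cohort), not as sampled individuals: expectations are
# identical, and the acceptance comparisons are free of Monte Carlo noise.
#
# Diagnosed CRC is split by mode of detection (screen vs symptom) and years
# since diagnosis 0..cap, because the excess mortality schedule depends on
# both. The cap substate is sticky with zero excess mortality (long-term
# survivors).

state_names <- function(ysd_cap) {
  c("no_lesion", "nonadv_adenoma", "adv_adenoma", "preclin_crc",
    paste0("clin_screen_", 0:ysd_cap),
    paste0("clin_symptom_", 0:ysd_cap),
    "dead_crc", "dead_other")
}

clin_idx <- function(mass, mode) grep(paste0("^clin_", mode, "_"), names(mass))

#' Construct a cohort state distribution
#'
#' @param sex `"male"` or `"female"`.
#' @param age current age in years.
#' @param mass named numeric vector of state-occupancy fractions over the
#'   full state space (see [initial_distribution()]); must be non-negative
#'   and sum to 1 within 1e-12.
#' @param ysd_cap years-since-diagnosis cap matching the parameter set.
#' @return An object of class `crc_state_dist`.
#' @export
state_distribution <- function(sex, age, mass, ysd_cap = 14L) {
  nm <- state_names(ysd_cap)
  if (is.null(names(mass))) names(mass) <- nm
  stopifnot(identical(names(mass), nm))
  if (any(mass < -1e-15))
    stop("state masses must be non-negative", call. = FALSE)
  if (abs(sum(mass) - 1) > 1e-12)
    stop(sprintf("state masses sum to %.15f, not 1", sum(mass)), call. = FALSE)
  structure(list(sex = sex, age = age, mass = pmax(mass, 0),
                 ysd_cap = as.integer(ysd_cap)),
            class = "crc_state_dist")
}

#' @export
print.crc_state_dist <- function(x, ...) {
  cat(sprintf("<crc_state_dist> %s, age %d\n", x$sex, x$age))
  alive <- sum(x$mass) - x$mass[["dead_crc"]] - x$mass[["dead_other"]]
  clin <- sum(x$mass[grep("^clin_", names(x$mass))])
  cat(sprintf("  alive %.4f (diagnosed CRC %.5f), dead CRC %.5f, dead other %.4f\n",
              alive, clin, x$mass[["dead_crc"]], x$mass[["dead_other"]]))
  invisible(x)
}

#' Starting distribution of a previously unscreened cohort
#'
#' Places the starting lesion prevalences for the cohort's sex and starting
#' age into the non-advanced adenoma, advanced adenoma and preclinical CRC
#' states, with the remainder lesion-free. Nobody starts with diagnosed
#' cancer and nobody starts dead.
#'
#' @param params a `crc_params` object.
#' @param sex `"male"` or `"female"`.
#' @param start_age starting age in years (must resolve in the prevalence
#'   table; the reference analyses start at 50, the early-start sensitivity
#'   analysis at 45).
#' @return A `crc_state_dist` at `start_age`.
#' @export
initial_distribution <- function(params, sex, start_age) {
  if (start_age < 45 || start_age >= 100)
    stop(sprintf("start age %s outside supported range [45, 100)", start_age),
         call. = FALSE)
  prev <- prevalence_at(params, sex, start_age)
  cap <- params$meta$ysd_cap
  mass <- stats::setNames(numeric(length(state_names(cap))), state_names(cap))
  mass[LESION_STATES] <- prev
  mass["no_lesion"] <- 1 - sum(prev)
  state_distribution(sex, start_age, mass, cap)
}

empty_flows <- function() {
  data.frame(age = integer(0), new_screen_dx = numeric(0),
             new_symptom_dx = numeric(0), crc_deaths = numeric(0),
             other_deaths = numeric(0), n_fit = numeric(0),
             n_colonoscopy = numeric(0))
}

#' Propagate a cohort through one year of natural history
#'
#' Applies, in this fixed order: (1) lesion progression along the
#' adenoma-carcinoma sequence (including the preclinical-to-clinical
#' transition, booked as a symptom-detected diagnosis) with years since
#' diagnosis advancing for already-diagnosed cancer; (2) CRC-specific death
#' for diagnosed cancer, by mode of detection and years since diagnosis;
#' (3) other-cause death for every alive state at the all-cause rate.
#' Screening events are applied separately before this step (see
#' [apply_fit()], [apply_colonoscopy()]). Competing risks are multiplicative
#' in the stated order. Total mass is conserved exactly.
#'
#' Flows from one state advance at most one step per year: all transition
#' masses are computed from the start-of-year distribution.
#'
#' @param dist a `crc_state_dist`; its age must be below 100.
#' @param params a `crc_params` object.
#' @return A list with elements `dist` (the distribution one year older) and
#'   `flows` (one-row data frame: symptom-detected diagnoses, CRC deaths and
#'   other-cause deaths that occurred during the year, at the starting age).
#' @export
advance_year <- function(dist, params) {
  age <- dist$age
  if (age >= 100)
    stop("cannot advance beyond age 100 (horizon exceeded)", call. = FALSE)
  cap <- dist$ysd_cap
  m <- dist$mass
  sex <- dist$sex

  r <- vapply(seq_len(nrow(TRANSITION_EDGES)), function(i)
    resolve_rate(params, sex, age, TRANSITION_EDGES$from[i],
                 TRANSITION_EDGES$to[i]), 0)

  # (1) progression, non-cascading (all flows from start-of-year masses)
  f1 <- m[["no_lesion"]] * r[1]
  f2 <- m[["nonadv_adenoma"]] * r[2]
  f3 <- m[["adv_adenoma"]] * r[3]
  f4 <- m[["preclin_crc"]] * r[4]

  out <- m
  out[["no_lesion"]] <- m[["no_lesion"]] - f1
  out[["nonadv_adenoma"]] <- m[["nonadv_adenoma"]] + f1 - f2
  out[["adv_adenoma"]] <- m[["adv_adenoma"]] + f2 - f3
  out[["preclin_crc"]] <- m[["preclin_crc"]] + f3 - f4

  for (mode in c("screen", "symptom")) {
    ix <- clin_idx(m, mode)
    old <- m[ix]
    shifted <- c(0, old[-length(old)])
    shifted[length(shifted)] <- shifted[length(shifted)] + old[length(old)]
    out[ix] <- shifted
  }
  out[["clin_symptom_0"]] <- out[["clin_symptom_0"]] + f4

  # (2) CRC-specific death, by mode and years since diagnosis
  crc_d <- 0
  for (mode in c("screen", "symptom")) {
    ix <- clin_idx(out, mode)
    qs <- vapply(0:cap, function(y) crc_q(params, mode, y), 0)
    d <- out[ix] * qs
    out[ix] <- out[ix] - d
    crc_d <- crc_d + sum(d)
  }
  out[["dead_crc"]] <- out[["dead_crc"]] + crc_d

  # (3) other-cause death for every alive state
  q <- all_cause_q(params, sex, age)
  alive_ix <- setdiff(seq_along(out), match(c("dead_crc", "dead_other"), names(out)))
  other_d <- sum(out[alive_ix]) * q
  out[alive_ix] <- out[alive_ix] * (1 - q)
  out[["dead_other"]] <- out[["dead_other"]] + other_d

  flows <- data.frame(age = age, new_screen_dx = 0, new_symptom_dx = f4,
                      crc_deaths = crc_d, other_deaths = other_d,
                      n_fit = 0, n_colonoscopy = 0)
  list(dist = state_distribution(sex, age + 1L, out, cap), flows = flows)
}

#' Run a cohort with no screening
#'
#' The no-screening natural-history run is the baseline against which every
#' screening scenario's reductions are computed.
#'
#' @param params a `crc_params` object.
#' @param sex `"male"` or `"female"`.
#' @param start_age starting age (years).
#' @param horizon number of one-year cycles; `start_age + horizon` must not
#'   exceed 100.
#' @return A list with `states` (the `horizon + 1` distributions, including
#'   the initial one) and `flows` (data frame with one row per simulated
#'   year).
#' @export
run_unscreened <- function(params, sex, start_age, horizon) {
  if (start_age + horizon > 100)
    stop("horizon exceeds age 100", call. = FALSE)
  dist <- initial_distribution(params, sex, start_age)
  states <- vector("list", horizon + 1)
  states[[1]] <- dist
  flows <- vector("list", horizon)
  for (y in seq_len(horizon)) {
    step <- advance_year(dist, params)
    dist <- step$dist
    states[[y + 1]] <- dist
    flows[[y]] <- step$flows
  }
  list(states = states, flows = do.call(rbind, flows))
}
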