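# Screening events ----------------------------------------------------------
#
# A screening event interrupts the natural history: detected adenomas are
# removed (back to the lesion-free state), detected preclinical cancer
# becomes screen-detected clinical cancer at 0 years since diagnosis, which
# switches its mortality schedule to the (more favourable) screen-detected
# mode. People with already-diagnosed cancer and the dead are outside the
# screening-eligible pool.

eligible_states <- c("no_lesion", LESION_STATES)

event_result <- function(age, modality, removed_nonadv = 0, removed_adv = 0,
                         detected_preclin = 0, n_fit = 0, n_colonoscopy = 0) {
  data.frame(age = age, modality = modality, removed_nonadv = removed_nonadv,
             removed_adv = removed_adv, detected_preclin = detected_preclin,
             n_fit = n_fit, n_colonoscopy = n_colonoscopy)
}

#' Apply a screening colonoscopy to a cohort
#'
#' Of the participating eligible mass in each lesion state, the fraction
#' given by the colonoscopy's per-state sensitivity is detected: adenomas
#' (non-advanced and advanced) are removed back to the lesion-free state;
#' preclinical cancer becomes screen-detected clinical cancer at 0 years
#' since diagnosis. Non-participating and undetected mass is unchanged.
#'
#' @param dist a `crc_state_dist`.
#' @param params a `crc_params` object.
#' @param participation fraction of the eligible alive mass attending, in
#'   \[0, 1\].
#' @return A list with `dist` (post-event distribution, same age) and
#'   `result` (one-row data frame: removals, detections, tests performed).
#' @export
apply_colonoscopy <- function(dist, params, participation = 1) {
  stopifnot(participation >= 0, participation <= 1)
  s <- test_perf(params, "colonoscopy")
  m <- dist$mass

  rem_na <- participation * s[["sens_nonadv_adenoma"]] * m[["nonadv_adenoma"]]
  rem_ad <- participation * s[["sens_adv_adenoma"]] * m[["adv_adenoma"]]
  det_pc <- participation * s[["sens_preclin_crc"]] * m[["preclin_crc"]]

  m[["nonadv_adenoma"]] <- m[["nonadv_adenoma"]] - rem_na
  m[["adv_adenoma"]] <- m[["adv_adenoma"]] - rem_ad
  m[["no_lesion"]] <- m[["no_lesion"]] + rem_na + rem_ad
  m[["preclin_crc"]] <- m[["preclin_crc"]] - det_pc
  m[["clin_screen_0"]] <- m[["clin_screen_0"]] + det_pc

  n_colo <- participation * sum(dist$mass[eligible_states])
  list(dist = state_distribution(dist$sex, dist$age, m, dist$ysd_cap),
       result = event_result(dist$age, "colonoscopy", rem_na, rem_ad, det_pc,
                             n_fit = 0, n_colonoscopy = n_colo))
}

#' Apply a FIT screening round to a cohort
#'
#' Participants are tested with the fecal immunochemical test; a positive
#' result triggers a diagnostic colonoscopy. For lesion-bearing
#' participants the positivity probability is the FIT's per-state
#' sensitivity, and the diagnostic colonoscopy then detects the lesion with
#' the colonoscopy's sensitivity for that state (so the detection
#' probability is the product of the two). Lesion-free participants test
#' positive with probability 1 - specificity and receive a colonoscopy with
#' no state change. The colonoscopy count includes every positive.
#'
#' @inheritParams apply_colonoscopy
#' @return A list with `dist` and `result` as in [apply_colonoscopy()];
#'   `result$n_fit` counts FITs performed and `result$n_colonoscopy` the
#'   diagnostic colonoscopies (true and false positives).
#' @export
apply_fit <- function(dist, params, participation = 1) {
  stopifnot(participation >= 0, participation <= 1)
  sf <- test_perf(params, "fit")
  sc <- test_perf(params, "colonoscopy")
  m <- dist$mass

  pos_na <- participation * sf[["sens_nonadv_adenoma"]] * m[["nonadv_adenoma"]]
  pos_ad <- participation * sf[["sens_adv_adenoma"]] * m[["adv_adenoma"]]
  pos_pc <- participation * sf[["sens_preclin_crc"]] * m[["preclin_crc"]]
  pos_false <- participation * (1 - sf[["specificity"]]) * m[["no_lesion"]]

  rem_na <- pos_na * sc[["sens_nonadv_adenoma"]]
  rem_ad <- pos_ad * sc[["sens_adv_adenoma"]]
  det_pc <- pos_pc * sc[["sens_preclin_crc"]]

  m[["nonadv_adenoma"]] <- m[["nonadv_adenoma"]] - rem_na
  m[["adv_adenoma"]] <- m[["adv_adenoma"]] - rem_ad
  m[["no_lesion"]] <- m[["no_lesion"]] + rem_na + rem_ad
  m[["preclin_crc"]] <- m[["preclin_crc"]] - det_pc
  m[["clin_screen_0"]] <- m[["clin_screen_0"]] + det_pc

  n_fit <- participation * sum(dist$mass[eligible_states])
  n_colo <- pos_na + pos_ad + pos_pc + pos_false
  list(dist = state_distribution(dist$sex, dist$age, m, dist$ysd_cap),
       result = event_result(dist$age, "fit", rem_na, rem_ad, det_pc,
                             n_fit = n_fit, n_colonoscopy = n_colo))
}

apply_screen <- function(dist, params, modality, participation = 1) {
  switch(modality,
         fit = apply_fit(dist, params, participation),
         colonoscopy = apply_colonoscopy(dist, params, participation),
         stop(sprintf("unknown screening modality '%s'", modality), call. = FALSE))
}
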