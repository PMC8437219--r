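# Screening strategies and adherence patterns -------------------------------

#' Define a screening strategy
#'
#' A strategy is a test modality plus the explicit list of ages at which it
#' is offered.
#'
#' @param modality `"fit"` or `"colonoscopy"`.
#' @param ages strictly increasing integer ages within \[45, 100\].
#' @return An object of class `crc_strategy`.
#' @examples
#' strategy_fit_annual()            # FIT every year, ages 50-75
#' strategy_colonoscopy()           # colonoscopy at 50, 60, 70
#' screening_strategy("fit", seq(50, 74, by = 2))
#' @export
screening_strategy <- function(modality = c("fit", "colonoscopy"), ages) {
  modality <- match.arg(modality)
  ages <- as.integer(ages)
  if (!length(ages)) stop("a strategy needs at least one offered age", call. = FALSE)
  if (any(diff(ages) <= 0)) stop("offered ages must be strictly increasing",
                                 call. = FALSE)
  if (min(ages) < 45 || max(ages) > 100)
    stop("offered ages must lie within [45, 100]", call. = FALSE)
  structure(list(modality = modality, ages = ages), class = "crc_strategy")
}

#' @rdname screening_strategy
#' @param start,end first and last offered age for annual FIT (inclusive).
#' @export
strategy_fit_annual <- function(start = 50, end = 75) {
  screening_strategy("fit", seq(start, end))
}

#' @rdname screening_strategy
#' @export
strategy_colonoscopy <- function(ages = c(50, 60, 70)) {
  screening_strategy("colonoscopy", ages)
}

#' @export
print.crc_strategy <- function(x, ...) {
  cat(sprintf("<crc_strategy> %s at %d offered age(s): %s\n", x$modality,
              length(x$ages), paste(x$ages, collapse = ", ")))
  invisible(x)
}

#' Define an adherence pattern
#'
#' Two idealized longitudinal patterns that yield the same overall adherence
#' level but very different exposure to screening:
#' * **selective** — a fixed fraction `p` of the population attends every
#'   offered round; the remaining `1 - p` never attends.
#' * **sporadic** — the entire population attends, but only at a subset of
#'   the offered ages.
#'
#' @param p fraction of the population that is fully adherent, in \[0, 1\].
#' @return An object of class `crc_pattern`.
#' @examples
#' selective_adherence(0.5)
#' sporadic_adherence(c(50, 60))
#' sporadic_every(strategy_fit_annual(), k = 2)   # ages 50, 52, ..., 74
#' @export
selective_adherence <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1)
  structure(list(variant = "selective", p = p), class = "crc_pattern")
}

#' @rdname selective_adherence
#' @param ages the attended ages; must be a non-empty subset of the
#'   strategy's offered ages.
#' @export
sporadic_adherence <- function(ages) {
  ages <- as.integer(ages)
  if (!length(ages)) stop("sporadic pattern needs at least one attended age",
                          call. = FALSE)
  structure(list(variant = "sporadic", ages = sort(ages)), class = "crc_pattern")
}

#' @rdname selective_adherence
#' @param strategy a `crc_strategy` whose offered ages are attended every
#'   `k` rounds, anchored at the first offered age.
#' @param k attend every k-th offered age.
#' @export
sporadic_every <- function(strategy, k) {
  stopifnot(inherits(strategy, "crc_strategy"), k >= 1)
  sporadic_adherence(strategy$ages[seq(1, length(strategy$ages), by = k)])
}

#' @export
print.crc_pattern <- function(x, ...) {
  if (x$variant == "selective")
    cat(sprintf("<crc_pattern> selective: %.0f%% of the population fully adherent\n",
                100 * x$p))
  else
    cat(sprintf("<crc_pattern> sporadic: whole population at ages %s\n",
                paste(x$ages, collapse = ", ")))
  invisible(x)
}

#' Overall adherence level of a pattern under a strategy
#'
#' Adherence is the product of the fraction of people ever screened and the
#' fraction of offered tests actually used. For a selective pattern the
#' second factor is 1, so the level equals the adherent fraction `p`; for a
#' sporadic pattern the first factor is 1, so the level is the number of
#' attended ages over the number of offered ages.
#'
#' @param pattern a `crc_pattern`.
#' @param strategy a `crc_strategy`.
#' @return The adherence level, a fraction in \[0, 1\].
#' @examples
#' adherence_level(selective_adherence(0.5), strategy_fit_annual())   # 0.5
#' adherence_level(sporadic_every(strategy_fit_annual(), 2),
#'                 strategy_fit_annual())                             # 13/26
#' @export
adherence_level <- function(pattern, strategy) {
  stopifnot(inherits(pattern, "crc_pattern"), inherits(strategy, "crc_strategy"))
  if (!length(strategy$ages)) stop("empty strategy", call. = FALSE)
  if (pattern$variant == "selective") return(pattern$p)
  if (!all(pattern$ages %in% strategy$ages))
    stop("sporadic attended ages must be a subset of the offered ages",
         call. = FALSE)
  length(pattern$ages) / length(strategy$ages)
}

#' Expand a pattern into weighted sub-cohort screening plans
#'
#' A selective pattern splits the population into a fully adherent
#' sub-cohort of weight `p` that attends every offered age, and an
#' unscreened sub-cohort of weight `1 - p`. A sporadic pattern is a single
#' cohort of weight 1 attending the pattern's ages. Weights always sum
#' to 1; attendance within a sub-cohort is always complete, which is what
#' makes scenario outcomes exactly linear in `p` for selective patterns.
#'
#' @inheritParams adherence_level
#' @return A list of sub-cohorts, each a list with elements `weight`,
#'   `ages` (screening event ages, possibly empty) and `modality`.
#' @export
build_cohort_plan <- function(pattern, strategy) {
  stopifnot(inherits(pattern, "crc_pattern"), inherits(strategy, "crc_strategy"))
  if (pattern$variant == "selective") {
    plan <- list(list(weight = pattern$p, ages = strategy$ages,
                      modality = strategy$modality))
    if (pattern$p < 1)
      plan <- c(plan, list(list(weight = 1 - pattern$p, ages = integer(0),
                                modality = strategy$modality)))
    if (pattern$p == 0)
      plan <- plan[-1]
    return(plan)
  }
  if (!all(pattern$ages %in% strategy$ages))
    stop("sporadic attended ages must be a subset of the offered ages",
         call. = FALSE)
  list(list(weight = 1, ages = pattern$ages, modality = strategy$modality))
}
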