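# Canonical state vocabulary ------------------------------------------------

LESION_STATES <- c("nonadv_adenoma", "adv_adenoma", "preclin_crc")

TRANSITION_EDGES <- data.frame(
  from = c("no_lesion", "nonadv_adenoma", "adv_adenoma", "preclin_crc"),
  to   = c("nonadv_adenoma", "adv_adenoma", "preclin_crc", "clin_crc"),
  stringsAsFactors = FALSE
)

TEST_MEASURES <- c("sens_nonadv_adenoma", "sens_adv_adenoma",
                   "sens_preclin_crc", "specificity")

SEXES <- c("male", "female")

#' Assemble a validated parameter set
#'
#' A parameter set bundles everything the cohort simulator consumes for one
#' population: starting lesion prevalences, annual transition probabilities
#' along the adenoma-carcinoma sequence, screening-test performance, and the
#' mortality/life-table inputs. All components are plain data frames so that
#' sets round-trip losslessly through the delimited-text format of
#' [write_param_set()] / [load_param_set()].
#'
#' @param prevalence data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `state` (one of `nonadv_adenoma`, `adv_adenoma`, `preclin_crc`),
#'   `value`, and optional `ci_lower`, `ci_upper`. Fractions of the cohort
#'   starting in each lesion state; the remainder starts lesion-free.
#'   Age bands are half-open `[age_lo, age_hi)`.
#' @param transitions data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `from`, `to`, `value`, and optional `ci_lower`, `ci_upper`. Annual
#'   transition probabilities for the four progression edges
#'   (no lesion -> non-advanced adenoma -> advanced adenoma ->
#'   preclinical CRC -> clinical CRC).
#' @param tests data frame with columns `modality` (`fit`, `colonoscopy`),
#'   `measure` (per-state sensitivity or `specificity`), `value`.
#' @param mortality all-cause annual death probability: columns `sex`,
#'   `age` (single years), `value`.
#' @param crc_mortality CRC-specific annual death probability for diagnosed
#'   cancer: columns `mode` (`screen`, `symptom`), `years_since_dx`
#'   (0 .. `ysd_cap` - 1), `value`. Beyond `ysd_cap` years since diagnosis
#'   the excess mortality is zero (long-term survivors).
#' @param life_expectancy remaining life expectancy in years: columns `sex`,
#'   `age`, `value`. Used to weight premature deaths into years of
#'   potential life lost.
#' @param source free-text label recording where the numbers came from.
#' @param variant which column of the uncertainty interval the rates were
#'   taken from: `"point"`, `"ci-lower"` or `"ci-upper"`.
#' @param ysd_cap number of years since diagnosis over which CRC-specific
#'   mortality is tracked (default 14).
#'
#' @return An object of class `crc_params`.
#' @seealso [load_param_set()], [generate_param_set()], [resolve_rate()]
#' @export
param_set <- function(prevalence, transitions, tests, mortality,
                      crc_mortality, life_expectancy,
                      source = "unspecified", variant = "point",
                      ysd_cap = 14L) {
  variant <- match.arg(variant, c("point", "ci-lower", "ci-upper"))
  params <- structure(
    list(
      prevalence = as.data.frame(prevalence),
      transitions = as.data.frame(transitions),
      tests = as.data.frame(tests),
      mortality = as.data.frame(mortality),
      crc_mortality = as.data.frame(crc_mortality),
      life_expectancy = as.data.frame(life_expectancy),
      meta = list(source = source, variant = variant,
                  ysd_cap = as.integer(ysd_cap))
    ),
    class = "crc_params"
  )
  validate_param_set(params)
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant the simulator relies on: probabilities in
#' \[0, 1\], per-band prevalences summing to at most 1, confidence bounds
#' bracketing their point estimates, one-year outflow (progression plus
#' other-cause death) never exceeding 1, strictly decreasing remaining life
#' expectancy, and full age coverage of the simulated range 45-100 for both
#' sexes. Violations that indicate a broken input abort with the offending
#' key; implausible-but-legal orderings (FIT more sensitive than colonoscopy,
#' screen-detected mortality above symptom-detected) only warn.
#'
#' @param params a `crc_params` object.
#' @return `params`, invisibly, if all checks pass.
#' @export
validate_param_set <- function(params) {
  stopifnot(inherits(params, "crc_params"))
  pv <- params$prevalence
  tr <- params$transitions
  te <- params$tests
  mo <- params$mortality
  cm <- params$crc_mortality
  le <- params$life_expectancy

  chk_frac <- function(df, col, what) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad)) {
      key <- paste(vapply(bad[1], function(i) {
        paste(unlist(df[i, setdiff(names(df), c("value", "ci_lower", "ci_upper"))]),
              collapse = "/")
      }, ""), "=", df[[col]][bad[1]])
      stop(sprintf("%s: %s outside [0, 1] at %s", what, col, key), call. = FALSE)
    }
  }

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")),
           call. = FALSE)
  }
  need(pv, c("sex", "age_lo", "age_hi", "state", "value"), "prevalence")
  need(tr, c("sex", "age_lo", "age_hi", "from", "to", "value"), "transitions")
  need(te, c("modality", "measure", "value"), "tests")
  need(mo, c("sex", "age", "value"), "mortality")
  need(cm, c("mode", "years_since_dx", "value"), "crc_mortality")
  need(le, c("sex", "age", "value"), "life_expectancy")

  chk_frac(pv, "value", "prevalence")
  chk_frac(tr, "value", "transitions")
  chk_frac(te, "value", "tests")
  chk_frac(mo, "value", "mortality")
  chk_frac(cm, "value", "crc_mortality")

  chk_ci <- function(df, what) {
    if (all(c("ci_lower", "ci_upper") %in% names(df))) {
      ok <- is.na(df$ci_lower) | is.na(df$ci_upper) |
        (df$ci_lower <= df$value & df$value <= df$ci_upper)
      if (!all(ok))
        stop(sprintf("%s: CI bounds do not bracket the point estimate (row %d)",
                     what, which(!ok)[1]), call. = FALSE)
    }
  }
  chk_ci(pv, "prevalence")
  chk_ci(tr, "transitions")

  # prevalences for one (sex, band) must leave non-negative lesion-free mass
  key <- paste(pv$sex, pv$age_lo, pv$age_hi)
  sums <- tapply(pv$value, key, sum)
  if (any(sums > 1 + 1e-12))
    stop(sprintf("prevalence: lesion fractions sum to %.4f > 1 for %s",
                 max(sums), names(sums)[which.max(sums)]), call. = FALSE)

  # outflow (progression + worst-case other-cause death within band) <= 1
  for (i in seq_len(nrow(tr))) {
    ages <- seq(max(tr$age_lo[i], 45), min(tr$age_hi[i] - 1, 100))
    q <- mo$value[mo$sex == tr$sex[i] & mo$age %in% ages]
    if (length(q) && tr$value[i] + max(q) > 1 + 1e-12)
      stop(sprintf(
        "transitions: outflow %s->%s plus all-cause mortality exceeds 1 for %s [%d,%d)",
        tr$from[i], tr$to[i], tr$sex[i], tr$age_lo[i], tr$age_hi[i]), call. = FALSE)
  }

  # test performance: colonoscopy should dominate FIT per lesion state
  sens <- TEST_MEASURES[TEST_MEASURES != "specificity"]
  for (m in sens) {
    f <- te$value[te$modality == "fit" & te$measure == m]
    k <- te$value[te$modality == "colonoscopy" & te$measure == m]
    if (length(f) && length(k) && k < f)
      warning(sprintf("tests: colonoscopy %s (%.3f) below FIT (%.3f)", m, k, f),
              call. = FALSE)
  }

  # screen-detected CRC mortality should not exceed symptom-detected
  for (y in unique(cm$years_since_dx)) {
    qs <- cm$value[cm$mode == "screen" & cm$years_since_dx == y]
    qy <- cm$value[cm$mode == "symptom" & cm$years_since_dx == y]
    if (length(qs) && length(qy) && qs > qy)
      warning(sprintf(
        "crc_mortality: screen-detected exceeds symptom-detected at %d years since diagnosis",
        y), call. = FALSE)
  }

  # remaining life expectancy strictly decreasing in age
  for (s in unique(le$sex)) {
    v <- le$value[le$sex == s][order(le$age[le$sex == s])]
    if (any(diff(v) >= 0))
      stop(sprintf("life_expectancy: not strictly decreasing in age for %s", s),
           call. = FALSE)
  }

  # full coverage of the simulated age range for both sexes
  for (s in SEXES) {
    for (a in c(45, 72, 99)) {
      for (i in seq_len(nrow(TRANSITION_EDGES))) {
        resolve_rate(params, s, a, TRANSITION_EDGES$from[i], TRANSITION_EDGES$to[i])
      }
    }
    if (!all(45:100 %in% mo$age[mo$sex == s]))
      stop(sprintf("mortality: ages 45-100 not fully covered for %s", s),
           call. = FALSE)
    if (!all(45:100 %in% le$age[le$sex == s]))
      stop(sprintf("life_expectancy: ages 45-100 not fully covered for %s", s),
           call. = FALSE)
  }
  invisible(params)
}

#' Look up an annual transition probability
#'
#' Age bands are half-open: an age belongs to the band with
#' `age_lo <= age < age_hi`. Ages at or beyond the upper end of the last
#' band reuse that band's value (rates for ages past the last band, e.g.
#' 80+, extrapolate the oldest available band).
#'
#' @param params a `crc_params` object.
#' @param sex `"male"` or `"female"`.
#' @param age age in years, between 45 and 100.
#' @param from,to state names of one progression edge, e.g.
#'   `"adv_adenoma"`, `"preclin_crc"`.
#' @return The annual transition probability, a single number.
#' @export
resolve_rate <- function(params, sex, age, from, to) {
  if (age < 45 || age > 100)
    stop(sprintf("age %s outside supported range [45, 100]", age), call. = FALSE)
  tr <- params$transitions
  rows <- tr[tr$sex == sex & tr$from == from & tr$to == to, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no transition rate for %s %s->%s", sex, from, to), call. = FALSE)
  hit <- rows$age_lo <= age & age < rows$age_hi
  if (any(hit)) return(rows$value[which(hit)[1]])
  top <- which.max(rows$age_hi)
  if (age >= rows$age_hi[top]) return(rows$value[top])   # extrapolate last band
  stop(sprintf("no age band contains age %s for %s %s->%s", age, sex, from, to),
       call. = FALSE)
}

# internal band lookup for prevalence (same half-open + extrapolation rule)
prevalence_at <- function(params, sex, age) {
  pv <- params$prevalence
  out <- stats::setNames(numeric(length(LESION_STATES)), LESION_STATES)
  for (st in LESION_STATES) {
    rows <- pv[pv$sex == sex & pv$state == st, , drop = FALSE]
    if (!nrow(rows))
      stop(sprintf("no starting prevalence for %s %s", sex, st), call. = FALSE)
    hit <- rows$age_lo <= age & age < rows$age_hi
    if (any(hit)) {
      out[st] <- rows$value[which(hit)[1]]
    } else if (age >= max(rows$age_hi)) {
      out[st] <- rows$value[which.max(rows$age_hi)]
    } else {
      stop(sprintf("no prevalence band contains age %s for %s %s", age, sex, st),
           call. = FALSE)
    }
  }
  out
}

all_cause_q <- function(params, sex, age) {
  v <- params$mortality$value[params$mortality$sex == sex &
                                params$mortality$age == age]
  if (!length(v))
    stop(sprintf("no all-cause mortality for %s age %s", sex, age), call. = FALSE)
  v[1]
}

# CRC-specific annual death probability; zero at/after the tracking cap
crc_q <- function(params, mode, ysd) {
  if (ysd >= params$meta$ysd_cap) return(0)
  cm <- params$crc_mortality
  v <- cm$value[cm$mode == mode & cm$years_since_dx == ysd]
  if (!length(v)) return(0)
  v[1]
}

test_perf <- function(params, modality) {
  te <- params$tests[params$tests$modality == modality, , drop = FALSE]
  if (!nrow(te)) stop(sprintf("no test performance for '%s'", modality),
                      call. = FALSE)
  stats::setNames(te$value, te$measure)[TEST_MEASURES]
}

#' @export
print.crc_params <- function(x, ...) {
  cat("<crc_params> parameter set\n")
  cat("  source:  ", x$meta$source, "\n", sep = "")
  cat("  variant: ", x$meta$variant, "\n", sep = "")
  cat(sprintf("  %d prevalence rows, %d transition rows, %d test rows\n",
              nrow(x$prevalence), nrow(x$transitions), nrow(x$tests)))
  cat(sprintf("  CRC mortality tracked %d years since diagnosis\n",
              x$meta$ysd_cap))
  invisible(x)
}

# Plain-text persistence ----------------------------------------------------

#' Write a parameter set to a directory of delimited tables
#'
#' Emits one tab-separated file per component plus a `manifest.yml` naming
#' them. Numeric columns are written with full double precision so that
#' `load_param_set(write_param_set(p, d))` reproduces every value
#' bit-exactly.
#'
#' @param params a `crc_params` object.
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_param_set <- function(params, dir) {
  stopifnot(inherits(params, "crc_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(prevalence = "prevalence.tsv", transitions = "transitions.tsv",
             tests = "test_performance.tsv", mortality = "mortality_all_cause.tsv",
             crc_mortality = "crc_mortality.tsv",
             life_expectancy = "life_expectancy.tsv")
  for (nm in names(files)) {
    df <- params[[nm]]
    for (col in names(df)) {
      if (is.double(df[[col]]))
        df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.17g", df[[col]]))
    }
    utils::write.table(df, file.path(dir, files[[nm]]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(
    list(source = params$meta$source, ysd_cap = params$meta$ysd_cap,
         files = as.list(files)),
    file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Load a parameter set from a directory of delimited tables
#'
#' Reads the `manifest.yml` written by [write_param_set()] (or assembled by
#' hand) and the tables it names. The `variant` argument implements the
#' confidence-interval swap used for sensitivity analysis: with
#' `"ci-lower"` / `"ci-upper"`, every prevalence and transition rate that
#' carries interval bounds is replaced by its lower/upper 95% limit;
#' parameters without bounds keep their point values.
#'
#' @param path directory containing `manifest.yml` and the parameter tables.
#' @param variant `"point"` (default), `"ci-lower"` or `"ci-upper"`.
#' @return A validated `crc_params` object tagged with `variant`.
#' @export
load_param_set <- function(path, variant = c("point", "ci-lower", "ci-upper")) {
  variant <- match.arg(variant)
  mf_path <- file.path(path, "manifest.yml")
  if (!file.exists(mf_path))
    stop(sprintf("no manifest.yml under '%s'", path), call. = FALSE)
  mf <- yaml::read_yaml(mf_path)

  rd <- function(name) {
    f <- file.path(path, mf$files[[name]])
    if (!file.exists(f)) stop(sprintf("parameter table '%s' missing", f),
                              call. = FALSE)
    utils::read.delim(f, stringsAsFactors = FALSE)
  }
  pick_variant <- function(df) {
    if (variant == "point" || !all(c("ci_lower", "ci_upper") %in% names(df)))
      return(df)
    col <- if (variant == "ci-lower") "ci_lower" else "ci_upper"
    has <- !is.na(df[[col]])
    df$value[has] <- df[[col]][has]
    df
  }

  param_set(
    prevalence = pick_variant(rd("prevalence")),
    transitions = pick_variant(rd("transitions")),
    tests = rd("tests"),
    mortality = rd("mortality"),
    crc_mortality = rd("crc_mortality"),
    life_expectancy = rd("life_expectancy"),
    source = if (is.null(mf$source)) "unspecified" else mf$source,
    variant = variant,
    ysd_cap = if (is.null(mf$ysd_cap)) 14L else as.integer(mf$ysd_cap)
  )
}
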