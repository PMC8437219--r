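test_that("generation is deterministic given the seed and varies across seeds", {
  a <- generate_param_set(synth_spec(seed = 4))
  b <- generate_param_set(synth_spec(seed = 4))
  c <- generate_param_set(synth_spec(seed = 5))
  expect_identical(a$transitions$value, b$transitions$value)
  expect_identical(a$prevalence$value, b$prevalence$value)
  expect_false(identical(a$transitions$value, c$transitions$value))
})

test_that("generated sets pass validation with monotone age trends", {
  for (seed in 1:5) {
    p <- generate_param_set(synth_spec(seed = seed))
    expect_silent(validate_param_set(p))
    pv <- p$prevalence
    for (s in unique(pv$sex)) {
      for (st in unique(pv$state)) {
        v <- pv$value[pv$sex == s & pv$state == st]
        v <- v[order(pv$age_lo[pv$sex == s & pv$state == st])]
        expect_true(all(diff(v) >= 0),
                    label = sprintf("prevalence nondecreasing (%s, %s, seed %d)",
                                    s, st, seed))
      }
    }
  }
})

test_that("infeasible specifications are rejected with a diagnosis", {
  expect_error(synth_spec(prevalence_50 = c(nonadv_adenoma = 0.3,
                                            adv_adenoma = 0.05,
                                            preclin_crc = 0.003),
                          prevalence_75 = c(nonadv_adenoma = 0.2,
                                            adv_adenoma = 0.1,
                                            preclin_crc = 0.01)),
               "prevalence at 75")
  expect_error(synth_spec(fit_spec = 1.4), "\\[0, 1\\]")
})

test_that("default parameters imply a plausible no-screening lifetime CRC risk", {
  spec <- synth_spec()
  p <- generate_param_set(spec)
  for (sex in c("male", "female")) {
    base <- run_scenario(scenario_config(sex), p)
    risk <- base$cases / base$cohort_size
    expect_gte(risk, spec$target_lifetime_risk[1])
    expect_lte(risk, spec$target_lifetime_risk[2])
  }
})

test_that("zero transition rates mean the cohort never develops new lesions", {
  spec <- synth_spec(transition_50 = c(no_nonadv = 0, nonadv_adv = 0,
                                       adv_preclin = 0, preclin_clin = 0),
                     transition_75 = c(no_nonadv = 0, nonadv_adv = 0,
                                       adv_preclin = 0, preclin_clin = 0))
  p <- generate_param_set(spec)
  out <- run_unscreened(p, "male", 50, 30)
  expect_equal(sum(out$flows$new_symptom_dx), 0)
  first <- out$states[[1]]$mass
  last <- out$states[[31]]$mass
  # lesion fractions only shrink through death, never grow
  alive_scale <- sum(last[c("no_lesion", "nonadv_adenoma", "adv_adenoma",
                            "preclin_crc")])
  expect_equal(last[["nonadv_adenoma"]] / alive_scale,
               first[["nonadv_adenoma"]])
})

test_that("the null degenerate set produces no CRC under any scenario", {
  d <- degenerate_sets()
  for (cfg in list(scenario_config("male"),
                   scenario_config("female", strategy_fit_annual(),
                                   selective_adherence(0.5)),
                   scenario_config("male", strategy_colonoscopy(),
                                   sporadic_adherence(c(50, 70))))) {
    out <- run_scenario(cfg, d[["null"]])
    expect_equal(out$cases, 0)
    expect_equal(out$deaths, 0)
    expect_equal(out$ypll, 0)
  }
})

test_that("the deterministic chain forces diagnosis timing exactly", {
  d <- degenerate_sets()
  det <- d[["deterministic-chain"]]

  # non-advanced adenoma at age a is diagnosed clinical CRC at age a + 3
  dist <- dist_in_state("nonadv_adenoma", age = 50L)
  for (i in 1:3) dist <- advance_year(dist, det)$dist
  expect_equal(dist$age, 53)
  expect_equal(dist$mass[["clin_symptom_0"]], 1)

  # a cohort starting in advanced adenoma books all diagnoses 2 years in
  dist <- dist_in_state("adv_adenoma", age = 60L)
  s1 <- advance_year(dist, det)
  s2 <- advance_year(s1$dist, det)
  expect_equal(s1$flows$new_symptom_dx, 0)
  expect_equal(s2$flows$new_symptom_dx, 1)
})

test_that("the useless test makes every screening scenario equal its baseline", {
  d <- degenerate_sets()
  useless <- d[["useless-test"]]
  for (cfg in list(scenario_config("male", strategy_fit_annual(),
                                   selective_adherence(1)),
                   scenario_config("female", strategy_colonoscopy(),
                                   sporadic_adherence(c(50, 60, 70))))) {
    out <- run_scenario(cfg, useless)
    expect_identical(out$cases, out$baseline$cases)
    expect_identical(out$deaths, out$baseline$deaths)
    expect_identical(out$ypll, out$baseline$ypll)
    expect_identical(out$reductions, c(cases = 0, deaths = 0, ypll = 0))
  }
})
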