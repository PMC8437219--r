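test_that("parameter sets round-trip through the delimited-text format bit-exactly", {
  p <- generate_param_set(synth_spec(seed = 7))
  dir <- withr::local_tempdir()
  write_param_set(p, dir)
  q <- load_param_set(dir, "point")
  for (comp in c("prevalence", "transitions", "tests", "mortality",
                 "crc_mortality", "life_expectancy")) {
    for (col in names(p[[comp]])) {
      if (is.numeric(p[[comp]][[col]]))
        expect_identical(q[[comp]][[col]], p[[comp]][[col]],
                         label = paste(comp, col))
      else
        expect_equal(q[[comp]][[col]], p[[comp]][[col]])
    }
  }
  expect_identical(q$meta$variant, "point")
})

test_that("CI variants select the stored bounds and are ordered around the point estimate", {
  p <- generate_param_set(synth_spec(seed = 3))
  dir <- withr::local_tempdir()
  write_param_set(p, dir)
  lo <- load_param_set(dir, "ci-lower")
  hi <- load_param_set(dir, "ci-upper")
  expect_identical(lo$meta$variant, "ci-lower")
  expect_identical(hi$transitions$value, p$transitions$ci_upper)
  expect_identical(lo$transitions$value, p$transitions$ci_lower)
  expect_true(all(lo$transitions$value <= p$transitions$value))
  expect_true(all(p$transitions$value <= hi$transitions$value))
  expect_true(all(lo$prevalence$value <= p$prevalence$value))
  expect_true(all(p$prevalence$value <= hi$prevalence$value))
  # parameters without CI bounds keep their point values
  expect_identical(lo$tests$value, p$tests$value)
  expect_identical(lo$mortality$value, p$mortality$value)
})

test_that("validation rejects out-of-range probabilities naming the offending key", {
  p <- generate_param_set(synth_spec())
  p$transitions$value[3] <- 1.2
  expect_error(validate_param_set(p), "outside \\[0, 1\\]")
  p2 <- generate_param_set(synth_spec())
  p2$prevalence$value[p2$prevalence$state == "nonadv_adenoma" &
                        p2$prevalence$sex == "male"] <- 0.6
  p2$prevalence$value[p2$prevalence$state == "adv_adenoma" &
                        p2$prevalence$sex == "male"] <- 0.5
  p2$prevalence$ci_upper <- NA_real_
  p2$prevalence$ci_lower <- NA_real_
  expect_error(validate_param_set(p2), "sum")
})

test_that("validation rejects CI bounds that do not bracket the point estimate", {
  p <- generate_param_set(synth_spec())
  p$transitions$ci_lower[5] <- p$transitions$value[5] + 0.01
  expect_error(validate_param_set(p), "bracket")
})

test_that("rate lookup uses half-open bands, extrapolates past the last band, and rejects out-of-range ages", {
  p <- flat_params(r = c(0.1, 0.2, 0.3, 0.4))
  # replace male no_lesion row with two bands to probe the boundary rule
  tr <- p$transitions
  i <- which(tr$sex == "male" & tr$from == "no_lesion")
  tr <- tr[-i, ]
  tr <- rbind(tr,
              data.frame(sex = "male", age_lo = 45, age_hi = 70,
                         from = "no_lesion", to = "nonadv_adenoma",
                         value = 0.01, ci_lower = NA_real_, ci_upper = NA_real_),
              data.frame(sex = "male", age_lo = 70, age_hi = 80,
                         from = "no_lesion", to = "nonadv_adenoma",
                         value = 0.05, ci_lower = NA_real_, ci_upper = NA_real_))
  p$transitions <- tr
  expect_equal(resolve_rate(p, "male", 69, "no_lesion", "nonadv_adenoma"), 0.01)
  # boundary age belongs to the upper band: [70, 80) contains 70
  expect_equal(resolve_rate(p, "male", 70, "no_lesion", "nonadv_adenoma"), 0.05)
  expect_equal(resolve_rate(p, "male", 72, "no_lesion", "nonadv_adenoma"), 0.05)
  # ages at or past the last band's end reuse the last band
  expect_equal(resolve_rate(p, "male", 95, "no_lesion", "nonadv_adenoma"), 0.05)
  expect_error(resolve_rate(p, "male", 44, "no_lesion", "nonadv_adenoma"),
               "outside supported range")
  expect_error(resolve_rate(p, "male", 101, "no_lesion", "nonadv_adenoma"),
               "outside supported range")
})

test_that("band lookup in a synthetic table matches a hand table read", {
  p <- generate_param_set(synth_spec(seed = 11))
  tr <- p$transitions
  row <- tr[tr$sex == "female" & tr$from == "adv_adenoma" &
              tr$age_lo <= 72 & 72 < tr$age_hi, ]
  expect_equal(resolve_rate(p, "female", 72, "adv_adenoma", "preclin_crc"),
               row$value)
})

test_that("one-year outflow including other-cause death never exceeds 1", {
  for (seed in c(1, 5, 9)) {
    p <- generate_param_set(synth_spec(seed = seed))
    tr <- p$transitions
    for (i in seq_len(nrow(tr))) {
      ages <- seq(max(tr$age_lo[i], 45), min(tr$age_hi[i] - 1, 100))
      qmax <- max(p$mortality$value[p$mortality$sex == tr$sex[i] &
                                      p$mortality$age %in% ages])
      expect_lte(tr$value[i] + qmax, 1)
    }
  }
})
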