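test_that("the initial distribution is the arithmetic complement of the starting prevalences", {
  p <- flat_params(prev = c(nonadv_adenoma = 0.20, adv_adenoma = 0.05,
                            preclin_crc = 0.002))
  d <- initial_distribution(p, "male", 50)
  expect_equal(d$mass[["no_lesion"]], 0.748)
  expect_equal(d$mass[["nonadv_adenoma"]], 0.20)
  expect_equal(d$mass[["adv_adenoma"]], 0.05)
  expect_equal(d$mass[["preclin_crc"]], 0.002)
  expect_equal(sum(d$mass), 1)
  expect_equal(sum(d$mass[grep("^clin_|^dead_", names(d$mass))]), 0)
  expect_error(initial_distribution(p, "male", 40), "outside supported range")
})

test_that("a lesion-free immortal cohort is unchanged by a year of natural history", {
  p <- flat_params()   # zero rates, zero mortality
  d0 <- initial_distribution(p, "female", 50)
  step <- advance_year(d0, p)
  expect_equal(step$dist$age, 51)
  expect_equal(step$dist$mass, d0$mass, tolerance = 1e-15)
  expect_equal(step$flows$crc_deaths, 0)
  expect_error(advance_year(state_distribution("male", 100L, d0$mass), p),
               "age 100")
})

test_that("pure other-cause attrition follows the closed form (1 - q)^n", {
  q <- 0.03
  p <- flat_params(q_all = q)
  out <- run_unscreened(p, "male", 50, 25)
  for (n in c(1, 10, 25)) {
    alive <- sum(out$states[[n + 1]]$mass) - out$states[[n + 1]]$mass[["dead_other"]]
    expect_equal(alive, (1 - q)^n, tolerance = 1e-12)
  }
})

test_that("the cohort engine matches the matrix-power oracle for an age-independent chain", {
  r <- c(0.03, 0.05, 0.08, 0.22)
  q <- 0.02
  prev <- c(nonadv_adenoma = 0.15, adv_adenoma = 0.04, preclin_crc = 0.005)
  p <- flat_params(r = r, prev = prev, q_all = q)
  P <- one_year_matrix(r, q)
  v <- c(1 - sum(prev), prev[1], prev[2], prev[3], 0, 0)

  dist <- initial_distribution(p, "male", 50)
  for (n in 1:50) {
    dist <- advance_year(dist, p)$dist
    v <- as.numeric(v %*% P)
    expect_equal(aggregate_mass(dist), v, tolerance = 1e-10,
                 label = sprintf("year %d", n))
  }
})

test_that("mass is conserved and dead states absorb monotonically over a full run", {
  p <- default_params()
  for (sex in c("male", "female")) {
    out <- run_unscreened(p, sex, 50, 50)
    dead_prev <- 0
    for (s in out$states) {
      expect_lt(abs(sum(s$mass) - 1), 1e-12)
      dead <- s$mass[["dead_crc"]] + s$mass[["dead_other"]]
      expect_gte(dead, dead_prev - 1e-15)
      dead_prev <- dead
    }
  }
})

test_that("cumulative diagnoses equal the mass that ever entered the clinical states", {
  p <- default_params()
  out <- run_unscreened(p, "male", 50, 50)
  booked <- sum(out$flows$new_symptom_dx)
  # mass ever diagnosed = still-diagnosed mass + CRC deaths + other-cause
  # deaths that occurred from a diagnosed state; reconstruct the latter by
  # conservation: everyone who entered clinical either remains there or died
  last <- out$states[[51]]$mass
  still <- sum(last[grep("^clin_", names(last))])
  died_crc <- last[["dead_crc"]]
  expect_gte(booked, still + died_crc)   # other-cause deaths from clinical >= 0
  # tight conservation check with other-cause mortality removed
  p0 <- p
  p0$mortality$value <- 0
  p0$life_expectancy$value <- 60 - 0.5 * (p0$life_expectancy$age - 45)
  out0 <- run_unscreened(p0, "male", 50, 50)
  last0 <- out0$states[[51]]$mass
  expect_equal(sum(out0$flows$new_symptom_dx),
               sum(last0[grep("^clin_", names(last0))]) + last0[["dead_crc"]],
               tolerance = 1e-12)
})

test_that("CRC-specific mortality applies only to diagnosed cancer and respects the cap", {
  cap <- 3L
  p <- flat_params(crc_q_symptom = 0.2, ysd_cap = cap)
  dist <- dist_in_state("clin_symptom_0", age = 60L, ysd_cap = cap)
  masses <- numeric(5)
  for (i in 1:5) {
    step <- advance_year(dist, p)
    dist <- step$dist
    masses[i] <- step$flows$crc_deaths
  }
  # years-since-diagnosis advances each year; mortality stops at the cap
  expect_equal(masses[1], 0.2)              # at ysd 1
  expect_equal(masses[2], 0.8 * 0.2)        # at ysd 2
  expect_equal(masses[3], 0)                # ysd 3 = cap: long-term survivor
  expect_equal(masses[4], 0)
  expect_equal(dist$mass[[paste0("clin_symptom_", cap)]], 0.8^2)

  # preclinical cancer never dies of CRC before diagnosis
  p2 <- flat_params(crc_q_symptom = 0.5, crc_q_screen = 0.5)
  d2 <- dist_in_state("preclin_crc", age = 60L)
  s2 <- advance_year(d2, p2)
  expect_equal(s2$flows$crc_deaths, 0)
})

test_that("run_unscreened enforces the age-100 horizon", {
  p <- flat_params()
  expect_error(run_unscreened(p, "male", 60, 41), "exceeds age 100")
  expect_silent(run_unscreened(p, "male", 60, 40))
})
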