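ae <- species_params("ae_vexans")
cs <- species_params("cs_melanura")

test_that("species parameter files load and validate", {
  expect_s3_class(ae, "mosq_species")
  expect_equal(ae$development$embryo$a, 1.9)
  expect_equal(ae$development$larva$a, 1.86)
  expect_equal(cs$development$larva$a, 2.25)
  expect_equal(ae$gonotrophic[c("mean", "sd", "lower", "upper")],
               list(mean = 10, sd = 1, lower = 7, upper = 13))
  expect_error(species_params("no_such_species"), "unknown species")
  bad <- unclass(ae)
  bad$gonotrophic$lower <- 11
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(species_params(f), "bracket")
})

test_that("development time follows the temperature power law", {
  # halving the temperature multiplies the mean duration by 2^a
  r <- mosquitodyn:::dev_mean(ae, "embryo", 10) /
    mosquitodyn:::dev_mean(ae, "embryo", 20)
  expect_equal(r, 2^1.90, tolerance = 1e-12)
  r2 <- mosquitodyn:::dev_mean(cs, "larva", 10) /
    mosquitodyn:::dev_mean(cs, "larva", 20)
  expect_equal(r2, 2^2.25, tolerance = 1e-12)

  # sampled means converge to A * T^-a
  m_true <- mosquitodyn:::dev_mean(ae, "larva", 25)
  d <- withr::with_seed(1, development_time(ae, "larva", 25, n = 1e5))
  expect_lt(abs(mean(d) - m_true), 3 * sd(d) / sqrt(1e5) + 0.05)
  expect_true(all(d >= 1))

  # degenerate sd: every draw equals the rounded mean
  ae0 <- ae
  ae0$development$stage_time_sd <- 0
  d0 <- development_time(ae0, "embryo", 25, n = 100)
  expect_true(all(d0 == round(mosquitodyn:::dev_mean(ae, "embryo", 25))))
})

test_that("gonotrophic cycles respect their distributions", {
  g <- withr::with_seed(2, gonotrophic_length(ae, t10 = 20, n = 1e5))
  expect_true(all(g >= 7 & g <= 13))
  expect_lt(abs(mean(g) - 10), 3 * sd(g) / sqrt(1e5) + 0.01)

  # Cs.melanura: warmer weather shortens the cycle
  warm <- withr::with_seed(3, gonotrophic_length(cs, 25, n = 1e4))
  cold <- withr::with_seed(3, gonotrophic_length(cs, 12, n = 1e4))
  expect_lt(mean(warm), mean(cold))
  expect_true(all(warm >= 1))
})

test_that("daily survival combines dryness and density dependence", {
  base <- daily_survival(ae, "larva", t10 = 24, p10 = 3,
                         stage_abundance = 0)
  expect_equal(base, mosquitodyn:::base_survival(ae, "larva", 24))
  # the dry-spell rule: below 1 mm/day is strictly worse
  dry <- daily_survival(ae, "larva", 24, p10 = 0.5, stage_abundance = 0)
  expect_lt(dry, base)
  expect_equal(dry, base * ae$survival$dry_penalty)
  # rule disabled when rainfall effects are off
  expect_equal(daily_survival(ae, "larva", 24, 0.5, 0,
                              rainfall_effects = FALSE), base)
  # linear density dependence hits zero at 1/slope
  slope <- ae$survival$dd_larva_slope
  expect_equal(daily_survival(ae, "larva", 24, 3, 1 / slope), 0)
  half <- daily_survival(ae, "larva", 24, 3, 0.5 / slope)
  expect_equal(half, base * 0.5)
  # adults feel no crowding term
  expect_equal(daily_survival(ae, "adult", 24, 3, 1e9),
               daily_survival(ae, "adult", 24, 3, 0))
  expect_error(daily_survival(ae, "larva", 24, 3, -1), "abundance")
  # probabilities stay in [0, 1] across extreme temperatures
  for (t in c(-10, 0, 15, 30, 45)) {
    s <- daily_survival(ae, "adult", t, 3, 0)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("oviposition success follows the configured response", {
  # Ae.vexans: linear in humidity, so damp beats dry
  p_hi <- mosquitodyn:::ovi_prob(ae, 20, 90)
  p_lo <- mosquitodyn:::ovi_prob(ae, 20, 40)
  expect_gt(p_hi, p_lo)
  # Cs.melanura: increasing quadratic in temperature
  expect_gt(mosquitodyn:::ovi_prob(cs, 28, 70),
            mosquitodyn:::ovi_prob(cs, 15, 70))
  # Bernoulli draws track the probability
  k <- withr::with_seed(4, sum(oviposition_success(ae, 20, 80, n = 1e5)))
  p <- mosquitodyn:::ovi_prob(ae, 20, 80)
  expect_lt(abs(k / 1e5 - p), 3 * sqrt(p * (1 - p) / 1e5))
  # degenerate probabilities
  ae0 <- ae; ae0$bloodmeal <- list(type = "linear_rh", b0 = 0, b1 = 0)
  expect_false(any(oviposition_success(ae0, 20, 80, n = 1000)))
})

test_that("egg batches grow with rainfall and respect their mean", {
  m_wet <- mosquitodyn:::egg_batch_mean(ae, 10)
  m_dry <- mosquitodyn:::egg_batch_mean(ae, 0)
  expect_gt(m_wet, m_dry)
  b <- withr::with_seed(5, egg_batch(ae, precip = 4, n = 1e5))
  m <- mosquitodyn:::egg_batch_mean(ae, 4)
  expect_lt(abs(mean(b) - m), 3 * ae$eggs$sd / sqrt(1e5) + 0.01)
  expect_true(all(b >= 0))
  ae0 <- ae; ae0$eggs$sd <- 0
  expect_true(all(egg_batch(ae0, 4, n = 50) ==
                    round(mosquitodyn:::egg_batch_mean(ae, 4))))
})
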