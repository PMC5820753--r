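# Buffer speciation, rate-constant extraction and physiological predictions.

test_that("base concentration follows Henderson-Hasselbalch", {
  expect_equal(base_concentration(buffer_spec(0.15, 7.0, 7.0)), 0.075)
  expect_equal(base_concentration(blood_buffer()), 0.1073, tolerance = 1e-3)
  # fully deprotonated limit
  b <- buffer_spec(0.15, 12.8, 6.8)
  expect_equal(base_concentration(b), 0.15, tolerance = 1e-4)
  # speciation conserves mass
  for (ph in c(3, 6.8, 7.2, 11)) {
    sp <- buffer_speciation(buffer_spec(0.15, ph, 6.8))
    expect_equal(unname(sum(sp)), 0.15, tolerance = 1e-12)
  }
  expect_error(buffer_spec(0, 7, 7), "> 0")
  expect_error(buffer_spec(0.1, 15, 7), "between")
})

test_that("first-order fits recover noiseless and noisy decays", {
  tr <- gen_trace(1e-4, 100, 0, fixture_spec(1, 50))
  fit <- fit_first_order(tr)
  expect_equal(fit$k_obs, 1e-4, tolerance = 1e-9)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)

  # with baseline and negative amplitude (inverted CD band)
  tr2 <- gen_trace(3e-5, -40, 12, fixture_spec(2, 40))
  fit2 <- fit_first_order(tr2)
  expect_equal(fit2$k_obs, 3e-5, tolerance = 1e-8)
  expect_equal(fit2$baseline, 12, tolerance = 1e-5)

  # H/D exchange rise
  tr3 <- gen_trace(2e-4, 0.95, 0, fixture_spec(3, 30), kind = "hd_exchange")
  fit3 <- fit_first_order(tr3)
  expect_equal(fit3$k_obs, 2e-4, tolerance = 1e-8)

  # noisy recovery within 3 standard errors
  trn <- gen_trace(5e-5, 100, 0, fixture_spec(7, 50, "gaussian", 1))
  fitn <- fit_first_order(trn)
  expect_lt(abs(fitn$k_obs - 5e-5), 3 * fitn$k_obs_se)

  expect_error(fit_first_order(kinetic_trace(1:5, rep(2, 5))), "constant")
  expect_error(kinetic_trace(1:4, c(1, 2, 3, 4)), "5 points")
})

test_that("noisy first-order recovery is unbiased over many replicates", {
  errs <- ses <- numeric(200)
  for (r in 1:200) {
    tr <- gen_trace(5e-5, 100, 0, fixture_spec(100 + r, 40, "gaussian", 1))
    f <- fit_first_order(tr)
    errs[r] <- f$k_obs - 5e-5
    ses[r] <- f$k_obs_se
  }
  expect_lt(abs(mean(errs)), mean(ses))
})

test_that("hydrolysis correction subtracts parallel loss channels", {
  expect_equal(correct_hydrolysis(1.2e-5, 0), 1.2e-5)
  expect_equal(correct_hydrolysis(1.2e-5, 0.2e-5), 1.0e-5)
  expect_warning(
    out <- correct_hydrolysis(1.00e-5, 1.01e-5, se_total = 1e-7,
                              se_hydrolysis = 1e-7),
    "flooring")
  expect_identical(out, 0)
  expect_error(correct_hydrolysis(1.0e-5, 2.0e-5, 1e-8, 1e-8),
               "combined uncertainty")
})

test_that("buffer-dilution series yield k_gb by OLS", {
  conc <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5)
  exact <- data.frame(base_concentration = conc,
                      k_obs = 1e-6 + 2e-4 * conc)
  fit <- extract_kgb(exact)
  expect_equal(fit$kgb, 2e-4, tolerance = 1e-9)
  expect_equal(fit$intercept, 1e-6, tolerance = 1e-9)

  noisy <- gen_buffer_series(5e-5, 0, conc,
                             fixture_spec(11, noise = "gaussian",
                                          sigma = 0.05))
  fitn <- extract_kgb(noisy)
  expect_lt(abs(fitn$kgb - 5e-5), 3 * fitn$kgb_se)

  # unbiased over replicates
  errs <- ses <- numeric(200)
  for (r in 1:200) {
    s <- gen_buffer_series(5e-5, 1e-7, conc,
                           fixture_spec(500 + r, noise = "gaussian",
                                        sigma = 0.05))
    f <- extract_kgb(s)
    errs[r] <- f$kgb - 5e-5
    ses[r] <- f$kgb_se
  }
  expect_lt(abs(mean(errs)), mean(ses))

  expect_warning(extract_kgb(data.frame(
    base_concentration = c(0.1, 0.2, 0.3), k_obs = c(3e-5, 2e-5, 1e-5))),
    "negative")
  expect_error(extract_kgb(exact[1, ]), "3")
  expect_error(extract_kgb(data.frame(base_concentration = rep(0.1, 3),
                                      k_obs = c(1, 2, 3) * 1e-5)),
               "distinct")
})

test_that("protonation and temperature corrections apply their closed forms", {
  expect_equal(protonation_correction(2e-4, 1), 2e-4)
  expect_equal(protonation_correction(2e-4, 0.5), 4e-4)
  expect_error(protonation_correction(2e-4, 0), "0, 1")

  expect_equal(temperature_correction(1e-4, 300, 300, 20), 1e-4)
  expect_equal(temperature_correction(1e-4, 300, 320, 0), 1e-4)
  expect_equal(temperature_correction(1, 298.15, 310.15, 20), 3.69,
               tolerance = 0.001)
})

test_that("racemized fraction and half-life follow first-order kinetics", {
  sc <- exposure_scenario()
  expect_equal(racemized_fraction(1e-4, exposure_scenario(duration_s = 0)),
               0)
  expect_equal(racemized_fraction(10^(-0.11 * (-48.8) - 9.81), sc), 0.285,
               tolerance = 0.01)
  long <- exposure_scenario(duration_s = 1e12)
  expect_equal(racemized_fraction(1e-4, long), 1, tolerance = 1e-12)
  expect_error(racemized_fraction(-1, sc), ">= 0")

  p <- predict_racemization(-48.8)
  expect_equal(p$half_life_s * p$k_obs, log(2))
  expect_gte(p$fraction_racemized, 0)
  expect_lte(p$fraction_racemized, 1)
})

test_that("racemized fraction is monotone in rate, duration and base", {
  set.seed(99)
  for (i in 1:30) {
    kgb <- 10^runif(1, -7, -3)
    dur <- runif(1, 1e3, 2e5)
    buf <- buffer_spec(runif(1, 0.01, 0.5), 7.2, 6.8)
    f0 <- racemized_fraction(kgb, exposure_scenario(buf, dur))
    expect_gte(racemized_fraction(kgb * runif(1, 1, 10),
                                  exposure_scenario(buf, dur)), f0)
    expect_gte(racemized_fraction(kgb,
                                  exposure_scenario(buf, dur * runif(1, 1, 10))),
               f0)
    buf2 <- buffer_spec(buf$total_concentration * runif(1, 1, 3), 7.2, 6.8)
    expect_gte(racemized_fraction(kgb, exposure_scenario(buf2, dur)), f0)
  }
})

test_that("closed-form ee decay matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:100) {
    k <- 10^runif(1, -6, -2)
    t_end <- runif(1, 0.1, 5) / k
    sol <- deSolve::lsoda(
      y = c(ee = 1), times = c(0, t_end),
      func = function(t, y, p) list(-p$k * y), parms = list(k = k),
      rtol = 1e-10, atol = 1e-12)
    expect_equal(sol[2, "ee"], exp(-k * t_end), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("risk classes bin the 24 h fraction with a closed upper bound", {
  expect_identical(classify_risk(0), "low")
  expect_identical(classify_risk(0.009999), "low")
  expect_identical(classify_risk(0.01), "medium")
  expect_identical(classify_risk(0.10), "medium")
  expect_identical(classify_risk(0.100001), "high")
  expect_identical(classify_risk(0.285), "high")
  expect_identical(classify_risk(c(0, 0.05, 0.5)),
                   c("low", "medium", "high"))
  custom <- risk_thresholds(0.001, 0.5)
  expect_identical(classify_risk(0.3, custom), "medium")
  expect_error(risk_thresholds(0.5, 0.1), "low < high")
  expect_error(classify_risk(1.5), "\\[0, 1\\]")
})
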