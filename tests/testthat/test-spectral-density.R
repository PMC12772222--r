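ctx <- acquisition_context(field_T = 14.1)

test_that("null spectral density gives zero rates and NOE of 1", {
  r <- gen_rates_from_J(0, 0, 0, ctx)
  expect_equal(unlist(r), c(R1 = 0, R2 = 0, NOE = 1))
  back <- reduced_spectral_density(r$R1, r$R2, r$NOE, ctx)
  expect_equal(back$J0, 0)
  expect_equal(back$JwN, 0)
  expect_equal(back$JwH087, 0)
})

test_that("forward/inverse mapping round-trips to 1e-10 relative", {
  set.seed(31)
  n <- 1000
  J0 <- runif(n, 1e-12, 1e-8)
  JwN <- runif(n, 1e-12, 2e-9)
  JwH <- runif(n, 1e-13, 1e-10)
  r <- gen_rates_from_J(J0, JwN, JwH, ctx)
  back <- reduced_spectral_density(r$R1, r$R2, r$NOE, ctx)
  expect_lt(max(abs(back$J0 - J0) / J0), 1e-10)
  expect_lt(max(abs(back$JwN - JwN) / JwN), 1e-10)
  expect_lt(max(abs(back$JwH087 - JwH) / JwH), 1e-10)
  expect_false(any(back$out_of_model))
})

test_that("full-expression forward model matches an independent oracle", {
  for (tc in c(1e-9, 5e-9, 10e-9)) {
    got <- rates_from_lorentzian(tc, ctx)
    want <- oracle_full_rates(tc, B0 = 14.1)
    expect_equal(got$R1, want$R1, tolerance = 1e-10)
    expect_equal(got$R2, want$R2, tolerance = 1e-10)
    expect_equal(got$NOE, want$NOE, tolerance = 1e-10)
  }
})

test_that("reduced mapping recovers the Lorentzian limit within 10%", {
  for (tc in c(1e-9, 5e-9, 10e-9)) {
    full <- rates_from_lorentzian(tc, ctx)
    m <- reduced_spectral_density(full$R1, full$R2, full$NOE, ctx)
    # the reduced-vs-full approximation error itself, quantified first:
    approx_err <- abs(gen_rates_from_J(full$J0, full$JwN, full$JwH087,
                                       ctx)$R1 - full$R1) / full$R1
    expect_lt(approx_err, 0.05)
    expect_lt(abs(m$J0 - full$J0) / full$J0, 0.10)
    expect_lt(abs(m$JwN - full$JwN) / full$JwN, 0.10)
  }
})

test_that("NOE of 1 forces J(0.87wH) = 0", {
  m <- reduced_spectral_density(1.5, 4.0, 1.0, ctx)
  expect_equal(m$JwH087, 0)
})

test_that("lower T2 at fixed T1 strictly raises R2/R1 and J(0)", {
  T1 <- 0.70
  T2 <- seq(0.32, 0.12, by = -0.04)
  ratios <- r2_over_r1(rep(T1, length(T2)), T2)
  expect_true(all(diff(ratios) > 0))
  m <- reduced_spectral_density(rep(1 / T1, length(T2)), 1 / T2,
                                rep(0.8, length(T2)), ctx)
  expect_true(all(diff(m$J0) > 0))
})

test_that("negative J(0) is returned but flagged out of model", {
  # exchange-inflated R2 drives the inferred J(0) up, not negative;
  # an inconsistently small R2 drives it negative
  r <- gen_rates_from_J(2e-9, 1e-9, 2e-11, ctx)
  m <- reduced_spectral_density(r$R1, r$R2 * 0.05, r$NOE, ctx)
  expect_true(m$J0 < 0)
  expect_true(m$out_of_model)
})

test_that("acquisition context validates and exposes the constants", {
  expect_error(acquisition_context(), "exactly one")
  expect_error(acquisition_context(field_T = 14.1, freq_MHz = 600),
               "exactly one")
  a <- acquisition_context(field_T = 14.1)
  b <- acquisition_context(freq_MHz = a$omega_H / (2 * pi) / 1e6)
  expect_equal(b$field_T, 14.1, tolerance = 1e-9)
  expect_equal(a$omega_N / a$omega_H, 2.71261804e7 / 2.6752218744e8,
               tolerance = 1e-9)
})
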