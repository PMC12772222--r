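test_that("noiseless decays are recovered exactly", {
  t <- seq(0.05, 1.75, length.out = 8)
  fit <- fit_monoexponential(t, 100 * exp(-t / 0.67), mc_reps = 0)
  expect_equal(fit$T, 0.67, tolerance = 1e-8)
  expect_equal(fit$I0, 100, tolerance = 1e-8)
  expect_false(fit$invalid)
})

test_that("degenerate inputs fail loudly", {
  t <- c(0.1, 0.2, 0.3, 0.4)
  expect_error(fit_monoexponential(t, rep(5, 4)), "no decay")
  expect_error(fit_monoexponential(c(0.1, 0.1, 0.2), c(3, 2, 1)),
               "strictly increasing")
  expect_error(fit_monoexponential(c(0.1, 0.2), c(2, 1)), "at least 3")
})

test_that("fit is scale-equivariant in the intensities", {
  set.seed(4)
  t <- seq(0, 1.2, by = 0.2)
  I <- 80 * exp(-t / 0.4) + rnorm(length(t), 0, 2)
  f1 <- fit_monoexponential(t, I, mc_reps = 0)
  f2 <- fit_monoexponential(t, 17 * I, mc_reps = 0)
  expect_equal(f2$T, f1$T, tolerance = 1e-9)
  expect_equal(f2$I0, 17 * f1$I0, tolerance = 1e-7)
})

test_that("fit agrees with grid-search and nls oracles under noise", {
  set.seed(11)
  t <- seq(0.02, 1.0, length.out = 10)
  for (Ttrue in c(0.25, 0.67)) {
    I <- 100 * exp(-t / Ttrue) + rnorm(length(t), 0, 5)
    fit <- fit_monoexponential(t, I, mc_reps = 0)
    g <- oracle_grid_fit(t, I)
    expect_equal(fit$T, g$T, tolerance = 1e-3)
    nlsfit <- minpack.lm::nlsLM(I ~ A * exp(-t / Tc),
                                start = list(A = max(I), Tc = 0.5))
    expect_equal(fit$T, coef(nlsfit)[["Tc"]], tolerance = 1e-6)
    expect_equal(fit$I0, coef(nlsfit)[["A"]], tolerance = 1e-5)
  }
})

test_that("Monte-Carlo errors behave: small study recovers T and covers truth", {
  # 48-point sampling across 0.05T..2.5T; the full-precision study (denser
  # sampling, all five planted T values) runs in the acceptance suite
  Ttrue <- 0.29
  t <- Ttrue * seq(0.05, 2.5, length.out = 48)
  n_seeds <- 40
  rel_err <- covered <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    d <- gen_decay(Ttrue, 100, t, noise_sd = 0.05, seed = 1000 + s)
    fit <- fit_monoexponential(d$delay_s, d$intensity, mc_reps = 100,
                               seed = s)
    rel_err[s] <- abs(fit$T - Ttrue) / Ttrue
    covered[s] <- abs(fit$T - Ttrue) <= 1.96 * fit$T_err
  }
  expect_lt(median(rel_err), 0.04)
  expect_gte(mean(covered), 0.9)
})

test_that("decay_fit methods are coherent", {
  t <- seq(0, 1.4, by = 0.2)
  fit <- fit_monoexponential(t, 50 * exp(-t / 0.3), mc_reps = 0)
  expect_named(coef(fit), c("I0", "T"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fitted(fit) + residuals(fit),
               fit$data$intensity, tolerance = 1e-12)
  expect_output(print(fit), "Monoexponential")
  sm <- summary(fit)
  expect_identical(sm$parameter, c("T", "I0"))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(length(t), 3L))
})

test_that("NOE ratio and first-order error propagation are correct", {
  expect_equal(compute_noe(5, 5)$noe, 1.0)
  expect_equal(compute_noe(0.23 * 80, 80)$noe, 0.23)
  expect_error(compute_noe(1, 0), "zero")
  # propagated SE vs Monte-Carlo draw
  set.seed(2)
  Isat <- 23; Iref <- 100; s_sat <- 1.5; s_ref <- 2
  got <- compute_noe(Isat, Iref, s_sat, s_ref)$noe_err
  draws <- rnorm(10000, Isat, s_sat) / rnorm(10000, Iref, s_ref)
  expect_lt(abs(got - sd(draws)) / sd(draws), 0.05)
})

test_that("group aggregation matches hand arithmetic and flags singletons", {
  agg <- aggregate_relaxation(c(0.63, 0.67, 0.71), rep("gland", 3))
  expect_equal(agg$mean, 0.67)
  expect_equal(agg$sd, 0.04)
  single <- aggregate_relaxation(0.5, "urea")
  expect_true(is.na(single$sd))
  expect_equal(single$n, 1L)
  # independent spreadsheet-style recomputation on a random table
  set.seed(9)
  v <- runif(60); g <- sample(c("a", "b", "c"), 60, replace = TRUE)
  agg <- aggregate_relaxation(v, g)
  for (i in seq_len(nrow(agg))) {
    vv <- v[g == agg$group[i]]
    m <- sum(vv) / length(vv)
    s <- sqrt(sum((vv - m)^2) / (length(vv) - 1))
    expect_equal(agg$mean[i], m, tolerance = 1e-12)
    expect_equal(agg$sd[i], s, tolerance = 1e-12)
  }
})

test_that("R2/R1 equals T1/T2 and is scale-invariant", {
  expect_equal(r2_over_r1(0.70, 0.25), 2.8)
  expect_equal(r2_over_r1(0.4, 0.4), 1.0)
  expect_equal(r2_over_r1(3 * 0.7, 3 * 0.25), r2_over_r1(0.7, 0.25))
  expect_warning(out <- r2_over_r1(c(0.7, NA), c(0.25, 0.3)), "skipped")
  expect_true(is.na(out[2]))
})
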