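test_that("ideal linear N-H...O geometry is detected; boundary excluded", {
  sys <- make_linear_hbond_system(dNO = 2.9, angle = 180)
  got <- detect_hbonds(sys, 1)
  expect_identical(nrow(got), 1L)
  expect_equal(got$dDA, 2.9, tolerance = 1e-9)
  expect_equal(got$angle, 180, tolerance = 1e-6)
  expect_identical(got$scope, "inter")
  # same pair beyond the 3.5 A cutoff
  far <- make_linear_hbond_system(dNO = 3.6, angle = 180)
  expect_identical(nrow(detect_hbonds(far, 1)), 0L)
  # good distance, bad angle
  bent <- make_linear_hbond_system(dNO = 2.9, angle = 120)
  expect_identical(nrow(detect_hbonds(bent, 1)), 0L)
})

test_that("missing hydrogens with require_explicit_H is an error", {
  sys <- make_linear_hbond_system()
  sys$atoms <- sys$atoms[sys$atoms$elesy != "H", , drop = FALSE]
  sys$xyz <- sys$xyz[c(1, 3), , , drop = FALSE]
  expect_error(detect_hbonds(sys, 1), "no hydrogens")
  relaxed <- detect_hbonds(sys, 1,
                           hbond_criteria(require_explicit_H = FALSE))
  expect_identical(nrow(relaxed), 1L)
  expect_true(is.na(relaxed$angle))
})

test_that("detector matches the exhaustive oracle on random systems", {
  for (s in 1:12) {
    sys <- make_random_system(seed = 1000 + s, with_box = (s %% 2 == 0))
    expect_same_bondset(sys, 1)
  }
})

test_that("minimum-image equals naive distances for a large box", {
  sys <- make_random_system(seed = 7, with_box = FALSE, L = 10)
  big <- sys; big$box <- c(100, 100, 100)
  a <- detect_hbonds(sys, 1); b <- detect_hbonds(big, 1)
  expect_identical(paste(a$donor, a$h, a$acceptor),
                   paste(b$donor, b$h, b$acceptor))
  expect_equal(a$dDA, b$dDA, tolerance = 1e-12)
})

test_that("pair frequencies: planted always-on bond and recount oracle", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(
    n_frames = 50, inter_bond_occupancy = 1,
    bond_occupancy_bound = 0, bond_occupancy_unbound = 0, seed = 6))
  bonds <- detect_hbonds_all(pe$system)
  pf <- pair_frequency_table(bonds, list(c("ARG", "TYR")))
  expect_equal(pf$frequency[pf$scope == "inter"], 1.0)
  expect_equal(pf$frequency[pf$scope == "intra"], 0.0)
  # exhaustive per-frame recount
  manual_inter <- mean(vapply(bonds, function(b)
    any(b$scope == "inter" &
          ((b$donor_resid == "ARG" & b$acceptor_resid == "TYR") |
             (b$donor_resid == "TYR" & b$acceptor_resid == "ARG"))), TRUE))
  expect_equal(pf$frequency[pf$scope == "inter"], manual_inter)
  expect_error(pair_frequency_table(bonds, list(c("ARG", "TYQ"))),
               "unknown residue")
})

test_that("frequencies are invariant under frame permutation", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 40, seed = 9))
  bonds <- detect_hbonds_all(pe$system)
  pf1 <- pair_frequency_table(bonds, list(c("ARG", "TYR")))
  set.seed(1)
  pf2 <- pair_frequency_table(sample(bonds), list(c("ARG", "TYR")))
  expect_equal(pf1$frequency, pf2$frequency)
})

test_that("conditional frequency: identities, degenerate strata, Wilson", {
  e <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  cf <- conditional_frequency(e, e)
  expect_equal(cf$p, c(1, 0))
  never <- conditional_frequency(e, rep(FALSE, 5))
  expect_false(never$defined[1])
  expect_true(is.na(never$p[1]))
  expect_error(conditional_frequency(c(TRUE), c(TRUE, FALSE)), "mismatch")
  # total probability identity on random series
  set.seed(14)
  for (r in 1:20) {
    ev <- runif(200) < 0.3; cond <- runif(200) < 0.6
    cf <- conditional_frequency(ev, cond)
    pc <- mean(cond)
    lhs <- mean(ev)
    rhs <- cf$p[1] * pc + cf$p[2] * (1 - pc)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})
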