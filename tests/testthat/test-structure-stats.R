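test_that("ion binding: zero case, planted recovery, exhaustive oracle", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(
    n_frames = 30, ion_bound_fraction = 0, seed = 3))
  ib <- ion_binding_fraction(pe$system, select_atoms(pe$system, resid = "PO4"))
  expect_equal(ib$fraction, 0)
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 400, seed = 8))
  sys <- pe$system
  ion <- select_atoms(sys, resid = "PO4")
  tgt <- select_atoms(sys, protein = TRUE, heavy = TRUE)
  ib <- ion_binding_fraction(sys, ion, tgt)
  p <- 0.71; se <- sqrt(p * (1 - p) / 400)
  expect_lt(abs(ib$fraction - p), 3 * se)
  expect_identical(ib$per_frame, pe$truth$ion_bound)
  want <- oracle_ion_bound(sys, ion, tgt, 4.0)
  expect_identical(unname(ib$per_frame), want)
  expect_error(ion_binding_fraction(sys, integer(0)), "empty")
})

test_that("hydration shell counts match planting and the oracle", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(
    n_frames = 10, ion_bound_fraction = 0, n_shell = 5, seed = 12))
  sys <- pe$system
  tgt <- select_atoms(sys, resid = "ARG", elety = c("NE", "NH1", "NH2"))
  expect_identical(hydration_shell_count(sys, 1, tgt), 5L)
  for (f in c(1, 5, 10))
    expect_identical(hydration_shell_count(sys, f, tgt),
                     oracle_shell_count(sys, f, tgt, 3.4))
  nowater <- sys
  keep <- sys$atoms$resid != "HOH"
  nowater$atoms <- sys$atoms[keep, , drop = FALSE]
  nowater$xyz <- sys$xyz[keep, , , drop = FALSE]
  expect_warning(out <- hydration_shell_count(nowater, 1, tgt), "no waters")
  expect_identical(out, 0L)
})

test_that("displacement recovers the planted delta", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 500, seed = 21))
  sys <- pe$system
  tgt <- select_atoms(sys, resid = "ARG", elety = c("NE", "NH1", "NH2"))
  counts <- hydration_shell_series(sys, tgt)
  ib <- ion_binding_fraction(sys, select_atoms(sys, resid = "PO4"))
  disp <- shell_displacement(ib$per_frame, counts)
  expect_equal(disp$displacement, 3.0, tolerance = 0.2)
  expect_identical(counts, pe$truth$shell_count)
})

test_that("planted cation-pi pose is recovered to 1e-6 A with exact class", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 2, seed = 31))
  cp <- detect_cation_pi(pe$system, 1)
  planted <- cp[cp$ring_chain == "B", ]
  expect_identical(nrow(planted), 1L)
  expect_equal(planted$d_eta1, 4.0, tolerance = 1e-6)
  expect_equal(planted$d_eta2, 4.5, tolerance = 1e-6)
  expect_identical(planted$geometry_class, "T-shaped")
  expect_true(planted$asymmetric)
  expect_equal(planted$theta1, 90, tolerance = 1e-6)
})

test_that("face-on stack classifies stacked and symmetric", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(
    n_frames = 1, cationpi_geometry = list(d_eta1 = 4, d_eta2 = 4,
                                           theta = 0), seed = 32))
  cp <- detect_cation_pi(pe$system, 1)
  planted <- cp[cp$ring_chain == "B", ]
  expect_identical(planted$geometry_class, "stacked")
  expect_false(planted$asymmetric)
  expect_equal(planted$theta1, 0, tolerance = 1e-6)
})

test_that("intermediate geometry falls between the class boundaries", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(
    n_frames = 1, cationpi_geometry = list(d_eta1 = 4.2, d_eta2 = 4.2,
                                           theta = 45), seed = 33))
  cp <- detect_cation_pi(pe$system, 1)
  expect_identical(cp$geometry_class[cp$ring_chain == "B"], "intermediate")
})

test_that("classification is invariant under rigid motion and relabelling", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 1, seed = 34))
  sys <- pe$system
  ref <- detect_cation_pi(sys, 1)
  ref <- ref[order(ref$ring_chain), ]
  # random rotation + translation
  set.seed(2)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]),
                 cos(th[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0,
                 cos(th[2])), 3, byrow = TRUE)
  R <- Rx %*% Ry
  rot <- sys
  rot$xyz[, , 1] <- sweep(sys$xyz[, , 1] %*% t(R), 2, c(5, -3, 2), "+")
  got <- detect_cation_pi(rot, 1)
  got <- got[order(got$ring_chain), ]
  expect_equal(got$d_eta1, ref$d_eta1, tolerance = 1e-9)
  expect_equal(got$theta1, ref$theta1, tolerance = 1e-6)
  expect_identical(got$geometry_class, ref$geometry_class)
  # swap the NH1/NH2 labels
  swap <- sys
  nh <- which(swap$atoms$resid == "ARG" &
                swap$atoms$elety %in% c("NH1", "NH2"))
  swap$atoms$elety[nh] <- rev(swap$atoms$elety[nh])
  got2 <- detect_cation_pi(swap, 1)
  got2 <- got2[order(got2$ring_chain), ]
  expect_equal(got2$d_eta1, ref$d_eta1, tolerance = 1e-12)
  expect_identical(got2$geometry_class, ref$geometry_class)
})

test_that("cation-pi detector matches the exhaustive oracle", {
  for (s in 1:10) {
    sys <- make_random_system(seed = 300 + s, with_box = (s %% 2 == 0))
    got <- detect_cation_pi(sys, 1)
    got_keys <- sort(sprintf("%s %d|%s %d|%s|%.6f|%.6f",
                             got$arg_chain, got$arg_resno,
                             got$ring_chain, got$ring_resno,
                             got$geometry_class, got$d_eta1, got$d_eta2))
    expect_identical(got_keys, oracle_cation_pi(sys, 1))
  }
})

test_that("incomplete rings are skipped with a warning", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 1, seed = 35))
  sys <- pe$system
  drop <- which(sys$atoms$chain == "B" & sys$atoms$elety == "CG")
  keep <- setdiff(seq_len(nrow(sys$atoms)), drop)
  sys$atoms <- sys$atoms[keep, , drop = FALSE]
  sys$xyz <- sys$xyz[keep, , , drop = FALSE]
  expect_warning(cp <- detect_cation_pi(sys, 1), "incomplete")
  expect_false(any(cp$ring_chain == "B"))
})
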