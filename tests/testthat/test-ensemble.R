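test_that("deterministic occupancies give exact conditional frequencies", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(
    n_frames = 100, bond_occupancy_bound = 1, bond_occupancy_unbound = 0,
    seed = 41))
  sys <- pe$system
  bonds <- detect_hbonds_all(sys)
  intra <- vapply(bonds, function(b)
    any(b$scope == "intra" & b$donor_resid == "ARG" &
          b$acceptor_resid == "TYR"), TRUE)
  ib <- ion_binding_fraction(sys, select_atoms(sys, resid = "PO4"))
  cf <- conditional_frequency(intra, ib$per_frame)
  expect_equal(cf$p[cf$stratum == "conditional"], 1.0)
  expect_equal(cf$p[cf$stratum == "complement"], 0.0)
})

test_that("sidecar truth and geometry re-derivation agree on every frame", {
  pe <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 120, seed = 42))
  sys <- pe$system
  bonds <- detect_hbonds_all(sys)
  arg_tyr <- function(b, sc) any(b$scope == sc &
    ((b$donor_resid == "ARG" & b$acceptor_resid == "TYR") |
       (b$donor_resid == "TYR" & b$acceptor_resid == "ARG")))
  intra <- vapply(bonds, arg_tyr, TRUE, sc = "intra")
  inter <- vapply(bonds, arg_tyr, TRUE, sc = "inter")
  ib <- ion_binding_fraction(sys, select_atoms(sys, resid = "PO4"))
  tgt <- select_atoms(sys, resid = "ARG", elety = c("NE", "NH1", "NH2"))
  counts <- hydration_shell_series(sys, tgt)
  expect_identical(intra, pe$truth$intra_bond)
  expect_identical(inter, pe$truth$inter_bond)
  expect_identical(unname(ib$per_frame), unname(pe$truth$ion_bound))
  expect_identical(counts, pe$truth$shell_count)
})

test_that("generation is seed-deterministic down to the written bytes", {
  spec <- planted_ensemble_spec(n_frames = 8, seed = 77)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_planted_ensemble(gen_planted_ensemble(spec), f1)
  write_planted_ensemble(gen_planted_ensemble(spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(paste0(f1, ".truth.tsv")),
                   readLines(paste0(f2, ".truth.tsv")))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(planted_ensemble_spec(ion_bound_fraction = 1.2), "\\[0, 1\\]")
  expect_error(planted_ensemble_spec(hydration_delta = 9, n_shell = 8),
               "hydration_delta")
  expect_error(planted_ensemble_spec(n_frames = 0), "n_frames")
  expect_error(planted_ensemble_spec(
    cationpi_geometry = list(d_eta1 = -1, d_eta2 = 4, theta = 90)),
    "distances")
})

test_that("spectator chains extend the system without touching the truth", {
  pe2 <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 10, seed = 5))
  pe4 <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 10,
                                                    n_chains = 4, seed = 5))
  expect_identical(length(unique(pe4$system$atoms$chain)),
                   length(unique(pe2$system$atoms$chain)) + 2L)
  expect_identical(pe4$truth, pe2$truth)
})
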