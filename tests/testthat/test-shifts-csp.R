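mk_table <- function(motifs, nuclei, shifts, state = "s",
                     residue_type = NULL) {
  if (is.null(residue_type)) residue_type <- substr(motifs, 1, 1)
  data.frame(state = state, motif = motifs, reporter_index = 1L,
             residue_type = residue_type, nucleus = nuclei,
             component_rank = 1L, shift_ppm = shifts)
}

test_that("a 0.27 ppm 15N Arg perturbation is significant; identity is not", {
  a <- mk_table("R", "N", 120.00)
  b <- mk_table("R", "N", 120.27)
  out <- compute_csp(a, b)
  expect_equal(out$delta, 0.27)
  expect_true(out$significant)
  same <- compute_csp(a, a)
  expect_equal(same$delta, 0)
  expect_false(any(same$significant))
})

test_that("planted super-threshold sites are recovered exactly (brute force)", {
  set.seed(21)
  n <- 20
  motifs <- sprintf("G%02d", seq_len(n))
  nuc <- rep(c("H", "N"), length.out = n)
  base <- runif(n, 8, 120)
  delta <- runif(n, 0.001, 0.5) * sample(c(-1, 1), n, replace = TRUE)
  thr <- default_csp_thresholds()
  # plant exactly 7 super-threshold sites, rest forced sub-threshold
  super <- sample(n, 7)
  delta[-super] <- delta[-super] * 0
  delta[-super] <- runif(n - 7, 0, 0.8) * thr[nuc[-super]] *
    sample(c(-1, 1), n - 7, replace = TRUE)
  delta[super] <- sign(delta[super]) * (thr[nuc[super]] + runif(7, 0.01, 0.3))
  a <- mk_table(motifs, nuc, base, residue_type = "G")
  b <- mk_table(motifs, nuc, base + delta, residue_type = "G")
  out <- compute_csp(a, b)
  # exhaustive manual scan
  manual <- abs(b$shift_ppm - a$shift_ppm) > unname(thr[nuc])
  expect_identical(out$significant[match(paste(motifs, nuc),
                                         paste(out$motif, out$nucleus))],
                   manual)
  expect_identical(sum(out$significant), 7L)
})

test_that("CSP is antisymmetric and monotone in the threshold", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    motifs <- sprintf("M%03d", seq_len(n))
    nuc <- sample(c("H", "N", "CA"), n, replace = TRUE)
    a <- mk_table(motifs, nuc, runif(n, 0, 130))
    b <- mk_table(motifs, nuc, a$shift_ppm + rnorm(n, 0, 0.2))
    ab <- compute_csp(a, b); ba <- compute_csp(b, a)
    expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
    lo <- compute_csp(a, b, thresholds = c(H = 0.03, N = 0.1, C = 0.1))
    hi <- compute_csp(a, b, thresholds = c(H = 0.06, N = 0.2, C = 0.2))
    expect_lte(sum(hi$significant), sum(lo$significant))
  }
})

test_that("unmatched keys are reported, never dropped silently", {
  a <- mk_table(c("R", "GG"), c("N", "N"), c(120, 108))
  b <- mk_table(c("R", "AY"), c("N", "N"), c(120.1, 115))
  out <- compute_csp(a, b)
  expect_equal(nrow(out), 1)
  un <- attr(out, "unmatched")
  expect_setequal(un$motif, c("GG", "AY"))
  expect_error(compute_csp(mk_table("R", "N", 1), mk_table("G", "N", 1)),
               "share no")
})

test_that("motif-site labels validate the reporter position", {
  expect_identical(motif_site("AAG", 2, "A"), "AAG@2")
  expect_error(motif_site("AAG", 2, "G"), "does not match")
  expect_error(motif_site("AAG", 5, "A"), "outside")
})
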