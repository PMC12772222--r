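# "interior" below = residues more than two positions from either chain
# terminus, where the bridge/turn patterns are fully defined.

interior_mask <- function(tab) {
  ok <- logical(nrow(tab))
  for (ch in unique(tab$chain)) {
    idx <- which(tab$chain == ch)
    ok[idx[seq(3, length(idx) - 2)]] <- TRUE
  }
  ok
}

test_that("ideal alpha helix assigns >= 90% H in the interior", {
  ss <- assign_secondary_structure(build_alpha_helix(12))
  inner <- interior_mask(ss$table)
  expect_gte(mean(ss$classes[inner] == "H"), 0.9)
  expect_true(all(ss$hbonds$energy < -0.5))
})

test_that("isolated extended chain is all coil", {
  ss <- assign_secondary_structure(build_extended_chain(10))
  expect_true(all(ss$classes == "C"))
  expect_identical(nrow(ss$hbonds), 0L)
})

test_that("ideal antiparallel sheet assigns >= 90% E in the interior", {
  ss <- assign_secondary_structure(build_beta_sheet(8))
  inner <- interior_mask(ss$table)
  expect_gte(mean(ss$classes[inner] == "E"), 0.9)
  # cross-strand bonds only
  expect_true(all(ss$table$chain[ss$hbonds$donor] !=
                    ss$table$chain[ss$hbonds$acceptor]))
})

test_that("missing backbone atoms degrade to coil with a warning", {
  sys <- build_extended_chain(6)
  drop <- which(sys$atoms$resno == 3 & sys$atoms$elety == "O")
  keep <- setdiff(seq_len(nrow(sys$atoms)), drop)
  sys$atoms <- sys$atoms[keep, , drop = FALSE]
  sys$xyz <- sys$xyz[keep, , , drop = FALSE]
  expect_warning(ss <- assign_secondary_structure(sys), "missing backbone")
  expect_identical(ss$classes[3], "C")
})

test_that("composition tally matches hand arithmetic and the recount oracle", {
  cls <- c(rep("E", 87), rep("C", 13))
  comp <- ss_composition_by_residue_type(cls, strrep("A", 100))
  expect_equal(comp$by_type$E[comp$by_type$residue_type == "A"], 0.87)
  # mixed sequence vs independent tally
  set.seed(6)
  seqv <- sample(c("A", "G", "Q"), 200, replace = TRUE)
  cls <- sample(c("H", "E", "C"), 200, replace = TRUE)
  comp <- ss_composition_by_residue_type(cls, paste(seqv, collapse = ""))
  want <- oracle_ss_tally(cls, seqv)
  for (tp in names(want)) {
    row <- comp$by_type[comp$by_type$residue_type == tp, ]
    expect_equal(unlist(row[c("H", "E", "C")]),
                 want[[tp]][c("H", "E", "C")], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(comp$global["E"]), mean(cls == "E"), tolerance = 1e-12)
  # absent types are simply not listed
  expect_false("Y" %in% comp$by_type$residue_type)
  expect_error(ss_composition_by_residue_type(cls, "AG"), "mismatch")
})
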