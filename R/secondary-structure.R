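# Simplified DSSP-style secondary-structure assignment (3 classes:
# H = helix, E = strand, C = coil) from backbone geometry, using the
# Kabsch-Sander electrostatic hydrogen-bond energy
#   E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
# (donor amide N-H of residue i, acceptor carbonyl C=O of residue j),
# bond when E < -0.5 kcal/mol.

.ks_energy <- function(N, H, C, O, box = NULL) {
  rON <- .vec_dist(O, N, box); rCH <- .vec_dist(C, H, box)
  rOH <- .vec_dist(O, H, box); rCN <- .vec_dist(C, N, box)
  27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# residue table of backbone atom indices; NA where absent
.backbone_index <- function(system) {
  a <- system$atoms
  prot <- !a$resid %in% .nonprotein_resids
  key <- unique(data.frame(chain = a$chain, resno = a$resno)[prot, ])
  key <- key[order(key$chain, key$resno), , drop = FALSE]
  find <- function(ch, rn, name) {
    i <- which(a$chain == ch & a$resno == rn & a$elety == name)
    if (length(i)) i[1] else NA_integer_
  }
  key$N <- mapply(find, key$chain, key$resno, "N")
  key$H <- mapply(find, key$chain, key$resno, "H")
  key$CA <- mapply(find, key$chain, key$resno, "CA")
  key$C <- mapply(find, key$chain, key$resno, "C")
  key$O <- mapply(find, key$chain, key$resno, "O")
  key$resid <- vapply(seq_len(nrow(key)), function(i) {
    a$resid[a$chain == key$chain[i] & a$resno == key$resno[i]][1]
  }, "")
  rownames(key) <- NULL
  key
}

#' Assign simplified secondary structure (H/E/C) to one frame
#'
#' Computes Kabsch-Sander hydrogen-bond energies between all backbone
#' amide donors and carbonyl acceptors (sequence-adjacent residues in the
#' same chain excluded), then:
#' * helix (H): two consecutive i -> i+4 turns mark residues i+1..i+4;
#' * strand (E): parallel or antiparallel bridge patterns, extended to
#'   ladders;
#' * everything else coil (C).
#' Helix takes precedence over strand for a residue carrying both
#' patterns.  Residues with missing backbone atoms (or prolines, which
#' have no amide H) cannot donate; residues missing C/O cannot accept;
#' fully unresolvable residues are assigned C with a warning.
#'
#' @param system a `molecular_system`.
#' @param frame frame index.
#' @return list of class `ss_assignment`: `table` (data.frame chain,
#'   resno, resid, class), `classes` (character vector), `hbonds`
#'   (data.frame donor/acceptor residue row indices and energies,
#'   kcal/mol).
#' @export
assign_secondary_structure <- function(system, frame = 1) {
  stopifnot(inherits(system, "molecular_system"))
  X <- frame_coords(system, frame)
  bb <- .backbone_index(system)
  n <- nrow(bb)
  incomplete <- is.na(bb$N) | is.na(bb$C) | is.na(bb$O)
  if (any(incomplete))
    warning(sum(incomplete), " residue(s) with missing backbone atoms ",
            "assigned C")
  # donor i (N,H) -> acceptor j (C,O)
  can_donate <- !is.na(bb$N) & !is.na(bb$H)
  can_accept <- !is.na(bb$C) & !is.na(bb$O)
  hb <- matrix(FALSE, n, n)
  energies <- list()
  for (i in which(can_donate)) for (j in which(can_accept)) {
    if (i == j) next
    if (bb$chain[i] == bb$chain[j] && abs(bb$resno[i] - bb$resno[j]) < 2) next
    # cheap prefilter: N...O beyond 5.2 A cannot reach -0.5 kcal/mol
    if (.vec_dist(X[bb$N[i], ], X[bb$O[j], ], system$box) > 5.2) next
    e <- .ks_energy(X[bb$N[i], ], X[bb$H[i], ], X[bb$C[j], ], X[bb$O[j], ],
                    system$box)
    if (e < -0.5) {
      hb[i, j] <- TRUE
      energies[[length(energies) + 1]] <- data.frame(donor = i, acceptor = j,
                                                     energy = e)
    }
  }
  # sequence successor within the same chain
  succ <- c(seq_len(n)[-1], NA)
  succ[bb$chain != c(bb$chain[-1], "")] <- NA
  prev <- c(NA, seq_len(n)[-n])
  prev[bb$chain != c("", bb$chain[-n])] <- NA
  step <- function(i, k) {  # i + k within chain, else NA
    while (k > 0 && !is.na(i)) { i <- succ[i]; k <- k - 1 }
    while (k < 0 && !is.na(i)) { i <- prev[i]; k <- k + 1 }
    i
  }
  HB <- function(i, j) !is.na(i) && !is.na(j) && hb[i, j]
  cls <- rep("C", n)
  # strands: bridge patterns
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3 && bb$chain[i] == bb$chain[j]) next
    anti <- (HB(i, j) && HB(j, i)) ||
      (HB(step(i, -1), step(j, 1)) && HB(step(j, -1), step(i, 1)))
    para <- (HB(step(i, -1), j) && HB(j, step(i, 1))) ||
      (HB(step(j, -1), i) && HB(i, step(j, 1)))
    if (anti || para) { cls[i] <- "E"; cls[j] <- "E" }
  }
  # helices: consecutive i -> i+4 turns
  turn4 <- vapply(seq_len(n), function(i) HB(step(i, 4), i), TRUE)
  for (i in seq_len(n - 1)) {
    if (turn4[i] && i + 1 <= n && turn4[i + 1]) {
      idx <- vapply(1:4, function(k) step(i, k), 0L)
      cls[idx[!is.na(idx)]] <- "H"
    }
  }
  structure(list(
    table = data.frame(chain = bb$chain, resno = bb$resno, resid = bb$resid,
                       class = cls),
    classes = cls,
    hbonds = if (length(energies)) do.call(rbind, energies)
    else data.frame(donor = integer(), acceptor = integer(), energy = numeric())
  ), class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat("Secondary-structure assignment (", length(x$classes), " residues):\n",
      sep = "")
  for (ch in unique(x$table$chain)) {
    cat(sprintf("  %s: %s\n", ch,
                paste(x$classes[x$table$chain == ch], collapse = "")))
  }
  invisible(x)
}

#' Secondary-structure composition by residue type
#'
#' Fraction of each class per residue type (count(class & type) /
#' count(type)) plus global class fractions.
#'
#' @param assignment an `ss_assignment` (or a character vector of H/E/C
#'   classes, in which case `sequence` must be given).
#' @param sequence optional one-letter residue-type vector/string matching
#'   the assignment length.
#' @return list with `by_type` (data.frame residue_type, n, H, E, C) and
#'   `global` (named fractions).  Residue types absent from the input are
#'   simply not listed.
#' @export
ss_composition_by_residue_type <- function(assignment, sequence = NULL) {
  if (inherits(assignment, "ss_assignment")) {
    cls <- assignment$classes
    if (is.null(sequence))
      sequence <- vapply(assignment$table$resid, .aa3to1, "")
  } else cls <- as.character(assignment)
  if (is.null(sequence)) stop("sequence required for a bare class vector")
  if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != length(cls)) stop("assignment/sequence length mismatch")
  types <- sort(unique(sequence))
  by_type <- do.call(rbind, lapply(types, function(tp) {
    sel <- sequence == tp
    data.frame(residue_type = tp, n = sum(sel),
               H = mean(cls[sel] == "H"),
               E = mean(cls[sel] == "E"),
               C = mean(cls[sel] == "C"))
  }))
  list(by_type = by_type,
       global = c(H = mean(cls == "H"), E = mean(cls == "E"),
                  C = mean(cls == "C")))
}

.aa3to1 <- function(res) {
  m <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
  out <- m[res]
  out[is.na(out)] <- "X"
  unname(out)
}
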