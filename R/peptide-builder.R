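# Ideal-geometry backbone builders, used to construct reference
# secondary-structure fixtures (helix, extended chain, antiparallel
# sheet) from internal coordinates.

# Place atom D given positions A, B, C, the bond length C-D, the angle
# B-C-D (degrees) and the torsion A-B-C-D (degrees).  NeRF construction.
.place_atom <- function(A, B, C, r, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180; chi <- chi_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone from phi/psi angles
#'
#' Constructs an all-Ala backbone (atoms N, H, CA, C, O; the first
#' residue has no amide H) with standard bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231, N-H 1.01 angstrom;
#' omega fixed at 180 degrees).  The amide H and carbonyl O are placed in
#' the peptide plane along the external bisector of their heavy-atom
#' neighbours.
#'
#' @param n number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled to length `n`).
#' @param chain chain identifier.
#' @param resid residue name used for every residue.
#' @return a `molecular_system` with one frame.
#' @examples
#' helix <- build_peptide(10, phi = -57, psi = -47)
#' @export
build_peptide <- function(n, phi = -139, psi = 135, chain = "A",
                          resid = "ALA") {
  stopifnot(n >= 2)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  Npos <- CApos <- Cpos <- matrix(NA_real_, n, 3)
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(1.458, 0, 0)
  a <- (180 - 111.2) * pi / 180
  Cpos[1, ] <- CApos[1, ] + 1.525 * c(cos(a), sin(a), 0)
  for (i in 2:n) {
    Npos[i, ] <- .place_atom(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                             1.329, 116.2, psi[i - 1])
    CApos[i, ] <- .place_atom(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                              1.458, 121.7, 180)
    Cpos[i, ] <- .place_atom(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                             1.525, 111.2, phi[i])
  }
  # pseudo N after the last residue fixes the last carbonyl direction
  pseudoN <- .place_atom(Npos[n, ], CApos[n, ], Cpos[n, ], 1.329, 116.2, psi[n])
  bisector_place <- function(centre, nb1, nb2, r) {
    u <- nb1 - centre; u <- u / sqrt(sum(u^2))
    v <- nb2 - centre; v <- v / sqrt(sum(v^2))
    w <- -(u + v); w <- w / sqrt(sum(w^2))
    centre + r * w
  }
  atoms <- list(); coords <- list()
  add <- function(name, rn, p, ele) {
    atoms[[length(atoms) + 1]] <<- data.frame(elety = name, resid = resid,
                                              chain = chain, resno = rn,
                                              elesy = ele)
    coords[[length(coords) + 1]] <<- p
  }
  for (i in seq_len(n)) {
    add("N", i, Npos[i, ], "N")
    if (i > 1)
      add("H", i, bisector_place(Npos[i, ], Cpos[i - 1, ], CApos[i, ], 1.01), "H")
    add("CA", i, CApos[i, ], "C")
    add("C", i, Cpos[i, ], "C")
    nextN <- if (i < n) Npos[i + 1, ] else pseudoN
    add("O", i, bisector_place(Cpos[i, ], CApos[i, ], nextN, 1.231), "O")
  }
  molecular_system(do.call(rbind, atoms), do.call(rbind, coords))
}

#' Ideal alpha-helix fixture
#'
#' @param n number of residues.
#' @return a `molecular_system`: single chain at phi = -57, psi = -47.
#' @export
build_alpha_helix <- function(n = 12) build_peptide(n, phi = -57, psi = -47)

#' Ideal extended single chain fixture (no hydrogen-bond partners)
#'
#' @param n number of residues.
#' @return a `molecular_system` at phi = -139, psi = 135.
#' @export
build_extended_chain <- function(n = 10) build_peptide(n, phi = -139, psi = 135)

#' Ideal two-strand antiparallel beta-sheet fixture
#'
#' Analytic flat-sheet template: strand A runs +x, strand B runs -x at an
#' inter-strand spacing giving N...O = 2.9 angstrom, with each residue's
#' N-H and C=O pointing to the same side and sides alternating along the
#' strand, so alternate residues form the canonical narrow
#' (bidirectional) hydrogen-bonded pairs and the residues in between are
#' bridged by the wide-pair pattern.  Twist is omitted deliberately: the
#' fixture is a reference geometry for the bond-energy and bridge logic,
#' not a physical model.
#'
#' @param n residues per strand.
#' @return a `molecular_system` with chains A and B.
#' @export
build_beta_sheet <- function(n = 8) {
  stopifnot(n >= 4)
  dy <- 4.13                       # N...O' = dy - 1.23 = 2.90 angstrom
  atoms <- list(); coords <- list()
  add <- function(name, ch, rn, p, ele) {
    atoms[[length(atoms) + 1]] <<- data.frame(elety = name, resid = "ALA",
                                              chain = ch, resno = rn,
                                              elesy = ele)
    coords[[length(coords) + 1]] <<- p
  }
  h_a <- function(i) if (i %% 2 == 1) 1 else -1   # strand A side pattern
  for (i in seq_len(n)) {
    x <- 3.5 * i; s <- h_a(i)
    add("N", "A", i, c(x, 0, 0), "N")
    add("H", "A", i, c(x, s * 1.0, 0), "H")
    add("CA", "A", i, c(x + 1.0, -0.4 * s, 0), "C")
    add("C", "A", i, c(x + 2.0, 0, 0), "C")
    add("O", "A", i, c(x + 2.0, s * 1.23, 0), "O")
  }
  # strand B: residue j pairs with A residue n+1-j; N'_j sits over the
  # partner's carbonyl carbon position
  for (j in seq_len(n)) {
    i <- n + 1 - j
    x <- 3.5 * i + 2.0
    s <- -h_a(i)                   # mirrored side pattern
    add("N", "B", j, c(x, dy, 0), "N")
    add("H", "B", j, c(x, dy + s * 1.0, 0), "H")
    add("CA", "B", j, c(x - 1.0, dy - 0.4 * s, 0), "C")
    add("C", "B", j, c(x - 2.0, dy, 0), "C")
    add("O", "B", j, c(x - 2.0, dy + s * 1.23, 0), "O")
  }
  molecular_system(do.call(rbind, atoms), do.call(rbind, coords))
}
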