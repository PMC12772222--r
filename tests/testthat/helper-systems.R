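# Random small-system generator for property tests of the geometric
# detectors.  Systems mix protein chains (N/O/H atoms so H-bonds can
# occur), Arg guanidinium groups, aromatic rings, waters, and ions, at
# random positions in a cube; optionally periodic.

make_random_system <- function(seed, n_res = 12, with_box = FALSE, L = 18) {
  set.seed(seed)
  atoms <- list(); coords <- list()
  add <- function(elety, resid, chain, resno, ele, p) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      elety = elety, resid = resid, chain = chain, resno = resno, elesy = ele)
    coords[[length(coords) + 1]] <<- p
  }
  rnd <- function() runif(3, 0, L)
  rdir <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
  resno <- 0
  for (ch in c("A", "B")) for (r in seq_len(n_res)) {
    resno <- resno + 1
    kind <- sample(c("plain", "arg", "tyr", "plain"), 1)
    p0 <- rnd()
    if (kind == "plain") {
      add("N", "GLY", ch, r, "N", p0)
      add("H", "GLY", ch, r, "H", p0 + 1.0 * rdir())
      add("O", "GLY", ch, r, "O", p0 + runif(3, -2, 2))
      add("C", "GLY", ch, r, "C", p0 + runif(3, -2, 2))
    } else if (kind == "arg") {
      add("CZ", "ARG", ch, r, "C", p0)
      d1 <- rdir(); d2 <- rdir()
      add("NH1", "ARG", ch, r, "N", p0 + 1.33 * d1)
      add("HH11", "ARG", ch, r, "H", p0 + 2.3 * d1)
      add("NH2", "ARG", ch, r, "N", p0 + 1.33 * d2)
      add("O", "ARG", ch, r, "O", p0 + runif(3, -3, 3))
    } else {
      # planar hexagon, random orientation, slight optional pucker
      cen <- p0
      u <- rdir(); v0 <- rdir()
      v <- v0 - sum(v0 * u) * u; v <- v / sqrt(sum(v^2))
      w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (k in 0:5) {
        ang <- k * pi / 3
        add(nm[k + 1], "TYR", ch, r, "C",
            cen + 1.39 * (cos(ang) * u + sin(ang) * v) +
              0.02 * rnorm(1) * w)
      }
      add("OH", "TYR", ch, r, "O", cen + 2.75 * u)
    }
  }
  for (w in 1:8) add("O", "HOH", "W", w, "O", rnd())
  add("P", "PO4", "I", 1, "P", rnd())
  add("CL", "CLA", "I", 2, "CL", rnd())
  molecular_system(do.call(rbind, atoms), do.call(rbind, coords),
                   box = if (with_box) c(L, L, L) else NULL)
}

# canonical hand-placed N-H...O=C geometry for direct H-bond checks
make_linear_hbond_system <- function(dNO = 2.9, angle = 180) {
  th <- (180 - angle) * pi / 180
  atoms <- rbind(
    data.frame(elety = "N", resid = "GLY", chain = "A", resno = 1, elesy = "N"),
    data.frame(elety = "H", resid = "GLY", chain = "A", resno = 1, elesy = "H"),
    data.frame(elety = "O", resid = "GLY", chain = "B", resno = 1, elesy = "O"))
  # H on the x axis; acceptor rotated off-axis by (180 - angle)
  dHO <- dNO - 1.0
  xyz <- rbind(c(0, 0, 0),
               c(1.0, 0, 0),
               c(1.0 + dHO * cos(th), dHO * sin(th), 0))
  molecular_system(atoms, xyz)
}

expect_same_bondset <- function(system, frame = 1,
                                criteria = hbond_criteria()) {
  got <- detect_hbonds(system, frame, criteria)
  got_keys <- sort(paste(got$donor, got$h, got$acceptor))
  want <- oracle_hbonds(system, frame, criteria$dist_max, criteria$angle_min)
  expect_identical(got_keys, want)
}
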