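# Independent oracles: exhaustive / closed-form re-implementations kept
# deliberately separate from the package code paths they check.

# grid-search monoexponential fit: exhaustive scan over T with profiled
# amplitude
oracle_grid_fit <- function(t, I, T_lo = 1e-3, T_hi = 20, n_grid = 20000) {
  Ts <- exp(seq(log(T_lo), log(T_hi), length.out = n_grid))
  sse <- vapply(Ts, function(Tv) {
    e <- exp(-t / Tv)
    I0 <- sum(I * e) / sum(e * e)
    sum((I - I0 * e)^2)
  }, 0)
  Tbest <- Ts[which.min(sse)]
  e <- exp(-t / Tbest)
  list(T = Tbest, I0 = sum(I * e) / sum(e * e))
}

# full-expression dipolar/CSA rigid-rotor rates, written from scratch
# with its own constants (checks rates_from_lorentzian and, in the
# high-frequency limit, gen_rates_from_J)
oracle_full_rates <- function(tau_c, B0, r_NH_A = 1.02, dsigma_ppm = -160) {
  mu0 <- 4 * pi * 1e-7; hbar <- 6.62607015e-34 / (2 * pi)
  gH <- 2.6752218744e8; gN <- 2.71261804e7  # magnitudes
  wH <- gH * B0; wN <- gN * B0
  d <- mu0 * hbar * gH * gN / (4 * pi * (r_NH_A * 1e-10)^3)
  cc <- wN * abs(dsigma_ppm) * 1e-6 / sqrt(3)
  J <- function(w) 0.4 * tau_c / (1 + (w * tau_c)^2)
  # 15N has negative gamma: double quantum at wH - wN, zero quantum wH + wN
  R1 <- (d^2 / 4) * (J(wH + wN) + 3 * J(wN) + 6 * J(wH - wN)) + cc^2 * J(wN)
  R2 <- (d^2 / 8) * (4 * J(0) + J(wH + wN) + 3 * J(wN) + 6 * J(wH) +
                       6 * J(wH - wN)) + (cc^2 / 6) * (4 * J(0) + 3 * J(wN))
  sigma <- (d^2 / 4) * (6 * J(wH - wN) - J(wH + wN))
  list(R1 = R1, R2 = R2, NOE = 1 - (gH / gN) * sigma / R1,
       J0 = J(0), JwN = J(wN), JwH087 = J(0.87 * wH))
}

# exhaustive H-bond scan: every (H, donor, acceptor) combination tested
# directly from raw coordinates
oracle_hbonds <- function(system, frame, dist_max = 3.5, angle_min = 150) {
  X <- system$xyz[, , frame]
  a <- system$atoms
  box <- system$box
  mi <- function(v) if (is.null(box)) v else v - box * round(v / box)
  dd <- function(i, j) sqrt(sum(mi(X[i, ] - X[j, ])^2))
  found <- character(0)
  h_atoms <- which(a$elesy == "H")
  no_atoms <- which(a$elesy %in% c("N", "O"))
  for (h in h_atoms) {
    # the H's covalent heavy partner
    dists <- vapply(no_atoms, function(d) dd(h, d), 0)
    if (!any(dists <= 1.2)) next
    don <- no_atoms[which.min(dists)]
    for (acc in no_atoms) {
      if (acc == don || acc == h) next
      if (a$chain[acc] == a$chain[don] && a$resno[acc] == a$resno[don]) next
      if (dd(don, acc) > dist_max) next
      u <- mi(X[don, ] - X[h, ]); v <- mi(X[acc, ] - X[h, ])
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang >= angle_min)
        found <- c(found, paste(don, h, acc))
    }
  }
  sort(found)
}

# exhaustive per-frame ion binding booleans
oracle_ion_bound <- function(system, ion_idx, target_idx, cutoff) {
  box <- system$box
  vapply(seq_len(dim(system$xyz)[3]), function(f) {
    X <- system$xyz[, , f]
    for (i in ion_idx) for (j in target_idx) {
      v <- X[i, ] - X[j, ]
      if (!is.null(box)) v <- v - box * round(v / box)
      if (sqrt(sum(v^2)) <= cutoff) return(TRUE)
    }
    FALSE
  }, TRUE)
}

# exhaustive water-shell count
oracle_shell_count <- function(system, frame, target_idx, radius) {
  X <- system$xyz[, , frame]
  a <- system$atoms
  box <- system$box
  wat <- which(a$resid %in% c("HOH", "WAT", "SOL", "TIP") & a$elesy == "O")
  n <- 0L
  for (w in wat) {
    inshell <- FALSE
    for (j in target_idx) {
      v <- X[w, ] - X[j, ]
      if (!is.null(box)) v <- v - box * round(v / box)
      if (sqrt(sum(v^2)) <= radius) { inshell <- TRUE; break }
    }
    if (inshell) n <- n + 1L
  }
  n
}

# exhaustive cation-pi scan (same geometric definitions, independent
# search): returns sorted "argres|ringres|class" strings plus distances
oracle_cation_pi <- function(system, frame, window = 6.0) {
  X <- system$xyz[, , frame]
  a <- system$atoms
  box <- system$box
  mi <- function(v) if (is.null(box)) v else v - box * round(v / box)
  rk <- paste(a$chain, a$resno)
  out <- character(0)
  for (rg in unique(rk[a$resid %in% c("TYR", "PHE")])) {
    ridx <- which(rk == rg &
                    a$elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
    if (length(ridx) != 6) next
    P <- X[ridx, , drop = FALSE]
    if (!is.null(box))
      for (k in 2:6) P[k, ] <- P[1, ] + mi(P[k, ] - P[1, ])
    cen <- colMeans(P)
    s <- svd(sweep(P, 2, cen))
    nrm <- s$v[, 3]
    for (ag in unique(rk[a$resid == "ARG"])) {
      nh <- which(rk == ag & a$elety %in% c("NH1", "NH2"))
      if (length(nh) != 2) next
      vs <- lapply(nh, function(i) mi(X[i, ] - cen))
      d <- vapply(vs, function(v) sqrt(sum(v^2)), 0)
      th <- vapply(vs, function(v)
        acos(min(1, abs(sum(v * nrm)) / sqrt(sum(v^2)))) * 180 / pi, 0)
      o <- order(d); d <- d[o]; th <- th[o]
      if (d[1] > window) next
      cls <- if (min(th) <= 30) "stacked"
      else if (max(th) >= 60) "T-shaped" else "intermediate"
      out <- c(out, sprintf("%s|%s|%s|%.6f|%.6f", ag, rg, cls, d[1], d[2]))
    }
  }
  sort(out)
}

# independent class recount for SS composition
oracle_ss_tally <- function(classes, sequence) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  out <- list()
  for (tp in sort(unique(sequence))) {
    sel <- sequence == tp
    out[[tp]] <- c(H = sum(classes[sel] == "H") / sum(sel),
                   E = sum(classes[sel] == "E") / sum(sel),
                   C = sum(classes[sel] == "C") / sum(sel))
  }
  out
}
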