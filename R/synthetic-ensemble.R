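# Planted-truth coordinate ensembles.
#
# The generator builds a minimal two-chain reporter system in which every
# interaction statistic the geometry module measures has a planted,
# per-frame known value:
#
#   chain A  ARG 1   guanidinium (NE, CZ, NH1, NH2 + HH11/HH21) posed
#                    against the chain-B Tyr ring at the requested
#                    cation-pi geometry; donor for both reporter H-bonds
#   chain A  TYR 2   remote residue whose OH shuttles in/out of H-bond
#                    geometry with Arg NH2 (the intramolecular bond)
#   chain B  TYR 1   aromatic ring (cation-pi target); its OH shuttles
#                    in/out of H-bond geometry with Arg NH1 (the
#                    intermolecular bond)
#   ion      PO4 P   inside/outside the binding cutoff per frame
#   waters   HOH O   first-shell population around the Arg side-chain
#                    nitrogens, reduced by `hydration_delta` in ion-bound
#                    frames
#
# Geometry is the test target, not physics: residues are idealised rigid
# fragments (no force-field relaxation), waters are single O atoms, and
# explicit H atoms exist exactly where hydrogen-bond detection needs
# them.  Every planted state is logged to a ground-truth sidecar table.

#' Specification for a planted coordinate ensemble
#'
#' @param n_frames number of frames (>= 1).
#' @param bond_occupancy_bound,bond_occupancy_unbound occupancy of the
#'   intramolecular Arg-Tyr hydrogen bond conditional on the ion-bound
#'   state of the frame (probabilities; defaults 0.24 / 0.10, magnitudes
#'   mirroring phosphate-condensate MD statistics).
#' @param inter_bond_occupancy unconditional occupancy of the
#'   intermolecular Arg-Tyr hydrogen bond (default 0.54).
#' @param ion_bound_fraction fraction of frames with the ion inside the
#'   binding cutoff (default 0.71).
#' @param hydration_delta number of first-shell waters displaced in
#'   ion-bound frames (default 3; must not exceed `n_shell`).
#' @param n_shell baseline first-shell water count (default 8).
#' @param cationpi_geometry list with `d_eta1`, `d_eta2` (angstrom,
#'   N-eta to ring centroid) and `theta` (degrees, both N-eta vectors vs
#'   ring normal); default the asymmetric T-shaped pose
#'   `list(d_eta1 = 4.0, d_eta2 = 4.5, theta = 90)`.
#' @param n_chains total chains (>= 2); chains beyond the two reporter
#'   chains are inert spectator copies of the Tyr chain placed far away.
#' @param box optional orthorhombic box triple (angstrom).
#' @param seed integer seed.
#' @return object of class `planted_ensemble_spec`.
#' @export
planted_ensemble_spec <- function(n_frames = 200,
                                  bond_occupancy_bound = 0.24,
                                  bond_occupancy_unbound = 0.10,
                                  inter_bond_occupancy = 0.54,
                                  ion_bound_fraction = 0.71,
                                  hydration_delta = 3,
                                  n_shell = 8,
                                  cationpi_geometry = list(d_eta1 = 4.0,
                                                           d_eta2 = 4.5,
                                                           theta = 90),
                                  n_chains = 2,
                                  box = NULL,
                                  seed = 1L) {
  probs <- c(bond_occupancy_bound, bond_occupancy_unbound,
             inter_bond_occupancy, ion_bound_fraction)
  if (any(probs < 0 | probs > 1)) stop("occupancies must be in [0, 1]")
  if (n_frames < 1) stop("n_frames must be >= 1")
  g <- cationpi_geometry
  if (any(c(g$d_eta1, g$d_eta2) <= 0)) stop("cation-pi distances must be > 0")
  if (hydration_delta < 0 || hydration_delta > n_shell)
    stop("hydration_delta must be in [0, n_shell]")
  if (n_chains < 2) stop("n_chains must be >= 2")
  structure(list(n_frames = as.integer(n_frames),
                 bond_occupancy_bound = bond_occupancy_bound,
                 bond_occupancy_unbound = bond_occupancy_unbound,
                 inter_bond_occupancy = inter_bond_occupancy,
                 ion_bound_fraction = ion_bound_fraction,
                 hydration_delta = as.integer(hydration_delta),
                 n_shell = as.integer(n_shell),
                 cationpi_geometry = g,
                 n_chains = as.integer(n_chains),
                 box = box, seed = as.integer(seed)),
            class = "planted_ensemble_spec")
}

.hexagon_ring <- function(centre = c(0, 0, 0), radius = 1.39) {
  ang <- (0:5) * pi / 3
  t(vapply(ang, function(a) centre + radius * c(cos(a), sin(a), 0),
           numeric(3)))
}

#' Generate a planted coordinate ensemble
#'
#' See [planted_ensemble_spec()] for the planted quantities.  The
#' returned truth table has one row per frame with the planted states;
#' [write_ensemble()] plus [write_tsv()] on the truth table emit the
#' multi-model PDB and its ground-truth sidecar.
#'
#' @param spec a [planted_ensemble_spec()].
#' @return list of class `planted_ensemble` with `system`
#'   (a `molecular_system`), `truth` (data.frame frame, ion_bound,
#'   intra_bond, inter_bond, shell_count), and `spec`.
#' @export
gen_planted_ensemble <- function(spec) {
  stopifnot(inherits(spec, "planted_ensemble_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  g <- spec$cationpi_geometry
  th <- g$theta * pi / 180

  ## --- static scaffold (frame-independent atoms) ---------------------
  ringB <- .hexagon_ring()                       # centroid at origin, normal z
  pos_eta <- function(d, phi) d * c(sin(th) * cos(phi), sin(th) * sin(phi),
                                    cos(th))
  p_nh1 <- pos_eta(g$d_eta1, 0)
  p_nh2 <- pos_eta(g$d_eta2, 30 * pi / 180)
  mid <- (p_nh1 + p_nh2) / 2
  u_out <- if (sqrt(sum(mid^2)) > 1e-9) mid / sqrt(sum(mid^2)) else c(0, 0, 1)
  p_cz <- mid + 1.33 * u_out
  p_ne <- p_cz + 1.33 * u_out
  # orthonormal frame anchored on the guanidinium axis
  ref <- if (abs(u_out[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * u_out) * u_out; e2 <- e2 / sqrt(sum(e2^2))
  # donor H directions: along the NH1->NH2 axis, pointing apart, so the
  # two shuttling acceptors can never approach the opposite nitrogen
  sep <- p_nh1 - p_nh2
  dir1 <- if (sqrt(sum(sep^2)) > 1e-9) sep / sqrt(sum(sep^2)) else e2
  dir2 <- -dir1
  p_hh11 <- p_nh1 + 1.01 * dir1
  p_hh21 <- p_nh2 + 1.01 * dir2
  # acceptor positions for bond-on / bond-off states (linear N-H...O)
  p_ohB_on  <- p_nh1 + 2.90 * dir1
  p_ohB_off <- p_nh1 + 5.50 * dir1
  p_ohA_on  <- p_nh2 + 2.90 * dir2
  p_ohA_off <- p_nh2 + 5.50 * dir2
  # inert backbones (Arg backbone trails off along the guanidinium axis)
  argA_bb <- rbind(p_ne + 1.4 * u_out + 1.0 * e2,
                   p_ne + 2.7 * u_out + 1.0 * e2,
                   p_ne + 4.0 * u_out + 1.5 * e2,
                   p_ne + 4.0 * u_out + 2.7 * e2)
  tyrA_bb <- rbind(c(14, 0, 3), c(15.1, 0, 3.6), c(16.2, 0, 3), c(16.6, 1, 2.6))
  tyrB_bb <- rbind(c(-8, 0, -2), c(-6.9, 0, -2.6), c(-5.8, 0, -2),
                   c(-5.4, -1, -1.6))
  p_ion_bound <- p_ne - 3.2 * e2
  p_ion_free <- c(40, 40, 40)
  # shell waters: cone of directions around the free local axis e3
  # (perpendicular to both the guanidinium axis and the ion/backbone
  # directions), so no planted pose can collide with them
  e3 <- c(u_out[2] * e2[3] - u_out[3] * e2[2],
          u_out[3] * e2[1] - u_out[1] * e2[3],
          u_out[1] * e2[2] - u_out[2] * e2[1])
  alpha <- 35 * pi / 180
  shell_dirs <- t(vapply(seq_len(spec$n_shell), function(i) {
    phi <- 2 * pi * (i - 1) / spec$n_shell
    cos(alpha) * e3 + sin(alpha) * (cos(phi) * u_out + sin(phi) * e2)
  }, numeric(3)))
  p_shell <- sweep(3.0 * shell_dirs, 2, p_ne, "+")
  p_bulk <- function(i) c(30 + 2.5 * i, 30, 30)

  row <- function(elety, resid, chain, resno, ele)
    data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
               elesy = ele)
  atoms <- rbind(
    row("N", "ARG", "A", 1L, "N"), row("CA", "ARG", "A", 1L, "C"),
    row("C", "ARG", "A", 1L, "C"), row("O", "ARG", "A", 1L, "O"),
    row("NE", "ARG", "A", 1L, "N"), row("CZ", "ARG", "A", 1L, "C"),
    row("NH1", "ARG", "A", 1L, "N"), row("NH2", "ARG", "A", 1L, "N"),
    row("HH11", "ARG", "A", 1L, "H"), row("HH21", "ARG", "A", 1L, "H"),
    row("N", "TYR", "A", 2L, "N"), row("CA", "TYR", "A", 2L, "C"),
    row("C", "TYR", "A", 2L, "C"), row("O", "TYR", "A", 2L, "O"),
    row("CG", "TYR", "A", 2L, "C"), row("CD1", "TYR", "A", 2L, "C"),
    row("CE1", "TYR", "A", 2L, "C"), row("CZ", "TYR", "A", 2L, "C"),
    row("CE2", "TYR", "A", 2L, "C"), row("CD2", "TYR", "A", 2L, "C"),
    row("OH", "TYR", "A", 2L, "O"),
    row("N", "TYR", "B", 1L, "N"), row("CA", "TYR", "B", 1L, "C"),
    row("C", "TYR", "B", 1L, "C"), row("O", "TYR", "B", 1L, "O"),
    row("CG", "TYR", "B", 1L, "C"), row("CD1", "TYR", "B", 1L, "C"),
    row("CE1", "TYR", "B", 1L, "C"), row("CZ", "TYR", "B", 1L, "C"),
    row("CE2", "TYR", "B", 1L, "C"), row("CD2", "TYR", "B", 1L, "C"),
    row("OH", "TYR", "B", 1L, "O")
  )
  static <- rbind(argA_bb[1, ], argA_bb[2, ], argA_bb[3, ], argA_bb[4, ],
                  p_ne, p_cz, p_nh1, p_nh2, p_hh11, p_hh21,
                  tyrA_bb, .hexagon_ring(centre = c(15, 0, 7)), p_ohA_off,
                  tyrB_bb, ringB, p_ohB_off)
  # spectator chains (inert Tyr-ring copies far in -x)
  if (spec$n_chains > 2) {
    for (k in seq_len(spec$n_chains - 2)) {
      ch <- LETTERS[2 + k]
      atoms <- rbind(atoms,
                     row("CG", "TYR", ch, 1L, "C"), row("CD1", "TYR", ch, 1L, "C"),
                     row("CE1", "TYR", ch, 1L, "C"), row("CZ", "TYR", ch, 1L, "C"),
                     row("CE2", "TYR", ch, 1L, "C"), row("CD2", "TYR", ch, 1L, "C"))
      static <- rbind(static, .hexagon_ring(centre = c(-30 - 15 * k, 0, 0)))
    }
  }
  n_prot <- nrow(atoms)
  atoms <- rbind(atoms, row("P", "PO4", "I", 1L, "P"))
  for (w in seq_len(spec$n_shell + 2))
    atoms <- rbind(atoms, row("O", "HOH", "W", w, "O"))
  i_ion <- n_prot + 1L
  i_wat <- n_prot + 1L + seq_len(spec$n_shell + 2)
  i_ohA <- which(atoms$chain == "A" & atoms$resno == 2 & atoms$elety == "OH")
  i_ohB <- which(atoms$chain == "B" & atoms$elety == "OH")

  ## --- per-frame states ----------------------------------------------
  nf <- spec$n_frames
  ion_bound <- runif(nf) < spec$ion_bound_fraction
  intra <- runif(nf) < ifelse(ion_bound, spec$bond_occupancy_bound,
                              spec$bond_occupancy_unbound)
  inter <- runif(nf) < spec$inter_bond_occupancy
  shell_n <- spec$n_shell - ifelse(ion_bound, spec$hydration_delta, 0L)

  base <- rbind(static, p_ion_free,
                p_shell, p_bulk(1), p_bulk(2))
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) {
    X <- base
    X[i_ion, ] <- if (ion_bound[f]) p_ion_bound else p_ion_free
    X[i_ohA, ] <- if (intra[f]) p_ohA_on else p_ohA_off
    X[i_ohB, ] <- if (inter[f]) p_ohB_on else p_ohB_off
    if (shell_n[f] < spec$n_shell) {
      out_idx <- i_wat[seq(shell_n[f] + 1, spec$n_shell)]
      for (k in seq_along(out_idx))
        X[out_idx[k], ] <- p_bulk(2 + k)
    }
    xyz[, , f] <- X
  }
  sys <- molecular_system(atoms, xyz, box = spec$box)

  # infeasibility check: cross-residue atom clashes in frame 1
  X1 <- xyz[, , 1]
  dm <- .pair_dists(X1, X1, spec$box)
  reskey <- paste(atoms$chain, atoms$resno)
  clash <- which(dm < 0.8 & outer(reskey, reskey, "!="), arr.ind = TRUE)
  if (nrow(clash))
    stop("geometrically infeasible spec: atoms ",
         atoms$elety[clash[1, 1]], "/", atoms$elety[clash[1, 2]],
         " overlap (", sprintf("%.2f", dm[clash[1, , drop = FALSE]]), " A)")

  structure(list(
    system = sys,
    truth = data.frame(frame = seq_len(nf),
                       ion_bound = ion_bound,
                       intra_bond = intra,
                       inter_bond = inter,
                       shell_count = as.integer(shell_n)),
    spec = spec
  ), class = "planted_ensemble")
}

#' @export
print.planted_ensemble <- function(x, ...) {
  cat(sprintf("Planted ensemble: %d frames (seed %d)\n",
              x$spec$n_frames, x$spec$seed))
  cat(sprintf("  planted: ion bound %.2f | intra H-bond %.2f/%.2f ",
              x$spec$ion_bound_fraction, x$spec$bond_occupancy_bound,
              x$spec$bond_occupancy_unbound))
  cat(sprintf("| inter H-bond %.2f | delta-hydration %d\n",
              x$spec$inter_bond_occupancy, x$spec$hydration_delta))
  g <- x$spec$cationpi_geometry
  cat(sprintf("  cation-pi pose: d = %.2f / %.2f A, theta = %.0f deg\n",
              g$d_eta1, g$d_eta2, g$theta))
  invisible(x)
}

#' Write a planted ensemble and its ground-truth sidecar
#'
#' @param ensemble a `planted_ensemble`.
#' @param pdb_path multi-model PDB output path.
#' @param truth_path sidecar TSV path (default: `pdb_path` with
#'   `.truth.tsv` appended).
#' @return invisible list of the two paths.
#' @export
write_planted_ensemble <- function(ensemble, pdb_path,
                                   truth_path = paste0(pdb_path, ".truth.tsv")) {
  stopifnot(inherits(ensemble, "planted_ensemble"))
  write_ensemble(ensemble$system, pdb_path,
                 header = sprintf("SYNTHETIC PLANTED ENSEMBLE seed=%d",
                                  ensemble$spec$seed))
  write_tsv(ensemble$truth, truth_path,
            header_comments = sprintf("synthetic ground truth, seed=%d",
                                      ensemble$spec$seed))
  invisible(list(pdb = pdb_path, truth = truth_path))
}
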