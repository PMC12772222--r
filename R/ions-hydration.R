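# Ion-binding fractions and hydration-shell statistics.

#' Ion-binding fraction over an ensemble
#'
#' A frame counts as "bound" when at least one ion atom lies within
#' `cutoff` of at least one heavy atom of the target selection (default
#' cutoff 4.0 angstrom, a package convention echoed into output
#' provenance).  Minimum-image convention applies when a box is present.
#'
#' @param system a `molecular_system`.
#' @param ion_idx integer atom indices of the ion selection (see
#'   [select_atoms()]).
#' @param target_idx atom indices of the target selection; default: all
#'   protein heavy atoms.
#' @param cutoff binding cutoff, angstrom.
#' @return list with `fraction`, `per_frame` (logical vector), `per_ion`
#'   (frames x ions logical matrix), `cutoff`.
#' @export
ion_binding_fraction <- function(system, ion_idx,
                                 target_idx = select_atoms(system, protein = TRUE,
                                                           heavy = TRUE),
                                 cutoff = 4.0) {
  stopifnot(inherits(system, "molecular_system"), cutoff > 0)
  if (!length(ion_idx)) stop("empty ion selection")
  if (!length(target_idx)) stop("empty target selection")
  nf <- n_frames(system)
  per_ion <- matrix(FALSE, nf, length(ion_idx))
  for (f in seq_len(nf)) {
    X <- frame_coords(system, f)
    dm <- .pair_dists(X[ion_idx, , drop = FALSE],
                      X[target_idx, , drop = FALSE], system$box)
    per_ion[f, ] <- apply(dm <= cutoff, 1, any)
  }
  per_frame <- apply(per_ion, 1, any)
  list(fraction = mean(per_frame), per_frame = per_frame,
       per_ion = per_ion, cutoff = cutoff)
}

#' Count first-shell waters around a target selection
#'
#' Number of distinct water oxygens (residue name HOH/WAT/SOL/TIP) within
#' `radius` of any atom of the target selection in one frame.
#'
#' @param system a `molecular_system`.
#' @param frame frame index.
#' @param target_idx atom indices defining the solvation target (e.g. the
#'   Arg side-chain nitrogens).
#' @param radius first-shell radius, angstrom (default 3.4).
#' @return integer water count (0 with a warning when the system has no
#'   waters).
#' @export
hydration_shell_count <- function(system, frame, target_idx, radius = 3.4) {
  stopifnot(radius > 0)
  if (!length(target_idx)) stop("empty target selection")
  wat <- select_atoms(system, resid = c("HOH", "WAT", "SOL", "TIP"),
                      element = "O")
  if (!length(wat)) {
    warning("system contains no waters")
    return(0L)
  }
  X <- frame_coords(system, frame)
  dm <- .pair_dists(X[wat, , drop = FALSE], X[target_idx, , drop = FALSE],
                    system$box)
  sum(apply(dm <= radius, 1, any))
}

#' Hydration-shell counts per frame
#'
#' @inheritParams hydration_shell_count
#' @return integer vector, one count per frame.
#' @export
hydration_shell_series <- function(system, target_idx, radius = 3.4) {
  vapply(seq_len(n_frames(system)), function(f)
    hydration_shell_count(system, f, target_idx, radius), 0L)
}

#' Mean hydration-shell displacement on binding
#'
#' Mean first-shell water count in unbound frames minus the mean in bound
#' frames: the average number of waters displaced by the bound ion.
#'
#' @param bound logical per-frame bound series (e.g. from
#'   [ion_binding_fraction()]).
#' @param counts integer per-frame shell counts (from
#'   [hydration_shell_series()]).
#' @return list with `displacement`, `mean_bound`, `mean_unbound`,
#'   `n_bound`, `n_unbound`; displacement is NA when either stratum is
#'   empty.
#' @export
shell_displacement <- function(bound, counts) {
  if (length(bound) != length(counts)) stop("series length mismatch")
  nb <- sum(bound); nu <- sum(!bound)
  mb <- if (nb) mean(counts[bound]) else NA_real_
  mu <- if (nu) mean(counts[!bound]) else NA_real_
  list(displacement = mu - mb, mean_bound = mb, mean_unbound = mu,
       n_bound = nb, n_unbound = nu)
}
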