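# Cation-pi detection and geometric classification of Arg-aromatic
# contacts.
#
# For each Arg guanidinium / aromatic-ring pair the two terminal nitrogens
# (N-eta: NH1/NH2) are measured against the ring centroid; theta is the
# angle between the least-squares ring normal and the centroid->N-eta
# vector, folded to [0, 90] degrees (the ring normal has no preferred
# sign).  theta near 0: the nitrogen sits over the pi face (stacked);
# theta near 90: it approaches the ring edge (T-shaped).

.ring_atoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

#' Detect and classify cation-pi contacts in one frame
#'
#' Considers every pairing of an Arg guanidinium (NH1/NH2 present) with an
#' aromatic ring (Tyr or Phe; the 6 ring carbons CG, CD1, CD2, CE1, CE2,
#' CZ) whose closer N-eta lies within `window` of the ring centroid.
#' Distances are reported sorted (`d_eta1 <= d_eta2`, invariant under
#' NH1/NH2 relabelling) with the matching angles.  Classification:
#' stacked when `min(theta) <= 30` degrees, else T-shaped when
#' `max(theta) >= 60` degrees, else intermediate; `asymmetric` flags
#' `d_eta2 - d_eta1 >= asym_min` (default 0.3 angstrom).  An incomplete
#' ring skips the pair with a warning.
#'
#' @param system a `molecular_system`.
#' @param frame frame index.
#' @param window detection window on `min(d_eta1, d_eta2)`, angstrom;
#'   default 6.0, covering the 4-6 angstrom range expected for cation-pi
#'   contacts with margin.
#' @param asym_min asymmetry threshold, angstrom.
#' @return data.frame with columns `arg_chain`, `arg_resno`,
#'   `ring_chain`, `ring_resno`, `ring_resid`, `d_eta1`, `d_eta2`,
#'   `theta1`, `theta2` (degrees, paired with the sorted distances),
#'   `geometry_class`, `asymmetric`.
#' @export
detect_cation_pi <- function(system, frame = 1, window = 6.0,
                             asym_min = 0.3) {
  stopifnot(inherits(system, "molecular_system"), window > 0)
  X <- frame_coords(system, frame)
  a <- system$atoms
  res_key <- paste(a$chain, a$resno)
  args <- unique(res_key[a$resid == "ARG"])
  rings <- unique(res_key[a$resid %in% c("TYR", "PHE")])
  out <- list()
  for (rg in rings) {
    ridx <- which(res_key == rg & a$elety %in% .ring_atoms)
    if (length(ridx) != 6) {
      warning("incomplete aromatic ring at ", rg, ": pair skipped")
      next
    }
    # image ring atoms consistently around the first ring atom before
    # averaging (minimum image can split a ring across the boundary)
    P <- X[ridx, , drop = FALSE]
    if (!is.null(system$box))
      for (k in 2:6) P[k, ] <- P[1, ] + .vec_diff(P[k, ], P[1, ], system$box)
    centroid <- colMeans(P)
    normal <- .plane_normal(P)
    for (ag in args) {
      nh <- which(res_key == ag & a$elety %in% c("NH1", "NH2"))
      if (length(nh) != 2) next
      v1 <- .vec_diff(X[nh[1], ], centroid, system$box)
      v2 <- .vec_diff(X[nh[2], ], centroid, system$box)
      d <- c(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
      th <- vapply(list(v1, v2), function(v) {
        ang <- acos(pmin(1, pmax(-1, abs(sum(v * normal)) / sqrt(sum(v^2))))) *
          180 / pi
        ang
      }, 0)
      ord <- order(d)
      d <- d[ord]; th <- th[ord]
      if (d[1] > window) next
      cls <- if (min(th) <= 30) "stacked"
      else if (max(th) >= 60) "T-shaped"
      else "intermediate"
      parts_a <- strsplit(ag, " ")[[1]]; parts_r <- strsplit(rg, " ")[[1]]
      out[[length(out) + 1]] <- data.frame(
        arg_chain = parts_a[1], arg_resno = as.integer(parts_a[2]),
        ring_chain = parts_r[1], ring_resno = as.integer(parts_r[2]),
        ring_resid = a$resid[ridx[1]],
        d_eta1 = d[1], d_eta2 = d[2], theta1 = th[1], theta2 = th[2],
        geometry_class = cls, asymmetric = (d[2] - d[1]) >= asym_min
      )
    }
  }
  if (!length(out))
    return(data.frame(arg_chain = character(), arg_resno = integer(),
                      ring_chain = character(), ring_resno = integer(),
                      ring_resid = character(), d_eta1 = numeric(),
                      d_eta2 = numeric(), theta1 = numeric(),
                      theta2 = numeric(), geometry_class = character(),
                      asymmetric = logical()))
  do.call(rbind, out)
}
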