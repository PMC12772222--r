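# Hydrogen-bond detection and occupancy statistics on coordinate
# ensembles.

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow common trajectory-analysis convention: donor-acceptor
#' heavy-atom distance <= 3.5 angstrom and D-H...A angle >= 150 degrees,
#' with explicit hydrogens required.
#'
#' @param dist_max donor...acceptor maximum distance, angstrom.
#' @param angle_min minimum D-H...A angle, degrees (in (0, 180]).
#' @param require_explicit_H if TRUE (default) a bond needs an explicit
#'   hydrogen satisfying the angle; if FALSE, detection is distance-only
#'   and the angle column is NA.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_max = 3.5, angle_min = 150,
                           require_explicit_H = TRUE) {
  stopifnot(dist_max > 0, angle_min > 0, angle_min <= 180)
  structure(list(dist_max = dist_max, angle_min = angle_min,
                 require_explicit_H = require_explicit_H),
            class = "hbond_criteria")
}

# hydrogens covalently attached to N/O donors: H within 1.2 A
.donor_h_pairs <- function(system, X) {
  a <- system$atoms
  h_idx <- which(a$elesy == "H")
  d_idx <- which(a$elesy %in% c("N", "O"))
  if (!length(h_idx) || !length(d_idx))
    return(data.frame(donor = integer(), h = integer()))
  dm <- .pair_dists(X[h_idx, , drop = FALSE], X[d_idx, , drop = FALSE],
                    system$box)
  near <- which(dm <= 1.2, arr.ind = TRUE)
  if (!nrow(near)) return(data.frame(donor = integer(), h = integer()))
  # each H belongs to its nearest covalent heavy partner
  best <- tapply(seq_len(nrow(near)), near[, 1], function(rows) {
    rows[which.min(dm[near[rows, , drop = FALSE]])]
  })
  sel <- near[unlist(best), , drop = FALSE]
  data.frame(donor = d_idx[sel[, 2]], h = h_idx[sel[, 1]])
}

#' Detect hydrogen bonds in one frame
#'
#' Finds all (donor, H, acceptor) triples with donor and acceptor among
#' N/O atoms, D...A distance within `criteria$dist_max` and D-H...A angle
#' at the hydrogen >= `criteria$angle_min`.  Each bond is tagged
#' intramolecular or intermolecular by the chain identity of donor and
#' acceptor residues.  Minimum-image convention applies when the system
#' has a box.
#'
#' @param system a `molecular_system`.
#' @param frame frame index.
#' @param criteria an [hbond_criteria()].
#' @return data.frame with columns `donor`, `h`, `acceptor` (atom
#'   indices), `dDA` (angstrom), `angle` (degrees), `donor_chain`,
#'   `donor_resno`, `donor_resid`, `acceptor_chain`, `acceptor_resno`,
#'   `acceptor_resid`, `scope` ("intra"/"inter").
#' @export
detect_hbonds <- function(system, frame = 1, criteria = hbond_criteria()) {
  stopifnot(inherits(system, "molecular_system"))
  X <- frame_coords(system, frame)
  a <- system$atoms
  acc_idx <- which(a$elesy %in% c("N", "O"))
  if (criteria$require_explicit_H) {
    if (!any(a$elesy == "H"))
      stop("require_explicit_H is set but the system has no hydrogens; ",
           "candidate donors: ",
           paste(unique(paste0(a$resid, a$resno, ":", a$elety)[acc_idx]),
                 collapse = " "))
    dh <- .donor_h_pairs(system, X)
  } else {
    dh <- data.frame(donor = acc_idx, h = NA_integer_)
  }
  empty <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      dDA = numeric(), angle = numeric(),
                      donor_chain = character(), donor_resno = integer(),
                      donor_resid = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_resid = character(),
                      scope = character())
  if (!nrow(dh)) return(empty)
  dm <- .pair_dists(X[dh$donor, , drop = FALSE],
                    X[acc_idx, , drop = FALSE], system$box)
  hits <- which(dm <= criteria$dist_max, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  out <- list()
  for (r in seq_len(nrow(hits))) {
    di <- dh$donor[hits[r, 1]]; hi <- dh$h[hits[r, 1]]
    ai <- acc_idx[hits[r, 2]]
    if (ai == di) next
    # an H never "accepts" from its own donor pair partner sharing atoms
    if (!is.na(hi) && ai == hi) next
    ang <- if (is.na(hi)) NA_real_ else
      .angle_deg(X[di, ], X[hi, ], X[ai, ], system$box)
    if (!is.na(ang) && ang < criteria$angle_min) next
    out[[length(out) + 1]] <- data.frame(
      donor = di, h = hi, acceptor = ai,
      dDA = dm[hits[r, 1], hits[r, 2]], angle = ang,
      donor_chain = a$chain[di], donor_resno = a$resno[di],
      donor_resid = a$resid[di],
      acceptor_chain = a$chain[ai], acceptor_resno = a$resno[ai],
      acceptor_resid = a$resid[ai],
      scope = if (a$chain[di] == a$chain[ai]) "intra" else "inter"
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # drop donor-acceptor pairs within the same residue (covalent context)
  same <- res$donor_chain == res$acceptor_chain &
    res$donor_resno == res$acceptor_resno
  res <- res[!same, , drop = FALSE]
  if (!criteria$require_explicit_H) {
    # distance-only mode has no donor/acceptor direction: deduplicate
    res <- res[res$donor < res$acceptor, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Detect hydrogen bonds in every frame
#'
#' @inheritParams detect_hbonds
#' @return list of per-frame data.frames (see [detect_hbonds()]).
#' @export
detect_hbonds_all <- function(system, criteria = hbond_criteria()) {
  lapply(seq_len(n_frames(system)), function(f)
    detect_hbonds(system, f, criteria))
}

#' Residue-pair hydrogen-bond frequency table
#'
#' For each residue-type pair and scope, the fraction of frames containing
#' at least one qualifying bond (frame-presence convention, matching
#' percent-of-time occupancy reporting).  Per-bond-instance averaging
#' (mean bonds per frame) is available via `convention = "instances"`.
#'
#' @param bonds_by_frame list of per-frame bond tables from
#'   [detect_hbonds_all()].
#' @param pairs list of 2-element character vectors of residue names,
#'   e.g. `list(c("ARG", "TYR"))`; unordered.
#' @param scopes character subset of `c("intra", "inter")`.
#' @param known_resids residue names considered valid (for catching
#'   misspelled pair specs); default: any name seen in the bonds plus the
#'   20 standard residues.
#' @param convention `"presence"` (default) or `"instances"`.
#' @return data.frame with columns `pair`, `scope`, `frequency`,
#'   `n_frames`, sorted by decreasing frequency; attribute `"series"` is
#'   a named list of per-frame logical (or count) vectors.
#' @export
pair_frequency_table <- function(bonds_by_frame, pairs,
                                 scopes = c("inter", "intra"),
                                 known_resids = NULL,
                                 convention = c("presence", "instances")) {
  convention <- match.arg(convention)
  if (is.null(known_resids))
    known_resids <- unique(c(unlist(lapply(bonds_by_frame, function(b)
      c(b$donor_resid, b$acceptor_resid))), .standard_resids))
  for (p in pairs)
    if (!all(p %in% known_resids))
      stop("unknown residue type in pair spec: ",
           paste(setdiff(p, known_resids), collapse = ", "))
  nf <- length(bonds_by_frame)
  rows <- list(); series <- list()
  for (p in pairs) for (sc in scopes) {
    per_frame <- vapply(bonds_by_frame, function(b) {
      if (!nrow(b)) return(0L)
      hit <- b$scope == sc &
        ((b$donor_resid == p[1] & b$acceptor_resid == p[2]) |
           (b$donor_resid == p[2] & b$acceptor_resid == p[1]))
      sum(hit)
    }, 0L)
    lab <- paste0(paste(p, collapse = "-"), " ", sc)
    freq <- if (convention == "presence") mean(per_frame >= 1L)
    else mean(per_frame)
    rows[[lab]] <- data.frame(pair = paste(p, collapse = "-"), scope = sc,
                              frequency = freq, n_frames = nf)
    series[[lab]] <- if (convention == "presence") per_frame >= 1L else per_frame
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$frequency, out$pair, out$scope), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "series") <- series
  out
}

.standard_resids <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL")

#' Conditional contact frequency
#'
#' Stratifies a per-frame event series by a per-frame condition series:
#' P(event | condition), P(event | not condition), with counts and Wilson
#' 95% intervals.  An empty stratum is reported as undefined (NA), never
#' as 0.
#'
#' @param event logical vector, one element per frame.
#' @param condition logical vector, same length.
#' @return data.frame with rows `conditional` and `complement`: columns
#'   `stratum`, `p`, `lo`, `hi` (Wilson 95%), `events`, `frames`,
#'   `defined`.
#' @export
conditional_frequency <- function(event, condition) {
  if (length(event) != length(condition)) stop("series length mismatch")
  event <- as.logical(event); condition <- as.logical(condition)
  one <- function(mask, label) {
    n <- sum(mask)
    if (n == 0)
      return(data.frame(stratum = label, p = NA_real_, lo = NA_real_,
                        hi = NA_real_, events = 0L, frames = 0L,
                        defined = FALSE))
    k <- sum(event[mask])
    ci <- .wilson_ci(k, n)
    data.frame(stratum = label, p = k / n, lo = ci[1], hi = ci[2],
               events = k, frames = n, defined = TRUE)
  }
  rbind(one(condition, "conditional"), one(!condition, "complement"))
}

.wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}
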