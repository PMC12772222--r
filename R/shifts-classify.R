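# Random-coil-referenced secondary-structure classification.
#
# Secondary shifts Delta = delta_obs - delta_RC carry the classic CSI sign
# patterns: beta-sheet pulls Ca and CO upfield (negative Delta) and Cb
# downfield (positive); alpha-helix is the mirror image.  The consensus
# rule below uses a symmetric dead band around random coil so that small
# deviations stay RC.

#' Random-coil reference shifts
#'
#' Loads the random-coil reference table shipped with the package
#' (conventional published random-coil values for Ca/Cb/CO of the 20
#' standard residue types, in ppm referenced to DSS), or a user-supplied
#' TSV with columns `residue_type`, `nucleus`, `shift_ppm`.  The file is
#' plain text and editable: swap in any other reference set.
#'
#' @param path optional path to an alternative table.
#' @return data.frame with columns `residue_type`, `nucleus`, `shift_ppm`.
#' @export
random_coil_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "random_coil_shifts.tsv", package = "silknmr",
                        mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_type", "nucleus", "shift_ppm")
  if (!all(need %in% names(tab))) stop("random-coil table needs columns: ",
                                       paste(need, collapse = ", "))
  tab
}

.rc_lookup <- function(rc_table, residue_type, nucleus) {
  i <- which(rc_table$residue_type == residue_type & rc_table$nucleus == nucleus)
  if (!length(i)) return(NA_real_)
  rc_table$shift_ppm[i[1]]
}

#' Default classification rule parameters
#'
#' Dead-band thresholds (ppm) of the consensus secondary-shift rule:
#' `ca_cb` is the magnitude a Ca or Cb secondary shift must reach to vote
#' for a structured class, `co` the same for CO (CO strengthens a call but
#' is never required).
#'
#' @return list with `ca_cb = 0.7` and `co = 0.5`.
#' @export
default_classify_rule <- function() list(ca_cb = 0.7, co = 0.5)

#' Classify secondary structure from secondary chemical shifts
#'
#' Computes per-nucleus secondary shifts \eqn{\Delta = \delta_{obs} -
#' \delta_{RC}} and applies the consensus rule: beta requires
#' \eqn{\Delta C\alpha \le -t} and (when Cb exists for the residue type)
#' \eqn{\Delta C\beta \ge +t}; alpha the mirror pattern
#' (\eqn{\Delta C\alpha \ge +t}, \eqn{\Delta C\beta \le -t}); anything
#' inside the dead band is RC; two strong but conflicting votes give
#' "ambiguous".  For residues without Cb (Gly) the Ca vote decides.  CO
#' strengthens but is not required.
#'
#' @param shifts named numeric vector of observed shifts in ppm, names
#'   among `CA`, `CB`, `CO` (at least CA or CB required).
#' @param residue_type one-letter residue type.
#' @param rc_table random-coil reference, see [random_coil_table()].
#' @param rule thresholds, see [default_classify_rule()].
#' @return list of class `structure_call`: `class` in
#'   `c("beta", "alpha", "RC", "ambiguous")`, `evidence` (named secondary
#'   shifts, ppm), `residue_type`.
#' @examples
#' rc <- random_coil_table()
#' classify_secondary_structure(c(CA = 50.5, CB = 21.1), "A", rc)$class
#' @export
classify_secondary_structure <- function(shifts, residue_type,
                                         rc_table = random_coil_table(),
                                         rule = default_classify_rule()) {
  shifts <- shifts[!is.na(shifts)]
  if (!any(c("CA", "CB") %in% names(shifts)))
    stop("need at least a CA or CB shift")
  sec <- vapply(names(shifts), function(nuc) {
    rcv <- .rc_lookup(rc_table, residue_type, nuc)
    if (is.na(rcv)) stop("residue type ", residue_type,
                         " nucleus ", nuc, " missing from random-coil table")
    unname(shifts[[nuc]] - rcv)
  }, 0)
  vote <- function(nuc, beta_dir, t) {
    if (!nuc %in% names(sec)) return(NA_character_)
    d <- sec[[nuc]] * beta_dir       # positive means beta-wards
    if (d >= t) "beta" else if (d <= -t) "alpha" else "RC"
  }
  t <- rule$ca_cb
  vca <- vote("CA", -1, t)           # beta: Ca upfield
  vcb <- vote("CB", +1, t)           # beta: Cb downfield
  vco <- vote("CO", -1, rule$co)     # beta: CO upfield (supporting only)
  votes <- c(CA = vca, CB = vcb)
  votes <- votes[!is.na(votes)]
  cls <- if (length(votes) == 2) {
    if (votes[1] == votes[2]) unname(votes[1])
    else if (all(votes != "RC")) "ambiguous"   # strong conflicting signs
    else "RC"
  } else unname(votes[1])
  # a lone structured vote contradicted by a strong opposite CO is ambiguous
  if (!is.na(vco) && cls %in% c("beta", "alpha") && vco != "RC" && vco != cls &&
      length(votes) == 1) cls <- "ambiguous"
  structure(list(class = cls, evidence = sec, residue_type = residue_type),
            class = "structure_call")
}

#' @export
print.structure_call <- function(x, ...) {
  cat(sprintf("Structure call: %s (%s)\n", x$class, x$residue_type))
  cat("  secondary shifts (ppm):",
      paste(sprintf("%s=%+.2f", names(x$evidence), x$evidence), collapse = "  "),
      "\n")
  invisible(x)
}

#' Classify every site of a shift table
#'
#' Applies [classify_secondary_structure()] to each (site, component) of a
#' long-format shift table, gathering its CA/CB/CO rows.
#'
#' @param tab shift table (see [read_shift_table()]).
#' @inheritParams classify_secondary_structure
#' @return data.frame with `site_id`, `residue_type`, `component_rank`,
#'   `class`, and secondary-shift evidence columns `dCA`, `dCB`, `dCO`.
#' @export
classify_shift_table <- function(tab, rc_table = random_coil_table(),
                                 rule = default_classify_rule()) {
  tab <- .check_shift_table(tab)
  tab <- tab[tab$nucleus %in% c("CA", "CB", "CO"), , drop = FALSE]
  key <- paste(tab$motif, tab$reporter_index, tab$component_rank, sep = "|")
  out <- lapply(unique(key), function(k) {
    rows <- tab[key == k, , drop = FALSE]
    sh <- setNames(rows$shift_ppm, rows$nucleus)
    call <- classify_secondary_structure(sh, rows$residue_type[1], rc_table, rule)
    data.frame(
      site_id = motif_site(rows$motif[1], rows$reporter_index[1], rows$residue_type[1]),
      residue_type = rows$residue_type[1],
      component_rank = rows$component_rank[1],
      class = call$class,
      dCA = if ("CA" %in% names(call$evidence)) call$evidence[["CA"]] else NA_real_,
      dCB = if ("CB" %in% names(call$evidence)) call$evidence[["CB"]] else NA_real_,
      dCO = if ("CO" %in% names(call$evidence)) call$evidence[["CO"]] else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Assign multi-component resonances to canonical class positions
#'
#' Each observed component shift is assigned to the nearest canonical
#' class position in ppm (e.g. Arg Ca populations at 54.6, 55.8 and 57.2
#' ppm against canonical beta / RC positions).  Exact ties are labelled
#' "ambiguous".
#'
#' @param components numeric vector of observed component shifts (ppm).
#' @param canonical named numeric vector of canonical class positions,
#'   names are class labels (e.g. `c(beta = 54.6, RC = 56.5)`).
#' @return data.frame with `component` (ppm), `class`, `distance` (ppm to
#'   the winning position).
#' @examples
#' assign_components(c(54.6, 55.8, 57.2), c(beta = 54.6, RC = 56.5))
#' @export
assign_components <- function(components, canonical) {
  if (!length(components)) stop("empty component list")
  if (is.null(names(canonical)) || !length(canonical))
    stop("canonical positions must be a named vector")
  out <- lapply(components, function(x) {
    d <- abs(x - canonical)
    winners <- names(canonical)[d - min(d) < 1e-9]  # tolerance for ppm ties
    data.frame(component = x,
               class = if (length(winners) > 1) "ambiguous" else winners,
               distance = min(d))
  })
  do.call(rbind, out)
}

#' Predicted-vs-experimental shift statistics
#'
#' Given an ensemble of predicted shift tables (e.g. one per structural
#' model, from an external shift predictor) and one experimental table,
#' computes per (residue_type, nucleus): the ensemble mean and sample SD
#' of the predictions, and MAE / RMSD / bias of the ensemble mean against
#' experiment, plus a global summary row.
#'
#' @param predicted list of shift tables (>= 1).
#' @param experimental shift table.
#' @return data.frame with columns `residue_type`, `nucleus`, `n`,
#'   `pred_mean`, `ensemble_sd` (mean over sites of the per-site
#'   prediction SD; NA for a single table), `mae`, `rmsd`, `bias`; final
#'   row has residue_type = "ALL".
#' @export
compare_predicted_experimental <- function(predicted, experimental) {
  if (!length(predicted)) stop("need at least one predicted table")
  predicted <- lapply(predicted, .check_shift_table)
  experimental <- .check_shift_table(experimental)
  ke <- .shift_key(experimental)
  pred_mat <- vapply(predicted, function(p) {
    kp <- .shift_key(p)
    p$shift_ppm[match(ke, kp)]
  }, numeric(length(ke)))
  pred_mat <- matrix(pred_mat, nrow = length(ke))
  shared <- rowSums(!is.na(pred_mat)) == ncol(pred_mat)
  if (!any(shared)) stop("no shared (site, nucleus) keys")
  pm <- rowMeans(pred_mat[shared, , drop = FALSE])
  psd <- if (ncol(pred_mat) > 1) apply(pred_mat[shared, , drop = FALSE], 1, sd)
  else rep(NA_real_, sum(shared))
  err <- pm - experimental$shift_ppm[shared]
  grp <- paste(experimental$residue_type[shared], experimental$nucleus[shared], sep = "|")
  one <- function(idx, label_rt, label_nuc) data.frame(
    residue_type = label_rt, nucleus = label_nuc, n = length(idx),
    pred_mean = mean(pm[idx]),
    ensemble_sd = if (all(is.na(psd[idx]))) NA_real_ else mean(psd[idx]),
    mae = mean(abs(err[idx])),
    rmsd = sqrt(mean(err[idx]^2)),
    bias = mean(err[idx])
  )
  groups <- sort(unique(grp))
  per <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(grp == g)
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    one(idx, parts[1], parts[2])
  }))
  rbind(per, one(seq_along(err), "ALL", "ALL"))
}
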