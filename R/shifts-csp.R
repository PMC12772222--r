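# Chemical-shift perturbation (CSP) analysis across sample states.
#
# Shift tables are plain data.frames with columns
#   state, motif, reporter_index, residue_type, nucleus, component_rank,
#   shift_ppm
# where (motif, reporter_index, residue_type) names a MotifSite: a reporter
# residue in its motif context (e.g. the middle Ala of "AAG").  The join
# key across states is (site_id, nucleus, component_rank), never a residue
# number, because assignments in repetitive spidroin sequences are by
# motif context.

#' Build a motif-site identifier
#'
#' @param motif residue-type string giving the motif context (e.g. "AAG").
#' @param reporter_index 1-based position of the reporter residue within
#'   the motif.
#' @param residue_type one-letter residue type of the reporter; must match
#'   the marked motif position.
#' @return character site id of the form `"AAG@2"`.
#' @export
motif_site <- function(motif, reporter_index, residue_type) {
  motif <- toupper(motif)
  if (any(reporter_index < 1 | reporter_index > nchar(motif)))
    stop("reporter_index outside motif bounds")
  at <- substr(motif, reporter_index, reporter_index)
  if (any(at != toupper(residue_type)))
    stop("residue_type does not match the marked motif position")
  paste0(motif, "@", reporter_index)
}

#' Default CSP significance thresholds (ppm) by nucleus class
#'
#' 0.03 ppm for 1H and 0.1 ppm for 15N, the established significance
#' thresholds for protein CSP analysis; 13C defaults to 0.1 ppm (a package
#' convention, exposed here for override).
#'
#' @return named numeric vector with elements `H`, `N`, `C`.
#' @export
default_csp_thresholds <- function() c(H = 0.03, N = 0.1, C = 0.1)

.nucleus_class <- function(nucleus) {
  first <- toupper(substr(nucleus, 1, 1))
  ifelse(first %in% c("H", "N", "C"), first, NA_character_)
}

.shift_key <- function(tab) {
  paste(tab$motif, tab$reporter_index, tab$nucleus,
        if ("component_rank" %in% names(tab)) tab$component_rank else 1L,
        sep = "|")
}

.check_shift_table <- function(tab, name = "shift table") {
  need <- c("motif", "reporter_index", "residue_type", "nucleus", "shift_ppm")
  if (!all(need %in% names(tab)))
    stop(name, " missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  if (!"component_rank" %in% names(tab)) tab$component_rank <- 1L
  if (any(!is.finite(tab$shift_ppm))) stop(name, " contains non-finite shifts")
  if (anyDuplicated(.shift_key(tab)))
    stop(name, " has duplicate (site, nucleus, component_rank) keys")
  tab
}

#' Chemical-shift perturbations between two sample states
#'
#' For every (site, nucleus, component) key shared by the two tables,
#' computes the signed perturbation \eqn{\Delta\delta = \delta_B -
#' \delta_A} and flags significance per nucleus-class threshold.
#' Sites present in only one table (e.g. exchange-broadened out of one
#' state) are reported separately, never dropped silently.
#'
#' @param table_A,table_B shift tables (see [read_shift_table()]); A is the
#'   reference state.
#' @param thresholds named numeric vector of significance thresholds in
#'   ppm by nucleus class (`H`, `N`, `C`); default
#'   [default_csp_thresholds()].
#' @return data.frame with columns `site_id`, `motif`, `reporter_index`,
#'   `residue_type`, `nucleus`, `component_rank`, `shift_A`, `shift_B`,
#'   `delta` (ppm), `threshold_used`, `significant`; attribute
#'   `"unmatched"` holds a data.frame of keys found in only one table.
#' @examples
#' a <- data.frame(motif = "R", reporter_index = 1, residue_type = "R",
#'                 nucleus = "N", shift_ppm = 120.00)
#' b <- transform(a, shift_ppm = 120.27)
#' compute_csp(a, b)$significant
#' @export
compute_csp <- function(table_A, table_B, thresholds = default_csp_thresholds()) {
  table_A <- .check_shift_table(table_A, "table_A")
  table_B <- .check_shift_table(table_B, "table_B")
  ka <- .shift_key(table_A); kb <- .shift_key(table_B)
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("tables share no (site, nucleus) keys")
  ia <- match(shared, ka); ib <- match(shared, kb)
  nuc <- table_A$nucleus[ia]
  cls <- .nucleus_class(nuc)
  thr <- unname(thresholds[cls])
  if (any(is.na(thr)))
    stop("no threshold for nucleus class of: ",
         paste(unique(nuc[is.na(thr)]), collapse = ", "))
  delta <- table_B$shift_ppm[ib] - table_A$shift_ppm[ia]
  out <- data.frame(
    site_id = motif_site(table_A$motif[ia], table_A$reporter_index[ia],
                         table_A$residue_type[ia]),
    motif = table_A$motif[ia],
    reporter_index = table_A$reporter_index[ia],
    residue_type = table_A$residue_type[ia],
    nucleus = nuc,
    component_rank = table_A$component_rank[ia],
    shift_A = table_A$shift_ppm[ia],
    shift_B = table_B$shift_ppm[ib],
    delta = delta,
    threshold_used = thr,
    significant = abs(delta) > thr
  )
  only_a <- table_A[!(ka %in% kb), c("motif", "reporter_index", "nucleus")]
  only_b <- table_B[!(kb %in% ka), c("motif", "reporter_index", "nucleus")]
  unmatched <- rbind(
    if (nrow(only_a)) cbind(only_a, missing_from = "B"),
    if (nrow(only_b)) cbind(only_b, missing_from = "A")
  )
  attr(out, "unmatched") <- unmatched
  out
}

#' State-to-state shift differences with explicit multi-component pairing
#'
#' Computes signed \eqn{\Delta\delta} maps between two states (e.g. fiber
#' vs gland).  Where a resonance is split into several components in
#' either state, the pairing must be resolved explicitly via `pairing`
#' (component labels are assigned manually in practice); unresolved
#' multiplicity is an error listing the offending sites, never a silent
#' average.
#'
#' @param table_A,table_B shift tables; A is the reference state.
#' @param pairing optional data.frame with columns `motif`,
#'   `reporter_index`, `nucleus`, `component_A`, `component_B` resolving
#'   which component of A maps to which of B; keys with a single component
#'   on both sides pair automatically.
#' @return data.frame with columns as [compute_csp()] minus significance,
#'   plus `component_A`, `component_B`.
#' @export
delta_between_states <- function(table_A, table_B, pairing = NULL) {
  table_A <- .check_shift_table(table_A, "table_A")
  table_B <- .check_shift_table(table_B, "table_B")
  base_key <- function(tab) paste(tab$motif, tab$reporter_index, tab$nucleus, sep = "|")
  ka <- base_key(table_A); kb <- base_key(table_B)
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("tables share no (site, nucleus) keys")
  pk <- if (!is.null(pairing))
    paste(pairing$motif, pairing$reporter_index, pairing$nucleus, sep = "|")
  rows <- lapply(shared, function(k) {
    a <- table_A[ka == k, , drop = FALSE]
    b <- table_B[kb == k, , drop = FALSE]
    if (nrow(a) == 1 && nrow(b) == 1) {
      pair <- data.frame(component_A = a$component_rank, component_B = b$component_rank)
    } else {
      if (is.null(pairing) || !any(pk == k))
        return(structure(k, unresolved = TRUE))
      pair <- pairing[pk == k, c("component_A", "component_B"), drop = FALSE]
    }
    ia <- match(pair$component_A, a$component_rank)
    ib <- match(pair$component_B, b$component_rank)
    if (any(is.na(ia)) || any(is.na(ib)))
      stop("pairing refers to missing component at ", k)
    data.frame(
      site_id = motif_site(a$motif[ia], a$reporter_index[ia], a$residue_type[ia]),
      motif = a$motif[ia], reporter_index = a$reporter_index[ia],
      residue_type = a$residue_type[ia], nucleus = a$nucleus[ia],
      component_A = pair$component_A, component_B = pair$component_B,
      shift_A = a$shift_ppm[ia], shift_B = b$shift_ppm[ib],
      delta = b$shift_ppm[ib] - a$shift_ppm[ia]
    )
  })
  bad <- vapply(rows, function(r) isTRUE(attr(r, "unresolved")), TRUE)
  if (any(bad))
    stop("unresolved multi-component pairing at: ",
         paste(unlist(rows[bad]), collapse = "; "),
         " (supply `pairing` for these keys)")
  do.call(rbind, rows)
}

#' Read / write shift tables
#'
#' TSV with columns `state`, `motif`, `reporter_index`, `residue_type`,
#' `nucleus`, `component_rank`, `shift_ppm`.
#'
#' @param path file path.
#' @return data.frame shift table.
#' @export
read_shift_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .check_shift_table(tab, path)
}

#' @rdname read_shift_table
#' @param tab shift table to write.
#' @export
write_shift_table <- function(tab, path) {
  write_tsv(tab, path)
  invisible(path)
}
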