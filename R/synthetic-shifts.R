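# Synthetic shift tables with planted secondary-structure classes.

#' Canonical secondary-shift offsets used to plant structure classes
#'
#' Offsets (ppm) added to the random-coil reference when planting a class:
#' chosen to exceed the classification dead band with margin, and editable
#' (pass a modified copy to [gen_shift_table()]).
#'
#' @return list with named vectors `beta`, `alpha`, `RC` over CA/CB/CO.
#' @export
planted_shift_offsets <- function() list(
  beta  = c(CA = -2.0, CB = +2.0, CO = -1.5),
  alpha = c(CA = +3.0, CB = -1.0, CO = +1.8),
  RC    = c(CA = 0, CB = 0, CO = 0)
)

#' Generate a shift table with planted secondary-structure classes
#'
#' For each residue of `sequence` with planted class `ss_assignment[i]`,
#' emits CA/CB/CO shifts equal to the random-coil reference plus the
#' canonical offset for that class plus Gaussian noise.  With
#' `noise_sd = 0` the planted class is exactly recoverable by
#' [classify_secondary_structure()].
#'
#' @param sequence residue-type string (one-letter codes).
#' @param ss_assignment character vector of planted classes, one of
#'   `"beta"`, `"alpha"`, `"RC"` per residue.
#' @param noise_sd Gaussian noise SD in ppm (>= 0).
#' @param seed integer seed.
#' @param rc_table random-coil reference, see [random_coil_table()].
#' @param offsets planted offsets, see [planted_shift_offsets()].
#' @param state state label stored in the table.
#' @return shift table data.frame (see [read_shift_table()]); each residue
#'   becomes its own single-residue motif site.  Attribute `"truth"`
#'   holds the planted classes.
#' @examples
#' tab <- gen_shift_table("AGQ", c("beta", "RC", "alpha"), noise_sd = 0)
#' classify_shift_table(tab)$class
#' @export
gen_shift_table <- function(sequence, ss_assignment, noise_sd = 0, seed = 1L,
                            rc_table = random_coil_table(),
                            offsets = planted_shift_offsets(),
                            state = "synthetic") {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) != length(ss_assignment))
    stop("sequence and ss_assignment lengths differ")
  if (!all(ss_assignment %in% names(offsets)))
    stop("unknown planted class: ",
         paste(setdiff(ss_assignment, names(offsets)), collapse = ", "))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_along(res)) {
    for (nuc in c("CA", "CB", "CO")) {
      rcv <- .rc_lookup(rc_table, res[i], nuc)
      if (is.na(rcv)) {
        if (nuc == "CB") next  # Gly has no CB
        stop("residue type ", res[i], " nucleus ", nuc,
             " missing from random-coil table")
      }
      off <- offsets[[ss_assignment[i]]][[nuc]]
      rows[[length(rows) + 1]] <- data.frame(
        state = state,
        motif = paste0(res[i], i),   # unique single-residue motif label
        reporter_index = 1L,
        residue_type = res[i],
        nucleus = nuc,
        component_rank = 1L,
        shift_ppm = rcv + off + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- data.frame(position = seq_along(res),
                                   residue_type = res, class = ss_assignment)
  out
}
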