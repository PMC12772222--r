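# Site-level relaxation tables: from long decay TSVs to fitted
# T1/T2/NOE, rates, ratios, and spectral densities.

#' Generate synthetic relaxation decay inputs for a set of sample states
#'
#' Emits a long decay table (columns `state`, `motif`, `residue_type`,
#' `experiment`, `delay_s`, `intensity`, `intensity_err`) for each state
#' and motif site.  Default state means emulate the study conditions for
#' spidroin in intact gland, phosphate-condensed and urea-solubilised
#' states (T1 about 0.67/0.70/0.71 s, T2 0.29/0.25/0.31 s, NOE
#' 0.23/0.24/0.05); per-site values scatter around the state mean with
#' relative SD `site_rel_sd`.  NOE is represented as a saturated/reference
#' intensity pair (`delay_s` 1 and 0).
#'
#' @param states named list; each element a list with `T1`, `T2` (s) and
#'   `NOE`.
#' @param motifs data.frame with columns `motif`, `residue_type` naming
#'   the reporter sites.
#' @param delays_T1,delays_T2 delay grids in seconds.
#' @param noise_sd intensity noise as fraction of I0.
#' @param site_rel_sd relative SD of per-site true values around the
#'   state mean.
#' @param I0 amplitude.
#' @param seed integer seed.
#' @return data.frame decay table; attribute `"truth"` holds the planted
#'   per-site T1/T2/NOE.
#' @export
gen_relaxation_inputs <- function(
    states = list(
      gland = list(T1 = 0.67, T2 = 0.29, NOE = 0.23),
      condensed = list(T1 = 0.70, T2 = 0.25, NOE = 0.24),
      urea = list(T1 = 0.71, T2 = 0.31, NOE = 0.05)),
    motifs = data.frame(
      motif = c("GAA", "AAG", "AAA", "GG", "GY", "RG", "QQ"),
      residue_type = c("A", "A", "A", "G", "Y", "G", "Q")),
    delays_T1 = seq(0.05, 1.75, length.out = 8),
    delays_T2 = seq(0.01, 0.71, length.out = 8),
    noise_sd = 0.05, site_rel_sd = 0.06, I0 = 100, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rows <- list(); truth <- list()
  for (st in names(states)) {
    for (m in seq_len(nrow(motifs))) {
      tT1 <- states[[st]]$T1 * exp(rnorm(1, 0, site_rel_sd))
      tT2 <- states[[st]]$T2 * exp(rnorm(1, 0, site_rel_sd))
      tNOE <- states[[st]]$NOE + rnorm(1, 0, site_rel_sd)
      truth[[length(truth) + 1]] <- data.frame(
        state = st, motif = motifs$motif[m], T1 = tT1, T2 = tT2, NOE = tNOE)
      mk <- function(experiment, delays, Tval) data.frame(
        state = st, motif = motifs$motif[m],
        residue_type = motifs$residue_type[m], experiment = experiment,
        delay_s = delays,
        intensity = I0 * exp(-delays / Tval) +
          rnorm(length(delays), 0, noise_sd * I0),
        intensity_err = noise_sd * I0)
      rows[[length(rows) + 1]] <- mk("T1", delays_T1, tT1)
      rows[[length(rows) + 1]] <- mk("T2", delays_T2, tT2)
      rows[[length(rows) + 1]] <- data.frame(
        state = st, motif = motifs$motif[m],
        residue_type = motifs$residue_type[m], experiment = "NOE",
        delay_s = c(0, 1),
        intensity = c(I0, I0 * tNOE) + rnorm(2, 0, noise_sd * I0),
        intensity_err = noise_sd * I0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Fit a full relaxation table from a long decay table
#'
#' Groups the decay table by (state, motif), fits T1 and T2 decays with
#' [fit_monoexponential()], computes the NOE from the saturated/reference
#' pair (`experiment == "NOE"`, `delay_s` 1/0), then derives R1, R2 and
#' R2/R1, and -- when an acquisition context is supplied -- the reduced
#' spectral densities.
#'
#' @param decays long decay data.frame (see [gen_relaxation_inputs()] for
#'   the column contract).
#' @param ctx optional [acquisition_context()] for spectral-density
#'   columns.
#' @param mc_reps Monte-Carlo error replicates per fit.
#' @param seed integer seed for the Monte-Carlo resampling.
#' @return data.frame with one row per (state, motif): `T1`, `T1_err`,
#'   `T2`, `T2_err`, `NOE`, `NOE_err`, `R1`, `R2`, `R2_over_R1`, and with
#'   `ctx` also `J0`, `JwN`, `JwH087`, `J0_over_JwH`, `out_of_model`.
#' @export
fit_relaxation_table <- function(decays, ctx = NULL, mc_reps = 200,
                                 seed = 1L) {
  need <- c("state", "motif", "experiment", "delay_s", "intensity")
  if (!all(need %in% names(decays)))
    stop("decay table missing columns: ",
         paste(setdiff(need, names(decays)), collapse = ", "))
  key <- unique(decays[, c("state", "motif")])
  rows <- list()
  for (i in seq_len(nrow(key))) {
    sel <- decays$state == key$state[i] & decays$motif == key$motif[i]
    sub <- decays[sel, , drop = FALSE]
    fit_one <- function(exp_name) {
      d <- sub[sub$experiment == exp_name, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      d <- d[order(d$delay_s), , drop = FALSE]
      fit_monoexponential(d$delay_s, d$intensity, mc_reps = mc_reps,
                          seed = seed + i)
    }
    f1 <- fit_one("T1"); f2 <- fit_one("T2")
    noe_rows <- sub[sub$experiment == "NOE", , drop = FALSE]
    noe <- noe_err <- NA_real_
    if (nrow(noe_rows) >= 2) {
      iref <- noe_rows$intensity[noe_rows$delay_s == 0][1]
      isat <- noe_rows$intensity[noe_rows$delay_s != 0][1]
      er <- if ("intensity_err" %in% names(noe_rows))
        noe_rows$intensity_err else NULL
      nn <- compute_noe(isat, iref,
                        I_sat_err = if (!is.null(er)) er[noe_rows$delay_s != 0][1],
                        I_ref_err = if (!is.null(er)) er[noe_rows$delay_s == 0][1])
      noe <- nn$noe; noe_err <- nn$noe_err
    }
    rt <- if ("residue_type" %in% names(sub)) sub$residue_type[1] else NA
    T1 <- if (is.null(f1)) NA_real_ else f1$T
    T2 <- if (is.null(f2)) NA_real_ else f2$T
    rows[[i]] <- data.frame(
      state = key$state[i], motif = key$motif[i], residue_type = rt,
      T1 = T1, T1_err = if (is.null(f1)) NA_real_ else f1$T_err,
      T2 = T2, T2_err = if (is.null(f2)) NA_real_ else f2$T_err,
      NOE = noe, NOE_err = noe_err,
      R1 = 1 / T1, R2 = 1 / T2,
      R2_over_R1 = if (is.finite(T1) && is.finite(T2))
        suppressWarnings(r2_over_r1(T1, T2)) else NA_real_,
      invalid_fit = (!is.null(f1) && f1$invalid) || (!is.null(f2) && f2$invalid)
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(ctx)) {
    ok <- is.finite(out$R1) & is.finite(out$R2) & is.finite(out$NOE)
    jm <- reduced_spectral_density(out$R1[ok], out$R2[ok], out$NOE[ok], ctx)
    out$J0 <- out$JwN <- out$JwH087 <- out$J0_over_JwH <- NA_real_
    out$out_of_model <- NA
    out$J0[ok] <- jm$J0; out$JwN[ok] <- jm$JwN; out$JwH087[ok] <- jm$JwH087
    out$J0_over_JwH[ok] <- jm$J0_over_JwH
    out$out_of_model[ok] <- jm$out_of_model
  }
  out
}
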