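# Config-driven end-to-end pipeline with deterministic outputs.
#
# The config is a single JSON document.  One master seed fans out to
# per-stage seeds by a documented derivation (seed + stage-name character
# hash, modulo 2^31 - 1), so stages are individually reproducible.
# Every tunable threshold is echoed into the report provenance exactly
# once; timestamps go to the stderr log only, keeping all output files
# byte-identical across reruns with the same (config, seed).

.default_config <- function() list(
  seed = 1L,
  out_dir = "silknmr_out",
  stages = list(simulate = TRUE, relaxation = TRUE, shifts = TRUE,
                structure = TRUE),
  simulate = list(
    n_frames = 200L,
    sequence = list(n_repeats = 4L, polyA_len = 6L)
  ),
  relaxation = list(
    freq_MHz = 600,
    r_NH = 1.02,
    delta_sigma_N = -160,
    noise_sd = 0.05,
    mc_reps = 200L
  ),
  shifts = list(
    csp_threshold_H = 0.03,
    csp_threshold_N = 0.1,
    csp_threshold_C = 0.1,
    classify_threshold_ca_cb = 0.7,
    classify_threshold_co = 0.5,
    noise_sd = 0.3
  ),
  structure = list(
    ensemble_pdb = NULL,
    hbond_dist_max = 3.5,
    hbond_angle_min = 150,
    ion_cutoff = 4.0,
    shell_radius = 3.4,
    cationpi_window = 6.0
  )
)

.stage_seed <- function(master, stage) {
  (as.integer(master) %% 1000000000L + sum(utf8ToInt(stage)) * 7919L) %%
    2000000000L
}

#' Validate a pipeline configuration
#'
#' Schema-checks a config (path to a JSON file or an R list): unknown
#' keys are rejected, types and sign constraints are checked, defaults
#' are filled in.  All problems are collected and reported together.
#'
#' @param config path to a JSON config or a named list.
#' @return validated config list (class `silknmr_config`) with defaults
#'   filled; on any violation an error listing every problem.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- .default_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key: ", unknown))
  for (sec in intersect(names(config), names(def))) {
    if (is.list(def[[sec]]) && !is.null(config[[sec]])) {
      if (!is.list(config[[sec]])) {
        errs <- c(errs, paste0(sec, ": must be an object"))
        next
      }
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad)) errs <- c(errs, paste0("unknown key: ", sec, ".", bad))
    }
  }
  cfg <- modifyList(def, config[intersect(names(config), names(def))])
  num_pos <- c("relaxation.freq_MHz", "relaxation.r_NH",
               "shifts.csp_threshold_H", "shifts.csp_threshold_N",
               "shifts.csp_threshold_C", "shifts.classify_threshold_ca_cb",
               "shifts.classify_threshold_co",
               "structure.hbond_dist_max", "structure.ion_cutoff",
               "structure.shell_radius", "structure.cationpi_window")
  for (p in num_pos) {
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      errs <- c(errs, paste0(p, ": must be a positive number"))
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    errs <- c(errs, "seed: must be an integer")
  for (nn in c("relaxation.noise_sd", "shifts.noise_sd")) {
    parts <- strsplit(nn, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || v < 0) errs <- c(errs, paste0(nn, ": must be >= 0"))
  }
  ang <- cfg$structure$hbond_angle_min
  if (!is.numeric(ang) || ang <= 0 || ang > 180)
    errs <- c(errs, "structure.hbond_angle_min: must be in (0, 180]")
  if (!is.null(cfg$structure$ensemble_pdb) &&
      !file.exists(cfg$structure$ensemble_pdb))
    errs <- c(errs, paste0("structure.ensemble_pdb: file not found: ",
                           cfg$structure$ensemble_pdb))
  if (length(errs))
    stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "silknmr_config"
  cfg
}

.log_msg <- function(level, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate feeds the
#' three analysis branches; the branches are independent of each other).
#' A failing branch is recorded and does not stop the other branches.
#' All outputs are TSV/JSON under `out_dir`; reruns with the same
#' (config, seed) are byte-identical.
#'
#' @param config path to a JSON config, or a list (see
#'   [validate_config()]); stage toggles live under `stages`.
#' @return an `analysis_report` list: `status` ("ok"/"partial"/"failed"),
#'   `stages` (per-stage status and output files), `tables` (the main
#'   result data.frames), `provenance` (seeds, thresholds, versions),
#'   `warnings`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(status = "ok", stages = list(), tables = list(),
                 provenance = list(
                   package_version = tryCatch(
                     as.character(utils::packageVersion("silknmr")),
                     error = function(e) "dev"),
                   seed = cfg$seed,
                   config = unclass(cfg)),
                 warnings = character(0))
  warn <- function(msg) {
    report$warnings <<- c(report$warnings, msg)
    .log_msg("WARN", msg)
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) {
      .log_msg("INFO", "stage ", name, " disabled, skipping")
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    .log_msg("INFO", "stage ", name, " starting")
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        warn(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      report$status <<- "partial"
      .log_msg("ERROR", "stage ", name, " failed: ", conditionMessage(res))
      return(invisible(NULL))
    }
    report$stages[[name]] <<- c(list(status = "ok"), res)
    invisible(res)
  }

  sim <- NULL
  run_stage("simulate", function() {
    seed <- .stage_seed(cfg$seed, "simulate")
    seq_spec <- repeat_spec(n_repeats = cfg$simulate$sequence$n_repeats,
                            polyA_len = cfg$simulate$sequence$polyA_len,
                            seed = seed)
    rs <- gen_repeat_sequence(seq_spec)
    fasta <- file.path(cfg$out_dir, "sequence.fasta")
    write_fasta(rs, fasta)
    decays <- gen_relaxation_inputs(noise_sd = cfg$relaxation$noise_sd,
                                    seed = seed)
    decay_path <- file.path(cfg$out_dir, "decays.tsv")
    write_tsv(decays, decay_path,
              header_comments = sprintf("synthetic decays, seed=%d", seed))
    shift_seq <- "AAAAAAGGQGGYGGRGGA"
    classes <- c(rep("beta", 6), rep("RC", 12))
    tab_gland <- gen_shift_table(shift_seq, rep("RC", 18), state = "gland",
                                 noise_sd = 0, seed = seed)
    tab_fiber <- gen_shift_table(shift_seq, classes, state = "fiber",
                                 noise_sd = 0, seed = seed + 1L)
    write_shift_table(tab_gland, file.path(cfg$out_dir, "shifts_gland.tsv"))
    write_shift_table(tab_fiber, file.path(cfg$out_dir, "shifts_fiber.tsv"))
    ens <- gen_planted_ensemble(planted_ensemble_spec(
      n_frames = cfg$simulate$n_frames, seed = seed))
    paths <- write_planted_ensemble(ens, file.path(cfg$out_dir, "ensemble.pdb"))
    sim <<- list(decays = decays, tab_gland = tab_gland,
                 tab_fiber = tab_fiber, ensemble = ens)
    list(files = c(fasta, decay_path, paths$pdb, paths$truth),
         seed = seed)
  })

  run_stage("relaxation", function() {
    seed <- .stage_seed(cfg$seed, "relaxation")
    if (is.null(sim)) stop("relaxation stage needs simulated decays")
    ctx <- acquisition_context(freq_MHz = cfg$relaxation$freq_MHz,
                               r_NH = cfg$relaxation$r_NH,
                               delta_sigma_N = cfg$relaxation$delta_sigma_N)
    tab <- fit_relaxation_table(sim$decays, ctx = ctx,
                                mc_reps = cfg$relaxation$mc_reps, seed = seed)
    path <- file.path(cfg$out_dir, "relaxation.tsv")
    write_tsv(tab, path, header_comments = sprintf(
      "freq_MHz=%g r_NH=%g delta_sigma_N=%g mc_reps=%d seed=%d",
      cfg$relaxation$freq_MHz, cfg$relaxation$r_NH,
      cfg$relaxation$delta_sigma_N, cfg$relaxation$mc_reps, seed))
    report$tables$relaxation <<- tab
    list(files = path, seed = seed)
  })

  run_stage("shifts", function() {
    if (is.null(sim)) stop("shifts stage needs simulated tables")
    thr <- c(H = cfg$shifts$csp_threshold_H, N = cfg$shifts$csp_threshold_N,
             C = cfg$shifts$csp_threshold_C)
    csp <- compute_csp(sim$tab_gland, sim$tab_fiber, thresholds = thr)
    rule <- list(ca_cb = cfg$shifts$classify_threshold_ca_cb,
                 co = cfg$shifts$classify_threshold_co)
    calls <- classify_shift_table(sim$tab_fiber, rule = rule)
    p1 <- file.path(cfg$out_dir, "csp.tsv")
    p2 <- file.path(cfg$out_dir, "structure_calls.tsv")
    write_tsv(csp, p1, header_comments = sprintf(
      "thresholds H=%g N=%g C=%g ppm", thr["H"], thr["N"], thr["C"]))
    write_tsv(calls, p2, header_comments = sprintf(
      "classify thresholds ca_cb=%g co=%g ppm", rule$ca_cb, rule$co))
    report$tables$csp <<- csp
    report$tables$structure_calls <<- calls
    list(files = c(p1, p2))
  })

  run_stage("structure", function() {
    sys <- if (!is.null(cfg$structure$ensemble_pdb))
      read_ensemble(cfg$structure$ensemble_pdb)
    else if (!is.null(sim)) sim$ensemble$system
    else stop("structure stage needs an ensemble (simulate disabled and no ",
              "structure.ensemble_pdb)")
    crit <- hbond_criteria(cfg$structure$hbond_dist_max,
                           cfg$structure$hbond_angle_min)
    bonds <- detect_hbonds_all(sys, crit)
    pf <- pair_frequency_table(bonds, list(c("ARG", "TYR")))
    ion_idx <- select_atoms(sys, resid = c("PO4", "CL", "CLA", "NA", "SOD"))
    files <- character(0)
    ion <- NULL
    if (length(ion_idx)) {
      ion <- ion_binding_fraction(sys, ion_idx,
                                  cutoff = cfg$structure$ion_cutoff)
      sel_n <- select_atoms(sys, resid = "ARG", elety = c("NE", "NH1", "NH2"))
      hyd <- hydration_shell_series(sys, sel_n,
                                    radius = cfg$structure$shell_radius)
      disp <- shell_displacement(ion$per_frame, hyd)
      series <- attr(pf, "series")
      intra_series <- series[["ARG-TYR intra"]]
      cond <- conditional_frequency(intra_series, ion$per_frame)
      ion_tab <- data.frame(frame = seq_along(ion$per_frame),
                            ion_bound = ion$per_frame,
                            shell_waters = hyd,
                            arg_tyr_intra = intra_series,
                            arg_tyr_inter = series[["ARG-TYR inter"]])
      p_ion <- file.path(cfg$out_dir, "ion_binding.tsv")
      write_tsv(ion_tab, p_ion, header_comments = sprintf(
        "ion_cutoff=%g shell_radius=%g", cfg$structure$ion_cutoff,
        cfg$structure$shell_radius))
      p_hyd <- file.path(cfg$out_dir, "hydration.tsv")
      write_tsv(data.frame(ion_bound_fraction = ion$fraction,
                           displacement = disp$displacement,
                           mean_bound = disp$mean_bound,
                           mean_unbound = disp$mean_unbound,
                           p_intra_bound = cond$p[1],
                           p_intra_unbound = cond$p[2]), p_hyd)
      files <- c(files, p_ion, p_hyd)
      report$tables$ion <<- list(fraction = ion$fraction,
                                 displacement = disp$displacement,
                                 conditional = cond)
    }
    cp <- detect_cation_pi(sys, 1, window = cfg$structure$cationpi_window)
    ss <- assign_secondary_structure(sys, 1)
    comp <- ss_composition_by_residue_type(ss)
    p_pf <- file.path(cfg$out_dir, "pair_freqs.tsv")
    p_cp <- file.path(cfg$out_dir, "cationpi.tsv")
    p_ss <- file.path(cfg$out_dir, "ss.tsv")
    write_tsv(pf, p_pf, header_comments = sprintf(
      "hbond dist_max=%g angle_min=%g convention=presence",
      crit$dist_max, crit$angle_min))
    write_tsv(cp, p_cp, header_comments = sprintf(
      "window=%g", cfg$structure$cationpi_window))
    write_tsv(ss$table, p_ss)
    report$tables$pair_freqs <<- pf
    report$tables$cationpi <<- cp
    report$tables$ss_composition <<- comp
    list(files = c(p_pf, p_cp, p_ss, files))
  })

  failed <- vapply(report$stages, function(s) identical(s$status, "failed"),
                   TRUE)
  if (any(failed)) report$status <- if (all(failed)) "failed" else "partial"
  jsonlite::write_json(
    list(status = report$status,
         stages = lapply(report$stages, function(s)
           s[setdiff(names(s), "files")]),
         provenance = report$provenance,
         warnings = report$warnings),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("silknmr pipeline report -- status:", x$status, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-11s %s\n", nm, x$stages[[nm]]$status))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
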