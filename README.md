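# silknmr

NMR relaxation, chemical-shift, and coordinate-ensemble interaction
analytics for studies of spider-silk protein (spidroin) liquid-liquid
phase separation and fiber assembly.

Spidroins such as MaSp1 are stored in the major ampullate gland as a
concentrated intrinsically disordered solution, condense via
phosphate-triggered liquid-liquid phase separation (LLPS), and are spun
into a beta-sheet-rich fiber.  Following that pathway quantitatively
means combining three data streams, and `silknmr` implements the
analysis chain for all of them:

* **Backbone dynamics** — monoexponential fitting of ¹⁵N T₁/T₂ decay
  series with Monte-Carlo parameter errors, heteronuclear NOE, R₂/R₁,
  and reduced spectral-density mapping of {R₁, R₂, NOE} onto
  J(0), J(ω_N), J(0.87 ω_H) via

  σ_NH = R₁(NOE − 1)(γ_N/γ_H),  J(0.87ω_H) = 4σ_NH/(5d²),
  J(ω_N) = [R₁ − (7d²/4)J(0.87ω_H)] / (3d²/4 + c²),
  J(0) = [R₂ − (13d²/8)J(0.87ω_H) − (3d²/8 + c²/2)J(ω_N)] / (d²/2 + 2c²/3),

  with d = μ₀hγ_Hγ_N/(8π²r³) and c = ω_NΔσ/√3.
* **Chemical shifts across states** — per-motif-site chemical-shift
  perturbations with per-nucleus significance thresholds (0.03 ppm ¹H,
  0.1 ppm ¹⁵N), random-coil-referenced secondary-structure
  classification (β / α / coil / ambiguous, including multi-component
  resonances), state-to-state Δδ maps with explicit component pairing,
  and predicted-vs-experimental shift statistics.
* **Ensemble interaction geometry** — on multi-model PDB coordinate
  ensembles: hydrogen-bond detection (3.5 Å / 150°, explicit H) and
  residue-pair occupancy tables, ion-binding fractions and conditional
  contact statistics with Wilson intervals, hydration-shell
  displacement, cation–π detection and T-shaped/stacked classification
  of Arg–Tyr contacts, and simplified Kabsch–Sander H/E/C
  secondary-structure assignment.
* **Synthetic data with planted truth** — generators for MaSp1-like
  repeat sequences, decay series, shift tables and coordinate
  ensembles whose parameters are known exactly, so every stage of the
  chain is testable end to end without external data.
* **Pipeline** — a JSON-config-driven orchestrator with deterministic,
  provenance-stamped TSV outputs (`run_pipeline()`), plus a thin CLI at
  `inst/cli/silknmr-cli.R`.

## Worked example

Fit a synthetic condensed-phase-like T₁ decay and map spectral
densities:

```r
library(silknmr)

t <- seq(0.05, 1.75, length.out = 8)
d <- gen_decay(T = 0.70, I0 = 100, delays = t, noise_sd = 0.05, seed = 1)
fit <- fit_monoexponential(d$delay_s, d$intensity, mc_reps = 200, seed = 1)
fit
#> Monoexponential decay fit: I(t) = I0 * exp(-t/T)
#>   T  = 0.755835 s +/- 0.0587
#>   I0 = 96.2292 +/- 4.35
#>   8 points, residual SD 4.27

r2_over_r1(fit$T, 0.25)
#> [1] 3.023339

ctx <- acquisition_context(freq_MHz = 600)
jm <- reduced_spectral_density(R1 = 1 / fit$T, R2 = 1 / 0.25, NOE = 0.24, ctx)
jm$J0
#> [1] 9.550515e-10
```

The fitted T₁ recovers the planted 0.70 s within its Monte-Carlo error
bar (an 8-point series at 5% noise carries ~8% error, which the bar
reflects); a T₁/T₂ near 3 and a J(0) around 1 ns/rad are the magnitudes
that distinguish the condensed phase's restricted slow motions from its
preserved fast dynamics.

Recover planted interaction statistics from a synthetic 2000-frame
ensemble:

```r
pe  <- gen_planted_ensemble(planted_ensemble_spec(n_frames = 2000, seed = 1))
sys <- pe$system
ion <- ion_binding_fraction(sys, select_atoms(sys, resid = "PO4"))
ion$fraction
#> [1] 0.7055

cp <- detect_cation_pi(sys, 1)
cp[cp$ring_chain == "B", c("d_eta1", "d_eta2", "geometry_class", "asymmetric")]
#>   d_eta1 d_eta2 geometry_class asymmetric
#> 1      4    4.5       T-shaped       TRUE
```

The ion-bound fraction recovers the planted 0.71 to binomial precision,
and the Arg guanidinium is found contacting the Tyr ring at exactly the
planted 4.0 / 4.5 Å asymmetric T-shaped pose.

Run the whole pipeline on the bundled demo configuration:

```r
cfg <- system.file("extdata", "demo_config.json", package = "silknmr")
report <- run_pipeline(cfg)
report
#> silknmr pipeline report -- status: ok
#>   simulate    ok
#>   relaxation  ok
#>   shifts      ok
#>   structure   ok
```

Outputs (`relaxation.tsv`, `csp.tsv`, `structure_calls.tsv`,
`pair_freqs.tsv`, `ion_binding.tsv`, `hydration.tsv`, `cationpi.tsv`,
`ss.tsv`, `report.json`) land in the configured output directory and
are byte-identical across reruns with the same config and seed.

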