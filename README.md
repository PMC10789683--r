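# pplcvp

Estimating the tidal change in pleural pressure (ΔPpl) from the
respiratory swing of central venous pressure (ΔCVP), calibrated by an
end-expiratory occlusion test — with a ground-truth waveform simulator,
validity filtering, compliance partitioning, and method-agreement
statistics.

## The problem

Transpulmonary pressure — airway minus pleural pressure — is the
lung-distending pressure that protective ventilation tries to limit, but
pleural pressure is hard to measure: the esophageal-balloon surrogate
(Pes) is technically demanding and rarely used. The CVP waveform, already
monitored in most critically ill patients, transmits pleural pressure
swings *partially*, with an unknown attenuation. The occlusion test (OT)
calibrates it: with the airway closed at end-expiration and the chest
gently squeezed, no gas flows, so the airway pressure change equals the
pleural pressure change, and

κ = ΔPaw/ΔCVP during OT

measures the reciprocal of the pleural-to-CVP transmission. During
ventilation the corrected estimate is then

**cΔCVP-derived ΔPpl = κ × ΔCVP**.

If the transmission is the same during occlusion and ventilation this is
an identity — the package's central, machine-precision-tested invariant —
and everything else (hold-window plateau extraction with cardiac-cycle
averaging of CVP, the 0.8–1.2 validity band, the exclusion cascade,
Crs/Ccw/CL partitioning, Bland–Altman and repeated-measures correlation)
is the machinery needed to run that identity as a study. Because no public
recordings exist for this design, the package ships a single-compartment
cardio-respiratory simulator with known ground truth emulating the
original protocol: 10 subjects × 6 conditions (three intravascular-volume
states × two chest-wall-compliance states).

## Worked example

```r
library(pplcvp)

# one subject, one condition, known truth: CL 25, Ccw 100 mL/cmH2O,
# transmission T = 0.5 (true kappa = 2), TV 300 mL, PEEP 6 cmH2O
rec <- simulate_condition(subject_params(cl = 25),
                          condition_spec(ccw = 100, transmission = 0.5),
                          vent_settings(tidal_volume = 300),
                          seed = 1, noise_free = TRUE)
as.data.frame(process_record(rec)[, c("d_paw", "d_dppl", "d_cvp", "kappa",
                                      "est_dppl", "crs", "ccw", "cl")])
#>   d_paw d_dppl d_cvp kappa est_dppl crs ccw cl
#> 1    15      3   1.5     2        3  20 100 25
```

The driving pressure is TV/Crs = 300·(1/25 + 1/100) = 15 cmH2O, the
pleural swing TV/Ccw = 3 cmH2O, the CVP swing T·3 = 1.5 cmH2O; the
occlusion test recovers κ = 2 and the corrected estimate κ·ΔCVP = 3 cmH2O
equals the directly measured swing exactly, while the compliance partition
(Crs 20, Ccw 100, CL 25 mL/cmH2O) inverts the generator.

A full study, with cardiac oscillation and measurement noise:

```r
report <- run_study(study_config(n_subjects = 10, master_seed = 20240115))
report
#> <study_report> 60 conditions from 10 subjects (seed 20240115)
#>   excluded: 0 dppl_paw_failure, 18 pes_ratio_out_of_band, 0 cvp_failure
#>   cdcvp_vs_dppl: n = 60, bias 0.05, precision 0.23 cmH2O, rmcorr r = 0.999
#>   pes_vs_dppl: n = 42, bias -0.61, precision 0.55 cmH2O, rmcorr r = 0.998
#>   pes_vs_cdcvp: n = 42, bias -0.62, precision 0.58 cmH2O, rmcorr r = 0.998
```

Bias is the mean difference estimate − reference (cmH2O), precision the SD
of the differences, and rmcorr the common within-subject correlation; the
esophageal comparisons lose conditions to the 0.8–1.2 balloon-validity
band, mirroring how such studies exclude failed measurements.

## Analysis scripts

The numbered scripts under `analysis/` run the study end to end and write
tables/figures under `results/`:

```sh
Rscript analysis/01_simulate_study.R   # cohort + example waveform CSVs
Rscript analysis/02_estimate.R         # per-condition estimates, exclusions
Rscript analysis/03_agreement.R        # rmcorr + Bland-Altman, figures
Rscript analysis/04_robustness.R       # null-model and violation sweeps
```

## Package layout

- `R/` — simulator (`simulate_condition`, `draw_study`), waveform I/O and
  hold handling (`read_record`, `detect_holds`, `plateau`), estimation
  (`calibrate_ot`, `tidal_deltas`, `compute_compliances`,
  `apply_exclusions`), agreement (`bland_altman`, `rmcorr`,
  `summarize_study`), pipeline (`run_study`, `scenario_sweep`).
- `vignettes/estimating-pleural-pressure-from-cvp.Rmd` — the model, its
  assumptions, parameter priors, and the package's design decisions.
- `tests/testthat/` — unit, property and end-to-end tests.
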