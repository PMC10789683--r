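## Study-level parameter priors and the study generator.
##
## Defaults are truncated normals centered on the calibration experiment's
## group means and SDs: subject weight 43.2 +/- 1.8 kg, chest wall
## compliance ~89 (normal) vs ~37 (banded abdomen) mL/cmH2O, end-expiratory
## CVP rising from ~7.5 to ~19.7 mmHg across the six volume-status x
## chest-wall cells, calibration ratio kappa 2.2 +/- 1.3, esophageal
## transmission 0.9 +/- 0.1. Venous/abdominal pressures are specified in
## mmHg and converted to cmH2O (x 1.36) at this layer.

tn <- function(mean, sd, lo = -Inf, hi = Inf) {
  c(mean = mean, sd = sd, lo = lo, hi = hi)
}

draw1 <- function(p) rtruncnorm(1, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]])

#' Default parameter priors for a simulated study
#'
#' @param noise_sd named white-noise SDs (cmH2O) for the pressure channels.
#' @return nested list of priors; each leaf is `c(mean, sd, lo, hi)` of a
#'   truncated normal. Override individual entries to change the study
#'   population, or set all `sd` to 0 for a deterministic cohort.
#' @export
default_priors <- function(noise_sd = c(paw = 0.3, pes = 0.3,
                                        dppl = 0.3, cvp = 0.3)) {
  list(
    subject = list(
      weight = tn(43.2, 1.8, 35, 55),            # kg
      cl = tn(30, 9, 12, 60),                    # mL/cmH2O
      airway_resistance = tn(10, 2, 5, 20),      # cmH2O.s/L
      pes_transmission = tn(0.9, 0.1, 0.7, 1.1), # dimensionless
      cardiac_rate = tn(87.9, 16.8, 60, 130),    # bpm
      cardiac_amplitude = tn(2, 0.5, 0.5, 4)     # cmH2O
    ),
    condition = list(
      ccw = list(N = tn(89.0, 25.6, 40, 160),    # mL/cmH2O
                 L = tn(36.8, 16.8, 15, 90)),
      # end-expiratory CVP in mmHg per (volume status, chest wall) cell
      cvp_baseline_mmHg = list(
        low_N = tn(7.5, 1.0, 3, 30), low_L = tn(11.7, 1.5, 3, 30),
        normal_N = tn(12.2, 1.2, 3, 30), normal_L = tn(15.7, 2.6, 3, 30),
        high_N = tn(14.9, 2.6, 3, 30), high_L = tn(19.7, 3.3, 3, 30)
      ),
      kappa = tn(2.2, 1.3, 1.05, 5),             # true kappa = 1/transmission
      abdominal_mmHg = list(N = tn(7.6, 3.5, 0, 15), L = tn(20, 3.2, 12, 28)),
      end_expiratory_ppl = tn(3, 1, 0, 8)        # cmH2O
    ),
    noise_sd = noise_sd,
    tv_per_kg = 8,                               # mL/kg
    # optional model violation: relative drift of the CVP transmission
    # between occlusion test and ventilation, per volume level
    # (drift = gradient * (volume index - 2), index 1/2/3 = low/normal/high)
    transmission_drift_gradient = 0
  )
}

CONDITION_GRID <- data.frame(
  volume_status = rep(c("low", "normal", "high"), each = 2),
  ccw_level = rep(c("N", "L"), times = 3),
  stringsAsFactors = FALSE
)

#' Draw a full simulated study
#'
#' Samples `n_subjects` subjects from the priors and simulates each under
#' the six-condition protocol (volume status low, normal, high; within each,
#' chest wall normal then banded). Subject-level parameters persist across
#' that subject's six conditions; condition-level parameters (chest wall
#' compliance, CVP baseline, transmission, abdominal pressure) are drawn per
#' condition. Per-record seeds are derived deterministically from
#' `master_seed`, so the same seed reproduces the study bit-for-bit.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param priors prior list, see [default_priors()].
#' @param master_seed integer master seed.
#' @param noise_free disable cardiac oscillation and noise in all records.
#' @param n_breaths ordinary breaths per record.
#' @param peep,resp_rate,insp_frac,sample_rate ventilator settings shared by
#'   all subjects (tidal volume is `tv_per_kg * weight` per subject).
#' @return a list of [wf_record()]s of length `n_subjects * 6`, ordered by
#'   subject then protocol position, with a `params` attribute (tibble of
#'   the drawn ground-truth parameters, one row per record).
#' @export
draw_study <- function(n_subjects, priors = default_priors(),
                       master_seed = 1, noise_free = FALSE, n_breaths = 5,
                       peep = 6, resp_rate = 18, insp_frac = 0.4,
                       sample_rate = 100) {
  if (n_subjects < 2) {
    stop("`n_subjects` must be >= 2 (repeated-measures statistics are ",
         "undefined for a single subject)", call. = FALSE)
  }
  grad <- priors$transmission_drift_gradient %||% 0

  params <- with_seed(derive_seed(master_seed, 0), {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      sp <- priors$subject
      weight <- draw1(sp$weight)
      subj <- list(
        subject = s,
        weight = weight,
        cl = draw1(sp$cl),
        airway_resistance = draw1(sp$airway_resistance),
        pes_transmission = draw1(sp$pes_transmission),
        cardiac_rate = draw1(sp$cardiac_rate),
        cardiac_amplitude = draw1(sp$cardiac_amplitude),
        tidal_volume = priors$tv_per_kg * weight
      )
      for (g in seq_len(nrow(CONDITION_GRID))) {
        vs <- CONDITION_GRID$volume_status[g]
        cw <- CONDITION_GRID$ccw_level[g]
        cp <- priors$condition
        kappa_true <- draw1(cp$kappa)
        transmission <- 1 / kappa_true
        vi <- match(vs, c("low", "normal", "high"))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          !!!subj,
          volume_status = vs, ccw_level = cw,
          ccw = draw1(cp$ccw[[cw]]),
          cvp_baseline = mmHg_to_cmH2O(
            draw1(cp$cvp_baseline_mmHg[[paste(vs, cw, sep = "_")]])),
          transmission = transmission,
          transmission_drift = grad * (vi - 2),
          abdominal_pressure = mmHg_to_cmH2O(draw1(cp$abdominal_mmHg[[cw]])),
          end_expiratory_ppl = draw1(cp$end_expiratory_ppl)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
  params$record <- seq_len(nrow(params))

  records <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    subject <- subject_params(
      weight = p$weight, cl = p$cl,
      airway_resistance = p$airway_resistance,
      pes_transmission = p$pes_transmission,
      cardiac_rate = p$cardiac_rate,
      cardiac_amplitude = p$cardiac_amplitude,
      noise_sd = priors$noise_sd
    )
    cond <- condition_spec(
      volume_status = p$volume_status, ccw_level = p$ccw_level,
      ccw = p$ccw, cvp_baseline = p$cvp_baseline,
      transmission = p$transmission,
      transmission_drift = p$transmission_drift,
      abdominal_pressure = p$abdominal_pressure,
      end_expiratory_ppl = p$end_expiratory_ppl
    )
    vent <- vent_settings(
      tidal_volume = p$tidal_volume, peep = peep, resp_rate = resp_rate,
      insp_frac = insp_frac, sample_rate = sample_rate
    )
    rec <- simulate_condition(subject, cond, vent, n_breaths = n_breaths,
                              seed = derive_seed(master_seed, i),
                              noise_free = noise_free)
    rec$truth$subject_id <- p$subject
    rec
  })
  attr(records, "params") <- params
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a
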