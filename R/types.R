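#' Ventilator settings
#'
#' Volume-controlled ventilation parameters for the waveform simulator.
#'
#' @param tidal_volume tidal volume (mL); must be positive.
#' @param peep positive end-expiratory pressure (cmH2O).
#' @param resp_rate respiratory rate (breaths/min).
#' @param insp_frac fraction of the breath cycle spent in inspiration
#'   (0 < insp_frac < 1).
#' @param sample_rate sampling rate of the recorded waveforms (Hz, >= 50).
#' @return an object of class `vent_settings`.
#' @export
#' @examples
#' vent_settings(tidal_volume = 350)
vent_settings <- function(tidal_volume, peep = 6, resp_rate = 18,
                          insp_frac = 0.4, sample_rate = 100) {
  stopifnot(is.numeric(tidal_volume), length(tidal_volume) == 1)
  if (tidal_volume <= 0) stop("`tidal_volume` must be positive", call. = FALSE)
  if (peep < 0) stop("`peep` must be non-negative", call. = FALSE)
  if (resp_rate <= 0) stop("`resp_rate` must be positive", call. = FALSE)
  if (insp_frac <= 0 || insp_frac >= 1) {
    stop("`insp_frac` must be strictly between 0 and 1", call. = FALSE)
  }
  if (sample_rate < 50) stop("`sample_rate` must be >= 50 Hz", call. = FALSE)
  structure(
    list(
      tidal_volume = tidal_volume, peep = peep, resp_rate = resp_rate,
      insp_frac = insp_frac, sample_rate = sample_rate
    ),
    class = "vent_settings"
  )
}

#' Subject-level physiological parameters
#'
#' Parameters that persist for one subject across all experimental
#' conditions: body size, lung mechanics, esophageal transmission and
#' cardiac interference on the CVP channel.
#'
#' @param weight body weight (kg).
#' @param cl lung compliance (mL/cmH2O), > 0.
#' @param airway_resistance airway resistance (cmH2O.s/L).
#' @param pes_transmission ratio of the esophageal swing to the true pleural
#'   swing (dimensionless, 0.7--1.1); values outside the 0.8--1.2 validity
#'   band downstream model balloon mis-calibration.
#' @param cardiac_rate heart rate (beats/min).
#' @param cardiac_amplitude amplitude of the cardiac oscillation on CVP
#'   (cmH2O).
#' @param noise_sd named numeric vector of white-noise SDs (cmH2O) for the
#'   pressure channels `paw`, `pes`, `dppl`, `cvp`.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(weight = 43, cl = 30, airway_resistance = 10,
                           pes_transmission = 0.9, cardiac_rate = 80,
                           cardiac_amplitude = 2,
                           noise_sd = c(paw = 0.3, pes = 0.3,
                                        dppl = 0.3, cvp = 0.3)) {
  if (cl <= 0) stop("lung compliance `cl` must be positive", call. = FALSE)
  if (airway_resistance <= 0) {
    stop("`airway_resistance` must be positive", call. = FALSE)
  }
  if (pes_transmission < 0.7 || pes_transmission > 1.1) {
    stop("`pes_transmission` must lie in [0.7, 1.1]", call. = FALSE)
  }
  if (cardiac_rate <= 0) stop("`cardiac_rate` must be positive", call. = FALSE)
  if (cardiac_amplitude < 0) {
    stop("`cardiac_amplitude` must be non-negative", call. = FALSE)
  }
  full <- c(paw = 0, pes = 0, dppl = 0, cvp = 0)
  if (is.null(names(noise_sd))) {
    full[] <- noise_sd
  } else {
    full[names(noise_sd)] <- noise_sd
  }
  if (any(full < 0)) stop("`noise_sd` entries must be >= 0", call. = FALSE)
  structure(
    list(
      weight = weight, cl = cl, airway_resistance = airway_resistance,
      pes_transmission = pes_transmission, cardiac_rate = cardiac_rate,
      cardiac_amplitude = cardiac_amplitude, noise_sd = full
    ),
    class = "subject_params"
  )
}

#' Condition-level parameters
#'
#' Ground-truth parameters describing one experimental condition: the
#' intravascular volume state (shifting the CVP baseline), the chest-wall
#' compliance state, and the pleural-to-CVP transmission fraction.
#'
#' @param volume_status one of `"low"`, `"normal"`, `"high"`.
#' @param ccw_level chest-wall state: `"N"` (normal) or `"L"` (low
#'   compliance, abdominal band).
#' @param ccw chest wall compliance (mL/cmH2O), > 0.
#' @param cvp_baseline end-expiratory CVP (cmH2O).
#' @param transmission fraction of a pleural pressure change transmitted to
#'   CVP (dimensionless, 0 < transmission <= 1.5). The true calibration
#'   ratio is `kappa = 1/transmission`.
#' @param transmission_drift relative change of the transmission between
#'   the occlusion test and tidal ventilation (0 = the calibration
#'   assumption holds exactly; nonzero values deliberately violate it, for
#'   sensitivity analyses).
#' @param abdominal_pressure intra-abdominal pressure (cmH2O); descriptive.
#' @param end_expiratory_ppl end-expiratory pleural pressure (cmH2O).
#' @return an object of class `condition_spec`.
#' @export
condition_spec <- function(volume_status = "normal", ccw_level = "N",
                           ccw = 89, cvp_baseline = 16, transmission = 0.45,
                           abdominal_pressure = 10, end_expiratory_ppl = 3,
                           transmission_drift = 0) {
  volume_status <- match.arg(volume_status, c("low", "normal", "high"))
  ccw_level <- match.arg(ccw_level, c("N", "L"))
  if (ccw <= 0) stop("chest wall compliance `ccw` must be positive", call. = FALSE)
  if (transmission <= 0 || transmission > 1.5) {
    stop("`transmission` must lie in (0, 1.5]", call. = FALSE)
  }
  structure(
    list(
      volume_status = volume_status, ccw_level = ccw_level, ccw = ccw,
      cvp_baseline = cvp_baseline, transmission = transmission,
      abdominal_pressure = abdominal_pressure,
      end_expiratory_ppl = end_expiratory_ppl,
      transmission_drift = transmission_drift
    ),
    class = "condition_spec"
  )
}
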