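## The core method: occlusion-test calibration (kappa = dPaw/dCVP), tidal
## pressure swings from holds, the corrected CVP-derived pleural swing
## (kappa * dCVP), validity filtering and compliance partitioning.

reading_value <- function(x) {
  if (inherits(x, "plateau_reading")) x$value else as.numeric(x)
}

reading_set <- function(readings) {
  ## accept either a named numeric vector or a named list of
  ## plateau_reading objects
  if (is.numeric(readings)) return(as.list(readings))
  lapply(readings, reading_value)
}

#' Calibrate the CVP transmission from an occlusion test
#'
#' With the airway closed at end-expiration, a chest squeeze changes airway
#' pressure by exactly the pleural pressure change. The calibration ratio
#' `kappa = dPaw/dCVP` therefore measures the reciprocal of the
#' pleural-to-CVP transmission, and the validity ratios `dPes/dPaw` and
#' `d-Ppl/dPaw` check the esophageal balloon and the pleural catheter
#' against the occlusion standard (valid when inside `band`, boundaries
#' inclusive).
#'
#' A tidal CVP swing smaller than `eps_cvp` makes `kappa` numerically
#' unstable; the calibration is then flagged as an occlusion-test failure
#' (`ot_failed = TRUE`, `kappa = NA`) with a classed warning
#' (`pplcvp_ot_failure`), and downstream comparisons drop the condition.
#'
#' @param baseline,squeeze named sets of plateau values (named numeric
#'   vector, or named list of [plateau()] readings) for the occlusion-test
#'   baseline and squeeze windows. `paw` and `cvp` are required; `pes` and
#'   `dppl` are used when present.
#' @param band validity band for the transmission ratios.
#' @param eps_cvp minimum usable occlusion-test CVP swing (cmH2O).
#' @return an object of class `ot_calibration`: deltas per channel,
#'   `kappa`, validity ratios and flags, `ot_failed`.
#' @export
#' @examples
#' calibrate_ot(c(paw = 6, cvp = 16), c(paw = 16, cvp = 21))
calibrate_ot <- function(baseline, squeeze, band = c(0.8, 1.2),
                         eps_cvp = 0.5) {
  b <- reading_set(baseline)
  s <- reading_set(squeeze)
  need <- c("paw", "cvp")
  if (!all(need %in% names(b)) || !all(need %in% names(s))) {
    stop("occlusion-test readings must include `paw` and `cvp`",
         call. = FALSE)
  }
  delta <- function(ch) {
    if (ch %in% names(b) && ch %in% names(s)) s[[ch]] - b[[ch]] else NA_real_
  }
  d_paw <- delta("paw")
  d_cvp <- delta("cvp")
  d_pes <- delta("pes")
  d_dppl <- delta("dppl")
  ot_failed <- abs(d_cvp) < eps_cvp
  kappa <- if (ot_failed) NA_real_ else d_paw / d_cvp
  if (ot_failed) {
    warning(
      structure(
        class = c("pplcvp_ot_failure", "warning", "condition"),
        list(message = sprintf(
          "occlusion-test failure: |dCVP| = %.3g < %.3g cmH2O, kappa unstable",
          abs(d_cvp), eps_cvp), call = NULL)
      )
    )
  }
  ratio_pes <- if (is.na(d_pes)) NA_real_ else d_pes / d_paw
  ratio_dppl <- if (is.na(d_dppl)) NA_real_ else d_dppl / d_paw
  in_band <- function(r) !is.na(r) & r >= band[1] & r <= band[2]
  structure(
    list(d_paw = d_paw, d_pes = d_pes, d_cvp = d_cvp, d_dppl = d_dppl,
         kappa = kappa, ratio_pes = ratio_pes, ratio_dppl = ratio_dppl,
         valid_pes = in_band(ratio_pes), valid_dppl = in_band(ratio_dppl),
         ot_failed = ot_failed, band = band, eps_cvp = eps_cvp),
    class = "ot_calibration"
  )
}

#' @export
print.ot_calibration <- function(x, ...) {
  cat(sprintf(
    "<ot_calibration> kappa = %.3g (dPaw %.3g / dCVP %.3g)%s\n",
    x$kappa, x$d_paw, x$d_cvp, if (x$ot_failed) " [OT FAILED]" else ""))
  cat(sprintf("  dPes/dPaw = %.3g (%s), d-Ppl/dPaw = %.3g (%s)\n",
              x$ratio_pes, if (isTRUE(x$valid_pes)) "valid" else "invalid",
              x$ratio_dppl, if (isTRUE(x$valid_dppl)) "valid" else "invalid"))
  invisible(x)
}

#' Partition respiratory-system compliance into lung and chest wall
#'
#' `Crs = TV / (plateau - total PEEP)`, `Ccw = TV / d-Ppl swing`, and
#' `CL = TV / (driving pressure - d-Ppl swing)`; elastances are additive,
#' `1/Crs = 1/CL + 1/Ccw`. When the pleural swing equals or exceeds the
#' driving pressure the lung compliance is undefined and returned as `NA`
#' with `cl_defined = FALSE`.
#'
#' @param tv tidal volume (mL).
#' @param plateau_paw inspiratory plateau pressure (cmH2O).
#' @param total_peep airway pressure during the expiratory hold (cmH2O).
#' @param d_dppl tidal swing of the directly measured pleural pressure
#'   (cmH2O), > 0.
#' @return list with `crs`, `ccw`, `cl` (mL/cmH2O) and `cl_defined`.
#' @export
#' @examples
#' compute_compliances(300, 21, 6, 3) # crs 20, ccw 100, cl 25
compute_compliances <- function(tv, plateau_paw, total_peep, d_dppl) {
  if (plateau_paw <= total_peep) {
    stop("`plateau_paw` must exceed `total_peep`", call. = FALSE)
  }
  if (is.na(d_dppl) || d_dppl <= 0) {
    stop("`d_dppl` must be positive", call. = FALSE)
  }
  dp <- plateau_paw - total_peep
  crs <- tv / dp
  ccw <- tv / d_dppl
  if (d_dppl >= dp) {
    return(list(crs = crs, ccw = ccw, cl = NA_real_, cl_defined = FALSE))
  }
  list(crs = crs, ccw = ccw, cl = tv / (dp - d_dppl), cl_defined = TRUE)
}

#' Tidal pressure swings and the corrected CVP estimate
#'
#' Differences inspiratory hold minus expiratory hold per channel, the
#' corrected CVP-derived pleural swing `est_dppl = kappa * dCVP`, and the
#' compliance partition. Missing channels flag the affected comparisons but
#' do not block the others.
#'
#' @param insp,exp named plateau sets (see [calibrate_ot()]) from the
#'   inspiratory and expiratory holds; `paw` and `cvp` required.
#' @param cal an [calibrate_ot()] result. Must not be OT-failed for the
#'   CVP-derived estimate; if it is, `est_dppl` is `NA`.
#' @param tv tidal volume (mL).
#' @return an object of class `delta_set`.
#' @export
tidal_deltas <- function(insp, exp, cal, tv) {
  stopifnot(inherits(cal, "ot_calibration"))
  i <- reading_set(insp)
  e <- reading_set(exp)
  if (!all(c("paw", "cvp") %in% names(i)) ||
      !all(c("paw", "cvp") %in% names(e))) {
    stop("hold readings must include `paw` and `cvp`", call. = FALSE)
  }
  delta <- function(ch) {
    if (ch %in% names(i) && ch %in% names(e)) i[[ch]] - e[[ch]] else NA_real_
  }
  d_paw <- delta("paw")
  d_pes <- delta("pes")
  d_cvp <- delta("cvp")
  d_dppl <- delta("dppl")
  est_dppl <- if (cal$ot_failed) NA_real_ else cal$kappa * d_cvp
  comp <- if (!is.na(d_dppl) && d_dppl > 0 && d_paw > 0) {
    compute_compliances(tv, i$paw, e$paw, d_dppl)
  } else {
    list(crs = if (d_paw > 0) tv / d_paw else NA_real_,
         ccw = NA_real_, cl = NA_real_, cl_defined = FALSE)
  }
  structure(
    list(d_paw = d_paw, d_pes = d_pes, d_cvp = d_cvp, d_dppl = d_dppl,
         est_dppl = est_dppl, tidal_volume = tv,
         crs = comp$crs, ccw = comp$ccw, cl = comp$cl,
         cl_defined = comp$cl_defined,
         kappa = cal$kappa, ratio_pes = cal$ratio_pes,
         ratio_dppl = cal$ratio_dppl,
         valid_pes = cal$valid_pes, valid_dppl = cal$valid_dppl,
         ot_failed = cal$ot_failed),
    class = "delta_set"
  )
}

#' @export
print.delta_set <- function(x, ...) {
  cat(sprintf(
    "<delta_set> dPaw %.3g | d-Ppl %.3g | dPes %.3g | dCVP %.3g -> est dPpl %.3g\n",
    x$d_paw, x$d_dppl, x$d_pes, x$d_cvp, x$est_dppl))
  cat(sprintf("  Crs %.3g, Ccw %.3g, CL %.3g mL/cmH2O; kappa %.3g\n",
              x$crs, x$ccw, x$cl, x$kappa))
  invisible(x)
}

#' Process one simulated or recorded condition end to end
#'
#' Reads the occlusion-test and hold windows from the record's annotations,
#' calibrates kappa, forms the tidal deltas and compliances, and returns a
#' one-row tibble ready for study-level filtering and agreement analysis.
#' The tidal volume is measured from the volume channel (inspiratory-hold
#' minus expiratory-hold plateau), not taken from the ground truth.
#'
#' @param record a [wf_record()] with `ot_baseline`, `ot_squeeze`,
#'   `exp_hold` and `insp_hold` annotations.
#' @param band,eps_cvp validity thresholds, see [calibrate_ot()].
#' @param avg_frac plateau averaging fraction, see [plateau()].
#' @return a one-row [tibble::tibble()].
#' @export
process_record <- function(record, band = c(0.8, 1.2), eps_cvp = 0.5,
                           avg_frac = 0.5) {
  stopifnot(inherits(record, "wf_record"))
  holds <- detect_holds(record)
  win <- function(label) {
    w <- holds[holds$label == label, , drop = FALSE]
    if (!nrow(w)) stop("record has no `", label, "` window", call. = FALSE)
    w[1, ]
  }
  read_set <- function(label, channels = c("paw", "pes", "dppl", "cvp")) {
    w <- win(label)
    out <- lapply(channels, function(ch) plateau(record, w, ch, avg_frac))
    names(out) <- channels
    out
  }
  otb <- read_set("ot_baseline")
  ots <- read_set("ot_squeeze")
  cal <- withCallingHandlers(
    calibrate_ot(otb, ots, band = band, eps_cvp = eps_cvp),
    pplcvp_ot_failure = function(w) invokeRestart("muffleWarning")
  )
  ihold <- read_set("insp_hold")
  ehold <- read_set("exp_hold")
  tv <- reading_value(plateau(record, win("insp_hold"), "volume", avg_frac)) -
    reading_value(plateau(record, win("exp_hold"), "volume", avg_frac))
  ds <- tidal_deltas(ihold, ehold, cal, tv)

  truth <- record$truth
  tr <- function(field, sub = "condition") {
    if (is.null(truth)) NA_real_ else as.numeric(truth[[sub]][[field]])
  }
  tibble::tibble(
    subject = if (!is.null(truth$subject_id)) truth$subject_id else NA_integer_,
    volume_status = if (!is.null(truth)) truth$condition$volume_status else NA,
    ccw_level = if (!is.null(truth)) truth$condition$ccw_level else NA,
    tidal_volume = tv,
    total_peep = reading_value(ehold$paw),
    plateau_paw = reading_value(ihold$paw),
    d_paw = ds$d_paw, d_pes = ds$d_pes, d_cvp = ds$d_cvp,
    d_dppl = ds$d_dppl, est_dppl = ds$est_dppl,
    kappa = ds$kappa, ratio_pes = ds$ratio_pes, ratio_dppl = ds$ratio_dppl,
    valid_pes = ds$valid_pes, valid_dppl = ds$valid_dppl,
    ot_failed = ds$ot_failed, cvp_failed = FALSE,
    crs = ds$crs, ccw = ds$ccw, cl = ds$cl, cl_defined = ds$cl_defined,
    n_cvp_exp = ehold$cvp$n, n_cvp_insp = ihold$cvp$n,
    n_cvp_otb = otb$cvp$n, n_cvp_ots = ots$cvp$n,
    truth_transmission = tr("transmission"),
    truth_ccw = tr("ccw"),
    truth_cl = tr("cl", "subject"),
    truth_d_dppl = if (is.null(truth)) NA_real_ else {
      as.numeric(truth$vent$tidal_volume) / tr("ccw")
    }
  )
}

#' Apply the study's exclusion cascade
#'
#' Validity filtering in cascade order. (1) Conditions whose occlusion-test
#' `d-Ppl/dPaw` ratio falls outside the validity band indicate a failed
#' airway-pressure or pleural-catheter measurement and are removed from
#' every comparison. (2) Among the remainder, an out-of-band `dPes/dPaw`
#' ratio removes the condition from the esophageal comparisons. (3) A CVP
#' measurement failure or occlusion-test failure removes it from the
#' CVP-derived comparisons.
#'
#' @param conditions tibble of processed conditions (see
#'   [process_record()]); must carry `valid_dppl`, `valid_pes`, `ot_failed`,
#'   `cvp_failed`.
#' @return list with `sets` (tibbles `pes_vs_dppl`, `cdcvp_vs_dppl`,
#'   `pes_vs_cdcvp`), `accounting` (exclusion counts per cause, in cascade
#'   order) and `n_total`.
#' @export
apply_exclusions <- function(conditions) {
  stopifnot(all(c("valid_dppl", "valid_pes", "ot_failed", "cvp_failed") %in%
                  names(conditions)))
  n_total <- nrow(conditions)
  ok_dppl <- conditions$valid_dppl %in% TRUE
  stage1 <- conditions[ok_dppl, , drop = FALSE]
  pes_ok <- stage1$valid_pes %in% TRUE
  cvp_ok <- !(stage1$ot_failed %in% TRUE) & !(stage1$cvp_failed %in% TRUE)
  sets <- list(
    pes_vs_dppl = stage1[pes_ok, , drop = FALSE],
    cdcvp_vs_dppl = stage1[cvp_ok, , drop = FALSE],
    pes_vs_cdcvp = stage1[pes_ok & cvp_ok, , drop = FALSE]
  )
  accounting <- tibble::tibble(
    cause = c("dppl_paw_failure", "pes_ratio_out_of_band", "cvp_failure"),
    stage = 1:3,
    n_excluded = c(sum(!ok_dppl), sum(!pes_ok), sum(!cvp_ok)),
    removed_from = c("all comparisons", "esophageal comparisons",
                     "CVP-derived comparisons")
  )
  list(sets = sets, accounting = accounting, n_total = n_total)
}
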