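## Synthetic cardio-respiratory waveform generator.
##
## Single-compartment respiratory mechanics under volume-controlled
## ventilation: constant inspiratory flow, passive expiration with time
## constant R*Crs, 1/Crs = 1/CL + 1/Ccw. At zero flow paw = PEEP + V/Crs;
## the pleural swing is V/Ccw; the esophageal channel sees a fixed fraction
## of it (balloon transmission) and the CVP channel a condition-specific
## fraction T (the quantity the occlusion-test calibration inverts), plus a
## cardiac sinusoid and white measurement noise.

FLOW_QUIESCENT <- 0.005 # L/s; expiratory flow below this counts as zero flow

crs_of <- function(subject, cond) {
  crs <- 1 / (1 / subject$cl + 1 / cond$ccw)
  if (!is.finite(crs) || crs <= 0) {
    stop("non-physical mechanics: Crs must be positive", call. = FALSE)
  }
  crs
}

## Segment builders return list(paw, flow, volume, swing) where swing is the
## pleural excursion above its end-expiratory value (V/Ccw during
## ventilation, the squeeze profile during an occlusion test).
seg_const <- function(n, paw, volume, swing, ot = FALSE) {
  list(paw = rep(paw, n), flow = rep(0, n), volume = rep(volume, n),
       swing = rep(swing, n), ot = rep(ot, n))
}

build_breath <- function(vent, crs, ccw, resistance, insp_hold = 0) {
  rate <- vent$sample_rate
  dt <- 1 / rate
  cycle <- 60 / vent$resp_rate
  ti <- vent$insp_frac * cycle
  te <- cycle - ti
  tv <- vent$tidal_volume
  n_i <- round(ti * rate)
  n_e <- round(te * rate)
  tau <- resistance * crs / 1000 # s; Crs converted to L/cmH2O

  t_i <- (seq_len(n_i) - 1) * dt
  flow_i <- tv / 1000 / ti # L/s
  v_i <- tv * t_i / ti
  insp <- list(
    paw = vent$peep + v_i / crs + resistance * flow_i,
    flow = rep(flow_i, n_i), volume = v_i, swing = v_i / ccw,
    ot = rep(FALSE, n_i)
  )

  hold <- NULL
  if (insp_hold > 0) {
    hold <- seg_const(round(insp_hold * rate), vent$peep + tv / crs, tv,
                      tv / ccw)
  }

  ## Normalized exponential so volume reaches exactly zero at end-expiration
  ## (the truncated remainder, < 1e-4 of TV at default time constants, is
  ## folded into the profile rather than left trapped).
  t_e <- (seq_len(n_e) - 1) * dt
  E <- exp(-te / tau)
  v_e <- tv * (exp(-t_e / tau) - E) / (1 - E)
  flow_e <- -(tv / 1000) / tau * exp(-t_e / tau) / (1 - E)
  exp_seg <- list(
    paw = vent$peep + v_e / crs + resistance * flow_e,
    flow = flow_e, volume = v_e, swing = v_e / ccw,
    ot = rep(FALSE, n_e)
  )

  ## time within expiration after which |flow| < FLOW_QUIESCENT
  flow0 <- (tv / 1000) / tau / (1 - E)
  t_quiet <- if (flow0 <= FLOW_QUIESCENT) 0 else {
    min(te, tau * log(flow0 / FLOW_QUIESCENT))
  }

  list(insp = insp, hold = hold, expn = exp_seg,
       ti = ti, te = te, t_quiet = t_quiet)
}

build_ot <- function(vent, squeeze_magnitude, baseline_dur, squeeze_dur,
                     ramp_dur = 1, release_dur = 0.5) {
  rate <- vent$sample_rate
  n_b <- round(baseline_dur * rate)
  n_r <- round(ramp_dur * rate)
  n_s <- round(squeeze_dur * rate)
  n_rel <- round(release_dur * rate)
  t_r <- (seq_len(n_r) - 1) / rate
  t_rel <- (seq_len(n_rel) - 1) / rate
  s_ramp <- squeeze_magnitude * (1 - cos(pi * t_r / ramp_dur)) / 2
  s_rel <- squeeze_magnitude * (1 + cos(pi * t_rel / release_dur)) / 2
  swing <- c(rep(0, n_b), s_ramp, rep(squeeze_magnitude, n_s), s_rel)
  dt <- 1 / rate
  ## window ends sit on the last sample inside the phase, so plateau reads
  ## never touch the neighbouring segment
  list(
    seg = list(paw = vent$peep + swing, flow = rep(0, length(swing)),
               volume = rep(0, length(swing)), swing = swing,
               ot = rep(TRUE, length(swing))),
    baseline = c(0, baseline_dur - dt),
    squeeze = c(baseline_dur + ramp_dur,
                baseline_dur + ramp_dur + squeeze_dur - dt)
  )
}

assemble_record <- function(segments, annotations, subject, cond, vent,
                            seed, noise_free) {
  paw <- unlist(lapply(segments, `[[`, "paw"), use.names = FALSE)
  flow <- unlist(lapply(segments, `[[`, "flow"), use.names = FALSE)
  volume <- unlist(lapply(segments, `[[`, "volume"), use.names = FALSE)
  swing <- unlist(lapply(segments, `[[`, "swing"), use.names = FALSE)
  is_ot <- unlist(lapply(segments, `[[`, "ot"), use.names = FALSE)
  n <- length(paw)
  dt <- 1 / vent$sample_rate
  t <- (seq_len(n) - 1) * dt

  ee_ppl <- cond$end_expiratory_ppl
  dppl <- ee_ppl + swing
  pes <- ee_ppl + subject$pes_transmission * swing
  ## the calibration assumption is that pleural-to-CVP transmission is the
  ## same during the occlusion test and ventilation; transmission_drift
  ## deliberately breaks it for sensitivity studies
  drift <- cond$transmission_drift %||% 0
  t_eff <- cond$transmission * (1 + drift * (1 - is_ot))
  cvp <- cond$cvp_baseline + t_eff * swing

  amp <- if (noise_free) 0 else subject$cardiac_amplitude
  nsd <- if (noise_free) c(paw = 0, pes = 0, dppl = 0, cvp = 0) else {
    subject$noise_sd
  }
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    if (amp > 0) {
      cvp <- cvp + amp * sin(2 * pi * subject$cardiac_rate / 60 * t + phase)
    }
    for (ch in c("paw", "pes", "dppl", "cvp")) {
      if (nsd[[ch]] > 0) {
        noise <- rnorm(n, 0, nsd[[ch]])
        if (ch == "paw") paw <- paw + noise
        if (ch == "pes") pes <- pes + noise
        if (ch == "dppl") dppl <- dppl + noise
        if (ch == "cvp") cvp <- cvp + noise
      }
    }
  })

  ann <- do.call(rbind, annotations)
  wf_record(
    time = t,
    channels = data.frame(paw = paw, flow = flow, volume = volume,
                          pes = pes, dppl = dppl, cvp = cvp),
    annotations = ann, sample_rate = vent$sample_rate,
    truth = list(subject = unclass(subject), condition = unclass(cond),
                 vent = unclass(vent), seed = seed)
  )
}

#' Simulate one experimental condition
#'
#' Generates an annotated waveform record for one subject under one
#' condition: an occlusion test (optional), a run of ordinary breaths, an
#' expiratory hold and an inspiratory hold, following the recording protocol
#' of the calibration experiment. Identical inputs and seed give a
#' bit-identical record.
#'
#' @param subject a [subject_params()].
#' @param cond a [condition_spec()].
#' @param vent a [vent_settings()].
#' @param n_breaths number of ordinary breaths before the holds (>= 3).
#' @param seed integer seed (required; reproducibility contract).
#' @param include_ot prepend an occlusion-test segment.
#' @param noise_free disable cardiac oscillation and measurement noise.
#' @param squeeze_magnitude occlusion-test chest-squeeze size (cmH2O).
#' @param hold_dur duration of the inspiratory/expiratory holds (s).
#' @param ot_baseline_dur,ot_squeeze_dur occlusion-test window durations (s).
#' @return a [wf_record()] with `exp_hold`, `insp_hold`, `breath_start` and
#'   (if requested) `ot_baseline`/`ot_squeeze` annotations and a ground
#'   truth snapshot.
#' @export
#' @examples
#' rec <- simulate_condition(subject_params(cl = 25),
#'                           condition_spec(ccw = 100),
#'                           vent_settings(tidal_volume = 300),
#'                           seed = 1, noise_free = TRUE)
#' rec
simulate_condition <- function(subject, cond, vent, n_breaths = 5, seed,
                               include_ot = TRUE, noise_free = FALSE,
                               squeeze_magnitude = 10, hold_dur = 3,
                               ot_baseline_dur = 3, ot_squeeze_dur = 2) {
  stopifnot(inherits(subject, "subject_params"),
            inherits(cond, "condition_spec"),
            inherits(vent, "vent_settings"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_breaths < 3) stop("`n_breaths` must be >= 3", call. = FALSE)
  if (squeeze_magnitude <= 0) {
    stop("`squeeze_magnitude` must be positive", call. = FALSE)
  }
  crs <- crs_of(subject, cond)
  rate <- vent$sample_rate
  dt <- 1 / rate

  segments <- list()
  annotations <- list()
  t_at <- 0
  push <- function(seg) {
    segments[[length(segments) + 1L]] <<- seg
    t_at <<- t_at + length(seg$paw) * dt
  }
  annotate <- function(label, t_start, t_end) {
    annotations[[length(annotations) + 1L]] <<-
      data.frame(label = label, t_start = t_start, t_end = t_end)
  }

  if (include_ot) {
    ot <- build_ot(vent, squeeze_magnitude, ot_baseline_dur, ot_squeeze_dur)
    annotate("ot_baseline", t_at + ot$baseline[1], t_at + ot$baseline[2])
    annotate("ot_squeeze", t_at + ot$squeeze[1], t_at + ot$squeeze[2])
    push(ot$seg)
  }

  breath <- build_breath(vent, crs, cond$ccw, subject$airway_resistance)
  for (b in seq_len(n_breaths)) {
    annotate("breath_start", t_at, t_at)
    push(breath$insp)
    exp_start <- t_at
    push(breath$expn)
    if (b == n_breaths) {
      ## expiratory hold appended at end-expiration; the annotation spans
      ## the whole zero-flow quiescent interval (tail of the passive
      ## expiration plus the hold itself)
      annotate("exp_hold", exp_start + breath$t_quiet, t_at + hold_dur - dt)
      push(seg_const(round(hold_dur * rate), vent$peep, 0, 0))
    }
  }

  withhold <- build_breath(vent, crs, cond$ccw, subject$airway_resistance,
                           insp_hold = hold_dur)
  annotate("breath_start", t_at, t_at)
  push(withhold$insp)
  annotate("insp_hold", t_at, t_at + hold_dur - dt)
  push(withhold$hold)
  push(withhold$expn)

  assemble_record(segments, annotations, subject, cond, vent, seed,
                  noise_free)
}

#' Simulate a stand-alone occlusion test
#'
#' Airway closed at end-expiration, then a smooth chest squeeze raising
#' pleural pressure by `squeeze_magnitude`. With no gas flow the airway
#' pressure change equals the pleural pressure change exactly; the CVP
#' change is the transmitted fraction, so the calibration ratio recovered
#' downstream is `1/transmission`.
#'
#' @inheritParams simulate_condition
#' @param baseline_dur,squeeze_dur window durations (s).
#' @return a [wf_record()] with `ot_baseline` and `ot_squeeze` annotations.
#' @export
simulate_occlusion_test <- function(subject, cond, vent,
                                    squeeze_magnitude = 10, seed,
                                    noise_free = FALSE, baseline_dur = 3,
                                    squeeze_dur = 2) {
  stopifnot(inherits(subject, "subject_params"),
            inherits(cond, "condition_spec"),
            inherits(vent, "vent_settings"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (squeeze_magnitude <= 0) {
    stop("`squeeze_magnitude` must be positive", call. = FALSE)
  }
  crs_of(subject, cond) # parameter validation
  ot <- build_ot(vent, squeeze_magnitude, baseline_dur, squeeze_dur)
  annotations <- list(
    data.frame(label = "ot_baseline", t_start = ot$baseline[1],
               t_end = ot$baseline[2]),
    data.frame(label = "ot_squeeze", t_start = ot$squeeze[1],
               t_end = ot$squeeze[2])
  )
  assemble_record(list(ot$seg), annotations, subject, cond, vent, seed,
                  noise_free)
}
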