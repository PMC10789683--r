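## Shared fixtures: small noise-free building blocks used across tests.

quiet_subject <- function(cl = 25, ...) {
  subject_params(cl = cl, noise_sd = c(paw = 0, pes = 0, dppl = 0, cvp = 0),
                 cardiac_amplitude = 0, ...)
}

toy_vent <- function(tv = 300, ...) vent_settings(tidal_volume = tv, ...)

toy_condition <- function(ccw = 100, transmission = 0.5,
                          cvp_baseline = 16, ...) {
  condition_spec(ccw = ccw, transmission = transmission,
                 cvp_baseline = cvp_baseline, ...)
}

## noise-free condition record with known closed-form mechanics
toy_record <- function(seed = 1, include_ot = TRUE, ...) {
  simulate_condition(quiet_subject(), toy_condition(), toy_vent(),
                     seed = seed, noise_free = TRUE,
                     include_ot = include_ot, ...)
}

hold_window <- function(record, label) {
  h <- detect_holds(record)
  h[h$label == label, , drop = FALSE][1, ]
}

read_holdset <- function(record, label,
                         channels = c("paw", "pes", "dppl", "cvp")) {
  w <- hold_window(record, label)
  out <- lapply(channels, function(ch) plateau(record, w, ch))
  names(out) <- channels
  out
}

## zero-variance priors centred so every condition passes all filters
deterministic_priors <- function() {
  p <- default_priors(noise_sd = c(paw = 0, pes = 0, dppl = 0, cvp = 0))
  strip <- function(x) {
    if (is.numeric(x) && all(c("mean", "sd") %in% names(x))) {
      x[["sd"]] <- 0
      x
    } else if (is.list(x)) lapply(x, strip) else x
  }
  strip(p)
}

## 60-condition validity-flag fixture with the study's failure pattern:
## 5 pleural/airway measurement failures, 14 out-of-band esophageal ratios
## (one of them on a record that already failed the pleural check), and
## 2 CVP measurement failures on otherwise clean records.
exclusion_fixture <- function() {
  n <- 60
  tibble::tibble(
    record = seq_len(n),
    valid_dppl = !(seq_len(n) %in% 1:5),
    valid_pes = !(seq_len(n) %in% 5:18),
    ot_failed = FALSE,
    cvp_failed = seq_len(n) %in% 19:20
  )
}
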