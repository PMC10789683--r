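## Waveform records: the multichannel container passed between modules, its
## CSV + sidecar-JSON serialization, hold-window handling and plateau reads.

WF_CHANNELS <- c("paw", "flow", "volume", "pes", "dppl", "cvp")
HOLD_LABELS <- c("exp_hold", "insp_hold", "ot_baseline", "ot_squeeze")

default_units <- function() {
  c(time = "s", paw = "cmH2O", flow = "L/s", volume = "mL",
    pes = "cmH2O", dppl = "cmH2O", cvp = "cmH2O")
}

#' Construct a waveform record
#'
#' A uniformly sampled multichannel recording of airway pressure, flow,
#' volume, esophageal pressure, directly measured pleural pressure and CVP,
#' together with event annotations (holds, occlusion-test windows, breath
#' starts) and, for simulated data, a ground-truth parameter snapshot.
#'
#' @param time numeric vector of sample times (s), uniform grid.
#' @param channels data frame with columns `paw`, `flow`, `volume`, `pes`,
#'   `dppl`, `cvp`, same number of rows as `time`.
#' @param annotations data frame with columns `label`, `t_start`, `t_end`.
#' @param sample_rate sampling rate (Hz).
#' @param units named character vector of channel units.
#' @param truth optional list of ground-truth parameters (simulated records).
#' @return an object of class `wf_record`.
#' @export
wf_record <- function(time, channels, annotations = NULL,
                      sample_rate = NULL, units = default_units(),
                      truth = NULL) {
  channels <- as.data.frame(channels)
  missing_ch <- setdiff(WF_CHANNELS, names(channels))
  if (length(missing_ch)) {
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  channels <- channels[WF_CHANNELS]
  if (nrow(channels) != length(time)) {
    stop("channels and time grid have different lengths", call. = FALSE)
  }
  if (length(time) >= 3) {
    dts <- diff(time)
    if (diff(range(dts)) > 1e-9 * max(dts)) {
      stop("time grid is not uniform", call. = FALSE)
    }
  }
  if (is.null(sample_rate)) sample_rate <- 1 / mean(diff(time))
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(), t_start = numeric(),
                              t_end = numeric())
  }
  annotations <- as.data.frame(annotations)[c("label", "t_start", "t_end")]
  if (nrow(annotations)) {
    lo <- min(time) - 1e-9
    hi <- max(time) + 1e-9
    if (any(annotations$t_start < lo) || any(annotations$t_end > hi) ||
        any(annotations$t_end < annotations$t_start)) {
      stop("annotations must lie within the record", call. = FALSE)
    }
  }
  structure(
    list(time = as.numeric(time), channels = channels,
         annotations = annotations, sample_rate = sample_rate,
         units = units, truth = truth),
    class = "wf_record"
  )
}

#' @export
print.wf_record <- function(x, ...) {
  cat(sprintf(
    "<wf_record> %.1f s @ %g Hz, %d samples, %d annotations%s\n",
    diff(range(x$time)), x$sample_rate, length(x$time),
    nrow(x$annotations), if (!is.null(x$truth)) ", with ground truth" else ""
  ))
  if (nrow(x$annotations)) {
    print(utils::head(x$annotations, 10))
  }
  invisible(x)
}

#' Write a waveform record to CSV plus sidecar JSON
#'
#' Channels go to `<path>.csv` (full-precision, round-trip exact);
#' annotations, units, sampling rate, and any ground-truth snapshot go to
#' `<path>.json`.
#'
#' @param record a [wf_record()].
#' @param path file path stem (without extension).
#' @return the path stem, invisibly.
#' @seealso [read_record()]
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "wf_record"))
  path <- sub("\\.csv$", "", path)
  df <- cbind(time = record$time, record$channels)
  ## 17 significant digits guarantee the decimal text parses back to the
  ## identical double (bit-exact round trip)
  cols <- lapply(df, function(x) sub("^\\s+", "", sprintf("%.17g", x)))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, paste0(path, ".csv"))
  side <- list(
    sample_rate = record$sample_rate,
    units = as.list(record$units),
    annotations = record$annotations,
    truth = record$truth
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a waveform record written by [write_record()]
#'
#' Validates the schema (required channels, uniform time grid) and converts
#' any pressure channel declared in mmHg to cmH2O (factor 1.36).
#'
#' @param path file path stem (with or without `.csv`).
#' @return a [wf_record()].
#' @export
read_record <- function(path) {
  path <- sub("\\.csv$", "", path)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  if (!file.exists(csv)) stop("no such file: ", csv, call. = FALSE)
  ## base read.csv parses doubles via strtod, preserving the bit-exact
  ## round trip of the 17-digit representation
  df <- utils::read.csv(csv)
  missing_ch <- setdiff(c("time", WF_CHANNELS), names(df))
  if (length(missing_ch)) {
    stop("schema error: missing column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  side <- if (file.exists(json)) {
    jsonlite::read_json(json, simplifyVector = TRUE)
  } else {
    list()
  }
  units <- default_units()
  if (!is.null(side$units)) units[names(side$units)] <- unlist(side$units)
  for (ch in c("paw", "pes", "dppl", "cvp")) {
    u <- units[[ch]]
    if (identical(u, "mmHg")) {
      df[[ch]] <- mmHg_to_cmH2O(df[[ch]])
      units[[ch]] <- "cmH2O"
    } else if (!identical(u, "cmH2O")) {
      stop("schema error: channel `", ch, "` has unsupported unit `", u, "`",
           call. = FALSE)
    }
  }
  ann <- side$annotations
  if (is.null(ann) || !length(ann)) ann <- NULL
  wf_record(
    time = df$time, channels = df[WF_CHANNELS], annotations = ann,
    sample_rate = if (!is.null(side$sample_rate)) side$sample_rate else NULL,
    units = units, truth = side$truth
  )
}

#' Locate hold and occlusion-test windows
#'
#' Annotation-first policy: when the record carries hold annotations these
#' are returned as-is (the experimental events are known). Detection from
#' the flow signal -- maximal intervals with `|flow| < flow_eps` lasting at
#' least `min_dur`, labelled inspiratory/expiratory by the lung volume level
#' during the interval -- is a fallback for unannotated data, or can be
#' forced with `force_detect = TRUE`.
#'
#' @param record a [wf_record()].
#' @param flow_eps zero-flow threshold (L/s).
#' @param min_dur minimum window duration (s). The default is chosen to
#'   exceed the quiescent tail of an ordinary passive expiration.
#' @param force_detect ignore annotations and detect from flow.
#' @return a data frame of windows: `label`, `t_start`, `t_end`, `source`.
#' @export
detect_holds <- function(record, flow_eps = 0.005, min_dur = 1.5,
                         force_detect = FALSE) {
  stopifnot(inherits(record, "wf_record"))
  ann <- record$annotations
  ann <- ann[ann$label %in% HOLD_LABELS, , drop = FALSE]
  if (nrow(ann) && !force_detect) {
    ann$source <- "annotation"
    rownames(ann) <- NULL
    return(ann)
  }
  flow <- record$channels$flow
  vol <- record$channels$volume
  t <- record$time
  quiet <- abs(flow) < flow_eps
  if (!any(quiet)) {
    return(data.frame(label = character(), t_start = numeric(),
                      t_end = numeric(), source = character()))
  }
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (t[ends] - t[starts]) >= min_dur
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(label = character(), t_start = numeric(),
                      t_end = numeric(), source = character()))
  }
  vmid <- (max(vol) + min(vol)) / 2
  label <- vapply(seq_along(starts), function(i) {
    if (mean(vol[starts[i]:ends[i]]) > vmid) "insp_hold" else "exp_hold"
  }, character(1))
  data.frame(label = label, t_start = t[starts], t_end = t[ends],
             source = "detected")
}

window_samples <- function(record, window) {
  idx <- which(record$time >= window$t_start - 1e-9 &
                 record$time <= window$t_end + 1e-9)
  if (length(idx) < 2) {
    stop("window contains fewer than 2 samples", call. = FALSE)
  }
  idx
}

#' Read a plateau value from a hold window
#'
#' For `paw`, `pes`, `dppl` and `volume` the plateau is the mean over the
#' last `avg_frac` of the window (the early part is skipped to let
#' post-occlusion equilibration settle). For `cvp` the cardiac oscillation
#' is removed by averaging over the largest whole number of cardiac cycles
#' that fit in that sub-window; the cycle length is estimated from the
#' autocorrelation peak of the full window in the `lag_band` lag range. If
#' the sub-window is shorter than one estimated cycle the function falls
#' back to a plain mean with a degraded-precision warning.
#'
#' @param record a [wf_record()].
#' @param window one row of a window table (list or data frame row with
#'   `t_start`, `t_end`), e.g. from [detect_holds()].
#' @param channel channel name.
#' @param avg_frac fraction of the window (taken from its end) used for
#'   averaging.
#' @param lag_band autocorrelation search band for the cardiac cycle (s).
#' @return an object of class `plateau_reading`: a list with `channel`,
#'   `value`, `n` (effective number of averaged samples), `n_cycles`
#'   (cardiac cycles averaged; `NA` for non-CVP channels), and the window.
#' @export
plateau <- function(record, window, channel, avg_frac = 0.5,
                    lag_band = c(0.4, 2)) {
  stopifnot(inherits(record, "wf_record"),
            channel %in% c(WF_CHANNELS, "time"))
  idx <- window_samples(record, window)
  x <- record$channels[[channel]][idx]
  dt <- 1 / record$sample_rate
  dur <- (length(x) - 1) * dt
  sub_span <- avg_frac * dur
  n_sub <- max(2L, as.integer(round(sub_span / dt)) + 1L)
  sub <- tail(x, n_sub)
  reading <- function(value, n, n_cycles) {
    structure(
      list(channel = channel, value = value, n = n, n_cycles = n_cycles,
           window = as.list(window)[c("label", "t_start", "t_end")]),
      class = "plateau_reading"
    )
  }
  if (!identical(channel, "cvp")) {
    return(reading(mean(sub), length(sub), NA_real_))
  }
  lag_band[2] <- min(lag_band[2], dur / 2)
  cycle <- estimate_cycle(x, dt, lag_band)
  if (is.na(cycle) || cycle <= 0) {
    ## no periodic component found -- plain mean is unbiased then anyway
    return(reading(mean(sub), length(sub), 0))
  }
  refined <- prony_refine(x, dt, cycle)
  if (!is.na(refined)) cycle <- refined
  n_cyc <- floor(((n_sub - 1) * dt) / cycle)
  if (n_cyc < 1) {
    warning("window shorter than one cardiac cycle; ",
            "falling back to plain mean (degraded precision)",
            call. = FALSE)
    return(reading(mean(sub), length(sub), 0))
  }
  ## fitted-constant read: regress the whole-cycle span on
  ## {1, sin, cos} at the cardiac frequency; over whole cycles the
  ## harmonic terms are orthogonal to the constant, so this equals the
  ## cycle mean, while absorbing any partial-cycle leakage exactly
  span <- n_cyc * cycle
  tsub <- (seq_along(sub) - 1) * dt
  keep <- tsub >= (max(tsub) - span - 1e-9)
  ts <- tsub[keep]
  xs <- sub[keep]
  w <- 2 * pi / cycle
  X <- cbind(1, sin(w * ts), cos(w * ts))
  beta <- tryCatch(solve(crossprod(X), crossprod(X, xs)),
                   error = function(e) NULL)
  value <- if (is.null(beta)) mean(xs) else beta[1]
  reading(value, length(xs), n_cyc)
}

#' @export
print.plateau_reading <- function(x, ...) {
  cat(sprintf("<plateau_reading> %s = %.4g (%s window, n = %d%s)\n",
              x$channel, x$value, x$window$label, x$n,
              if (!is.na(x$n_cycles)) {
                sprintf(", %g cardiac cycles", x$n_cycles)
              } else ""))
  invisible(x)
}
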