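test_that("write/read round-trips a record bit-exactly", {
  rec <- simulate_condition(subject_params(cl = 25), toy_condition(),
                            toy_vent(), seed = 8)
  path <- file.path(withr::local_tempdir(), "rec")
  write_record(rec, path)
  back <- read_record(path)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$annotations$label, rec$annotations$label)
  expect_equal(back$annotations$t_start, rec$annotations$t_start)
  expect_equal(back$sample_rate, rec$sample_rate)
})

test_that("schema violations are rejected with the offending field named", {
  rec <- toy_record(include_ot = FALSE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec")
  write_record(rec, path)
  df <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  readr::write_csv(df[setdiff(names(df), "cvp")], paste0(path, ".csv"))
  expect_error(read_record(path), "cvp")
  ## non-uniform time grid
  df2 <- df
  df2$time[5] <- df2$time[5] + 0.004
  readr::write_csv(df2, paste0(path, ".csv"))
  expect_error(read_record(path), "uniform")
})

test_that("a CVP channel declared in mmHg is converted on read", {
  rec <- toy_record(include_ot = FALSE)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec")
  rec$units[["cvp"]] <- "mmHg"
  write_record(rec, path)
  back <- read_record(path)
  ## hand conversion of sample points: 1 mmHg = 1.36 cmH2O
  for (i in c(1, 100, 500)) {
    expect_equal(back$channels$cvp[i], rec$channels$cvp[i] * 1.36)
  }
  expect_equal(back$units[["cvp"]], "cmH2O")
})

test_that("hold detection agrees with the simulator annotations", {
  ## property: over seeded noise-free records the detected zero-flow
  ## windows match the annotated holds with midpoints within 0.1 s
  for (seed in 1:100) {
    rec <- simulate_condition(
      quiet_subject(cl = runif(1, 15, 40)),
      toy_condition(ccw = runif(1, 30, 120)),
      toy_vent(tv = runif(1, 250, 400)),
      seed = seed, noise_free = TRUE, include_ot = FALSE)
    ann <- rec$annotations[rec$annotations$label %in%
                             c("exp_hold", "insp_hold"), ]
    det <- detect_holds(rec, force_detect = TRUE)
    expect_equal(nrow(det), 2)
    ann <- ann[order(ann$t_start), ]
    det <- det[order(det$t_start), ]
    expect_equal(det$label, ann$label)
    mid_a <- (ann$t_start + ann$t_end) / 2
    mid_d <- (det$t_start + det$t_end) / 2
    expect_lt(max(abs(mid_a - mid_d)), 0.1)
  }
})

test_that("detection edge cases behave", {
  rec <- simulate_condition(subject_params(cl = 25), toy_condition(),
                            toy_vent(), seed = 2, include_ot = FALSE)
  ## a zero threshold on a noisy record finds nothing
  expect_equal(nrow(detect_holds(rec, flow_eps = 0, force_detect = TRUE)), 0)
  ## one long apnea is a single window
  n <- 500
  apnea <- wf_record(
    time = seq(0, by = 0.01, length.out = n),
    channels = data.frame(paw = rep(6, n), flow = 0, volume = 0,
                          pes = 3, dppl = 3, cvp = 16))
  expect_equal(nrow(detect_holds(apnea)), 1)
  ## annotations take precedence over detection
  byann <- detect_holds(rec)
  expect_true(all(byann$source == "annotation"))
})

test_that("plateau reads constants exactly and removes cardiac oscillation", {
  n <- 301
  t <- seq(0, 3, length.out = n)
  const <- wf_record(
    time = t,
    channels = data.frame(paw = rep(6, n), flow = 0, volume = 0,
                          pes = 3, dppl = 3, cvp = 16))
  w <- list(label = "exp_hold", t_start = 0, t_end = 3)
  expect_equal(plateau(const, w, "paw")$value, 6)
  ## cvp = 12 + 2 sin(2*pi*1.3*t): cycle-averaged mean within 0.05 of 12
  osc <- const
  osc$channels$cvp <- 12 + 2 * sin(2 * pi * 1.3 * t)
  r <- plateau(osc, w, "cvp")
  expect_equal(r$value, 12, tolerance = 0.05)
  expect_gte(r$n_cycles, 1)
})

test_that("cvp plateau is invariant to adding whole cardiac cycles to the window", {
  f <- 80 / 60
  cycle <- 1 / f
  dt <- 0.01
  base <- function(dur) {
    n <- round(dur / dt) + 1
    t <- (0:(n - 1)) * dt
    wf_record(time = t,
              channels = data.frame(paw = 6, flow = 0, volume = 0, pes = 3,
                                    dppl = 3,
                                    cvp = 16 + 2 * sin(2 * pi * f * t + 0.7)))
  }
  vals <- vapply(0:3, function(k) {
    dur <- 3 + k * cycle
    plateau(base(dur), list(label = "exp_hold", t_start = 0, t_end = dur),
            "cvp", avg_frac = 1)$value
  }, numeric(1))
  expect_lt(diff(range(vals)), 1e-6)
})

test_that("a window shorter than one cardiac cycle degrades with a warning", {
  f <- 1.3
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  rec <- wf_record(time = t,
                   channels = data.frame(paw = 6, flow = 0, volume = 0,
                                         pes = 3, dppl = 3,
                                         cvp = 16 + 2 * sin(2 * pi * f * t)))
  expect_warning(
    plateau(rec, list(label = "exp_hold", t_start = 0, t_end = 2), "cvp",
            avg_frac = 0.3),
    "cardiac cycle")
})
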