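test_that("single-compartment mechanics give the closed-form plateau and pleural swing", {
  ## CL 25, Ccw 100 -> Crs 20; TV 300 -> driving pressure 15, dPpl 3
  rec <- toy_record()
  row <- process_record(rec)
  expect_equal(row$total_peep, 6)
  expect_equal(row$plateau_paw - row$total_peep, 15)
  expect_equal(row$d_dppl, 3)
  ## linear transmission T = 0.5: tidal dCVP = 1.5
  expect_equal(row$d_cvp, 1.5)
})

test_that("occlusion identity holds exactly at zero flow", {
  rec <- simulate_occlusion_test(quiet_subject(), toy_condition(),
                                 toy_vent(), seed = 3, noise_free = TRUE)
  sq <- hold_window(rec, "ot_squeeze")
  bl <- hold_window(rec, "ot_baseline")
  idx <- function(w) which(rec$time >= w$t_start & rec$time <= w$t_end)
  d_paw <- rec$channels$paw[idx(sq)] - mean(rec$channels$paw[idx(bl)])
  d_dppl <- rec$channels$dppl[idx(sq)] - mean(rec$channels$dppl[idx(bl)])
  expect_lt(max(abs(d_paw - d_dppl)), 1e-9)
  expect_equal(mean(d_paw), 10, tolerance = 1e-9)
  ## T = 0.5, squeeze 10 -> dCVP = 5, kappa = 2
  cal <- calibrate_ot(read_holdset(rec, "ot_baseline"),
                      read_holdset(rec, "ot_squeeze"))
  expect_equal(cal$d_cvp, 5, tolerance = 1e-9)
  expect_equal(cal$kappa, 2, tolerance = 1e-9)
})

test_that("elastance additivity is readable off the simulated record", {
  for (cl in c(20, 35)) {
    for (ccw in c(37, 89)) {
      rec <- simulate_condition(quiet_subject(cl = cl),
                                toy_condition(ccw = ccw), toy_vent(),
                                seed = 11, noise_free = TRUE)
      row <- process_record(rec)
      expect_lt(abs(1 / row$crs - (1 / cl + 1 / ccw)), 1e-9)
      expect_equal(row$ccw, ccw, tolerance = 1e-9)
      expect_equal(row$cl, cl, tolerance = 1e-9)
    }
  }
})

test_that("expiratory hold reads airway pressure equal to PEEP and volume returns to end-expiration", {
  rec <- toy_record()
  ehold <- hold_window(rec, "exp_hold")
  expect_equal(plateau(rec, ehold, "paw")$value, 6, tolerance = 1e-12)
  ## volume returns exactly to the end-expiratory level at each breath start
  starts <- rec$annotations[rec$annotations$label == "breath_start", ]
  v0 <- rec$channels$volume[vapply(starts$t_start, function(t) {
    which.min(abs(rec$time - t))
  }, integer(1))]
  expect_lt(max(abs(v0)), 1e-6 * 300)
  expect_true(all(rec$channels$volume >= -1e-12))
})

test_that("records contain the required annotated maneuvers", {
  rec <- toy_record()
  labs <- rec$annotations$label
  expect_gte(sum(labs == "exp_hold"), 1)
  expect_gte(sum(labs == "insp_hold"), 1)
  expect_gte(sum(labs == "ot_baseline"), 1)
  expect_gte(sum(labs == "ot_squeeze"), 1)
})

test_that("same seed gives a bit-identical record, different seed differs", {
  s <- subject_params(cl = 25)
  a <- simulate_condition(s, toy_condition(), toy_vent(), seed = 5)
  b <- simulate_condition(s, toy_condition(), toy_vent(), seed = 5)
  c <- simulate_condition(s, toy_condition(), toy_vent(), seed = 6)
  expect_identical(a$channels, b$channels)
  expect_false(identical(a$channels$cvp, c$channels$cvp))
})

test_that("shifting the CVP baseline moves the level but not the swing", {
  reads <- lapply(c(10, 20, 27), function(base) {
    rec <- simulate_condition(quiet_subject(),
                              toy_condition(cvp_baseline = base),
                              toy_vent(), seed = 2, noise_free = TRUE)
    c(insp = plateau(rec, hold_window(rec, "insp_hold"), "cvp")$value,
      exp = plateau(rec, hold_window(rec, "exp_hold"), "cvp")$value)
  })
  levels <- vapply(reads, `[[`, numeric(1), "exp")
  swings <- vapply(reads, function(r) r[["insp"]] - r[["exp"]], numeric(1))
  expect_equal(levels, c(10, 20, 27), tolerance = 1e-9)
  expect_lt(diff(range(swings)), 1e-9)
})

test_that("non-physical parameters are rejected", {
  expect_error(subject_params(cl = -5), "positive")
  expect_error(condition_spec(ccw = 0), "positive")
  expect_error(condition_spec(transmission = 2), "1.5")
  expect_error(vent_settings(tidal_volume = -1), "positive")
  expect_error(vent_settings(tidal_volume = 300, insp_frac = 1), "between")
  expect_error(
    simulate_condition(quiet_subject(), toy_condition(), toy_vent(),
                       n_breaths = 2, seed = 1),
    ">= 3")
  expect_error(
    simulate_occlusion_test(quiet_subject(), toy_condition(), toy_vent(),
                            squeeze_magnitude = 0, seed = 1),
    "positive")
})

test_that("draw_study follows the six-condition protocol deterministically", {
  st1 <- draw_study(3, master_seed = 9, n_breaths = 3)
  st2 <- draw_study(3, master_seed = 9, n_breaths = 3)
  expect_length(st1, 18)
  expect_identical(lapply(st1, `[[`, "channels"),
                   lapply(st2, `[[`, "channels"))
  p <- attr(st1, "params")
  ## protocol order within each subject: low (N, L), normal, high
  expect_equal(p$volume_status[1:6],
               rep(c("low", "normal", "high"), each = 2))
  expect_equal(p$ccw_level[1:6], rep(c("N", "L"), 3))
  ## subject-level parameters persist across the subject's conditions
  per_subj <- tapply(p$cl, p$subject, function(x) diff(range(x)))
  expect_true(all(per_subj == 0))
  expect_error(draw_study(1), ">= 2")
})

test_that("zero-variance priors produce identical subjects", {
  st <- draw_study(3, priors = deterministic_priors(), master_seed = 4,
                   n_breaths = 3)
  p <- attr(st, "params")
  expect_equal(length(unique(p$weight)), 1)
  expect_equal(length(unique(p$transmission)), 1)
  expect_identical(st[[1]]$channels$paw, st[[7]]$channels$paw)
})
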