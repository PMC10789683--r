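test_that("occlusion-test calibration computes kappa and validity ratios", {
  cal <- calibrate_ot(c(paw = 6, cvp = 16, pes = 3, dppl = 3),
                      c(paw = 16, cvp = 21, pes = 12.2, dppl = 13))
  expect_equal(cal$kappa, 2)
  expect_equal(cal$ratio_pes, 0.92)
  expect_true(cal$valid_pes)
  expect_true(cal$valid_dppl)
  expect_false(cal$ot_failed)
  ## balloon ratio just below the band is invalid
  cal2 <- calibrate_ot(c(paw = 0, cvp = 0, pes = 0), c(paw = 10, cvp = 5, pes = 7.9))
  expect_equal(cal2$ratio_pes, 0.79)
  expect_false(cal2$valid_pes)
})

test_that("kappa from a noise-free occlusion test inverts the transmission", {
  for (tr in c(0.3, 0.45, 0.8, 1.2)) {
    ot <- simulate_occlusion_test(quiet_subject(),
                                  toy_condition(transmission = tr),
                                  toy_vent(), seed = 21, noise_free = TRUE)
    cal <- calibrate_ot(read_holdset(ot, "ot_baseline"),
                        read_holdset(ot, "ot_squeeze"))
    expect_equal(cal$kappa, 1 / tr, tolerance = 1e-9)
  }
})

test_that("a vanishing occlusion-test CVP swing is flagged as OT failure", {
  expect_warning(
    cal <- calibrate_ot(c(paw = 6, cvp = 16), c(paw = 16, cvp = 16.3)),
    class = "pplcvp_ot_failure")
  expect_true(cal$ot_failed)
  expect_true(is.na(cal$kappa))
})

test_that("tidal deltas form the corrected estimate est = kappa * dCVP", {
  cal <- suppressWarnings(
    calibrate_ot(c(paw = 0, cvp = 0), c(paw = 11, cvp = 5)))
  cal$kappa <- 2.2 # exact arithmetic check
  ds <- tidal_deltas(c(paw = 21, cvp = 19), c(paw = 6, cvp = 16), cal,
                     tv = 300)
  expect_equal(ds$est_dppl, 2.2 * 3)
  ## zero swing maps to zero estimate
  ds0 <- tidal_deltas(c(paw = 21, cvp = 16), c(paw = 6, cvp = 16), cal,
                      tv = 300)
  expect_equal(ds0$est_dppl, 0)
})

test_that("noise-free end-to-end: corrected estimate equals the direct pleural swing", {
  ## the method's correctness core, across transmissions and mechanics
  for (tr in c(0.35, 0.6, 1.1)) {
    rec <- simulate_condition(quiet_subject(cl = 32),
                              toy_condition(ccw = 55, transmission = tr),
                              toy_vent(tv = 340), seed = 31,
                              noise_free = TRUE)
    row <- process_record(rec)
    expect_lt(abs(row$est_dppl - row$d_dppl), 1e-9)
  }
})

test_that("kappa is scale-invariant: rescaling CVP units cancels in the estimate", {
  rec <- toy_record(seed = 17)
  base <- process_record(rec)
  for (c_scale in c(1 / 1.36, 2, 10)) {
    scaled <- rec
    scaled$channels$cvp <- scaled$channels$cvp * c_scale
    row <- process_record(scaled)
    expect_equal(row$kappa, base$kappa / c_scale, tolerance = 1e-9)
    expect_equal(row$est_dppl, base$est_dppl, tolerance = 1e-9)
  }
})

test_that("compliance partition matches the closed form and is degenerate-safe", {
  cc <- compute_compliances(300, 21, 6, 3)
  expect_equal(cc$crs, 20)
  expect_equal(cc$ccw, 100)
  expect_equal(cc$cl, 25)
  expect_lt(abs(1 / cc$crs - (1 / cc$cl + 1 / cc$ccw)), 1e-12)
  ## pleural swing consuming the whole driving pressure: CL undefined
  cc2 <- compute_compliances(300, 21, 6, 15)
  expect_false(cc2$cl_defined)
  expect_true(is.na(cc2$cl))
  expect_error(compute_compliances(300, 6, 6, 3), "exceed")
  expect_error(compute_compliances(300, 21, 6, -1), "positive")
})

test_that("exclusion boundaries are inclusive", {
  ratios <- c(0.75, 0.8, 0.9, 1.0, 1.2, 1.25)
  tab <- tibble::tibble(
    valid_dppl = ratios >= 0.8 & ratios <= 1.2,
    valid_pes = TRUE, ot_failed = FALSE, cvp_failed = FALSE
  )
  out <- apply_exclusions(tab)
  expect_equal(nrow(out$sets$cdcvp_vs_dppl), 4)
  ## the band check itself is inclusive at both ends
  cal <- calibrate_ot(c(paw = 0, cvp = 0, pes = 0, dppl = 0),
                      c(paw = 10, cvp = 5, pes = 8, dppl = 12))
  expect_true(cal$valid_pes)
  expect_true(cal$valid_dppl)
})

test_that("an all-valid study keeps all 60 conditions in every comparison", {
  tab <- tibble::tibble(valid_dppl = rep(TRUE, 60), valid_pes = TRUE,
                        ot_failed = FALSE, cvp_failed = FALSE)
  out <- apply_exclusions(tab)
  expect_true(all(vapply(out$sets, nrow, integer(1)) == 60))
})

test_that("the engineered failure pattern reproduces the study's comparison sizes", {
  out <- apply_exclusions(exclusion_fixture())
  expect_equal(nrow(out$sets$pes_vs_dppl), 42)
  expect_equal(nrow(out$sets$cdcvp_vs_dppl), 53)
  expect_equal(nrow(out$sets$pes_vs_cdcvp), 40)
  ## accounting conserves records per comparison
  acc <- out$accounting
  expect_equal(out$n_total - acc$n_excluded[acc$cause == "dppl_paw_failure"],
               55)
})
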