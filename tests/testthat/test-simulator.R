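test_that("type constructors enforce their invariants", {
  expect_error(respiratory_system(rrs = 0, crs = 40), "rrs")
  expect_error(respiratory_system(rrs = 10), "bilinear|linear")
  expect_error(respiratory_system(rrs = 10, c_below = 20, c_above = 40), "lip")
  expect_error(respiratory_system(rrs = 10, crs = 40, c_below = 20,
                                  c_above = 40, lip = 10), "not both")
  expect_error(respiratory_system(rrs = 10, crs = 40, aop = -1), "aop")
  expect_error(vent_circuit(ccirc = 0), "ccirc")
  expect_error(vent_settings(insp_flow = 0), "insp_flow")
  expect_error(sim_options(integrator_step = 0.02, fs = 100), "integrator_step")
  expect_error(detection_config(min_pause_s = 0.1), "min_pause_s")
  expect_error(detection_config(closure_threshold = 0), "closure_threshold")
  expect_s3_class(respiratory_system(rrs = 10, crs = 40, aop = 10),
                  "respiratory_system")
})

test_that("simulated insufflation matches the closed-form equation of motion", {
  sys <- respiratory_system(rrs = 10, crs = 40)
  stg <- vent_settings(insp_flow = 60, tidal_volume = 420, peep = 5,
                       pause_s = 0.4)
  # a near-rigid circuit makes the numerical model coincide with the
  # single-compartment closed form
  w <- simulate_breath(sys, vent_circuit(ccirc = 0.01), stg)
  onset <- detect_onset(w)
  cf <- closed_form_linear(sys, stg, t_grid = seq(0, 0.42, by = 0.01))
  # the sample at the onset instant still holds the pre-insufflation
  # pressure; from the next sample on the two solutions must agree
  d <- w$paw[(onset + 1):(onset + 42)] - cf$paw[-1]
  expect_lt(max(abs(d)), 0.05)

  pp <- measure_peak_plateau(w)
  expect_equal(pp$peak, 5 + 10 * 1 + 420 / 40, tolerance = 0.1 / 25.5)
  expect_equal(pp$plateau, 5 + 420 / 40, tolerance = 0.1 / 15.5)
  expect_equal(pp$p_res, 10, tolerance = 0.1 / 10)
})

test_that("closed_form_linear checks its domain and substitutes directly", {
  sys <- respiratory_system(rrs = 10, crs = 40)
  stg <- vent_settings(insp_flow = 60, peep = 5)
  cf <- closed_form_linear(sys, stg, t_grid = c(0, 0.2))
  expect_equal(cf$paw[1], 5 + 10 * 1)            # onset: PEEP + resistive step
  expect_equal(cf$paw[2], 5 + 10 + 200 / 40)     # 0.2 s: + elastic pressure
  expect_error(closed_form_linear(respiratory_system(rrs = 10, c_below = 20,
                                                     c_above = 40, lip = 10),
                                  stg, 0.1), "linear")
  expect_error(closed_form_linear(respiratory_system(rrs = 10, crs = 40,
                                                     aop = 10), stg, 0.1),
               "closure")
  expect_error(closed_form_linear(sys, stg, t_grid = c(0, 1)), "insufflation")
})

test_that("delivered volume is conserved between circuit and lung", {
  sc <- bench_scenario("aop10")
  w <- simulate_breath(sc$system, sc$circuit, vent_settings(peep = 5),
                       sim_options(keep_state = TRUE))
  st <- attr(w, "state")
  onset <- detect_onset(w)
  # over insufflation + occlusion: delivered = circuit-stored + lung
  idx <- onset:(onset + round((0.42 + 0.4) * 100))
  delivered <- pmin(1000 * 1 * (w$t[idx] - w$t[onset]), 420) # 1 L/s up to Vt
  circuit <- sc$circuit$ccirc * (st$paw_clean[idx] - st$paw_clean[onset])
  lung <- st$lung_volume[idx] - st$lung_volume[onset]
  expect_lt(max(abs(delivered - (circuit + lung))), 1)
  # and the volume channel is the trapezoidal integral of flow by definition
  expect_equal(w$volume, 1000 * pracma::cumtrapz(w$t, w$flow)[, 1])
})

test_that("the airway opens at the configured opening pressure", {
  opening_pressure <- function(aop) {
    w <- simulate_breath(
      respiratory_system(rrs = 10, crs = 40, aop = aop),
      vent_circuit(2), vent_settings(peep = 5),
      sim_options(fs = 1000, keep_state = TRUE)
    )
    st <- attr(w, "state")
    onset <- detect_onset(w)
    # last sample before any gas enters the lung: its pressure sits just
    # below the opening threshold (within one 1 kHz sample of the event)
    i <- which(st$lung_volume > st$lung_volume[onset] + 1e-6)[1]
    st$paw_clean[i - 1]
  }
  ps <- vapply(c(8, 10, 12, 14), opening_pressure, numeric(1))
  expect_true(all(abs(ps - c(8, 10, 12, 14)) < 0.5))
  # raising the AOP by 2 raises the transition pressure by 2
  expect_true(all(abs(diff(ps) - 2) < 0.2))
})

test_that("PEEP at or above the AOP reproduces the closure-free waveform", {
  stg <- vent_settings(peep = 12)
  wa <- simulate_breath(respiratory_system(rrs = 10, crs = 40, aop = 10),
                        vent_circuit(), stg)
  wn <- simulate_breath(respiratory_system(rrs = 10, crs = 40),
                        vent_circuit(), stg)
  expect_lt(max(abs(wa$paw - wn$paw)), 0.05)
  expect_false(pcond_method(wa)$closure_detected)
})

test_that("an AOP at or below PEEP is legal and unreachable settings are not", {
  expect_no_error(simulate_breath(respiratory_system(rrs = 10, crs = 40, aop = 4),
                                  settings = vent_settings(peep = 5)))
  expect_error(
    simulate_breath(respiratory_system(rrs = 10, crs = 40),
                    settings = vent_settings(rr = 40, pause_s = 1.2)),
    "unreachable"
  )
})

test_that("the low-flow maneuver shows the circuit-compliance first slope", {
  w <- bench_5("aop10", peep = 5)
  r <- standard_method(w)
  # first slope ~ flow / circuit compliance, second ~ flow / Crs
  expect_equal(r$slope1, (5 / 60) * 1000 / 2, tolerance = 0.1)
  expect_equal(r$slope2, (5 / 60) * 1000 / 40, tolerance = 0.1)
  # break near AOP + Rrs * flow = 10.83
  expect_equal(r$p_break, 10 + 10 * 5 / 60, tolerance = 0.02)
})

test_that("simulated breaths are reproducible from the seed", {
  sc <- bench_scenario("control1")
  w1 <- simulate_breath(sc$system, sc$circuit, vent_settings(peep = 5),
                        sim_options(noise_sd = 0.3, seed = 42))
  w2 <- simulate_breath(sc$system, sc$circuit, vent_settings(peep = 5),
                        sim_options(noise_sd = 0.3, seed = 42))
  expect_identical(w1$paw, w2$paw)
  w3 <- simulate_breath(sc$system, sc$circuit, vent_settings(peep = 5),
                        sim_options(noise_sd = 0.3, seed = 43))
  expect_false(identical(w1$paw, w3$paw))
})
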