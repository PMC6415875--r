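test_that("a chamber at room equilibrium yields zero flux", {
  t <- seq(30, 3600, by = 60)
  inside <- cal_trace(t, rep(400, length(t)))
  room <- cal_trace(t, rep(400, length(t)), location = "room")
  fl <- invert_flux(inside, room, seal_properties("parafilm"),
                    area_fn = 1e-5)
  expect_equal(fl$J_umol_m2_s, rep(0, length(t)))
  expect_equal(fl$membrane_term_umol_m2_s, rep(0, length(t)))
})

test_that("inversion reproduces the simulated flux away from kinks", {
  for (preset in c("parafilm_day10_dark", "micropore_day10_light")) {
    inv <- invert_preset(preset)
    truth <- inv$truth$flux
    J_true <- approx(truth$time_s, truth$J_umol_m2_s,
                     xout = inv$flux$time_s)$y
    err <- abs(inv$flux$J_umol_m2_s - J_true)
    # exclude the two averaged samples around the ramp/exponential kink and
    # the one-sided-difference endpoints
    tp <- inv$scenario[[paste0(inv$scenario$start_phase, "_model")]]$t_peak_s
    interior <- abs(inv$flux$time_s - tp) > 150 &
      inv$flux$time_s > 90 &
      inv$flux$time_s < max(inv$flux$time_s) - 90
    J_max <- max(abs(truth$J_umol_m2_s))
    expect_lt(max(err[interior]) / J_max, 0.01)
  }
})

test_that("membrane correction has the right sign and permeable limit", {
  t <- seq(30, 3600, by = 60)
  # dish pinned at room level but with C_in < C_out: the membrane influx
  # must be attributed to plant uptake (more negative J)
  inside <- cal_trace(t, rep(300, length(t)))
  room <- cal_trace(t, rep(400, length(t)), location = "room")
  fl <- invert_flux(inside, room, seal_properties("parafilm"),
                    area_fn = 1e-5)
  expect_true(all(fl$J_umol_m2_s < 0))

  # near-perfectly permeable seal with C_in = C_out: J -> 0
  big <- seal_properties("parafilm", D_eff_m2s = 1e-4)
  inside2 <- cal_trace(t, rep(400, length(t)))
  fl2 <- invert_flux(inside2, room, big, area_fn = 1e-5)
  expect_equal(fl2$J_umol_m2_s, rep(0, length(t)))
})

test_that("scaling the leaf area divides the flux exactly", {
  inv <- invert_preset("parafilm_day10_dark")
  sc <- inv$scenario
  tr <- averaged_pair(simulate_chamber(sc))
  law <- sc$area_law
  f2 <- invert_flux(tr$inside, tr$room, sc$seal, sc$geometry,
                    area_fn = function(t)
                      3 * leaf_area_at(law, 10 + t / 86400))
  expect_equal(f2$J_umol_m2_s, inv$flux$J_umol_m2_s / 3, tolerance = 1e-12)
})

test_that("unsynchronized or uncalibrated traces are refused", {
  t <- seq(30, 3600, by = 60)
  inside <- cal_trace(t, rep(400, length(t)))
  room_off <- cal_trace(t + 45, rep(400, length(t)), location = "room")
  expect_error(invert_flux(inside, room_off, seal_properties("parafilm"),
                           area_fn = 1e-5), "not synchronized")
  raw <- sensor_trace(t, rep(400, length(t)))
  expect_error(invert_flux(raw, inside, seal_properties("parafilm"),
                           area_fn = 1e-5), "calibrated")
  expect_error(invert_flux(inside, cal_trace(t, rep(400, length(t)),
                                             location = "room"),
                           seal_properties("parafilm"), area_fn = 0),
               "positive")
})

test_that("per-day light/dark means are computed per phase", {
  sched <- light_schedule(t0_phase = "light")
  t <- seq(30, 86400 - 30, by = 60)
  ph <- schedule_phase(sched, t)
  ppm <- ifelse(ph$phase == "light", 380, 420)
  tr <- cal_trace(t, ppm)
  pm <- period_means(tr, sched)
  expect_equal(pm$mean_ppm[pm$phase == "light"], 380)
  expect_equal(pm$mean_ppm[pm$phase == "dark"], 420)

  # constant trace: both means equal
  pm2 <- period_means(cal_trace(t, rep(400, length(t))), sched)
  expect_equal(pm2$mean_ppm, c(400, 400))

  # a trace missing the whole dark phase has no dark row (missing, not 0)
  tl <- cal_trace(t[t < 16 * 3600], rep(400, sum(t < 16 * 3600)))
  pml <- period_means(tl, sched)
  expect_false("dark" %in% pml$phase)

  # sparse phase coverage is flagged
  tsp <- cal_trace(t[t < 2 * 3600], rep(400, sum(t < 2 * 3600)))
  expect_true(period_means(tsp, sched)$flagged)
})

test_that("extreme post-transition rates of change are detected", {
  sched <- light_schedule(t0_phase = "light")
  t <- seq(30, 86400 - 30, by = 60)
  # linear decrease at 6 ppm/min in light, increase 3.7 ppm/min in dark
  ph <- schedule_phase(sched, t)
  ppm <- ifelse(ph$phase == "light", 500 - 6 * ph$t_since_transition_s / 60,
                200 + 3.7 * ph$t_since_transition_s / 60)
  r <- max_rate_of_change(cal_trace(t, ppm), sched)
  expect_equal(r$max_decrease_ppm_min[r$to_phase == "light"], -6,
               tolerance = 1e-9)
  expect_equal(r$max_increase_ppm_min[r$to_phase == "dark"], 3.7,
               tolerance = 1e-6)

  # constant trace: zero rates
  r0 <- max_rate_of_change(cal_trace(t, rep(400, length(t))), sched)
  expect_equal(r0$max_decrease_ppm_min, c(0, 0))
  expect_equal(r0$max_increase_ppm_min, c(0, 0))

  # simulated day-10 Micropore day: uptake spike after light-on would show
  # as a negative extreme; here dark phase shows positive extreme
  inv <- invert_preset("micropore_day10_dark")
  tr <- averaged_pair(simulate_chamber(inv$scenario))$inside
  rd <- max_rate_of_change(tr, light_schedule(t0_phase = "dark"))
  expect_gt(rd$max_increase_ppm_min[1], 0)
})
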