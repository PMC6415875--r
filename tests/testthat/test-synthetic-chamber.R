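test_that("plant flux model ramps to the peak and relaxes exponentially", {
  m <- plant_flux_model("dark", J_max = 8.19, J_ss = 0.86,
                        tau_s = 44 * 60, t_peak_s = 180)
  expect_equal(plant_flux(180, m), 8.19)
  expect_equal(plant_flux(1e9, m), 0.86, tolerance = 1e-12)
  # one time constant past the peak: J_ss + (J_max - J_ss)/e
  expect_equal(plant_flux(180 + 44 * 60, m),
               0.86 + (8.19 - 0.86) / exp(1), tolerance = 1e-12)
  # continuity at the peak and linear ramp before it
  expect_equal(plant_flux(90, m), 8.19 / 2)
  expect_error(plant_flux_model("dark", 8, 1, tau_s = 0, t_peak_s = 10),
               "tau")
  # sign conventions enforced per phase
  expect_error(plant_flux_model("light", J_max = 5, J_ss = 1,
                                tau_s = 10, t_peak_s = 1), "uptake")
  expect_error(plant_flux_model("dark", J_max = 1, J_ss = 5,
                                tau_s = 10, t_peak_s = 1), "release")
})

test_that("chamber at equilibrium with no plants stays constant", {
  sc <- chamber_scenario(start_phase = "light", duration_s = 3600,
                         C0_ppm = 400, room_ppm = 400, noise_sd_ppm = 0,
                         seed = 1)
  sim <- simulate_chamber(sc)
  expect_equal(diff(range(sim$truth$co2_ppm)), 0, tolerance = 1e-9)
})

test_that("empty-dish relaxation follows the closed-form exponential", {
  sc <- chamber_scenario(seal = seal_properties("parafilm"),
                         start_phase = "light", duration_s = 6 * 3600,
                         C0_ppm = 600, room_ppm = 400, noise_sd_ppm = 0,
                         seed = 1)
  sim <- simulate_chamber(sc)
  tau <- with(sc, geometry$volume_m3 * seal$thickness_m /
                (seal$D_eff_m2s * geometry$seal_area_m2))
  expect_equal(tau, 1.28975e4, tolerance = 1e-3)
  expected <- 400 + 200 * exp(-sim$truth$time_s / tau)
  # explicit Euler at 1 s vs closed form: relative deviation ~ dt/(2 tau)
  expect_lt(max(abs(sim$truth$co2_ppm - expected)) / 200, 1e-3)
})

test_that("chamber deviation is linear in the initial displacement", {
  mk <- function(c0) {
    sc <- chamber_scenario(start_phase = "light", duration_s = 3600,
                           C0_ppm = c0, room_ppm = 400, noise_sd_ppm = 0,
                           seed = 1)
    simulate_chamber(sc)$truth$co2_ppm - 400
  }
  expect_equal(mk(800), 2 * mk(600), tolerance = 1e-9)
})

test_that("simulated traces conserve mass when noise is off", {
  sc <- chamber_preset("parafilm_day10_dark", seed = 1, noise_sd_ppm = 0)
  sim <- simulate_chamber(sc)
  tr <- sim$truth
  g <- sc$seal$permeability_m_s * sc$geometry$seal_area_m2
  C <- ppm_to_molar(tr$co2_ppm, sc$T_K, sc$P_Pa)
  Cr <- ppm_to_molar(tr$room_ppm, sc$T_K, sc$P_Pa)
  # V * dC = sum over steps of (J A + g (C_room - C)) dt  (Euler quadrature)
  n <- length(C)
  influx <- sum(tr$flux$J_umol_m2_s[-n] * 1e-6 * tr$area_m2[-n] +
                  g * (Cr[-n] - C[-n])) * sc$dt_s
  expect_equal(sc$geometry$volume_m3 * (C[n] - C[1]), influx,
               tolerance = 1e-9)
})

test_that("identical scenario and seed reproduce traces exactly", {
  a <- simulate_chamber(chamber_preset("micropore_day10_dark", seed = 9))
  b <- simulate_chamber(chamber_preset("micropore_day10_dark", seed = 9))
  expect_identical(a$inside$co2_ppm, b$inside$co2_ppm)
  c <- simulate_chamber(chamber_preset("micropore_day10_dark", seed = 10))
  expect_false(identical(a$inside$co2_ppm, c$inside$co2_ppm))
})

test_that("unstable integration steps are refused", {
  expect_error(
    simulate_chamber(chamber_scenario(seal = seal_properties("micropore"),
                                      duration_s = 600, dt_s = 60,
                                      seed = 1)),
    "unstable")
})

test_that("box-decay simulation matches its closed form", {
  geo <- dish_geometry()
  perm <- 1.0e-9 / 46.9e-6  # Parafilm permeability
  bd <- simulate_box_decay(perm, geo, box_ppm = 3000, C0_ppm = 400,
                           duration_s = 7200, noise_sd_ppm = 0, seed = 1)
  tau <- geo$volume_m3 / (perm * geo$seal_area_m2)
  expected <- 3000 - 2600 * exp(-bd$truth$time_s / tau)
  expect_lt(max(abs(bd$inside$co2_ppm - expected)) / 2600, 1e-9)

  # impermeable seal: constant inside trace
  bd0 <- simulate_box_decay(0, geo, duration_s = 600, noise_sd_ppm = 0)
  expect_equal(diff(range(bd0$inside$co2_ppm)), 0)

  # long-time limit: inside approaches the box level
  bdl <- simulate_box_decay(8e-8 / 67.9e-6, geo, box_ppm = 3000,
                            duration_s = 20 * 233, noise_sd_ppm = 0)
  expect_equal(tail(bdl$inside$co2_ppm, 1), 3000, tolerance = 1e-6)
})
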