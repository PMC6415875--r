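# shared fixtures built in code

# a calibrated trace from plain vectors
cal_trace <- function(time_s, ppm, location = "inside", id = "t") {
  sensor_trace(time_s, ppm, sensor_id = id, location = location,
               calibrated = TRUE)
}

# noiseless averaged + calibrated inside/room pair from a simulation
averaged_pair <- function(sim, window_s = 60) {
  ins <- average_window(sim$inside, window_s)
  rm <- average_window(sim$room, window_s)
  attr(ins, "calibrated") <- TRUE
  attr(rm, "calibrated") <- TRUE
  list(inside = ins, room = rm)
}

# noiseless single-phase inversion of a preset scenario; returns flux series
# plus the scenario
invert_preset <- function(preset, seed = 1) {
  sc <- chamber_preset(preset, seed = seed, noise_sd_ppm = 0)
  sim <- simulate_chamber(sc)
  tr <- averaged_pair(sim)
  law <- sc$area_law
  d0 <- sc$start_day
  flux <- invert_flux(tr$inside, tr$room, sc$seal, sc$geometry,
                      area_fn = function(t) leaf_area_at(law, d0 + t / 86400))
  list(flux = flux, scenario = sc, truth = sim$truth)
}
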