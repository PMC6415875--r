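#' Plant CO2 exchange kinetics after a light transition
#'
#' Within each light or dark phase the whole-culture exchange rate J_plant
#' (umol m-2 s-1, uptake negative, release positive) is modelled as a linear
#' ramp from 0 to an extremum `J_max` reached `t_peak_s` seconds after the
#' transition, followed by exponential relaxation toward the asymptote
#' `J_ss` with time constant `tau_s`:
#' `J(t) = J_ss + (J_max - J_ss) * exp(-(t - t_peak)/tau)` for `t >= t_peak`.
#' In light both values are <= 0 with |J_max| >= |J_ss| (peak uptake decays
#' toward a small steady uptake); in dark both are >= 0 with J_max >= J_ss.
#'
#' @param phase `"light"` or `"dark"`.
#' @param J_max extremum flux shortly after the transition (umol m-2 s-1).
#' @param J_ss asymptotic flux (umol m-2 s-1).
#' @param tau_s relaxation time constant (s), > 0.
#' @param t_peak_s delay from transition to the extremum (s), >= 0.
#' @return An object of class `plant_flux_model`.
#' @export
plant_flux_model <- function(phase = c("light", "dark"), J_max, J_ss,
                             tau_s, t_peak_s) {
  phase <- match.arg(phase)
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0", call. = FALSE)
  if (t_peak_s < 0) stop("t_peak_s must be >= 0", call. = FALSE)
  if (phase == "light") {
    if (J_max > 0 || J_ss > 0 || abs(J_max) < abs(J_ss)) {
      stop("light phase needs J_max <= J_ss <= 0 (uptake negative)",
           call. = FALSE)
    }
  } else {
    if (J_max < 0 || J_ss < 0 || J_max < J_ss) {
      stop("dark phase needs J_max >= J_ss >= 0 (release positive)",
           call. = FALSE)
    }
  }
  structure(list(phase = phase, J_max = J_max, J_ss = J_ss,
                 tau_s = tau_s, t_peak_s = t_peak_s),
            class = "plant_flux_model")
}

#' Evaluate a plant flux model
#'
#' @param t_since_transition_s time since the light/dark transition (s, >= 0).
#' @param model a [plant_flux_model()].
#' @return Flux in umol m-2 s-1 (vectorized over time).
#' @export
plant_flux <- function(t_since_transition_s, model) {
  stopifnot(inherits(model, "plant_flux_model"))
  t <- t_since_transition_s
  if (any(t < 0)) stop("t_since_transition_s must be >= 0", call. = FALSE)
  tp <- model$t_peak_s
  ramp <- if (tp > 0) model$J_max * pmin(t, tp) / tp else
    rep(model$J_max, length(t))
  decay <- model$J_ss + (model$J_max - model$J_ss) *
    exp(-(pmax(t, tp) - tp) / model$tau_s)
  ifelse(t < tp, ramp, decay)
}

#' Reference transition-kinetics presets
#'
#' Kinetic parameters characteristic of 15-plant Arabidopsis cultures in
#' sealed 10 cm dishes. For day-10 Parafilm-sealed cultures the dark-period
#' release peaks at 8.19 umol m-2 s-1 within ~3 min of lights-off and relaxes
#' (tau = 44 min) to 0.86; the light-period uptake peaks at -11.33 within
#' ~9 min of lights-on and relaxes (tau = 28 min) to -1.080. Micropore-sealed
#' cultures reach steady state (10 dark, -19.3 light) within ~20 min, modelled
#' here with tau = 5 min and a ~10% overshoot. Day-6 Parafilm light kinetics
#' peak at -27.7 and relax to -4.40; the time constant is taken equal to the
#' day-10 light value since the early-stage relaxation is not separately
#' characterized.
#'
#' @return Named list of [plant_flux_model()] objects:
#'   `parafilm_day10_dark`, `parafilm_day10_light`, `parafilm_day6_light`,
#'   `micropore_day10_dark`, `micropore_day10_light`.
#' @export
flux_presets <- function() {
  list(
    parafilm_day10_dark = plant_flux_model(
      "dark", J_max = 8.19, J_ss = 0.86, tau_s = 44 * 60, t_peak_s = 3 * 60),
    parafilm_day10_light = plant_flux_model(
      "light", J_max = -11.33, J_ss = -1.080, tau_s = 28 * 60,
      t_peak_s = 9 * 60),
    parafilm_day6_light = plant_flux_model(
      "light", J_max = -27.7, J_ss = -4.40, tau_s = 28 * 60,
      t_peak_s = 9 * 60),
    micropore_day10_dark = plant_flux_model(
      "dark", J_max = 11, J_ss = 10, tau_s = 5 * 60, t_peak_s = 2 * 60),
    micropore_day10_light = plant_flux_model(
      "light", J_max = -21.2, J_ss = -19.3, tau_s = 5 * 60, t_peak_s = 2 * 60)
  )
}

#' Leaf-area growth law
#'
#' Total projected leaf area of the culture as a power law of plant age,
#' `A(t) = a * t^b` (t in days since sowing, A in m^2). The default
#' (a = 1.14e-7, b = 2.5) gives ~0.1 cm^2 at day 6 and ~0.36 cm^2 at day 10
#' for a 15-plant culture, consistent with the observed extreme trace slopes
#' of a few ppm/min.
#'
#' @param a prefactor (m^2 day^-b), > 0.
#' @param b exponent.
#' @return Object of class `leaf_area_law`; callable via [leaf_area_at()].
#' @export
leaf_area_law <- function(a = 1.14e-7, b = 2.5) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0", call. = FALSE)
  structure(list(a = a, b = b), class = "leaf_area_law")
}

#' @rdname leaf_area_law
#' @param law a `leaf_area_law`.
#' @param day_since_sowing plant age in days (> 0).
#' @export
leaf_area_at <- function(law, day_since_sowing) {
  stopifnot(inherits(law, "leaf_area_law"))
  if (any(day_since_sowing <= 0)) stop("day must be > 0", call. = FALSE)
  law$a * day_since_sowing^law$b
}

# linear sensor response applied when generating raw readings
sensor_model <- function(gain = 1, offset = 0, noise_sd_ppm = 3) {
  if (noise_sd_ppm < 0) stop("noise_sd_ppm must be >= 0", call. = FALSE)
  list(gain = gain, offset = offset, noise_sd_ppm = noise_sd_ppm)
}

#' Chamber simulation scenario
#'
#' Bundles everything [simulate_chamber()] needs: dish geometry, seal
#' membrane, per-phase plant flux models, leaf-area law, room CO2 model,
#' sensor responses, sampling and seed. The simulation starts exactly at a
#' phase transition into `start_phase`, at plant age `start_day`.
#'
#' @param geometry a [dish_geometry()].
#' @param seal a [seal_properties()].
#' @param light_model,dark_model [plant_flux_model()]s (either may be `NULL`
#'   if the simulated span never enters that phase; `NULL` means J = 0).
#' @param area_law a [leaf_area_law()], or a constant area in m^2.
#' @param start_day plant age (days since sowing) at simulation start.
#' @param start_phase phase entered at t = 0.
#' @param duration_s simulated span (s).
#' @param dt_s integration/sampling step (s), <= 1 recommended; checked
#'   against the explicit-scheme stability bound.
#' @param C0_ppm initial in-dish concentration (ppm).
#' @param room_ppm room concentration (ppm); scalar, or a function of time_s
#'   (e.g. to add experimenter-breathing excursions).
#' @param noise_sd_ppm i.i.d. Gaussian sensor noise sd per sample (ppm);
#'   default 3, consistent with +-30 ppm-class NDIR hardware.
#' @param inside_sensor,room_sensor linear sensor responses
#'   `list(gain, offset)` used to produce raw readings
#'   (`raw = gain * ppm + offset + noise`); defaults are ideal sensors.
#' @param T_K,P_Pa temperature and pressure for the ppm/molar conversion.
#' @param seed integer seed for the sensor noise (mandatory).
#' @return An object of class `chamber_scenario`.
#' @export
chamber_scenario <- function(geometry = dish_geometry(),
                             seal = seal_properties("parafilm"),
                             light_model = NULL, dark_model = NULL,
                             area_law = leaf_area_law(),
                             start_day = 10,
                             start_phase = c("light", "dark"),
                             duration_s = 16 * 3600, dt_s = 1,
                             C0_ppm = 400, room_ppm = 400,
                             noise_sd_ppm = 3,
                             inside_sensor = list(gain = 1, offset = 0),
                             room_sensor = list(gain = 1, offset = 0),
                             T_K = 294.15, P_Pa = 101325, seed) {
  start_phase <- match.arg(start_phase)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory in a chamber_scenario", call. = FALSE)
  }
  if (noise_sd_ppm < 0) stop("noise_sd_ppm must be >= 0", call. = FALSE)
  if (duration_s <= 0 || dt_s <= 0) {
    stop("duration_s and dt_s must be positive", call. = FALSE)
  }
  if (is.numeric(area_law)) {
    a0 <- area_law
    if (a0 <= 0) stop("constant leaf area must be > 0", call. = FALSE)
    area_law <- structure(list(a = a0, b = 0), class = "leaf_area_law")
  }
  structure(list(geometry = geometry, seal = seal,
                 light_model = light_model, dark_model = dark_model,
                 area_law = area_law, start_day = start_day,
                 start_phase = start_phase, duration_s = duration_s,
                 dt_s = dt_s, C0_ppm = C0_ppm, room_ppm = room_ppm,
                 noise_sd_ppm = noise_sd_ppm,
                 inside_sensor = inside_sensor, room_sensor = room_sensor,
                 T_K = T_K, P_Pa = P_Pa, seed = as.integer(seed)),
            class = "chamber_scenario")
}

#' Day-10 / day-6 reference chamber scenarios
#'
#' Ready-made single-phase scenarios combining the default dish geometry,
#' measured seal properties, the [flux_presets()] kinetics and the default
#' leaf-area law. Initial in-dish concentrations are near the corresponding
#' phase-entry values (end of the preceding phase).
#'
#' @param name one of `"parafilm_day10_dark"`, `"parafilm_day10_light"`,
#'   `"parafilm_day6_light"`, `"micropore_day10_dark"`,
#'   `"micropore_day10_light"`.
#' @param seed seed for sensor noise.
#' @param noise_sd_ppm sensor noise sd (ppm); set 0 for noiseless runs.
#' @param inside_sensor,room_sensor linear sensor responses, see
#'   [chamber_scenario()].
#' @return A [chamber_scenario()].
#' @export
chamber_preset <- function(name, seed, noise_sd_ppm = 3,
                           inside_sensor = list(gain = 1, offset = 0),
                           room_sensor = list(gain = 1, offset = 0)) {
  presets <- flux_presets()
  spec <- switch(name,
    parafilm_day10_dark = list(seal = "parafilm", day = 10, phase = "dark",
                               C0 = 290, dur = 8 * 3600),
    parafilm_day10_light = list(seal = "parafilm", day = 10, phase = "light",
                                C0 = 480, dur = 16 * 3600),
    parafilm_day6_light = list(seal = "parafilm", day = 6, phase = "light",
                               C0 = 433, dur = 16 * 3600),
    micropore_day10_dark = list(seal = "micropore", day = 10, phase = "dark",
                                C0 = 364, dur = 8 * 3600),
    micropore_day10_light = list(seal = "micropore", day = 10,
                                 phase = "light", C0 = 418, dur = 16 * 3600),
    stop("unknown chamber preset: ", name, call. = FALSE))
  model <- presets[[name]]
  chamber_scenario(
    seal = seal_properties(spec$seal),
    light_model = if (spec$phase == "light") model else NULL,
    dark_model = if (spec$phase == "dark") model else NULL,
    start_day = spec$day, start_phase = spec$phase,
    duration_s = spec$dur, C0_ppm = spec$C0,
    noise_sd_ppm = noise_sd_ppm,
    inside_sensor = inside_sensor, room_sensor = room_sensor,
    seed = seed)
}

#' Forward-simulate a sealed-chamber CO2 trace
#'
#' Integrates the chamber mass balance
#' `V dC/dt = J_plant(t) A_plant(t) + (D_eff/Dx) A_seal (C_room - C)`
#' with an explicit (forward Euler) scheme at step `dt_s`, converts to ppm,
#' and produces raw sensor readings for the in-dish and room sensors
#' (linear response plus i.i.d. Gaussian noise). The noiseless ground truth
#' (concentration, plant flux, leaf area) is returned alongside.
#'
#' @param scenario a [chamber_scenario()].
#' @return A list with elements `inside` and `room` (raw [sensor_trace()]s),
#'   and `truth`: a list with `time_s`, `co2_ppm` (noiseless in-dish trace),
#'   `room_ppm`, `flux` (data frame `time_s`, `J_umol_m2_s`, `phase`,
#'   `t_since_transition_s`), `area_m2`, plus the scenario itself.
#' @export
simulate_chamber <- function(scenario) {
  stopifnot(inherits(scenario, "chamber_scenario"))
  sc <- scenario
  g <- seal_conductance(sc$seal, sc$geometry)  # m^3/s
  V <- sc$geometry$volume_m3
  # explicit-scheme stability guard (membrane term)
  tau_chamber <- V / g
  if (sc$dt_s > tau_chamber / 10) {
    stop(sprintf(
      "integration step %g s unstable: must be <= V*Dx/(D_eff*A_seal)/10 = %g s",
      sc$dt_s, tau_chamber / 10), call. = FALSE)
  }
  n <- floor(sc$duration_s / sc$dt_s)
  tgrid <- (0:n) * sc$dt_s

  sched <- light_schedule(t0_phase = sc$start_phase)
  ph <- schedule_phase(sched, tgrid)
  J <- numeric(n + 1L)
  for (p in c("light", "dark")) {
    m <- sc[[paste0(p, "_model")]]
    idx <- ph$phase == p
    if (any(idx)) {
      J[idx] <- if (is.null(m)) 0 else
        plant_flux(ph$t_since_transition_s[idx], m)
    }
  }
  A <- leaf_area_at(sc$area_law, sc$start_day + tgrid / 86400)
  room <- if (is.function(sc$room_ppm)) sc$room_ppm(tgrid) else
    rep(sc$room_ppm, n + 1L)

  # work in mol m-3; J is umol m-2 s-1
  C0 <- ppm_to_molar(sc$C0_ppm, sc$T_K, sc$P_Pa)
  Croom <- ppm_to_molar(room, sc$T_K, sc$P_Pa)
  src <- (J[-(n + 1L)] * 1e-6 * A[-(n + 1L)] + g * Croom[-(n + 1L)]) / V
  decay <- 1 - g * sc$dt_s / V
  # C[k+1] = decay * C[k] + dt * src[k]  (explicit Euler), via linear recursion
  C <- c(C0, stats::filter(sc$dt_s * src, filter = decay,
                           method = "recursive", init = C0))
  C_ppm <- molar_to_ppm(as.numeric(C), sc$T_K, sc$P_Pa)

  set.seed(sc$seed)
  noise_in <- rnorm(n + 1L, 0, sc$noise_sd_ppm)
  noise_rm <- rnorm(n + 1L, 0, sc$noise_sd_ppm)
  raw_in <- sc$inside_sensor$gain * C_ppm + sc$inside_sensor$offset + noise_in
  raw_rm <- sc$room_sensor$gain * room + sc$room_sensor$offset + noise_rm

  list(
    inside = sensor_trace(tgrid, raw_in, sensor_id = "inside",
                          location = "inside", calibrated = FALSE),
    room = sensor_trace(tgrid, raw_rm, sensor_id = "room",
                        location = "room", calibrated = FALSE),
    truth = list(time_s = tgrid, co2_ppm = C_ppm, room_ppm = room,
                 flux = data.frame(time_s = tgrid, J_umol_m2_s = J,
                                   phase = ph$phase,
                                   t_since_transition_s =
                                     ph$t_since_transition_s),
                 area_m2 = A, scenario = sc)
  )
}

#' Simulate calibration-standard readings for a linear sensor
#'
#' @param sensor linear response `list(gain, offset)`.
#' @param true_ppm standard-gas concentrations (default 0/100/500/1000 ppm).
#' @param reading_noise_sd sd of the reading noise (ppm); 0 for exact.
#' @param sensor_id id recorded in the table.
#' @param seed optional seed used when `reading_noise_sd > 0`.
#' @return Data frame `sensor_id`, `true_ppm`, `raw_reading`.
#' @export
simulate_calibration_standards <- function(sensor,
                                           true_ppm = c(0, 100, 500, 1000),
                                           reading_noise_sd = 0,
                                           sensor_id = "sensor",
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- sensor$gain * true_ppm + sensor$offset +
    rnorm(length(true_ppm), 0, reading_noise_sd)
  data.frame(sensor_id = sensor_id, true_ppm = true_ppm, raw_reading = raw)
}

#' Simulate a box-decay permeability experiment
#'
#' A sealed dish (initial concentration `C0_ppm`) sits in a large box held at
#' `box_ppm` (a CO2 source, e.g. sublimated dry ice, well mixed by a fan).
#' CO2 enters the dish through the seal only, so the in-dish concentration
#' relaxes toward the box level with time constant
#' `V * Dx / (D_eff * A_seal)`. The constant-coefficient linear ODE is
#' integrated with its exact exponential update, so the noiseless trace
#' matches the closed form to machine precision.
#'
#' @param permeability_m_s seal permeability D_eff/Dx (m/s); 0 is allowed
#'   (impermeable seal, constant trace).
#' @param geometry a [dish_geometry()].
#' @param box_ppm box concentration (ppm), above the dish initial level.
#' @param C0_ppm initial in-dish concentration (ppm).
#' @param duration_s simulated span (s).
#' @param dt_s sampling step (s).
#' @param noise_sd_ppm Gaussian sensor noise sd per sample (ppm).
#' @param seed seed for the noise.
#' @return List `inside`, `box` (raw [sensor_trace()]s) and `truth`
#'   (noiseless in-dish ppm and the time constant `tau_s`).
#' @export
simulate_box_decay <- function(permeability_m_s,
                               geometry = dish_geometry(),
                               box_ppm = 3000, C0_ppm = 400,
                               duration_s = 3600, dt_s = 1,
                               noise_sd_ppm = 3, seed = 1) {
  if (permeability_m_s < 0) stop("permeability must be >= 0", call. = FALSE)
  if (box_ppm < C0_ppm) {
    stop("box_ppm must be above the dish initial level", call. = FALSE)
  }
  n <- floor(duration_s / dt_s)
  tgrid <- (0:n) * dt_s
  g <- permeability_m_s * geometry$seal_area_m2
  if (g > 0) {
    tau <- geometry$volume_m3 / g
    C <- box_ppm - (box_ppm - C0_ppm) * exp(-tgrid / tau)
  } else {
    tau <- Inf
    C <- rep(C0_ppm, n + 1L)
  }
  set.seed(seed)
  inside <- C + rnorm(n + 1L, 0, noise_sd_ppm)
  box <- box_ppm + rnorm(n + 1L, 0, noise_sd_ppm)
  list(
    inside = sensor_trace(tgrid, inside, sensor_id = "dish",
                          location = "inside", calibrated = TRUE),
    box = sensor_trace(tgrid, box, sensor_id = "box", location = "room",
                       calibrated = TRUE),
    truth = list(time_s = tgrid, co2_ppm = C, tau_s = tau)
  )
}
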