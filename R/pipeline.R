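#' Load a pipeline configuration
#'
#' Reads a YAML configuration and applies overrides (e.g. from CLI flags).
#' Missing fields fall back to package defaults: default dish geometry,
#' Parafilm seal, 60-s averaging window, growth-room temperature and
#' pressure, default leaf-area law.
#'
#' @param path YAML file, or `NULL` to start from defaults.
#' @param overrides named list merged over the file values (nested lists are
#'   merged shallowly).
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  defaults <- list(outdir = "chamberflux_out", seed = 1L, window_s = 60,
                   temperature_K = 294.15, pressure_Pa = 101325,
                   stages = character(0),
                   scenario = list(preset = "parafilm_day10_dark"),
                   leaf_area = list(a = 1.14e-7, b = 2.5))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (cfg$window_s <= 0 || cfg$temperature_K <= 0 || cfg$pressure_Pa <= 0) {
    stop("physical configuration parameters must be positive", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.dep_error <- function(stage, what) {
  stop(sprintf("stage '%s' missing dependency: %s", stage, what),
       call. = FALSE)
}

.cfg_seal <- function(config, stage) {
  s <- config$seal
  if (is.null(s)) .dep_error(stage, "seal (config key 'seal')")
  if (is.character(s)) return(seal_properties(s))
  seal_properties(s$seal, thickness_m = s$thickness_m,
                  D_eff_m2s = s$D_eff_m2s)
}

.cfg_geometry <- function(config, stage) {
  g <- config$geometry
  if (is.null(g) || identical(g, "default")) return(dish_geometry())
  do.call(dish_geometry, g)
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order, reading and writing
#' artifact files under `config$outdir` and logging each stage's parameters.
#' Supported stages: `simulate` (forward chamber simulation from a preset
#' scenario; writes raw sensor CSVs, calibration standards and ground
#' truth), `calibrate` (fit + apply calibration, average), `leafarea`
#' (power-law fit of a `(day, area_m2)` CSV), `flux` (mass-balance
#' inversion), `kinetics` (transition fit + steady state), `diffusivity`
#' (box-decay permeability estimate), `pathways` (MRPP pathway testing of a
#' counts TSV). An empty stage list is a no-op.
#'
#' @param config a `run_config` from [load_config()], or a path to a YAML
#'   file.
#' @param quiet suppress per-stage messages.
#' @return Named list of artifact paths written, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stages <- config$stages
  if (!length(stages)) return(invisible(list()))
  order <- c("simulate", "calibrate", "leafarea", "diffusivity", "flux",
             "kinetics", "pathways", "hue", "starch")
  unknown <- setdiff(stages, order)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- order[order %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- list()
  p <- function(f) file.path(config$outdir, f)

  for (stage in stages) {
    say("[%s] seed=%d outdir=%s", stage, config$seed, config$outdir)
    if (stage == "simulate") {
      preset <- config$scenario$preset
      inside_sensor <- list(gain = 0.96, offset = 18)
      room_sensor <- list(gain = 1.02, offset = -8)
      sim <- simulate_chamber(chamber_preset(
        preset, seed = config$seed,
        inside_sensor = inside_sensor, room_sensor = room_sensor))
      write_sensor_csv(sim$inside, p("inside_raw.csv"))
      write_sensor_csv(sim$room, p("room_raw.csv"))
      std <- rbind(
        simulate_calibration_standards(inside_sensor, sensor_id = "inside"),
        simulate_calibration_standards(room_sensor, sensor_id = "room"))
      write_results(std, p("calibration_standards.tsv"), config = config,
                    seed = config$seed, extra = c(scenario = preset))
      write_results(sim$truth$flux, p("true_flux.tsv"), config = config,
                    seed = config$seed, extra = c(scenario = preset))
      sc <- sim$truth$scenario
      days <- seq(4, 14)
      write_results(
        data.frame(day = days, area_m2 = leaf_area_at(sc$area_law, days)),
        p("leaf_areas.tsv"), config = config, seed = config$seed)
      art$simulate <- p(c("inside_raw.csv", "room_raw.csv",
                          "calibration_standards.tsv", "true_flux.tsv",
                          "leaf_areas.tsv"))
    } else if (stage == "calibrate") {
      need <- p(c("inside_raw.csv", "room_raw.csv",
                  "calibration_standards.tsv"))
      if (!all(file.exists(need))) {
        .dep_error(stage, "raw traces + calibration standards (run 'simulate')")
      }
      std <- read_results(p("calibration_standards.tsv"))
      for (loc in c("inside", "room")) {
        tr <- read_sensor_csv(p(paste0(loc, "_raw.csv")), location =
                                if (loc == "inside") "inside" else "room",
                              sensor_id = loc)
        model <- fit_calibration(std[std$sensor_id == loc, ])
        cal <- average_window(apply_calibration(tr, model),
                              window_s = config$window_s)
        write_sensor_csv(cal, p(paste0(loc, "_cal.csv")))
      }
      art$calibrate <- p(c("inside_cal.csv", "room_cal.csv"))
    } else if (stage == "leafarea") {
      if (!file.exists(p("leaf_areas.tsv"))) {
        .dep_error(stage, "leaf_areas.tsv (day, area_m2)")
      }
      la <- read_results(p("leaf_areas.tsv"))
      fit <- fit_power_law(la$day, la$area_m2)
      write_results(
        data.frame(a = fit$a, b = fit$b, r_squared = fit$r_squared,
                   n = fit$n),
        p("leaf_area_fit.tsv"), config = config, seed = config$seed)
      art$leafarea <- p("leaf_area_fit.tsv")
    } else if (stage == "diffusivity") {
      dcfg <- config$diffusivity
      if (is.null(dcfg)) {
        .dep_error(stage, "config key 'diffusivity' (inside/box trace files)")
      }
      geometry <- .cfg_geometry(config, stage)
      inside <- read_sensor_csv(dcfg$inside, "inside", calibrated = TRUE)
      box <- read_sensor_csv(dcfg$box, "room", calibrated = TRUE)
      est <- estimate_permeability(inside, box, geometry,
                                   thickness_m = dcfg$thickness_m,
                                   seal = dcfg$seal)
      pts <- attr(est, "points")
      out <- rbind(pts, data.frame(time_s = NA, D_t = NA))
      write_results(
        data.frame(D_mean_m2s = est$D_eff_m2s, D_se_m2s = est$D_se_m2s,
                   permeability_m_s = est$permeability_m_s,
                   n_points = nrow(pts)),
        p("diffusivity.tsv"), config = config, seed = config$seed)
      art$diffusivity <- p("diffusivity.tsv")
    } else if (stage == "flux") {
      if (is.null(config$seal)) .dep_error(stage, "seal (config key 'seal')")
      need <- p(c("inside_cal.csv", "room_cal.csv"))
      if (!all(file.exists(need))) {
        .dep_error(stage, "calibrated traces (run 'calibrate')")
      }
      seal <- .cfg_seal(config, stage)
      geometry <- .cfg_geometry(config, stage)
      inside <- read_sensor_csv(p("inside_cal.csv"), "inside",
                                calibrated = TRUE)
      room <- read_sensor_csv(p("room_cal.csv"), "room", calibrated = TRUE)
      law <- if (file.exists(p("leaf_area_fit.tsv"))) {
        f <- read_results(p("leaf_area_fit.tsv"))
        leaf_area_law(f$a, f$b)
      } else {
        leaf_area_law(config$leaf_area$a, config$leaf_area$b)
      }
      start_day <- config$start_day %||%
        switch(config$scenario$preset, parafilm_day6_light = 6, 10)
      fl <- invert_flux(inside, room, seal, geometry,
                        area_fn = function(t)
                          leaf_area_at(law, start_day + t / 86400),
                        T_K = config$temperature_K,
                        P_Pa = config$pressure_Pa)
      write_results(fl, p("flux.tsv"), config = config, seed = config$seed,
                    extra = c(seal = seal$seal))
      art$flux <- p("flux.tsv")
    } else if (stage == "kinetics") {
      if (!file.exists(p("flux.tsv"))) {
        .dep_error(stage, "flux.tsv (run 'flux')")
      }
      fl <- read_results(p("flux.tsv"))
      kin <- fit_transition_kinetics(fl, transition_s = 0,
                                     phase_end_s = max(fl$time_s))
      ss <- steady_state_flux(fl, 0, max(fl$time_s))
      write_results(
        data.frame(t_peak_s = kin$t_peak_s, J_max = kin$J_max,
                   J_ss = kin$J_ss, tau_min = kin$tau_min,
                   r_squared = kin$r_squared, undefined = kin$undefined,
                   tail_mean = ss$mean, tail_se = ss$se),
        p("kinetics.tsv"), config = config, seed = config$seed)
      art$kinetics <- p("kinetics.tsv")
    } else if (stage == "pathways") {
      pcfg <- config$pathways
      if (is.null(pcfg)) {
        .dep_error(stage,
                   "config key 'pathways' (counts/labels/gmt files)")
      }
      counts <- as.matrix(read.csv(pcfg$counts, sep = "\t", row.names = 1))
      labels <- read.csv(pcfg$labels)$group
      sets <- read_gmt(pcfg$gmt)
      res <- mrpp_pathways(counts, labels, sets,
                           q = pcfg$q %||% 0.05,
                           n_perm = pcfg$n_perm %||% 10000,
                           seed = config$seed)
      write_results(res, p("pathways.tsv"), config = config,
                    seed = config$seed)
      art$pathways <- p("pathways.tsv")
    } else if (stage %in% c("hue", "starch")) {
      icfg <- config[[stage]]
      if (is.null(icfg) || is.null(icfg$image)) {
        .dep_error(stage, sprintf("config key '%s' (image file)", stage))
      }
      img <- png::readPNG(icfg$image)
      area <- segment_leaf_area(img, scale_m_per_px = icfg$scale_m_per_px %||% 1e-4)
      mask <- attr(area, "n_pixels") > 0
      hsv_px <- rgb2hsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                        as.vector(img[, , 3]), maxColorValue = 1)
      leafmask <- matrix(hsv_px[1, ] * 360 >= 60 & hsv_px[1, ] * 360 <= 180 &
                           hsv_px[2, ] >= 0.15 & hsv_px[3, ] >= 0.15,
                         nrow = dim(img)[1])
      if (stage == "hue") {
        hd <- hue_density(img, leafmask,
                          bandwidth = icfg$bandwidth %||% 0.8)
        write_results(data.frame(angle_deg = hd$angle_deg,
                                 density = hd$density),
                      p("hue_density.tsv"), config = config,
                      seed = config$seed)
        art$hue <- p("hue_density.tsv")
      } else {
        sc <- starch_score(img, leafmask)
        sc$background <- attr(sc, "background")
        write_results(sc, p("starch_scores.tsv"), config = config,
                      seed = config$seed)
        art$starch <- p("starch_scores.tsv")
      }
    }
  }
  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
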