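# Structured-text configuration and delimited-table round-tripping.

.parse_dispersion_cfg <- function(cfg, base_dir = ".") {
  type <- cfg$type %||% stop("dispersion entry missing 'type'")
  switch(type,
    # YAML 1.1 reads a bare `n` key as boolean FALSE; accept both spellings
    constant = dispersion_constant(cfg$n %||% cfg[["FALSE"]],
                                   cfg$k %||% 0),
    builtin = builtin_dispersion(cfg$name),
    table = {
      path <- cfg$file
      if (!file.exists(path)) path <- file.path(base_dir, cfg$file)
      read_dispersion_table(path)
    },
    drude_lorentz = dispersion_drude_lorentz(
      eps_inf = cfg$eps_inf %||% 1,
      plasma_energy_ev = cfg$plasma_energy_ev,
      f0 = cfg$f0 %||% 1, gamma0_ev = cfg$gamma0_ev,
      oscillators = if (!is.null(cfg$oscillators))
        do.call(rbind, lapply(cfg$oscillators, as.data.frame))),
    stop("unknown dispersion type: ", type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a layer-stack configuration from YAML
#'
#' The file holds `incident_angle_deg` and a `layers` list; each layer
#' has `name`, `thickness_nm` (a number or `semi_infinite`) and a
#' `dispersion` block (`type: constant | builtin | table |
#' drude_lorentz`). Table paths are resolved relative to the config file.
#'
#' @param path Path to the YAML file.
#' @return A [layer_stack()].
#' @export
read_stack_config <- function(path) {
  if (!file.exists(path)) stop("stack config not found: ", path)
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  layers <- lapply(cfg$layers, function(l) {
    th <- l$thickness_nm
    if (is.character(th) && th == "semi_infinite") th <- SEMI_INFINITE
    optical_layer(l$name, th, .parse_dispersion_cfg(l$dispersion, base_dir))
  })
  layer_stack(layers, cfg$incident_angle_deg)
}

#' Read an acquisition configuration from YAML
#'
#' Recognized keys: `led_centers_nm`, `led_fwhm_nm`, `led_response_ms`,
#' `exposure_ms`, `thresholds_nm`.
#'
#' @param path Path to the YAML file.
#' @return List with elements `bank` ([led_bank()]), `bands`
#'   ([band_configs()]) and `timing` ([timing_model()]).
#' @export
read_acquisition_config <- function(path) {
  if (!file.exists(path)) stop("acquisition config not found: ", path)
  cfg <- yaml::read_yaml(path)
  bank <- led_bank(
    centers_nm = as.numeric(cfg$led_centers_nm %||% c(730, 740, 756, 777, 805)),
    fwhm_nm = if (!is.null(cfg$led_fwhm_nm)) as.numeric(cfg$led_fwhm_nm),
    response_ms = cfg$led_response_ms %||% 2)
  bands <- band_configs(bank,
                        thresholds_nm = as.numeric(
                          cfg$thresholds_nm %||% bank$centers_nm[2:3]))
  timing <- timing_model(cfg$led_response_ms %||% 2,
                         cfg$exposure_ms %||% 33)
  list(bank = bank, bands = bands, timing = timing)
}

#' Read a synthetic-scenario configuration from YAML
#'
#' The file holds frame geometry (`width`, `height`, optional
#' `n_channels`), `frame_rate_s`, `duration_s`, `base_ri`, `noise_sd`,
#' `seed` and a named `courses` map; each course has `type: staircase |
#' langmuir | constant` and its parameters. Staircase levels may be given
#' as `levels_riu` or as `levels_nacl_percent` (converted with
#' [nacl_to_delta_ri()]).
#'
#' @param path Path to the YAML file.
#' @return List with elements `scenario` ([scenario_spec()]) and `rois`
#'   ([roi_map()]).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("scenario config not found: ", path)
  cfg <- yaml::read_yaml(path)
  courses <- lapply(cfg$courses, function(co) {
    switch(co$type,
      staircase = {
        lv <- if (!is.null(co$levels_riu)) as.numeric(co$levels_riu)
              else nacl_to_delta_ri(as.numeric(co$levels_nacl_percent))
        course_staircase(lv, co$dwell_s)
      },
      langmuir = course_langmuir(co$kon, co$koff, co$conc, co$rmax_riu,
                                 co$t_on, co$t_off),
      constant = course_constant(co$delta_riu %||% 0),
      stop("unknown course type: ", co$type))
  })
  rois <- six_channel_roi_map(width = cfg$width %||% 96,
                              height = cfg$height %||% 64,
                              n_channels = cfg$n_channels %||% 6)
  scen <- scenario_spec(courses, frame_rate_s = cfg$frame_rate_s %||% 1,
                        duration_s = cfg$duration_s,
                        base_ri = cfg$base_ri %||% 1.333,
                        noise_sd = cfg$noise_sd %||% 2e-3,
                        seed = cfg$seed %||% 1L)
  list(scenario = scen, rois = rois,
       angle_deg = if (!is.null(cfg$angle_deg)) as.numeric(cfg$angle_deg))
}

#' Write / read a reflectance spectrum as 2-column delimited text
#'
#' @param spectrum A `reflectance_spectrum` data frame.
#' @param path Output file.
#' @return `path` (write) or the spectrum (read), invisibly for write.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(spectrum[, c("wavelength_nm", "rp")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(tab, class = c("reflectance_spectrum", "data.frame"))
}

#' Write / read a sensorgram as delimited text
#'
#' Columns `time_s`, `roi_id`, `rw_nm`, `band_id`, `clamped`; one row per
#' (time, ROI).
#'
#' @param sensorgram A `sensorgram` data frame.
#' @param path File path.
#' @return `path` (write, invisibly) or the sensorgram (read).
#' @export
write_sensorgram <- function(sensorgram, path) {
  utils::write.table(sensorgram, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(tab, class = c("sensorgram", "data.frame"))
}
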