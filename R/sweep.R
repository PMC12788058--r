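# Replication of the algorithm-validation simulation: resonance red-shift
# sweep vs analyte refractive index, tracked both by dense-grid search
# (truth) and by the adaptive second-order fitting tracker.

#' Solve the initialization incidence angle
#'
#' Real systems are initialized by adjusting the incidence angle until the
#' resonance wavelength sits inside band 1. This solves, by bisection, the
#' angle at which the dense-grid resonance wavelength of `stack` equals
#' `target_rw_nm` (default 735 nm, the middle of the band-1 selection
#' range).
#'
#' @param stack A [layer_stack()] (analyte at the starting refractive
#'   index).
#' @param target_rw_nm Desired resonance wavelength at initialization, nm.
#' @param angle_bracket_deg Search bracket for the angle, degrees.
#' @param dip_search_nm Wavelength range used to locate the dip while
#'   solving (wider than the LED span so the dip is visible throughout).
#' @return The incidence angle in degrees.
#' @export
solve_init_angle <- function(stack, target_rw_nm = 735,
                             angle_bracket_deg = c(49, 56),
                             dip_search_nm = c(620, 1000)) {
  f <- function(th)
    tryCatch(true_rw(stack, angle_deg = th, search_range_nm = dip_search_nm,
                     grid_step_nm = 0.05) - target_rw_nm,
             error = function(e) NA_real_)
  # coarse scan first: the dip leaves the search window at extreme angles
  angles <- seq(angle_bracket_deg[1], angle_bracket_deg[2], by = 0.25)
  vals <- vapply(angles, f, numeric(1))
  ok <- which(!is.na(vals))
  cross <- ok[which(diff(sign(vals[ok])) != 0 &
                      diff(ok) == 1L)]
  if (length(cross) == 0L)
    stop("no angle in the bracket places the dip at the target wavelength")
  i <- cross[1]
  stats::uniroot(f, c(angles[i], angles[i + 1L]), tol = 1e-7)$root
}

#' Refractive-index sweep with true and ASF-tracked resonance wavelengths
#'
#' Steps the analyte refractive index upward from `ri_start` in increments
#' of `ri_step` while the dense-grid resonance wavelength remains inside
#' `window_nm`. At every step the true resonance wavelength is found by
#' dense-grid search and the ASF estimate by the band-switching tracker
#' (noise-free sampling at the LED centers), with the tracker state
#' carried across steps starting from band 1.
#'
#' @param stack A [layer_stack()]; its analyte layer is swept.
#' @param angle_deg Incidence angle; `NULL` (default) solves it with
#'   [solve_init_angle()] so the sweep starts mid-band-1.
#' @param ri_start Starting analyte refractive index, default 1.333.
#' @param ri_step Refractive-index increment, default 0.002.
#' @param bank,bands LED bank and band configuration.
#' @param window_nm Operational wavelength window, default the LED span.
#' @param max_steps Safety cap on the number of sweep points.
#' @return A data frame with columns `ri`, `true_rw_nm`, `asf_rw_nm`,
#'   `band_id`, `clamped`, plus attributes `angle_deg`.
#' @export
simulate_sweep <- function(stack = gold_chip_stack(analyte_n = 1.333),
                           angle_deg = NULL, ri_start = 1.333,
                           ri_step = 0.002, bank = led_bank(),
                           bands = band_configs(bank),
                           window_nm = range(bank$centers_nm),
                           max_steps = 60L) {
  stack <- set_analyte_ri(stack, ri_start)
  if (is.null(angle_deg))
    angle_deg <- solve_init_angle(stack,
                                  target_rw_nm = mean(
                                    bands[[1]]$selection_range_nm))
  state <- asf_state(active_band = 1L)
  rows <- list()
  ri <- ri_start
  for (i in seq_len(max_steps)) {
    st <- set_analyte_ri(stack, ri)
    tr <- tryCatch(
      true_rw(st, angle_deg = angle_deg, search_range_nm = window_nm,
              grid_step_nm = 0.01),
      error = function(e) NA_real_)
    if (is.na(tr)) break
    sampler <- function(led_ids)
      sample_leds(function(l) rp_multilayer(st, l, angle_deg),
                  bank, led_ids)
    est <- asf_converge(state, sampler, bands)
    state <- est$state
    rows[[i]] <- data.frame(ri = ri, true_rw_nm = tr,
                            asf_rw_nm = est$rw_nm,
                            band_id = est$band_id, clamped = est$clamped)
    ri <- ri + ri_step
  }
  out <- do.call(rbind, rows)
  attr(out, "angle_deg") <- angle_deg
  out
}

#' Sensitivity slopes of a refractive-index sweep
#'
#' Ordinary least-squares slopes (nm/RIU) of the true and ASF resonance
#' wavelengths against refractive index, and their relative difference.
#'
#' @param sweep Output of [simulate_sweep()].
#' @return List with `true_slope`, `asf_slope` (nm/RIU) and
#'   `rel_error` = |asf - true| / true.
#' @export
sweep_sensitivity <- function(sweep) {
  stopifnot(nrow(sweep) >= 2L)
  ct <- linear_calibration(sweep$ri, sweep$true_rw_nm)
  ca <- linear_calibration(sweep$ri, sweep$asf_rw_nm)
  list(true_slope = ct$slope, asf_slope = ca$slope,
       rel_error = abs(ca$slope - ct$slope) / abs(ct$slope))
}
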