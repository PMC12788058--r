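# Calibration and figure-of-merit layer: sensitivity regression, baseline
# noise RMS, refractive-index resolution, limit of detection, dynamic
# range, net shift, NaCl concentration -> refractive-index conversion.

#' Ordinary least-squares calibration line
#'
#' Fits `y = intercept + slope * x` by least squares (via [stats::lm()]).
#' `r_squared` is the squared Pearson correlation of (x, y).
#'
#' @param x Predictor (refractive index in RIU, or concentration).
#' @param y Response (resonance-wavelength shift in nm).
#' @return A `calibration_curve` list with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
linear_calibration <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) < 2L)
    stop("calibration requires at least two distinct x values")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> slope = %.6g, intercept = %.6g, r2 = %.6f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Baseline noise statistics of a sensorgram trace
#'
#' Root-mean-square of the resonance wavelength about its mean over a
#' baseline time window (mean removal only, no further detrending),
#' matching the usual flat-baseline noise test.
#'
#' @param sensorgram A sensorgram data frame (`time_s`, `roi_id`, `rw_nm`).
#' @param roi ROI id to evaluate.
#' @param window Length-2 time interval (s).
#' @param min_samples Minimum samples required in the window, default 10.
#' @return A `noise_stats` list with `rms_nm`, `window`, `n_samples`.
#' @export
baseline_rms <- function(sensorgram, roi, window, min_samples = 10L) {
  sub <- sensorgram[sensorgram$roi_id == roi &
                      sensorgram$time_s >= window[1] &
                      sensorgram$time_s <= window[2], ]
  rw <- sub$rw_nm[!is.na(sub$rw_nm)]
  if (length(rw) < min_samples)
    stop("baseline window holds fewer than ", min_samples, " samples")
  structure(list(rms_nm = sqrt(mean((rw - mean(rw))^2)),
                 window = window, n_samples = length(rw)),
            class = "noise_stats")
}

#' Refractive-index resolution
#'
#' \deqn{\sigma_{RI} = \frac{\sigma_n}{\sigma_s}\,\Delta\sigma_{SD}}
#' where \eqn{\sigma_s/\sigma_n} is the calibration slope (nm/RIU) and
#' \eqn{\Delta\sigma_{SD}} the baseline noise RMS (nm); i.e. noise RMS
#' divided by sensitivity.
#'
#' @param curve A `calibration_curve` with positive slope (nm/RIU).
#' @param noise A `noise_stats` (or a bare RMS value in nm).
#' @return Resolution in RIU.
#' @export
rir <- function(curve, noise) {
  rms <- if (inherits(noise, "noise_stats")) noise$rms_nm else noise
  stopifnot(rms >= 0)
  if (!is.numeric(curve$slope) || curve$slope <= 0)
    stop("invalid calibration: slope must be > 0")
  rms / curve$slope
}

#' Limit of detection
#'
#' \deqn{LOD = 3 \delta_N / S} with \eqn{\delta_N} the standard deviation
#' of the blank channel (in response units) and \eqn{S} the calibration
#' slope (response units per concentration unit).
#'
#' @param blank_sd Blank standard deviation (same units as the
#'   calibration response), `>= 0`.
#' @param curve A `calibration_curve` with positive slope.
#' @return Limit of detection in concentration units.
#' @export
lod <- function(blank_sd, curve) {
  stopifnot(blank_sd >= 0)
  if (!is.numeric(curve$slope) || curve$slope <= 0)
    stop("invalid calibration: slope must be > 0")
  3 * blank_sd / curve$slope
}

#' NaCl concentration to refractive-index change
#'
#' Linear conversion anchored at the 13% w/v endpoint: a 13% NaCl
#' solution differs from pure water by 0.0241 RIU, so
#' `delta_n = percent * 0.0241 / 13` RIU (about 1.854e-3 RIU per percent;
#' standard refractometry tables agree to ~2 significant figures).
#' Outside the validated 0-13% range the linear form is extrapolated with
#' a warning.
#'
#' @param percent_w_v NaCl concentration in percent weight/volume.
#' @return Refractive-index difference from pure water, RIU.
#' @export
nacl_to_delta_ri <- function(percent_w_v) {
  if (any(percent_w_v < 0 | percent_w_v > 13))
    warning("NaCl concentration outside validated range [0, 13]%; ",
            "linear conversion extrapolated")
  percent_w_v / 13 * 0.0241
}

#' Net resonance-wavelength shift between two time windows
#'
#' Mean resonance wavelength over `post_window` minus the mean over
#' `pre_window`, for one ROI: the before/after-reaction net shift.
#'
#' @param sensorgram A sensorgram data frame.
#' @param roi ROI id.
#' @param pre_window,post_window Length-2 time intervals (s) inside the
#'   trace.
#' @return Net shift in nm.
#' @export
net_shift <- function(sensorgram, roi, pre_window, post_window) {
  pick <- function(win) {
    sub <- sensorgram[sensorgram$roi_id == roi &
                        sensorgram$time_s >= win[1] &
                        sensorgram$time_s <= win[2], ]
    rw <- sub$rw_nm[!is.na(sub$rw_nm)]
    if (length(rw) == 0L) stop("window [", win[1], ", ", win[2],
                               "] lies outside the trace")
    mean(rw)
  }
  pick(post_window) - pick(pre_window)
}

#' Dynamic range of the tracker over analyte refractive index
#'
#' Width (in RIU) of the analyte refractive-index interval over which the
#' noise-free tracker error |ASF rw - true rw| stays within
#' `tolerance_nm` while the dip remains inside the LED span. The analyte
#' index is scanned upward from the value placing the dip at the lower
#' window edge until the dip exits the window or the tolerance is
#' exceeded.
#'
#' @param stack A [layer_stack()].
#' @param angle_deg Incidence angle (degrees); defaults to the stack's.
#' @param bank,bands LED bank and band configuration.
#' @param tolerance_nm Permitted tracking error, default 0.5 nm.
#' @param n_grid Number of refractive-index evaluation points, default 25.
#' @param dip_search_nm Wide wavelength range used to follow the dip.
#' @return The dynamic range in RIU, with attribute `detail` (data frame
#'   of the scanned points).
#' @export
dynamic_range <- function(stack, angle_deg = stack$incident_angle_deg,
                          bank = led_bank(), bands = band_configs(bank),
                          tolerance_nm = 0.5, n_grid = 25L,
                          dip_search_nm = c(620, 1000)) {
  window <- range(bank$centers_nm)
  dip_at <- function(n)
    true_rw(set_analyte_ri(stack, n), angle_deg = angle_deg,
            search_range_nm = dip_search_nm, grid_step_nm = 0.05)
  # refractive indices placing the dip at the window edges; coarse scan
  # first because the dip leaves the search window at extreme indices
  edge_ri <- function(target) {
    f <- function(n)
      tryCatch(dip_at(n) - target, error = function(e) NA_real_)
    ns <- seq(1.27, 1.43, by = 0.005)
    vals <- vapply(ns, f, numeric(1))
    ok <- which(!is.na(vals))
    cross <- ok[which(diff(sign(vals[ok])) != 0 & diff(ok) == 1L)]
    if (length(cross) == 0L)
      stop("no analyte index places the dip at ", target, " nm")
    i <- cross[1]
    stats::uniroot(f, c(ns[i], ns[i + 1L]), tol = 1e-7)$root
  }
  # keep 0.25 nm inside the window edges so the dip stays interior
  ri_lo <- edge_ri(window[1] + 0.25)
  ri_hi <- edge_ri(window[2] - 0.25)
  ris <- seq(ri_lo, ri_hi, length.out = n_grid)
  err <- vapply(ris, function(n) {
    st <- set_analyte_ri(stack, n)
    tr <- true_rw(st, angle_deg = angle_deg, search_range_nm = window,
                  grid_step_nm = 0.01)
    sampler <- function(led_ids)
      sample_leds(function(l) rp_multilayer(st, l, angle_deg),
                  bank, led_ids)
    init <- fullscan_init(sampler(seq_along(bank$centers_nm)),
                          domain_nm = window)
    est <- asf_converge(asf_state(band_for_rw(init$rw_nm, bands)),
                        sampler, bands)
    abs(est$rw_nm - tr)
  }, numeric(1))
  ok <- err <= tolerance_nm
  # widest contiguous run of in-tolerance points
  runs <- rle(ok)
  if (!any(runs$values)) {
    rng <- 0
  } else {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    wi <- which(runs$values)
    widths <- ris[ends[wi]] - ris[starts[wi]]
    rng <- max(widths)
  }
  attr(rng, "detail") <- data.frame(ri = ris, error_nm = err, ok = ok)
  rng
}
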