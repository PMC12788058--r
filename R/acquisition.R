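# The five-LED illumination bank, the three overlapping fit bands with
# trigger regions, discrete wavelength sampling and the scan-cycle timing.

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scan-cycle timing model
#'
#' @param led_response_ms LED response (settling) time per wavelength in
#'   ms, default 2.
#' @param exposure_ms Camera exposure time per wavelength in ms, default 33.
#' @return A `timing_model` object.
#' @export
timing_model <- function(led_response_ms = 2, exposure_ms = 33) {
  stopifnot(led_response_ms >= 0, exposure_ms >= 0)
  structure(list(led_response_ms = led_response_ms,
                 exposure_ms = exposure_ms), class = "timing_model")
}

#' Time of one scanning cycle
#'
#' One cycle illuminates `n_wavelengths` LEDs sequentially; each costs the
#' LED response time plus the camera exposure time:
#' `n_wavelengths * (led_response_ms + exposure_ms)`. With the default
#' 2 ms / 33 ms constants a three-wavelength cycle takes 105 ms and a
#' five-wavelength full scan 175 ms.
#'
#' @param n_wavelengths Number of wavelengths sampled per cycle, `>= 1`.
#' @param timing A [timing_model()].
#' @return Cycle time in ms.
#' @export
cycle_time_ms <- function(n_wavelengths, timing = timing_model()) {
  if (!is.numeric(n_wavelengths) || any(n_wavelengths < 1))
    stop("n_wavelengths must be >= 1")
  n_wavelengths * (timing$led_response_ms + timing$exposure_ms)
}

#' The five-LED illumination bank
#'
#' @param centers_nm Strictly ascending LED center wavelengths in nm,
#'   exactly five, each within `[700, 850]`.
#'   Default `c(730, 740, 756, 777, 805)`.
#' @param fwhm_nm Optional LED line width (FWHM, nm): scalar or length-5
#'   vector; `NULL` (default) means delta-function sampling at the centers.
#' @param response_ms LED response time in ms, default 2.
#' @return A `led_bank` object.
#' @export
led_bank <- function(centers_nm = c(730, 740, 756, 777, 805),
                     fwhm_nm = NULL, response_ms = 2) {
  stopifnot(length(centers_nm) == 5L, all(diff(centers_nm) > 0),
            all(centers_nm >= 700 & centers_nm <= 850),
            response_ms >= 0)
  if (!is.null(fwhm_nm)) {
    fwhm_nm <- rep_len(fwhm_nm, 5L)
    stopifnot(all(fwhm_nm > 0))
  }
  structure(list(centers_nm = as.numeric(centers_nm), fwhm_nm = fwhm_nm,
                 response_ms = response_ms), class = "led_bank")
}

#' Three overlapping fit bands over the LED bank
#'
#' Band k uses LEDs k..k+2; its fit range is the span of that triple's
#' centers. With the default bank: band 1 fits on 730-756 nm, band 2 on
#' 740-777 nm, band 3 on 756-805 nm, so 740-756 and 756-777 are trigger
#' bands where adjacent triples overlap. Selection ranges (which band a
#' resonance wavelength belongs to) are half-open at the switch
#' thresholds: by default band 1 is `[730, 740)`, band 2 `[740, 777)`,
#' band 3 `[777, 805]`, matching the band partition of the operational
#' spectrum; a stepwise red-shift convergence therefore passes clamped
#' estimates at 756 (band 1's fit edge) and 777 before resolving inside
#' band 3. Setting `thresholds_nm = c(740, 756)` instead switches to the
#' third LED triple as soon as an estimate reaches 756 nm.
#'
#' @param bank A [led_bank()].
#' @param thresholds_nm The two switch thresholds (defaults
#'   `c(740, 777)`, the centers of LEDs 2 and 4).
#' @return List of three `band_config` objects.
#' @export
band_configs <- function(bank = led_bank(),
                         thresholds_nm = bank$centers_nm[c(2, 4)]) {
  stopifnot(length(thresholds_nm) == 2L, diff(thresholds_nm) > 0)
  c1 <- bank$centers_nm[1]; c5 <- bank$centers_nm[5]
  sel <- list(c(c1, thresholds_nm[1]),
              c(thresholds_nm[1], thresholds_nm[2]),
              c(thresholds_nm[2], c5))
  lapply(1:3, function(k) {
    ids <- k:(k + 2L)
    structure(list(
      band_id = k,
      led_ids = ids,
      fit_range_nm = range(bank$centers_nm[ids]),
      selection_range_nm = sel[[k]],
      upshift_threshold_nm = if (k < 3) thresholds_nm[k] else NA_real_,
      downshift_threshold_nm = if (k > 1) thresholds_nm[k - 1] else NA_real_),
      class = "band_config")
  })
}

#' Which band a resonance wavelength belongs to
#'
#' Selection intervals are half-open `[lo, hi)` with the final band closed
#' at its upper edge, so every wavelength in the operational range maps to
#' exactly one band.
#'
#' @param rw_nm Resonance wavelength(s) in nm.
#' @param bands Band list from [band_configs()].
#' @return Integer band id(s) in 1..3.
#' @export
band_for_rw <- function(rw_nm, bands = band_configs()) {
  lo <- bands[[1]]$selection_range_nm[1]
  hi <- bands[[3]]$selection_range_nm[2]
  if (any(rw_nm < lo | rw_nm > hi))
    stop(sprintf("resonance wavelength outside operational range [%g, %g] nm",
                 lo, hi))
  t1 <- bands[[2]]$selection_range_nm[1]
  t2 <- bands[[3]]$selection_range_nm[1]
  ifelse(rw_nm >= t2, 3L, ifelse(rw_nm >= t1, 2L, 1L))
}

#' Sample a reflectance spectrum at LED wavelengths
#'
#' Each active LED contributes one `(wavelength, intensity)` point. With
#' delta-function LEDs (the default) the intensity is the provider's value
#' at the center wavelength; with a finite `fwhm_nm` it is the mean of the
#' provider weighted by a symmetric Gaussian line profile (numerical
#' quadrature over center +- 3 sd). Optional additive zero-mean Gaussian
#' noise is reproducible under `seed`.
#'
#' @param provider Function mapping wavelength (nm, vectorized) to
#'   reflectance.
#' @param bank A [led_bank()].
#' @param led_ids Which LEDs to fire (default all five).
#' @param noise_sd Additive intensity noise sd, default 0.
#' @param seed Optional integer seed for the noise.
#' @return Data frame `sampled_points` with columns `wavelength_nm`,
#'   `intensity`, ascending in wavelength.
#' @export
sample_leds <- function(provider, bank = led_bank(),
                        led_ids = seq_along(bank$centers_nm),
                        noise_sd = 0, seed = NULL) {
  stopifnot(length(led_ids) >= 1L, noise_sd >= 0)
  led_ids <- sort(led_ids)
  centers <- bank$centers_nm[led_ids]
  if (is.null(bank$fwhm_nm)) {
    y <- provider(centers)
  } else {
    y <- vapply(seq_along(led_ids), function(i) {
      sd <- bank$fwhm_nm[led_ids[i]] / (2 * sqrt(2 * log(2)))
      grid <- seq(centers[i] - 5 * sd, centers[i] + 5 * sd, length.out = 401)
      w <- stats::dnorm(grid, centers[i], sd)
      sum(w * provider(grid)) / sum(w)
    }, numeric(1))
  }
  if (noise_sd > 0)
    y <- y + .with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  structure(data.frame(wavelength_nm = centers, intensity = y),
            class = c("sampled_points", "data.frame"))
}
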