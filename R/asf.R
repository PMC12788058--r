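# Adaptive second-order fitting (ASF): full-spectrum fourth-order
# initialization, three-point quadratic resonance estimation with
# clamping, trigger-band switching, stepwise convergence and tracking.
#
# All fits are exact interpolations (3 points per parabola, 5 per
# quartic): point counts equal parameter counts. Fits are performed in
# wavelength coordinates centered on the sample mean for conditioning.

.rw_estimate <- function(rw_nm, clamped, fit, band_id = NA_integer_,
                         degenerate = FALSE) {
  structure(list(rw_nm = rw_nm, band_id = band_id, clamped = clamped,
                 degenerate = degenerate, fit = fit),
            class = "rw_estimate")
}

#' @export
print.rw_estimate <- function(x, ...) {
  cat(sprintf("<rw_estimate> rw = %.3f nm, band = %s%s%s\n", x$rw_nm,
              ifelse(is.na(x$band_id), "?", x$band_id),
              if (x$clamped) ", clamped" else "",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Resonance wavelength from an exact three-point parabola
#'
#' Interpolates the parabola `R(u) = c0 + c1 u + c2 u^2` (u = wavelength
#' centered on the sample mean) exactly through three sampled points. If
#' the parabola opens upward (`c2 > 0`) and its vertex lies inside the fit
#' range, the vertex is the resonance-wavelength estimate. Otherwise the
#' estimate is clamped to the fit-range endpoint toward lower fitted
#' intensity and flagged. Collinear points (zero curvature) give a
#' degenerate fit, clamped to the endpoint with lower measured intensity.
#'
#' @param points A data frame with columns `wavelength_nm`, `intensity`;
#'   exactly 3 rows, distinct wavelengths.
#' @param fit_range_nm Length-2 interval on which the fit is valid
#'   (the active LED triple's span).
#' @return An `rw_estimate` with fields `rw_nm`, `clamped`, `degenerate`
#'   and `fit` (list with `a`, `b`, `c` in raw wavelength coordinates,
#'   `vertex_nm`, `domain_nm`).
#' @export
quadratic_rw <- function(points, fit_range_nm) {
  stopifnot(nrow(points) == 3L, length(fit_range_nm) == 2L,
            fit_range_nm[2] > fit_range_nm[1])
  x <- points$wavelength_nm; y <- points$intensity
  if (anyDuplicated(x)) stop("duplicate wavelengths in quadratic fit")
  o <- order(x); x <- x[o]; y <- y[o]
  x0 <- mean(x); u <- x - x0
  co <- unname(solve(cbind(1, u, u^2), y))   # c0, c1, c2 (centered)
  c2 <- co[3]
  # raw-coordinate coefficients R(lambda) = a l^2 + b l + c
  a <- c2
  b <- co[2] - 2 * c2 * x0
  cc <- co[1] - co[2] * x0 + c2 * x0^2
  peval <- function(lam) co[1] + co[2] * (lam - x0) + c2 * (lam - x0)^2
  scale <- max(abs(y), 1e-12)
  if (abs(c2) < 1e-14 * scale) {
    # collinear: clamp toward the measured lower-intensity end
    rw <- if (y[1] <= y[3]) fit_range_nm[1] else fit_range_nm[2]
    return(.rw_estimate(rw, clamped = TRUE,
                        fit = list(a = a, b = b, c = cc,
                                   vertex_nm = NA_real_,
                                   domain_nm = fit_range_nm),
                        degenerate = TRUE))
  }
  vertex <- x0 - co[2] / (2 * c2)
  fit <- list(a = a, b = b, c = cc, vertex_nm = vertex,
              domain_nm = fit_range_nm)
  if (c2 > 0 && vertex >= fit_range_nm[1] && vertex <= fit_range_nm[2])
    return(.rw_estimate(vertex, clamped = FALSE, fit = fit))
  # vertex outside the range (or inverted parabola): report the endpoint
  # with lower fitted intensity
  ends <- fit_range_nm
  rw <- ends[which.min(peval(ends))]
  .rw_estimate(rw, clamped = TRUE, fit = fit, degenerate = c2 <= 0)
}

#' Initial resonance estimate from a five-point quartic full scan
#'
#' Interpolates a degree-4 polynomial exactly through the five full-scan
#' points and returns the wavelength minimizing it on `domain_nm`:
#' real roots of the derivative cubic with positive second derivative,
#' tie-broken by lowest fitted value then smaller wavelength. If the
#' quartic has no interior minimum, the lower-valued endpoint is returned,
#' flagged clamped.
#'
#' @param points A data frame with columns `wavelength_nm`, `intensity`;
#'   exactly 5 rows at distinct wavelengths.
#' @param domain_nm Search domain, default `c(730, 805)`.
#' @return An `rw_estimate` whose `fit` holds the centered quartic
#'   coefficients (`coef_centered`, `center_nm`) and `domain_nm`.
#' @export
fullscan_init <- function(points, domain_nm = c(730, 805)) {
  stopifnot(nrow(points) == 5L, length(domain_nm) == 2L)
  x <- points$wavelength_nm; y <- points$intensity
  if (anyDuplicated(x)) stop("duplicate wavelengths in quartic interpolation")
  o <- order(x); x <- x[o]; y <- y[o]
  x0 <- mean(x); u <- x - x0
  V <- outer(u, 0:4, `^`)
  co <- unname(solve(V, y))              # centered quartic coefficients
  peval <- function(lam) drop(outer(lam - x0, 0:4, `^`) %*% co)
  # derivative cubic c1 + 2 c2 u + 3 c3 u^2 + 4 c4 u^3
  dcoef <- co[2:5] * (1:4)
  roots <- polyroot(dcoef)
  tol <- 1e-8 * max(abs(x - x0), 1)
  re <- Re(roots)[abs(Im(roots)) < 1e-6 * (1 + Mod(roots))]
  cand <- re[re + x0 >= domain_nm[1] & re + x0 <= domain_nm[2]]
  if (length(cand)) {
    d2 <- 2 * co[3] + 6 * co[4] * cand + 12 * co[5] * cand^2
    cand <- cand[d2 > 0]
  }
  fit <- list(coef_centered = co, center_nm = x0, domain_nm = domain_nm)
  if (length(cand)) {
    lam <- cand + x0
    val <- peval(lam)
    best <- order(val, lam)[1]           # lowest value, then smaller lambda
    return(.rw_estimate(lam[best], clamped = FALSE, fit = fit))
  }
  ends <- domain_nm
  rw <- ends[which.min(peval(ends))]
  .rw_estimate(rw, clamped = TRUE, fit = fit)
}

#' Tracker state for the adaptive band-switching loop
#'
#' @param active_band Active band id in 1..3, default 1.
#' @param last_rw_nm Last resonance estimate (nm) or `NA`.
#' @param switch_count Band switches performed in the current convergence
#'   cycle (at most 2: three bands, monotone progression).
#' @return An `asf_state` object.
#' @export
asf_state <- function(active_band = 1L, last_rw_nm = NA_real_,
                      switch_count = 0L) {
  stopifnot(active_band %in% 1:3, switch_count >= 0)
  structure(list(active_band = as.integer(active_band),
                 last_rw_nm = last_rw_nm,
                 switch_count = as.integer(switch_count)),
            class = "asf_state")
}

#' One adaptive-fitting step: sample the active triple, fit, maybe switch
#'
#' Samples the active band's LED triple, runs [quadratic_rw()] on that
#' band's fit range, then re-selects the active band from the estimate:
#' `rw >= 756` selects band 3, `740 <= rw < 756` band 2, `rw < 740`
#' band 1 (thresholds from the band configuration; downshifts mirror
#' upshifts so blue-shifts during rinse phases track equally).
#'
#' @param state An [asf_state()].
#' @param sampler Function `(led_ids) -> sampled_points` returning the
#'   three points at the triple's center wavelengths.
#' @param bands Band list from [band_configs()].
#' @return List with elements `estimate` (an `rw_estimate`, `band_id` set
#'   to the band used for the fit) and `state` (updated).
#' @export
asf_step <- function(state, sampler, bands = band_configs()) {
  stopifnot(inherits(state, "asf_state"))
  band <- bands[[state$active_band]]
  pts <- sampler(band$led_ids)
  est <- quadratic_rw(pts, band$fit_range_nm)
  est$band_id <- band$band_id
  if (est$clamped && band$band_id > 1L &&
      est$rw_nm == band$fit_range_nm[1]) {
    # clamp at the lower fit edge: the dip lies blueward, mirror the
    # upshift rule by stepping one band down (a bare threshold lookup
    # would keep band 3 active forever at exactly 756 nm)
    new_band <- band$band_id - 1L
  } else {
    new_band <- band_for_rw(est$rw_nm, bands)
  }
  switched <- new_band != state$active_band
  new_state <- asf_state(
    active_band = new_band, last_rw_nm = est$rw_nm,
    switch_count = if (switched) state$switch_count + 1L else
      state$switch_count)
  list(estimate = est, state = new_state)
}

#' Run adaptive-fitting steps until the active band is stable
#'
#' Repeats [asf_step()] until a step leaves the active band unchanged or
#' `max_steps` is reached. Because the three bands are totally ordered and
#' each switch moves one band toward the dip, at most two switches (three
#' fits) ever occur in one convergence call.
#'
#' Clamped estimates at band edges are the mechanism that drives
#' switching, not the best available reading: if the final fit of a cycle
#' is clamped but an earlier fit in the same cycle produced an unclamped
#' (interior-vertex) estimate, that unclamped estimate is reported. This
#' matters for dips inside a trigger band, where the band reached last
#' may see the dip at its edge while the band passed through resolved it
#' cleanly.
#'
#' @inheritParams asf_step
#' @param max_steps Maximum number of fits, default 3.
#' @return The reported `rw_estimate`, with extra fields `state` (final
#'   [asf_state()]) and `n_fits`.
#' @export
asf_converge <- function(state, sampler, bands = band_configs(),
                         max_steps = 3L) {
  stopifnot(max_steps >= 1L)
  state$switch_count <- 0L
  est <- NULL
  best_unclamped <- NULL
  visited <- integer(0)
  for (i in seq_len(max_steps)) {
    before <- state$active_band
    visited <- c(visited, before)
    res <- asf_step(state, sampler, bands)
    est <- res$estimate
    if (!est$clamped) best_unclamped <- est
    state <- res$state
    if (state$active_band == before) break
    # a dip at a band boundary can ping-pong between the two adjacent
    # bands; stop on revisit, stay in the band that produced the last
    # fit, and let the unclamped estimate win
    if (state$active_band %in% visited) {
      state$active_band <- est$band_id
      state$switch_count <- state$switch_count - 1L
      break
    }
  }
  if (est$clamped && !is.null(best_unclamped)) est <- best_unclamped
  est$state <- state
  est$n_fits <- i
  est
}

#' Track resonance wavelengths over time for one or more ROIs
#'
#' Runs the adaptive tracker over a time-ordered table of per-ROI, per-LED
#' intensities (such as [extract_roi_series()] output). For each ROI the
#' tracker is initialized at the first time point by a five-point quartic
#' full scan ([fullscan_init()]); each subsequent time point is resolved
#' by [asf_converge()] with the ROI's band state carried forward. If a
#' ROI's estimates are clamped for more than `reinit_after` consecutive
#' time points the tracker re-acquires with a full scan. ROIs with
#' all-zero intensity at a time point are flagged missing (`NA`), never
#' fabricated.
#'
#' @param roi_series Data frame with columns `time_s`, `roi_id`,
#'   `wavelength_nm`, `intensity`: all five LED intensities per
#'   (time, ROI).
#' @param bank A [led_bank()].
#' @param bands Band list from [band_configs()].
#' @param reinit_after Consecutive-clamp count that triggers full-scan
#'   re-acquisition, default 3.
#' @return A `sensorgram` data frame with columns `time_s`, `roi_id`,
#'   `rw_nm`, `band_id`, `clamped`, one row per (time, ROI).
#' @export
asf_track <- function(roi_series, bank = led_bank(),
                      bands = band_configs(), reinit_after = 3L) {
  need <- c("time_s", "roi_id", "wavelength_nm", "intensity")
  stopifnot(all(need %in% names(roi_series)))
  out <- list()
  for (roi in unique(roi_series$roi_id)) {
    sub <- roi_series[roi_series$roi_id == roi, ]
    times <- sort(unique(sub$time_s))
    state <- NULL
    n_clamped <- 0L
    rows <- vector("list", length(times))
    for (ti in seq_along(times)) {
      pts <- sub[sub$time_s == times[ti], c("wavelength_nm", "intensity")]
      pts <- pts[order(pts$wavelength_nm), ]
      if (all(pts$intensity == 0)) {
        rows[[ti]] <- data.frame(time_s = times[ti], roi_id = roi,
                                 rw_nm = NA_real_, band_id = NA_integer_,
                                 clamped = NA)
        next
      }
      lookup <- function(led_ids) {
        idx <- match(bank$centers_nm[led_ids], pts$wavelength_nm)
        if (anyNA(idx)) stop("LED centers missing from roi_series")
        data.frame(wavelength_nm = pts$wavelength_nm[idx],
                   intensity = pts$intensity[idx])
      }
      if (is.null(state) || n_clamped > reinit_after) {
        init <- fullscan_init(lookup(seq_along(bank$centers_nm)),
                              domain_nm = range(bank$centers_nm))
        state <- asf_state(active_band = band_for_rw(init$rw_nm, bands))
        n_clamped <- 0L
      }
      est <- asf_converge(state, lookup, bands)
      state <- est$state
      n_clamped <- if (est$clamped) n_clamped + 1L else 0L
      rows[[ti]] <- data.frame(time_s = times[ti], roi_id = roi,
                               rw_nm = est$rw_nm, band_id = est$band_id,
                               clamped = est$clamped)
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("sensorgram", "data.frame"))
}
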