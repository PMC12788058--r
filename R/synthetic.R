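# Synthetic fixture generator: per-LED 2-D intensity frames over time for
# a multi-channel flow cell with prescribed per-ROI refractive-index time
# courses (staircases, 1:1 binding) and seeded noise.

#' Named rectangular regions of interest on a pixel grid
#'
#' Rectangles are 0-based, half-open `[x0, x1) x [y0, y1)` on a
#' `width x height` grid, must lie within bounds and must not overlap.
#'
#' @param rects Named list of length-4 integer vectors `c(x0, y0, x1, y1)`.
#' @param width,height Frame dimensions in pixels.
#' @return A `roi_map` object.
#' @export
roi_map <- function(rects, width, height) {
  stopifnot(is.list(rects), length(rects) >= 1L,
            !is.null(names(rects)), all(nzchar(names(rects))))
  occ <- matrix(FALSE, nrow = height, ncol = width)
  for (nm in names(rects)) {
    r <- rects[[nm]]
    stopifnot(length(r) == 4L)
    if (r[1] < 0 || r[2] < 0 || r[3] > width || r[4] > height ||
        r[3] <= r[1] || r[4] <= r[2])
      stop("ROI '", nm, "' out of bounds or empty")
    rows <- (r[2] + 1L):r[4]; cols <- (r[1] + 1L):r[3]
    if (any(occ[rows, cols])) stop("ROI '", nm, "' overlaps another ROI")
    occ[rows, cols] <- TRUE
  }
  structure(list(rects = rects, width = width, height = height),
            class = "roi_map")
}

#' Six parallel flow-cell channels as vertical ROI stripes
#'
#' Emulates a six-channel flow cell: `n_channels` equal-width stripes
#' separated by background gaps.
#'
#' @param width,height Frame size in pixels (default 96 x 64).
#' @param n_channels Number of channels, default 6.
#' @param gap_px Background gap between stripes, default 4 px.
#' @param margin_px Vertical margin at top and bottom, default 6 px.
#' @return A `roi_map` with ROIs `ch1` ... `chN`.
#' @export
six_channel_roi_map <- function(width = 96, height = 64, n_channels = 6,
                                gap_px = 4, margin_px = 6) {
  w <- (width - (n_channels + 1) * gap_px) %/% n_channels
  stopifnot(w >= 1)
  rects <- stats::setNames(lapply(seq_len(n_channels), function(i) {
    x0 <- gap_px * i + w * (i - 1)
    c(x0, margin_px, x0 + w, height - margin_px)
  }), paste0("ch", seq_len(n_channels)))
  roi_map(rects, width, height)
}

# ---- refractive-index time courses --------------------------------------

#' Refractive-index time courses for synthetic scenarios
#'
#' `course_staircase()` holds each level for `dwell_s` seconds in order;
#' `course_langmuir()` follows 1:1 binding kinetics (see
#' [langmuir_delta_ri()]); `course_constant()` is a flat offset (blank /
#' baseline channel).
#'
#' @param levels_riu Staircase levels as refractive-index offsets (RIU).
#' @param dwell_s Dwell time per staircase level, s.
#' @param kon Association rate, 1/(M s). @param koff Dissociation rate,
#'   1/s. @param conc Analyte concentration, M. @param rmax_riu Saturation
#'   response, RIU. @param t_on,t_off Association start/stop times, s.
#' @param delta_riu Constant offset, RIU.
#' @return A `ri_course` object.
#' @name ri_course
NULL

#' @rdname ri_course
#' @export
course_staircase <- function(levels_riu, dwell_s) {
  stopifnot(length(levels_riu) >= 1L, dwell_s > 0)
  structure(list(type = "staircase", levels_riu = levels_riu,
                 dwell_s = dwell_s), class = "ri_course")
}

#' @rdname ri_course
#' @export
course_langmuir <- function(kon, koff, conc, rmax_riu, t_on, t_off) {
  stopifnot(kon >= 0, koff >= 0, conc >= 0, rmax_riu >= 0, t_off >= t_on)
  if (kon == 0 && conc > 0)
    stop("degenerate kinetics: kon = 0 with conc > 0")
  structure(list(type = "langmuir", kon = kon, koff = koff, conc = conc,
                 rmax_riu = rmax_riu, t_on = t_on, t_off = t_off),
            class = "ri_course")
}

#' @rdname ri_course
#' @export
course_constant <- function(delta_riu = 0) {
  structure(list(type = "constant", delta_riu = delta_riu),
            class = "ri_course")
}

#' Refractive-index offset of a time course at time t
#'
#' For a Langmuir course the association phase follows
#' \deqn{\Delta n(t) = R_{eq} (1 - e^{-(k_{on} C + k_{off})(t - t_{on})})}
#' with \eqn{R_{eq} = R_{max} C / (C + K_D)}, \eqn{K_D = k_{off}/k_{on}},
#' and exponential dissociation at rate \eqn{k_{off}} after `t_off`
#' (continuous at `t_off`).
#'
#' @param t Time(s) in seconds, `>= 0`.
#' @param course A `ri_course`.
#' @return Refractive-index offset(s) in RIU.
#' @export
langmuir_delta_ri <- function(t, course) {
  stopifnot(inherits(course, "ri_course"), all(t >= 0))
  delta_ri_at(t, course)
}

#' Evaluate any refractive-index course at time t
#'
#' @inheritParams langmuir_delta_ri
#' @return Refractive-index offset(s) in RIU.
#' @export
delta_ri_at <- function(t, course) {
  switch(course$type,
    constant = rep(course$delta_riu, length(t)),
    staircase = {
      idx <- pmin(floor(t / course$dwell_s) + 1L,
                  length(course$levels_riu))
      course$levels_riu[pmax(idx, 1L)]
    },
    langmuir = {
      kobs <- course$kon * course$conc + course$koff
      req <- if (course$kon == 0) 0 else {
        kd <- course$koff / course$kon
        course$rmax_riu * course$conc / (course$conc + kd)
      }
      r_assoc <- function(tt) req * (1 - exp(-kobs * (tt - course$t_on)))
      out <- numeric(length(t))
      a <- t >= course$t_on & t <= course$t_off
      d <- t > course$t_off
      out[a] <- r_assoc(t[a])
      out[d] <- r_assoc(course$t_off) *
        exp(-course$koff * (t[d] - course$t_off))
      out
    },
    stop("unknown course type"))
}

#' A synthetic acquisition scenario
#'
#' Binds per-ROI refractive-index time courses to a frame-acquisition
#' protocol and noise model. `noise_sd` is additive per-pixel Gaussian
#' noise in reflectance units; its default (2e-3) was fixed so that the
#' tracked baseline RMS of a default six-channel ROI is about 0.014 nm.
#'
#' @param courses Named list of `ri_course` objects, one per ROI (names
#'   must match the ROI map).
#' @param frame_rate_s Time between frames, s (default 1).
#' @param duration_s Total duration, s.
#' @param base_ri Baseline analyte refractive index, default 1.333.
#' @param noise_sd Per-pixel additive reflectance noise sd, default 2e-3.
#' @param seed Integer seed making every rendering reproducible.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(courses, frame_rate_s = 1, duration_s,
                          base_ri = 1.333, noise_sd = 2e-3, seed = 1L) {
  stopifnot(is.list(courses), !is.null(names(courses)),
            all(vapply(courses, inherits, logical(1), "ri_course")),
            frame_rate_s > 0, duration_s >= frame_rate_s, noise_sd >= 0)
  structure(list(courses = courses, frame_rate_s = frame_rate_s,
                 duration_s = duration_s, base_ri = base_ri,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Render per-LED frames for a scenario
#'
#' For every frame time and LED, pixels inside ROI `r` take the stack's
#' reflectance with the analyte index `base_ri + delta_n_r(t)` at that
#' LED's center wavelength; background pixels take a fixed non-resonant
#' level (0.85). Per-pixel Gaussian noise (sd `scenario$noise_sd`,
#' reflectance units) is added, values are clamped to `[0, 1]` and
#' quantized to the bit depth with round-half-even. Rendering is
#' deterministic under the scenario seed.
#'
#' @param scenario A [scenario_spec()].
#' @param stack A [layer_stack()].
#' @param bank A [led_bank()].
#' @param rois A [roi_map()]; its names must cover the scenario courses.
#' @param angle_deg Incidence angle; defaults to the stack's.
#' @param bit_depth Bits per pixel, default 16.
#' @param background Background reflectance level, default 0.85.
#' @return A `frame_stack`: list with `data` (integer array
#'   `[height, width, n_led, n_time]`), `led_centers_nm`, `times_s`,
#'   `bit_depth`, `seed`, `base_ri`, `angle_deg`.
#' @export
render_frames <- function(scenario, stack = default_spr_stack(),
                          bank = led_bank(), rois,
                          angle_deg = stack$incident_angle_deg,
                          bit_depth = 16L, background = 0.85) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(rois, "roi_map"),
            all(names(scenario$courses) %in% names(rois$rects)))
  times <- seq(0, scenario$duration_s, by = scenario$frame_rate_s)
  nl <- length(bank$centers_nm)
  full <- 2^bit_depth - 1
  H <- rois$height; W <- rois$width
  arr <- array(0L, dim = c(H, W, nl, length(times)))
  .with_seed(scenario$seed, {
    for (ti in seq_along(times)) {
      # per-ROI reflectance at each LED for this frame time
      refl <- lapply(names(scenario$courses), function(nm) {
        dn <- delta_ri_at(times[ti], scenario$courses[[nm]])
        st <- set_analyte_ri(stack, scenario$base_ri + dn)
        rp_multilayer(st, bank$centers_nm, angle_deg)
      })
      names(refl) <- names(scenario$courses)
      for (li in seq_len(nl)) {
        fr <- matrix(background, nrow = H, ncol = W)
        for (nm in names(scenario$courses)) {
          r <- rois$rects[[nm]]
          fr[(r[2] + 1L):r[4], (r[1] + 1L):r[3]] <- refl[[nm]][li]
        }
        if (scenario$noise_sd > 0)
          fr <- fr + matrix(stats::rnorm(H * W, 0, scenario$noise_sd),
                            nrow = H, ncol = W)
        fr <- pmin(pmax(fr, 0), 1)
        arr[, , li, ti] <- as.integer(round(fr * full))
      }
    }
  })
  structure(list(data = arr, led_centers_nm = bank$centers_nm,
                 times_s = times, bit_depth = bit_depth,
                 seed = scenario$seed, base_ri = scenario$base_ri,
                 angle_deg = angle_deg),
            class = "frame_stack")
}

#' Mean ROI intensities per LED over time
#'
#' Averages pixel intensities over each ROI for every (time, LED) and
#' rescales to reflectance units (`/ (2^bit_depth - 1)`). Optional
#' per-LED flat-field normalization divides each (ROI, LED) trace by its
#' value at the first frame, cancelling unequal LED powers.
#'
#' @param frames A `frame_stack` from [render_frames()] or
#'   [read_frame_stack()].
#' @param rois A [roi_map()] (must fit within the frame bounds).
#' @param normalize `"none"` (default) or `"first_frame"`.
#' @return Long data frame with columns `time_s`, `roi_id`,
#'   `wavelength_nm`, `intensity`.
#' @export
extract_roi_series <- function(frames, rois,
                               normalize = c("none", "first_frame")) {
  normalize <- match.arg(normalize)
  d <- dim(frames$data)
  stopifnot(rois$height <= d[1], rois$width <= d[2])
  full <- 2^frames$bit_depth - 1
  out <- list()
  for (nm in names(rois$rects)) {
    r <- rois$rects[[nm]]
    if (r[3] <= r[1] || r[4] <= r[2]) stop("empty ROI: ", nm)
    rows <- (r[2] + 1L):r[4]; cols <- (r[1] + 1L):r[3]
    m <- apply(frames$data[rows, cols, , , drop = FALSE], c(3, 4), mean) /
      full                              # [led, time]
    if (normalize == "first_frame") {
      ref <- m[, 1]
      if (any(ref == 0)) stop("flat-field reference frame has zero mean")
      m <- m / ref
    }
    out[[nm]] <- data.frame(
      time_s = rep(frames$times_s, each = length(frames$led_centers_nm)),
      roi_id = nm,
      wavelength_nm = rep(frames$led_centers_nm, length(frames$times_s)),
      intensity = as.vector(m))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a frame stack as multi-page 16-bit TIFFs plus metadata
#'
#' One multi-page TIFF per LED (pages = time points) and a
#' `metadata.yaml` sidecar recording LED centers, times, bit depth and
#' seed.
#'
#' @param frames A `frame_stack`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- 2^frames$bit_depth - 1
  for (li in seq_along(frames$led_centers_nm)) {
    pages <- lapply(seq_along(frames$times_s), function(ti)
      frames$data[, , li, ti] / full)
    tiff::writeTIFF(pages,
                    file.path(dir, sprintf("led%d.tif", li)),
                    bits.per.sample = 16L)
  }
  meta <- list(led_centers_nm = frames$led_centers_nm,
               times_s = frames$times_s,
               bit_depth = frames$bit_depth, seed = frames$seed,
               base_ri = frames$base_ri, angle_deg = frames$angle_deg)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param dir Directory holding `led*.tif` and `metadata.yaml`.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  full <- 2^meta$bit_depth - 1
  nl <- length(meta$led_centers_nm)
  nt <- length(meta$times_s)
  arr <- NULL
  for (li in seq_len(nl)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("led%d.tif", li)),
                            all = TRUE)
    if (is.null(arr))
      arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), nl, nt))
    for (ti in seq_len(nt))
      arr[, , li, ti] <- as.integer(round(pages[[ti]] * full))
  }
  structure(list(data = arr,
                 led_centers_nm = as.numeric(meta$led_centers_nm),
                 times_s = as.numeric(meta$times_s),
                 bit_depth = meta$bit_depth, seed = meta$seed,
                 base_ri = meta$base_ri, angle_deg = meta$angle_deg),
            class = "frame_stack")
}
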