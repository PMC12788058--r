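# Dispersion models for the optical media in the sensing stack.
#
# Field convention: time dependence exp(-i*omega*t), so passive media have
# Im(eps) >= 0 and the complex index is n + i*k with k >= 0.

#' Constant (wavelength-independent) refractive index
#'
#' @param n Real refractive index, `n >= 0`.
#' @param k Extinction coefficient, `k >= 0` (default 0, lossless).
#' @return A `dispersion` object of variant `"constant"`.
#' @examples
#' water <- dispersion_constant(1.333)
#' permittivity(water, 750)
#' @export
dispersion_constant <- function(n, k = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(k), length(k) == 1L, k >= 0)
  structure(list(variant = "constant", n = n, k = k),
            class = c("dispersion_constant", "dispersion"))
}

#' Tabulated (wavelength, n, k) dispersion with linear interpolation
#'
#' Optical constants are interpolated linearly in wavelength between table
#' rows. Requests outside the tabulated support are an error: no
#' extrapolation is performed.
#'
#' @param wavelength_nm Strictly ascending wavelengths in nm.
#' @param n,k Real and imaginary parts of the complex index at each row,
#'   both `>= 0`.
#' @return A `dispersion` object of variant `"tabulated"`.
#' @export
dispersion_table <- function(wavelength_nm, n, k) {
  stopifnot(length(wavelength_nm) >= 2L,
            length(n) == length(wavelength_nm),
            length(k) == length(wavelength_nm))
  if (any(diff(wavelength_nm) <= 0))
    stop("tabulated wavelengths must be strictly ascending")
  if (any(n < 0) || any(k < 0))
    stop("tabulated n and k must be non-negative (passive medium)")
  structure(list(variant = "tabulated",
                 wavelength_nm = as.numeric(wavelength_nm),
                 n = as.numeric(n), k = as.numeric(k)),
            class = c("dispersion_table", "dispersion"))
}

#' Read a 3-column dispersion table from delimited text
#'
#' Expects whitespace/tab-delimited columns `wavelength_nm`, `n`, `k`;
#' lines starting with `#` are comments.
#'
#' @param path Path to the table file.
#' @return A `dispersion` object of variant `"tabulated"`.
#' @export
read_dispersion_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  need <- c("wavelength_nm", "n", "k")
  if (!all(need %in% names(tab)))
    stop("dispersion table must have columns wavelength_nm, n, k: ", path)
  dispersion_table(tab$wavelength_nm, tab$n, tab$k)
}

#' Drude-Lorentz analytic permittivity model
#'
#' \deqn{\varepsilon(E) = \varepsilon_\infty
#'   - \frac{f_0 E_p^2}{E^2 + i \Gamma_0 E}
#'   + \sum_j \frac{f_j E_p^2}{E_j^2 - E^2 - i \Gamma_j E}}
#' with photon energy \eqn{E} in eV. Under the exp(-i\eqn{\omega}t)
#' convention this yields Im(\eqn{\varepsilon}) >= 0 for positive damping.
#'
#' @param eps_inf High-frequency permittivity offset.
#' @param plasma_energy_ev Plasma energy \eqn{E_p} in eV.
#' @param f0,gamma0_ev Drude oscillator strength and damping (eV).
#' @param oscillators Optional data frame with columns `f`, `gamma_ev`,
#'   `energy_ev` for bound (Lorentz) oscillators.
#' @return A `dispersion` object of variant `"drude_lorentz"`.
#' @export
dispersion_drude_lorentz <- function(eps_inf = 1, plasma_energy_ev,
                                     f0 = 1, gamma0_ev,
                                     oscillators = NULL) {
  stopifnot(plasma_energy_ev > 0, gamma0_ev >= 0, f0 >= 0)
  if (!is.null(oscillators))
    stopifnot(all(c("f", "gamma_ev", "energy_ev") %in% names(oscillators)))
  structure(list(variant = "drude_lorentz", eps_inf = eps_inf,
                 plasma_energy_ev = plasma_energy_ev, f0 = f0,
                 gamma0_ev = gamma0_ev, oscillators = oscillators),
            class = c("dispersion_drude_lorentz", "dispersion"))
}

#' Complex relative permittivity of a medium at given wavelengths
#'
#' Returns \eqn{\varepsilon = (n + ik)^2} under the exp(-i\eqn{\omega}t)
#' sign convention, so Im(\eqn{\varepsilon}) >= 0 for passive media.
#'
#' @param model A `dispersion` object.
#' @param wavelength_nm Vacuum wavelength(s) in nm.
#' @return Complex vector of permittivities, one per wavelength.
#' @export
permittivity <- function(model, wavelength_nm) {
  UseMethod("permittivity")
}

#' @export
permittivity.dispersion_constant <- function(model, wavelength_nm) {
  eps <- complex(real = model$n, imaginary = model$k)^2
  rep(eps, length(wavelength_nm))
}

#' @export
permittivity.dispersion_table <- function(model, wavelength_nm) {
  rng <- range(model$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf(
      "wavelength outside tabulated support [%.2f, %.2f] nm (no extrapolation)",
      rng[1], rng[2]))
  n <- stats::approx(model$wavelength_nm, model$n, xout = wavelength_nm)$y
  k <- stats::approx(model$wavelength_nm, model$k, xout = wavelength_nm)$y
  complex(real = n, imaginary = k)^2
}

#' @export
permittivity.dispersion_drude_lorentz <- function(model, wavelength_nm) {
  ev <- 1239.84193 / wavelength_nm
  ep2 <- model$plasma_energy_ev^2
  eps <- model$eps_inf -
    model$f0 * ep2 / (ev^2 + 1i * model$gamma0_ev * ev)
  if (!is.null(model$oscillators)) {
    for (j in seq_len(nrow(model$oscillators))) {
      o <- model$oscillators[j, ]
      eps <- eps + o$f * ep2 / (o$energy_ev^2 - ev^2 - 1i * o$gamma_ev * ev)
    }
  }
  eps
}

#' Complex refractive index n + ik at given wavelengths
#'
#' Principal square root of the permittivity, branch chosen so that
#' Im(n + ik) >= 0 (decaying wave in a passive medium).
#'
#' @inheritParams permittivity
#' @return Complex vector of refractive indices.
#' @export
refractive_index <- function(model, wavelength_nm) {
  m <- sqrt(permittivity(model, wavelength_nm))
  ifelse(Im(m) < 0, -m, m)
}

# ---- Built-in material models -------------------------------------------

#' Built-in material dispersion models
#'
#' `gold_table()` loads the packaged tabulated gold optical constants
#' (Johnson-Christy-style n, k table, 413-1937 nm).
#' `gold_drude_lorentz()` returns an analytic Drude-Lorentz gold model
#' (Rakic-style parameterization, plasma energy 9.03 eV, Drude term plus
#' five bound oscillators). `chromium_table()` loads the packaged synthetic
#' chromium table (representative NIR values for the thin adhesion layer).
#' `sf11_sellmeier()` evaluates the Schott SF11 Sellmeier dispersion and
#' returns it as a finely tabulated model over 400-1200 nm.
#'
#' @return A `dispersion` object.
#' @name builtin_materials
NULL

#' @rdname builtin_materials
#' @export
gold_table <- function() {
  read_dispersion_table(
    system.file("extdata", "gold_jc.tsv", package = "wsprsim",
                mustWork = TRUE))
}

#' @rdname builtin_materials
#' @export
gold_drude_lorentz <- function() {
  dispersion_drude_lorentz(
    eps_inf = 1, plasma_energy_ev = 9.03,
    f0 = 0.760, gamma0_ev = 0.053,
    oscillators = data.frame(
      f        = c(0.024, 0.010, 0.071, 0.601, 4.384),
      gamma_ev = c(0.241, 0.345, 0.870, 2.494, 2.214),
      energy_ev = c(0.415, 0.830, 2.969, 4.304, 13.32)))
}

#' @rdname builtin_materials
#' @export
chromium_table <- function() {
  read_dispersion_table(
    system.file("extdata", "chromium_synthetic.tsv", package = "wsprsim",
                mustWork = TRUE))
}

#' @rdname builtin_materials
#' @export
sf11_sellmeier <- function() {
  lam_um <- seq(0.40, 1.20, by = 0.005)
  l2 <- lam_um^2
  n2 <- 1 +
    1.73759695 * l2 / (l2 - 0.013188707) +
    0.313747346 * l2 / (l2 - 0.0623068142) +
    1.89878101 * l2 / (l2 - 155.23629)
  dispersion_table(lam_um * 1000, sqrt(n2), rep(0, length(l2)))
}

#' Resolve a built-in material model by name
#'
#' @param name One of `"gold_jc"`, `"gold_drude_lorentz"`,
#'   `"chromium_synthetic"`, `"sf11"`.
#' @return A `dispersion` object.
#' @export
builtin_dispersion <- function(name) {
  switch(name,
         gold_jc = gold_table(),
         gold_drude_lorentz = gold_drude_lorentz(),
         chromium_synthetic = chromium_table(),
         sf11 = sf11_sellmeier(),
         stop("unknown built-in dispersion model: ", name))
}
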