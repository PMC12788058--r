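# p-polarized reflectance of a dispersive multilayer in the Kretschmann
# configuration, via the characteristic (transfer) matrix method.
#
# Branch choice: exp(-i*omega*t) time dependence, so the decaying-wave
# branch has Im(kz) >= 0; for lossless propagating waves Re(kz) >= 0.

# kz for one layer, vectorized over wavelength. eps: complex vector,
# k0, kx: real vectors (rad/nm).
.kz_layer <- function(eps, k0, kx) {
  kz <- sqrt(eps * k0^2 - kx^2 + 0i)
  flip <- Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

#' p-polarized reflectance of a multilayer stack
#'
#' Computes \eqn{|r_p|^2} by the characteristic-matrix method for the full
#' stack, vectorized over wavelength. The in-plane wave vector is
#' \eqn{k_x = (2\pi/\lambda)\, n_p(\lambda) \sin\theta} with \eqn{n_p} the
#' (real part of the) incidence-medium index.
#'
#' @param stack A [layer_stack()].
#' @param wavelength_nm Vacuum wavelength(s) in nm.
#' @param angle_deg Incidence angle in degrees; defaults to the stack's.
#' @return Reflectance value(s) in `[0, 1]` for passive media.
#' @examples
#' st <- default_spr_stack()
#' rp_multilayer(st, c(730, 756, 805))
#' @export
rp_multilayer <- function(stack, wavelength_nm,
                          angle_deg = stack$incident_angle_deg) {
  stopifnot(inherits(stack, "layer_stack"),
            angle_deg > 0, angle_deg < 90)
  if (length(wavelength_nm) == 0L) return(numeric(0))
  lam <- as.numeric(wavelength_nm)
  theta <- angle_deg * pi / 180
  k0 <- 2 * pi / lam

  eps <- lapply(stack$layers,
                function(l) permittivity(l$dispersion, lam))
  if (any(!vapply(eps, function(e) all(is.finite(e)), logical(1))))
    stop("non-finite permittivity at requested wavelength")

  n1 <- Re(sqrt(eps[[1]]))
  kx <- k0 * n1 * sin(theta)

  nlay <- length(stack$layers)
  kz1 <- .kz_layer(eps[[1]], k0, kx)
  kzN <- .kz_layer(eps[[nlay]], k0, kx)
  q1 <- kz1 / eps[[1]]
  qN <- kzN / eps[[nlay]]

  # characteristic matrix product over interior layers
  m11 <- m22 <- rep(1 + 0i, length(lam))
  m12 <- m21 <- rep(0 + 0i, length(lam))
  if (nlay > 2L) {
    for (j in 2:(nlay - 1L)) {
      kz <- .kz_layer(eps[[j]], k0, kx)
      q <- kz / eps[[j]]
      d <- kz * stack$layers[[j]]$thickness_nm
      cd <- cos(d); sd <- sin(d)
      a11 <- cd;            a12 <- -1i * sd / q
      a21 <- -1i * q * sd;  a22 <- cd
      t11 <- m11 * a11 + m12 * a21
      t12 <- m11 * a12 + m12 * a22
      t21 <- m21 * a11 + m22 * a21
      t22 <- m21 * a12 + m22 * a22
      m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
    }
  }
  num <- q1 * (m11 + m12 * qN) - (m21 + m22 * qN)
  den <- q1 * (m11 + m12 * qN) + (m21 + m22 * qN)
  r <- num / den
  R <- Mod(r)^2
  # guard against tiny floating excursions above 1 for lossless TIR
  pmin(pmax(R, 0), 1 + 1e-12)
}

#' Reflectance spectrum over a wavelength grid
#'
#' @param stack A [layer_stack()].
#' @param wavelengths_nm Ascending vacuum wavelengths in nm.
#' @param angle_deg Incidence angle in degrees; defaults to the stack's.
#' @return A data frame of class `reflectance_spectrum` with columns
#'   `wavelength_nm` and `rp`.
#' @export
spr_spectrum <- function(stack, wavelengths_nm,
                         angle_deg = stack$incident_angle_deg) {
  if (length(wavelengths_nm) > 1L && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly ascending")
  rp <- rp_multilayer(stack, wavelengths_nm, angle_deg)
  structure(data.frame(wavelength_nm = as.numeric(wavelengths_nm), rp = rp),
            class = c("reflectance_spectrum", "data.frame"))
}

#' True resonance wavelength by dense-grid minimum search
#'
#' Locates the reflectance minimum (the SPR dip) on a dense wavelength
#' grid and refines it by 3-point parabolic interpolation of the samples
#' bracketing the grid argmin. Ties on the grid break toward the smaller
#' wavelength. A minimum on the range boundary is an error (the dip lies
#' outside the search range).
#'
#' @param stack A [layer_stack()].
#' @param angle_deg Incidence angle in degrees; defaults to the stack's.
#' @param search_range_nm Length-2 interval to search, default c(730, 805).
#' @param grid_step_nm Grid step in nm, default 0.01.
#' @return The resonance wavelength in nm.
#' @export
true_rw <- function(stack, angle_deg = stack$incident_angle_deg,
                    search_range_nm = c(730, 805), grid_step_nm = 0.01) {
  stopifnot(length(search_range_nm) == 2L,
            search_range_nm[2] > search_range_nm[1], grid_step_nm > 0)
  grid <- seq(search_range_nm[1], search_range_nm[2], by = grid_step_nm)
  R <- rp_multilayer(stack, grid, angle_deg)
  i <- which.min(R)
  if (i == 1L || i == length(grid))
    stop("reflectance minimum on search-range boundary: dip outside range")
  # parabolic refinement through the three bracketing samples
  y1 <- R[i - 1L]; y2 <- R[i]; y3 <- R[i + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom > 0) 0.5 * (y1 - y3) / denom else 0
  grid[i] + delta * grid_step_nm
}

#' Surface-plasmon resonance-condition residual
#'
#' Diagnostic for the matching condition \eqn{k_{SP} \approx k_x}:
#' \deqn{k_{SP} = \frac{2\pi}{\lambda}
#'   \sqrt{\frac{\varepsilon_m \varepsilon_d}
#'              {\varepsilon_m + \varepsilon_d}}, \qquad
#'   k_x = \frac{2\pi}{\lambda} n_p \sin\theta}
#' with \eqn{\varepsilon_m} the gold layer's permittivity and
#' \eqn{\varepsilon_d} the analyte's. Returns
#' \eqn{|\mathrm{Re}(k_{SP}) - k_x|} in rad/nm.
#'
#' @param stack A [layer_stack()] containing a layer named `"gold"` (or,
#'   failing that, any interior layer with negative real permittivity).
#' @param wavelength_nm Vacuum wavelength in nm (vectorized).
#' @param angle_deg Incidence angle in degrees; defaults to the stack's.
#' @return Non-negative residual(s) in rad/nm.
#' @export
resonance_residual <- function(stack, wavelength_nm,
                               angle_deg = stack$incident_angle_deg) {
  lam <- as.numeric(wavelength_nm)
  names_ <- vapply(stack$layers, function(l) l$name, character(1))
  im <- which(names_ == "gold")
  if (length(im) == 0L) {
    # fall back: interior metal-like layer (Re(eps) < 0 at the midpoint)
    interior <- setdiff(seq_along(stack$layers),
                        c(1L, length(stack$layers)))
    re_eps <- vapply(interior, function(j)
      Re(permittivity(stack$layers[[j]]$dispersion, stats::median(lam))),
      numeric(1))
    im <- interior[which(re_eps < 0)]
    if (length(im) == 0L) stop("no metal layer found in stack")
  }
  eps_m <- permittivity(stack$layers[[im[1]]]$dispersion, lam)
  eps_d <- permittivity(stack$layers[[length(stack$layers)]]$dispersion, lam)
  if (any(Mod(eps_m + eps_d) < 1e-9))
    stop("singular configuration: eps_m + eps_d ~ 0 (pole of k_SP)")
  k0 <- 2 * pi / lam
  ksp <- k0 * sqrt(eps_m * eps_d / (eps_m + eps_d))
  np <- Re(sqrt(permittivity(stack$layers[[1]]$dispersion, lam)))
  kx <- k0 * np * sin(angle_deg * pi / 180)
  abs(Re(ksp) - kx)
}
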