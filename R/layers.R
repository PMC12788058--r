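# Optical layer stacks for the Kretschmann configuration:
# incidence medium (prism) first, analyte last; interior layers finite.

#' Marker for a semi-infinite layer thickness
#' @export
SEMI_INFINITE <- Inf

#' A single optical layer
#'
#' @param name Layer name (informational; `"gold"` and `"analyte"` are
#'   recognized by [resonance_residual()]).
#' @param thickness_nm Positive finite thickness in nm, or [SEMI_INFINITE]
#'   for the bounding media.
#' @param dispersion A `dispersion` object for the layer material.
#' @return An `optical_layer` object.
#' @export
optical_layer <- function(name, thickness_nm, dispersion) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(dispersion, "dispersion"))
  if (!is.infinite(thickness_nm) && thickness_nm <= 0)
    stop("layer thickness must be > 0 nm or SEMI_INFINITE")
  structure(list(name = name, thickness_nm = thickness_nm,
                 dispersion = dispersion),
            class = "optical_layer")
}

#' An ordered multilayer stack with a fixed incidence angle
#'
#' Layers are ordered from the incidence medium (prism) to the final
#' medium (analyte). The first and last layers must be semi-infinite and
#' all interior layers finite.
#'
#' @param layers List of [optical_layer()] objects, length >= 2.
#' @param incident_angle_deg Internal incidence angle at the prism base,
#'   in degrees, strictly between 0 and 90.
#' @return A `layer_stack` object.
#' @export
layer_stack <- function(layers, incident_angle_deg) {
  stopifnot(is.list(layers), length(layers) >= 2L,
            all(vapply(layers, inherits, logical(1), "optical_layer")),
            is.numeric(incident_angle_deg),
            incident_angle_deg > 0, incident_angle_deg < 90)
  thick <- vapply(layers, function(l) l$thickness_nm, numeric(1))
  n <- length(layers)
  if (!is.infinite(thick[1]) || !is.infinite(thick[n]))
    stop("first and last layers must be semi-infinite")
  if (n > 2L && any(is.infinite(thick[-c(1L, n)])))
    stop("interior layers must have finite thickness")
  structure(list(layers = layers,
                 incident_angle_deg = incident_angle_deg),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, incidence %.2f deg\n",
              length(x$layers), x$incident_angle_deg))
  for (l in x$layers) {
    th <- if (is.infinite(l$thickness_nm)) "semi-inf"
          else sprintf("%.1f nm", l$thickness_nm)
    cat(sprintf("  %-10s %-9s [%s]\n", l$name, th, l$dispersion$variant))
  }
  invisible(x)
}

#' Default prism / Cr / Au / analyte sensing stack
#'
#' SF11-type prism (constant n = 1.785 by default), optional 2 nm chromium
#' adhesion layer, 48 nm gold film, aqueous analyte. Incidence angle
#' defaults to 51.2 degrees.
#'
#' @param analyte_n Analyte refractive index (RIU), default 1.333 (water).
#' @param incident_angle_deg Internal incidence angle, default 51.2.
#' @param gold Dispersion model for gold; default [gold_table()].
#' @param gold_thickness_nm Gold film thickness, default 48 nm.
#' @param include_cr Include the 2 nm chromium adhesion layer? Default TRUE.
#' @param cr_thickness_nm Chromium thickness, default 2 nm.
#' @param prism Dispersion model for the prism; default constant 1.785.
#' @return A `layer_stack`.
#' @export
default_spr_stack <- function(analyte_n = 1.333,
                              incident_angle_deg = 51.2,
                              gold = gold_table(),
                              gold_thickness_nm = 48,
                              include_cr = TRUE,
                              cr_thickness_nm = 2,
                              prism = dispersion_constant(1.785)) {
  layers <- list(optical_layer("prism", SEMI_INFINITE, prism))
  if (include_cr)
    layers <- c(layers, list(
      optical_layer("chromium", cr_thickness_nm, chromium_table())))
  layers <- c(layers, list(
    optical_layer("gold", gold_thickness_nm, gold),
    optical_layer("analyte", SEMI_INFINITE,
                  dispersion_constant(analyte_n))))
  layer_stack(layers, incident_angle_deg)
}

#' Bare gold-coated chip stack (no adhesion layer)
#'
#' Prism / 48 nm gold / analyte, the configuration of the
#' algorithm-validation simulation: a gold-coated sensing chip with no
#' chromium adhesion layer.
#'
#' @inheritParams default_spr_stack
#' @return A `layer_stack`.
#' @export
gold_chip_stack <- function(analyte_n = 1.333, incident_angle_deg = 51.2,
                            gold = gold_table(), gold_thickness_nm = 48,
                            prism = dispersion_constant(1.785)) {
  default_spr_stack(analyte_n = analyte_n,
                    incident_angle_deg = incident_angle_deg,
                    gold = gold, gold_thickness_nm = gold_thickness_nm,
                    include_cr = FALSE, prism = prism)
}

#' Replace the analyte refractive index of a stack
#'
#' Returns a copy of `stack` whose final (analyte) layer has constant
#' refractive index `n`.
#'
#' @param stack A `layer_stack`.
#' @param n New analyte refractive index (RIU).
#' @param k Analyte extinction coefficient, default 0.
#' @return A `layer_stack`.
#' @export
set_analyte_ri <- function(stack, n, k = 0) {
  i <- length(stack$layers)
  stack$layers[[i]]$dispersion <- dispersion_constant(n, k)
  stack
}
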