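# Independent oracles and shared fixtures for the test suite.

# Recursive single-interface Fresnel cascade for p-polarization.
# Independent of the characteristic-matrix implementation: combines
# interface coefficients bottom-up with phase factors.
fresnel_rp_cascade <- function(stack, wavelength_nm, angle_deg) {
  lam <- wavelength_nm
  theta <- angle_deg * pi / 180
  eps <- lapply(stack$layers, function(l) permittivity(l$dispersion, lam))
  k0 <- 2 * pi / lam
  kx <- k0 * Re(sqrt(eps[[1]])) * sin(theta)
  kz <- lapply(eps, function(e) {
    z <- sqrt(e * k0^2 - kx^2 + 0i)
    if (Im(z) < 0 || (Im(z) == 0 && Re(z) < 0)) z <- -z
    z
  })
  n <- length(eps)
  r_if <- function(j) {  # interface j | j+1, p-polarization
    (eps[[j + 1]] * kz[[j]] - eps[[j]] * kz[[j + 1]]) /
      (eps[[j + 1]] * kz[[j]] + eps[[j]] * kz[[j + 1]])
  }
  r <- r_if(n - 1)
  if (n > 2) {
    for (j in (n - 2):1) {
      ph <- exp(2i * kz[[j + 1]] * stack$layers[[j + 1]]$thickness_nm)
      r <- (r_if(j) + r * ph) / (1 + r_if(j) * r * ph)
    }
  }
  Mod(r)^2
}

# random passive stack for property tests
random_stack <- function() {
  mats <- list(
    function() dispersion_constant(runif(1, 0.2, 4), runif(1, 0, 5)),
    function() gold_table(),
    function() chromium_table())
  n_int <- sample(0:3, 1)
  layers <- list(optical_layer("inc", SEMI_INFINITE,
                               dispersion_constant(runif(1, 1.4, 1.9))))
  for (j in seq_len(n_int)) {
    layers <- c(layers, list(optical_layer(
      paste0("L", j), runif(1, 1, 60), mats[[sample(3, 1)]]())))
  }
  layers <- c(layers, list(optical_layer(
    "analyte", SEMI_INFINITE, dispersion_constant(runif(1, 1.30, 1.42)))))
  layer_stack(layers, runif(1, 15, 85))
}

# brute-force dense-grid argmin of the reflectance (no parabolic refine)
brute_rw <- function(stack, angle_deg, range_nm, step_nm = 0.001) {
  grid <- seq(range_nm[1], range_nm[2], by = step_nm)
  grid[which.min(rp_multilayer(stack, grid, angle_deg))]
}

# replication fixtures, solved once per test run
.fixture_env <- new.env()
chip_stack <- function() {
  if (is.null(.fixture_env$stack)) .fixture_env$stack <- gold_chip_stack()
  .fixture_env$stack
}
chip_angle <- function() {
  if (is.null(.fixture_env$angle))
    .fixture_env$angle <- solve_init_angle(chip_stack())
  .fixture_env$angle
}

# analyte RI placing the dense-grid dip of `stack` at `target` nm
ri_for_dip <- function(stack, angle, target, bracket = c(1.31, 1.36)) {
  f <- function(n) {
    v <- tryCatch(true_rw(set_analyte_ri(stack, n), angle,
                          search_range_nm = c(640, 1000),
                          grid_step_nm = 0.02),
                  error = function(e) NA_real_)
    if (is.na(v)) 500 else v - target
  }
  stats::uniroot(f, bracket, tol = 1e-10)$root
}

# noise-free sampler over a stack's spectrum at the LED centers
chip_sampler <- function(stack, angle, bank = led_bank()) {
  function(led_ids)
    sample_leds(function(l) rp_multilayer(stack, l, angle), bank, led_ids)
}
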