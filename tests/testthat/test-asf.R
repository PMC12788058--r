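mk_pts <- function(x, y) data.frame(wavelength_nm = x, intensity = y)

test_that("quadratic_rw recovers generating-parabola vertices exactly", {
  pts <- mk_pts(c(730, 740, 756), 0.1 + 2e-4 * (c(730, 740, 756) - 750)^2)
  est <- quadratic_rw(pts, c(730, 756))
  expect_equal(est$rw_nm, 750)
  expect_false(est$clamped)

  set.seed(31)
  for (i in 1:100) {
    a <- runif(1, 1e-5, 1e-2)
    v <- runif(1, 741, 776)
    c0 <- runif(1, 0, 0.3)
    x <- c(740, 756, 777)
    est <- quadratic_rw(mk_pts(x, c0 + a * (x - v)^2), c(740, 777))
    expect_lt(abs(est$rw_nm - v), 1e-9)
    expect_false(est$clamped)
  }
})

test_that("a dip beyond the triple's span clamps to the band edge", {
  # band-1 samples of a spectrum whose dip lies at 783 nm: intensities
  # strictly decreasing, vertex beyond the span -> clamp at 756
  st <- set_analyte_ri(chip_stack(), ri_for_dip(chip_stack(), chip_angle(), 783))
  pts <- chip_sampler(st, chip_angle())(1:3)
  expect_true(all(diff(pts$intensity) < 0))
  est <- quadratic_rw(pts, c(730, 756))
  expect_equal(est$rw_nm, 756)
  expect_true(est$clamped)
})

test_that("degenerate quadratic fits clamp toward the lower-intensity end", {
  # collinear decreasing
  x <- c(740, 756, 777)
  est <- quadratic_rw(mk_pts(x, 0.5 - 0.004 * (x - 740)), c(740, 777))
  expect_true(est$degenerate)
  expect_true(est$clamped)
  expect_equal(est$rw_nm, 777)
  # collinear increasing
  est2 <- quadratic_rw(mk_pts(x, 0.3 + 0.004 * (x - 740)), c(740, 777))
  expect_equal(est2$rw_nm, 740)
  # inverted parabola
  est3 <- quadratic_rw(mk_pts(x, 0.5 - 1e-4 * (x - 758)^2), c(740, 777))
  expect_true(est3$clamped)
  expect_error(quadratic_rw(mk_pts(c(740, 740, 777), 1:3), c(740, 777)),
               "duplicate")
})

test_that("fullscan_init reproduces generating polynomials", {
  x <- c(730, 740, 756, 777, 805)
  # quartic with zero cubic/quartic terms: parabola with vertex 770
  est <- fullscan_init(mk_pts(x, 0.2 + 1e-4 * (x - 770)^2))
  expect_equal(est$rw_nm, 770, tolerance = 1e-9)
  expect_false(est$clamped)
  # strictly decreasing intensities: clamp at the red end
  est2 <- fullscan_init(mk_pts(x, seq(0.9, 0.1, length.out = 5)))
  expect_equal(est2$rw_nm, 805)
  expect_true(est2$clamped)
  expect_error(fullscan_init(mk_pts(c(730, 730, 756, 777, 805), 1:5)),
               "duplicate")
})

test_that("fullscan_init matches a dense-grid search of its own interpolant", {
  st <- chip_stack()
  pts <- chip_sampler(st, chip_angle())(1:5)
  est <- fullscan_init(pts)
  # dense-grid oracle: evaluate the exact interpolant through the five
  # points by the Lagrange basis (independent of the solver path)
  x <- pts$wavelength_nm; y <- pts$intensity
  grid <- seq(730, 805, by = 0.001)
  vals <- rowSums(vapply(seq_along(x), function(j) {
    others <- x[-j]
    y[j] * Reduce(`*`, lapply(others, function(o)
      (grid - o) / (x[j] - o)))
  }, numeric(length(grid))))
  expect_lt(abs(est$rw_nm - grid[which.min(vals)]), 0.01)
})

test_that("random generating quartics with interior minima are recovered", {
  set.seed(17)
  x <- c(730, 740, 756, 777, 805)
  grid <- seq(730, 805, by = 0.001)
  G <- outer(grid, 0:4, `^`)
  for (i in 1:25) {
    co <- c(runif(1, 0, 1), rnorm(3) * c(1e-2, 1e-4, 1e-6), runif(1, 1e-9, 1e-7))
    y <- drop(outer(x, 0:4, `^`) %*% co)
    est <- fullscan_init(mk_pts(x, y))
    oracle <- grid[which.min(drop(G %*% co))]
    if (!est$clamped) expect_lt(abs(est$rw_nm - oracle), 0.01)
    else expect_true(oracle %in% c(730, 805) ||
                       abs(est$rw_nm - oracle) < 0.01)
  }
})

test_that("asf_step stays put for in-band dips and switches on the thresholds", {
  st <- chip_stack(); th <- chip_angle()
  bands <- band_configs()
  # in-band case: dip at 735, tracker in band 1
  s735 <- set_analyte_ri(st, ri_for_dip(st, th, 735))
  r <- asf_step(asf_state(1L), chip_sampler(s735, th), bands)
  expect_equal(r$state$active_band, 1L)
  expect_lt(abs(r$estimate$rw_nm - 735), 1)
  # the worked red-shift example: dip at 783, tracker in band 1;
  # stepwise estimates 756 (clamp), 777 (clamp), then ~783
  s783 <- set_analyte_ri(st, ri_for_dip(st, th, 783))
  r1 <- asf_step(asf_state(1L), chip_sampler(s783, th), bands)
  expect_equal(r1$estimate$rw_nm, 756)       # clamped at band 1's fit edge
  expect_true(r1$estimate$clamped)
  expect_equal(r1$state$active_band, 2L)
  r2 <- asf_step(r1$state, chip_sampler(s783, th), bands)
  expect_equal(r2$estimate$rw_nm, 777)       # clamped at band 2's fit edge
  expect_true(r2$estimate$clamped)
  expect_equal(r2$state$active_band, 3L)
  r3 <- asf_step(r2$state, chip_sampler(s783, th), bands)
  expect_equal(r3$state$active_band, 3L)
  expect_lt(abs(r3$estimate$rw_nm - 783), 1)
  # early-switch thresholds skip the 777 intermediate
  early <- band_configs(thresholds_nm = c(740, 756))
  r1e <- asf_step(asf_state(1L), chip_sampler(s783, th), early)
  expect_equal(r1e$state$active_band, 3L)
})

test_that("downshifts mirror upshifts for blue-shifting dips", {
  st <- chip_stack(); th <- chip_angle()
  s735 <- set_analyte_ri(st, ri_for_dip(st, th, 735))
  est <- asf_converge(asf_state(3L), chip_sampler(s735, th))
  expect_equal(est$state$active_band, 1L)
  expect_lt(abs(est$rw_nm - 735), 1)
})

test_that("asf_converge needs at most three fits and at most two switches", {
  st <- chip_stack(); th <- chip_angle()
  set.seed(5)
  # interior dips: within ~10 nm of the red window edge the band-3
  # parabola clamps at 805 and the error is bounded by the distance to
  # the edge instead
  for (target in runif(12, 732, 790)) {
    s <- set_analyte_ri(st, ri_for_dip(st, th, target))
    est <- asf_converge(asf_state(1L), chip_sampler(s, th))
    expect_lte(est$n_fits, 3L)
    expect_lte(est$state$switch_count, 2L)
    # honest tracking bound for a Fresnel dip at these LED spacings
    expect_lt(abs(est$rw_nm - target), 4.5)
  }
  # near-edge dip: reported clamped at the window edge
  s_edge <- set_analyte_ri(st, ri_for_dip(st, th, 800))
  est <- asf_converge(asf_state(3L), chip_sampler(s_edge, th))
  expect_true(est$clamped)
  expect_equal(est$rw_nm, 805)
})

test_that("band-1 and band-2 fits agree for dips well inside the trigger zone", {
  st <- chip_stack(); th <- chip_angle()
  bands <- band_configs()
  for (target in c(748, 750, 752)) {
    s <- set_analyte_ri(st, ri_for_dip(st, th, target))
    sp <- chip_sampler(s, th)
    e1 <- quadratic_rw(sp(1:3), bands[[1]]$fit_range_nm)
    e2 <- quadratic_rw(sp(2:4), bands[[2]]$fit_range_nm)
    expect_lt(abs(e1$rw_nm - e2$rw_nm), 1)
  }
})

test_that("asf_track follows a constant series and flags dead ROIs", {
  st <- set_analyte_ri(chip_stack(), ri_for_dip(chip_stack(), chip_angle(), 752))
  bank <- led_bank()
  refl <- rp_multilayer(st, bank$centers_nm, chip_angle())
  times <- 0:9
  ser <- rbind(
    data.frame(time_s = rep(times, each = 5), roi_id = "live",
               wavelength_nm = rep(bank$centers_nm, 10),
               intensity = rep(refl, 10)),
    data.frame(time_s = rep(times, each = 5), roi_id = "dead",
               wavelength_nm = rep(bank$centers_nm, 10),
               intensity = 0))
  sg <- asf_track(ser, bank)
  live <- sg[sg$roi_id == "live", ]
  expect_equal(length(unique(live$rw_nm)), 1L)   # constant input, constant rw
  expect_equal(length(unique(live$band_id)), 1L) # no band switch
  dead <- sg[sg$roi_id == "dead", ]
  expect_true(all(is.na(dead$rw_nm)))
})

test_that("tracking a staircase of spectra is monotone and crosses bands", {
  st <- chip_stack(); th <- chip_angle()
  bank <- led_bank()
  targets <- c(735, 735, 748, 748, 762, 762, 788, 788)
  rows <- lapply(seq_along(targets), function(i) {
    s <- set_analyte_ri(st, ri_for_dip(st, th, targets[i]))
    data.frame(time_s = i - 1, roi_id = "ch1",
               wavelength_nm = bank$centers_nm,
               intensity = rp_multilayer(s, bank$centers_nm, th))
  })
  sg <- asf_track(do.call(rbind, rows), bank)
  expect_true(all(diff(sg$rw_nm) > -0.5))
  expect_equal(sort(unique(sg$band_id)), 1:3)
  expect_true(all(abs(sg$rw_nm - targets) < 3.5))
})
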