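test_that("default machine model echoes its stated library", {
  m <- default_machine_model()
  expect_length(m$energies, 97)
  expect_equal(m$energies[1], 71.3)
  expect_equal(m$energies[97], 228.8)
  expect_true(all(diff(m$energies) > 0))
  expect_equal(m$sigma_air(71.3), 5.7)
  expect_equal(m$sigma_air(228.8), 2.5)
  expect_true(all(diff(m$sigma_air(m$energies)) < 0))
})

test_that("HU to stopping power mapping", {
  expect_equal(hu_to_rsp(0), 1)
  expect_equal(hu_to_rsp(-1000), 0)
  expect_equal(hu_to_rsp(-500), 0.5)
  expect_equal(hu_to_rsp(1024), 1.5)
  expect_warning(r <- hu_to_rsp(-1200), "clamped")
  expect_equal(r, 0)
})

test_that("WEPL accumulation along rays", {
  # 10 cm of water traversed along z
  ct <- image_grid(array(0, c(20, 20, 40)), spacing = rep(2.5, 3))
  r <- wepl_along_ray(ct, entry = c(25, 25, 1.25), direction = c(0, 0, 1),
                      step = 1)
  expect_equal(max(r$wepl_mm), 97, tolerance = 3)   # 38.75 mm to last sample
  expect_true(all(diff(r$wepl_mm) >= 0))
  # uniform RSP 0.5 halves the depth
  ct2 <- image_grid(array(-500, c(20, 20, 40)), spacing = rep(2.5, 3))
  r2 <- wepl_along_ray(ct2, c(25, 25, 1.25), c(0, 0, 1), step = 1)
  expect_equal(max(r2$wepl_mm), max(r$wepl_mm) / 2, tolerance = 1e-6)
  # two-slab case: 5 cm water + 5 cm RSP 0.25 = 6.25 cm (derived)
  arr <- array(0, c(8, 8, 40))
  arr[, , 21:40] <- -750
  ct3 <- image_grid(arr, spacing = rep(2.5, 3))
  r3 <- wepl_along_ray(ct3, c(10, 10, 1.25), c(0, 0, 1), step = 0.5)
  at_100mm <- r3$wepl_mm[which.min(abs(r3$t_mm - 98.75))]
  expect_equal(at_100mm, 48.75 + 48.75 * 0.25 + 1.25 * 0.625, tolerance = 2.5)
  # a ray missing the body returns an empty result
  miss <- wepl_along_ray(image_grid(array(-1000, c(8, 8, 8)), rep(2.5, 3)),
                         c(10, 10, 1), c(0, 0, 1))
  expect_length(miss$wepl_mm, 0)
})

test_that("Bragg curve range, peak position and distal cutoff", {
  m <- default_machine_model()
  # R(228.8 MeV) = 0.022 * 228.8^1.77 mm, evaluated independently
  expect_equal(m$range_mm(228.8), 0.022 * 228.8^1.77)
  expect_equal(round(m$range_mm(228.8) / 10, 1), 33.0)
  for (E in c(80, 150, 228.8)) {
    R <- m$range_mm(E)
    z <- seq(0, R + 40, by = 0.1)
    dd <- bragg_depth_dose(E, z, m)
    expect_equal(max(dd), 1, tolerance = 5e-3)
    expect_lt(abs(z[which.max(dd)] - R), 2)         # peak within 2 mm of R
    expect_equal(dd[z > R + 30], rep(0, sum(z > R + 30)))  # distal zero
  }
  expect_error(bragg_depth_dose(150, c(-1, 5), m), ">= 0")
})

test_that("range scaling moves the distal falloff proportionally", {
  m <- default_machine_model()
  E <- 150; R <- m$range_mm(E)
  z <- seq(0, 1.1 * R + 30, by = 0.01)
  z80 <- function(scale) {
    dd <- bragg_depth_dose(E, z / scale, m)
    pk <- which.max(dd)
    z[pk - 1 + which(dd[pk:length(dd)] < 0.8)[1]]
  }
  expect_equal(z80(1.05) / z80(1), 1.05, tolerance = 2e-3)
})

test_that("spot dose: linearity, lateral Gaussian, integral conservation", {
  w <- water_tank()
  d1 <- compute_dose_grid(w$ct, w$plan, 1, w$machine)
  d2 <- compute_dose_grid(w$ct, w$plan, 2, w$machine)
  expect_equal(d2$data, 2 * d1$data)
  # lateral profile at a fixed depth matches the predicted sigma to < 1%
  k <- 30
  wepl_k <- (k - 0.5) * 2.5
  sig <- sqrt(w$machine$sigma_air(150)^2 + (w$machine$sigma_growth_k * wepl_k)^2)
  x <- ((1:40) - 1) * 2.5   # voxel centres (origin at the first centre)
  lat <- d1$data[, 21, k]   # through the spot axis at y = 50
  use <- abs(x - 50) < 2 * sig & lat > 0
  # log-linear fit of the Gaussian: slope of log(dose) vs squared radius
  co <- stats::coef(stats::lm(log(lat[use]) ~ I((x[use] - 50)^2)))
  sig_fit <- sqrt(-1 / (2 * co[2]))
  expect_equal(unname(sig_fit), sig, tolerance = 0.01)
  # integral depth dose: plane sums track the depth-dose curve to < 0.5%
  # despite the 3.5 sigma lateral truncation
  plane <- apply(d1$data, 3, sum)
  dd <- bragg_depth_dose(150, ((1:80) - 0.5) * 2.5, w$machine)
  ratio <- plane[10:55] / dd[10:55]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.005)
})

test_that("setup-shift scenario displaces the dose by the shift", {
  w <- water_tank()
  nom <- compute_dose_grid(w$ct, w$plan, 100, w$machine)
  sh <- compute_dose_grid(w$ct, w$plan, 100, w$machine,
                          scenario(shift_mm = c(5, 0, 0)))
  cx <- function(d) {
    i <- which(d$data > 0)
    sum(((arrayInd(i, dim(d$data))[, 1] - 0.5) * 2.5) * d$data[i]) / sum(d$data[i])
  }
  expect_equal(abs(cx(sh) - cx(nom)), 5, tolerance = 0.3)
})

test_that("influence columns reproduce the dense dose and compose linearly", {
  w <- water_tank()
  roi <- array(FALSE, dim(w$ct$data)); roi[15:25, 15:25, 20:70] <- TRUE
  infl <- build_influence(w$ct, w$plan, w$machine, scenario(), roi)
  dense <- compute_dose_grid(w$ct, w$plan, 1, w$machine)
  expect_equal(compose_dose(infl, 1), dense$data[infl$roi_idx],
               tolerance = 1e-12)
  expect_equal(compose_dose(infl, 3) + compose_dose(infl, 4),
               compose_dose(infl, 7), tolerance = 1e-12)
  expect_error(build_influence(w$ct, local({
    p <- w$plan; p$spots <- p$spots[0, ]; p
  }), w$machine, scenario(), roi), "no spots")
  # the single-spot accessor reproduces the dense grid exactly
  sd1 <- spot_dose(w$ct, w$plan, w$machine, index = 1)
  full <- array(0, dim(w$ct$data)); full[sd1$idx] <- sd1$dose
  expect_equal(full, dense$data, tolerance = 1e-15)
})
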