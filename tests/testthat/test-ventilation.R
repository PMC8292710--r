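test_that("the HU-pair ventilation identity reproduces its worked values", {
  # air volume doubled: HU_ex -500, HU_in -666.67 -> 1.0
  expect_equal(hu_pair_ventilation(-2000 / 3, -500), 1.0, tolerance = 1e-12)
  # no change in volume -> 0
  expect_equal(hu_pair_ventilation(-500, -500), 0)
  expect_equal(hu_pair_ventilation(-123.4, -123.4), 0)
  # derived: 1000 * (-250) / (-500 * 250) = 2
  expect_equal(hu_pair_ventilation(-750, -500), 2.0)
  # near-singular guards
  expect_true(is.na(hu_pair_ventilation(-500, 0.5)))
  expect_true(is.na(hu_pair_ventilation(-999.9, -500)))
  expect_false(is.na(hu_pair_ventilation(-998, -500)))
})

test_that("ventilation of a phase against itself is identically zero", {
  fx <- small_phantom()
  lung <- fx$anatomy$lung_left | fx$anatomy$lung_right
  d <- dim(fx$exhale$data)
  zero <- displacement_field(array(0, c(d, 3)), fx$exhale$spacing,
                             fx$exhale$origin)
  vm <- compute_ventilation(fx$exhale, fx$exhale, zero, lung)
  expect_equal(range(vm$values[vm$valid]), c(0, 0))
  # dvf/grid mismatch errors
  bad <- displacement_field(array(0, c(10, 10, 10, 3)), fx$exhale$spacing,
                            fx$exhale$origin)
  expect_error(compute_ventilation(fx$exhale, fx$exhale, bad, lung),
               "grid")
})

test_that("lung segmentation recovers the phantom masks", {
  fx <- small_phantom()
  an <- fx$anatomy
  seg <- segment_lungs(fx$exhale,
                       exclusions = list(an$airway, an$tumor, an$vessels))
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice(seg$left, an$lung_left), 0.98)
  expect_gt(dice(seg$right, an$lung_right), 0.98)
  expect_equal(sum(seg$left & an$tumor) + sum(seg$right & an$tumor), 0)
  # a water-only volume has no lung
  water <- image_grid(array(0, c(32, 32, 32)), spacing = rep(5, 3))
  expect_error(segment_lungs(water), "fewer than 2")
})

test_that("normalization to the global maximum", {
  d <- c(4, 4, 4)
  vals <- array(NA_real_, d); valid <- array(FALSE, d)
  vals[1:8] <- c(0, 0.1, 0.2, 0.4, -0.3, 0.05, 0.8, 0.3)
  valid[1:8] <- TRUE
  vm <- normalize_to_max(ventilation_map(vals, valid, rep(1, 3), rep(0, 3)))
  expect_equal(vm$percent[7], 100)           # max voxel
  expect_equal(vm$percent[1], 0)             # zero stays zero
  expect_equal(vm$percent[4], 50)            # half of max
  expect_equal(vm$percent[5], 0)             # negative clipped before scaling
  # all-zero map cannot be normalized
  z <- ventilation_map(array(0, d), array(TRUE, d), rep(1, 3), rep(0, 3))
  expect_error(normalize_to_max(z), "cannot normalize")
})

test_that("regional profile: shares, partitions and degenerate input", {
  fx <- small_phantom()
  an <- fx$anatomy
  lungs <- list(left = an$lung_left, right = an$lung_right)
  # uniform ventilation: share equals the volume share of each region
  vals <- array(NA_real_, dim(an$f_air)); valid <- array(FALSE, dim(an$f_air))
  lung <- an$lung_left | an$lung_right
  vals[lung] <- 0.2; valid[lung] <- TRUE
  vmu <- ventilation_map(vals, valid, an$spacing, an$origin)
  pu <- regional_profile(vmu, lungs)
  expect_equal(pu$share_pct, pu$volume_pct, tolerance = 1e-9)
  expect_equal(sum(pu$share_pct), 100, tolerance = 1e-9)
  # zeroing one region removes its share and renormalizes the rest
  kz <- which(apply(an$lung_left, 3, any))
  cut <- min(kz) - 0.5 + 2 * (max(kz) - min(kz) + 1) / 3   # superior-third edge
  vals2 <- vals; sel <- an$lung_left
  sel[, , seq_len(dim(sel)[3]) <= cut] <- FALSE   # superior third of left lung
  vals2[sel] <- 0
  p2 <- regional_profile(ventilation_map(vals2, valid, an$spacing, an$origin),
                         lungs)
  expect_equal(p2$share_pct[p2$lung == "left" & p2$region == "superior"], 0,
               tolerance = 1e-6)
  expect_equal(sum(p2$share_pct), 100, tolerance = 1e-9)
  # share matches a brute-force slab summation oracle
  gt <- ground_truth_ventilation(fx$dvf, an)
  prof <- regional_profile(gt, lungs)
  oracle <- local({
    v <- gt$values; v[!gt$valid] <- 0; v <- pmax(v, 0)
    tot <- 0; res <- c()
    for (side in c("left", "right")) {
      m <- lungs[[side]]
      kz <- range(which(apply(m, 3, any)))
      edges <- kz[1] - 0.5 + (kz[2] - kz[1] + 1) * (0:3) / 3
      for (r in 1:3) {
        s <- 0
        for (k in seq_len(dim(m)[3]))
          if (k > edges[r] && k <= edges[r + 1]) s <- s + sum(v[, , k][m[, , k]])
        res <- c(res, s); tot <- tot + s
      }
    }
    100 * res / tot
  })
  expect_equal(prof$share_pct, oracle, tolerance = 1e-9)
})

test_that("eligibility screen is inclusive at the 15-point boundary", {
  base <- data.frame(lung = rep(c("left", "right"), each = 3),
                     region = rep(c("inferior", "middle", "superior"), 2),
                     volume_cc = rep(100, 6))
  # homogeneous: shares equal expectations -> not eligible
  prof <- base
  prof$share_pct <- rep(100 / 6, 6)
  prof$volume_pct <- rep(100 / 6, 6)
  expect_false(screen_eligibility(prof)$eligible)
  # one region at zero with expected 16.67 -> eligible (deficit 16.67)
  prof$share_pct <- c(0, rep(20, 5))
  el <- screen_eligibility(prof)
  expect_true(el$eligible)
  expect_equal(el$max_deficit, 100 / 6, tolerance = 1e-9)
  # deficit exactly at the threshold counts ("15% or more")
  prof$share_pct <- c(100 / 6 - 15, rep(100 / 6 + 3, 5))
  expect_true(screen_eligibility(prof)$eligible)
  expect_false(screen_eligibility(prof, deficit_threshold = 15.001)$eligible)
})
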