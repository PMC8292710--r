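#' Deformable 4DCT lung phantom
#'
#' Generates a synthetic thorax with two lungs, airway, tumor and organs at
#' risk, plus a smooth tissue-conserving breathing deformation with an
#' analytically known Jacobian. Because the Hounsfield model is
#' `HU = -1000 * f_air` (soft tissue at a configurable HU), the fractional
#' ventilation of every voxel is available in closed form as
#' `(J - 1) / f_air`, giving every downstream stage (registration,
#' ventilation imaging, functional structures, planning, interplay) a known
#' ground truth.
#'
#' @name phantom4d
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Phantom geometry and tissue configuration
#'
#' Geometry is expressed as fractions of the grid extent so the same
#' anatomy scales across grid sizes; tissue parameters are absolute.
#' Defaults: 96^3 voxels at 2.5 mm isotropic (matching a 2.5 mm dose grid),
#' air fraction bounds 0.3-0.8 in parenchyma, a 10 mm radius tumor in the
#' right lung moving 6 mm cranio-caudally (the cohort median maximal tumor
#' amplitude), and a severe ventilation defect (expansion attenuated to 5%)
#' in the middle third of the right lung.
#'
#' @param dims integer length-3 grid size (each >= 32).
#' @param spacing voxel spacing, mm.
#' @param f_air_bounds range of the parenchymal air-fraction field.
#' @param tumor_radius_mm tumor sphere radius, mm.
#' @param tumor_amplitude_mm peak-to-peak rigid tumor excursion, mm.
#' @param amplitude_mm peak parenchymal displacement magnitude, mm.
#' @param defect_factor multiplier on local expansion inside the defect
#'   region (1 = no defect, 0 = no ventilation).
#' @param defect_lung,defect_region which lung third carries the defect.
#' @param tissue_hu,tumor_hu,airway_f_air tissue model parameters.
#' @param vessel_fraction fraction of the lung volume occupied by the
#'   dense vascular speckle (0 disables it).
#' @param vessel_hu HU of vessel voxels.
#' @param noise_hu standard deviation of optional additive HU noise.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(96, 96, 96), spacing = c(2.5, 2.5, 2.5),
                           f_air_bounds = c(0.3, 0.8),
                           tumor_radius_mm = 10, tumor_amplitude_mm = 6,
                           amplitude_mm = 8, defect_factor = 0.05,
                           defect_lung = c("right", "left"),
                           defect_region = c("middle", "inferior", "superior"),
                           tissue_hu = 0, tumor_hu = 30, airway_f_air = 0.9,
                           vessel_fraction = 0.07, vessel_hu = 50,
                           noise_hu = 0) {
  if (any(dims < 32)) stop("grid dims must be >= 32 in every axis")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  stopifnot(f_air_bounds[1] >= 0, f_air_bounds[2] < 1,
            f_air_bounds[1] < f_air_bounds[2])
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 f_air_bounds = f_air_bounds,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_amplitude_mm = tumor_amplitude_mm,
                 amplitude_mm = amplitude_mm,
                 defect_factor = defect_factor,
                 defect_lung = match.arg(defect_lung),
                 defect_region = match.arg(defect_region),
                 tissue_hu = tissue_hu, tumor_hu = tumor_hu,
                 airway_f_air = airway_f_air,
                 vessel_fraction = vessel_fraction, vessel_hu = vessel_hu,
                 noise_hu = noise_hu),
            class = "phantom_config")
}

# normalized coordinates of every voxel relative to grid extent, plus mm
phantom_coords <- function(config) {
  d <- config$dims; sp <- config$spacing
  extent <- d * sp
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  X <- array(rep.int(x, d[2] * d[3]), d)
  Y <- array(rep.int(rep(y, each = d[1]), d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  list(X = X, Y = Y, Z = Z, extent = extent,
       origin = sp / 2)   # voxel centres; voxel (1,1,1) at spacing/2
}

ellipsoid_mask <- function(co, centre_frac, radii_frac) {
  cx <- centre_frac * co$extent; r <- radii_frac * co$extent
  ((co$X - cx[1]) / r[1])^2 + ((co$Y - cx[2]) / r[2])^2 +
    ((co$Z - cx[3]) / r[3])^2 <= 1
}

tube_mask <- function(co, centre_frac_xy, radius_frac, z_frac) {
  cx <- centre_frac_xy * co$extent[1:2]; r <- radius_frac * co$extent[1]
  ((co$X - cx[1])^2 + (co$Y - cx[2])^2 <= r^2) &
    co$Z >= z_frac[1] * co$extent[3] & co$Z <= z_frac[2] * co$extent[3]
}

phantom_geometry <- function(config) {
  list(body_c = c(0.50, 0.50), body_r = c(0.44, 0.36), body_z = c(0.04, 0.96),
       lungL_c = c(0.285, 0.49, 0.54), lungR_c = c(0.715, 0.49, 0.54),
       lung_r = c(0.16, 0.215, 0.33),
       airway_c = c(0.50, 0.44), airway_r = 0.035, airway_z = c(0.54, 0.93),
       tumor_c = c(0.685, 0.49, 0.45),
       eso_c = c(0.50, 0.565), eso_r = 0.022,
       cord_c = c(0.50, 0.76), cord_r = 0.027,
       heart_c = c(0.42, 0.57, 0.40), heart_r = c(0.125, 0.115, 0.15))
}

#' Build the reference (peak-exhale) phantom anatomy
#'
#' @param config a [phantom_config()].
#' @param seed integer RNG seed; the anatomy is bit-identical for a given
#'   seed and config.
#' @return a `phantom_anatomy`: logical masks (`body`, `lung_left`,
#'   `lung_right`, `airway`, `tumor`, `esophagus`, `heart`, `cord`), the
#'   air-fraction field `f_air`, the defect descriptor, and grid geometry.
#' @export
build_reference_anatomy <- function(config = phantom_config(), seed = 1) {
  co <- phantom_coords(config)
  geo <- phantom_geometry(config)
  body <- (((co$X - geo$body_c[1] * co$extent[1]) / (geo$body_r[1] * co$extent[1]))^2 +
           ((co$Y - geo$body_c[2] * co$extent[2]) / (geo$body_r[2] * co$extent[2]))^2 <= 1) &
    co$Z >= geo$body_z[1] * co$extent[3] & co$Z <= geo$body_z[2] * co$extent[3]
  lungL <- ellipsoid_mask(co, geo$lungL_c, geo$lung_r)
  lungR <- ellipsoid_mask(co, geo$lungR_c, geo$lung_r)
  airway <- tube_mask(co, geo$airway_c, geo$airway_r, geo$airway_z)
  heart <- ellipsoid_mask(co, geo$heart_c, geo$heart_r)
  eso <- tube_mask(co, geo$eso_c, geo$eso_r, geo$body_z)
  cord <- tube_mask(co, geo$cord_c, geo$cord_r, geo$body_z)
  tc <- geo$tumor_c * co$extent
  tumor <- (co$X - tc[1])^2 + (co$Y - tc[2])^2 + (co$Z - tc[3])^2 <=
    config$tumor_radius_mm^2
  host <- if (geo$tumor_c[1] > 0.5) lungR else lungL
  if (any(tumor & !host))
    stop("tumor radius ", config$tumor_radius_mm,
         " mm exceeds the host lung extent: shrink tumor_radius_mm or move tumor_c")
  lungL <- lungL & !airway & !heart & !eso & !cord
  lungR <- lungR & !airway & !heart & !eso & !cord
  # pulmonary vasculature: dense (airless) speckle that keeps its HU
  # across phases; anchors intensity-based registration and is excluded
  # from the ventilation domain, as clinical processing excludes vessels
  vess_field <- with_seed(seed + 1000003L, {
    noise <- array(stats::rnorm(prod(config$dims)), config$dims)
    gaussian_smooth3(noise, sigma_vox = 4 / mean(config$spacing))
  })
  inlung <- (lungL | lungR) & !tumor
  vessels <- array(FALSE, config$dims)
  if (config$vessel_fraction > 0) {
    thr <- stats::quantile(vess_field[inlung], 1 - config$vessel_fraction)
    vessels <- inlung & vess_field >= thr
  }
  lungL <- lungL & !vessels
  lungR <- lungR & !vessels
  parenchyma <- (lungL | lungR) & !tumor
  # smooth seeded air-fraction field, rescaled exactly into the bounds
  f_air <- with_seed(seed, {
    noise <- array(stats::rnorm(prod(config$dims)), config$dims)
    gaussian_smooth3(noise, sigma_vox = 10 / mean(config$spacing))
  })
  v <- f_air[parenchyma]
  rng <- range(v)
  b <- config$f_air_bounds
  f <- array(0, config$dims)
  f[parenchyma] <- b[1] + (v - rng[1]) / (rng[2] - rng[1]) * (b[2] - b[1])
  f[airway & body] <- config$airway_f_air
  structure(list(config = config, body = body,
                 lung_left = lungL & !tumor, lung_right = lungR & !tumor,
                 airway = airway & body, tumor = tumor,
                 vessels = vessels,
                 esophagus = eso & body, heart = heart & body,
                 cord = cord & body, f_air = f,
                 defect = list(lung = config$defect_lung,
                               region = config$defect_region,
                               factor = config$defect_factor),
                 spacing = config$spacing, origin = co$origin,
                 seed = seed),
            class = "phantom_anatomy")
}

#' Displacement fields
#'
#' Per-voxel 3-vectors in physical mm on the exhale grid, mapping each
#' exhale voxel centre `x` to its inhale position `x + u(x)`.
#'
#' @param u 4D array `(nx, ny, nz, 3)` of displacements (mm).
#' @param spacing,origin grid geometry.
#' @param convention direction flag; only `"exhale_to_inhale"` is used.
#' @export
displacement_field <- function(u, spacing, origin,
                               convention = "exhale_to_inhale") {
  stopifnot(length(dim(u)) == 4L, dim(u)[4] == 3L)
  structure(list(u = u, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), convention = convention),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat("<displacement_field> dims", paste(dim(x$u)[1:3], collapse = "x"),
      " max |u| =", signif(max(m), 4), "mm\n")
  invisible(x)
}

det3_field <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33) {
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Jacobian determinant of a displacement field
#'
#' `J = det(I + du/dx)` by central differences; the local volume ratio of
#' the deformation `x -> x + u(x)`.
#'
#' @param dvf a `displacement_field`.
#' @return 3D array of Jacobian determinants.
#' @export
dvf_jacobian <- function(dvf) {
  g1 <- gradient3(dvf$u[, , , 1], dvf$spacing)
  g2 <- gradient3(dvf$u[, , , 2], dvf$spacing)
  g3 <- gradient3(dvf$u[, , , 3], dvf$spacing)
  det3_field(1 + g1[[1]], g1[[2]], g1[[3]],
             g2[[1]], 1 + g2[[2]], g2[[3]],
             g3[[1]], g3[[2]], 1 + g3[[3]])
}

#' Synthesize the ground-truth breathing displacement field
#'
#' A superposition of compact-support smooth bumps: one anisotropic radial
#' expansion per lung (cranio-caudal dominant) plus seeded low-frequency
#' bumps. Inside the configured defect region the local expansion is scaled
#' by `defect_factor`. The field is rescaled so the maximum displacement
#' magnitude on the grid equals `amplitude_mm` exactly, is zero outside the
#' lungs (hence outside the body), and is checked to keep `J > 0`.
#'
#' @param anatomy a `phantom_anatomy`.
#' @param amplitude_mm maximum displacement magnitude, mm.
#' @param defect_factor expansion multiplier in the defect region, in [0,1].
#' @param seed seed for the random bump coefficients.
#' @param n_bumps number of random perturbation bumps.
#' @return a `displacement_field` (exhale to inhale).
#' @export
synthesize_dvf <- function(anatomy,
                           amplitude_mm = anatomy$config$amplitude_mm,
                           defect_factor = anatomy$config$defect_factor,
                           seed = anatomy$seed, n_bumps = 6) {
  stopifnot(amplitude_mm >= 0, defect_factor >= 0, defect_factor <= 1)
  config <- anatomy$config
  co <- phantom_coords(config)
  geo <- phantom_geometry(config)
  d <- config$dims
  u <- array(0, c(d, 3))
  # diaphragm-like stretch per lung: apex fixed, base displaced inferiorly,
  # so du_z/dz > 0 (expansion) throughout the lung; the compensating
  # compression that returns u to zero sits in the airless soft tissue
  # below the base, where tissue conservation places no constraint. The
  # defect attenuates the *slope* of the axial profile inside its z-band
  # (then integrated), which scales local expansion by defect_factor
  # without boundary shear.
  decay_mm <- 25
  zc <- (seq_len(d[3]) - 0.5) * config$spacing[3]
  defect_sides <- if (anatomy$defect$lung == "right") "lungR_c" else "lungL_c"
  for (side in c("lungL_c", "lungR_c")) {
    cx <- geo[[side]] * co$extent
    r <- geo$lung_r * co$extent
    z_top <- cx[3] + r[3]; z_bot <- cx[3] - r[3]
    L <- z_top - z_bot
    atten_z <- rep(1, d[3])
    if (side %in% defect_sides && defect_factor < 1) {
      third <- L / 3
      band <- switch(anatomy$defect$region,
                     inferior = c(z_bot, z_bot + third),
                     middle = c(z_bot + third, z_bot + 2 * third),
                     superior = c(z_bot + 2 * third, z_top))
      m <- (1 / (1 + exp(-(zc - band[1]) / 2.5))) *
        (1 / (1 + exp((zc - band[2]) / 2.5)))
      atten_z <- 1 - (1 - defect_factor) * m
    }
    slope <- ifelse(zc >= z_bot & zc <= z_top, 1 / L, 0) * atten_z
    # axial(z) = integral of the slope from z up to the apex
    dz <- config$spacing[3]
    ax <- rev(cumsum(rev(slope))) * dz - slope * dz / 2
    ax_base <- ax[max(which(zc <= z_bot), 1)]
    below <- pmin(pmax((zc - (z_bot - decay_mm)) / decay_mm, 0), 1)
    ax <- ifelse(zc < z_bot, ax_base * below^2 * (3 - 2 * below), ax)
    axial <- array(rep(ax, each = d[1] * d[2]), d)
    atten3 <- array(rep(atten_z, each = d[1] * d[2]), d)
    px <- (co$X - cx[1]) / (1.12 * r[1]); py <- (co$Y - cx[2]) / (1.12 * r[2])
    rxy2 <- px^2 + py^2
    lat <- ifelse(rxy2 < 1, (1 - rxy2)^2, 0)
    uz <- -axial * lat
    u[, , , 3] <- u[, , , 3] + uz
    # lateral coupling attenuated in the defect band too (pure z-shear at
    # the band edge, so the Jacobian stays positive)
    u[, , , 1] <- u[, , , 1] - 0.15 * uz * px * atten3
    u[, , , 2] <- u[, , , 2] - 0.15 * uz * py * atten3
    # seeded low-frequency perturbation bumps for this lung, attenuated in
    # the defect band on the defect side
    bumps <- with_seed(seed + (side == "lungR_c"), {
      lapply(seq_len(n_bumps), function(i) {
        list(centre = (geo[[side]] + stats::runif(3, -0.35, 0.35) * geo$lung_r) * co$extent,
             radius = stats::runif(1, 0.3, 0.5) * geo$lung_r * co$extent,
             amp = stats::runif(3, -0.08, 0.08) * c(0.5, 0.5, 1))
      })
    })
    for (b in bumps) {
      bx <- (co$X - b$centre[1]) / b$radius[1]
      by <- (co$Y - b$centre[2]) / b$radius[2]
      bz <- (co$Z - b$centre[3]) / b$radius[3]
      r2 <- bx^2 + by^2 + bz^2
      w <- ifelse(r2 < 1, (1 - r2)^2, 0) * atten3
      for (k in 1:3) u[, , , k] <- u[, , , k] + b$amp[k] * w
    }
  }
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  mmax <- max(mag)
  s <- if (mmax > 0) amplitude_mm / mmax else 0
  u <- u * s
  dvf <- displacement_field(u, config$spacing, co$origin)
  minJ <- min(dvf_jacobian(dvf))
  if (minJ <= 0)
    stop("amplitude ", amplitude_mm, " mm folds the deformation (min J = ",
         signif(minJ, 4), " <= 0)")
  dvf
}

# phase air fraction under tissue conservation: f_c = 1 - (1 - f_air)/J_c
phase_air_fraction <- function(anatomy, Jc) {
  f <- anatomy$f_air
  fc <- array(0, dim(f))
  aired <- f > 0
  fc[aired] <- 1 - (1 - f[aired]) / Jc[aired]
  if (any(fc[aired] < -1e-9)) {
    stop("tissue volume exceeds deformed voxel volume (min phase air fraction ",
         signif(min(fc[aired]), 4), "): reduce amplitude")
  }
  fc[aired] <- pmax(fc[aired], 0)
  fc
}

# reference HU field of the anatomy (peak exhale)
reference_hu <- function(anatomy, f = anatomy$f_air) {
  config <- anatomy$config
  hu <- array(-1000, dim(f))
  hu[anatomy$body] <- config$tissue_hu
  aired <- f > 0
  hu[aired] <- -1000 * f[aired] + config$tissue_hu * (1 - f[aired])
  hu[anatomy$vessels] <- config$vessel_hu
  hu[anatomy$tumor] <- config$tumor_hu
  hu
}

#' Tumor mask at a breathing phase
#'
#' Rigid cranio-caudal translation by `c * tumor_amplitude_mm` (inferior
#' for inhale), superposed on the parenchymal deformation.
#' @param anatomy a `phantom_anatomy`.
#' @param c phase fraction in [0, 1].
#' @export
tumor_mask_at_phase <- function(anatomy, c) {
  config <- anatomy$config
  co <- phantom_coords(config)
  geo <- phantom_geometry(config)
  tc <- geo$tumor_c * co$extent + c * config$tumor_amplitude_mm * c(0, 0, -1)
  (co$X - tc[1])^2 + (co$Y - tc[2])^2 + (co$Z - tc[3])^2 <=
    config$tumor_radius_mm^2
}

#' Render one breathing phase of the phantom
#'
#' Tissue conservation: an exhale voxel of volume `v` with air fraction
#' `f_air` carries tissue `t = (1 - f_air) v`; at phase `c` its mapped
#' region has volume `J_c v`, so the phase air fraction is
#' `1 - (1 - f_air)/J_c` and `HU = -1000 * f_air_phase` (soft-tissue HU
#' configurable). With `mode = "grid"` the phase image is resampled onto
#' the fixed grid (inverse mapping by fixed-point iteration, trilinear
#' interpolation, rigid tumor stamped at its translated position). With
#' `mode = "pair"` no resampling occurs: the function returns, for every
#' exhale voxel, the exact HU value at its displaced position
#' `x + c u(x)` — the interpolation-free mapped-pair view used for the
#' analytic closure checks.
#'
#' @param anatomy a `phantom_anatomy`.
#' @param dvf the ground-truth `displacement_field` (full inhale).
#' @param c phase fraction in [0, 1] (0 = exhale reference, 1 = full inhale).
#' @param mode `"grid"` (resampled `image_grid`) or `"pair"`.
#' @param noise_hu additive Gaussian HU noise (grid mode only).
#' @return an `image_grid`, or for `"pair"` a list with `hu_exhale` and
#'   `hu_inhale_at_mapped` arrays on the exhale grid.
#' @export
render_phase <- function(anatomy, dvf, c, mode = c("grid", "pair"),
                         noise_hu = anatomy$config$noise_hu) {
  mode <- match.arg(mode)
  stopifnot(c >= 0, c <= 1)
  config <- anatomy$config
  uc <- dvf$u * c
  Jc <- dvf_jacobian(displacement_field(uc, dvf$spacing, dvf$origin))
  fc <- phase_air_fraction(anatomy, Jc)
  hu_phase <- reference_hu(anatomy, fc)
  if (mode == "pair") {
    return(list(hu_exhale = reference_hu(anatomy),
                hu_inhale_at_mapped = hu_phase,
                jacobian = Jc))
  }
  d <- config$dims
  out <- reference_hu(anatomy)   # voxels outside the motion support unchanged
  mag <- sqrt(uc[, , , 1]^2 + uc[, , , 2]^2 + uc[, , , 3]^2)
  reach <- ceiling(max(mag) / min(config$spacing)) + 1L
  cand <- mag > 0
  if (reach > 0 && any(cand)) {
    for (axis in 1:3) for (by in c(-1L, 1L)) {
      tmp <- cand
      for (r in seq_len(reach)) tmp <- tmp | shift_array(cand, axis, by * r)
      cand <- tmp
    }
  }
  idx <- which(cand)
  if (length(idx)) {
    pts <- grid_points(list(data = out, spacing = config$spacing,
                            origin = dvf$origin))[idx, , drop = FALSE]
    x <- pts
    for (it in 1:15) {
      ux <- cbind(interp_trilinear(uc[, , , 1], x, dvf$spacing, dvf$origin, fill = 0),
                  interp_trilinear(uc[, , , 2], x, dvf$spacing, dvf$origin, fill = 0),
                  interp_trilinear(uc[, , , 3], x, dvf$spacing, dvf$origin, fill = 0))
      x <- pts - ux
    }
    out[idx] <- interp_trilinear(hu_phase, x, dvf$spacing, dvf$origin,
                                 fill = -1000)
  }
  tm <- tumor_mask_at_phase(anatomy, c)
  out[tm] <- config$tumor_hu
  if (noise_hu > 0) out <- out + array(stats::rnorm(length(out), 0, noise_hu), d)
  image_grid(out, config$spacing, dvf$origin)
}

#' Ground-truth ventilation map from the analytic deformation
#'
#' Tissue conservation gives `Vin = J v - t`, `Vex = v - t` with
#' `t = (1 - f_air) v`, hence `(Vin - Vex)/Vex = (J - 1)/f_air`.
#'
#' @param dvf ground-truth `displacement_field`.
#' @param anatomy a `phantom_anatomy`.
#' @return a `ventilation_map` on the exhale grid (parenchyma mask; voxels
#'   with `f_air = 0` flagged undefined).
#' @export
ground_truth_ventilation <- function(dvf, anatomy) {
  J <- dvf_jacobian(dvf)
  mask <- (anatomy$lung_left | anatomy$lung_right)
  vals <- array(NA_real_, dim(J))
  ok <- mask & anatomy$f_air > 0
  vals[ok] <- (J[ok] - 1) / anatomy$f_air[ok]
  ventilation_map(vals, valid = ok, spacing = dvf$spacing,
                  origin = dvf$origin)
}

#' Breathing trace configuration
#'
#' Waveform `c(t) = ((1 - cos(2 pi t / T)) / 2)^p` with `p = 2` by default
#' (longer dwell near exhale, as in quiet breathing); a `max_inhale` start
#' offsets time by half a period so that `c(0) = 1`.
#'
#' @param period_s breathing period, s (study values: 3, 5, 7).
#' @param start_phase `"max_exhale"` (c(0)=0) or `"max_inhale"` (c(0)=1).
#' @param amplitude_mm tumor motion amplitude, mm.
#' @param n_phases number of 4DCT phase bins (>= 2).
#' @param shape_p waveform exponent.
#' @export
breathing_config <- function(period_s = 5,
                             start_phase = c("max_exhale", "max_inhale"),
                             amplitude_mm = 6, n_phases = 10, shape_p = 2) {
  stopifnot(period_s > 0, amplitude_mm >= 0, n_phases >= 2)
  structure(list(period_s = period_s, start_phase = match.arg(start_phase),
                 amplitude_mm = amplitude_mm, n_phases = as.integer(n_phases),
                 shape_p = shape_p),
            class = "breathing_config")
}

#' Evaluate the breathing waveform
#' @param t time(s), s.
#' @param breathing a [breathing_config()].
#' @return phase fraction `c(t)` in [0, 1].
#' @export
breathing_waveform <- function(t, breathing) {
  t0 <- if (breathing$start_phase == "max_inhale") breathing$period_s / 2 else 0
  ((1 - cos(2 * pi * (t + t0) / breathing$period_s)) / 2)^breathing$shape_p
}

#' Generate the full 4DCT study
#'
#' Phase `k` (k = 0..K-1) uses `c_k` from the waveform sampled at
#' `t = k T / K` with a `max_exhale` start, so the sequence contains the
#' exact peak-exhale (`c = 0`) and, for even `K`, peak-inhale (`c = 1`)
#' phases. The tumor translates rigidly by `c_k * amplitude`.
#'
#' @param anatomy a `phantom_anatomy`.
#' @param dvf ground-truth full-inhale `displacement_field`.
#' @param breathing a [breathing_config()].
#' @return list with `phases` (image_grids), `phase_c` (c_k values), `dvfs`
#'   (per-phase displacement fields `c_k u`), `tumor_masks`, the exhale
#'   `anatomy`, and the ground-truth `ventilation` map.
#' @export
make_4dct <- function(anatomy, dvf,
                      breathing = breathing_config(
                        amplitude_mm = anatomy$config$tumor_amplitude_mm)) {
  K <- breathing$n_phases
  ck <- ((1 - cos(2 * pi * (0:(K - 1)) / K)) / 2)^breathing$shape_p
  ck[1] <- 0
  cache <- list()
  phases <- vector("list", K); dvfs <- vector("list", K)
  tmasks <- vector("list", K)
  for (k in seq_len(K)) {
    key <- sprintf("%.12f", ck[k])
    if (is.null(cache[[key]]))
      cache[[key]] <- render_phase(anatomy, dvf, ck[k])
    phases[[k]] <- cache[[key]]
    dvfs[[k]] <- displacement_field(dvf$u * ck[k], dvf$spacing, dvf$origin)
    tmasks[[k]] <- tumor_mask_at_phase(anatomy, ck[k])
  }
  list(phases = phases, phase_c = ck, dvfs = dvfs, tumor_masks = tmasks,
       anatomy = anatomy, breathing = breathing,
       ventilation = ground_truth_ventilation(dvf, anatomy))
}
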