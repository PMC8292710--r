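#' Simplified scanned-proton dose model
#'
#' An analytic pencil-beam engine: water-equivalent path length (WEPL) by
#' ray accumulation of relative stopping power, an analytic Bragg depth
#' dose with range `R(E) = 0.022 E^1.77` mm, a lateral Gaussian whose
#' in-air sigma comes from the machine model and grows with depth, and
#' explicit setup/range uncertainty scenarios. Dose is linear in spot
#' monitor units (MU). Beams are axis-aligned (cardinal gantry angles), so
#' WEPL is a cumulative sum along a grid axis.
#'
#' @name dose_engine
NULL

#' Default synchrotron machine model
#'
#' 97 discrete energies geometrically spaced over 71.3-228.8 MeV, in-air
#' sigma at isocenter log-linear in energy through 5.7 mm at 71.3 MeV and
#' 2.5 mm at 228.8 MeV, with spot MU cap and delivery timing parameters.
#'
#' @param max_mu maximum MU deliverable per spot per paint.
#' @param spot_switch_ms lateral spot switch time, ms.
#' @param layer_switch_s energy-layer switch time, s.
#' @param mu_rate MU delivery rate, MU/s.
#' @param sigma_growth_k in-patient lateral sigma growth coefficient:
#'   `sigma^2(depth) = sigma_air^2 + (k * wepl)^2`.
#' @return list of class `machine_model` with `energies` (MeV),
#'   `sigma_air(E)` (mm), `range_mm(E)`, timing and calibration fields.
#' @export
default_machine_model <- function(max_mu = 5, spot_switch_ms = 2,
                                  layer_switch_s = 2, mu_rate = 100,
                                  sigma_growth_k = 0.03) {
  e_lo <- 71.3; e_hi <- 228.8; n <- 97L
  energies <- exp(seq(log(e_lo), log(e_hi), length.out = n))
  energies[1] <- e_lo; energies[n] <- e_hi
  slope <- log(2.5 / 5.7) / log(e_hi / e_lo)
  sigma_air <- function(E) 5.7 * (E / e_lo)^slope
  range_mm <- function(E) 0.022 * E^1.77
  m <- list(energies = energies, sigma_air = sigma_air, range_mm = range_mm,
            max_mu = max_mu, spot_switch_ms = spot_switch_ms,
            layer_switch_s = layer_switch_s, mu_rate = mu_rate,
            sigma_growth_k = sigma_growth_k)
  # calibration: the reference spot (median energy, water) deposits
  # 1 Gy[RBE] at its Bragg peak per 100 MU; RBE 1.1 is folded in.
  e_ref <- energies[(n + 1) %/% 2]
  s2 <- sigma_air(e_ref)^2 + (sigma_growth_k * range_mm(e_ref))^2
  m$calibration_gy_per_mu <- 0.01 * 2 * pi * s2
  class(m) <- "machine_model"
  m
}

#' Hounsfield units to relative proton stopping power
#'
#' Piecewise linear: `1 + HU/1000` for HU <= 0 (air 0, water 1) and
#' `1 + HU/2048` above 0. Values below -1000 are clamped with a warning.
#'
#' @param hu numeric HU values (vectorized).
#' @return relative stopping power.
#' @export
hu_to_rsp <- function(hu) {
  if (any(hu < -1000)) {
    warning("HU below -1000 clamped to -1000")
    hu <- pmax(hu, -1000)
  }
  ifelse(hu <= 0, 1 + hu / 1000, 1 + hu / 1024 * 0.5)
}

#' Cumulative water-equivalent path length along a ray
#'
#' Trapezoidal accumulation of `RSP * step` from the entry point; returns
#' the cumulative WEPL at each sample together with the sample positions.
#'
#' @param ct `image_grid` (HU).
#' @param entry physical entry point, mm.
#' @param direction unit direction vector.
#' @param step step length, mm (<= min spacing).
#' @return list with `t_mm` (distance along ray), `wepl_mm`, `points`.
#' @export
wepl_along_ray <- function(ct, entry, direction, step = min(ct$spacing) / 2) {
  direction <- direction / sqrt(sum(direction^2))
  d <- dim(ct$data)
  extent <- sqrt(sum((d * ct$spacing)^2))
  t <- seq(0, extent, by = step)
  pts <- cbind(entry[1] + t * direction[1],
               entry[2] + t * direction[2],
               entry[3] + t * direction[3])
  rsp <- hu_to_rsp(interp_trilinear(ct$data, pts, ct$spacing, ct$origin,
                                    fill = -1000))
  inside <- !is.na(rsp)
  if (!any(rsp[inside] > 1e-6)) {
    return(list(t_mm = numeric(0), wepl_mm = numeric(0),
                points = pts[0, , drop = FALSE]))
  }
  w <- c(0, cumsum((rsp[-1] + rsp[-length(rsp)]) / 2 * step))
  list(t_mm = t, wepl_mm = w, points = pts)
}

# WEPL volume for an axis-aligned beam: cumulative midpoint sum of RSP
# along `axis` in direction `dir` (+1 = increasing index). WEPL at a voxel
# centre counts half of its own RSP.
wepl_volume <- function(ct, axis, dir = +1) {
  rsp <- array(hu_to_rsp(ct$data), dim(ct$data))
  sp <- ct$spacing[axis]
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(rsp, perm)
  if (dir < 0) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  cs <- apply(m, 2, cumsum)
  w <- (cs - m / 2) * sp
  w <- array(w, da)
  if (dir < 0) w <- w[rev(seq_len(da[1])), , , drop = FALSE]
  aperm(w, order(perm))
}

#' Analytic Bragg depth-dose curve
#'
#' Range `R(E) = alpha E^p` (alpha = 0.0022 cm MeV^-p, p = 1.77). The
#' curve is an entrance plateau times a Gaussian peak of width equal to
#' the range-straggling sigma, cut by a sigmoidal distal falloff at `R`,
#' normalized to unit peak, and exactly zero beyond the falloff tail.
#' Evaluated at `wepl / range_scale`, the whole curve (including the
#' distal 80% falloff depth) scales by `range_scale`.
#'
#' @param E proton energy, MeV.
#' @param wepl water-equivalent depth(s), mm (>= 0).
#' @param machine a `machine_model` (for the valid energy range).
#' @return normalized depth dose (unit peak).
#' @export
bragg_depth_dose <- function(E, wepl, machine = default_machine_model()) {
  if (any(wepl < 0)) stop("wepl must be >= 0")
  R <- machine$range_mm(E)
  sR <- pmax(1, 0.12 * R^0.935 / 10)   # straggling sigma, mm
  zp <- R
  shape <- (0.25 + 0.1 * wepl / R + 4 * exp(-(wepl - zp)^2 / (2 * sR^2))) /
    (1 + exp((wepl - R) / (0.35 * sR)))
  shape[wepl > R + 4 * sR] <- 0
  peak <- bragg_peak_value(E, machine)
  shape / peak
}

# cached unit-normalization constant per (energy, machine geometry)
bragg_peak_env <- new.env(parent = emptyenv())
bragg_peak_value <- function(E, machine) {
  key <- sprintf("%.6f", E)
  v <- bragg_peak_env[[key]]
  if (!is.null(v)) return(v)
  R <- machine$range_mm(E)
  sR <- max(1, 0.12 * R^0.935 / 10)
  z <- seq(max(0, R - 6 * sR), R + 2 * sR, by = 0.05)
  zp <- R
  s <- (0.25 + 0.1 * z / R + 4 * exp(-(z - zp)^2 / (2 * sR^2))) /
    (1 + exp((z - R) / (0.35 * sR)))
  v <- max(s)
  bragg_peak_env[[key]] <- v
  v
}

#' Beam description (axis-aligned)
#'
#' @param axis grid axis the beam travels along (1 = x, 2 = y, 3 = z).
#' @param dir +1 (increasing index) or -1.
#' @param label optional name.
#' @export
beam_geometry <- function(axis, dir = +1, label = NULL) {
  stopifnot(axis %in% 1:3, dir %in% c(-1, 1))
  list(axis = as.integer(axis), dir = as.integer(dir),
       label = label %||% sprintf("beam_axis%d_dir%+d", axis, dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uncertainty scenario
#' @param shift_mm length-3 setup shift, mm.
#' @param range_scale proton range scale factor (1 = nominal).
#' @export
scenario <- function(shift_mm = c(0, 0, 0), range_scale = 1) {
  list(shift_mm = as.numeric(shift_mm), range_scale = range_scale)
}

# per-beam WEPL sampled in the scenario frame: patient shifted by +s
# relative to the beam is equivalent to evaluating the nominal engine on
# the CT resampled at x - s, then reading dose at x + s. W(x) below is the
# WEPL the shifted patient's voxel x actually sees.
scenario_wepl <- function(ct, beam, sc) {
  if (all(abs(sc$shift_mm) < 1e-12)) return(wepl_volume(ct, beam$axis, beam$dir))
  ct_sh <- translate_image(ct, -sc$shift_mm, fill = -1000)
  w <- wepl_volume(ct_sh, beam$axis, beam$dir)
  wg <- image_grid(w, ct$spacing, ct$origin)
  translate_image(wg, sc$shift_mm, fill = 0)$data
}

# evaluate one spot's dose (Gy[RBE] per MU) at the voxels of `sub_idx`
# (linear indices into the grid), given the scenario WEPL volume `W`.
# Returns a list(idx, dose) of the strictly positive values; the support
# is truncated geometrically (3.5 sigma lateral, distal falloff tail) so
# the kept values are identical whichever voxel subset is evaluated —
# influence columns and dense dose grids agree exactly.
spot_dose_values <- function(spot, beam, machine, W, grid_dim, spacing,
                             origin, sub_idx, range_scale = 1,
                             shift_mm = c(0, 0, 0)) {
  lat_axes <- setdiff(1:3, beam$axis)
  arr_ind <- arrayInd(sub_idx, grid_dim)
  wv <- W[sub_idx] / range_scale
  E <- spot$energy
  R <- machine$range_mm(E)
  sR <- max(1, 0.12 * R^0.935 / 10)
  keep <- wv <= R + 4 * sR
  if (!any(keep)) return(list(idx = integer(0), dose = numeric(0)))
  arr_ind <- arr_ind[keep, , drop = FALSE]
  idx <- sub_idx[keep]; wv <- wv[keep]
  p1 <- origin[lat_axes[1]] + (arr_ind[, lat_axes[1]] - 1) * spacing[lat_axes[1]] +
    shift_mm[lat_axes[1]]
  p2 <- origin[lat_axes[2]] + (arr_ind[, lat_axes[2]] - 1) * spacing[lat_axes[2]] +
    shift_mm[lat_axes[2]]
  r2 <- (p1 - spot$lat1)^2 + (p2 - spot$lat2)^2
  s2 <- machine$sigma_air(E)^2 + (machine$sigma_growth_k * wv * range_scale)^2
  inlat <- r2 <= 3.5^2 * s2
  if (!any(inlat)) return(list(idx = integer(0), dose = numeric(0)))
  idx <- idx[inlat]; wv <- wv[inlat]; r2 <- r2[inlat]; s2 <- s2[inlat]
  depth <- bragg_depth_dose(E, wv, machine)
  dose <- depth * exp(-r2 / (2 * s2)) / (2 * pi * s2) *
    machine$calibration_gy_per_mu
  keep2 <- dose > 0
  list(idx = idx[keep2], dose = dose[keep2])
}

# bounding sub-volume indices for a spot: lateral window of +-half_mm
# around the spot, full depth extent
spot_subgrid_idx <- function(spot, beam, grid_dim, spacing, origin, half_mm,
                             shift_mm = c(0, 0, 0)) {
  lat_axes <- setdiff(1:3, beam$axis)
  rng <- vector("list", 3)
  rng[[beam$axis]] <- seq_len(grid_dim[beam$axis])
  for (a in lat_axes) {
    centre <- if (a == lat_axes[1]) spot$lat1 else spot$lat2
    lo <- max(1, floor((centre - shift_mm[a] - half_mm - origin[a]) / spacing[a]) + 1)
    hi <- min(grid_dim[a], ceiling((centre - shift_mm[a] + half_mm - origin[a]) / spacing[a]) + 1)
    if (lo > hi) return(integer(0))
    rng[[a]] <- lo:hi
  }
  i <- rng[[1]]; j <- rng[[2]]; k <- rng[[3]]
  as.vector(outer(outer(i, (j - 1) * grid_dim[1], `+`),
                  (k - 1) * grid_dim[1] * grid_dim[2], `+`))
}

#' Single-spot dose contribution (sparse, per MU)
#'
#' Evaluates one spot of a plan on its truncated support and returns the
#' sparse contribution in Gy[RBE] per MU. `range_scale` implements the
#' range-uncertainty scenario (WEPL divided by the scale).
#'
#' @param ct planning `image_grid` (HU).
#' @param plan a `spot_plan`; `index` selects the spot row.
#' @param machine `machine_model`.
#' @param index spot row in `plan$spots`.
#' @param range_scale proton range scale factor.
#' @return list with `idx` (linear voxel indices) and `dose` (Gy per MU).
#' @export
spot_dose <- function(ct, plan, machine, index = 1, range_scale = 1) {
  d <- dim(ct$data)
  sp_row <- plan$spots[index, ]
  beam <- plan$beams[[sp_row$beam]]
  W <- wepl_volume(ct, beam$axis, beam$dir)
  half_mm <- 3.5 * sqrt(machine$sigma_air(min(machine$energies))^2 +
                          (machine$sigma_growth_k * machine$range_mm(sp_row$energy))^2)
  spot <- list(lat1 = sp_row$lat1, lat2 = sp_row$lat2, energy = sp_row$energy)
  sub <- spot_subgrid_idx(spot, beam, d, ct$spacing, ct$origin, half_mm)
  if (!length(sub)) {
    warning("spot axis misses the body; zero contribution")
    return(list(idx = integer(0), dose = numeric(0)))
  }
  out <- spot_dose_values(spot, beam, machine, W, d, ct$spacing, ct$origin,
                          sub, range_scale = range_scale)
  if (!length(out$idx)) warning("spot deposits no dose on the grid")
  out
}

#' Influence structure: per-spot dose columns on a region of interest
#'
#' Applies the scenario (setup shift by resampling the CT, range scale by
#' dividing WEPL) and evaluates every spot's dose on the ROI voxels.
#' `compose_dose(influence, w)` is exactly `sum_i w_i d_i`.
#'
#' @param ct planning `image_grid` (HU).
#' @param plan a `spot_plan` (see [place_spots()]).
#' @param machine `machine_model`.
#' @param sc a [scenario()].
#' @param roi logical array: voxels on which columns are stored.
#' @return list of class `influence`: sparse `Matrix` (`n_roi` x n_spots),
#'   `roi_idx`, grid geometry.
#' @export
build_influence <- function(ct, plan, machine, sc = scenario(), roi) {
  if (nrow(plan$spots) == 0) stop("plan has no spots")
  d <- dim(ct$data)
  roi_idx <- which(roi)
  roi_pos <- integer(length(ct$data)); roi_pos[roi_idx] <- seq_along(roi_idx)
  trip_i <- vector("list", nrow(plan$spots))
  trip_x <- vector("list", nrow(plan$spots))
  W_by_beam <- lapply(plan$beams, function(b) scenario_wepl(ct, b, sc))
  sig_max <- machine$sigma_air(min(machine$energies))
  s_beam <- plan$spots$beam; s_E <- plan$spots$energy
  s_l1 <- plan$spots$lat1; s_l2 <- plan$spots$lat2
  for (si in seq_along(s_beam)) {
    beam <- plan$beams[[s_beam[si]]]
    W <- W_by_beam[[s_beam[si]]]
    half_mm <- 3.5 * sqrt(sig_max^2 +
                            (machine$sigma_growth_k * machine$range_mm(s_E[si]))^2)
    spot <- list(lat1 = s_l1[si], lat2 = s_l2[si], energy = s_E[si])
    sub <- spot_subgrid_idx(spot, beam, d, ct$spacing, ct$origin, half_mm,
                            sc$shift_mm)
    sub <- sub[roi_pos[sub] > 0]
    if (!length(sub)) { trip_i[[si]] <- integer(0); trip_x[[si]] <- numeric(0); next }
    val <- spot_dose_values(spot, beam, machine, W, d, ct$spacing, ct$origin,
                            sub, range_scale = sc$range_scale,
                            shift_mm = sc$shift_mm)
    trip_i[[si]] <- roi_pos[val$idx]
    trip_x[[si]] <- val$dose
  }
  ns <- lengths(trip_i)
  A <- Matrix::sparseMatrix(i = unlist(trip_i),
                            j = rep.int(seq_along(ns), ns),
                            x = unlist(trip_x),
                            dims = c(length(roi_idx), nrow(plan$spots)))
  structure(list(A = A, roi_idx = roi_idx, dim = d,
                 spacing = ct$spacing, origin = ct$origin,
                 scenario = sc),
            class = "influence")
}

#' Compose dose from an influence structure and spot weights
#' @param influence an `influence` from [build_influence()].
#' @param w spot weights (MU), length = number of spots.
#' @return numeric vector of dose on the ROI voxels.
#' @export
compose_dose <- function(influence, w) {
  as.numeric(influence$A %*% w)
}

#' Full-grid dose for a weighted plan (dense accumulation)
#'
#' Used for final dose maps and the 4D dynamic dose; evaluates every spot
#' on its truncated support and accumulates into a dense grid.
#'
#' @param ct `image_grid`; `plan` a `spot_plan`; `w` spot MU weights.
#' @param machine `machine_model`; `sc` a [scenario()].
#' @return `image_grid` of dose (Gy[RBE]).
#' @export
compute_dose_grid <- function(ct, plan, w, machine, sc = scenario()) {
  d <- dim(ct$data)
  out <- array(0, d)
  W_by_beam <- lapply(plan$beams, function(b) scenario_wepl(ct, b, sc))
  sig_max <- machine$sigma_air(min(machine$energies))
  s_beam <- plan$spots$beam; s_E <- plan$spots$energy
  s_l1 <- plan$spots$lat1; s_l2 <- plan$spots$lat2
  for (si in seq_along(s_beam)) {
    if (w[si] <= 0) next
    beam <- plan$beams[[s_beam[si]]]
    half_mm <- 3.5 * sqrt(sig_max^2 +
                            (machine$sigma_growth_k * machine$range_mm(s_E[si]))^2)
    spot <- list(lat1 = s_l1[si], lat2 = s_l2[si], energy = s_E[si])
    sub <- spot_subgrid_idx(spot, beam, d, ct$spacing, ct$origin, half_mm,
                            sc$shift_mm)
    if (!length(sub)) next
    val <- spot_dose_values(spot, beam, machine, W_by_beam[[s_beam[si]]], d,
                            ct$spacing, ct$origin, sub,
                            range_scale = sc$range_scale,
                            shift_mm = sc$shift_mm)
    out[val$idx] <- out[val$idx] + w[si] * val$dose
  }
  image_grid(out, ct$spacing, ct$origin)
}
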