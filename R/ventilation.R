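#' Ventilation maps
#'
#' Per-voxel fractional air-content change between exhale and inhale,
#' stored on the peak-exhale grid, with a validity mask (voxels excluded by
#' the near-singular-denominator guard or undefined ground truth) and an
#' optional percent-of-global-max view.
#'
#' @param values 3D array of fractional ventilation (NA outside validity).
#' @param valid logical array of the same shape.
#' @param spacing,origin exhale grid geometry.
#' @param percent optional percent-of-max array.
#' @export
ventilation_map <- function(values, valid, spacing, origin, percent = NULL) {
  stopifnot(identical(dim(values), dim(valid)))
  gm <- if (any(valid)) max(values[valid]) else NA_real_
  structure(list(values = values, valid = valid, spacing = spacing,
                 origin = origin, global_max = gm, percent = percent),
            class = "ventilation_map")
}

#' @export
print.ventilation_map <- function(x, ...) {
  cat("<ventilation_map>", sum(x$valid), "valid voxels, global max",
      signif(x$global_max, 4),
      if (!is.null(x$percent)) "(normalized view present)" else "", "\n")
  invisible(x)
}

#' Fractional ventilation from a mapped Hounsfield-unit pair
#'
#' The air-content identity for a mapped exhale/inhale voxel pair:
#' `(Vin - Vex)/Vex = 1000 (HUin - HUex) / (HUex (1000 + HUin))`.
#' A value of 0 means no volume change; 1.0 means the air volume doubled
#' from exhale to inhale.
#'
#' @param hu_in,hu_ex Hounsfield units of the mapped inhale/exhale pair
#'   (vectorized).
#' @param eps_hu near-singular guard: pairs with `|HUex| < eps_hu` or
#'   `|1000 + HUin| < eps_hu` return NA.
#' @return numeric vector of fractional ventilation values.
#' @export
hu_pair_ventilation <- function(hu_in, hu_ex, eps_hu = 1) {
  out <- 1000 * (hu_in - hu_ex) / (hu_ex * (1000 + hu_in))
  out[abs(hu_ex) < eps_hu | abs(1000 + hu_in) < eps_hu] <- NA_real_
  out
}

#' Compute a ventilation image from an exhale/inhale pair
#'
#' For each exhale voxel `x` in the mask, `HUex` is the exhale grid value
#' and `HUin` is sampled at the mapped position `x + u(x)` (trilinear by
#' default). With `sampling = "presampled"`, `inhale` is taken as an array
#' of HU values already evaluated at the mapped positions (one per exhale
#' voxel) — the interpolation-free path used for analytic closure checks.
#'
#' @param exhale `image_grid` (peak exhale, HU).
#' @param inhale `image_grid`, or with `"presampled"` an array/`image_grid`
#'   of mapped HU values on the exhale grid.
#' @param dvf exhale-to-inhale `displacement_field` on the exhale grid.
#' @param mask logical array restricting the computation (lung mask).
#' @param eps_hu singular-denominator guard in HU.
#' @param sampling `"trilinear"` or `"presampled"`.
#' @return a [ventilation_map()].
#' @export
compute_ventilation <- function(exhale, inhale, dvf, mask,
                                eps_hu = 1,
                                sampling = c("trilinear", "presampled")) {
  sampling <- match.arg(sampling)
  d <- dim(exhale$data)
  stopifnot(identical(dim(mask), d))
  if (!all(abs(dvf$spacing - exhale$spacing) < 1e-6) ||
      !identical(dim(dvf$u)[1:3], d))
    stop("displacement field grid does not match the exhale image grid")
  idx <- which(mask)
  hu_ex <- exhale$data[idx]
  if (sampling == "presampled") {
    arr <- if (inherits(inhale, "image_grid")) inhale$data else inhale
    stopifnot(identical(dim(arr), d))
    hu_in <- arr[idx]
  } else {
    if (!grid_compatible(exhale, inhale))
      stop("exhale/inhale grid geometry mismatch")
    pts <- grid_points(exhale)[idx, , drop = FALSE]
    pts[, 1] <- pts[, 1] + dvf$u[, , , 1][idx]
    pts[, 2] <- pts[, 2] + dvf$u[, , , 2][idx]
    pts[, 3] <- pts[, 3] + dvf$u[, , , 3][idx]
    hu_in <- interp_trilinear(inhale$data, pts, inhale$spacing, inhale$origin,
                              fill = -1000)
  }
  v <- hu_pair_ventilation(hu_in, hu_ex, eps_hu = eps_hu)
  vals <- array(NA_real_, d)
  vals[idx] <- v
  valid <- array(FALSE, d)
  valid[idx] <- !is.na(v)
  ventilation_map(vals, valid, exhale$spacing, exhale$origin)
}

#' Normalize a ventilation map to its global maximum
#'
#' Negative values (possible with noise or registration error) are clipped
#' to 0 before normalization; the percent view is `100 * value / max`.
#'
#' @param vmap a [ventilation_map()].
#' @return the map with the `percent` view populated.
#' @export
normalize_to_max <- function(vmap) {
  if (!any(vmap$valid)) stop("no valid voxels to normalize")
  vals <- vmap$values
  vals[vmap$valid] <- pmax(vals[vmap$valid], 0)
  gm <- max(vals[vmap$valid])
  if (gm <= 0) stop("global maximum ventilation is <= 0; cannot normalize")
  pct <- array(NA_real_, dim(vals))
  pct[vmap$valid] <- 100 * vals[vmap$valid] / gm
  out <- ventilation_map(vals, vmap$valid, vmap$spacing, vmap$origin,
                         percent = pct)
  out$global_max <- gm
  out
}

#' Intensity-based lung segmentation
#'
#' Thresholds the HU window, keeps the two largest 6-connected components,
#' assigns left/right by the midline, removes exclusion masks (airway,
#' tumor) and applies one round of 6-neighbourhood morphological closing.
#'
#' @param ct exhale `image_grid` (HU).
#' @param hu_window inclusive HU window for lung parenchyma.
#' @param exclusions optional list of logical arrays removed from the
#'   result (e.g. airway, tumor).
#' @return list with logical arrays `left` and `right`.
#' @export
segment_lungs <- function(ct, hu_window = c(-1000, -250), exclusions = list()) {
  d <- dim(ct$data)
  cand <- ct$data >= hu_window[1] & ct$data <= hu_window[2]
  # drop external air attached to the volume faces: require value > -1000+5
  cand <- cand & ct$data > -999.5
  lab <- connected_components(cand)
  sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
  if (length(sizes) < 2)
    stop("fewer than 2 candidate lung components found; ",
         "adjust hu_window (used [", hu_window[1], ", ", hu_window[2], "])")
  keep <- as.numeric(names(sizes)[1:2])
  comp1 <- lab == keep[1]; comp2 <- lab == keep[2]
  cx1 <- mean(which(comp1, arr.ind = TRUE)[, 1])
  cx2 <- mean(which(comp2, arr.ind = TRUE)[, 1])
  left <- if (cx1 < cx2) comp1 else comp2
  right <- if (cx1 < cx2) comp2 else comp1
  close6 <- function(m) {
    dil <- m
    for (axis in 1:3) dil <- dil | shift_array(m, axis, 1L) | shift_array(m, axis, -1L)
    ero <- dil
    for (axis in 1:3) ero <- ero & shift_array(dil, axis, 1L) & shift_array(dil, axis, -1L)
    ero
  }
  left <- close6(left); right <- close6(right)
  for (ex in exclusions) { left <- left & !ex; right <- right & !ex }
  list(left = left, right = right)
}

#' Regional ventilation profile (six lung thirds)
#'
#' Each lung's cranio-caudal bounding extent is split into three
#' equal-height slabs (superior/middle/inferior); the regional share is the
#' clipped-positive ventilation sum in the region as a percent of the total
#' over both lungs.
#'
#' @param vmap a [ventilation_map()].
#' @param lungs list with logical arrays `left` and `right`.
#' @return data.frame of class `regional_profile`: lung, region, voxel
#'   volume (cc), ventilation share (%), volume share (%).
#' @export
regional_profile <- function(vmap, lungs) {
  stopifnot(any(lungs$left), any(lungs$right))
  vox_cc <- prod(vmap$spacing) / 1000
  vals <- vmap$values
  vals[!vmap$valid] <- 0
  vals <- pmax(vals, 0)
  rows <- list()
  for (side in c("left", "right")) {
    m <- lungs[[side]]
    kz <- which(apply(m, 3, any))
    z0 <- min(kz); z1 <- max(kz)
    if (z1 - z0 + 1 < 3)
      stop(side, " lung spans fewer than 3 slices; cannot form thirds")
    # half-open bands on slice index, offset by 0.5 so integer slices can
    # never sit exactly on an edge (no double counting)
    edges <- z0 - 0.5 + (z1 - z0 + 1) * c(0, 1, 2, 3) / 3
    for (r in 1:3) {
      sl <- seq_len(dim(m)[3])
      inband <- sl > edges[r] & sl <= edges[r + 1]
      region <- m & rep(inband, each = prod(dim(m)[1:2]))
      rows[[length(rows) + 1]] <- data.frame(
        lung = side, region = c("inferior", "middle", "superior")[r],
        volume_cc = sum(region) * vox_cc,
        vent_sum = sum(vals[region]))
    }
  }
  df <- do.call(rbind, rows)
  total <- sum(df$vent_sum)
  if (total <= 0) stop("total ventilation is zero; no profile")
  df$share_pct <- 100 * df$vent_sum / total
  df$volume_pct <- 100 * df$volume_cc / sum(df$volume_cc)
  df$vent_sum <- NULL
  class(df) <- c("regional_profile", "data.frame")
  df
}

#' Screen functional-planning eligibility from the regional profile
#'
#' The expected share of each region is its volume fraction of the total
#' lung; the deficit is `expected - observed` in percentage points. A
#' patient is eligible when any regional deficit reaches the threshold
#' (inclusive: "15% or more").
#'
#' @param profile a [regional_profile()].
#' @param deficit_threshold eligibility threshold in percentage points.
#' @return list with `eligible`, `max_deficit`, and the per-region table.
#' @export
screen_eligibility <- function(profile, deficit_threshold = 15) {
  deficit <- profile$volume_pct - profile$share_pct
  out <- data.frame(lung = profile$lung, region = profile$region,
                    expected_pct = profile$volume_pct,
                    observed_pct = profile$share_pct,
                    deficit_pct = deficit)
  list(eligible = max(deficit) >= deficit_threshold,
       max_deficit = max(deficit),
       threshold = deficit_threshold,
       regions = out)
}
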