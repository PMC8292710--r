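#' Volumetric image grids
#'
#' An `image_grid` is a 3D numeric array (HU, dose, or any scalar field)
#' carrying physical geometry: voxel spacing (mm) and the physical position
#' of the first voxel centre (origin, mm). Axis convention: dimension 1 is
#' left-right (x), dimension 2 anterior-posterior (y), dimension 3
#' inferior-superior (z, cranio-caudal). Physical coordinate of voxel
#' `(i,j,k)` is `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(data, spacing = c(2.5, 2.5, 2.5), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> dims", paste(dim(x$data), collapse = "x"),
      " spacing", paste(signif(x$spacing, 4), collapse = "/"), "mm",
      " range [", signif(min(x$data), 5), ",", signif(max(x$data), 5), "]\n")
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$data)

grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$data)[1:3], dim(b$data)[1:3]) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Physical coordinates of every voxel centre
#'
#' @param g an `image_grid` (or any object with `spacing`, `origin`, `data`).
#' @return n-by-3 matrix of physical coordinates (mm), voxels in array order.
#' @export
grid_points <- function(g) {
  d <- dim(g$data)[1:3]
  i <- rep.int(seq_len(d[1]), d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  cbind(g$origin[1] + (i - 1) * g$spacing[1],
        g$origin[2] + (j - 1) * g$spacing[2],
        g$origin[3] + (k - 1) * g$spacing[3])
}

#' Trilinear interpolation of a 3D array at physical points
#'
#' Points outside the grid return `fill`. The workhorse sampler used by the
#' warper, the phase renderer and the dose engine; fully vectorized.
#'
#' @param arr 3D numeric array.
#' @param pts n-by-3 matrix of physical points (mm).
#' @param spacing,origin grid geometry of `arr`.
#' @param fill value returned for points outside the grid (default `NA`).
#' @return numeric vector of length `nrow(pts)`.
#' @export
interp_trilinear <- function(arr, pts, spacing, origin, fill = NA_real_) {
  d <- dim(arr)
  fx <- (pts[, 1] - origin[1]) / spacing[1] + 1
  fy <- (pts[, 2] - origin[2]) / spacing[2] + 1
  fz <- (pts[, 3] - origin[3]) / spacing[3] + 1
  inside <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  i0 <- pmin(pmax(floor(fx), 1), d[1] - 1L)
  j0 <- pmin(pmax(floor(fy), 1), d[2] - 1L)
  k0 <- pmin(pmax(floor(fz), 1), d[3] - 1L)
  # degenerate single-slab axes: clamp offsets to the only voxel
  if (d[1] == 1L) i0 <- rep(1, length(fx))
  if (d[2] == 1L) j0 <- rep(1, length(fy))
  if (d[3] == 1L) k0 <- rep(1, length(fz))
  wx <- pmin(pmax(fx - i0, 0), 1); wy <- pmin(pmax(fy - j0, 0), 1)
  wz <- pmin(pmax(fz - k0, 0), 1)
  sx <- if (d[1] > 1L) 1L else 0L
  sy <- if (d[2] > 1L) 1L else 0L
  sz <- if (d[3] > 1L) 1L else 0L
  n12 <- d[1] * d[2]
  base <- (i0 - 1) + (j0 - 1) * d[1] + (k0 - 1) * n12 + 1
  v000 <- arr[base]
  v100 <- arr[base + sx]
  v010 <- arr[base + sy * d[1]]
  v110 <- arr[base + sx + sy * d[1]]
  v001 <- arr[base + sz * n12]
  v101 <- arr[base + sx + sz * n12]
  v011 <- arr[base + sy * d[1] + sz * n12]
  v111 <- arr[base + sx + sy * d[1] + sz * n12]
  c00 <- v000 * (1 - wx) + v100 * wx
  c10 <- v010 * (1 - wx) + v110 * wx
  c01 <- v001 * (1 - wx) + v101 * wx
  c11 <- v011 * (1 - wx) + v111 * wx
  out[inside] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
    (c01 * (1 - wy) + c11 * wy) * wz
  out
}

#' Translate (resample) an image by a physical offset
#'
#' `output(x) = input(x + shift_mm)`: content appears moved by `-shift_mm`.
#'
#' @param g `image_grid`.
#' @param shift_mm length-3 physical offset (mm).
#' @param fill out-of-grid fill value.
#' @export
translate_image <- function(g, shift_mm, fill = -1000) {
  pts <- grid_points(g)
  pts[, 1] <- pts[, 1] + shift_mm[1]
  pts[, 2] <- pts[, 2] + shift_mm[2]
  pts[, 3] <- pts[, 3] + shift_mm[3]
  v <- interp_trilinear(g$data, pts, g$spacing, g$origin, fill = fill)
  image_grid(array(v, dim(g$data)), g$spacing, g$origin)
}

# shift a 3D array by integer voxels along one axis, zero (or `fill`) padded
shift_array <- function(arr, axis, by, fill = 0) {
  if (by == 0) return(arr)
  d <- dim(arr)
  out <- array(fill, d)
  idx_src <- vector("list", 3); idx_dst <- vector("list", 3)
  for (a in 1:3) { idx_src[[a]] <- seq_len(d[a]); idx_dst[[a]] <- seq_len(d[a]) }
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- seq_len(n - by); idx_src[[axis]] <- (by + 1):n }
  else { idx_dst[[axis]] <- (-by + 1):n; idx_src[[axis]] <- seq_len(n + by) }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# separable Gaussian smoothing (voxel-unit sigma per axis), replicate edges
gaussian_smooth3 <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3)
  out <- arr
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2)); k <- k / sum(k)
    acc <- array(0, dim(arr)); wsum <- array(0, dim(arr))
    ones <- array(1, dim(arr))
    for (m in seq_along(k)) {
      by <- m - r - 1L
      acc <- acc + k[m] * shift_array(out, axis, by, fill = 0)
      wsum <- wsum + k[m] * shift_array(ones, axis, by, fill = 0)
    }
    out <- acc / wsum
  }
  out
}

# central-difference gradient of a 3D array, per mm; one-sided at edges
gradient3 <- function(arr, spacing) {
  g <- vector("list", 3)
  for (axis in 1:3) {
    fwd <- shift_array(arr, axis, 1L)
    bwd <- shift_array(arr, axis, -1L)
    d <- dim(arr); n <- d[axis]
    denom <- array(2 * spacing[axis], d)
    idx <- vector("list", 3); for (a in 1:3) idx[[a]] <- seq_len(d[a])
    i1 <- idx; i1[[axis]] <- 1L
    iN <- idx; iN[[axis]] <- n
    # forward/backward one-sided at the two faces
    fwd[i1[[1]], i1[[2]], i1[[3]]] <- fwd[i1[[1]], i1[[2]], i1[[3]]]
    bwd[i1[[1]], i1[[2]], i1[[3]]] <- arr[i1[[1]], i1[[2]], i1[[3]]]
    denom[i1[[1]], i1[[2]], i1[[3]]] <- spacing[axis]
    fwd[iN[[1]], iN[[2]], iN[[3]]] <- arr[iN[[1]], iN[[2]], iN[[3]]]
    denom[iN[[1]], iN[[2]], iN[[3]]] <- spacing[axis]
    g[[axis]] <- (fwd - bwd) / denom
  }
  g
}

# 6-neighbour Laplacian (per mm^2), zero-gradient boundary
laplacian3 <- function(arr, spacing) {
  out <- array(0, dim(arr))
  for (axis in 1:3) {
    fwd <- shift_array(arr, axis, 1L)
    bwd <- shift_array(arr, axis, -1L)
    d <- dim(arr); n <- d[axis]
    idx <- vector("list", 3); for (a in 1:3) idx[[a]] <- seq_len(d[a])
    i1 <- idx; i1[[axis]] <- 1L; iN <- idx; iN[[axis]] <- n
    bwd[i1[[1]], i1[[2]], i1[[3]]] <- arr[i1[[1]], i1[[2]], i1[[3]]]
    fwd[iN[[1]], iN[[2]], iN[[3]]] <- arr[iN[[1]], iN[[2]], iN[[3]]]
    out <- out + (fwd + bwd - 2 * arr) / spacing[axis]^2
  }
  out
}

# downsample by 2 (2x2x2 block mean); used by the registration pyramid
downsample2 <- function(g) {
  d <- dim(g$data)
  d2 <- pmax(1L, d %/% 2L)
  a <- g$data[seq_len(2 * d2[1]), seq_len(2 * d2[2]), seq_len(2 * d2[3]), drop = FALSE]
  a <- (a[seq(1, 2 * d2[1], 2), , , drop = FALSE] + a[seq(2, 2 * d2[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * d2[2], 2), , drop = FALSE] + a[, seq(2, 2 * d2[2], 2), , drop = FALSE]) / 2
  a <- (a[, , seq(1, 2 * d2[3], 2), drop = FALSE] + a[, , seq(2, 2 * d2[3], 2), drop = FALSE]) / 2
  image_grid(array(a, d2), g$spacing * 2, g$origin + g$spacing / 2)
}

# labels 6-connected components of a logical mask by max-label propagation
connected_components <- function(mask) {
  lab <- array(0, dim(mask))
  lab[mask] <- which(mask)
  repeat {
    nxt <- lab
    for (axis in 1:3) {
      nxt <- pmax(nxt, shift_array(lab, axis, 1L), shift_array(lab, axis, -1L))
    }
    nxt[!mask] <- 0
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}
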