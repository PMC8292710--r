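#' Functional-lung and planning structures
#'
#' Derives the planning structure set from the ventilation image and the
#' per-phase tumor masks: functional lung by the percent-of-max threshold,
#' the iGTV as the union of tumor positions over the phases, the CTV and
#' PTV margin chain, and the optimization substructures used by the
#' functional-avoidance objectives.
#'
#' @name structures
NULL

#' Threshold the normalized ventilation map into a functional-lung mask
#'
#' Voxels at or above `threshold_pct` percent of the global maximum,
#' intersected with the lung mask.
#'
#' @param vmap a normalized [ventilation_map()] (percent view present).
#' @param lung_mask logical array.
#' @param threshold_pct lower intensity threshold, percent of global max.
#' @return logical array.
#' @export
functional_lung_mask <- function(vmap, lung_mask, threshold_pct = 15) {
  if (is.null(vmap$percent))
    stop("ventilation map has no percent view; call normalize_to_max() first")
  m <- !is.na(vmap$percent) & vmap$percent >= threshold_pct & lung_mask
  if (!any(m)) warning("functional lung mask is empty at threshold ",
                       threshold_pct, "%")
  m
}

# squared Euclidean distance (mm^2) from a mask, exact up to `cap_mm`;
# separable min-convolution with offsets capped at the needed radius
squared_edt <- function(mask, spacing, cap_mm) {
  big <- (cap_mm + max(spacing)) ^ 2 * 4 + 1
  dt <- array(big, dim(mask))
  dt[mask] <- 0
  for (axis in 1:3) {
    k <- ceiling(cap_mm / spacing[axis]) + 1L
    cur <- dt
    for (s in seq(-k, k)) {
      if (s == 0) next
      cand <- shift_array(cur, axis, s, fill = big) + (s * spacing[axis])^2
      dt <- pmin(dt, cand)
    }
  }
  dt
}

#' Isotropic physical-distance margin expansion of a mask
#'
#' Euclidean-distance-transform dilation: the result contains every voxel
#' whose centre lies within `margin_mm` physical millimetres of a mask
#' voxel centre, optionally clipped to the body.
#'
#' @param mask logical array.
#' @param margin_mm margin in mm (>= 0).
#' @param spacing voxel spacing, mm.
#' @param clip optional logical array to intersect with (body mask).
#' @return logical array.
#' @export
expand_margin <- function(mask, margin_mm, spacing, clip = NULL) {
  if (margin_mm < 0) stop("margin must be >= 0")
  out <- if (margin_mm == 0) mask
  else squared_edt(mask, spacing, margin_mm) <= margin_mm^2 + 1e-6
  if (!is.null(clip)) out <- out & clip
  out
}

#' Internal gross tumor volume from the per-phase tumor masks
#'
#' Voxelwise union over all breathing phases.
#'
#' @param tumor_masks list of logical arrays (one per phase, >= 1).
#' @return logical array.
#' @export
build_igtv <- function(tumor_masks) {
  stopifnot(length(tumor_masks) >= 1)
  out <- Reduce(`|`, tumor_masks)
  if (!any(out)) stop("union of phase tumor masks is empty")
  out
}

#' Build the full planning structure set
#'
#' Margin chain: GTV (reference-phase tumor) -> iGTV (union over phases) ->
#' CTV (`ctv_margin_mm` isotropic, default 8 mm within the stated 6-10 mm
#' range) -> PTV (+5 mm). Lung-dose structures exclude the iGTV. The
#' functional lung (normalized ventilation >= `functional_threshold_pct`)
#' is split into the avoidance substructures used by the optimizer:
#' functional minus PTV, and functional rings 0-1 cm and 1-3 cm from the
#' PTV.
#'
#' @param anatomy `phantom_anatomy` (or any list providing body, lung and
#'   OAR masks with the same names).
#' @param vmap normalized [ventilation_map()].
#' @param tumor_masks list of per-phase tumor masks.
#' @param ctv_margin_mm,ptv_margin_mm margins, mm.
#' @param functional_threshold_pct functional-lung threshold, percent.
#' @return list of class `structure_set`: named logical masks plus margin
#'   metadata.
#' @export
make_structures <- function(anatomy, vmap, tumor_masks,
                            ctv_margin_mm = 8, ptv_margin_mm = 5,
                            functional_threshold_pct = 15) {
  sp <- anatomy$spacing
  body <- anatomy$body
  gtv <- tumor_masks[[1]]
  igtv <- build_igtv(tumor_masks)
  ctv <- expand_margin(igtv, ctv_margin_mm, sp, clip = body)
  ptv <- expand_margin(ctv, ptv_margin_mm, sp, clip = body)
  lungs_all <- anatomy$lung_left | anatomy$lung_right
  igtv_halo <- expand_margin(igtv, 5, sp)
  tumor_in_right <- sum(igtv_halo & anatomy$lung_right) >
    sum(igtv_halo & anatomy$lung_left)
  ipsi <- if (tumor_in_right) anatomy$lung_right else anatomy$lung_left
  contra <- if (tumor_in_right) anatomy$lung_left else anatomy$lung_right
  func_total <- functional_lung_mask(vmap, lungs_all, functional_threshold_pct)
  ring1 <- expand_margin(ptv, 10, sp, clip = body) & !ptv
  ring3 <- expand_margin(ptv, 30, sp, clip = body) & !expand_margin(ptv, 10, sp)
  s <- list(
    gtv = gtv, igtv = igtv, ctv = ctv, ptv = ptv,
    lung_ipsi = ipsi & !igtv, lung_contra = contra & !igtv,
    lung_total = lungs_all & !igtv,
    functional_total = func_total & !igtv,
    functional_ipsi = func_total & ipsi & !igtv,
    functional_contra = func_total & contra & !igtv,
    functional_minus_ptv = func_total & !ptv & !igtv,
    functional_ring_0_1cm = func_total & ring1,
    functional_ring_1_3cm = func_total & ring3,
    esophagus = anatomy$esophagus, heart = anatomy$heart, cord = anatomy$cord,
    body = body)
  structure(c(s, list(margins = list(ctv_mm = ctv_margin_mm,
                                     ptv_mm = ptv_margin_mm,
                                     functional_threshold_pct = functional_threshold_pct),
                      spacing = sp)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  nm <- names(x)[vapply(x, is.logical, TRUE)]
  vox_cc <- prod(x$spacing) / 1000
  for (n in nm)
    cat(sprintf("  %-22s %8.1f cc\n", n, sum(x[[n]]) * vox_cc))
  invisible(x)
}
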