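#' Dose-volume histogram and plan quality metrics
#'
#' Cumulative DVHs on fixed-width dose bins, the sorted-voxel Dx/Vx
#' rules, conformity and homogeneity indices, and the functional-lung
#' metric set (fV20, fV30, fMLD).
#'
#' @name metrics
NULL

#' Cumulative dose-volume histogram
#'
#' `V(d)` = percent of structure voxels with dose >= d, evaluated at the
#' bin edges; mean and max are exact (un-binned).
#'
#' @param dose `image_grid` or numeric array/vector of dose.
#' @param mask logical array (nonempty) selecting the structure; omit if
#'   `dose` is already the structure's voxel-dose vector.
#' @param bin_gy bin width, Gy.
#' @return list of class `dvh`: `edges_gy`, `volume_pct` (non-increasing,
#'   starts at 100), `n_voxels`, `mean_gy`, `max_gy`.
#' @export
cumulative_dvh <- function(dose, mask = NULL, bin_gy = 0.1) {
  d <- if (inherits(dose, "image_grid")) dose$data else dose
  v <- if (is.null(mask)) as.numeric(d) else {
    if (!any(mask)) stop("empty structure mask")
    d[mask]
  }
  if (!length(v)) stop("empty structure mask")
  mx <- max(v)
  edges <- seq(0, mx + bin_gy, by = bin_gy)
  vol <- vapply(edges, function(e) 100 * mean(v >= e), 1)
  structure(list(edges_gy = edges, volume_pct = vol, n_voxels = length(v),
                 mean_gy = mean(v), max_gy = mx),
            class = "dvh")
}

#' Minimum dose to the hottest x percent of a structure (Dx)
#'
#' Sorted-voxel rule: sort doses descending and take the value at
#' position `ceil(x/100 * n)`.
#'
#' @param doses numeric vector of structure voxel doses.
#' @param x percent volume in (0, 100].
#' @return Dx in Gy.
#' @export
dose_at_volume <- function(doses, x) {
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  s <- sort(doses, decreasing = TRUE)
  s[max(1L, ceiling(x / 100 * length(s)))]
}

#' Percent of a structure receiving at least a dose level (Vx)
#'
#' @param doses numeric vector of structure voxel doses.
#' @param dose_gy dose level, Gy.
#' @return percent of volume (exact voxel counting).
#' @export
volume_at_dose <- function(doses, dose_gy) {
  100 * mean(doses >= dose_gy)
}

#' Evaluate a DVH metric by name
#'
#' Specs: `"Dx"` / `"D5-D95"` (sorted-voxel rule), `"Vx"` (exact
#' counting; the functional-lung `fVx` is the same rule on the functional
#' mask), `"mean"`, `"max"`.
#'
#' @param doses numeric vector of structure voxel doses.
#' @param spec metric name, e.g. `"D95"`, `"V20"`, `"D5-D95"`, `"mean"`.
#' @return metric value (Gy for Dx/mean/max, % for Vx).
#' @export
dvh_metric <- function(doses, spec) {
  spec <- gsub("^f", "", spec)
  if (spec == "mean") return(mean(doses))
  if (spec == "max") return(max(doses))
  if (grepl("^D[0-9.]+-D[0-9.]+$", spec)) {
    xs <- as.numeric(sub("D", "", strsplit(spec, "-")[[1]]))
    return(dose_at_volume(doses, xs[1]) - dose_at_volume(doses, xs[2]))
  }
  if (grepl("^D[0-9.]+$", spec))
    return(dose_at_volume(doses, as.numeric(sub("D", "", spec))))
  if (grepl("^V[0-9.]+$", spec))
    return(volume_at_dose(doses, as.numeric(sub("V", "", spec))))
  stop("unknown metric spec: ", spec)
}

#' Conformity and homogeneity indices
#'
#' RTOG-style conformity index: body volume receiving at least the
#' prescription over the CTV volume. Homogeneity index: D5/D95 of the
#' CTV. (The literature has several definitions; these are the common
#' ones consistent with values near 1-2.)
#'
#' @param dose dose `image_grid`.
#' @param ctv logical CTV mask (nonempty).
#' @param rx prescription, Gy (> 0).
#' @param body optional body mask (defaults to the whole grid).
#' @return `conformity_index` and `homogeneity_index` return a number.
#' @export
conformity_index <- function(dose, ctv, rx, body = NULL) {
  if (rx <= 0) stop("rx must be > 0")
  if (!any(ctv)) stop("empty CTV")
  d <- dose$data
  iso <- if (is.null(body)) sum(d >= rx) else sum(d[body] >= rx)
  iso / sum(ctv)
}

#' @rdname conformity_index
#' @export
homogeneity_index <- function(dose, ctv) {
  if (!any(ctv)) stop("empty CTV")
  v <- dose$data[ctv]
  dose_at_volume(v, 5) / dose_at_volume(v, 95)
}

#' Standard metric table for a plan (Table-2 style rows)
#'
#' @param dose dose `image_grid`.
#' @param structures a `structure_set`.
#' @param rx prescription, Gy.
#' @return data.frame: structure, metric, value.
#' @export
plan_metric_table <- function(dose, structures, rx) {
  rows <- list()
  add <- function(structure, metric, value)
    rows[[length(rows) + 1]] <<- data.frame(structure = structure,
                                            metric = metric, value = value)
  dd <- dose$data
  ctv <- dd[structures$ctv]
  add("ctv", "max", max(ctv))
  add("ctv", "D99", dose_at_volume(ctv, 99))
  add("ctv", "CI", conformity_index(dose, structures$ctv, rx,
                                    body = structures$body))
  add("ctv", "HI", homogeneity_index(dose, structures$ctv))
  for (s in c("lung_total", "lung_ipsi", "lung_contra")) {
    v <- dd[structures[[s]]]
    add(s, "MLD", mean(v)); add(s, "V20", volume_at_dose(v, 20))
    add(s, "V5", volume_at_dose(v, 5))
  }
  add("esophagus", "mean", mean(dd[structures$esophagus]))
  add("heart", "mean", mean(dd[structures$heart]))
  add("cord", "max", max(dd[structures$cord]))
  for (s in c("functional_total", "functional_ipsi", "functional_contra")) {
    if (!any(structures[[s]])) next
    v <- dd[structures[[s]]]
    add(s, "fMLD", mean(v))
    for (x in c(5, 10, 20, 30)) add(s, paste0("fV", x), volume_at_dose(v, x))
  }
  do.call(rbind, rows)
}
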