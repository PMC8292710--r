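#' 4D dynamic delivery (interplay) simulation
#'
#' Assigns each delivered spot (after max-MU iso-layer repainting) to a
#' breathing phase from its absolute delivery time, deposits its dose on
#' that phase's anatomy, pulls every phase dose back to the reference
#' (exhale) grid through the known phase displacement field, and reports
#' the metric differences between nominal and dynamic dose. Delivery is a
#' single fraction — the worst case for interplay.
#'
#' @name interplay
NULL

#' Max-MU iso-layer repainting
#'
#' Each energy layer is delivered `N = ceil(max spot MU in layer /
#' max_mu)` times; every paint delivers `weight / N`, so total MU is
#' conserved exactly.
#'
#' @param plan a `spot_plan` with `weights` set (MU).
#' @param max_mu per-spot MU cap per paint (> 0).
#' @return the plan with `paints` (per-layer paint counts) attached.
#' @export
repaint_layers <- function(plan, max_mu) {
  if (max_mu <= 0) stop("max_mu must be > 0")
  key <- paste(plan$spots$beam, plan$spots$layer)
  mx <- tapply(plan$weights, key, max)
  paints <- pmax(1L, as.integer(ceiling(mx / max_mu)))
  names(paints) <- names(mx)
  plan$paints <- as.integer(paints[key])
  plan$max_mu <- max_mu
  plan
}

#' Timed delivery sequence
#'
#' Iso-layer order: all paints of a layer are delivered back-to-back
#' before the next layer. Time advances by `MU / rate` per spot plus the
#' spot switch per spot; each layer change (including between paints)
#' adds the layer switch time. Event times are delivery-completion times.
#'
#' @param plan a repainted `spot_plan` (see [repaint_layers()]).
#' @param machine `machine_model` (timing fields).
#' @return data.frame of class `timed_spot_sequence`: spot (index into
#'   `plan$spots`), paint, t_s (completion time), mu.
#' @export
delivery_timeline <- function(plan, machine) {
  if (machine$mu_rate <= 0) stop("MU rate must be positive")
  if (is.null(plan$paints)) plan$paints <- rep(1L, nrow(plan$spots))
  key <- paste(plan$spots$beam, plan$spots$layer)
  layers <- unique(key)
  t <- 0
  rows <- vector("list", 0)
  first_layer <- TRUE
  for (lk in layers) {
    idx <- which(key == lk)
    npaint <- as.integer(plan$paints[idx[1]])
    for (p in seq_len(npaint)) {
      if (!first_layer || p > 1) t <- t + machine$layer_switch_s
      first_layer <- FALSE
      mu <- plan$weights[idx] / npaint
      for (q in seq_along(idx)) {
        t <- t + mu[q] / machine$mu_rate
        rows[[length(rows) + 1]] <- c(idx[q], p, t, mu[q])
        if (q < length(idx)) t <- t + machine$spot_switch_ms / 1000
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("spot", "paint", "t_s", "mu")
  out$spot <- as.integer(out$spot); out$paint <- as.integer(out$paint)
  class(out) <- c("timed_spot_sequence", "data.frame")
  out
}

#' Breathing scenario enumeration for the interplay study
#'
#' Cartesian product of start phases and periods: 2 starts (max inhale,
#' max exhale) x 3 periods (3, 5, 7 s) = 6 scenarios by default.
#'
#' @param starts character vector of start phases.
#' @param periods_s numeric vector of periods, s.
#' @param amplitude_mm,n_phases passed to [breathing_config()].
#' @return list of [breathing_config()]s.
#' @export
enumerate_breathing_scenarios <- function(starts = c("max_inhale", "max_exhale"),
                                          periods_s = c(3, 5, 7),
                                          amplitude_mm = 6, n_phases = 10) {
  if (!length(starts) || !length(periods_s))
    stop("starts and periods must be nonempty")
  out <- list()
  for (s in starts) for (p in periods_s)
    out[[length(out) + 1]] <- breathing_config(
      period_s = p, start_phase = s, amplitude_mm = amplitude_mm,
      n_phases = n_phases)
  out
}

#' Simulate the 4D dynamic dose for one breathing trace
#'
#' Each timed event's phase fraction `c(t)` is mapped to the nearest 4DCT
#' phase bin; the event's MU deposits on that phase's CT, and each
#' phase's accumulated dose is pulled back to the reference grid by
#' trilinear sampling at `x + u_k(x)` through the known phase
#' displacement field.
#'
#' @param timed a `timed_spot_sequence`.
#' @param trace a [breathing_config()].
#' @param fourdct output of [make_4dct()] (phases + per-phase DVFs).
#' @param plan the `spot_plan`.
#' @param machine `machine_model`.
#' @return `image_grid` of accumulated dose on the reference grid.
#' @export
simulate_dynamic_dose <- function(timed, trace, fourdct, plan, machine) {
  K <- length(fourdct$phases)
  if (is.null(fourdct$dvfs) || length(fourdct$dvfs) != K)
    stop("4DCT is missing per-phase displacement fields")
  ck <- fourdct$phase_c
  c_t <- breathing_waveform(timed$t_s, trace)
  bin <- vapply(c_t, function(cv) which.min(abs(ck - cv)), 1L)
  ref <- fourdct$phases[[1]]
  d <- dim(ref$data)
  total <- array(0, d)
  pts <- NULL
  for (k in sort(unique(bin))) {
    ev <- which(bin == k)
    mu_by_spot <- tapply(timed$mu[ev], timed$spot[ev], sum)
    w <- numeric(nrow(plan$spots))
    w[as.integer(names(mu_by_spot))] <- as.numeric(mu_by_spot)
    dose_k <- compute_dose_grid(fourdct$phases[[k]], plan, w, machine)
    uk <- fourdct$dvfs[[k]]$u
    if (max(abs(uk)) == 0) {
      total <- total + dose_k$data
    } else {
      if (is.null(pts)) pts <- grid_points(ref)
      q <- pts
      q[, 1] <- q[, 1] + as.vector(uk[, , , 1])
      q[, 2] <- q[, 2] + as.vector(uk[, , , 2])
      q[, 3] <- q[, 3] + as.vector(uk[, , , 3])
      total <- total + array(
        interp_trilinear(dose_k$data, q, dose_k$spacing, dose_k$origin,
                         fill = 0), d)
    }
  }
  image_grid(total, ref$spacing, ref$origin)
}

#' Nominal-vs-dynamic metric differences
#'
#' The fixed interplay metric list: CTV D5-D95 and D95, mean lung dose,
#' mean esophagus dose, max cord dose, functional-lung V20 and V30, and
#' mean functional lung dose. Missing structures are listed as absent
#' (NA), never silently skipped.
#'
#' @param nominal,dynamic dose `image_grid`s on the same grid.
#' @param structures a `structure_set`.
#' @param rx prescription (carried through for context).
#' @return data.frame: metric, structure, nominal, dynamic, difference
#'   (nominal - dynamic).
#' @export
interplay_report <- function(nominal, dynamic, structures, rx) {
  stopifnot(identical(dim(nominal$data), dim(dynamic$data)))
  spec <- list(
    list(metric = "D5-D95 (Gy)", structure = "ctv",
         fn = function(d) dose_at_volume(d, 5) - dose_at_volume(d, 95)),
    list(metric = "D95 (Gy)", structure = "ctv",
         fn = function(d) dose_at_volume(d, 95)),
    list(metric = "MLD (Gy)", structure = "lung_total", fn = mean),
    list(metric = "mean (Gy)", structure = "esophagus", fn = mean),
    list(metric = "max (Gy)", structure = "cord", fn = max),
    list(metric = "fV20 (%)", structure = "functional_total",
         fn = function(d) 100 * mean(d >= 20)),
    list(metric = "fV30 (%)", structure = "functional_total",
         fn = function(d) 100 * mean(d >= 30)),
    list(metric = "fMLD (Gy)", structure = "functional_total", fn = mean))
  rows <- lapply(spec, function(s) {
    m <- structures[[s$structure]]
    if (is.null(m) || !any(m)) {
      data.frame(metric = s$metric, structure = s$structure,
                 nominal = NA_real_, dynamic = NA_real_,
                 difference = NA_real_)
    } else {
      a <- s$fn(nominal$data[m]); b <- s$fn(dynamic$data[m])
      data.frame(metric = s$metric, structure = s$structure,
                 nominal = a, dynamic = b, difference = a - b)
    }
  })
  do.call(rbind, rows)
}

#' Run the full interplay study over the breathing scenarios
#'
#' @param plan optimized, normalized `spot_plan` (weights set).
#' @param fourdct output of [make_4dct()].
#' @param structures `structure_set`.
#' @param machine `machine_model`.
#' @param scenarios list from [enumerate_breathing_scenarios()].
#' @param nominal optional precomputed nominal dose grid.
#' @return list: `nominal` dose, `per_scenario` (list of dose +
#'   report), `table` (long data.frame over scenarios and metrics).
#' @export
run_interplay_study <- function(plan, fourdct, structures, machine,
                                scenarios = enumerate_breathing_scenarios(
                                  amplitude_mm = fourdct$breathing$amplitude_mm),
                                nominal = NULL) {
  rp <- repaint_layers(plan, machine$max_mu)
  timed <- delivery_timeline(rp, machine)
  if (is.null(nominal))
    nominal <- compute_dose_grid(fourdct$phases[[1]], plan, plan$weights,
                                 machine)
  out <- list(); tabs <- list()
  for (i in seq_along(scenarios)) {
    dyn <- simulate_dynamic_dose(timed, scenarios[[i]], fourdct, rp, machine)
    rep_i <- interplay_report(nominal, dyn, structures,
                              plan$prescription_gy)
    rep_i$period_s <- scenarios[[i]]$period_s
    rep_i$start_phase <- scenarios[[i]]$start_phase
    out[[i]] <- list(dose = dyn, report = rep_i)
    tabs[[i]] <- rep_i
  }
  list(nominal = nominal, per_scenario = out, table = do.call(rbind, tabs))
}
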