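#' Robust spot-scanning plan optimization
#'
#' Spot placement on the CTV, the 21-scenario robust setup/range grid,
#' projected-gradient weight optimization with target + OAR + optional
#' functional-avoidance objectives, worst-case robustness evaluation with
#' the re-weighting escalation loop, and D99-based plan normalization.
#'
#' @name planner
NULL

#' Place energy layers and lateral spots covering the CTV
#'
#' Per beam: energy layers span the CTV's water-equivalent depth range
#' (closest machine energies at `layer_spacing_mm` WEPL steps); lateral
#' spots lie on a hexagonal grid covering the CTV's beam's-eye-view
#' projection expanded by one in-patient sigma plus the setup-uncertainty
#' margin. A spot is kept for a layer
#' only where the layer's depth intersects the (laterally dilated) CTV
#' depth span of its column.
#'
#' @param ct planning `image_grid`.
#' @param ctv logical CTV mask.
#' @param machine `machine_model`.
#' @param beams list of [beam_geometry()] (default: left lateral +
#'   anterior).
#' @param lateral_spacing_mm hexagonal spot pitch, mm.
#' @param layer_spacing_mm energy layer spacing in WEPL mm.
#' @param setup_margin_mm extra lateral and depth coverage margin for the
#'   setup uncertainty: without it, shifted-scenario CTV edge voxels fall
#'   outside the spot grid and no re-weighting can restore worst-case
#'   coverage.
#' @param prescription_gy,fractions prescription.
#' @return a `spot_plan`: `beams`, `spots` data.frame (beam, layer,
#'   energy, lat1, lat2), `weights` (MU, initialized to 0), prescription.
#' @export
place_spots <- function(ct, ctv, machine,
                        beams = list(beam_geometry(1, +1, "left_lateral"),
                                     beam_geometry(2, +1, "anterior")),
                        lateral_spacing_mm = 6, layer_spacing_mm = 6,
                        setup_margin_mm = 5,
                        prescription_gy = 60, fractions = 30) {
  if (!any(ctv)) stop("CTV mask is empty")
  d <- dim(ct$data)
  spots <- list()
  for (bi in seq_along(beams)) {
    beam <- beams[[bi]]
    W <- wepl_volume(ct, beam$axis, beam$dir)
    lat_axes <- setdiff(1:3, beam$axis)
    perm <- c(beam$axis, lat_axes)
    Wp <- aperm(W, perm); Cp <- aperm(ctv, perm)
    dW <- dim(Wp)
    Wm <- matrix(Wp, nrow = dW[1]); Cm <- matrix(Cp, nrow = dW[1])
    wmin <- suppressWarnings(apply(ifelse(Cm, Wm, Inf), 2, min))
    wmax <- suppressWarnings(apply(ifelse(Cm, Wm, -Inf), 2, max))
    wmin <- matrix(wmin, dW[2], dW[3]); wmax <- matrix(wmax, dW[2], dW[3])
    gmin <- min(wmin); gmax <- max(wmax)
    if (!is.finite(gmin)) stop("CTV not traversed by beam ", beam$label)
    if (gmax > max(machine$range_mm(machine$energies)))
      stop("CTV deeper (", round(gmax), " mm WEPL) than the maximum machine range")
    # lateral grey dilation of the depth-span maps by the sigma margin
    e_mid <- machine$energies[which.min(abs(machine$range_mm(machine$energies) -
                                              (gmin + gmax) / 2))]
    # one in-patient sigma at mid depth, plus the setup margin
    margin_mm <- sqrt(machine$sigma_air(e_mid)^2 +
                        (machine$sigma_growth_k * (gmin + gmax) / 2)^2) +
      setup_margin_mm
    r1 <- ceiling(margin_mm / ct$spacing[lat_axes[1]])
    r2 <- ceiling(margin_mm / ct$spacing[lat_axes[2]])
    dil_min <- wmin; dil_max <- wmax
    for (s1 in -r1:r1) for (s2 in -r2:r2) {
      if (s1 == 0 && s2 == 0) next
      sh_min <- shift2(wmin, s1, s2, Inf); sh_max <- shift2(wmax, s1, s2, -Inf)
      dil_min <- pmin(dil_min, sh_min); dil_max <- pmax(dil_max, sh_max)
    }
    # energy layers over the global depth span
    targets <- seq(gmin, gmax, by = layer_spacing_mm)
    if (utils::tail(targets, 1) < gmax - 1e-9) targets <- c(targets, gmax)
    ranges <- machine$range_mm(machine$energies)
    layer_E <- unique(machine$energies[vapply(targets, function(t)
      which.min(abs(ranges - t)), 1L)])
    # hexagonal lateral grid over the dilated projection bounding box
    proj <- is.finite(dil_min)
    ij <- which(proj, arr.ind = TRUE)
    o1 <- ct$origin[lat_axes[1]]; o2 <- ct$origin[lat_axes[2]]
    sp1 <- ct$spacing[lat_axes[1]]; sp2 <- ct$spacing[lat_axes[2]]
    lo1 <- o1 + (min(ij[, 1]) - 1) * sp1 - lateral_spacing_mm
    hi1 <- o1 + (max(ij[, 1]) - 1) * sp1 + lateral_spacing_mm
    lo2 <- o2 + (min(ij[, 2]) - 1) * sp2 - lateral_spacing_mm
    hi2 <- o2 + (max(ij[, 2]) - 1) * sp2 + lateral_spacing_mm
    rows <- seq(lo2, hi2, by = lateral_spacing_mm * sqrt(3) / 2)
    for (li in seq_along(layer_E)) {
      E <- layer_E[li]; R <- machine$range_mm(E)
      for (ri in seq_along(rows)) {
        off <- if (ri %% 2 == 0) lateral_spacing_mm / 2 else 0
        cols <- seq(lo1 + off, hi1, by = lateral_spacing_mm)
        i1 <- round((cols - o1) / sp1) + 1
        i2 <- round((rows[ri] - o2) / sp2) + 1
        ok <- i1 >= 1 & i1 <= dim(proj)[1] & i2 >= 1 & i2 <= dim(proj)[2]
        if (!any(ok)) next
        lin <- (i2 - 1) * dim(proj)[1] + i1
        keep <- ok
        depth_margin <- layer_spacing_mm + setup_margin_mm + 0.05 * R
        keep[ok] <- proj[lin[ok]] &
          R >= dil_min[lin[ok]] - depth_margin &
          R <= dil_max[lin[ok]] + depth_margin
        if (!any(keep)) next
        spots[[length(spots) + 1]] <- data.frame(
          beam = bi, layer = li, energy = E,
          lat1 = cols[keep], lat2 = rows[ri])
      }
    }
  }
  spots <- do.call(rbind, spots)
  # canonical delivery order: beam, then layer (deep to shallow), then row
  spots <- spots[order(spots$beam, -spots$energy, spots$lat2, spots$lat1), ]
  rownames(spots) <- NULL
  structure(list(beams = beams, spots = spots,
                 weights = rep(0, nrow(spots)),
                 prescription_gy = prescription_gy, fractions = fractions),
            class = "spot_plan")
}

shift2 <- function(m, s1, s2, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  r <- seq_len(nrow(m)); c <- seq_len(ncol(m))
  rs <- r + s1; cs <- c + s2
  okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
  out[r[okr], c[okc]] <- m[rs[okr], cs[okc], drop = FALSE]
  out
}

#' @export
print.spot_plan <- function(x, ...) {
  cat("<spot_plan>", nrow(x$spots), "spots,", length(x$beams), "beams,",
      length(unique(paste(x$spots$beam, x$spots$layer))), "energy layers, Rx",
      x$prescription_gy, "Gy[RBE]\n")
  invisible(x)
}

#' Robust setup/range scenario grid
#'
#' The nominal scenario plus the 6 axis-aligned setup shifts of
#' `setup_mm`, crossed with range scales `{1 - range_pct/100, 1,
#' 1 + range_pct/100}`: 21 scenarios at the defaults (7 shifts x 3
#' scales), exactly one of which is nominal.
#'
#' @param setup_mm setup uncertainty, mm.
#' @param range_pct range uncertainty, percent.
#' @return list of [scenario()]s; the nominal has index
#'   `attr(, "nominal")`.
#' @export
robust_scenarios <- function(setup_mm = 5, range_pct = 5) {
  shifts <- list(c(0, 0, 0))
  if (setup_mm > 0) {
    for (axis in 1:3) for (sgn in c(-1, 1)) {
      v <- c(0, 0, 0); v[axis] <- sgn * setup_mm
      shifts[[length(shifts) + 1]] <- v
    }
  }
  scales <- unique(c(1, 1 - range_pct / 100, 1 + range_pct / 100))
  out <- list()
  for (sc in scales) for (sh in shifts)
    out[[length(out) + 1]] <- scenario(sh, sc)
  nominal <- which(vapply(out, function(s)
    all(s$shift_mm == 0) && s$range_scale == 1, TRUE))
  attr(out, "nominal") <- nominal
  out
}

#' Objective term and objective set constructors
#'
#' Term types: `"uniform_target"` (squared deviation from the dose level
#' over all robust scenarios), `"mean_dose"` (one-sided quadratic on the
#' structure mean above the level, nominal dose), `"max_dose"` /
#' `"dose_volume"` (one-sided per-voxel quadratic above the level,
#' nominal dose).
#'
#' @param structure structure name in the structure set.
#' @param type term type.
#' @param dose_gy dose level, Gy[RBE].
#' @param weight penalty weight (>= 0).
#' @param robust whether the term is evaluated over all scenarios (only
#'   meaningful for the target term).
#' @export
objective_term <- function(structure, type = c("uniform_target", "mean_dose",
                                               "max_dose", "dose_volume"),
                           dose_gy, weight = 1, robust = FALSE) {
  stopifnot(weight >= 0)
  list(structure = structure, type = match.arg(type), dose_gy = dose_gy,
       weight = weight, robust = robust)
}

#' Default objective sets for standard and functional plans
#'
#' The standard set prioritizes robust CTV coverage, then RTOG-style OAR
#' placeholders (the study's protocols are not printed). The functional
#' set adds avoidance terms on the functional-lung substructures.
#'
#' @param mode `"standard"` or `"functional"`.
#' @param rx prescription, Gy[RBE].
#' @return list of [objective_term()]s with a target term present.
#' @export
default_objectives <- function(mode = c("standard", "functional"), rx = 60) {
  mode <- match.arg(mode)
  obj <- list(
    objective_term("ctv", "uniform_target", rx, weight = 100, robust = TRUE),
    objective_term("ctv", "max_dose", 1.08 * rx, weight = 20),
    objective_term("cord", "max_dose", 0.75 * rx, weight = 10),
    objective_term("esophagus", "mean_dose", 34, weight = 5),
    objective_term("heart", "mean_dose", 26, weight = 5),
    objective_term("lung_total", "mean_dose", 15, weight = 8))
  if (mode == "functional") {
    obj <- c(obj, list(
      objective_term("functional_minus_ptv", "mean_dose", 0, weight = 25),
      objective_term("functional_ring_1_3cm", "mean_dose", 0, weight = 10),
      objective_term("functional_total", "dose_volume", 20, weight = 10)))
  }
  obj
}

#' Assemble the planning problem (influence structures)
#'
#' Builds the nominal influence on the union of all objective structures
#' and, for each robust scenario, the CTV-restricted influence used by
#' the robust target term and the robustness evaluation.
#'
#' @param ct planning `image_grid`.
#' @param structures a `structure_set`.
#' @param plan a `spot_plan` from [place_spots()].
#' @param machine `machine_model`.
#' @param scenarios list from [robust_scenarios()].
#' @param extra_structures names always included in the nominal ROI.
#' @return list of class `planning_problem`.
#' @export
prepare_planning <- function(ct, structures, plan, machine,
                             scenarios = robust_scenarios(),
                             extra_structures = c("lung_ipsi", "lung_contra",
                                                  "functional_ipsi",
                                                  "functional_contra",
                                                  "functional_ring_0_1cm",
                                                  "functional_minus_ptv",
                                                  "functional_ring_1_3cm",
                                                  "functional_total")) {
  struct_names <- unique(c("ctv", "ptv", "cord", "esophagus", "heart",
                           "lung_total", extra_structures))
  struct_names <- struct_names[vapply(struct_names, function(n)
    !is.null(structures[[n]]) && any(structures[[n]]), TRUE)]
  roi <- Reduce(`|`, lapply(struct_names, function(n) structures[[n]]))
  nominal <- build_influence(ct, plan, machine, scenario(), roi)
  rows <- lapply(struct_names, function(n)
    match(which(structures[[n]]), nominal$roi_idx))
  names(rows) <- struct_names
  ctv_mask <- structures$ctv
  scen_infl <- lapply(scenarios, function(sc)
    build_influence(ct, plan, machine, sc, ctv_mask)$A)
  structure(list(ct = ct, plan = plan, machine = machine,
                 structures = structures, scenarios = scenarios,
                 nominal = nominal, rows = rows,
                 ctv_influences = scen_infl,
                 n_ctv = sum(ctv_mask)),
            class = "planning_problem")
}

plan_objective <- function(problem, objectives, w) {
  val <- 0
  for (term in objectives) {
    if (term$weight == 0) next
    if (term$type == "uniform_target") {
      infls <- if (term$robust) problem$ctv_influences
      else problem$ctv_influences[attr(problem$scenarios, "nominal")]
      tv <- 0
      for (A in infls) {
        dd <- as.numeric(A %*% w) - term$dose_gy
        tv <- tv + sum(dd^2) / length(dd)
      }
      val <- val + term$weight * tv / length(infls)
    } else {
      rows <- problem$rows[[term$structure]]
      if (is.null(rows)) next
      d <- as.numeric(problem$nominal$A[rows, , drop = FALSE] %*% w)
      if (term$type == "mean_dose") {
        ex <- max(0, mean(d) - term$dose_gy)
        val <- val + term$weight * ex^2
      } else {
        ex <- pmax(0, d - term$dose_gy)
        val <- val + term$weight * sum(ex^2) / length(ex)
      }
    }
  }
  val
}

plan_gradient <- function(problem, objectives, w) {
  g <- numeric(length(w))
  for (term in objectives) {
    if (term$weight == 0) next
    if (term$type == "uniform_target") {
      infls <- if (term$robust) problem$ctv_influences
      else problem$ctv_influences[attr(problem$scenarios, "nominal")]
      for (A in infls) {
        dd <- as.numeric(A %*% w) - term$dose_gy
        g <- g + term$weight * 2 *
          as.numeric(Matrix::crossprod(A, dd)) / (length(dd) * length(infls))
      }
    } else {
      rows <- problem$rows[[term$structure]]
      if (is.null(rows)) next
      A <- problem$nominal$A[rows, , drop = FALSE]
      d <- as.numeric(A %*% w)
      if (term$type == "mean_dose") {
        ex <- max(0, mean(d) - term$dose_gy)
        if (ex > 0)
          g <- g + term$weight * 2 * ex *
            as.numeric(Matrix::crossprod(A, rep(1 / length(d), length(d))))
      } else {
        ex <- pmax(0, d - term$dose_gy)
        if (any(ex > 0))
          g <- g + term$weight * 2 *
            as.numeric(Matrix::crossprod(A, ex)) / length(ex)
      }
    }
  }
  g
}

#' Optimize spot weights by projected gradient descent
#'
#' Minimizes the weighted objective sum with non-negative weights; the
#' backtracking step guarantees a non-increasing objective trace. The
#' warm start `w0` defaults to the uniform weighting that brings the mean
#' nominal CTV dose to the target level.
#'
#' @param problem a `planning_problem`.
#' @param objectives list of [objective_term()]s (target term required).
#' @param iters maximum iterations.
#' @param w0 optional warm-start weights.
#' @param tol relative objective-decrease stopping tolerance.
#' @return list: `weights`, `objective`, `trace`, `iterations`.
#' @export
optimize_weights <- function(problem, objectives, iters = 150, w0 = NULL,
                             tol = 1e-6) {
  target <- Filter(function(t) t$type == "uniform_target", objectives)
  if (!length(target)) stop("objective set must contain a uniform_target term")
  nsp <- ncol(problem$nominal$A)
  A_check <- problem$ctv_influences[[attr(problem$scenarios, "nominal")]]
  if (length(A_check@x) == 0 || all(A_check@x == 0))
    stop("influence is identically zero")
  if (is.null(w0)) {
    A0 <- problem$ctv_influences[[attr(problem$scenarios, "nominal")]]
    dmean <- mean(as.numeric(A0 %*% rep(1, nsp)))
    if (dmean <= 0) stop("unit weighting gives zero CTV dose")
    w0 <- rep(target[[1]]$dose_gy / dmean, nsp)
  }
  w <- pmax(w0, 0)
  E <- plan_objective(problem, objectives, w)
  trace <- E
  step <- NULL
  for (it in seq_len(iters)) {
    g <- plan_gradient(problem, objectives, w)
    if (is.null(step)) {
      gn <- sqrt(sum(g^2))
      step <- if (gn > 0) 0.05 * sqrt(sum(w^2)) / gn else 0
    }
    if (step == 0) break
    accepted <- FALSE
    for (bt in 1:12) {
      w_try <- pmax(w - step * g, 0)
      E_try <- plan_objective(problem, objectives, w_try)
      if (E_try <= E) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (E - E_try) / max(E, .Machine$double.eps)
    w <- w_try; E <- E_try
    trace <- c(trace, E)
    step <- step * 1.5
    if (rel < tol) break
  }
  list(weights = w, objective = E, trace = trace, iterations = length(trace) - 1)
}

#' Per-scenario CTV V95 and the worst case
#'
#' @param problem a `planning_problem`.
#' @param w spot weights.
#' @param rx prescription, Gy[RBE].
#' @return list: `v95` per scenario (%), `worst` (%), `pass`
#'   (worst >= 95).
#' @export
evaluate_robustness <- function(problem, w, rx = problem$plan$prescription_gy) {
  v95 <- vapply(problem$ctv_influences, function(A)
    100 * mean(as.numeric(A %*% w) >= 0.95 * rx), 1)
  list(v95 = v95, worst = min(v95), pass = min(v95) >= 95)
}

#' Robust re-weighting loop
#'
#' Optimizes, evaluates worst-case CTV V95, and while the 95%/95%
#' criterion fails multiplies the target weight by `factor` and
#' re-optimizes (warm-started), up to `max_rounds`. Because plans are
#' reported after D99 normalization, the evaluation driving the loop is
#' done on the normalized weights by default (a global rescale can
#' otherwise push a passing plan back under the gate). Failure to pass
#' is reported explicitly, never silently.
#'
#' @param problem a `planning_problem`.
#' @param objectives objective set.
#' @param max_rounds maximum escalation rounds.
#' @param factor target-weight multiplier per round.
#' @param iters optimizer iterations per round.
#' @param normalize evaluate robustness on the D99-normalized plan.
#' @return list: `weights` (optimizer output, un-normalized),
#'   `objectives` (final), `robustness`, `rounds`, `passed`, `opt`.
#' @export
reweight_until_robust <- function(problem, objectives, max_rounds = 3,
                                  factor = 2, iters = 150,
                                  normalize = TRUE) {
  rounds <- 0
  w0 <- NULL
  repeat {
    opt <- optimize_weights(problem, objectives, iters = iters, w0 = w0)
    w_eval <- opt$weights
    if (normalize) {
      A0 <- problem$ctv_influences[[attr(problem$scenarios, "nominal")]]
      if (dose_at_volume(as.numeric(A0 %*% opt$weights), 99) > 0)
        w_eval <- normalize_plan(problem, opt$weights)$weights
    }
    rob <- evaluate_robustness(problem, w_eval)
    if (rob$pass || rounds >= max_rounds) break
    if (factor <= 1) { rounds <- rounds + 1; if (rounds >= max_rounds) break; next }
    for (i in seq_along(objectives))
      if (objectives[[i]]$type == "uniform_target")
        objectives[[i]]$weight <- objectives[[i]]$weight * factor
    w0 <- opt$weights
    rounds <- rounds + 1
  }
  list(weights = opt$weights, objectives = objectives, robustness = rob,
       rounds = rounds, passed = rob$pass, opt = opt)
}

#' Normalize a plan so that CTV D99 equals 99% of prescription
#'
#' Dose is linear in the weights, so the global rescale
#' `s = 0.99 Rx / D99(CTV)` makes D99 exactly 99% of prescription.
#'
#' @param problem a `planning_problem`.
#' @param w spot weights.
#' @param rx prescription, Gy[RBE].
#' @return list: `weights` (scaled), `scale`, `d99_before`, `d99_after`.
#' @export
normalize_plan <- function(problem, w, rx = problem$plan$prescription_gy) {
  A0 <- problem$ctv_influences[[attr(problem$scenarios, "nominal")]]
  d <- as.numeric(A0 %*% w)
  d99 <- dose_at_volume(d, 99)
  if (d99 <= 0) stop("CTV D99 is zero; cannot normalize")
  s <- 0.99 * rx / d99
  list(weights = w * s, scale = s, d99_before = d99,
       d99_after = dose_at_volume(d * s, 99))
}
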