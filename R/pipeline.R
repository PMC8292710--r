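#' End-to-end functional-avoidance planning study on the phantom
#'
#' Chains the full pipeline: phantom generation, (optionally) deformable
#' registration, ventilation imaging, eligibility screening, structure
#' derivation, robust spot-weight optimization of a standard and a
#' functional-avoidance plan, D99 normalization, metric tables and NTCP
#' reduction. The interplay study is run separately on the returned
#' pieces via [run_interplay_study()].
#'
#' @param seed integer seed controlling every random element.
#' @param dims phantom grid size.
#' @param rx prescription, Gy[RBE].
#' @param use_registration estimate the DVF by [register_deformable()]
#'   instead of using the ground-truth field (slower).
#' @param config optional [phantom_config()] override.
#' @param machine optional [default_machine_model()] override.
#' @param scenarios robust scenario list.
#' @param lateral_spacing_mm,layer_spacing_mm spot/layer spacing.
#' @param opt_iters optimizer iterations per round.
#' @param max_rounds robustness re-weighting rounds.
#' @param make_phases render all 4DCT phases (needed for interplay).
#' @param verbose print stage progress.
#' @return list of class `fa_study` with the phantom pieces, ventilation
#'   products, structures, both plans (weights, robustness, normalized
#'   dose grids), metric tables, and the NTCP reduction table.
#' @export
run_functional_avoidance_study <- function(seed = 1, dims = c(96, 96, 96),
                                           rx = 60,
                                           use_registration = FALSE,
                                           config = NULL, machine = NULL,
                                           scenarios = robust_scenarios(),
                                           lateral_spacing_mm = 6,
                                           layer_spacing_mm = 6,
                                           opt_iters = 120, max_rounds = 3,
                                           make_phases = FALSE,
                                           verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(config)) config <- phantom_config(dims = dims)
  if (is.null(machine)) machine <- default_machine_model()
  say("phantom: anatomy + deformation")
  anatomy <- build_reference_anatomy(config, seed = seed)
  dvf_true <- synthesize_dvf(anatomy, seed = seed)
  exhale <- render_phase(anatomy, dvf_true, 0)
  inhale <- render_phase(anatomy, dvf_true, 1)
  fourdct <- NULL
  if (make_phases) {
    say("phantom: rendering all phases")
    fourdct <- make_4dct(anatomy, dvf_true)
  }
  dvf_used <- dvf_true
  registration <- NULL
  if (use_registration) {
    say("registration")
    dvf_used <- register_deformable(exhale, inhale)
    registration <- registration_error(
      dvf_used, dvf_true, anatomy$lung_left | anatomy$lung_right)
  }
  say("ventilation")
  parenchyma <- anatomy$lung_left | anatomy$lung_right
  vmap <- compute_ventilation(exhale, inhale, dvf_used, parenchyma)
  vmap <- normalize_to_max(vmap)
  profile <- regional_profile(vmap, list(left = anatomy$lung_left,
                                         right = anatomy$lung_right))
  eligibility <- screen_eligibility(profile)
  say("structures")
  tumor_masks <- lapply(c(0, 0.25, 0.5, 0.75, 1),
                        function(cc) tumor_mask_at_phase(anatomy, cc))
  structures <- make_structures(anatomy, vmap, tumor_masks)
  say("spot placement + influence matrices")
  plan0 <- place_spots(exhale, structures$ctv, machine,
                       lateral_spacing_mm = lateral_spacing_mm,
                       layer_spacing_mm = layer_spacing_mm,
                       prescription_gy = rx)
  problem <- prepare_planning(exhale, structures, plan0, machine, scenarios)
  plans <- list()
  for (mode in c("standard", "functional")) {
    say("optimizing ", mode, " plan")
    res <- reweight_until_robust(problem, default_objectives(mode, rx),
                                 max_rounds = max_rounds, iters = opt_iters)
    nrm <- normalize_plan(problem, res$weights, rx)
    rob <- evaluate_robustness(problem, nrm$weights, rx)
    plan <- plan0
    plan$weights <- nrm$weights
    say("  dose grid")
    dose <- compute_dose_grid(exhale, plan, nrm$weights, machine)
    plans[[mode]] <- list(plan = plan, weights = nrm$weights,
                          normalization = nrm, robustness = rob,
                          rounds = res$rounds, passed = rob$pass,
                          dose = dose,
                          metrics = plan_metric_table(dose, structures, rx))
  }
  fl <- function(mode) {
    m <- plans[[mode]]$metrics
    get1 <- function(metric) m$value[m$structure == "functional_total" &
                                       m$metric == metric]
    data.frame(patient = "phantom", fV20 = get1("fV20"),
               fV30 = get1("fV30"), fMLD = get1("fMLD"))
  }
  ntcp <- ntcp_reduction(fl("standard"), fl("functional"))
  structure(list(seed = seed, config = config, anatomy = anatomy,
                 dvf_true = dvf_true, dvf_used = dvf_used,
                 registration = registration,
                 exhale = exhale, inhale = inhale, fourdct = fourdct,
                 ventilation = vmap, profile = profile,
                 eligibility = eligibility, structures = structures,
                 machine = machine, problem = problem, rx = rx,
                 standard = plans$standard, functional = plans$functional,
                 ntcp = ntcp),
            class = "fa_study")
}

#' @export
print.fa_study <- function(x, ...) {
  cat("<fa_study> seed", x$seed, "grid",
      paste(dim(x$exhale$data), collapse = "x"), "\n")
  cat("  eligible:", x$eligibility$eligible,
      sprintf("(max regional deficit %.1f pp)\n", x$eligibility$max_deficit))
  for (mode in c("standard", "functional")) {
    p <- x[[mode]]
    cat(sprintf("  %-10s worst-case V95 %.1f%% (pass %s), D99 %.2f Gy\n",
                mode, p$robustness$worst, p$passed,
                p$normalization$d99_after))
  }
  s <- attr(x$ntcp, "summary")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  NTCP reduction %-5s %.2f pp\n", s$metric[i],
                100 * s$mean_delta[i]))
  invisible(x)
}
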