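# Shared fixtures, built lazily and cached for the whole test run.
# The "small" phantom (48^3 at 5 mm) keeps unit tests fast; the acceptance
# suite builds its own 96^3 study via acceptance_study().

.fixtures <- new.env(parent = emptyenv())

small_phantom <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- phantom_config(dims = c(48, 48, 48), spacing = rep(5, 3))
    an <- build_reference_anatomy(cfg, seed = 7)
    dvf <- synthesize_dvf(an)
    .fixtures$small <- list(
      cfg = cfg, anatomy = an, dvf = dvf,
      exhale = render_phase(an, dvf, 0),
      inhale = render_phase(an, dvf, 1))
  }
  .fixtures$small
}

# a 40-voxel-deep uniform water tank with a single mid-energy spot
water_tank <- function() {
  if (is.null(.fixtures$water)) {
    ct <- image_grid(array(0, c(40, 40, 80)), spacing = rep(2.5, 3))
    machine <- default_machine_model()
    beams <- list(beam_geometry(3, +1, "sup"))
    spots <- data.frame(beam = 1, layer = 1, energy = 150, lat1 = 50, lat2 = 50)
    plan <- structure(list(beams = beams, spots = spots, weights = 100,
                           prescription_gy = 60, fractions = 30),
                      class = "spot_plan")
    .fixtures$water <- list(ct = ct, machine = machine, plan = plan)
  }
  .fixtures$water
}

# brute-force margin-expansion oracle: direct distance check per voxel
oracle_expand <- function(mask, margin_mm, spacing) {
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dim(mask))
  all_v <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  for (i in seq_len(nrow(all_v))) {
    d2 <- (spacing[1] * (all_v[i, 1] - src[, 1]))^2 +
      (spacing[2] * (all_v[i, 2] - src[, 2]))^2 +
      (spacing[3] * (all_v[i, 3] - src[, 3]))^2
    if (min(d2) <= margin_mm^2 + 1e-6) out[all_v[i, 1], all_v[i, 2], all_v[i, 3]] <- TRUE
  }
  out
}

# sorted-voxel DVH oracle used against the package implementations
oracle_dx <- function(doses, x) {
  s <- sort(doses, decreasing = TRUE)
  s[max(1, ceiling(x / 100 * length(s)))]
}
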