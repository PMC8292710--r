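test_that("cumulative DVH shape and exact statistics", {
  dv <- cumulative_dvh(c(1, 2, 3), bin_gy = 0.5)
  expect_equal(dv$volume_pct[1], 100)
  expect_true(all(diff(dv$volume_pct) <= 0))
  expect_equal(dv$mean_gy, 2); expect_equal(dv$max_gy, 3)
  # V(2) by direct counting = 66.7%
  i2 <- which.min(abs(dv$edges_gy - 2))
  expect_equal(dv$volume_pct[i2], 100 * 2 / 3, tolerance = 1e-9)
  # uniform dose: V = 100 up to the dose, then 0
  du <- cumulative_dvh(rep(7, 10), bin_gy = 1)
  expect_equal(du$volume_pct[du$edges_gy <= 7], rep(100, 8))
  expect_equal(du$volume_pct[du$edges_gy > 7], 0)
  expect_error(cumulative_dvh(image_grid(array(1, c(2, 2, 2)), rep(1, 3)),
                              mask = array(FALSE, c(2, 2, 2))), "empty")
})

test_that("sorted-voxel Dx/Vx rules against the enumeration oracle", {
  v <- 1:20   # 20 equal voxels, 1..20 Gy
  expect_equal(dose_at_volume(v, 95), 2)   # hottest 95% -> 19th largest
  expect_equal(dose_at_volume(v, 5), 20)
  expect_equal(dvh_metric(v, "D5-D95"), 18)
  expect_equal(dvh_metric(c(0, 10), "mean"), 5)
  expect_equal(volume_at_dose(v, 10.5), 50)
  expect_error(dose_at_volume(v, 0), "in \\(0, 100\\]")
  expect_error(dose_at_volume(v, 101), "in \\(0, 100\\]")
  # property: on random <= 100-voxel instances Dx/Vx agree with the oracle
  # and satisfy the duality V(Dx) >= x
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:100, 1)
    doses <- round(stats::runif(n, 0, 70), 2)
    x <- sample(c(1, 5, 50, 95, 99, 100), 1)
    dx <- dose_at_volume(doses, x)
    expect_equal(dx, oracle_dx(doses, x))
    expect_gte(volume_at_dose(doses, dx), x - 100 / n)
  }
  # uniform dose: D95 = dose, D5-D95 = 0
  expect_equal(dvh_metric(rep(3.3, 7), "D5-D95"), 0)
})

test_that("conformity and homogeneity indices", {
  d <- c(4, 4, 4)
  dose <- array(0, d); ctv <- array(FALSE, d)
  ctv[1:10] <- TRUE; dose[1:10] <- 60
  g <- image_grid(dose, rep(2.5, 3))
  expect_equal(conformity_index(g, ctv, 60), 1)   # isodose == CTV
  expect_equal(homogeneity_index(g, ctv), 1)      # uniform target dose
  dose[11:15] <- 61                               # spill outside the CTV
  g2 <- image_grid(dose, rep(2.5, 3))
  expect_equal(conformity_index(g2, ctv, 60), 1.5)
  expect_error(conformity_index(g, array(FALSE, d), 60), "empty")
  expect_error(conformity_index(g, ctv, 0), "> 0")
})

test_that("metrics scale consistently under global dose scaling", {
  set.seed(9)
  v <- stats::runif(60, 0, 50)
  s <- 1.3
  expect_equal(volume_at_dose(s * v, 20), volume_at_dose(v, 20 / s))
  expect_equal(mean(s * v), s * mean(v))
  expect_equal(dose_at_volume(s * v, 95), s * dose_at_volume(v, 95))
})

test_that("logistic NTCP model behaviour", {
  m <- ntcp_model("fV20", b0 = -2, b1 = 0.1)
  expect_equal(ntcp_logistic(20, m), 0.5)         # logit zero
  expect_gt(ntcp_logistic(1e4, m), 0.999)         # saturates to 1
  x <- seq(0, 100, 5)
  expect_true(all(diff(ntcp_logistic(x, m)) > 0)) # monotone for b1 > 0
  expect_true(all(vapply(default_ntcp_models(), `[[`, "", "provenance") ==
                    "synthetic-default"))
})

test_that("NTCP reduction over paired plans", {
  std <- data.frame(patient = c("a", "b"), fV20 = c(30, 40),
                    fV30 = c(20, 25), fMLD = c(10, 12))
  # identical plans: zero reduction
  r0 <- ntcp_reduction(std, std)
  expect_equal(r0$delta, rep(0, 6))
  # functional dominates: all reductions positive, summary by arithmetic
  fun <- std; fun$fV20 <- c(22, 30); fun$fV30 <- c(15, 20); fun$fMLD <- c(8, 9)
  r1 <- ntcp_reduction(std, fun)
  expect_true(all(r1$delta > 0))
  s <- attr(r1, "summary")
  m20 <- default_ntcp_models()$fV20
  d_a <- ntcp_logistic(30, m20) - ntcp_logistic(22, m20)
  d_b <- ntcp_logistic(40, m20) - ntcp_logistic(30, m20)
  expect_equal(s$mean_delta[s$metric == "fV20"], mean(c(d_a, d_b)))
  expect_equal(s$max_delta[s$metric == "fV20"], max(d_a, d_b))
  expect_error(ntcp_reduction(std, fun[1, ]), "paired")
})

test_that("group comparison: ANOVA, paired t, corrected alpha", {
  set.seed(13)
  n <- 12
  base <- stats::rnorm(n, 20, 4)
  dat <- rbind(
    data.frame(patient = 1:n, group = "impt_standard", metric = "MLD",
               value = base),
    data.frame(patient = 1:n, group = "impt_functional", metric = "MLD",
               value = base - stats::rnorm(n, 1.5, 0.4)))
  res <- compare_groups(dat, family_size = 24)
  expect_equal(res$corrected_alpha, 0.05 / 24)
  # two groups: ANOVA F equals the squared unpaired t statistic
  tt <- stats::t.test(value ~ group, data = dat, var.equal = TRUE)
  expect_equal(res$anova$F[res$anova$layout == "all_groups"],
               unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$anova$p[res$anova$layout == "all_groups"], tt$p.value,
               tolerance = 1e-9)
  # paired t against the closed form on a 3-pair example
  d3 <- rbind(
    data.frame(patient = 1:3, group = "g1", metric = "m", value = c(5, 7, 9)),
    data.frame(patient = 1:3, group = "g2", metric = "m", value = c(4, 5, 9)))
  r3 <- compare_groups(d3, family_size = 1)
  diffs <- c(1, 2, 0)
  t_manual <- mean(diffs) / (stats::sd(diffs) / sqrt(3))
  expect_equal(r3$paired_t$t, t_manual, tolerance = 1e-12)
  # identical paired samples: t = 0, p = 1
  same <- rbind(
    data.frame(patient = 1:4, group = "g1", metric = "m", value = 1:4),
    data.frame(patient = 1:4, group = "g2", metric = "m", value = 1:4))
  rs <- compare_groups(same)
  expect_equal(rs$paired_t$t, 0)
  expect_equal(rs$paired_t$p, 1)
  # per-modality layout appears when groups encode modality_plan labels
  dat4 <- rbind(dat,
                transform(dat, group = sub("impt", "vmat", group),
                          value = value + 5))
  r4 <- compare_groups(dat4, family_size = 24)
  expect_true(any(grepl("within_", r4$anova$layout)))
  expect_error(compare_groups(dat[1, , drop = FALSE]), "2 groups")
})

test_that("plan metric table covers the Table-2-style rows", {
  fx <- small_phantom()
  an <- fx$anatomy
  gt <- normalize_to_max(ground_truth_ventilation(fx$dvf, an))
  ss <- make_structures(an, gt, list(an$tumor))
  dose <- image_grid(array(stats::runif(length(an$f_air), 0, 60),
                           dim(an$f_air)), an$spacing, an$origin)
  tab <- plan_metric_table(dose, ss, 60)
  expect_true(all(c("CI", "HI", "D99") %in% tab$metric))
  expect_true(any(tab$structure == "functional_total" & tab$metric == "fV20"))
  expect_true(all(is.finite(tab$value)))
})
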