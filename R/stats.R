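#' NTCP models and the study's statistical comparisons
#'
#' Logistic normal-tissue complication probability models on the
#' functional-lung metrics (fV20, fV30, fMLD), the absolute toxicity
#' reduction between paired plans, and the ANOVA + corrected paired
#' t-test comparison used for the metric tables.
#'
#' @name metrics_stats
NULL

#' Logistic NTCP model
#'
#' `p = 1 / (1 + exp(-(b0 + b1 x)))`; monotone increasing in the metric
#' when `b1 > 0`.
#'
#' @param metric one of `"fV20"`, `"fV30"`, `"fMLD"`.
#' @param b0,b1 intercept and slope (per metric unit).
#' @param endpoint toxicity endpoint label.
#' @param provenance provenance tag; anything but a fitted-coefficient
#'   source must keep the default `"synthetic-default"`, and reports
#'   carry the tag.
#' @export
ntcp_model <- function(metric = c("fV20", "fV30", "fMLD"), b0, b1,
                       endpoint = "grade2plus_pneumonitis",
                       provenance = "synthetic-default") {
  stopifnot(is.finite(b0), is.finite(b1))
  structure(list(metric = match.arg(metric), b0 = b0, b1 = b1,
                 endpoint = endpoint, provenance = provenance),
            class = "ntcp_model")
}

#' Default NTCP model set (synthetic placeholder coefficients)
#'
#' The published functional-lung pneumonitis model is used as
#' configuration; its coefficients are not part of this package's
#' sources, so these defaults are placeholders whose output magnitudes
#' are merely plausible (tens of percent at typical functional metric
#' values). Every model carries `provenance = "synthetic-default"`.
#'
#' @param endpoint `"grade2plus"` or `"grade3plus"`.
#' @return named list of [ntcp_model()]s for fV20, fV30, fMLD.
#' @export
default_ntcp_models <- function(endpoint = c("grade2plus", "grade3plus")) {
  endpoint <- match.arg(endpoint)
  shift <- if (endpoint == "grade3plus") -1.2 else 0
  list(
    fV20 = ntcp_model("fV20", b0 = -3.3 + shift, b1 = 0.05,
                      endpoint = paste0(endpoint, "_pneumonitis")),
    fV30 = ntcp_model("fV30", b0 = -2.6 + shift, b1 = 0.04,
                      endpoint = paste0(endpoint, "_pneumonitis")),
    fMLD = ntcp_model("fMLD", b0 = -2.3 + shift, b1 = 0.07,
                      endpoint = paste0(endpoint, "_pneumonitis")))
}

#' Evaluate a logistic NTCP model
#' @param x metric value(s).
#' @param model an [ntcp_model()].
#' @return probability in (0, 1).
#' @export
ntcp_logistic <- function(x, model) {
  1 / (1 + exp(-(model$b0 + model$b1 * x)))
}

#' Absolute NTCP reduction between paired standard and functional plans
#'
#' `delta = p(standard) - p(functional)` per patient per metric, with the
#' cohort mean and range.
#'
#' @param standard,functional data.frames with columns `patient` and one
#'   column per metric named as in the model set (paired by patient).
#' @param models named list of [ntcp_model()]s.
#' @return data.frame: metric, patient, p_standard, p_functional, delta,
#'   with a `summary` attribute (per-metric mean and range) and the
#'   provenance tags.
#' @export
ntcp_reduction <- function(standard, functional, models = default_ntcp_models()) {
  if (!identical(sort(standard$patient), sort(functional$patient)))
    stop("standard and functional inputs are not paired by patient")
  functional <- functional[match(standard$patient, functional$patient), ]
  rows <- list()
  for (mname in names(models)) {
    if (!mname %in% names(standard)) next
    ps <- ntcp_logistic(standard[[mname]], models[[mname]])
    pf <- ntcp_logistic(functional[[mname]], models[[mname]])
    rows[[mname]] <- data.frame(metric = mname, patient = standard$patient,
                                p_standard = ps, p_functional = pf,
                                delta = ps - pf)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(out, out$metric), function(g)
    data.frame(metric = g$metric[1], mean_delta = mean(g$delta),
               min_delta = min(g$delta), max_delta = max(g$delta))))
  attr(out, "summary") <- summ
  attr(out, "provenance") <- vapply(models, `[[`, "", "provenance")
  out
}

#' Group comparison: one-way ANOVA and corrected paired t-tests
#'
#' For each metric: one-way ANOVA across all plan groups (and, when
#' groups encode modality_plan labels, a per-modality two-group layout),
#' plus two-sided paired t-tests for the requested group pairs with a
#' Bonferroni-corrected alpha of `alpha / family_size`. With the
#' Table-2-style family of 24 metrics the corrected level is 0.05/24 =
#' 0.0021 (printed as 0.002).
#'
#' @param data long data.frame with columns `patient`, `group`, `metric`,
#'   `value`.
#' @param pairs list of length-2 character vectors of group names to
#'   compare pairwise (default: all group pairs).
#' @param alpha family-wise alpha.
#' @param family_size number of metrics in the testing family (defaults
#'   to the number of distinct metrics in `data`).
#' @return list: `anova` (per metric: F, p; plus per-modality rows when
#'   applicable), `paired_t` (per metric and pair: t, df, p,
#'   significant), `corrected_alpha`.
#' @export
compare_groups <- function(data, pairs = NULL, alpha = 0.05,
                           family_size = NULL) {
  stopifnot(all(c("patient", "group", "metric", "value") %in% names(data)))
  groups <- unique(data$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(family_size)) family_size <- length(unique(data$metric))
  corrected <- alpha / family_size
  if (is.null(pairs))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  an_rows <- list(); t_rows <- list()
  for (m in unique(data$metric)) {
    dm <- data[data$metric == m, ]
    if (any(table(dm$group) < 2)) stop("n < 2 in some group for metric ", m)
    fit <- stats::aov(value ~ group, data = dm)
    s <- summary(fit)[[1]]
    an_rows[[length(an_rows) + 1]] <- data.frame(
      metric = m, layout = "all_groups", F = s$`F value`[1], p = s$`Pr(>F)`[1])
    modality <- sub("_[^_]+$", "", dm$group)
    if (length(unique(modality)) > 1 &&
        !identical(sort(unique(modality)), sort(unique(dm$group)))) {
      for (mod in unique(modality)) {
        sub_d <- dm[modality == mod, ]
        if (length(unique(sub_d$group)) < 2) next
        fit2 <- stats::aov(value ~ group, data = sub_d)
        s2 <- summary(fit2)[[1]]
        an_rows[[length(an_rows) + 1]] <- data.frame(
          metric = m, layout = paste0("within_", mod),
          F = s2$`F value`[1], p = s2$`Pr(>F)`[1])
      }
    }
    for (pr in pairs) {
      a <- dm[dm$group == pr[1], ]; b <- dm[dm$group == pr[2], ]
      b <- b[match(a$patient, b$patient), ]
      diffs <- a$value - b$value
      if (stats::sd(diffs) < .Machine$double.eps^0.5 * max(1, mean(abs(diffs)))) {
        # zero-variance differences: t is 0 (identical) or infinite
        if (all(abs(diffs) < 1e-12)) {
          tt <- list(statistic = 0, parameter = length(diffs) - 1, p.value = 1)
        } else {
          tt <- list(statistic = sign(mean(diffs)) * Inf,
                     parameter = length(diffs) - 1, p.value = 0)
        }
      } else {
        tt <- stats::t.test(a$value, b$value, paired = TRUE)
      }
      t_rows[[length(t_rows) + 1]] <- data.frame(
        metric = m, group1 = pr[1], group2 = pr[2],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, significant = tt$p.value < corrected)
    }
  }
  list(anova = do.call(rbind, an_rows), paired_t = do.call(rbind, t_rows),
       corrected_alpha = corrected, family_size = family_size)
}
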