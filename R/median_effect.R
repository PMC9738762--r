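#' Fit the median-effect model to a single-agent cytotoxicity curve
#'
#' The median-effect equation `fa/fu = (D/Dm)^m` (fa = fraction affected,
#' fu = 1 - fa) linearizes to `log(fa/fu) = m log D - m log Dm`; the fit is
#' ordinary least squares on that line. Points with fa outside
#' `[epsilon, 1 - epsilon]` are excluded (the logit is undefined or unstable
#' there), as are zero-dose points.
#'
#' @param curve a `cytotoxicity_curve` (percent survival vs concentration) —
#'   fa is computed as `1 - percent_survival/100`.
#' @param epsilon fa clipping bound; default 0.005.
#' @return list of class `median_effect_fit`: `Dm` (nM), `m` (slope), `r`
#'   (linear correlation of the median-effect plot), `n_points_used`,
#'   `drug_id`.
#' @export
fit_median_effect <- function(curve, epsilon = 0.005) {
  stopifnot(inherits(curve, "cytotoxicity_curve"), epsilon > 0, epsilon < 0.5)
  D <- curve$concentration_nM
  fa <- 1 - curve$percent_survival / 100
  use <- D > 0 & fa >= epsilon & fa <= 1 - epsilon
  if (sum(use) < 3L) {
    stop(sprintf(
      "fewer than 3 usable points (excluded %d of %d: dose 0 or fa outside [%g, %g])",
      sum(!use), length(use), epsilon, 1 - epsilon))
  }
  x <- log10(D[use])
  yv <- log10(fa[use] / (1 - fa[use]))
  fit <- stats::lm(yv ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0) stop("median-effect slope m must be positive")
  Dm <- 10^(-stats::coef(fit)[1] / m)
  structure(
    list(Dm = unname(Dm), m = m, r = stats::cor(x, yv),
         n_points_used = sum(use), drug_id = attr(curve, "drug_id")),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit%s> Dm=%.4g nM m=%.3g r=%.4f (n=%d)\n",
              if (!is.null(x$drug_id) && !is.na(x$drug_id))
                paste0(" ", x$drug_id) else "",
              x$Dm, x$m, x$r, x$n_points_used))
  invisible(x)
}

# Dx: dose of a single agent producing fraction affected fa
median_effect_dose <- function(fit, fa) {
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination measurements at dose pairs
#'
#' @param d1,d2 doses (nM) of the two agents; at least one positive per pair.
#' @param fa observed fraction affected of each combination, in (0,1).
#' @param fixed_ratio whether the pairs follow a fixed dose ratio.
#' @return `data.frame` of class `combination_measurement`.
#' @export
combination_measurement <- function(d1, d2, fa, fixed_ratio = FALSE) {
  stopifnot(length(d1) == length(d2), length(fa) == length(d1),
            all(d1 >= 0), all(d2 >= 0), all(d1 + d2 > 0),
            all(fa > 0), all(fa < 1))
  out <- data.frame(d1 = d1, d2 = d2, fa = fa)
  attr(out, "fixed_ratio") <- fixed_ratio
  class(out) <- c("combination_measurement", "data.frame")
  out
}

#' Chou-Talalay combination index and dose-reduction index
#'
#' For each dose pair (d1, d2) with observed combined fraction affected fa,
#' the equi-effective single-agent doses are `Dx_j = Dm_j (fa/(1-fa))^(1/m_j)`
#' and the (mutually exclusive, two-term) combination index is
#' `CI = d1/Dx1 + d2/Dx2`. CI < 1 indicates synergy, 1 additivity, > 1
#' antagonism; CI in (0.3, 0.9] is labelled synergism and CI <= 0.3 strong
#' synergism (band edges fall to the lower band). The dose-reduction index
#' `DRI_j = Dx_j / d_j` is the fold by which drug j's dose is reduced at that
#' effect level (`NA` where `d_j = 0`).
#'
#' @param fit1,fit2 [fit_median_effect()] results for the two single agents.
#' @param combo a [combination_measurement()].
#' @param epsilon pairs with fa outside `(epsilon, 1 - epsilon)` are skipped
#'   with a warning.
#' @return `data.frame` of class `combination_index_result`: `d1`, `d2`,
#'   `fa`, `Dx1`, `Dx2`, `CI`, `DRI1`, `DRI2`, `label`.
#' @export
compute_ci <- function(fit1, fit2, combo, epsilon = 0.005) {
  stopifnot(inherits(fit1, "median_effect_fit"),
            inherits(fit2, "median_effect_fit"),
            inherits(combo, "combination_measurement"))
  ok <- combo$fa > epsilon & combo$fa < 1 - epsilon
  if (any(!ok)) {
    warning(sprintf("%d pair(s) skipped: fa outside (%g, %g)",
                    sum(!ok), epsilon, 1 - epsilon))
  }
  cm <- combo[ok, , drop = FALSE]
  Dx1 <- median_effect_dose(fit1, cm$fa)
  Dx2 <- median_effect_dose(fit2, cm$fa)
  CI <- cm$d1 / Dx1 + cm$d2 / Dx2
  out <- data.frame(
    d1 = cm$d1, d2 = cm$d2, fa = cm$fa, Dx1 = Dx1, Dx2 = Dx2, CI = CI,
    DRI1 = ifelse(cm$d1 > 0, Dx1 / cm$d1, NA_real_),
    DRI2 = ifelse(cm$d2 > 0, Dx2 / cm$d2, NA_real_),
    label = ci_label(CI),
    stringsAsFactors = FALSE
  )
  class(out) <- c("combination_index_result", "data.frame")
  out
}

#' Classify a combination index into synergy bands
#'
#' Bands: CI <= 0.3 `strong_synergism` (covers both the < 0.1 and 0.1-0.3
#' reporting ranges), 0.3 < CI <= 0.9 `synergism`, 0.9 < CI <= 1.1
#' `additive_window`, CI > 1.1 `antagonism_window`. The two synergy bands are
#' the conventional ones; the outer windows are the customary extensions and
#' are flagged here as conventions, not sharp claims.
#'
#' @param CI numeric vector of combination indices.
#' @return character vector of band labels.
#' @export
ci_label <- function(CI) {
  cut(CI, breaks = c(0, 0.3, 0.9, 1.1, Inf),
      labels = c("strong_synergism", "synergism", "additive_window",
                 "antagonism_window"),
      right = TRUE) |> as.character()
}

#' Isobologram coordinates at chosen effect levels
#'
#' For each effect level fa, returns the single-agent axis intercepts
#' `Dx1, Dx2` and, when combination pairs are supplied, the normalized
#' coordinates `(d1/Dx1, d2/Dx2)` of each pair at its own observed fa. A
#' point below the additivity line `x + y = 1` has CI < 1; the coordinate sum
#' *is* the CI.
#'
#' @param fit1,fit2 single-agent [fit_median_effect()] results.
#' @param fa_levels effect levels in (0,1).
#' @param combo optional [combination_measurement()].
#' @return list with `intercepts` (fa_level, Dx1, Dx2) and `combo_points`
#'   (d1, d2, fa, x = d1/Dx1, y = d2/Dx2) or `NULL`.
#' @export
isobologram_points <- function(fit1, fit2, fa_levels = c(0.5, 0.75, 0.9),
                               combo = NULL) {
  stopifnot(all(fa_levels > 0), all(fa_levels < 1))
  intercepts <- data.frame(
    fa_level = fa_levels,
    Dx1 = median_effect_dose(fit1, fa_levels),
    Dx2 = median_effect_dose(fit2, fa_levels)
  )
  combo_points <- NULL
  if (!is.null(combo)) {
    ci <- compute_ci(fit1, fit2, combo)
    combo_points <- data.frame(d1 = ci$d1, d2 = ci$d2, fa = ci$fa,
                               x = ci$d1 / ci$Dx1, y = ci$d2 / ci$Dx2)
  }
  list(intercepts = intercepts, combo_points = combo_points)
}
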