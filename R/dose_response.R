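#' Normalize plate readings to percent survival
#'
#' Divides each reading by the untreated-control mean and scales to percent,
#' so the control mean sits at 100 by definition. Control variability is
#' reported as a coefficient of variation.
#'
#' @param raw `data.frame` with columns `concentration_nM` (>= 0), `reading`
#'   and optionally `replicate` and `drug_id`.
#' @param control_readings numeric vector of untreated-control readings
#'   (length >= 2).
#' @param drug_id drug identifier for the curve (defaults to the one in `raw`).
#' @return `data.frame` of class `cytotoxicity_curve` with columns
#'   `concentration_nM`, `percent_survival`, `replicate`; attributes
#'   `drug_id`, `control_cv`.
#' @export
normalize_survival <- function(raw, control_readings,
                               drug_id = raw$drug_id[1]) {
  stopifnot(is.data.frame(raw),
            all(c("concentration_nM", "reading") %in% names(raw)),
            length(control_readings) >= 2)
  cm <- mean(control_readings)
  if (cm <= 0) stop("control mean must be positive")
  out <- data.frame(
    concentration_nM = raw$concentration_nM,
    percent_survival = raw$reading / cm * 100,
    replicate = if ("replicate" %in% names(raw)) raw$replicate else 1L,
    stringsAsFactors = FALSE
  )
  attr(out, "drug_id") <- if (is.null(drug_id)) NA_character_ else drug_id
  attr(out, "control_cv") <- stats::sd(control_readings) / cm
  class(out) <- c("cytotoxicity_curve", "data.frame")
  out
}

#' Build a cytotoxicity curve from already-normalized data
#'
#' @param concentration_nM,percent_survival,replicate point-wise vectors.
#' @param drug_id drug identifier.
#' @return A `cytotoxicity_curve` data frame (see [normalize_survival()]).
#' @export
cytotoxicity_curve <- function(concentration_nM, percent_survival,
                               replicate = 1L, drug_id = NA_character_) {
  stopifnot(length(concentration_nM) == length(percent_survival),
            all(concentration_nM >= 0))
  out <- data.frame(concentration_nM = concentration_nM,
                    percent_survival = percent_survival,
                    replicate = replicate, stringsAsFactors = FALSE)
  attr(out, "drug_id") <- drug_id
  class(out) <- c("cytotoxicity_curve", "data.frame")
  out
}

# 4PL survival at dose D (decreasing: top at D -> 0, bottom at D -> Inf)
fourpl_value <- function(D, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (D / ic50)^hill)
}

#' Fit a variable-slope sigmoidal (four-parameter logistic) dose-response model
#'
#' Model: `S(D) = bottom + (top - bottom) / (1 + (D / ic50)^hill)` with
#' `hill > 0`, fitted by Levenberg-Marquardt least squares on log10
#' concentration. Zero-dose points are excluded from the sigmoid fit (they
#' anchor the normalization only). Replicates are fitted as pooled points, so
#' the residual sum of squares reflects replicate scatter. Initialization:
#' top = max observed, bottom = min observed, ic50 = concentration whose mean
#' survival is nearest the half-range, hill = 1.
#'
#' A fitted `ic50` outside `[min(D)/10, max(D) * 10]` of the observed non-zero
#' concentrations is treated as an extrapolation and reported with
#' `converged = FALSE`. Monotone-increasing survival with concentration (no
#' kill) raises a "no response" error.
#'
#' @param curve a `cytotoxicity_curve` with >= 5 distinct non-zero
#'   concentrations.
#' @param weights `"none"` (default) or `"inverse_y"` for 1/Y weighting.
#' @return list of class `fourpl_fit`: `bottom`, `top`, `ic50` (nM), `hill`,
#'   `rss`, `converged`, `n_points`.
#' @export
fit_4pl <- function(curve, weights = c("none", "inverse_y")) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "cytotoxicity_curve"))
  pts <- curve[curve$concentration_nM > 0, , drop = FALSE]
  if (length(unique(pts$concentration_nM)) < 5L) {
    stop("need >= 5 distinct non-zero concentrations")
  }
  mu <- tapply(pts$percent_survival, pts$concentration_nM, mean)
  conc_sorted <- sort(unique(pts$concentration_nM))
  mu <- mu[as.character(conc_sorted)]
  if (all(diff(mu) > 0)) {
    stop("no response: survival increases monotonically with concentration")
  }

  D <- pts$concentration_nM
  y <- pts$percent_survival
  top0 <- max(y); bot0 <- min(y)
  half <- (top0 + bot0) / 2
  ic0 <- conc_sorted[which.min(abs(mu - half))]
  w <- if (weights == "inverse_y") 1 / pmax(abs(y), 1) else rep(1, length(y))

  # parameterize ic50 on log10 scale for stability and scale equivariance
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(D) - lic50))),
      start = list(bottom = bot0, top = top0, lic50 = log10(ic0), hill = 1),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  converged <- !is.null(fit)
  if (converged) {
    p <- stats::coef(fit)
    est <- list(bottom = unname(p["bottom"]), top = unname(p["top"]),
                ic50 = unname(10^p["lic50"]), hill = unname(p["hill"]))
    rss <- sum((y - fourpl_value(D, est$bottom, est$top, est$ic50, est$hill))^2)
  } else {
    est <- list(bottom = bot0, top = top0, ic50 = ic0, hill = 1)
    rss <- NA_real_
  }
  if (est$bottom > est$top) {  # enforce orientation (hill sign flip)
    est <- list(bottom = est$top, top = est$bottom, ic50 = est$ic50,
                hill = -est$hill)
  }
  window <- c(min(conc_sorted) / 10, max(conc_sorted) * 10)
  if (converged && (est$ic50 < window[1] || est$ic50 > window[2] ||
                    est$hill <= 0)) {
    converged <- FALSE
  }
  structure(
    c(est, list(rss = rss, converged = converged, n_points = length(y),
                drug_id = attr(curve, "drug_id"))),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit%s> ic50=%.4g nM hill=%.3g bottom=%.3g top=%.3g rss=%.3g %s\n",
    if (!is.null(x$drug_id) && !is.na(x$drug_id)) paste0(" ", x$drug_id) else "",
    x$ic50, x$hill, x$bottom, x$top, x$rss,
    if (x$converged) "(converged)" else "(NOT converged)"))
  invisible(x)
}

#' Exact permutation p-value for a Spearman rank correlation
#'
#' Enumerates all `n!` pairings of the ranks (feasible for n <= 8) and returns
#' the two-sided p-value: the fraction of permutations whose |rho| is at least
#' the observed |rho|. For 5 perfectly anti-correlated pairs only the two
#' perfect orderings reach |rho| = 1, giving p = 2/120 ~ 0.0167 — the exact
#' test behind a reported inverse correlation between the IC50s of a
#' secondary drug and of taxanes across a small cell-line set.
#'
#' @param x,y paired numeric vectors, 3 <= length <= 8, no ties within either.
#' @return list with `rho` (Spearman) and `p_value` (exact, two-sided).
#' @export
spearman_perm_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3, n <= 8)
  if (anyDuplicated(x) || anyDuplicated(y)) {
    stop("exact enumeration requires tie-free data")
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  ry <- rank(y)
  rx <- rank(x)
  perms <- all_permutations(n)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  list(rho = rho_obs, p_value = p)
}

# all permutations of 1..n as a (n!) x n matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
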