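#' Hill fit object
#'
#' Bundles a Hill cooperativity coefficient with the ligand concentration at
#' half saturation. The dissociation constant is `cu_half^n`; note that it
#' formally carries units of M^n but is reported on the molar scale, following
#' field convention.
#'
#' @param n Hill coefficient (> 0). Values below 1 indicate negative
#'   cooperativity, 1 noncooperative binding, above 1 positive cooperativity.
#' @param cu_half Ligand concentration at which half the protein is apo.
#' @return An object of class `cu_hill_fit` with fields `n`, `cu_half`, `kd`.
#' @export
hill_fit <- function(n, cu_half) {
  if (n <= 0) rlang::abort("Hill coefficient must be positive")
  if (cu_half <= 0) rlang::abort("cu_half must be positive")
  structure(list(n = n, cu_half = cu_half, kd = cu_half^n),
            class = "cu_hill_fit")
}

#' @export
print.cu_hill_fit <- function(x, ...) {
  cat(sprintf("<cu_hill_fit> n = %.4g, [CU]_0.5 = %.4g, Kd = %.4g\n",
              x$n, x$cu_half, x$kd))
  invisible(x)
}

#' Apo fraction at a given ligand concentration
#'
#' Fraction of the protein population in the apo (metal-free) state:
#' `1 / (CU^n / Kd + 1)`. Strictly decreasing in the ligand concentration,
#' tending to 1 as CU -> 0 and 0 as CU -> Inf.
#'
#' @param cu Ligand (labile copper) concentration, >= 0; vectorized.
#' @param fit A [hill_fit()].
#' @return Apo fraction in (0, 1].
#' @export
hill_apo_fraction <- function(cu, fit) {
  if (any(cu < 0)) rlang::abort("ligand concentration must be nonnegative")
  1 / ((cu / fit$cu_half)^fit$n + 1)
}

#' Hill coefficient from a single titration point
#'
#' Inverts the Hill equation at one point: given the apo fraction observed at
#' ligand concentration `cu` and the half-saturation concentration, the
#' coefficient is `log(1/f - 1) / log(cu / cu_half)`. The point must not sit
#' at half saturation, where the expression is indeterminate.
#'
#' @param apo_fraction Observed apo fraction, in (0, 1) and not equal to 0.5.
#' @param cu Ligand concentration at that point, not equal to `cu_half`.
#' @param cu_half Half-saturation ligand concentration.
#' @return The Hill coefficient implied by the point.
#' @export
hill_coefficient_point <- function(apo_fraction, cu, cu_half) {
  if (apo_fraction <= 0 || apo_fraction >= 1) {
    rlang::abort("apo fraction must lie strictly between 0 and 1")
  }
  if (abs(apo_fraction - 0.5) < 1e-12 || abs(cu / cu_half - 1) < 1e-12) {
    rlang::abort("indeterminate point: apo fraction 0.5 (cu = cu_half)")
  }
  log(1 / apo_fraction - 1) / log(cu / cu_half)
}

#' Hill coefficient from the 10-90% dynamic range
#'
#' The ratio of ligand concentrations at 10% and 90% apo fraction equals
#' `81^(1/n)`, so `n = log(81) / log(ratio)`. A noncooperative protein spans
#' an 81-fold range; stronger positive cooperativity compresses it (n = 4
#' gives a 3-fold range) while negative cooperativity stretches it.
#'
#' @param cu_at_10pct Ligand concentration where 10% of the protein is apo.
#' @param cu_at_90pct Ligand concentration where 90% is apo.
#' @return The Hill coefficient.
#' @export
hill_from_dynamic_range <- function(cu_at_10pct, cu_at_90pct) {
  if (cu_at_10pct <= 0 || cu_at_90pct <= 0) {
    rlang::abort("concentrations must be positive")
  }
  ratio <- cu_at_10pct / cu_at_90pct
  if (ratio <= 1) rlang::abort("dynamic-range ratio must exceed 1")
  log(81) / log(ratio)
}

#' Dissociation constant from the half-saturation concentration
#'
#' @param cu_half Ligand concentration at half saturation (> 0).
#' @param n Hill coefficient (> 0).
#' @return `cu_half^n` (units M^n, reported on the molar scale).
#' @export
kd_from_half_saturation <- function(cu_half, n) {
  if (cu_half <= 0 || n <= 0) rlang::abort("arguments must be positive")
  cu_half^n
}

#' Fit a Hill curve to titration points
#'
#' Estimates the Hill coefficient as the mean of per-point inversions
#' ([hill_coefficient_point()]) over informative points, excluding points near
#' the half-saturation midpoint where the inversion is ill-conditioned (the
#' "middle points" selection). The dissociation constant is then derived from
#' the supplied half-saturation concentration.
#'
#' @param points A data frame with columns `ligand` (concentration) and
#'   `apo_fraction`.
#' @param cu_half Half-saturation ligand concentration, taken as known (read
#'   off the titration plot).
#' @param range Points with apo fraction outside this open interval are
#'   discarded as saturated ends. Default `c(0.05, 0.95)`.
#' @param exclude_band Apo-fraction band around 0.5 excluded from the per-point
#'   inversion. Default `c(0.45, 0.55)`.
#' @return A [hill_fit()] with attributes `n_points` (points used) and
#'   `n_se` (standard error of the per-point coefficients).
#' @export
fit_hill_curve <- function(points, cu_half, range = c(0.05, 0.95),
                           exclude_band = c(0.45, 0.55)) {
  stopifnot(is.data.frame(points), all(c("ligand", "apo_fraction") %in% names(points)))
  usable <- points$apo_fraction > range[1] & points$apo_fraction < range[2]
  if (sum(usable) < 3) rlang::abort("need at least 3 points inside the usable range")
  mid <- points$apo_fraction >= exclude_band[1] & points$apo_fraction <= exclude_band[2]
  sel <- usable & !mid
  if (!any(sel)) rlang::abort("all points fall in the excluded midpoint band")
  ns <- mapply(hill_coefficient_point,
               points$apo_fraction[sel], points$ligand[sel],
               MoreArgs = list(cu_half = cu_half))
  fit <- hill_fit(mean(ns), cu_half)
  attr(fit, "n_points") <- sum(sel)
  attr(fit, "n_se") <- stats::sd(ns) / sqrt(sum(sel))
  fit
}

#' Recalibration anchor from the "free"-copper to the labile-pool scale
#'
#' Thermodynamic titrations of copper proteins are conventionally reported
#' against aqueous ("free") copper, whose cellular concentration (~1e-18 M) is
#' so low that it cannot carry trafficking flux. The titration axis is
#' therefore rescaled so that a chosen free-scale concentration (the average
#' of the MAC and ACE pK_d, 6.1e-19 M) maps onto the measured labile-pool
#' concentration in the reference condition (0.59 uM). The rescaling is a pure
#' multiplication and leaves Hill coefficients untouched.
#'
#' @param free_scale_anchor Free-copper concentration anchoring the original
#'   axis, in M. Default 6.1e-19.
#' @param cu_m10 Labile-pool concentration it is mapped to, in M.
#'   Default 0.59e-6.
#' @return An object of class `cu_anchor` with the unitless `factor`.
#' @export
calibration_anchor <- function(free_scale_anchor = 6.1e-19, cu_m10 = 0.59e-6) {
  if (free_scale_anchor <= 0 || cu_m10 <= 0) {
    rlang::abort("anchor concentrations must be positive")
  }
  structure(list(free_scale_anchor = free_scale_anchor, cu_m10 = cu_m10,
                 factor = cu_m10 / free_scale_anchor),
            class = "cu_anchor")
}

#' Recalibrate titration points onto the labile-pool scale
#'
#' Multiplies every ligand concentration by the anchor factor; apo fractions
#' are unchanged, so refitted Hill coefficients are identical to the original
#' ones.
#'
#' @param points Data frame with columns `ligand` and `apo_fraction`.
#' @param anchor A [calibration_anchor()].
#' @return The points tibble with rescaled `ligand`.
#' @export
recalibrate_axis <- function(points, anchor) {
  stopifnot(inherits(anchor, "cu_anchor"))
  dplyr::mutate(tibble::as_tibble(points), ligand = .data$ligand * anchor$factor)
}

#' Rescale a Hill fit onto the labile-pool scale
#'
#' @param fit A [hill_fit()] on the original axis.
#' @param anchor A [calibration_anchor()].
#' @return A [hill_fit()] with `cu_half` multiplied by the anchor factor and
#'   the same coefficient.
#' @export
recalibrate_hill_fit <- function(fit, anchor) {
  stopifnot(inherits(fit, "cu_hill_fit"), inherits(anchor, "cu_anchor"))
  hill_fit(fit$n, fit$cu_half * anchor$factor)
}

#' Generate noiseless or noisy Hill titration points
#'
#' Synthetic stand-in for digitized titration data: ligand concentrations are
#' log-spaced across a span around the half-saturation point and apo fractions
#' follow the Hill curve, optionally perturbed by multiplicative lognormal
#' noise (truncated to (0, 1)).
#'
#' @param fit A [hill_fit()] defining the generating curve.
#' @param n_points Number of points.
#' @param span Decades spanned either side of `cu_half`. Default 2.5.
#' @param noise_cv Coefficient of variation of multiplicative noise on the apo
#'   fraction; 0 gives exact curve points.
#' @return A tibble with columns `ligand`, `apo_fraction`.
#' @export
simulate_titration_points <- function(fit, n_points = 20, span = 2.5,
                                      noise_cv = 0) {
  lig <- fit$cu_half * 10^seq(-span, span, length.out = n_points)
  f <- hill_apo_fraction(lig, fit)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    f <- f * stats::rlnorm(n_points, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  }
  tibble::tibble(ligand = lig, apo_fraction = f)
}

#' Read or write titration points as two-column TSV
#'
#' The on-disk schema is `ligand_concentration_M` and `apo_fraction`,
#' tab-separated, with `#` comment lines permitted. In memory the ligand
#' column is called `ligand` (axis units are whatever the file carries; the
#' shipped fixtures use the free-copper M scale). Approximate reconstructions
#' of the MAC and ACE titrations ship with the package:
#' `system.file("extdata", "titration-points-mac.tsv", package = "cuflux")`.
#'
#' @param path File path.
#' @return `read_titration_points()` returns a tibble with columns `ligand`,
#'   `apo_fraction`.
#' @export
read_titration_points <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#")
  if (!all(c("ligand_concentration_M", "apo_fraction") %in% names(raw))) {
    rlang::abort("expected columns ligand_concentration_M, apo_fraction")
  }
  tibble::tibble(ligand = raw$ligand_concentration_M,
                 apo_fraction = raw$apo_fraction)
}

#' @rdname read_titration_points
#' @param points Data frame with columns `ligand`, `apo_fraction`.
#' @export
write_titration_points <- function(points, path) {
  stopifnot(all(c("ligand", "apo_fraction") %in% names(points)))
  out <- data.frame(ligand_concentration_M = points$ligand,
                    apo_fraction = points$apo_fraction)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default recalibrated Hill fits for MAC, ACE and CUP
#'
#' The printed titration parameters on the free-copper scale (half-saturation
#' 9.7e-20 M with n = 0.62 for MAC; 2.8e-18 M with n = 0.90 for ACE; for CUP
#' only Kd = 9.3e-19 M and n = 1.1 are available, so its half-saturation is
#' back-computed as Kd^(1/n)), rescaled to the labile-pool axis and expressed
#' in uM.
#'
#' @param anchor A [calibration_anchor()].
#' @return Named list of `cu_hill_fit` objects (`MAC`, `ACE`, `CUP`) with
#'   `cu_half` in uM on the labile-pool scale.
#' @export
default_hill_fits <- function(anchor = calibration_anchor()) {
  to_uM <- anchor$factor * 1e6
  list(
    MAC = hill_fit(0.62, 9.7e-20 * to_uM),
    ACE = hill_fit(0.90, 2.8e-18 * to_uM),
    CUP = hill_fit(1.1, (9.3e-19)^(1 / 1.1) * to_uM)
  )
}
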