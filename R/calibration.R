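#' Apparent rate constant of one reaction at one condition
#'
#' Inverts the rate law: the apparent constant is the steady-state rate
#' divided by the product of normalized rate-law factors evaluated at the
#' condition's state (excluding any logistic augmentation, whose effect is
#' exactly what the per-condition trend of the apparent constant reveals).
#'
#' @param network A `cu_network`.
#' @param reaction Reaction name.
#' @param steady_rate Steady-state rate (uM/min).
#' @param profile One condition row (component concentrations and `copper`).
#' @param ref A [cu_reference()].
#' @return Apparent rate constant (uM/min at the reference state).
#' @export
apparent_rate_constant <- function(network, reaction, steady_rate, profile, ref) {
  state <- unlist(profile[component_names()])
  f <- rate_factors(network, state, profile$copper, ref)[[reaction]]
  if (!is.finite(f) || f == 0) {
    rlang::abort(paste0("rate-law factor for ", reaction,
                        " is zero at this condition; apparent k undefined"))
  }
  steady_rate / f
}

#' Per-condition apparent rate constants for all reactions
#'
#' @param rate_table Long rate table from [steady_state_rate_table()].
#' @param conditions Assembled condition table.
#' @param network A `cu_network`.
#' @param ref A [cu_reference()].
#' @return Long tibble: `condition`, `reaction`, `rate`, `k_apparent`.
#' @export
apparent_rate_constants <- function(rate_table, conditions, network, ref) {
  out <- dplyr::left_join(rate_table, conditions, by = "condition")
  ks <- purrr::map_dbl(seq_len(nrow(out)), function(i) {
    apparent_rate_constant(network, out$reaction[i], out$rate[i],
                           out[i, ], ref)
  })
  tibble::tibble(condition = out$condition, reaction = out$reaction,
                 rate = out$rate, k_apparent = ks)
}

#' Classify reactions as invariant or trending
#'
#' A reaction's rate constant should not depend on the growth condition; a
#' systematic rise across the ordered titration series signals regulation
#' missing from the assumed rate law. A reaction is classified `trending` when
#' its apparent constants rise across the ordered conditions -- the maximum
#' drawdown (largest drop from a running maximum) must not exceed `mono_tol`
#' times the series range, so noise-level dips on a rising series are
#' tolerated while any systematic decline, whose drawdown equals the full
#' range, is rejected -- and the relative spread `max/min - 1` (minimum taken
#' over positive entries; structural zeros from floored rates are allowed to
#' lead the series) exceeds `rel_spread_threshold`. Everything else is
#' `invariant`.
#'
#' @param k_table Long tibble from [apparent_rate_constants()].
#' @param condition_order Condition labels from Cu-deficient to Cu-excess.
#' @param rel_spread_threshold Minimum relative spread for a trend.
#'   Default 0.5.
#' @param mono_tol Largest tolerated drawdown as a fraction of the series
#'   range. Default 0.25.
#' @return A tibble: `reaction`, `class`, `k_mean` (mean apparent constant),
#'   `spread`, plus a list-column `k_by_condition`.
#' @export
classify_invariance <- function(k_table,
                                condition_order = c("MBCS", "M0", "M10", "M50",
                                                    "M100", "M175", "M250"),
                                rel_spread_threshold = 0.5,
                                mono_tol = 0.25) {
  stopifnot(all(k_table$condition %in% condition_order))
  n_cond <- length(unique(k_table$condition))
  if (n_cond < 5) rlang::abort("need at least 5 conditions to classify invariance")
  k_table <- dplyr::arrange(k_table,
                            match(.data$condition, condition_order),
                            .data$reaction)
  split_k <- split(k_table, k_table$reaction)
  rows <- purrr::map(split_k, function(d) {
    k <- d$k_apparent
    pos <- k[k > 1e-12 * max(k)]
    spread <- if (length(pos)) max(pos) / min(pos) - 1 else 0
    k_range <- diff(range(k))
    drawdown <- max(cummax(k) - k)
    nondecr <- drawdown <= mono_tol * k_range + 1e-12 * max(abs(k), 1)
    trending <- nondecr && spread > rel_spread_threshold
    tibble::tibble(
      reaction = d$reaction[1],
      class = if (trending) "trending" else "invariant",
      k_mean = mean(k), spread = spread,
      k_by_condition = list(stats::setNames(k, d$condition))
    )
  })
  dplyr::bind_rows(rows)
}

# Logistic (soft Heaviside) factor in (0, 1): half-maximal at the setpoint,
# saturating at 1 for sensed concentrations far above it. The exponent is
# clamped to avoid overflow.
logistic_factor <- function(n_sens, sen_sp, sen) {
  z <- pmin(pmax(n_sens * (sen_sp - sen), -700), 700)
  1 / (1 + exp(z))
}

#' Logistic parameters for a regulated reaction
#'
#' @param k_invariant Maximal rate constant (> 0).
#' @param sen_sp Setpoint concentration of the sensed species (uM) at which
#'   the apparent constant is half-maximal.
#' @param n_sens Sensitivity factor (per uM, > 0 for feedforward regulation).
#' @param sensor Sensed species: `"CU"` or `"COPPER"`.
#' @return An object of class `cu_logistic`.
#' @export
cu_logistic <- function(k_invariant, sen_sp, n_sens, sensor = "CU") {
  if (k_invariant <= 0) rlang::abort("k_invariant must be positive")
  structure(list(k_invariant = k_invariant, sen_sp = sen_sp,
                 n_sens = n_sens, sensor = sensor),
            class = "cu_logistic")
}

#' @export
print.cu_logistic <- function(x, ...) {
  cat(sprintf("<cu_logistic> k_inv = %.4g, setpoint = %.4g uM (%s), n = %.4g /uM\n",
              x$k_invariant, x$sen_sp, x$sensor, x$n_sens))
  invisible(x)
}

#' Apparent rate constant under logistic regulation
#'
#' `k_invariant / (1 + exp(n * (sen_sp - sen)))`: increasing in the sensed
#' concentration, half-maximal at the setpoint, saturating at `k_invariant`.
#'
#' @param params A [cu_logistic()].
#' @param sen Sensed concentration (uM); vectorized.
#' @return Apparent rate constant.
#' @export
logistic_apparent_k <- function(params, sen) {
  if (any(sen < 0)) rlang::abort("sensed concentration must be nonnegative")
  params$k_invariant * logistic_factor(params$n_sens, params$sen_sp, sen)
}

#' Fit a logistic regulation curve to per-condition apparent constants
#'
#' Bounded nonlinear least squares on *relative* residuals (matching the
#' multiplicative measurement-error model, with a small weight floor so that
#' structurally zero observations still penalize models predicting flux
#' there), with multiple restarts. Starting values are drawn around the
#' data's range (setpoint within the sensed-concentration span, ceiling
#' between the largest apparent constant and `bounds[2]`), and the best of
#' `n_starts` converged fits is returned.
#'
#' @param k_points Apparent rate constants, one per condition.
#' @param sen_points Sensed concentrations (uM), same length.
#' @param sensor Sensed species label stored in the result.
#' @param bounds Optional c(lower, upper) for `k_invariant`. Default
#'   `c(max(k)/2, 5*max(k))`, mirroring the need to constrain the ceiling when
#'   the data do not reach saturation.
#' @param n_starts Number of random restarts. Default 20.
#' @param seed Seed for the restart draws. Default 1.
#' @return A [cu_logistic()] with attributes `rss` (weighted, relative-scale)
#'   and `convergence`.
#' @export
fit_logistic <- function(k_points, sen_points, sensor = "CU", bounds = NULL,
                         n_starts = 20, seed = 1) {
  keep <- is.finite(k_points) & is.finite(sen_points)
  k <- k_points[keep]; sen <- sen_points[keep]
  if (length(k) < 4) rlang::abort("need at least 4 (k, sen) pairs")
  kmax <- max(k)
  # the factor is bounded by 1, so the plateau constant must exceed the
  # largest noise-free k. The estimator additionally assumes the series
  # approaches saturation within the observed window (a series that never
  # does carries no setpoint information, and the trending classification
  # that feeds this fit requires a > 1.5-fold rise); under that assumption
  # the plateau sits within a small multiple of max(k), and capping it at
  # 5x keeps the search off the degenerate ridge where plateau and setpoint
  # grow together at slowly shrinking residual. Callers with
  # out-of-window setpoints must supply their own bounds.
  if (is.null(bounds)) bounds <- c(kmax / 2, 5 * kmax)
  span <- range(sen)
  # relative residuals: the measurement error feeding these apparent
  # constants is multiplicative, so absolute residuals would let the noisy
  # plateau swamp the near-zero floor points that pin the switch steepness.
  # The weight floor keeps structurally floored (zero) observations
  # informative: a model that predicts appreciable flux where none was
  # observed is penalized on the same relative scale.
  wt <- pmax(k, 1e-3 * kmax)
  resid_fn <- function(par) {
    (par[["ki"]] * logistic_factor(par[["ns"]], par[["sp"]], sen) - k) / wt
  }
  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  for (s in seq_len(n_starts)) {
    start <- c(
      ki = stats::runif(1, max(bounds[1], kmax), min(bounds[2], 2 * kmax)),
      sp = stats::runif(1, span[1], span[2]),
      ns = stats::runif(1, 0.1, 20) / max(diff(span), 1e-6)
    )
    fit <- try(minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(ki = bounds[1], sp = 0, ns = 1e-6),
      upper = c(ki = bounds[2], sp = 10 * span[2],
                ns = 1e3 / max(diff(span), 1e-6)),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000,
                                           ftol = 1e-12)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    converged <- fit$info %in% 1:4
    better <- is.null(best) ||
      (converged && !best$converged) ||
      (converged == best$converged && rss < best$rss)
    if (better) best <- list(fit = fit, rss = rss, converged = converged)
  }
  if (is.null(best)) rlang::abort("logistic fit failed from every start")
  cf <- best$fit$par
  out <- cu_logistic(cf[["ki"]], cf[["sp"]], cf[["ns"]], sensor = sensor)
  attr(out, "rss") <- best$rss
  attr(out, "convergence") <- best$converged
  out
}

#' Consolidate the calibrated parameter set
#'
#' Invariant reactions receive the mean of their per-condition apparent
#' constants; trending reactions receive logistic parameters fitted against
#' the sensed species (the labile pool for the metallothionein biosynthesis
#' and the CUP/OTH metallations, nutrient COPPER for the second importer).
#' The result is a complete parameterization of the dynamical system.
#'
#' @param classification Output of [classify_invariance()].
#' @param conditions Assembled condition table (provides the sensed
#'   concentrations per condition).
#' @param sensors Named character vector mapping each trending reaction to its
#'   sensed species.
#' @param seed Seed forwarded to [fit_logistic()].
#' @return An object of class `cu_params`: list with `k` (named vector of
#'   invariant constants) and `logistic` (named list of `cu_logistic`).
#' @export
consolidate_constants <- function(classification, conditions,
                                  sensors = c(BACUP = "CU", MCUPF = "CU",
                                              MOTHF = "CU", CUIN2 = "COPPER"),
                                  seed = 1) {
  trend <- classification$reaction[classification$class == "trending"]
  invar <- classification$reaction[classification$class == "invariant"]
  k <- stats::setNames(classification$k_mean[match(invar, classification$reaction)],
                       invar)
  logistic <- list()
  for (rxn in trend) {
    sensor <- if (rxn %in% names(sensors)) sensors[[rxn]] else "CU"
    kbc <- classification$k_by_condition[[match(rxn, classification$reaction)]]
    sen <- if (sensor == "COPPER") {
      conditions$copper[match(names(kbc), conditions$condition)]
    } else {
      conditions$CU[match(names(kbc), conditions$condition)]
    }
    logistic[[rxn]] <- fit_logistic(kbc, sen, sensor = sensor, seed = seed)
  }
  missing <- setdiff(classification$reaction, c(invar, trend))
  if (length(missing)) {
    rlang::abort(paste0("incomplete parameterization: ",
                        paste(missing, collapse = ", ")))
  }
  structure(list(k = k, logistic = logistic), class = "cu_params")
}

#' @export
print.cu_params <- function(x, ...) {
  cat("<cu_params> ", length(x$k), " invariant constants, ",
      length(x$logistic), " logistic reactions (",
      paste(names(x$logistic), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
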