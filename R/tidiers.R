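#' Tidy a Hill fit
#'
#' @param x A `cu_hill_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @export
tidy.cu_hill_fit <- function(x, ...) {
  tibble::tibble(term = c("n", "cu_half", "kd"),
                 estimate = c(x$n, x$cu_half, x$kd))
}

#' Glance at a Hill fit
#'
#' @param x A `cu_hill_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `cu_half`, `kd`, and, when the fit came from
#'   [fit_hill_curve()], `n_points` and `n_se`.
#' @export
glance.cu_hill_fit <- function(x, ...) {
  tibble::tibble(n = x$n, cu_half = x$cu_half, kd = x$kd,
                 n_points = attr(x, "n_points") %||% NA_integer_,
                 n_se = attr(x, "n_se") %||% NA_real_)
}

#' Tidy a logistic regulation fit
#'
#' @param x A `cu_logistic`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @export
tidy.cu_logistic <- function(x, ...) {
  tibble::tibble(term = c("k_invariant", "sen_sp", "n_sens"),
                 estimate = c(x$k_invariant, x$sen_sp, x$n_sens))
}

#' Glance at a logistic regulation fit
#'
#' @param x A `cu_logistic`.
#' @param ... Unused.
#' @return A one-row tibble: `k_invariant`, `sen_sp`, `n_sens`, `sensor`,
#'   `rss` (when fitted).
#' @export
glance.cu_logistic <- function(x, ...) {
  tibble::tibble(k_invariant = x$k_invariant, sen_sp = x$sen_sp,
                 n_sens = x$n_sens, sensor = x$sensor,
                 rss = attr(x, "rss") %||% NA_real_)
}

#' Tidy a consolidated parameter set
#'
#' Long view of all calibrated constants: one row per (reaction, term), where
#' invariant reactions contribute a single `k` term and logistic reactions
#' contribute `k_invariant`, `sen_sp` and `n_sens`.
#'
#' @param x A `cu_params`.
#' @param ... Unused.
#' @return A tibble: `reaction`, `term`, `estimate`.
#' @export
tidy.cu_params <- function(x, ...) {
  inv <- tibble::tibble(reaction = names(x$k), term = "k",
                        estimate = unname(x$k))
  lg <- purrr::map2(names(x$logistic), x$logistic, function(rxn, p) {
    tibble::tibble(reaction = rxn,
                   term = c("k_invariant", "sen_sp", "n_sens"),
                   estimate = c(p$k_invariant, p$sen_sp, p$n_sens))
  })
  dplyr::bind_rows(inv, lg)
}

#' Tidy a steady state
#'
#' @param x A `cu_steady_state`.
#' @param ... Unused.
#' @return A tibble: `component`, `concentration` (uM).
#' @export
tidy.cu_steady_state <- function(x, ...) {
  tibble::tibble(component = names(x$state), concentration = unname(x$state))
}

#' Glance at a steady state
#'
#' @param x A `cu_steady_state`.
#' @param ... Unused.
#' @return A one-row tibble: `residual`, `converged`, `t_used`.
#' @export
glance.cu_steady_state <- function(x, ...) {
  tibble::tibble(residual = x$residual, converged = x$converged,
                 t_used = x$t_used)
}
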