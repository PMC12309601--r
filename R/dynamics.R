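#' Assemble the dynamical system
#'
#' Binds the network, the consolidated rate constants (invariant scalars plus
#' logistic parameters for the regulated reactions), the reference state used
#' for rate-law normalization, and a fixed nutrient COPPER concentration into
#' an integrable ODE system. COPPER is a boundary condition, not a state
#' variable; growth dilution is the only removal process for every internal
#' component.
#'
#' @param network A `cu_network`.
#' @param params A `cu_params` from [consolidate_constants()].
#' @param ref A [cu_reference()].
#' @param copper Nutrient COPPER concentration, uM.
#' @param knockouts Character vector of reaction names whose rate constants
#'   are set to zero (in-silico deletions).
#' @return An object of class `cu_system`.
#' @export
cu_system <- function(network, params, ref, copper, knockouts = character()) {
  rxns <- network$reactions$name
  unknown <- setdiff(knockouts, rxns)
  if (length(unknown)) {
    rlang::abort(paste0("unknown reaction in knockouts: ",
                        paste(unknown, collapse = ", ")))
  }
  covered <- c(names(params$k), names(params$logistic))
  missing <- setdiff(rxns, covered)
  if (length(missing)) {
    rlang::abort(paste0("incomplete parameterization: no constant for ",
                        paste(missing, collapse = ", ")))
  }
  structure(list(network = network, params = params, ref = ref,
                 copper = copper, knockouts = knockouts,
                 S = stoichiometric_matrix(network)),
            class = "cu_system")
}

#' @export
print.cu_system <- function(x, ...) {
  cat(sprintf("<cu_system> COPPER = %g uM%s\n", x$copper,
              if (length(x$knockouts)) {
                paste0(", knockouts: ", paste(x$knockouts, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Knock out a reaction
#'
#' Returns a copy of the system with the reaction's rate constant set to zero,
#' the in-silico equivalent of deleting the gene/protein carrying it. All
#' other parameters are unchanged.
#'
#' @param system A `cu_system`.
#' @param reaction Reaction name (e.g. `"CUIN2"`).
#' @return The modified `cu_system`.
#' @export
knockout <- function(system, reaction) {
  if (!reaction %in% system$network$reactions$name) {
    rlang::abort(paste0("unknown reaction: ", reaction))
  }
  system$knockouts <- union(system$knockouts, reaction)
  system
}

#' Change the nutrient COPPER of a system
#'
#' @param system A `cu_system`.
#' @param copper New COPPER concentration (uM).
#' @return The modified system.
#' @export
set_copper <- function(system, copper) {
  system$copper <- copper
  system
}

# Full 25-vector of reaction rates at a state. Negative roundoff in the state
# is clipped before evaluating the laws.
system_rates <- function(system, state) {
  state <- pmax(state, 0)
  net <- system$network
  f <- rate_factors(net, state, system$copper, system$ref)
  k <- numeric(length(f))
  names(k) <- names(f)
  k[names(system$params$k)] <- system$params$k
  for (rxn in names(system$params$logistic)) {
    lp <- system$params$logistic[[rxn]]
    sen <- if (identical(lp$sensor, "COPPER")) system$copper else state[["CU"]]
    k[rxn] <- logistic_apparent_k(lp, sen)
  }
  k[system$knockouts] <- 0
  k * f
}

#' Derivative function of the assembled system
#'
#' Returns `function(t, y, parms)` in deSolve form computing `S %*% R(y)`.
#'
#' @param system A `cu_system`.
#' @return A function suitable for [deSolve::ode()].
#' @export
assemble_derivatives <- function(system) {
  comp <- component_names()
  force(system)
  function(t, y, parms = NULL) {
    names(y) <- comp
    r <- system_rates(system, y)
    list(as.numeric(system$S %*% r))
  }
}

#' Integrate the system
#'
#' Stiff-capable integration (lsoda) at relative tolerance 1e-8 and absolute
#' tolerance 1e-12 uM.
#'
#' @param system A `cu_system`.
#' @param y0 Named initial state (uM), nonnegative.
#' @param times Output time grid (min).
#' @return A `cu_trajectory`: tibble with `time` and one column per component.
#' @export
integrate_system <- function(system, y0, times) {
  if (any(y0 < 0)) rlang::abort("initial state must be nonnegative")
  comp <- component_names()
  y0 <- y0[comp]
  sol <- deSolve::ode(y = y0, times = times, func = assemble_derivatives(system),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort(paste0(
      "stiff integration failed; consider a smaller demetallation multiplier ",
      "(fast metal-exchange reactions set the stiffness of the system)"))
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  out[-1] <- pmax(as.matrix(out[-1]), 0)
  class(out) <- c("cu_trajectory", class(out))
  out
}

#' Numerical Jacobian of the system at a state
#'
#' @param system A `cu_system`.
#' @param state Named state vector.
#' @param eps Relative step for central differences.
#' @return A 10 x 10 matrix d(dC/dt)/dC.
#' @export
system_jacobian <- function(system, state, eps = 1e-6) {
  comp <- component_names()
  state <- state[comp]
  f <- function(y) as.numeric(system$S %*% system_rates(system, stats::setNames(y, comp)))
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(comp, comp))
  for (j in seq_len(n)) {
    h <- eps * max(abs(state[j]), 1e-3)
    yp <- state; yp[j] <- yp[j] + h
    ym <- state; ym[j] <- max(ym[j] - h, 0)
    J[, j] <- (f(yp) - f(ym)) / (yp[j] - ym[j])
  }
  J
}

#' Solve for a steady state (annealing)
#'
#' Integrates from the initial state for `t_max` minutes, then polishes the
#' endpoint with damped Newton iterations on the derivative function.
#' Integrating the assembled system from the per-condition concentration
#' estimates is the annealing step: the attractor self-corrects the minor
#' inconsistencies left by averaging rate constants across conditions and by
#' the logistic fits.
#'
#' @param system A `cu_system`.
#' @param y0 Named initial state.
#' @param t_max Integration horizon (min). Default 20000.
#' @param tol Convergence criterion on `max |dC/dt|` (uM/min). Default 1e-9.
#' @param newton_steps Maximum Newton polish iterations.
#' @return A list of class `cu_steady_state`: `state` (named vector),
#'   `residual`, `converged`, `t_used`.
#' @export
steady_state <- function(system, y0, t_max = 20000, tol = 1e-9,
                         newton_steps = 50) {
  comp <- component_names()
  traj <- integrate_system(system, y0, times = c(0, t_max / 4, t_max / 2, t_max))
  y <- unlist(traj[nrow(traj), comp])
  f <- function(y) as.numeric(system$S %*% system_rates(system, stats::setNames(y, comp)))
  res <- f(y)
  for (it in seq_len(newton_steps)) {
    if (max(abs(res)) < tol) break
    J <- system_jacobian(system, y)
    step <- try(solve(J, -res), silent = TRUE)
    if (inherits(step, "try-error")) break
    lambda <- 1
    repeat {
      y_new <- pmax(y + lambda * step, 0)
      res_new <- f(y_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    y <- y_new; res <- res_new
  }
  structure(list(state = y, residual = max(abs(res)),
                 converged = max(abs(res)) < tol, t_used = t_max),
            class = "cu_steady_state")
}

#' @export
print.cu_steady_state <- function(x, ...) {
  cat(sprintf("<cu_steady_state> residual = %.3g uM/min (%s)\n",
              x$residual, if (x$converged) "converged" else "NOT converged"))
  print(round(x$state, 5))
  invisible(x)
}

#' @rdname steady_state
#' @param check_factor When non-NULL, warn if any annealed component differs
#'   from its initial estimate by more than this factor (qualitative fidelity
#'   check).
#' @export
anneal <- function(system, y0, t_max = 20000, tol = 1e-9, check_factor = 2) {
  ss <- steady_state(system, y0, t_max = t_max, tol = tol)
  if (!is.null(check_factor)) {
    ratio <- ss$state / pmax(y0[component_names()], 1e-12)
    off <- ratio > check_factor | ratio < 1 / check_factor
    if (any(off)) {
      rlang::warn(paste0("annealed state differs from initial estimates by more than ",
                         check_factor, "x for: ",
                         paste(names(ratio)[off], collapse = ", ")))
    }
  }
  ss
}

# First time (on the sampled grid) from which `dev_fun` stays TRUE for at
# least `sustain` minutes; NA when never sustained.
first_sustained <- function(times, ok, sustain) {
  if (!any(ok)) return(NA_real_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (times[ends[i]] - times[starts[i]] >= sustain ||
        ends[i] == length(times)) {
      return(times[starts[i]])
    }
  }
  NA_real_
}

#' Perturb a component concentration
#'
#' Multiplies one component by `factor` at `t_event` (a state discontinuity;
#' the integration is restarted) and follows the relaxation back to the
#' attractor. Recovery is reached when every component is within
#' `recovery_band` (default 1%) of the pre-perturbation steady state and
#' stays there for `sustain` minutes. Per-component half-lives report the time
#' for each deviation to fall to half its value just after the perturbation.
#'
#' @param system A `cu_system`.
#' @param y0 Pre-perturbation steady state (annealed).
#' @param component Component to perturb (e.g. `"CU"`).
#' @param factor Multiplicative perturbation (> 0); 1 leaves the trajectory
#'   unperturbed.
#' @param t_event Perturbation time (min). Default 100.
#' @param t_end End of the simulation (min). Default 1500.
#' @param dt Output grid spacing (min). Default 1.
#' @param recovery_band Relative band defining recovery. Default 0.01.
#' @param sustain Minutes the state must remain in the band. Default 50.
#' @return A list of class `cu_perturbation`: `trajectory` (with the event
#'   marker attribute), `recovery_time` (min after the event), `half_life`
#'   (named per-component vector), `returned` (logical).
#' @export
perturb_component <- function(system, y0, component, factor,
                              t_event = 100, t_end = 1500, dt = 1,
                              recovery_band = 0.01, sustain = 50) {
  if (factor <= 0) rlang::abort("perturbation factor must be positive")
  comp <- component_names()
  y0 <- y0[comp]
  pre <- integrate_system(system, y0, times = seq(0, t_event, by = dt))
  y_pert <- unlist(pre[nrow(pre), comp])
  y_pert[component] <- y_pert[component] * factor
  post <- integrate_system(system, y_pert, times = seq(t_event, t_end, by = dt))
  post$time <- post$time  # grid already absolute
  traj <- dplyr::bind_rows(pre[-nrow(pre), ], post)
  attr(traj, "t_event") <- t_event

  M <- as.matrix(post[comp])
  rel_dev <- sweep(abs(sweep(M, 2, y0)), 2, pmax(y0, 1e-12), "/")
  ok <- apply(rel_dev <= recovery_band, 1, all)
  rec_t <- first_sustained(post$time, ok, sustain)
  recovery_time <- if (is.na(rec_t)) NA_real_ else rec_t - t_event

  dev0 <- rel_dev[1, ]
  half_life <- purrr::map_dbl(comp, function(cn) {
    if (dev0[[cn]] < 1e-9) return(0)
    idx <- which(rel_dev[, cn] <= dev0[[cn]] / 2)[1]
    if (is.na(idx)) NA_real_ else post$time[idx] - t_event
  })
  names(half_life) <- comp
  structure(list(trajectory = traj, recovery_time = recovery_time,
                 half_life = half_life, returned = !is.na(recovery_time)),
            class = "cu_perturbation")
}

#' Step the nutrient COPPER concentration
#'
#' Grows the cell at `copper_from` until `t_event`, switches the boundary
#' condition to `copper_to`, and follows the approach to the new steady state.
#' Per-component adjustment times report when each component comes within
#' `adjust_band` (default 5%) of its new steady-state value and stays there.
#'
#' @param system A `cu_system` (its own `copper` field is ignored).
#' @param y0 Steady state at `copper_from`.
#' @param copper_from,copper_to Nutrient COPPER before and after the step.
#' @param t_event Step time (min). Default 100.
#' @param t_end End of simulation (min). Default 3000.
#' @param dt Output grid (min). Default 1.
#' @param adjust_band Relative band for per-component adjustment. Default 0.05.
#' @param sustain Minutes the component must stay in band. Default 50.
#' @return A list of class `cu_step`: `trajectory`, `final_state`,
#'   `target_state` (directly annealed at `copper_to`), `adjust_time` (named
#'   vector, min after the event).
#' @export
step_nutrient <- function(system, y0, copper_from, copper_to,
                          t_event = 100, t_end = 3000, dt = 1,
                          adjust_band = 0.05, sustain = 50) {
  comp <- component_names()
  sys_from <- set_copper(system, copper_from)
  sys_to <- set_copper(system, copper_to)
  pre <- integrate_system(sys_from, y0[comp], times = seq(0, t_event, by = dt))
  y_sw <- unlist(pre[nrow(pre), comp])
  post <- integrate_system(sys_to, y_sw, times = seq(t_event, t_end, by = dt))
  traj <- dplyr::bind_rows(pre[-nrow(pre), ], post)
  attr(traj, "t_event") <- t_event

  target <- steady_state(sys_to, y_sw)$state
  M <- as.matrix(post[comp])
  adjust_time <- purrr::map_dbl(comp, function(cn) {
    dev <- abs(M[, cn] - target[[cn]]) / max(target[[cn]], 1e-12)
    t0 <- first_sustained(post$time, dev <= adjust_band, sustain)
    if (is.na(t0)) NA_real_ else t0 - t_event
  })
  names(adjust_time) <- comp
  structure(list(trajectory = traj,
                 final_state = unlist(post[nrow(post), comp]),
                 target_state = target, adjust_time = adjust_time),
            class = "cu_step")
}

#' Steady-state sweep over nutrient COPPER
#'
#' Solves the system to steady state at each COPPER concentration (each point
#' integrated for `t_settle` minutes and Newton-polished), continuing from the
#' previous point's state.
#'
#' @param system A `cu_system`.
#' @param copper_values COPPER concentrations to visit (uM).
#' @param y0 Starting state for the first point (annealed baseline).
#' @param t_settle Integration horizon per point (min). Default 20000.
#' @return A `cu_sweep` tibble: `copper`, the ten components, `total_cell_cu`,
#'   and `converged`.
#' @export
sweep_nutrient <- function(system, copper_values, y0, t_settle = 20000) {
  comp <- component_names()
  w <- cu_weight_vector(system$network)[comp]
  y <- y0[comp]
  rows <- purrr::map(copper_values, function(cp) {
    ss <- steady_state(set_copper(system, cp), y, t_max = t_settle)
    y <<- ss$state
    tibble::tibble(copper = cp, !!!as.list(ss$state),
                   total_cell_cu = sum(w * ss$state),
                   converged = ss$converged)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cu_sweep", class(out))
  out
}

#' Homeostatic slope of the labile pool
#'
#' Least-squares slope of the steady-state labile-pool concentration against
#' nutrient COPPER over a window (default 10-50 uM, the regulated regime),
#' reported in nM of CU per uM of COPPER. Flat is better: a perfectly
#' regulated pool would have slope zero.
#'
#' @param sweep_table A `cu_sweep`.
#' @param window COPPER window (uM). Default `c(10, 50)`.
#' @return Slope in nM/uM.
#' @export
homeostatic_slope <- function(sweep_table, window = c(10, 50)) {
  d <- dplyr::filter(sweep_table, .data$copper >= window[1],
                     .data$copper <= window[2])
  if (nrow(d) < 3) rlang::abort("need at least 3 sweep points in the window")
  unname(stats::coef(stats::lm(CU ~ copper, data = d))[2] * 1000)
}
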