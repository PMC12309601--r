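#' Study-calibrated template for the synthetic generator
#'
#' The defaults encode the calibrated study values: the M10 reference
#' concentrations and per-condition effective COPPER from
#' [assemble_condition_table()], logistic setpoints at the reference sensed
#' concentrations (labile pool for the three CU-sensed reactions, nutrient
#' COPPER for the second importer) so every switch is half-engaged at the
#' reference and traversed by the titration, with the importer switch steep
#' enough that its flux stays negligible at the Cu-deficient anchor, and a
#' quarter of the reference copper influx carried by the CTR-independent
#' importer.
#'
#' @return A list with `ref_conc`, `copper`, `logistic` (named list of
#'   `c(sp, ns)`), `phi`.
#' @export
default_truth_template <- function() {
  base <- assemble_condition_table()
  ref_conc <- unlist(base[base$condition == "M10", component_names()])
  copper <- stats::setNames(base$copper, base$condition)
  cu_ref <- ref_conc[["CU"]]
  list(
    ref_conc = ref_conc,
    copper = copper,
    logistic = list(
      BACUP = c(sp = cu_ref, ns = 8 / cu_ref),
      MCUPF = c(sp = cu_ref, ns = 8 / cu_ref),
      MOTHF = c(sp = cu_ref, ns = 8 / cu_ref),
      CUIN2 = c(sp = copper[["M10"]], ns = 1.5)
    ),
    phi = 0.25
  )
}

#' Generate a synthetic ground truth
#'
#' Constructs a fully parameterized instance of the copper-trafficking model
#' with known rate constants and known per-condition steady states, for
#' validating the estimation pipeline end to end. The construction is
#' reference-state-first: the reference (M10-analog) concentrations are drawn
#' by jittering the default calibrated values by up to +/-30% on the log scale,
#' and the rate constants are then *derived* so that the reference state is an
#' exact fixed point of the dynamical system:
#'
#' * dilution constants equal `alpha` times the reference concentration;
#' * each demetallation runs 100x faster than the dilution of its holo form
#'   (the fast-exchange convention shared with the estimation pipeline);
#' * each forward metallation balances demetallation plus holo dilution;
#' * each biosynthesis balances the total dilution of its apo/holo pair;
#' * the importers split the total copper influx `alpha * total_cu`, with the
#'   CTR-independent importer carrying a random fraction at the reference and
#'   a logistic setpoint placed so that its flux is negligible (relative
#'   < 1e-9) at the Cu-deficient anchor condition, keeping the pipeline's
#'   all-CUIN1 anchor assumption exactly satisfied.
#'
#' Because the forward and reverse metallation constants then satisfy
#' `k_f = k_r + k_d`, every fixed point of the system has holo/apo odds equal
#' to `odds_ref * (CU/CU_ref)^n` -- an exact effective titration curve with
#' the rate-law exponent as its coefficient -- so the pipeline's curve-based
#' partition of the transcription factors inverts the ground truth exactly.
#' The remaining conditions' steady states are solved by annealing plus Newton
#' polish to residual below 1e-10 uM/min.
#'
#' Draws that violate the qualitative structure of the study (labile pool not
#' strictly increasing with nutrient copper, non-positive states) or that
#' would make the recovery benchmark meaningless (a logistic setpoint outside
#' the window its sensed species actually traverses, so the emitted data
#' would carry no setpoint information) are rejected and redrawn, up to
#' `max_attempts`.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param oth_exponent Cooperativity exponent for OTH metallation. Default 1.
#' @param alpha Growth rate per minute. Default 0.0033.
#' @param template Generating template: a list with `ref_conc` (named
#'   reference concentrations, uM), `copper` (named per-condition COPPER, uM),
#'   `logistic` (named list of `c(sp, ns)` pairs for the four regulated
#'   reactions) and `phi` (fraction of the reference copper influx carried by
#'   the CTR-independent importer). Default [default_truth_template()], the
#'   study-calibrated values.
#' @param jitter_frac Half-width of the log-uniform jitter applied to every
#'   template quantity. Default 0.3 (+/-30%); 0 reproduces the template
#'   exactly.
#' @param max_attempts Rejection-sampling limit. Default 200; the guards
#'   reject a substantial fraction of draws, so the limit is generous.
#' @return An object of class `cu_ground_truth`: list with `network`, `params`
#'   (a `cu_params`), `ref`, `alpha`, `copper` (named per-condition vector),
#'   `states` (per-condition steady-state tibble with `total_cell_cu`),
#'   `fits` (exact effective titration fits for MAC and ACE, uM scale),
#'   `ctr_ratio`, `seed`.
#' @export
generate_ground_truth <- function(seed, oth_exponent = 1, alpha = 0.0033,
                                  template = default_truth_template(),
                                  jitter_frac = 0.3, max_attempts = 200) {
  if (jitter_frac < 0) rlang::abort("jitter_frac must be nonnegative")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  network <- build_canonical_network(oth_exponent = oth_exponent)
  comp <- component_names()
  w <- cu_weight_vector(network)[comp]
  base_ref <- template$ref_conc[comp]
  base_copper <- template$copper
  jitter <- function(x) {
    x * exp(stats::runif(length(x), log(1 - jitter_frac),
                         log(1 + jitter_frac)))
  }

  for (attempt in seq_len(max_attempts)) {
    ref_conc <- jitter(base_ref)
    copper <- sort(jitter(base_copper))
    names(copper) <- names(base_copper)
    cm10 <- copper[["M10"]]
    cu_ref <- ref_conc[["CU"]]
    total_ref <- sum(w * ref_conc)

    # logistic regulation: template setpoints/sensitivities, jittered.
    # Setpoints are drawn relative to the *drawn* reference sensed value, so
    # every draw keeps the switch near the operating window instead of
    # drifting away when the reference itself is jittered the other way.
    lg <- purrr::imap(template$logistic, function(p, rxn) {
      if (rxn == "CUIN2") {
        sp <- cm10 * jitter(p[["sp"]] / base_copper[["M10"]])
      } else {
        sp <- cu_ref * jitter(p[["sp"]] / base_ref[["CU"]])
      }
      cu_logistic(1, sp, jitter(p[["ns"]]),
                  sensor = if (rxn == "CUIN2") "COPPER" else "CU")
    })
    phi <- min(jitter(template$phi), 0.45)
    lf_at <- function(rxn, sen) {
      logistic_factor(lg[[rxn]]$n_sens, lg[[rxn]]$sen_sp, sen)
    }

    # rate constants derived so ref_conc is an exact fixed point
    holo <- c(MAC = "MAC", ACE = "ACE", CUP = "CUP", OTH = "OTH")
    k <- c(stats::setNames(alpha * ref_conc, dilution_name(comp)),
           stats::setNames(100 * alpha * ref_conc[holo],
                           paste0("M", names(holo), "R")))
    k[["MMACF"]] <- 101 * alpha * ref_conc[["MAC"]]
    k[["MACEF"]] <- 101 * alpha * ref_conc[["ACE"]]
    k[["BAMAC"]] <- alpha * (ref_conc[["aMAC"]] + ref_conc[["MAC"]])
    k[["BAACE"]] <- alpha * (ref_conc[["aACE"]] + ref_conc[["ACE"]])
    k[["BAOTH"]] <- alpha * (ref_conc[["aOTH"]] + ref_conc[["OTH"]])
    k[["BCTR"]] <- alpha * ref_conc[["CTR"]]
    for (rxn in c("MCUPF", "MOTHF")) {
      hn <- if (rxn == "MCUPF") "CUP" else "OTH"
      lg[[rxn]]$k_invariant <- 101 * alpha * ref_conc[[hn]] / lf_at(rxn, cu_ref)
    }
    lg[["BACUP"]]$k_invariant <-
      alpha * (ref_conc[["aCUP"]] + ref_conc[["CUP"]]) / lf_at("BACUP", cu_ref)

    # importer split at the reference: CUIN1 + CUIN2 = alpha * total_cu
    km1 <- network$reactions$km[network$reactions$name == "CUIN1"]
    km2 <- network$reactions$km[network$reactions$name == "CUIN2"]
    sat1 <- cm10 / (km1 + cm10)
    sat2 <- cm10 / (km2 + cm10)
    lg[["CUIN2"]]$k_invariant <- phi * alpha * total_ref /
      (lf_at("CUIN2", cm10) * sat2)
    k[["CUIN1"]] <- (1 - phi) * alpha * total_ref / sat1

    params <- structure(list(k = k, logistic = lg), class = "cu_params")
    ref <- cu_reference(ref_conc, alpha = alpha, copper_by_condition = copper)

    # CUIN2 must be negligible at the Cu-deficient anchor
    cuin2_anchor <- lg[["CUIN2"]]$k_invariant *
      lf_at("CUIN2", copper[["MBCS"]]) *
      copper[["MBCS"]] / (km2 + copper[["MBCS"]])
    if (cuin2_anchor / (alpha * total_ref) > 1e-9) next
    # the COPPER-sensed importer must have at least one condition on the
    # flank of its switch, or its setpoint is unidentifiable from the data
    lf2 <- lf_at("CUIN2", copper)
    if (!any(lf2 > 0.05 & lf2 < 0.95)) next

    states <- solve_truth_states(network, params, ref, copper, w)
    if (is.null(states)) next

    cu_by_cond <- stats::setNames(states$CU, states$condition)
    ordered <- cu_by_cond[names(base_copper)]
    if (any(diff(ordered) <= 0)) next
    # identifiability guard: the CU-sensed setpoints must sit strictly
    # inside the achieved labile-pool window, otherwise the emitted data
    # carry no setpoint information and the recovery benchmark is
    # meaningless
    sp_in_window <- all(purrr::map_lgl(c("BACUP", "MCUPF", "MOTHF"),
                                       function(rxn) {
      sp <- lg[[rxn]]$sen_sp
      sp > min(ordered) && sp < max(ordered)
    }))
    if (!sp_in_window) next

    fits <- list(
      MAC = hill_fit(0.62, cu_ref *
                       (ref_conc[["aMAC"]] / ref_conc[["MAC"]])^(1 / 0.62)),
      ACE = hill_fit(0.90, cu_ref *
                       (ref_conc[["aACE"]] / ref_conc[["ACE"]])^(1 / 0.90))
    )
    return(structure(list(
      network = network, params = params, ref = ref, alpha = alpha,
      copper = copper, states = states, fits = fits,
      ctr_ratio = ref_conc[["CTR"]] / ref_conc[["aMAC"]], seed = seed
    ), class = "cu_ground_truth"))
  }
  rlang::abort(paste0("no admissible ground truth found in ", max_attempts,
                      " attempts for seed ", seed))
}

# Per-condition exact steady states of a parameterized system, solved by
# continuation outward from the reference condition. Returns NULL when any
# solve fails to converge to residual < 1e-10 or produces a non-positive state.
solve_truth_states <- function(network, params, ref, copper, w) {
  comp <- component_names()
  labels <- names(copper)
  i_ref <- match("M10", labels)
  states <- matrix(NA_real_, nrow = length(labels), ncol = length(comp),
                   dimnames = list(labels, comp))
  states[i_ref, ] <- ref$concentrations[comp]
  solve_one <- function(lbl, y_start) {
    sys <- cu_system(network, params, ref, copper[[lbl]])
    ss <- steady_state(sys, y_start, t_max = 20000, tol = 1e-11)
    if (ss$residual > 1e-10 || any(ss$state <= 0)) return(NULL)
    ss$state
  }
  y <- states[i_ref, ]
  for (i in seq(i_ref + 1, length(labels))) {
    y <- solve_one(labels[i], y)
    if (is.null(y)) return(NULL)
    states[i, ] <- y
  }
  y <- states[i_ref, ]
  for (i in seq(i_ref - 1, 1)) {
    y <- solve_one(labels[i], y)
    if (is.null(y)) return(NULL)
    states[i, ] <- y
  }
  out <- tibble::as_tibble(states)
  out <- dplyr::bind_cols(tibble::tibble(condition = labels,
                                         copper = unname(copper)), out)
  out$total_cell_cu <- as.numeric(as.matrix(out[comp]) %*% w)
  out
}

#' @export
print.cu_ground_truth <- function(x, ...) {
  cat("<cu_ground_truth> seed ", x$seed, ", ", nrow(x$states),
      " conditions, labile pool ",
      sprintf("%.3g-%.3g uM", min(x$states$CU), max(x$states$CU)), "\n", sep = "")
  invisible(x)
}

#' Emit synthetic titration measurements from a ground truth
#'
#' Converts the ground truth's exact per-condition steady states into the
#' measurement table the estimation pipeline consumes: per-condition group
#' copper for the metallothionein (8 x CUP), other-protein (OTH) and labile
#' (CU) pools, the CUP and OTH fractional occupancies, plus the reference
#' apo-MAC concentration, the CTR/apo-MAC ratio and the Cu-deficient total
#' cellular copper. With `noise_cv > 0` every measured quantity is perturbed
#' by multiplicative lognormal noise (occupancies clamped to (0.01, 0.99)).
#' The transcription-factor titration fits are passed through exactly -- they
#' stand for an independent experiment.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param noise_cv Coefficient of variation of the measurement noise.
#'   Default 0 (noise-free emission).
#' @param seed Seed for the noise draws.
#' @return An object of class `cu_titration`: list with `raw` (input tibble
#'   for [assemble_condition_table()]), `fits`, `amac_m10`, `ctr_ratio`,
#'   `mbcs_total_cu`, `noise_cv`, `seed`.
#' @export
emit_titration <- function(truth, noise_cv = 0, seed = 1) {
  st <- truth$states
  raw <- tibble::tibble(
    condition = st$condition,
    copper = st$copper,
    cu_cup = 8 * st$CUP,
    cu_oth = st$OTH,
    cu_cu = st$CU,
    occ_cup = st$CUP / (st$aCUP + st$CUP),
    occ_oth = st$OTH / (st$aOTH + st$OTH)
  )
  amac_m10 <- st$aMAC[st$condition == "M10"]
  mbcs_total <- st$total_cell_cu[st$condition == "MBCS"]
  ctr_ratio <- truth$ctr_ratio
  if (noise_cv > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noisy <- function(x) x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
    raw$cu_cup <- noisy(raw$cu_cup)
    raw$cu_oth <- noisy(raw$cu_oth)
    raw$cu_cu <- noisy(raw$cu_cu)
    raw$occ_cup <- pmin(pmax(noisy(raw$occ_cup), 0.01), 0.99)
    raw$occ_oth <- pmin(pmax(noisy(raw$occ_oth), 0.01), 0.99)
    amac_m10 <- noisy(amac_m10)
    mbcs_total <- noisy(mbcs_total)
    ctr_ratio <- noisy(ctr_ratio)
  }
  structure(list(raw = raw, fits = truth$fits, amac_m10 = amac_m10,
                 ctr_ratio = ctr_ratio, mbcs_total_cu = mbcs_total,
                 noise_cv = noise_cv, seed = seed),
            class = "cu_titration")
}

#' Run the full estimation pipeline on an emitted titration
#'
#' Chains the condition-estimation, pathway-analysis and rate-calibration
#' stages exactly as they are applied to the study data: assembles the
#' per-condition component table from the measurements (transcription-factor
#' totals from the reference apo-MAC and the Cu-deficient copper anchor),
#' solves the steady-state rates through the basic-pathway basis, computes
#' apparent rate constants, classifies invariance, and consolidates the
#' parameter set.
#'
#' @param emission A [emit_titration()] result (or an equivalent list).
#' @param network A `cu_network`. Default the canonical network.
#' @param alpha Growth rate per minute. Default 0.0033.
#' @return A list with `conditions`, `ref`, `rate_table`, `k_table`,
#'   `classification`, `params`.
#' @export
run_estimation_pipeline <- function(emission,
                                    network = build_canonical_network(),
                                    alpha = 0.0033) {
  cu_m10 <- emission$raw$cu_cu[emission$raw$condition == "M10"]
  mac_total <- emission$amac_m10 / hill_apo_fraction(cu_m10, emission$fits$MAC)
  conditions <- assemble_condition_table(
    emission$raw, fits = emission$fits, mac_total = mac_total,
    ace_total = NULL, ctr_ratio = emission$ctr_ratio,
    mbcs_total_cu = emission$mbcs_total_cu
  )
  ref <- reference_from_conditions(conditions, alpha = alpha)
  rate_table <- steady_state_rate_table(conditions, network, ref)
  k_table <- apparent_rate_constants(rate_table, conditions, network, ref)
  classification <- classify_invariance(k_table)
  params <- consolidate_constants(classification, conditions)
  list(conditions = conditions, ref = ref, rate_table = rate_table,
       k_table = k_table, classification = classification, params = params)
}

#' Parameter-recovery report against a synthetic ground truth
#'
#' Emits measurements at the requested noise level, runs the estimation
#' pipeline, and compares the recovered parameters with the generating ones:
#' whether the trending set (`BACUP`, `MCUPF`, `MOTHF`, `CUIN2`) is recovered
#' exactly, the maximum relative error over the invariant rate constants, and
#' the relative error of each recovered logistic setpoint. One row per noise
#' seed.
#'
#' Noise can render an emitted dataset infeasible for the pipeline (for
#' example, a noisy Cu-deficient total-copper anchor below the copper already
#' accounted for by the other pools, leaving no room for the ACE total). Such
#' seeds are reported as rows of `NA` with the pipeline's error message in
#' the `error` column rather than aborting the whole report.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param noise_cv Measurement noise level. Default 0.
#' @param seeds Noise seeds, one pipeline run each. Default 1.
#' @return A tibble: `seed`, `trending_match`, `max_invariant_rel_err`,
#'   `sp_err_BACUP`, `sp_err_MCUPF`, `sp_err_MOTHF`, `sp_err_CUIN2`,
#'   `error`.
#' @export
parameter_recovery_report <- function(truth, noise_cv = 0, seeds = 1) {
  trending_true <- sort(names(truth$params$logistic))
  na_row <- function(s, msg) {
    sp_na <- stats::setNames(rep(NA_real_, length(trending_true)),
                             paste0("sp_err_", trending_true))
    tibble::tibble(seed = s, trending_match = NA,
                   max_invariant_rel_err = NA_real_, !!!as.list(sp_na),
                   error = msg)
  }
  rows <- purrr::map(seeds, function(s) {
    emission <- emit_titration(truth, noise_cv = noise_cv, seed = s)
    est <- tryCatch(
      run_estimation_pipeline(emission, network = truth$network,
                              alpha = truth$alpha),
      error = function(e) conditionMessage(e)
    )
    if (is.character(est)) return(na_row(s, est))
    trending_hat <- sort(names(est$params$logistic))
    match_ok <- identical(trending_hat, trending_true)
    shared <- intersect(names(est$params$k), names(truth$params$k))
    inv_err <- max(abs(est$params$k[shared] / truth$params$k[shared] - 1))
    sp_err <- purrr::map_dbl(trending_true, function(rxn) {
      hat <- est$params$logistic[[rxn]]
      if (is.null(hat)) return(NA_real_)
      abs(hat$sen_sp / truth$params$logistic[[rxn]]$sen_sp - 1)
    })
    names(sp_err) <- paste0("sp_err_", trending_true)
    tibble::tibble(seed = s, trending_match = match_ok,
                   max_invariant_rel_err = inv_err, !!!as.list(sp_err),
                   error = NA_character_)
  })
  dplyr::bind_rows(rows)
}
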