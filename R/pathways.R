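#' Null-space basis of a stoichiometric matrix
#'
#' Computes a fundamental algebraic null basis G of S from the reduced row
#' echelon form: one column per free (non-pivot) reaction, with unit entry at
#' the free reaction and the negated pivot-row coefficients elsewhere. For the
#' canonical 10 x 25 matrix this yields 15 columns (25 reactions minus row
#' rank 10).
#'
#' @param S Stoichiometric matrix (components x reactions).
#' @param tol Pivot tolerance for the row reduction.
#' @return A matrix G with `ncol(S) - rank(S)` columns spanning null(S), with
#'   reaction row names.
#' @export
null_basis <- function(S, tol = 1e-10) {
  S <- as.matrix(S)
  rr <- rref(S, tol = tol)
  R <- rr$mat
  pivots <- rr$pivots
  free <- setdiff(seq_len(ncol(S)), pivots)
  G <- matrix(0, nrow = ncol(S), ncol = length(free),
              dimnames = list(colnames(S), NULL))
  for (j in seq_along(free)) {
    f <- free[j]
    G[f, j] <- 1
    if (length(pivots)) G[pivots, j] <- -R[seq_along(pivots), f]
  }
  G
}

# Reduced row echelon form with partial pivoting. Returns the reduced matrix
# and the pivot column indices (so rank = length(pivots)).
rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A) * 1.0
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  r <- 1L
  for (cidx in seq_len(n)) {
    if (r > m) break
    p <- which.max(abs(A[r:m, cidx])) + r - 1L
    if (abs(A[p, cidx]) < tol) next
    if (p != r) A[c(p, r), ] <- A[c(r, p), ]
    A[r, ] <- A[r, ] / A[r, cidx]
    others <- setdiff(seq_len(m), r)
    A[others, ] <- A[others, ] - outer(A[others, cidx], A[r, ])
    pivots <- c(pivots, cidx)
    r <- r + 1L
  }
  list(mat = A, pivots = pivots)
}

#' Matrix rank by row reduction
#'
#' @param S A numeric matrix.
#' @param tol Pivot tolerance.
#' @return Integer rank.
#' @export
matrix_rank <- function(S, tol = 1e-10) {
  length(rref(S, tol = tol)$pivots)
}

#' Nonnegative basic-pathway basis
#'
#' Transforms a null basis G into a matrix W of the same dimension whose
#' columns are nonnegative and still span null(S): each column then represents
#' a physically meaningful basic pathway, a steady-state stoichiometric flow
#' through a subset of reactions.
#'
#' The construction is a Gauss-elimination-inspired sweep. Reactions (rows)
#' are processed in turn; in each row, every column with a negative entry is
#' replaced by itself plus a positive multiple of a pivot column that is
#' positive in that row, zeroing the negative entry. Because the update adds a
#' nonnegative multiple of a column that is already nonnegative in all
#' previously processed rows, processed rows stay nonnegative, and because
#' each update is an elementary column operation the columns remain linearly
#' independent. Columns that are entirely nonpositive are negated. If a row
#' has negative entries but no positive pivot the sweep restarts with a
#' different row ordering; if every ordering fails an error is raised (the
#' function never silently returns negative entries).
#'
#' Columns are normalized so their largest entry is 1. Pivot columns are
#' chosen with minimal support to keep pathways small where achievable.
#'
#' @param G Null basis from [null_basis()].
#' @param S Optional stoichiometric matrix used to verify `S %*% W = 0`.
#' @param tol Entries below `-tol` count as negative; the result is clipped of
#'   roundoff in `[-tol, 0]`.
#' @return Matrix W, same dimension as G, all entries >= 0.
#' @export
nonnegative_pathway_basis <- function(G, S = NULL, tol = 1e-9) {
  orders <- list(
    seq_len(nrow(G)),
    rev(seq_len(nrow(G))),
    order(rowSums(G < -tol)),
    order(-rowSums(G < -tol))
  )
  W <- NULL
  for (ord in orders) {
    W <- try(nnb_sweep(G, ord, tol), silent = TRUE)
    if (!inherits(W, "try-error")) break
  }
  if (inherits(W, "try-error")) {
    rlang::abort("no nonnegative basis found: every row ordering left a row without a positive pivot")
  }
  W[W < 0 & W > -tol] <- 0
  if (any(W < 0)) rlang::abort("internal error: negative entries remain in W")
  W <- sweep(W, 2, apply(W, 2, max), "/")
  if (!is.null(S)) {
    resid <- max(abs(S %*% W))
    if (resid > 1e-8) rlang::abort("S %*% W is not zero; basis construction failed")
  }
  colnames(W) <- paste0("BP", seq_len(ncol(W)))
  W
}

nnb_sweep <- function(G, row_order, tol) {
  W <- G
  for (i in row_order) {
    # columns that are nowhere positive can be flipped wholesale
    flip <- which(apply(W, 2, function(col) all(col <= tol)) & W[i, ] < -tol)
    if (length(flip)) W[, flip] <- -W[, flip]
    neg <- which(W[i, ] < -tol)
    if (!length(neg)) next
    pos <- which(W[i, ] > tol)
    if (!length(pos)) stop("stuck row")
    support <- colSums(abs(W[, pos, drop = FALSE]) > tol)
    p <- pos[order(support, -W[i, pos])][1]
    for (cc in neg) {
      lambda <- -W[i, cc] / W[i, p]
      W[, cc] <- W[, cc] + lambda * W[, p]
      W[i, cc] <- 0
    }
  }
  if (any(W < -tol)) stop("negative entries survived the sweep")
  W
}

# The 15 reactions assigned independent steady-state rates: all 10 dilutions,
# the four demetallations, and the second importer.
independent_reactions <- function(network) {
  c(paste0("D", toupper(sub("^a", "A", network$components$name))),
    "MMACR", "MACER", "MCUPR", "MOTHR", "CUIN2")
}

#' Assign the independent steady-state rates for one condition
#'
#' Each dilution rate is the exponential growth rate times the component's
#' steady-state concentration; each demetallation runs `demet_mult` times
#' faster than the dilution of the corresponding holo form (fast, nearly
#' equilibrated metal exchange); and the second importer carries whatever
#' copper influx the CTR-dependent importer does not, `alpha * total_cu -
#' CUIN1`, floored at zero.
#'
#' @param profile One row of [assemble_condition_table()] (a list or one-row
#'   tibble with the ten component concentrations and `total_cell_cu`).
#' @param alpha Growth rate per minute.
#' @param cuin1_rate CUIN1 rate for this condition (uM/min), from
#'   [calibrate_cuin1()].
#' @param demet_mult Demetallation/dilution rate multiplier. Default 100.
#' @return Named numeric vector of the 15 independent rates (uM/min).
#' @export
independent_rate_assignment <- function(profile, alpha, cuin1_rate,
                                        demet_mult = 100) {
  comp <- component_names()
  conc <- unlist(profile[comp])
  dil <- alpha * conc
  names(dil) <- dilution_name(comp)
  demet <- c(
    MMACR = demet_mult * dil[["DMAC"]],
    MACER = demet_mult * dil[["DACE"]],
    MCUPR = demet_mult * dil[["DCUP"]],
    MOTHR = demet_mult * dil[["DOTH"]]
  )
  cuin2 <- alpha * profile$total_cell_cu - cuin1_rate
  if (cuin2 < -1e-8) {
    rlang::warn(sprintf(
      "CUIN1 (%.3g) exceeds total copper influx (%.3g); flooring CUIN2 at 0",
      cuin1_rate, alpha * profile$total_cell_cu))
  }
  c(dil, demet, CUIN2 = max(cuin2, 0))
}

#' Calibrate the CTR-dependent importer from the Cu-deficient anchor
#'
#' Under the Cu-deficient (MBCS) condition all copper influx is assumed to
#' enter through the CTR-dependent importer, at rate `alpha * total_cu`.
#' Inverting the CUIN1 rate law at that condition gives the rate constant;
#' applying the law at every other condition's COPPER and CTR gives the
#' per-condition CUIN1 rates.
#'
#' @param conditions Assembled condition table.
#' @param ref A [cu_reference()] (provides the M10 CTR normalization and
#'   growth rate).
#' @param km1 Michaelis constant of the CTR importer (uM). Default 2.
#' @param anchor_condition Condition carrying the all-CUIN1 assumption.
#' @return A list with `k_cuin1` and a tibble `rates` (condition, cuin1).
#' @export
calibrate_cuin1 <- function(conditions, ref, km1 = 2,
                            anchor_condition = "MBCS") {
  i <- which(conditions$condition == anchor_condition)
  if (length(i) != 1) rlang::abort("anchor condition not found")
  copper0 <- conditions$copper[i]
  if (copper0 <= 0) {
    rlang::abort("anchor COPPER must be positive (set the trace background)")
  }
  ctr_ref <- ref$concentrations[["CTR"]]
  sat0 <- copper0 / (km1 + copper0)
  influx0 <- ref$alpha * conditions$total_cell_cu[i]
  k <- influx0 / (sat0 * conditions$CTR[i] / ctr_ref)
  rates <- tibble::tibble(
    condition = conditions$condition,
    cuin1 = k * conditions$copper / (km1 + conditions$copper) *
      conditions$CTR / ctr_ref
  )
  list(k_cuin1 = k, rates = rates)
}

#' Solve all 25 steady-state rates from the basic-pathway basis
#'
#' With the 15 independent rates assigned, the pathway coefficients are the
#' solution of the independent rows of `W %*% C = R_ind`; the full rate vector
#' is then `W %*% C`. Dependent rates are checked for nonnegativity and the
#' result satisfies `S %*% R = 0` by construction of W.
#'
#' @param W Nonnegative pathway basis from [nonnegative_pathway_basis()] with
#'   reaction row names.
#' @param independents Named vector of the 15 independent rates.
#' @param tol Dependent rates below `-tol` raise an infeasibility error;
#'   roundoff negatives above it are clipped to zero.
#' @return A list with `rates` (named 25-vector, uM/min) and `c_bp` (the 15
#'   pathway coefficients).
#' @export
solve_steady_state_rates <- function(W, independents, tol = 1e-8) {
  ind <- names(independents)
  if (!all(ind %in% rownames(W))) rlang::abort("independent reactions missing from W")
  A <- W[ind, , drop = FALSE]
  if (abs(det(A)) < 1e-300 || matrix_rank(A) < length(ind)) {
    rlang::abort("independent rows of W are singular; cannot solve for pathway coefficients")
  }
  c_bp <- solve(A, independents)
  R <- as.numeric(W %*% c_bp)
  names(R) <- rownames(W)
  if (any(R < -tol)) {
    bad <- names(R)[R < -tol]
    rlang::abort(paste0("infeasible steady state: negative dependent rates for ",
                        paste(bad, collapse = ", ")))
  }
  R[R < 0] <- 0
  list(rates = R, c_bp = c_bp)
}

#' Solve steady-state rates for every condition
#'
#' Runs the full pipeline: CUIN1 calibration at the Cu-deficient anchor,
#' independent-rate assignment, and the basic-pathway solve, per condition.
#'
#' @param conditions Assembled condition table.
#' @param network A `cu_network`.
#' @param ref A [cu_reference()].
#' @param demet_mult Demetallation/dilution multiplier. Default 100.
#' @param km1 Michaelis constant of the CTR importer.
#' @return A tibble in long form: `condition`, `reaction`, `rate` (uM/min),
#'   with the calibrated `k_cuin1` as an attribute.
#' @export
steady_state_rate_table <- function(conditions, network, ref,
                                    demet_mult = 100, km1 = 2) {
  S <- stoichiometric_matrix(network)
  W <- nonnegative_pathway_basis(null_basis(S), S = S)
  cal <- calibrate_cuin1(conditions, ref, km1 = km1)
  out <- purrr::map(seq_len(nrow(conditions)), function(i) {
    profile <- conditions[i, ]
    ind <- independent_rate_assignment(profile, ref$alpha,
                                       cal$rates$cuin1[i], demet_mult)
    sol <- solve_steady_state_rates(W, ind)
    tibble::tibble(condition = profile$condition,
                   reaction = names(sol$rates), rate = sol$rates)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "k_cuin1") <- cal$k_cuin1
  res
}

#' Copper flow-balance report
#'
#' Checks that total copper influx through the two importers balances the
#' copper-weighted dilution outflow, `CUIN1 + CUIN2 = alpha * total_cu`, for a
#' solved rate assignment.
#'
#' @param rates Named 25-vector of steady-state rates.
#' @param network A `cu_network`.
#' @param profile One condition row (needs `total_cell_cu`).
#' @param alpha Growth rate per minute.
#' @param tol Relative residual flagged as a violation.
#' @return A one-row tibble: `influx`, `outflow`, `residual`, `balanced`.
#' @export
verify_flow_balance <- function(rates, network, profile, alpha, tol = 1e-8) {
  influx <- rates[["CUIN1"]] + rates[["CUIN2"]]
  outflow <- alpha * profile$total_cell_cu
  resid <- abs(influx - outflow) / max(outflow, .Machine$double.eps)
  tibble::tibble(influx = influx, outflow = outflow,
                 residual = resid, balanced = resid < tol)
}
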