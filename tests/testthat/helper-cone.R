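# Independent oracle: extreme-ray enumeration of the polyhedral cone
# {v >= 0, S v = 0} by the double description method. Starts from the
# nonnegative orthant (rays = unit vectors) and intersects one equality
# constraint of S at a time; at each step, rays on the hyperplane are kept and
# adjacent (+,-) pairs are combined. Support minimality prunes non-extreme
# combinations (valid for pointed cones, which this is: v >= 0 contains no
# line). Written without reference to the package's basis construction.
enumerate_extreme_rays <- function(S, tol = 1e-9) {
  n <- ncol(S)
  rays <- diag(n)
  for (i in seq_len(nrow(S))) {
    a <- as.numeric(S[i, ])
    val <- as.numeric(a %*% rays)
    zero <- abs(val) <= tol * max(1, max(abs(rays)))
    pos <- which(!zero & val > 0)
    neg <- which(!zero & val < 0)
    keep <- rays[, zero, drop = FALSE]
    combos <- list()
    for (p in pos) {
      for (q in neg) {
        r <- val[p] * rays[, q] - val[q] * rays[, p]
        r[abs(r) < tol * max(abs(r))] <- 0
        combos[[length(combos) + 1]] <- r / max(r)
      }
    }
    if (length(combos)) {
      cand <- do.call(cbind, combos)
      all_rays <- cbind(keep, cand)
    } else {
      all_rays <- keep
    }
    # prune: a ray is extreme iff no other ray's support is a proper subset
    supports <- all_rays > tol
    m <- ncol(all_rays)
    extreme <- rep(TRUE, m)
    for (j in seq_len(m)) {
      if (!extreme[j]) next
      for (l in seq_len(m)) {
        if (l == j) next
        sub_j <- supports[, l] & !supports[, j]
        if (!any(sub_j) && any(supports[, j] & !supports[, l])) {
          extreme[j] <- FALSE
          break
        }
        if (!any(sub_j) && !any(supports[, j] & !supports[, l]) && l < j) {
          extreme[j] <- FALSE  # duplicate support: keep the first
          break
        }
      }
    }
    rays <- all_rays[, extreme, drop = FALSE]
  }
  rays <- sweep(rays, 2, apply(rays, 2, max), "/")
  rownames(rays) <- colnames(S)
  rays
}

# Nonnegative-combination membership: is x in cone(R)? Solved as a
# nonnegative least-squares problem with an independent solver.
in_cone <- function(x, R, tol = 1e-7) {
  fit <- pracma::lsqnonneg(R, as.numeric(x))
  sqrt(sum((R %*% fit$x - x)^2)) <= tol * max(1, sqrt(sum(x^2)))
}

# Column-span membership via least squares.
in_span <- function(x, B, tol = 1e-7) {
  cf <- qr.solve(qr(B), as.numeric(x))
  sqrt(sum((B %*% cf - x)^2)) <= tol * max(1, sqrt(sum(x^2)))
}
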