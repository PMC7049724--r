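# Raw-variance estimation from same-distance neighborhoods.
#
# With few (possibly single) replicates, the per-pair variance of the
# normalized counts cannot be estimated from replicates alone. Instead, for
# each pair (i,j) we treat all *other* valid pairs at the same genomic
# distance as a neighborhood over which the true normalized intensity is
# assumed constant, and compute a neighborhood mean (t_hat) and sample
# variance (w_hat, divisor m*|N| - 1). Subtracting the expected shot-noise
# contribution (z_hat) leaves an unbiased estimate of the raw variance
# v(q); these estimates are pooled across pairs and smoothed by a
# polynomial regression in log-log space.

# Collect, for one condition at one distance, the per-replicate normalized
# values and reciprocal normalization factors of all usable pairs.
# A pair is usable iff its q is defined (testable) in every replicate.
.dist_pairs <- function(qs, d) {
  n <- qs[[1L]]$bins$n_bins
  stopifnot(d >= 0L, d < n)
  i <- seq_len(n - d)
  j <- i + d
  m <- length(qs)
  Q <- vapply(qs, function(x) x$q[cbind(i, j)], numeric(n - d))
  Q <- matrix(Q, nrow = n - d, ncol = m)
  R <- vapply(qs, function(x) {
    1 / (x$beta$values[i] * x$beta$values[j] * x$s$values[d + 1L])
  }, numeric(n - d))
  R <- matrix(R, nrow = n - d, ncol = m)
  usable <- rowSums(is.na(Q) | !is.finite(R)) == 0L
  list(i = i - 1L, j = j - 1L, usable = usable,
       Q = Q[usable, , drop = FALSE], R = R[usable, , drop = FALSE], m = m)
}

#' Neighborhood mean and variance of normalized counts at one distance
#'
#' For every usable pair (i,j) at genomic distance `d` (both bins valid and
#' the size factor positive in every replicate of the condition), computes
#' the mean `t_hat` and sample variance `w_hat` of the normalized counts of
#' all *other* usable pairs at the same distance, across the condition's
#' replicates. The sample variance uses divisor `m * |N(i,j)| - 1`. Pairs
#' absent from a replicate's sparsity pattern contribute `q = 0`.
#'
#' @param qs List of per-replicate [normalize_matrix()] results for one
#'   condition.
#' @param d Genomic distance in bins (>= 1 for off-diagonal pairs).
#' @return A `data.table` with one row per pair at distance `d`: `i`, `j`
#'   (0-based), `t_hat`, `w_hat`, `n_nbr` (neighborhood size `|N(i,j)|`),
#'   and `usable`. `t_hat`/`w_hat` are `NA` for unusable pairs or when
#'   `m * |N| < 2`.
#' @export
neighborhood_moments <- function(qs, d) {
  dp <- .dist_pairs(qs, d)
  P <- nrow(dp$Q)
  m <- dp$m
  out <- data.table::data.table(i = dp$i, j = dp$j,
                                t_hat = NA_real_, w_hat = NA_real_,
                                n_nbr = ifelse(dp$usable, P - 1L, NA_integer_),
                                usable = dp$usable)
  M <- m * (P - 1L)
  if (P >= 2L && M >= 2L) {
    S1 <- sum(dp$Q)
    S2 <- sum(dp$Q^2)
    c1 <- rowSums(dp$Q)
    c2 <- rowSums(dp$Q^2)
    t_hat <- (S1 - c1) / M
    w_hat <- pmax((S2 - c2 - M * t_hat^2) / (M - 1), 0)
    out$t_hat[out$usable] <- t_hat
    out$w_hat[out$usable] <- w_hat
  }
  out
}

#' Shot-noise term of the neighborhood variance
#'
#' The expected Poisson (shot-noise) contribution to the neighborhood
#' sample variance of pair (i,j):
#' `z = q_avg[i,j] / (m |N|) * sum_k sum_{(u,v) in N} 1/(beta_u beta_v s_d)`.
#' Subtracting it from `w_hat` gives an unbiased estimate of the raw
#' variance function at `q[i,j]`.
#'
#' @param q_avg The condition-averaged `normalized_matrix` (from
#'   [average_normalized()]).
#' @param qs The per-replicate `normalized_matrix` list of the same
#'   condition (carrying each replicate's biases and size factors).
#' @param d Genomic distance in bins.
#' @return A `data.table` with `i`, `j` (0-based), `z_hat` and `usable`.
#' @export
shot_noise_term <- function(q_avg, qs, d) {
  dp <- .dist_pairs(qs, d)
  P <- nrow(dp$Q)
  m <- dp$m
  out <- data.table::data.table(i = dp$i, j = dp$j, z_hat = NA_real_,
                                usable = dp$usable)
  if (P >= 2L) {
    M <- m * (P - 1L)
    R1 <- sum(dp$R)
    r_own <- rowSums(dp$R)
    qa <- q_avg$q[cbind(dp$i[dp$usable] + 1L, dp$j[dp$usable] + 1L)]
    out$z_hat[out$usable] <- qa * (R1 - r_own) / M
  }
  out
}

#' Assemble raw-variance regression points for one condition
#'
#' Runs [neighborhood_moments()] and [shot_noise_term()] over a range of
#' distances and collects, per usable pair, the condition-averaged
#' normalized count and the raw-variance estimate `w_hat - z_hat`.
#'
#' @param qs Per-replicate `normalized_matrix` list for one condition.
#' @param q_avg The condition average from [average_normalized()].
#' @param distances Integer vector of distances to include (default: all
#'   off-diagonal distances).
#' @return A `data.table` with `i`, `j`, `distance`, `q`, `w_hat`, `z_hat`,
#'   `wz` (= `w_hat - z_hat`).
#' @export
variance_points <- function(qs, q_avg,
                            distances = seq_len(qs[[1L]]$bins$n_bins - 1L)) {
  res <- lapply(distances, function(d) {
    nm <- neighborhood_moments(qs, d)
    zt <- shot_noise_term(q_avg, qs, d)
    keep <- nm$usable & !is.na(nm$w_hat) & !is.na(zt$z_hat)
    if (!any(keep)) return(NULL)
    data.table::data.table(
      i = nm$i[keep], j = nm$j[keep], distance = d,
      q = q_avg$q[cbind(nm$i[keep] + 1L, nm$j[keep] + 1L)],
      w_hat = nm$w_hat[keep], z_hat = zt$z_hat[keep],
      wz = nm$w_hat[keep] - zt$z_hat[keep])
  })
  data.table::rbindlist(res)
}

#' Fit a smooth raw variance function
#'
#' Least-squares polynomial regression of `log(w - z)` on `log(q)` over
#' pairs with `q > 0` and `w - z > 0` (nonpositive raw-variance estimates
#' are rare and filtered out). The fitted function evaluates
#' `exp(poly(log q))`, with the argument clamped to the observed fit domain
#' so the polynomial is never extrapolated.
#'
#' @param q Normalized counts (predictor).
#' @param wz Raw-variance estimates `w_hat - z_hat` (response).
#' @param degree Polynomial degree (default 2). Reduced automatically if
#'   the surviving predictors have too few distinct values.
#' @param condition Optional label ("A"/"B") stored on the result.
#' @return An object of class `variance_function`: `coefficients` (of the
#'   polynomial in `log(q)`, ascending powers), `fit_domain` (range of
#'   `log(q)` used), `degree`, `n_points`, `condition`.
#' @export
fit_variance_function <- function(q, wz, degree = 2L, condition = NA_character_) {
  stopifnot(length(q) == length(wz), degree >= 0L)
  keep <- is.finite(q) & is.finite(wz) & q > 0 & wz > 0
  q <- q[keep]; wz <- wz[keep]
  if (length(q) < degree + 2L)
    stop("too few positive raw-variance points (", length(q),
         ") to fit degree ", degree,
         "; lower the degree or pool more distances")
  x <- log(q)
  deg <- min(degree, length(unique(x)) - 1L)
  if (deg >= 1L) {
    fit <- stats::lm(log(wz) ~ stats::poly(x, deg, raw = TRUE))
    coefs <- unname(stats::coef(fit))
  } else {
    coefs <- mean(log(wz))
  }
  structure(list(coefficients = coefs, fit_domain = range(x),
                 degree = deg, n_points = length(q), condition = condition),
            class = "variance_function")
}

#' Evaluate a fitted raw variance function
#'
#' Returns `v(q) >= 0`; by convention `v(0) = 0` (no raw variance at zero
#' expectation). Arguments outside the fit domain take the boundary value.
#'
#' @param vf A [fit_variance_function()] result.
#' @param q Nonnegative normalized counts (vectorized).
#' @return Nonnegative raw variances, same length as `q`.
#' @export
evaluate_variance <- function(vf, q) {
  stopifnot(inherits(vf, "variance_function"))
  out <- numeric(length(q))
  pos <- is.finite(q) & q > 0
  if (any(pos)) {
    x <- pmin(pmax(log(q[pos]), vf$fit_domain[1L]), vf$fit_domain[2L])
    lp <- outer(x, seq_along(vf$coefficients) - 1L, `^`) %*% vf$coefficients
    out[pos] <- exp(drop(lp))
  }
  out[!is.finite(q)] <- NA_real_
  out
}

#' @export
print.variance_function <- function(x, ...) {
  cat(sprintf(
    "<variance_function%s> degree %d on log(q) in [%.3g, %.3g], %d points\n",
    if (is.na(x$condition)) "" else paste0(" ", x$condition),
    x$degree, exp(x$fit_domain[1L]), exp(x$fit_domain[2L]), x$n_points))
  invisible(x)
}

#' A constant (often zero) raw variance function
#'
#' Convenience constructor, mainly for the pure shot-noise (Poisson) limit
#' `v = 0` in tests and simulations.
#'
#' @param value Constant raw variance (>= 0).
#' @return A `variance_function` evaluating to `value` for all `q > 0`.
#' @export
constant_variance <- function(value = 0) {
  stopifnot(value >= 0)
  structure(list(coefficients = if (value > 0) log(value) else -Inf,
                 fit_domain = c(-Inf, Inf), degree = 0L, n_points = 0L,
                 condition = NA_character_),
            class = "variance_function")
}
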