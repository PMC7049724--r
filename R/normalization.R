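#' Estimate locus-specific biases by iterative correction (ICE)
#'
#' Iterative proportional fitting of a multiplicative per-bin bias vector
#' beta so that the bias-corrected matrix `C[i,j] / (beta_i * beta_j)` has
#' (approximately) equal row sums over valid bins. Bins with the lowest
#' marginal counts (a configurable fraction, plus all zero-marginal bins)
#' are filtered out before balancing and flagged invalid. The returned
#' biases are rescaled to unit geometric mean over valid bins, so all depth
#' and scale information is carried by the size factors downstream.
#'
#' @param cm A [contact_matrix()].
#' @param max_iter Maximum number of balancing iterations.
#' @param tol Convergence tolerance on the maximum relative row-sum
#'   deviation.
#' @param low_count_fraction Fraction of bins (lowest nonzero marginals) to
#'   filter before balancing, in addition to zero-marginal bins.
#' @return An object of class `bias_vector`: list with `values` (numeric,
#'   `NA` on invalid bins, positive elsewhere) and `valid` (logical mask).
#' @export
estimate_ice_biases <- function(cm, max_iter = 300L, tol = 1e-5,
                                low_count_fraction = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$bins$n_bins
  C <- as_dense(cm)
  marg <- rowSums(C)
  valid <- marg > 0
  if (low_count_fraction > 0 && any(valid)) {
    thr <- stats::quantile(marg[valid], low_count_fraction, names = FALSE)
    drop <- valid & marg <= thr
    # never filter everything: keep bins strictly above the cut when the
    # quantile coincides with the maximum (e.g. constant marginals)
    if (!all(drop[valid])) valid <- valid & !drop
  }
  if (!any(valid)) stop("matrix too sparse to balance: all bins filtered")
  W <- C[valid, valid, drop = FALSE]
  b <- rep(1, sum(valid))
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    s <- s / mean(s)
    if (max(abs(s - 1)) < tol) break
    s[s == 0] <- 1
    W <- W / outer(s, s)
    b <- b * s
  }
  values <- rep(NA_real_, n)
  values[valid] <- b / exp(mean(log(b)))
  structure(list(values = values, valid = valid), class = "bias_vector")
}

#' A bias vector with an explicit validity mask
#'
#' @param values Positive bias per bin; `NA` allowed on invalid bins.
#' @param valid Logical mask of valid bins (defaults to `!is.na(values)`).
#' @return A `bias_vector`.
#' @export
bias_vector <- function(values, valid = !is.na(values)) {
  stopifnot(length(values) == length(valid))
  if (any(valid & (is.na(values) | values <= 0)))
    stop("bias values must be positive on valid bins")
  values[!valid] <- NA_real_
  structure(list(values = as.numeric(values), valid = valid),
            class = "bias_vector")
}

#' Estimate distance-specific size factors
#'
#' For each genomic distance d (in bins), the size factor is the median of
#' the bias-corrected counts `C[i,j] / (beta_i * beta_j)` over *all* pairs
#' at that distance whose two bins are valid, counting pairs with no stored
#' entry as zeros. This enforces that the median normalized count at each
#' distance is the same (one) across experiments. Distances with no valid
#' pair have `support_count = 0` and are unusable downstream.
#'
#' @param cm A [contact_matrix()].
#' @param beta A [bias_vector()] estimated on the same matrix.
#' @return An object of class `size_factors`: list with `values` (numeric,
#'   indexed by distance `0..n_bins-1`, `NA` where unsupported) and
#'   `support_count` (integer, valid pairs per distance).
#' @export
estimate_size_factors <- function(cm, beta) {
  stopifnot(inherits(cm, "contact_matrix"), inherits(beta, "bias_vector"))
  n <- cm$bins$n_bins
  stopifnot(length(beta$values) == n)
  C <- as_dense(cm)
  s <- rep(NA_real_, n)
  support <- integer(n)
  b <- beta$values
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    keep <- beta$valid[i] & beta$valid[j]
    support[d + 1L] <- sum(keep)
    if (support[d + 1L] > 0L) {
      vals <- C[cbind(i[keep], j[keep])] / (b[i[keep]] * b[j[keep]])
      s[d + 1L] <- stats::median(vals)
    }
  }
  structure(list(values = s, support_count = support),
            class = "size_factors")
}

#' Normalize a contact matrix by biases and size factors
#'
#' Computes the normalized counts
#' `q[i,j] = C[i,j] / (beta_i * beta_j * s_{|i-j|})` wherever the
#' denominator is positive. Pairs involving an invalid bin, or at a
#' distance whose size factor is zero or unsupported, are untestable and
#' stored as `NA`; pairs with no stored count have `q = 0`.
#'
#' @param cm A [contact_matrix()].
#' @param beta A [bias_vector()] for the same matrix.
#' @param s A [size_factors()] object from the same matrix/bias pair.
#' @return An object of class `normalized_matrix`: list with `bins`, dense
#'   symmetric matrix `q` (`NA` = untestable), `valid` bin mask, and the
#'   `beta` and `s` used (kept for downstream shot-noise terms).
#' @export
normalize_matrix <- function(cm, beta, s) {
  stopifnot(inherits(cm, "contact_matrix"), inherits(beta, "bias_vector"),
            inherits(s, "size_factors"))
  n <- cm$bins$n_bins
  C <- as_dense(cm)
  b <- beta$values
  bb <- outer(b, b)
  d_idx <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
  sd_mat <- matrix(s$values[d_idx], n, n)
  denom <- bb * sd_mat
  q <- C / denom
  q[!is.finite(q)] <- NA_real_
  q[is.na(denom) | (!is.na(denom) & denom == 0)] <- NA_real_
  structure(list(bins = cm$bins, q = q, valid = beta$valid,
                 beta = beta, s = s),
            class = "normalized_matrix")
}

new_normalized <- function(template, q) {
  structure(list(bins = template$bins, q = q, valid = template$valid,
                 beta = template$beta, s = template$s),
            class = "normalized_matrix")
}

#' Average normalized matrices over replicates
#'
#' Entrywise mean of per-replicate normalized matrices (the per-condition
#' estimate of the shared contact intensity). A pair untestable in any
#' replicate is untestable in the average; a bin invalid in any replicate
#' is invalid in the average.
#'
#' @param qs List of [normalize_matrix()] results sharing the same bins.
#' @return A `normalized_matrix` (its `beta`/`s` fields refer to the first
#'   replicate and are not meaningful for the average).
#' @export
average_normalized <- function(qs) {
  stopifnot(length(qs) >= 1L)
  b0 <- qs[[1L]]$bins
  for (x in qs) {
    stopifnot(inherits(x, "normalized_matrix"))
    if (!same_bins(x$bins, b0)) stop("mismatched bins across replicates")
  }
  qsum <- Reduce(`+`, lapply(qs, function(x) x$q))
  out <- new_normalized(qs[[1L]], qsum / length(qs))
  out$valid <- Reduce(`&`, lapply(qs, function(x) x$valid))
  out
}

#' Pooled normalized matrix over all replicates
#'
#' As [average_normalized()] but over every replicate regardless of
#' condition: the shared normalized count under the null hypothesis.
#'
#' @param qs List of per-replicate `normalized_matrix` objects (all m).
#' @return A `normalized_matrix`.
#' @export
pooled_normalized <- function(qs) average_normalized(qs)

#' Log fold change between two normalized matrices
#'
#' `log2((qA + pseudocount) / (qB + pseudocount))`, a diagnostic view of
#' the normalized data (never used in testing).
#'
#' @param qA,qB `normalized_matrix` objects on the same bins.
#' @param pseudocount Nonnegative stabilizer added to both sides.
#' @return A dense matrix of log2 fold changes (`NA` where either side is
#'   untestable).
#' @export
log_fold_change_matrix <- function(qA, qB, pseudocount = 1) {
  stopifnot(inherits(qA, "normalized_matrix"),
            inherits(qB, "normalized_matrix"),
            same_bins(qA$bins, qB$bins), pseudocount >= 0)
  log2((qA$q + pseudocount) / (qB$q + pseudocount))
}
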