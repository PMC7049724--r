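# Negative-binomial conditional exact test on pooled condition counts.
#
# The pooled count of condition A is approximated by a negative binomial
# matched to the sum of the per-replicate NB means and variances; the
# p-value conditions on the total count C = C^A + C^B and sums, over all
# splits a + b = C, the probabilities of splits no more likely than the
# observed one (ties included).

# relative tie tolerance on the probability scale, the convention used by
# stats::binom.test: outcomes with p(x,y) <= p(a,b) * (1 + 1e-7) count
.TIE_REL_TOL <- 1e-7

#' Moment-matched NB parameterization
#'
#' Maps a (mean, variance) pair to the negative binomial parameterization
#' used by the exact test. When the variance does not exceed the mean
#' (within a relative tolerance) the Poisson limit is returned as a
#' distinct branch so the log-pmf stays numerically stable; a zero mean is
#' a point mass at zero.
#'
#' @param mean Nonnegative mean.
#' @param variance Variance; must be `>= mean` up to a relative tolerance.
#' @param eps Relative tolerance for the Poisson / over-dispersed decision.
#' @return A list with `family` ("pointmass", "poisson" or "nbinom"),
#'   `mu`, and for the NB branch `size` (`mu^2 / (variance - mu)`).
#' @export
nb_parameters <- function(mean, variance, eps = 1e-8) {
  stopifnot(length(mean) == 1L, length(variance) == 1L, mean >= 0)
  if (mean == 0)
    return(list(family = "pointmass", mu = 0))
  if (variance < mean * (1 - 1e-6))
    stop(sprintf("variance (%g) below mean (%g): model violation",
                 variance, mean))
  if (variance <= mean * (1 + eps))
    return(list(family = "poisson", mu = mean))
  list(family = "nbinom", mu = mean, size = mean^2 / (variance - mean))
}

#' Log-pmf of a moment-matched NB / Poisson / point-mass distribution
#'
#' @param x Nonnegative integer quantiles (vectorized).
#' @param par A [nb_parameters()] result.
#' @return Log-probabilities.
#' @export
nb_log_pmf <- function(x, par) {
  switch(par$family,
    pointmass = ifelse(x == 0, 0, -Inf),
    poisson = stats::dpois(x, par$mu, log = TRUE),
    nbinom = stats::dnbinom(x, size = par$size, mu = par$mu, log = TRUE),
    stop("unknown family ", par$family))
}

# sorted summation makes the result invariant to the enumeration order,
# so exchanging the condition labels gives bit-identical p-values
logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(sort(x) - m)))
}

#' Null moments of the pooled condition counts for one pair
#'
#' Under the null hypothesis of a shared normalized count `q0`, the pooled
#' count of condition A has mean
#' `mu_A = sum_k beta_i^k beta_j^k s_d^k q0` over the condition's
#' replicates, and variance
#' `mu_A + sum_k (beta_i^k beta_j^k s_d^k)^2 v_A(q0)`, where `v_A` is the
#' condition's raw variance function evaluated at the pooled `q0`.
#'
#' @param factors Numeric vector of per-replicate normalization factors
#'   `beta_i^k * beta_j^k * s_d^k` for the condition's replicates.
#' @param q0 Pooled normalized count of the pair (across all replicates of
#'   both conditions).
#' @param vf The condition's [fit_variance_function()] result.
#' @return List with `mu` and `sigma2`; both 0 when `q0 = 0`.
#' @export
null_moments <- function(factors, q0, vf) {
  stopifnot(all(is.finite(factors)), is.finite(q0), q0 >= 0)
  v <- evaluate_variance(vf, q0)
  mu <- sum(factors) * q0
  list(mu = mu, sigma2 = mu + sum(factors^2) * v)
}

#' Conditional exact p-value for a differential contact
#'
#' Conditions on the total count `C = a + b` and enumerates all splits
#' `x + y = C`: `p = sum_{p(x,y) <= p(a,b)} p(x,y) / sum p(x,y)`, where
#' `p(x,y)` is the product of the two moment-matched NB pmfs. Ties with the
#' observed outcome are included, so `p > 0` always. Computation is in log
#' space with stable log-sum-exp. When both null means are zero but
#' `C > 0` (an undefined configuration) the p-value is 1.
#'
#' @param a,b Observed pooled counts (nonnegative integers).
#' @param momA,momB [null_moments()] of conditions A and B.
#' @return A p-value in (0, 1].
#' @export
conditional_pvalue <- function(a, b, momA, momB) {
  stopifnot(a >= 0, b >= 0, a == round(a), b == round(b))
  C <- a + b
  if (C == 0) return(1)
  parA <- nb_parameters(momA$mu, momA$sigma2)
  parB <- nb_parameters(momB$mu, momB$sigma2)
  x <- 0:C
  lp <- nb_log_pmf(x, parA) + nb_log_pmf(C - x, parB)
  if (all(lp == -Inf)) return(1)  # both null means zero, C > 0
  lp_obs <- lp[a + 1L]
  num <- logsumexp(lp[lp <= lp_obs + log1p(.TIE_REL_TOL)])
  den <- logsumexp(lp)
  min(exp(num - den), 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment over the tested pairs only (untestable pairs are
#' excluded from the number of tests).
#'
#' @param pvalues Numeric p-values in `[0, 1]`; `NA`s pass through.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}
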