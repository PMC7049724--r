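# normalized_matrix with prescribed dense q (beta/s unit), for direct
# neighborhood checks
nm_from_q <- function(q, beta = NULL, s = NULL) {
  n <- nrow(q)
  b <- if (is.null(beta)) unit_bias(n) else beta
  sf <- if (is.null(s)) const_sf(n) else s
  structure(list(bins = bins_n(n), q = q, valid = b$valid, beta = b, s = sf),
            class = "normalized_matrix")
}

test_that("neighborhood moments: constant distance band has zero variance", {
  n <- 6
  q <- matrix(0, n, n)
  for (i in 1:(n - 2)) q[i, i + 2] <- 3  # all q at d = 2 equal 3
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  nm <- neighborhood_moments(list(nm_from_q(q)), 2L)
  expect_equal(nm$t_hat, rep(3, 4))
  expect_equal(nm$w_hat, rep(0, 4))
  expect_equal(nm$n_nbr, rep(3L, 4))
})

test_that("neighborhood moments match the printed leave-one-out example", {
  # single replicate, three pairs at d with q = {1, 2, 3}; for the pair
  # with value 1: N = {2, 3}, t = 2.5, w = ((2-2.5)^2+(3-2.5)^2)/1 = 0.5
  n <- 4
  q <- matrix(0, n, n)
  q[1, 2] <- 1; q[2, 3] <- 2; q[3, 4] <- 3
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  nm <- neighborhood_moments(list(nm_from_q(q)), 1L)
  expect_equal(nm$t_hat[1], 2.5)
  expect_equal(nm$w_hat[1], 0.5)
  expect_equal(nm$t_hat[2], 2)     # N = {1, 3}
  expect_equal(nm$w_hat[2], 2)
  expect_equal(nm$n_nbr, rep(2L, 3))
})

test_that("neighborhood moments agree with brute force up to 8x8", {
  for (seed in 1:4) {
    n <- sample(4:8, 1)
    set.seed(seed)
    m <- 2L  # two replicates
    qs <- lapply(1:m, function(k) {
      q <- matrix(rpois(n * n, 4) / 2, n, n)
      q[lower.tri(q)] <- t(q)[lower.tri(q)]
      nm_from_q(q)
    })
    for (d in 1:(n - 1)) {
      nm <- neighborhood_moments(qs, d)
      if (n - d < 2) {
        expect_true(all(is.na(nm$t_hat)))
        next
      }
      for (r in seq_len(nrow(nm))) {
        bf <- brute_force_neighborhood(lapply(qs, `[[`, "q"),
                                       nm$i[r] + 1, nm$j[r] + 1)
        expect_equal(nm$t_hat[r], bf$t, info = sprintf("seed %d d %d", seed, d))
        expect_equal(nm$w_hat[r], bf$w, tolerance = 1e-12)
        expect_equal(nm$n_nbr[r], bf$n_nbr)
      }
    }
  }
})

test_that("two identical replicates rescale the variance by the pooled divisor", {
  n <- 5
  set.seed(2)
  q <- matrix(rpois(n * n, 6), n, n)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  one <- neighborhood_moments(list(nm_from_q(q)), 1L)
  two <- neighborhood_moments(list(nm_from_q(q), nm_from_q(q)), 1L)
  # same mean; sum of squared deviations doubles, divisor 2|N|-1 vs |N|-1
  P <- n - 1
  expect_equal(two$t_hat, one$t_hat)
  expect_equal(two$w_hat, one$w_hat * 2 * (P - 2) / (2 * (P - 1) - 1))
})

test_that("shot-noise term reduces to q/s under unit biases", {
  n <- 6
  q <- matrix(1.5, n, n); diag(q) <- 0
  s <- const_sf(n, 4)
  nm <- nm_from_q(q, s = s)
  zt <- shot_noise_term(nm, list(nm), 2L)
  expect_equal(zt$z_hat, rep(1.5 / 4, 4))
  # q = 0 at the focal pair -> z = 0
  q2 <- q; q2[1, 3] <- 0; q2[3, 1] <- 0
  nm2 <- nm_from_q(q2, s = s)
  zt2 <- shot_noise_term(nm2, list(nm2), 2L)
  expect_equal(zt2$z_hat[1], 0)
})

test_that("shot-noise term matches the summation oracle with heterogeneous biases", {
  n <- 6
  set.seed(8)
  b <- bias_vector(exp(rnorm(n, 0, 0.3)))
  sv <- const_sf(n, 2); sv$values <- runif(n, 1, 4)
  q <- matrix(runif(n * n, 0, 3), n, n)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  nm <- nm_from_q(q, beta = b, s = sv)
  for (d in 1:3) {
    zt <- shot_noise_term(nm, list(nm), d)
    us <- seq_len(n - d)
    for (r in seq_along(us)) {
      nbr <- us[us != us[r]]
      terms <- 1 / (b$values[nbr] * b$values[nbr + d] * sv$values[d + 1])
      z_oracle <- q[us[r], us[r] + d] * sum(terms) / (1 * length(nbr))
      expect_equal(zt$z_hat[r], z_oracle, info = sprintf("d %d r %d", d, r))
    }
  }
})

test_that("variance fit recovers a noiseless quadratic exactly", {
  alpha <- 0.05
  q <- exp(seq(log(0.2), log(50), length.out = 40))
  vf <- fit_variance_function(q, alpha * q^2, degree = 2)
  expect_equal(evaluate_variance(vf, q), alpha * q^2, tolerance = 1e-6)
  # negative raw-variance points are filtered, not fitted
  q2 <- c(q, 1, 2, 3)
  wz2 <- c(alpha * q^2, -1, -0.5, 0)
  vf2 <- fit_variance_function(q2, wz2, degree = 2)
  expect_equal(vf2$coefficients, vf$coefficients)
  expect_equal(vf2$n_points, vf$n_points)
})

test_that("constant points give a constant function; degenerate degree drops", {
  vf <- fit_variance_function(rep(2, 10), rep(0.7, 10), degree = 2)
  expect_equal(evaluate_variance(vf, c(0.5, 2, 9)), rep(0.7, 3))
  expect_error(fit_variance_function(c(1, 2), c(0.1, 0.2), degree = 2),
               "too few")
})

test_that("variance evaluation is nonnegative, zero at zero, clamped", {
  q <- exp(seq(0, 3, length.out = 20))
  vf <- fit_variance_function(q, 0.1 * q^2, degree = 2)
  expect_equal(evaluate_variance(vf, 0), 0)
  expect_true(all(evaluate_variance(vf, seq(0, 100, by = 5)) >= 0))
  # above the fit domain: boundary value, no extrapolation blow-up
  expect_equal(evaluate_variance(vf, 1e6),
               evaluate_variance(vf, max(q)))
  expect_equal(evaluate_variance(vf, 1e-9),
               evaluate_variance(vf, min(q)))
  expect_equal(evaluate_variance(constant_variance(0), c(0, 1, 10)),
               rep(0, 3))
})

test_that("raw-variance estimates center at zero for Poisson data", {
  # pure shot noise: v = 0, so the per-distance median of w - z is ~ 0
  cm <- simulate_matrix(80, decay_curve(300), seed = 31)
  beta <- bias_vector(rep(1, 80))
  s <- estimate_size_factors(cm, beta)
  q <- normalize_matrix(cm, beta, s)
  vp <- variance_points(list(q), average_normalized(list(q)))
  med <- vp[, list(med = median(wz)), by = "distance"]
  # per-distance medians straddle zero and are small relative to shot noise
  expect_lt(abs(median(med$med)), 0.02)
  expect_gt(mean(med$med <= 0), 0.3)
  expect_gt(mean(med$med >= 0), 0.3)
})

test_that("mean of w - z recovers a known raw variance on model data", {
  # NB counts with variance mu + 0.05 mu^2 at two distances; with s_d = mu_d
  # and beta = 1, q = 1 and v(1) = 0.05
  n <- 400
  set.seed(77)
  q <- matrix(NA_real_, n, n)
  mu_d <- c(800, 200)
  sfv <- rep(NA_real_, n); sfv[2:3] <- mu_d
  for (d in 1:2) {
    i <- seq_len(n - d)
    counts <- rnbinom(length(i), size = 1 / 0.05, mu = mu_d[d])
    q[cbind(i, i + d)] <- counts / mu_d[d]
    q[cbind(i + d, i)] <- q[cbind(i, i + d)]
  }
  nm <- nm_from_q(q, s = structure(list(values = sfv,
                                        support_count = rep(1L, n)),
                                   class = "size_factors"))
  vp <- variance_points(list(nm), average_normalized(list(nm)),
                        distances = 1:2)
  expect_equal(mean(vp$wz), 0.05, tolerance = 0.25)
})
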