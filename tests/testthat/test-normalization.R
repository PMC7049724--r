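test_that("ICE returns unit biases on a constant matrix", {
  n <- 6
  m <- matrix(5, n, n)
  cm <- cm_from_dense(m)
  beta <- estimate_ice_biases(cm, low_count_fraction = 0)
  expect_true(all(beta$valid))
  expect_equal(beta$values, rep(1, n), tolerance = 1e-6)
})

test_that("ICE recovers a planted row bias and equalizes row sums", {
  n <- 6
  planted <- c(1, 2, 1, 1, 1, 1)  # bin 2 twice as visible: its row is
  m <- 10 * outer(planted, planted) # scaled x2, its diagonal x4
  cm <- cm_from_dense(m)
  beta <- estimate_ice_biases(cm, tol = 1e-10, max_iter = 2000,
                              low_count_fraction = 0)
  b <- beta$values
  # bias enters twice per entry: scaling a row by 4 doubles its bias
  expect_equal(unname(b[2] / b[1]), 2, tolerance = 1e-4)
  corrected <- as_dense(cm) / outer(b, b)
  rs <- rowSums(corrected)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-4)
  # unit geometric mean
  expect_equal(exp(mean(log(b))), 1, tolerance = 1e-12)
})

test_that("ICE masks empty bins and rejects an all-empty matrix", {
  n <- 5
  m <- matrix(7, n, n)
  m[3, ] <- 0; m[, 3] <- 0
  beta <- estimate_ice_biases(cm_from_dense(m), low_count_fraction = 0)
  expect_false(beta$valid[3])
  expect_true(is.na(beta$values[3]))
  expect_error(estimate_ice_biases(contact_matrix(bins_n(4))),
               "too sparse")
})

test_that("ICE on an already-balanced matrix is a fixpoint", {
  n <- 10
  set.seed(42)
  # balanced by construction: constant off-diagonal rows
  m <- matrix(3, n, n)
  beta <- estimate_ice_biases(cm_from_dense(m), low_count_fraction = 0)
  expect_equal(beta$values, rep(1, n), tolerance = 1e-5)
})

test_that("size factors are per-distance medians over all valid pairs", {
  n <- 6
  m <- matrix(0, n, n)
  for (i in seq_len(n - 3)) m[i, i + 3] <- 7  # every pair at d = 3 is 7
  cm <- cm_from_dense(m)
  s <- estimate_size_factors(cm, unit_bias(n))
  expect_equal(s$values[4], 7)
  expect_equal(s$support_count[4], 3L)

  # zeros included in the median: counts {0, 0, 10, 0} at d = 2
  m2 <- matrix(0, n, n)
  m2[1, 3] <- 10
  s2 <- estimate_size_factors(cm_from_dense(m2), unit_bias(n))
  expect_equal(s2$values[3], 0)
})

test_that("size factors match an explicit enumeration oracle", {
  n <- 5
  set.seed(11)
  m <- matrix(rpois(n * n, 20), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  b <- c(1, 2, 1, 0.5, 1.5)
  cm <- cm_from_dense(m)
  mm <- as_dense(cm)
  s <- estimate_size_factors(cm, bias_vector(b))
  for (d in 0:(n - 1)) {
    ratios <- sapply(seq_len(n - d), function(i)
      mm[i, i + d] / (b[i] * b[i + d]))
    expect_equal(s$values[d + 1], median(ratios), info = paste("d =", d))
  }
})

test_that("normalization divides by biases and size factors elementwise", {
  n <- 5
  m <- matrix(0, n, n); m[1, 3] <- 10; m[3, 1] <- 10
  cm <- cm_from_dense(m)
  s <- const_sf(n, 5)
  q <- normalize_matrix(cm, unit_bias(n), s)
  expect_equal(q$q[1, 3], 2)
  expect_equal(q$q[2, 2], 0)  # absent entry normalizes to 0

  # zero size factor at a distance -> untestable (NA), not a value
  s0 <- const_sf(n, 5); s0$values[3] <- 0
  q0 <- normalize_matrix(cm, unit_bias(n), s0)
  expect_true(is.na(q0$q[1, 3]))
  expect_false(is.na(q0$q[1, 2]))

  # full table against the dense arithmetic oracle
  cm2 <- random_cm(n, lambda = 15, seed = 3)
  b <- c(0.5, 1, 2, 1, 1)
  sf <- estimate_size_factors(cm2, bias_vector(b))
  q2 <- normalize_matrix(cm2, bias_vector(b), sf)
  expect_equal(q2$q, dense_normalize_oracle(as_dense(cm2), b, sf$values))
})

test_that("replicate averaging and pooling are entrywise means", {
  n <- 6
  cms <- lapply(1:3, function(k) random_cm(n, lambda = 10, seed = k))
  qs <- lapply(cms, function(cm) {
    b <- unit_bias(n)
    normalize_matrix(cm, b, const_sf(n, 2))
  })
  expect_equal(average_normalized(qs[1])$q, qs[[1]]$q)  # identity
  avg <- average_normalized(qs)
  dense_mean <- Reduce(`+`, lapply(qs, `[[`, "q")) / 3
  expect_equal(avg$q, dense_mean)
  # pooled over all replicates equals the plain mean too
  expect_equal(pooled_normalized(qs)$q, dense_mean)
  # untestable in any replicate -> untestable in the average
  qs[[2]]$q[1, 4] <- NA; qs[[2]]$q[4, 1] <- NA
  expect_true(is.na(average_normalized(qs)$q[1, 4]))
})

test_that("log fold change matrix follows the pseudocount formula", {
  n <- 4
  qA <- normalize_matrix(random_cm(n, seed = 5), unit_bias(n), const_sf(n))
  qB <- normalize_matrix(random_cm(n, seed = 5), unit_bias(n), const_sf(n))
  expect_equal(log_fold_change_matrix(qA, qB, 1),
               matrix(0, n, n))
  qB2 <- qB; qB2$q <- qB$q / 2
  lfc <- log_fold_change_matrix(qA, qB2, 0)
  expect_equal(lfc[is.finite(lfc)],
               rep(1, sum(is.finite(lfc))))
  expect_equal(log_fold_change_matrix(qA, qB2, 1),
               log2((qA$q + 1) / (qA$q / 2 + 1)))
})

test_that("median normalized count is 1 at every supported distance", {
  cm <- simulate_matrix(60, decay_curve(200), seed = 9)
  beta <- estimate_ice_biases(cm)
  s <- estimate_size_factors(cm, beta)
  q <- normalize_matrix(cm, beta, s)
  n <- 60
  for (d in 1:(n - 1)) {
    if (is.na(s$values[d + 1]) || s$values[d + 1] == 0) next
    i <- seq_len(n - d)
    vals <- q$q[cbind(i, i + d)]
    vals <- vals[!is.na(vals)]
    expect_equal(median(vals), 1, tolerance = 1e-9,
                 info = paste("distance", d))
  }
})

test_that("normalized counts are invariant to a global count rescaling", {
  cm <- random_cm(10, lambda = 12, seed = 21)
  cm4 <- contact_matrix(cm$bins, cm$entries$i, cm$entries$j,
                        cm$entries$count * 4)
  b1 <- estimate_ice_biases(cm, low_count_fraction = 0)
  b4 <- estimate_ice_biases(cm4, low_count_fraction = 0)
  expect_equal(b1$values, b4$values, tolerance = 1e-6)
  s1 <- estimate_size_factors(cm, b1)
  s4 <- estimate_size_factors(cm4, b4)
  expect_equal(s4$values, 4 * s1$values, tolerance = 1e-6)
  expect_equal(normalize_matrix(cm4, b4, s4)$q,
               normalize_matrix(cm, b1, s1)$q, tolerance = 1e-6)
})
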