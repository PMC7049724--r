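# Shared fixture builders: everything is generated in code at test time.

bins_n <- function(n, chrom = "chr1", width = 10000L) {
  genomic_bins(chrom, n, width)
}

# contact matrix from a dense symmetric matrix given as upper-tri spec
cm_from_dense <- function(m, bins = bins_n(nrow(m))) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dense_to_contacts(m, bins)
}

# random symmetric count matrix, reproducible
random_cm <- function(n, lambda = 8, seed = 1, bins = bins_n(n)) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dense_to_contacts(m, bins)
}

unit_bias <- function(n) bias_vector(rep(1, n))

# size factors with constant value at every distance
const_sf <- function(n, value = 1) {
  structure(list(values = rep(value, n), support_count = rep(1L, n)),
            class = "size_factors")
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# independent brute-force conditional exact test, computed in plain
# probability space (no logs): the oracle for conditional_pvalue()
brute_force_pvalue <- function(a, b, muA, varA, muB, varB) {
  pmf <- function(x, mu, v) {
    if (mu == 0) return(as.numeric(x == 0))
    if (v <= mu * (1 + 1e-8)) return(dpois(x, mu))
    dnbinom(x, size = mu^2 / (v - mu), mu = mu)
  }
  C <- a + b
  if (C == 0) return(1)
  x <- 0:C
  p <- vapply(x, function(k) pmf(k, muA, varA) * pmf(C - k, muB, varB),
              numeric(1))
  if (sum(p) == 0) return(1)
  obs <- p[a + 1L]
  sum(p[p <= obs * (1 + 1e-7)]) / sum(p)
}

# dense-arithmetic normalization oracle: q = C / (b_i b_j s_d)
dense_normalize_oracle <- function(C, b, s) {
  n <- nrow(C)
  q <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- b[i] * b[j] * s[abs(i - j) + 1L]
    if (is.finite(den) && den > 0) q[i, j] <- C[i, j] / den
  }
  q
}

# brute-force neighborhood moments for one pair (1-based i, j), from dense
# per-replicate q matrices; neighborhood = all other pairs at |i-j| with
# non-NA q in every replicate
brute_force_neighborhood <- function(q_list, i, j) {
  n <- nrow(q_list[[1]])
  d <- abs(i - j)
  us <- seq_len(n - d)
  ok <- vapply(us, function(u)
    all(vapply(q_list, function(q) !is.na(q[u, u + d]), logical(1))),
    logical(1))
  nbr <- us[ok & us != min(i, j)]
  vals <- unlist(lapply(q_list, function(q) q[cbind(nbr, nbr + d)]))
  list(t = mean(vals),
       w = sum((vals - mean(vals))^2) / (length(vals) - 1),
       n_nbr = length(nbr))
}
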