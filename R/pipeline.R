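#' Full differential-contact analysis of a two-condition experiment set
#'
#' Runs the complete pipeline on one chromosome: per-replicate ICE
#' balancing, distance-specific size factors and normalized counts;
#' per-condition and pooled normalized averages; neighborhood raw-variance
#' estimation and polynomial smoothing per condition; NB conditional exact
#' test of the pooled counts per bin pair; Benjamini-Hochberg adjustment
#' over the testable pairs.
#'
#' @param es An [experiment_set()] with both conditions represented.
#' @param degree Polynomial degree of the raw variance fit.
#' @param min_count Minimum pooled total count (A + B) for a pair to be
#'   tested; pairs below it are reported untestable with reason
#'   `"low_count"`.
#' @param include_diagonal Test pairs at distance 0 (default `FALSE`:
#'   self-ligation artifacts dominate the diagonal).
#' @param ice_max_iter,ice_tol,low_count_fraction Passed to
#'   [estimate_ice_biases()].
#' @param pseudocount Pseudocount for the reported diagnostic log2 fold
#'   change (never used in testing).
#' @param verbose Print per-stage progress.
#' @return An object of class `accost_results`: a `data.table` with one row
#'   per candidate pair and columns `chrom`, `bin_i`, `bin_j`,
#'   `distance_bins`, `count_A`, `count_B`, `q_A`, `q_B`, `q_0`, `log2fc`,
#'   `p_value`, `q_value`, `testable`, `reason`; the fitted
#'   `variance_function`s and the per-replicate normalization are attached
#'   as attributes `variance_functions` and `normalization`.
#' @export
run_differential_test <- function(es, degree = 2L, min_count = 1L,
                                  include_diagonal = FALSE,
                                  ice_max_iter = 300L, ice_tol = 1e-5,
                                  low_count_fraction = 0.02,
                                  pseudocount = 1, verbose = FALSE) {
  stopifnot(inherits(es, "experiment_set"))
  chrom <- es$bins$chrom
  n <- es$bins$n_bins
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s | %s] %s", chrom, what, conditionMessage(e)),
           call. = FALSE))
  }

  say("[%s] balancing and normalizing %d replicates", chrom,
      length(es$matrices))
  qs <- stage("normalization", lapply(es$matrices, function(cm) {
    beta <- estimate_ice_biases(cm, max_iter = ice_max_iter, tol = ice_tol,
                                low_count_fraction = low_count_fraction)
    s <- estimate_size_factors(cm, beta)
    normalize_matrix(cm, beta, s)
  }))
  repsA <- replicates_of(es$design, "A")
  repsB <- replicates_of(es$design, "B")
  qA <- average_normalized(qs[repsA])
  qB <- average_normalized(qs[repsB])
  q0 <- pooled_normalized(qs)

  say("[%s] fitting raw variance functions", chrom)
  fit_cond <- function(cond_qs, avg, label) {
    vp <- stage(paste0("variance ", label),
                variance_points(cond_qs, avg))
    n_pos <- if (nrow(vp)) sum(is.finite(vp$wz) & vp$wz > 0 & vp$q > 0) else 0L
    if (n_pos < degree + 2L) {
      warning("condition ", label, ": only ", n_pos, " positive ",
              "raw-variance points; using the pure shot-noise limit v = 0",
              call. = FALSE)
      return(constant_variance(0))
    }
    stage(paste0("variance ", label),
          fit_variance_function(vp$q, vp$wz, degree = degree,
                                condition = label))
  }
  vfA <- fit_cond(qs[repsA], qA, "A")
  vfB <- fit_cond(qs[repsB], qB, "B")

  say("[%s] pooling counts and testing", chrom)
  CA <- as_dense(pool_condition_counts(es, "A"))
  CB <- as_dense(pool_condition_counts(es, "B"))

  d_min <- if (include_diagonal) 0L else 1L
  pairs <- data.table::rbindlist(lapply(d_min:(n - 1L), function(d) {
    i <- 0:(n - 1L - d)
    data.table::data.table(bin_i = i, bin_j = i + d, distance_bins = d)
  }))
  ii <- pairs$bin_i + 1L; jj <- pairs$bin_j + 1L
  dd <- pairs$distance_bins

  res <- data.table::data.table(
    chrom = chrom, pairs,
    count_A = CA[cbind(ii, jj)], count_B = CB[cbind(ii, jj)],
    q_A = qA$q[cbind(ii, jj)], q_B = qB$q[cbind(ii, jj)],
    q_0 = q0$q[cbind(ii, jj)])
  res$log2fc <- log2((res$q_A + pseudocount) / (res$q_B + pseudocount))

  # untestability reasons, in precedence order
  any_invalid <- Reduce(`|`, lapply(qs, function(x)
    !x$valid[ii] | !x$valid[jj]))
  s_bad <- Reduce(`|`, lapply(qs, function(x) {
    sv <- x$s$values[dd + 1L]
    is.na(sv) | sv == 0
  }))
  reason <- rep("", nrow(res))
  reason[res$count_A + res$count_B < min_count] <- "low_count"
  reason[!any_invalid & s_bad] <- "zero_size_factor"
  reason[any_invalid] <- "filtered_bin"
  res$testable <- reason == ""
  res$reason <- reason

  # per-condition normalization factor sums over the testable pairs
  bv <- lapply(qs, function(x) x$beta$values)
  sv <- lapply(qs, function(x) x$s$values)
  factor_sums <- function(reps, sel) {
    f1 <- 0; f2 <- 0
    for (k in reps) {
      f <- bv[[k]][ii[sel]] * bv[[k]][jj[sel]] * sv[[k]][dd[sel] + 1L]
      f1 <- f1 + f
      f2 <- f2 + f^2
    }
    list(f1 = f1, f2 = f2)
  }
  sel <- which(res$testable)
  res$p_value <- NA_real_
  if (length(sel)) {
    fA <- factor_sums(repsA, sel)
    fB <- factor_sums(repsB, sel)
    q0v <- res$q_0[sel]
    muA <- fA$f1 * q0v
    s2A <- muA + fA$f2 * evaluate_variance(vfA, q0v)
    muB <- fB$f1 * q0v
    s2B <- muB + fB$f2 * evaluate_variance(vfB, q0v)
    stopifnot(all(s2A >= muA), all(s2B >= muB))
    a <- res$count_A[sel]; b <- res$count_B[sel]
    res$p_value[sel] <- vapply(seq_along(sel), function(r) {
      conditional_pvalue(a[r], b[r],
                         list(mu = muA[r], sigma2 = s2A[r]),
                         list(mu = muB[r], sigma2 = s2B[r]))
    }, numeric(1))
  }
  res$q_value <- bh_adjust(res$p_value)

  say("[%s] %d pairs tested, %d untestable (%s)", chrom, length(sel),
      nrow(res) - length(sel),
      paste(sprintf("%s: %d", names(table(reason[reason != ""])),
                    table(reason[reason != ""])), collapse = ", "))
  data.table::setcolorder(res, c("chrom", "bin_i", "bin_j", "distance_bins",
                                 "count_A", "count_B", "q_A", "q_B", "q_0",
                                 "log2fc", "p_value", "q_value", "testable",
                                 "reason"))
  data.table::setattr(res, "variance_functions", list(A = vfA, B = vfB))
  data.table::setattr(res, "normalization", qs)
  data.table::setattr(res, "class", c("accost_results", class(res)))
  res[]
}

#' Write results to TSV
#'
#' @param results A [run_differential_test()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("chrom", "bin_i", "bin_j", "distance_bins", "count_A",
            "count_B", "q_A", "q_B", "q_0", "log2fc", "p_value", "q_value",
            "testable", "reason")
  data.table::fwrite(results[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return A `data.table`.
#' @export
read_results <- function(path) {
  data.table::fread(path, sep = "\t")
}
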