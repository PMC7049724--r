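# Numeric QC summaries (and optional plots) for calibration checks:
# p-value uniformity against U(0,1) and fold-change symmetry by distance.

#' Q-Q summary of p-values against the uniform distribution
#'
#' Sorts the p-values, pairs them with uniform plotting quantiles and
#' computes the exact Kolmogorov-Smirnov statistic
#' `D = sup |F_hat(t) - t|` against Uniform(0,1).
#'
#' @param pvalues Numeric p-values in `[0, 1]` (`NA`s dropped).
#' @return An object of class `qq_summary`: `p_sorted`, `uniform_q`
#'   (plotting positions `(i - 0.5)/n`), `n` and `ks`.
#' @export
qq_uniform <- function(pvalues) {
  p <- sort(pvalues[!is.na(pvalues)])
  n <- length(p)
  if (n == 0L) stop("no p-values")
  stopifnot(all(p >= 0 & p <= 1))
  i <- seq_len(n)
  ks <- max(pmax(i / n - p, p - (i - 1) / n))
  structure(list(p_sorted = p, uniform_q = (i - 0.5) / n, n = n, ks = ks),
            class = "qq_summary")
}

#' @export
print.qq_summary <- function(x, ...) {
  cat(sprintf("<qq_summary> n = %d, KS vs U(0,1) = %.4g\n", x$n, x$ks))
  invisible(x)
}

#' Asymptotic Kolmogorov-Smirnov critical value
#'
#' `c(alpha) / sqrt(n)` with `c(alpha) = sqrt(-log(alpha / 2) / 2)`
#' (one-sample, two-sided, large n).
#'
#' @param n Sample size.
#' @param alpha Significance level.
#' @return Critical KS statistic.
#' @export
ks_critical_value <- function(n, alpha = 0.01) {
  sqrt(-log(alpha / 2) / 2) / sqrt(n)
}

#' Median log fold change by distance stratum
#'
#' For each genomic-distance stratum, the median signed log2 fold change
#' among the significant pairs (p < `alpha`); when a stratum has fewer than
#' `top_n` significant pairs, its `top_n` smallest p-values are used
#' instead. A calibrated method shows medians near zero in every stratum on
#' null data.
#'
#' @param results A [run_differential_test()] result (or any data.frame
#'   with `distance_bins`, `p_value`, `log2fc`, `testable`).
#' @param breaks Distance-stratum breakpoints in bins (passed to `cut`,
#'   right-open).
#' @param alpha Significance threshold on the p-value.
#' @param top_n Minimum number of pairs per stratum summary.
#' @return A `data.table` with `stratum`, `n_pairs`, `n_used`,
#'   `median_log2fc`.
#' @export
lfc_by_distance <- function(results, breaks = NULL, alpha = 0.05,
                            top_n = 50L) {
  r <- data.table::as.data.table(results)[results$testable &
                                            !is.na(results$p_value), ]
  if (is.null(breaks)) {
    dmax <- max(r$distance_bins)
    breaks <- unique(round(c(0, 2^seq(0, ceiling(log2(dmax + 1)))) ))
    breaks <- c(breaks[breaks <= dmax], dmax + 1L)
  }
  r$stratum <- cut(r$distance_bins, breaks = breaks, right = FALSE,
                   include.lowest = FALSE)
  strat <- function(sub) {
    sig <- sub[sub$p_value < alpha, ]
    use <- if (nrow(sig) >= top_n) sig else
      sub[order(sub$p_value), ][seq_len(min(top_n, nrow(sub))), ]
    list(n_pairs = nrow(sub), n_used = nrow(use),
         median_log2fc = stats::median(use$log2fc))
  }
  out <- r[, strat(.SD), by = "stratum",
           .SDcols = c("p_value", "log2fc")]
  data.table::setorderv(out, "stratum")
  out[]
}

#' Plot a p-value Q-Q summary
#'
#' @param qq A [qq_uniform()] result.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `qq`, invisibly.
#' @export
plot_qq <- function(qq, main = "P-value uniformity", ...) {
  stopifnot(inherits(qq, "qq_summary"))
  graphics::plot(qq$uniform_q, qq$p_sorted, pch = ".",
                 xlab = "Uniform quantile", ylab = "Empirical p-value",
                 main = main, xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, col = "red")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("KS = %.4f (n = %d)", qq$ks, qq$n))
  invisible(qq)
}

#' Heatmap of a log-fold-change matrix
#'
#' @param lfc A dense log2 fold-change matrix (from
#'   [log_fold_change_matrix()]).
#' @param zlim Symmetric color range.
#' @param main Plot title.
#' @return `lfc`, invisibly.
#' @export
plot_lfc_heatmap <- function(lfc, zlim = c(-3, 3),
                             main = "log2 fold change") {
  m <- pmin(pmax(lfc, zlim[1L]), zlim[2L])
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m[, rev(seq_len(ncol(m)))],
                  col = pal, zlim = zlim, xlab = "bin", ylab = "bin",
                  main = main, useRaster = TRUE)
  invisible(lfc)
}
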