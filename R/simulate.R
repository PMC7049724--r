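# Synthetic Hi-C experiments with a controlled genomic distance effect.
#
# Counts for each bin pair are drawn independently (Poisson or NB) with a
# mean that decays as a power law of genomic distance, optionally modulated
# by locus-specific biases and planted differential contacts. The null
# calibration scenario uses two conditions whose decay curves share the
# power-law shape but differ in scale, so the only systematic difference
# between conditions is the distance effect itself.

#' Power-law contact decay curve
#'
#' Mean contact count at genomic distance `d` (in bins):
#' `mean(d) = max(anchor_mean * d^-exponent, floor)` for `d >= 1`.
#'
#' @param anchor_mean Mean count between neighboring bins (distance 1).
#' @param exponent Power-law decay exponent (>= 0).
#' @param floor Minimum mean at long range (> 0, keeps means positive).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(anchor_mean, exponent = 1, floor = 0.01) {
  if (!is.finite(anchor_mean) || anchor_mean <= 0)
    stop("anchor_mean must be positive")
  if (!is.finite(floor) || floor <= 0)
    stop("floor must be positive")
  if (exponent < 0) stop("exponent must be nonnegative")
  structure(list(anchor_mean = anchor_mean, exponent = exponent,
                 floor = floor), class = "decay_curve")
}

#' Evaluate a decay curve
#'
#' @param curve A [decay_curve()].
#' @param d Genomic distances in bins (>= 1), vectorized.
#' @return Mean contact counts.
#' @export
decay_mean <- function(curve, d) {
  stopifnot(inherits(curve, "decay_curve"), all(d >= 1))
  pmax(curve$anchor_mean * d^(-curve$exponent), curve$floor)
}

#' Expected contact counts of a simulated matrix
#'
#' Dense matrix of generation means `beta_i * beta_j * curve(|i-j|)` for
#' all off-diagonal pairs (the diagonal is left at 0: self-contacts are not
#' simulated).
#'
#' @param n_bins Number of bins (>= 2).
#' @param curve A [decay_curve()].
#' @param biases Optional positive per-bin bias vector (length `n_bins`);
#'   `NULL` means no position-specific biases.
#' @return An `n_bins x n_bins` symmetric numeric matrix.
#' @export
contact_means <- function(n_bins, curve, biases = NULL) {
  stopifnot(n_bins >= 2L)
  if (is.null(biases)) biases <- rep(1, n_bins)
  stopifnot(length(biases) == n_bins, all(biases > 0))
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  mu <- matrix(0, n_bins, n_bins)
  off <- d > 0
  mu[off] <- decay_mean(curve, d[off])
  mu * outer(biases, biases)
}

#' Planted differential contacts
#'
#' @param pairs Two-column matrix or data.frame of 0-based `(i, j)` bin
#'   pairs.
#' @param fold_change Positive multiplier applied to the generation means.
#' @param condition Condition ("A" or "B") whose means are modified.
#' @return An object of class `spike_spec`.
#' @export
spike_spec <- function(pairs, fold_change, condition = "B") {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, fold_change > 0,
            condition %in% c("A", "B"))
  structure(list(pairs = pairs, fold_change = fold_change,
                 condition = condition), class = "spike_spec")
}

#' Apply planted fold changes to generation means
#'
#' Multiplies the means of the listed pairs (and their mirror entries) by
#' the spike's fold change. Applied to means before sampling, never to
#' sampled counts.
#'
#' @param means Dense mean matrix from [contact_means()].
#' @param spec A [spike_spec()].
#' @return The modified mean matrix.
#' @export
apply_spikes <- function(means, spec) {
  stopifnot(is.matrix(means), inherits(spec, "spike_spec"))
  i <- spec$pairs[, 1L] + 1L
  j <- spec$pairs[, 2L] + 1L
  if (any(i < 1L | j < 1L | i > nrow(means) | j > ncol(means)))
    stop("spike pair out of matrix bounds")
  means[cbind(i, j)] <- means[cbind(i, j)] * spec$fold_change
  means[cbind(j, i)] <- means[cbind(i, j)]
  means
}

#' Simulate one contact matrix
#'
#' Each pair `i < j` is drawn independently with mean
#' `beta_i * beta_j * curve(|i - j|)`, from a Poisson distribution or a
#' negative binomial with variance `mu + dispersion * mu^2`. The diagonal
#' is left empty. Deterministic given `seed`.
#'
#' @param n_bins Number of bins (>= 2).
#' @param curve A [decay_curve()].
#' @param dist `"poisson"` or `"nb"`.
#' @param dispersion NB dispersion (ignored for Poisson; > 0 for NB).
#' @param biases Optional positive per-bin biases.
#' @param seed Integer RNG seed.
#' @param spikes Optional [spike_spec()] applied to the means (its
#'   `condition` field is ignored here; see [simulate_null_experiment()]).
#' @param bins Optional [genomic_bins()] (default: 10 kb bins named
#'   `"chrSim"`).
#' @return A [contact_matrix()].
#' @export
simulate_matrix <- function(n_bins, curve, dist = c("poisson", "nb"),
                            dispersion = 0, biases = NULL, seed = 1L,
                            spikes = NULL, bins = NULL) {
  dist <- match.arg(dist)
  if (is.null(bins)) bins <- genomic_bins("chrSim", n_bins, 10000L)
  stopifnot(bins$n_bins == n_bins)
  mu <- contact_means(n_bins, curve, biases)
  if (!is.null(spikes)) mu <- apply_spikes(mu, spikes)
  ut <- which(upper.tri(mu), arr.ind = TRUE)
  m <- mu[ut]
  set.seed(seed)
  counts <- if (dist == "poisson") {
    stats::rpois(length(m), m)
  } else {
    stopifnot(dispersion > 0)
    stats::rnbinom(length(m), size = 1 / dispersion, mu = m)
  }
  keep <- counts > 0
  contact_matrix(bins, ut[keep, 1L] - 1L, ut[keep, 2L] - 1L, counts[keep])
}

#' Simulate a two-condition experiment
#'
#' Generates `reps_per_condition` independent matrices per condition;
#' condition A uses `curveA` and condition B uses `curveB`, so with no
#' spikes the only systematic difference between conditions is the genomic
#' distance effect (a calibrated method should return uniform p-values).
#' Per-matrix child seeds are derived deterministically from the master
#' seed.
#'
#' @param n_bins Number of bins.
#' @param curveA,curveB [decay_curve()]s for the two conditions. Defaults:
#'   power-law decay with exponent 1 anchored at mean 1000 (A) and
#'   1500 (B) between neighboring bins.
#' @param reps_per_condition Replicates per condition.
#' @param seed Master integer seed.
#' @param dist,dispersion,biases Passed to [simulate_matrix()].
#' @param spikes Optional [spike_spec()]; applied only to the matrices of
#'   its `condition`.
#' @return An [experiment_set()] with replicates `A1..`, `B1..`.
#' @export
simulate_null_experiment <- function(n_bins = 500L,
                                     curveA = decay_curve(1000),
                                     curveB = decay_curve(1500),
                                     reps_per_condition = 1L,
                                     seed = 1L,
                                     dist = "poisson", dispersion = 0,
                                     biases = NULL, spikes = NULL) {
  stopifnot(reps_per_condition >= 1L)
  bins <- genomic_bins("chrSim", n_bins, 10000L)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 2L * reps_per_condition)
  ids <- c(paste0("A", seq_len(reps_per_condition)),
           paste0("B", seq_len(reps_per_condition)))
  conds <- rep(c("A", "B"), each = reps_per_condition)
  mats <- lapply(seq_along(ids), function(k) {
    curve <- if (conds[k] == "A") curveA else curveB
    sp <- if (!is.null(spikes) && spikes$condition == conds[k]) spikes
    simulate_matrix(n_bins, curve, dist = dist, dispersion = dispersion,
                    biases = biases, seed = child[k], spikes = sp,
                    bins = bins)
  })
  names(mats) <- ids
  experiment_set(experiment_design(ids, conds), mats)
}

#' Write an experiment set to disk
#'
#' Writes `bins.bed`, one sparse triplet file per replicate and a
#' `design.tsv` (replicate_id, condition, path) consumable by
#' [read_experiment_set()].
#'
#' @param es An [experiment_set()].
#' @param dir Output directory (created if missing).
#' @return The design file path, invisibly.
#' @export
write_experiment_set <- function(es, dir) {
  stopifnot(inherits(es, "experiment_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bins_bed(es$bins, file.path(dir, "bins.bed"))
  files <- paste0(es$design$replicate_ids, ".triplets.tsv")
  for (k in seq_along(files))
    write_sparse_triplets(es$matrices[[k]], file.path(dir, files[k]))
  d <- data.table::data.table(
    replicate_id = es$design$replicate_ids,
    condition = es$design$condition_of[es$design$replicate_ids],
    path = files)
  data.table::fwrite(d, file.path(dir, "design.tsv"), sep = "\t",
                     col.names = FALSE)
  invisible(file.path(dir, "design.tsv"))
}
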