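#' Two-condition experimental design
#'
#' Maps replicate labels to one of two conditions, "A" or "B". Both
#' conditions must have at least one replicate.
#'
#' @param replicate_ids Character vector of unique replicate labels.
#' @param conditions Character vector of the same length, each "A" or "B".
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(replicate_ids, conditions) {
  replicate_ids <- as.character(replicate_ids)
  conditions <- as.character(conditions)
  stopifnot(length(replicate_ids) == length(conditions),
            !anyDuplicated(replicate_ids))
  if (!all(conditions %in% c("A", "B")))
    stop("conditions must be 'A' or 'B'")
  if (!all(c("A", "B") %in% conditions))
    stop("both conditions need at least one replicate")
  structure(list(replicate_ids = replicate_ids,
                 condition_of = stats::setNames(conditions, replicate_ids)),
            class = "experiment_design")
}

#' Replicates assigned to a condition
#'
#' @param design An [experiment_design()].
#' @param condition "A" or "B".
#' @return Character vector of replicate ids (the set M(A) or M(B)).
#' @export
replicates_of <- function(design, condition) {
  stopifnot(inherits(design, "experiment_design"))
  if (!condition %in% c("A", "B")) stop("unknown condition: ", condition)
  design$replicate_ids[design$condition_of[design$replicate_ids] == condition]
}

#' A set of replicate contact matrices with a design
#'
#' @param design An [experiment_design()].
#' @param matrices Named list of [contact_matrix()] objects, one per
#'   replicate in `design`, all sharing the same bins.
#' @return An object of class `experiment_set`.
#' @export
experiment_set <- function(design, matrices) {
  stopifnot(inherits(design, "experiment_design"))
  if (!setequal(names(matrices), design$replicate_ids))
    stop("matrix names must match design replicate ids")
  matrices <- matrices[design$replicate_ids]
  b0 <- matrices[[1L]]$bins
  for (m in matrices) {
    stopifnot(inherits(m, "contact_matrix"))
    if (!same_bins(m$bins, b0)) stop("all matrices must share the same bins")
  }
  structure(list(design = design, matrices = matrices, bins = b0),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> %s | A: %s | B: %s\n", format(x$bins),
              paste(replicates_of(x$design, "A"), collapse = ","),
              paste(replicates_of(x$design, "B"), collapse = ",")))
  invisible(x)
}

#' Read an experiment set from a design file
#'
#' The design file is a headerless TSV with columns `replicate_id`,
#' `condition` (A or B) and `path` to that replicate's sparse triplet file.
#' Relative paths are resolved against the design file's directory.
#'
#' @param design_path Path to the design TSV.
#' @param bins A [genomic_bins()] (e.g. from [read_bins_bed()]).
#' @return An [experiment_set()].
#' @export
read_experiment_set <- function(design_path, bins) {
  d <- utils::read.table(design_path, header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("replicate_id", "condition", "path"))
  paths <- ifelse(grepl("^/", d$path), d$path,
                  file.path(dirname(design_path), d$path))
  mats <- lapply(paths, read_sparse_triplets, bins = bins)
  names(mats) <- d$replicate_id
  experiment_set(experiment_design(d$replicate_id, d$condition), mats)
}

#' Pool replicate counts within one condition
#'
#' Entrywise sum of the contact matrices of all replicates assigned to the
#' given condition: the test statistic C^A (or C^B).
#'
#' @param es An [experiment_set()].
#' @param condition "A" or "B".
#' @return A [contact_matrix()] of pooled counts.
#' @export
pool_condition_counts <- function(es, condition) {
  stopifnot(inherits(es, "experiment_set"))
  reps <- replicates_of(es$design, condition)
  if (length(reps) == 0L) stop("condition ", condition, " has no replicates")
  ent <- data.table::rbindlist(lapply(es$matrices[reps],
                                      function(m) m$entries))
  contact_matrix(es$bins, ent$i, ent$j, ent$count)
}
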