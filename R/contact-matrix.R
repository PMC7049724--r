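#' Sparse symmetric Hi-C contact matrix
#'
#' Stores intra-chromosomal contact counts for one chromosome as an
#' upper-triangular triplet list: entries are canonicalized to `i <= j`,
#' duplicates (including mirrored `(j, i)` records) are summed, and
#' zero-count entries are dropped. The matrix is symmetric by construction:
#' `C[i, j] == C[j, i]`.
#'
#' @param bins A [genomic_bins()] object.
#' @param i,j 0-based bin indices (equal length integer vectors).
#' @param count Nonnegative integer counts, same length as `i`.
#'
#' @return An object of class `contact_matrix` with fields `bins` and
#'   `entries` (a `data.table` with columns `i`, `j`, `count`, `i <= j`,
#'   sorted by `(i, j)`).
#' @export
contact_matrix <- function(bins, i = integer(), j = integer(),
                           count = numeric()) {
  stopifnot(inherits(bins, "genomic_bins"),
            length(i) == length(j), length(j) == length(count))
  i <- as.integer(i); j <- as.integer(j); count <- as.numeric(count)
  if (length(i)) {
    if (anyNA(i) || anyNA(j) || anyNA(count))
      stop("NA values in contact entries")
    if (min(i, j) < 0L || max(i, j) >= bins$n_bins)
      stop(sprintf("bin index out of range [0, %d)", bins$n_bins))
    if (any(count < 0)) stop("negative contact count")
    if (any(count != round(count))) stop("non-integer contact count")
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  e <- data.table::data.table(i = lo, j = hi, count = count)
  e <- e[, list(count = sum(count)), by = c("i", "j")]
  e <- e[e$count > 0, ]
  data.table::setkeyv(e, c("i", "j"))
  structure(list(bins = bins, entries = e), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s | %d stored pairs | total count %s\n",
              format(x$bins), nrow(x$entries),
              format(sum(x$entries$count))))
  invisible(x)
}

#' Densify a contact matrix
#'
#' @param cm A [contact_matrix()].
#' @return A symmetric `n_bins x n_bins` numeric matrix (zeros where no
#'   entry is stored).
#' @export
as_dense <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- cm$bins$n_bins
  m <- matrix(0, n, n)
  e <- cm$entries
  if (nrow(e)) {
    m[cbind(e$i + 1L, e$j + 1L)] <- e$count
    m[cbind(e$j + 1L, e$i + 1L)] <- e$count
  }
  m
}

#' Read a contact matrix from sparse triplet text
#'
#' Each line is `i<TAB>j<TAB>count` with 0-based bin indices (any
#' whitespace separator is accepted). Records with `i > j` are mirrored to
#' the upper triangle; duplicates are summed; zero-count lines are dropped.
#' An empty file yields an all-zero matrix.
#'
#' @param path Path to the triplet file.
#' @param bins A [genomic_bins()] object giving the matrix dimension.
#' @return A [contact_matrix()].
#' @export
read_sparse_triplets <- function(path, bins) {
  stopifnot(inherits(bins, "genomic_bins"))
  if (file.size(path) == 0)
    return(contact_matrix(bins))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, colClasses = "numeric",
                      col.names = c("i", "j", "count")),
    error = function(e) stop("malformed triplet file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  bad <- which(!stats::complete.cases(dt) |
                 dt$i != round(dt$i) | dt$j != round(dt$j))
  if (length(bad))
    stop(sprintf("malformed line %d in %s", bad[1L], path))
  if (any(dt$i < 0 | dt$j < 0 | dt$i >= bins$n_bins | dt$j >= bins$n_bins)) {
    k <- which(dt$i < 0 | dt$j < 0 | dt$i >= bins$n_bins |
                 dt$j >= bins$n_bins)[1L]
    stop(sprintf("line %d of %s: bin index out of range [0, %d)",
                 k, path, bins$n_bins))
  }
  contact_matrix(bins, dt$i, dt$j, dt$count)
}

#' Write a contact matrix as sparse triplet text
#'
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sparse_triplets <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  data.table::fwrite(cm$entries, path, sep = "\t", col.names = FALSE)
  if (nrow(cm$entries) == 0L) cat("", file = path)  # ensure file exists
  invisible(path)
}

#' Read a small dense whitespace-separated matrix as a contact matrix
#'
#' Convenience reader for hand-written fixtures. The matrix must be square
#' and symmetric; the upper triangle (including the diagonal) is stored.
#'
#' @param path Path to a dense whitespace-separated numeric matrix.
#' @param bins A [genomic_bins()]; must match the matrix dimension.
#' @return A [contact_matrix()].
#' @export
read_dense_matrix <- function(path, bins) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  dense_to_contacts(m, bins)
}

#' Build a contact matrix from a dense symmetric matrix
#'
#' @param m Square symmetric numeric matrix of counts.
#' @param bins A [genomic_bins()] with `n_bins == nrow(m)`.
#' @return A [contact_matrix()].
#' @export
dense_to_contacts <- function(m, bins) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), inherits(bins, "genomic_bins"),
            nrow(m) == bins$n_bins)
  if (!isSymmetric(unname(m)))
    stop("dense contact matrix must be symmetric")
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  contact_matrix(bins, idx[, 1L] - 1L, idx[, 2L] - 1L, m[idx])
}

#' Total contact count of a matrix
#'
#' Sums each off-diagonal pair once and the diagonal once.
#'
#' @param cm A [contact_matrix()].
#' @return A single number.
#' @export
total_count <- function(cm) sum(cm$entries$count)
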