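#' Genomic bins of a single chromosome
#'
#' A set of contiguous, non-overlapping fixed-width bins tiling one
#' chromosome. Bin indices are 0-based; coordinates are 0-based half-open
#' (BED convention). The last bin may be shorter than `bin_width`.
#'
#' @param chrom Chromosome name (single string).
#' @param n_bins Number of bins (>= 1).
#' @param bin_width Bin width in bp.
#' @param chrom_length Optional chromosome length in bp; defaults to
#'   `n_bins * bin_width` (i.e. a full-width last bin).
#'
#' @return An object of class `genomic_bins` with fields `chrom`,
#'   `bin_width`, `n_bins`, `start` (0-based start coordinate per bin) and
#'   `end`.
#' @export
genomic_bins <- function(chrom, n_bins, bin_width, chrom_length = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            n_bins >= 1L, bin_width >= 1L)
  n_bins <- as.integer(n_bins)
  bin_width <- as.integer(bin_width)
  if (is.null(chrom_length)) chrom_length <- as.numeric(n_bins) * bin_width
  start <- (seq_len(n_bins) - 1) * as.numeric(bin_width)
  end <- pmin(start + bin_width, chrom_length)
  if (any(end <= start))
    stop("chrom_length inconsistent with n_bins * bin_width")
  structure(
    list(chrom = chrom, n_bins = n_bins, bin_width = bin_width,
         start = start, end = end),
    class = "genomic_bins"
  )
}

#' @export
format.genomic_bins <- function(x, ...) {
  sprintf("<genomic_bins> %s: %d bins of %d bp", x$chrom, x$n_bins,
          x$bin_width)
}

#' @export
print.genomic_bins <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

same_bins <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$n_bins, b$n_bins) &&
    identical(a$bin_width, b$bin_width)
}

#' Read bin definitions from a BED3 file
#'
#' Expects a single chromosome, records sorted by start, contiguous and
#' non-overlapping. The bin width is inferred as the modal `end - start`;
#' only the final bin is allowed to be shorter.
#'
#' @param path Path to a BED3 file (chrom, start, end; tab- or
#'   whitespace-separated, no header).
#' @return A [genomic_bins()] object.
#' @export
read_bins_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end"))
  if (nrow(bed) == 0L) stop("empty BED file: ", path)
  chroms <- unique(bed$chrom)
  if (length(chroms) > 1L)
    stop("bin BED file must contain a single chromosome, found: ",
         paste(chroms, collapse = ", "))
  if (is.unsorted(bed$start, strictly = TRUE))
    stop("bin BED records must be sorted by start, strictly increasing")
  widths <- bed$end - bed$start
  if (any(widths <= 0)) stop("BED record with end <= start")
  gaps <- bed$start[-1L] - bed$end[-nrow(bed)]
  if (any(gaps != 0)) {
    k <- which(gaps != 0)[1L]
    stop(sprintf("bins must be contiguous: %s between records %d and %d",
                 if (gaps[k] > 0) "gap" else "overlap", k, k + 1L))
  }
  w <- as.integer(names(sort(table(widths), decreasing = TRUE))[1L])
  if (any(widths[-length(widths)] != w))
    stop("all bins but the last must have the modal width ", w)
  genomic_bins(chroms, nrow(bed), w, chrom_length = bed$end[nrow(bed)])
}

#' Write bin definitions as BED3
#'
#' @param bins A [genomic_bins()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  stopifnot(inherits(bins, "genomic_bins"))
  dt <- data.table::data.table(chrom = bins$chrom,
                               start = format(bins$start, scientific = FALSE,
                                              trim = TRUE),
                               end = format(bins$end, scientific = FALSE,
                                            trim = TRUE))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
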