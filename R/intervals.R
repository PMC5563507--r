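#' Genomic interval records
#'
#' All coordinates in this package follow the BED convention: 0-based,
#' half-open `[start, end)`. A peak summit is a single absolute base
#' position (0-based). Chromosome names are opaque strings; no "chr"
#' normalization is attempted.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": chromosome names must be nonempty")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(what, ": invalid coordinates (need 0 <= start < end) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(x)
}

# BED half-open -> 1-based closed GRanges
as_granges <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Test whether two genomic intervals share at least one base
#'
#' Implements the ">= 1 base overlap" co-occupancy rule. Under half-open
#' coordinates two intervals overlap iff `max(start) < min(end)` on the
#' same chromosome; adjacent intervals (`a$end == b$start`) do not overlap.
#'
#' @param a,b single-row data.frames (or lists) with `chrom`, `start`, `end`.
#' @return logical scalar.
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)
}

#' Merge overlapping intervals into their transitive union
#'
#' Collapses every chain of (>= 1 base) overlapping intervals into one
#' interval, returning disjoint intervals sorted by (chrom, start). This is
#' the primitive behind pCRM construction ("merged overlapping binding
#' peaks"). Delegates to `GenomicRanges::reduce()`.
#'
#' @param x interval data.frame (`chrom`, `start`, `end`); may be empty.
#' @return data.frame of disjoint sorted intervals covering the same bases.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- granges_to_df(GenomicRanges::reduce(as_granges(x)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total number of bases covered by a set of intervals
#'
#' @param x interval data.frame.
#' @return integer, size of the base-wise union.
#' @export
covered_length <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Warn when two interval sets share no chromosome names (likely a
# namespace mismatch such as "chr1" vs "1"); error when `fatal`.
check_chrom_namespace <- function(chroms_a, chroms_b, what_a, what_b,
                                  fatal = FALSE) {
  if (length(chroms_a) && length(chroms_b) &&
      !length(intersect(unique(chroms_a), unique(chroms_b)))) {
    msg <- sprintf(
      "no shared chromosome names between %s (%s, ...) and %s (%s, ...); likely namespace mismatch",
      what_a, paste(utils::head(unique(chroms_a), 3), collapse = ","),
      what_b, paste(utils::head(unique(chroms_b), 3), collapse = ","))
    if (fatal) stop(msg) else warning(msg)
    return(FALSE)
  }
  TRUE
}
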