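#' Distance from a peak summit to a gene body
#'
#' Zero when the summit lies inside the half-open body
#' `[start, end)`; otherwise the gap in bases to the nearest body edge
#' (`start - summit` upstream, `summit - end + 1` downstream, the +1
#' accounting for the half-open end). Strand is ignored: the association
#' window is symmetric around the gene body.
#'
#' @param summit integer summit position(s), 0-based.
#' @param body_start,body_end gene-body coordinates, 0-based half-open.
#' @return non-negative integer distance(s); chromosome equality is the
#'   caller's responsibility.
#' @export
summit_body_distance <- function(summit, body_start, body_end) {
  ifelse(summit < body_start, body_start - summit,
         ifelse(summit >= body_end, summit - body_end + 1L, 0L))
}

#' Associate peaks with genes by the summit-within-window rule
#'
#' A peak is associated with a gene when its summit falls within `window`
#' bases up- or downstream of the gene body (distance `<= window`,
#' inclusive; `window = 0` keeps only summit-inside-body hits). A peak may
#' associate with several genes and vice versa; no nearest-gene collapse
#' is applied. Implemented as a windowed `GenomicRanges::findOverlaps()`
#' sweep, exactly equivalent to the all-pairs scan.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `peak_id`,
#'   `summit`, `source`).
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param window association window in bases, default 5000.
#' @return data.frame with columns `peak_id`, `gene_id`, `tf`, `distance`,
#'   sorted by `(gene_id, peak_id)`.
#' @export
map_peaks_to_genes <- function(peaks, genes, window = 5000L) {
  stopifnot(window >= 0)
  window <- as.integer(window)
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      tf = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(genes)) return(empty)
  check_chrom_namespace(peaks$chrom, genes$chrom, "peaks", "gene models",
                        fatal = TRUE)

  # summit as a 1-bp interval against bodies expanded by `window` on
  # both sides; half-open body [s, e) plus inclusive distance <= window
  # admits summits in [s - window, e - 1 + window]
  summit_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$summit + 1L, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start + 1L - window, 1L),
                     end = genes$end + window))
  hits <- GenomicRanges::findOverlaps(summit_gr, gene_gr)
  if (!length(hits)) return(empty)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- summit_body_distance(peaks$summit[pi], genes$start[gi], genes$end[gi])
  keep <- d <= window  # guards the clipped-at-chromosome-start edge case
  out <- data.frame(peak_id = peaks$peak_id[pi][keep],
                    gene_id = genes$gene_id[gi][keep],
                    tf = peaks$source[pi][keep],
                    distance = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export peak-gene associations as TSV
#'
#' @param associations a [map_peaks_to_genes()] result.
#' @param path output TSV.
#' @export
write_associations <- function(associations, path) {
  write_tsv_stable(
    associations[, c("peak_id", "gene_id", "tf", "distance"), drop = FALSE],
    path)
}
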