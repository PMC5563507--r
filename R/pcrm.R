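#' Build putative cis-regulatory modules from pooled peak sets
#'
#' Pools the peaks of all TFs and transitively merges every chain of
#' (>= 1 base) overlapping peaks into one module, so each input peak
#' belongs to exactly one pCRM. Occupancy records, per module and TF,
#' whether the TF contributed a member peak (and the max member score,
#' for signal-mode shading).
#'
#' @param peak_sets named list (TF -> peak data.frame).
#' @return list with `regions` (data.frame: `chrom`, `start`, `end`,
#'   `pcrm_id`, `n_peaks`, one 0/1 `occ_<TF>` and one numeric
#'   `score_<TF>` column per TF), `members` (pcrm_id -> peak_ids), and
#'   `tf_panel`.
#' @export
build_pcrms <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) > 0L,
            !is.null(names(peak_sets)))
  tf_panel <- names(peak_sets)
  pooled <- do.call(rbind, lapply(tf_panel, function(tf) {
    p <- peak_sets[[tf]]
    if (is.null(p) || !nrow(p)) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               peak_id = p$peak_id, score = p$score, tf = tf,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || !nrow(pooled)) stop("all peak sets are empty")
  validate_intervals(pooled, "peak")

  gr <- as_granges(pooled)
  merged <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  stopifnot(length(hit) == nrow(pooled))  # each peak in exactly one module
  module_of <- S4Vectors::subjectHits(hit)

  n_mod <- length(merged)
  regions <- granges_to_df(merged)
  ord <- order(regions$chrom, regions$start)
  new_of_old <- integer(n_mod)
  new_of_old[ord] <- seq_len(n_mod)
  module_of <- new_of_old[module_of]
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  regions$pcrm_id <- sprintf("pcrm_%05d", seq_len(n_mod))
  regions$n_peaks <- as.integer(tabulate(module_of, n_mod))
  for (tf in tf_panel) {
    sel <- pooled$tf == tf
    occ <- rep(0L, n_mod)
    sc <- rep(NA_real_, n_mod)
    if (any(sel)) {
      mods <- module_of[sel]
      occ[unique(mods)] <- 1L
      agg <- tapply(pooled$score[sel], mods, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
      sc[as.integer(names(agg))] <- as.numeric(agg)
    }
    regions[[paste0("occ_", tf)]] <- occ
    regions[[paste0("score_", tf)]] <- sc
  }
  members <- split(pooled$peak_id, regions$pcrm_id[module_of])
  list(regions = regions, members = members, tf_panel = tf_panel)
}

#' Cluster occupancy patterns (k-means, deterministic)
#'
#' K-means on the rows of a binary (or signal) occupancy matrix with a
#' fixed seed and multiple restarts, keeping the best-inertia solution.
#' Rows are canonically re-ordered internally before clustering so the
#' result is invariant to input row order; clusters are relabeled in
#' decreasing size order (cluster 1 is the largest).
#'
#' @param occ numeric matrix, one row per module, one column per TF.
#' @param k number of clusters, default 8.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return integer vector of cluster labels (1..k), parallel to the rows
#'   of `occ`.
#' @export
cluster_occupancy <- function(occ, k = 8L, seed = 1L, nstart = 25L) {
  stopifnot(k >= 1L)
  if (!nrow(occ)) stop("empty occupancy matrix")
  n_patterns <- nrow(unique(occ))
  if (k > 1L && n_patterns < k) {
    warning("only ", n_patterns, " distinct occupancy patterns; using k = ",
            n_patterns)
    k <- n_patterns
  }
  if (k == 1L) return(rep(1L, nrow(occ)))
  ord <- do.call(order, c(lapply(seq_len(ncol(occ)), function(j) occ[, j])))
  fit <- withr::with_seed(as.integer(seed),
    stats::kmeans(occ[ord, , drop = FALSE], centers = k, nstart = nstart,
                  iter.max = 100L))
  labels_sorted <- fit$cluster
  labels <- integer(nrow(occ))
  labels[ord] <- labels_sorted
  # relabel by decreasing cluster size; break size ties by first occurrence
  sizes <- table(labels)
  new_id <- stats::setNames(seq_len(k),
                            names(sizes)[order(-as.integer(sizes),
                                               as.integer(names(sizes)))])
  as.integer(new_id[as.character(labels)])
}

#' Cluster pCRMs by TF occupancy and export a heatmap-ready matrix
#'
#' Bins modules into `k` clusters (default 8) on their binary occupancy
#' vectors; a signal mode clusters max peak scores instead. The returned
#' matrix has rows grouped by cluster for direct heatmap rendering.
#'
#' @param pcrms a [build_pcrms()] result.
#' @param k number of clusters, default 8.
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param use_signal cluster max-score columns instead of 0/1 occupancy.
#' @return list: `regions` (with `cluster_id` filled), `heatmap` (matrix,
#'   rows ordered by cluster then coordinate), `k`.
#' @export
cluster_pcrms <- function(pcrms, k = 8L, seed = 1L, use_signal = FALSE) {
  regions <- pcrms$regions
  cols <- paste0(if (use_signal) "score_" else "occ_", pcrms$tf_panel)
  occ <- as.matrix(regions[, cols, drop = FALSE])
  if (use_signal) occ[is.na(occ)] <- 0
  colnames(occ) <- pcrms$tf_panel
  labels <- cluster_occupancy(occ, k = k, seed = seed)
  regions$cluster_id <- labels
  ord <- order(labels, regions$chrom, regions$start)
  heatmap <- occ[ord, , drop = FALSE]
  rownames(heatmap) <- regions$pcrm_id[ord]
  list(regions = regions, heatmap = heatmap, k = length(unique(labels)))
}

#' Flag differential-binding regions co-bound by a reference TF
#'
#' A region is co-bound when it shares at least 1 base with any reference
#' peak (e.g. JunB peaks over differential JunD regions).
#'
#' @param diff_regions data.frame with `chrom`, `start`, `end`, `log2fc`,
#'   `pvalue`, `fdr`.
#' @param reference_peaks peak data.frame.
#' @return `diff_regions` with a logical `cobound` column.
#' @export
annotate_cobound <- function(diff_regions, reference_peaks) {
  validate_intervals(diff_regions, "diff region")
  diff_regions$cobound <- rep(FALSE, nrow(diff_regions))
  if (!nrow(diff_regions) || !nrow(reference_peaks)) return(diff_regions)
  check_chrom_namespace(diff_regions$chrom, reference_peaks$chrom,
                        "diff regions", "reference peaks")
  hits <- GenomicRanges::findOverlaps(as_granges(diff_regions),
                                      as_granges(reference_peaks))
  diff_regions$cobound[unique(S4Vectors::queryHits(hits))] <- TRUE
  diff_regions
}

#' Overlap fraction and venn counts between two peak sets
#'
#' The fraction of A-peaks overlapping (>= 1 base) at least one B-peak —
#' the statistic behind "68% of JunD peaks overlapped those of JunB" —
#' plus venn counts from both perspectives (which differ when overlaps
#' are not one-to-one).
#'
#' @param peaks_a,peaks_b peak data.frames; A must be nonempty.
#' @return list: `fraction_a_in_b`, `fraction_b_in_a`, `venn` (named:
#'   `a_only`, `b_only`, `a_shared`, `b_shared`).
#' @export
overlap_fraction <- function(peaks_a, peaks_b) {
  if (!nrow(peaks_a)) stop("peak set A is empty")
  if (!nrow(peaks_b))
    return(list(fraction_a_in_b = 0, fraction_b_in_a = NaN,
                venn = c(a_only = nrow(peaks_a), b_only = 0L,
                         a_shared = 0L, b_shared = 0L)))
  ga <- as_granges(peaks_a)
  gb <- as_granges(peaks_b)
  a_hit <- GenomicRanges::countOverlaps(ga, gb) > 0L
  b_hit <- GenomicRanges::countOverlaps(gb, ga) > 0L
  list(fraction_a_in_b = mean(a_hit),
       fraction_b_in_a = mean(b_hit),
       venn = c(a_only = sum(!a_hit), b_only = sum(!b_hit),
                a_shared = sum(a_hit), b_shared = sum(b_hit)))
}

#' Differential-binding summary by co-occupancy subtype
#'
#' For each subtype (co-bound vs not), the percentage of regions with
#' fold change >= `fc_threshold` (signed, per volcano quadrant:
#' `log2fc >= log2(fc_threshold)` up, `<= -log2(fc_threshold)` down) and
#' p < `p_threshold`, each over its subtype's total. Also returns volcano
#' coordinates with the p-value capped (default 1e-25).
#'
#' @param diff_regions data.frame with `cobound` set (see
#'   [annotate_cobound()]).
#' @param fc_threshold linear fold-change threshold, default 2.
#' @param p_threshold raw p threshold, default 0.01.
#' @param p_cap p-value floor for volcano export, default 1e-25.
#' @return list: `percentages` (named `cobound_up`, `cobound_down`,
#'   `noncobound_up`, `noncobound_down`), `totals` per subtype, and
#'   `volcano` (data.frame `log2fc`, `minus_log10_p`, `cobound`).
#' @export
diff_summary <- function(diff_regions, fc_threshold = 2, p_threshold = 0.01,
                         p_cap = 1e-25) {
  if (is.null(diff_regions$cobound) || any(is.na(diff_regions$cobound)))
    stop("cobound must be assigned on all regions (run annotate_cobound)")
  lfc_cut <- log2(fc_threshold)
  pct <- function(sel, dir_up) {
    n <- sum(sel)
    if (n == 0L) return(NA_real_)
    hit <- sel & diff_regions$pvalue < p_threshold &
      (if (dir_up) diff_regions$log2fc >= lfc_cut
       else diff_regions$log2fc <= -lfc_cut)
    100 * sum(hit) / n
  }
  cb <- diff_regions$cobound
  list(
    percentages = c(cobound_up = pct(cb, TRUE),
                    cobound_down = pct(cb, FALSE),
                    noncobound_up = pct(!cb, TRUE),
                    noncobound_down = pct(!cb, FALSE)),
    totals = c(cobound = sum(cb), noncobound = sum(!cb)),
    volcano = data.frame(
      log2fc = diff_regions$log2fc,
      minus_log10_p = -log10(pmax(diff_regions$pvalue, p_cap)),
      cobound = cb, stringsAsFactors = FALSE))
}

#' Export a pCRM table as BED-plus-columns TSV
#'
#' @param clustered a [cluster_pcrms()] result.
#' @param path output TSV.
#' @export
write_pcrm_table <- function(clustered, path) {
  regions <- clustered$regions
  keep <- c("chrom", "start", "end", "pcrm_id", "cluster_id", "n_peaks",
            grep("^occ_", names(regions), value = TRUE))
  write_tsv_stable(regions[, keep, drop = FALSE], path)
}
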