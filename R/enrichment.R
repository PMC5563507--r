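#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, input order
#' preserved. Validates the input range and delegates to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Build a subset signature gene set from a DE contrast
#'
#' The top `n` up- (or down-) regulated genes sorted ascending by raw
#' p-value; direction is the sign of log2FC. Ties on p are broken by
#' larger |log2FC|, then lexicographic gene id. No additional
#' significance filter is applied before the cut (configurable via
#' `require_fdr`).
#'
#' @param de_table DE data.frame.
#' @param direction `"up"` or `"down"`.
#' @param n signature size, default 100.
#' @param require_fdr optional FDR cutoff applied before the top-n cut
#'   (`NULL`, the default, means none).
#' @return character vector of gene ids (fewer than `n`, with a warning,
#'   when not enough genes qualify).
#' @export
signature_from_contrast <- function(de_table, direction = c("up", "down"),
                                    n = 100L, require_fdr = NULL) {
  direction <- match.arg(direction)
  stopifnot(n >= 1L)
  keep <- if (direction == "up") de_table$log2fc > 0 else de_table$log2fc < 0
  if (!is.null(require_fdr)) keep <- keep & de_table$fdr < require_fdr
  cand <- de_table[keep, , drop = FALSE]
  if (!nrow(cand)) stop("no ", direction, "-regulated genes to build a signature from")
  ord <- order(cand$pvalue, -abs(cand$log2fc), cand$gene_id)
  if (nrow(cand) < n)
    warning("only ", nrow(cand), " ", direction,
            "-regulated genes available (requested ", n, ")")
  cand$gene_id[utils::head(ord, n)]
}

#' Per-gene ranking metric for pre-ranked GSEA
#'
#' `s_g = -log10(p_g) * sign(log2FC_g)`, sorted descending. A p of zero
#' is capped at |s| = 320 (just below the double-precision -log10
#' underflow) so the ordering stays finite; ties are broken by gene id.
#'
#' @param de_table DE data.frame.
#' @param cap magnitude cap applied when p underflows to 0.
#' @return data.frame `gene_id`, `score`, descending by score.
#' @export
rank_metric <- function(de_table, cap = 320) {
  stopifnot(nrow(de_table) > 0L)
  if (anyDuplicated(de_table$gene_id)) stop("duplicate gene_id in DE table")
  mag <- ifelse(de_table$pvalue == 0, cap, -log10(de_table$pvalue))
  s <- mag * sign(de_table$log2fc)
  out <- data.frame(gene_id = de_table$gene_id, score = s,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# core weighted-KS running sum over hit positions.
# absw: |score|^weight for every ranked position; miss decrement 1/(N - Nh).
es_from_positions <- function(pos, absw, n) {
  nh <- length(pos)
  denom_hit <- sum(absw[pos])
  inc <- if (denom_hit > 0) absw[pos] / denom_hit else rep(1 / nh, nh)
  delta <- rep.int(-1 / (n - nh), n)
  delta[pos] <- inc
  running <- cumsum(delta)
  i <- which.max(abs(running))  # first extremum on ties: deterministic
  list(es = running[i], running = running, extremum = i)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The pre-ranked GSEA running-sum statistic: walking down the ranked
#' list, a gene-set hit increments by `|s_i|^weight / sum_hits |s|^weight`
#' and a miss decrements by `1 / (N - N_hits)`; the enrichment score is
#' the maximum-magnitude (signed) deviation. `weight = 0` gives the
#' classic unweighted KS statistic; `weight = 1` is the conventional
#' "weighted" setting.
#'
#' @param ranked a [rank_metric()]-style data.frame (`gene_id`, `score`),
#'   descending.
#' @param geneset character vector of member gene ids; must share at
#'   least one gene with the ranked list and must not cover it entirely.
#' @param weight exponent on |score| at hits, default 1.
#' @return list: `es` (in `[-1, 1]`), `running_sum`, `leading_edge`
#'   (member ids at/before a positive extremum, at/after a negative one).
#' @export
enrichment_score <- function(ranked, geneset, weight = 1) {
  hit <- ranked$gene_id %in% geneset
  nh <- sum(hit)
  n <- nrow(ranked)
  if (nh == 0L) stop("gene set shares no genes with the ranked list")
  if (nh == n) stop("gene set covers the whole ranked universe (degenerate)")
  absw <- abs(ranked$score)^weight
  r <- es_from_positions(which(hit), absw, n)
  leading <- if (r$es > 0) {
    ranked$gene_id[hit & seq_len(n) <= r$extremum]
  } else if (r$es < 0) {
    ranked$gene_id[hit & seq_len(n) >= r$extremum]
  } else character(0)
  list(es = r$es, running_sum = r$running, leading_edge = leading)
}

#' Pre-ranked GSEA with a gene-set permutation null
#'
#' For each gene set, the observed weighted-KS enrichment score is
#' compared against `nperm` random gene sets of the same size drawn from
#' the ranked universe (gene-set permutation — the null model coherent
#' for pre-ranked input). The permutation p-value counts same-signed null
#' scores at least as extreme, plus-one corrected, so it is never 0 and
#' never below `1 / (nperm + 1)`; NES divides the observed score by the
#' mean |null score| of the same sign.
#'
#' @param ranked a [rank_metric()]-style data.frame, descending.
#' @param gene_sets named list of character vectors.
#' @param nperm permutations, default 10000.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param weight KS weight, default 1.
#' @return data.frame: `set_name`, `size`, `es`, `nes`, `p_perm`, `nperm`,
#'   `n_null_same_sign` (nulls sharing the observed sign, the denominator
#'   basis of `p_perm`), `leading_edge_size`, plus a `leading_edge`
#'   list-column.
#' @export
gsea_preranked <- function(ranked, gene_sets, nperm = 10000L, seed = 1L,
                           weight = 1) {
  stopifnot(nperm >= 1L, is.list(gene_sets), length(gene_sets) > 0L)
  n <- nrow(ranked)
  absw <- abs(ranked$score)^weight
  rows <- withr::with_seed(as.integer(seed), lapply(names(gene_sets), function(nm) {
    members <- gene_sets[[nm]]
    nh <- sum(ranked$gene_id %in% members)
    if (nh >= n) stop("gene set '", nm, "' covers the whole universe")
    obs <- enrichment_score(ranked, members, weight = weight)
    null_es <- vapply(seq_len(nperm), function(i)
      es_from_positions(sample.int(n, nh), absw, n)$es, 0)
    same <- null_es * obs$es > 0 | (obs$es == 0 & null_es == 0)
    n_same <- sum(same)
    p <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + n_same)
    nes <- if (n_same > 0) obs$es / mean(abs(null_es[same])) else NA_real_
    list(row = data.frame(set_name = nm, size = nh, es = obs$es, nes = nes,
                          p_perm = p, nperm = as.integer(nperm),
                          n_null_same_sign = n_same,
                          leading_edge_size = length(obs$leading_edge),
                          stringsAsFactors = FALSE),
         leading_edge = obs$leading_edge)
  }))
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  out$leading_edge <- lapply(rows, `[[`, "leading_edge")
  rownames(out) <- NULL
  out
}
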