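#' Network construction configuration
#'
#' Holds the thresholds of the network stage: the FDR significance cutoff
#' `alpha` (strict `fdr < alpha`), the peak-association window, the
#' manually curated DIRECT edges (validated targets whose peaks fall
#' outside the window; the default list covers Ifng, Irf8 and Tbx21 for
#' JunB), and the orientation of the knockout tables. With
#' `ko_orientation = "ko_vs_wt"` (the default) a negative log2FC means the
#' gene went down when the TF was knocked out, i.e. the TF activates it.
#'
#' @param alpha FDR threshold, strict, default 0.05.
#' @param window association window in bases, default 5000.
#' @param manual_direct named list: TF -> gene_ids forced DIRECT.
#' @param ko_orientation `"ko_vs_wt"` or `"wt_vs_ko"`; the latter flips
#'   log2FC signs on ingestion.
#' @return a `network_config` list.
#' @export
network_config <- function(alpha = 0.05, window = 5000L,
                           manual_direct = list(JunB = c("Ifng", "Irf8", "Tbx21")),
                           ko_orientation = c("ko_vs_wt", "wt_vs_ko")) {
  stopifnot(alpha > 0, alpha < 1, window >= 0)
  structure(list(alpha = alpha, window = as.integer(window),
                 manual_direct = manual_direct,
                 ko_orientation = match.arg(ko_orientation)),
            class = "network_config")
}

#' Classify one gene of a knockout contrast as a network edge
#'
#' Rule set: a gene enters the network iff `fdr < alpha` (strict). Mode is
#' ACT when expression decreased in the knockout (`log2fc < 0` under
#' KO-vs-WT orientation), REP when it increased. Directness is DIRECT iff
#' at least one ChIP-seq peak summit lies within the window
#' (`n_proximal_peaks >= 1`) or the edge is manually curated. A
#' significant gene with log2FC exactly 0 has no defined mode and is
#' excluded with a warning.
#'
#' @param tf TF name.
#' @param gene_id gene id.
#' @param log2fc,fdr knockout-contrast statistics (KO-vs-WT orientation).
#' @param n_proximal_peaks number of associated peaks for (tf, gene).
#' @param config a [network_config()].
#' @param manual force-DIRECT flag.
#' @return one-row edge data.frame, or `NULL` when not significant.
#' @export
classify_target <- function(tf, gene_id, log2fc, fdr, n_proximal_peaks,
                            config = network_config(), manual = FALSE) {
  if (!(fdr < config$alpha)) return(NULL)
  if (log2fc == 0) {
    warning("gene ", gene_id, " significant with log2FC == 0; mode undefined, excluded")
    return(NULL)
  }
  data.frame(
    tf = tf, gene_id = gene_id,
    directness = if (n_proximal_peaks >= 1L || manual) "DIRECT" else "INDIRECT",
    mode = if (log2fc < 0) "ACT" else "REP",
    kd_log2fc = log2fc, kd_fdr = fdr,
    n_peaks = as.integer(n_proximal_peaks),
    manual_flag = as.logical(manual),
    stringsAsFactors = FALSE)
}

#' Build the TF -> gene regulatory network
#'
#' Integrates per-TF knockout DE tables with per-TF peak-gene
#' associations: every significantly differential gene (FDR < alpha)
#' becomes one edge per TF, DIRECT when it has >= 1 proximal peak (or is
#' manually curated), ACT/REP by the sign of its knockout log2FC. One
#' edge per (tf, gene) regardless of peak count; the count is kept in
#' `n_peaks`.
#'
#' @param de_tables named list (TF -> knockout DE data.frame).
#' @param associations named list (TF -> [map_peaks_to_genes()] result);
#'   TFs may be absent or empty (no ChIP data -> all INDIRECT).
#' @param config a [network_config()].
#' @return a `regulatory_network`: list with `edges` (sorted by
#'   `(tf, gene_id)`) and `nodes` (annotations, filled by
#'   [annotate_nodes()]).
#' @export
build_network <- function(de_tables, associations = list(),
                          config = network_config()) {
  stopifnot(is.list(de_tables), length(names(de_tables)) == length(de_tables))
  orphan <- setdiff(names(associations), names(de_tables))
  if (length(orphan))
    stop("associations provided for TF(s) without a DE table: ",
         paste(orphan, collapse = ", "))
  edge_list <- lapply(names(de_tables), function(tf) {
    de <- de_tables[[tf]]
    validate_de_table(de)
    if (config$ko_orientation == "wt_vs_ko") de$log2fc <- -de$log2fc
    sig <- de[de$fdr < config$alpha, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    zero <- sig$log2fc == 0
    if (any(zero)) {
      warning(sum(zero), " significant gene(s) with log2FC == 0 excluded for TF ",
              tf, " (mode undefined)")
      sig <- sig[!zero, , drop = FALSE]
    }
    if (!nrow(sig)) return(NULL)
    assoc <- associations[[tf]]
    n_peaks <- if (is.null(assoc) || !nrow(assoc)) {
      stats::setNames(integer(0), character(0))
    } else {
      tab <- table(assoc$gene_id)
      stats::setNames(as.integer(tab), names(tab))
    }
    np <- unname(n_peaks[sig$gene_id])
    np[is.na(np)] <- 0L
    manual <- sig$gene_id %in% config$manual_direct[[tf]]
    data.frame(
      tf = tf, gene_id = sig$gene_id,
      directness = ifelse(np >= 1L | manual, "DIRECT", "INDIRECT"),
      mode = ifelse(sig$log2fc < 0, "ACT", "REP"),
      kd_log2fc = sig$log2fc, kd_fdr = sig$fdr,
      n_peaks = as.integer(np), manual_flag = manual,
      stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges))
    edges <- data.frame(tf = character(), gene_id = character(),
                        directness = character(), mode = character(),
                        kd_log2fc = double(), kd_fdr = double(),
                        n_peaks = integer(), manual_flag = logical(),
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(edges = edges, nodes = NULL),
                   class = "regulatory_network")
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", nrow(x$edges), "edges,",
      length(unique(x$edges$gene_id)), "genes,",
      length(unique(x$edges$tf)), "TFs\n")
  if (nrow(x$edges)) {
    tab <- table(x$edges$tf, paste(x$edges$directness, x$edges$mode))
    print(tab)
  }
  invisible(x)
}

#' Quadrant concordance between two DE contrasts
#'
#' Restricted to genes significant (FDR < alpha) in BOTH tables — the
#' "red" co-significant genes — split into four sign quadrants of
#' (log2FC A, log2FC B). Concordance is the fraction regulated in the
#' same direction (both up + both down). Genes with a zero log2FC in
#' either table are excluded so the four fractions sum to one.
#'
#' @param de_a,de_b DE data.frames sharing a gene namespace.
#' @param alpha FDR threshold, strict, default 0.05.
#' @return list: `fractions` (named: `both_up`, `both_down`, `a_up_b_down`,
#'   `a_down_b_up`), `concordance`, `n` (co-significant genes used), and
#'   `genes` (per-quadrant id lists).
#' @export
quadrant_concordance <- function(de_a, de_b, alpha = 0.05) {
  sig_a <- de_a[de_a$fdr < alpha, c("gene_id", "log2fc")]
  sig_b <- de_b[de_b$fdr < alpha, c("gene_id", "log2fc")]
  m <- merge(sig_a, sig_b, by = "gene_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no co-significant genes between the two contrasts")
  m <- m[m$log2fc_a != 0 & m$log2fc_b != 0, , drop = FALSE]
  if (!nrow(m)) stop("no co-significant genes with nonzero log2FC")
  up_a <- m$log2fc_a > 0
  up_b <- m$log2fc_b > 0
  q <- list(both_up = m$gene_id[up_a & up_b],
            both_down = m$gene_id[!up_a & !up_b],
            a_up_b_down = m$gene_id[up_a & !up_b],
            a_down_b_up = m$gene_id[!up_a & up_b])
  fr <- vapply(q, length, 1L) / nrow(m)
  list(fractions = fr,
       concordance = unname(fr["both_up"] + fr["both_down"]),
       n = nrow(m), genes = q)
}

#' Group the common targets of two TFs by cooperative-regulation mode
#'
#' For every gene with edges from both TFs, the mode combination
#' `<modeA>:<modeB>` — one of ACT:ACT, ACT:REP, REP:ACT, REP:REP —
#' describes how the pair co-regulates it.
#'
#' @param network a `regulatory_network`.
#' @param tf_a,tf_b TF names present in the network.
#' @return data.frame with `gene_id`, `mode_a`, `mode_b`, `group`.
#' @export
pair_mode_groups <- function(network, tf_a, tf_b) {
  e <- network$edges
  for (tf in c(tf_a, tf_b))
    if (!tf %in% e$tf) stop("TF not present in network: ", tf)
  ea <- e[e$tf == tf_a, c("gene_id", "mode")]
  eb <- e[e$tf == tf_b, c("gene_id", "mode")]
  m <- merge(ea, eb, by = "gene_id", suffixes = c("_a", "_b"))
  m$group <- paste(m$mode_a, m$mode_b, sep = ":")
  m <- m[order(m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# order-statistics summary used by the boxplot-style outputs
fc_distribution_summary <- function(values) {
  if (!length(values))
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                values = numeric(0), empty = TRUE))
  list(n = length(values), median = stats::median(values),
       q1 = unname(stats::quantile(values, 0.25, type = 7)),
       q3 = unname(stats::quantile(values, 0.75, type = 7)),
       values = sort(values), empty = FALSE)
}

#' Net effect of a TF pair on subset-preferential expression
#'
#' For each of the four cooperative-regulation groups, the distribution of
#' subset-contrast log2FC (e.g. Th17 vs Th0) over the group members that
#' are significantly differential in that contrast (FDR < alpha) — the
#' boxplot behind the pair-mode net-effect figure. Empty groups are kept
#' and flagged.
#'
#' @param groups a [pair_mode_groups()] result.
#' @param subset_de subset-contrast DE data.frame.
#' @param alpha FDR threshold, strict.
#' @return named list over ACT:ACT, ACT:REP, REP:ACT, REP:REP with `n`,
#'   `median`, `q1`, `q3`, `values`, `empty`.
#' @export
net_effect_summary <- function(groups, subset_de, alpha = 0.05) {
  sig <- subset_de[subset_de$fdr < alpha, c("gene_id", "log2fc")]
  all_groups <- c("ACT:ACT", "ACT:REP", "REP:ACT", "REP:REP")
  out <- lapply(all_groups, function(g) {
    members <- groups$gene_id[groups$group == g]
    fc_distribution_summary(sig$log2fc[sig$gene_id %in% members])
  })
  names(out) <- all_groups
  out
}

#' Subset preference of one TF's activation or repression targets
#'
#' The distribution of subset-contrast log2FC (e.g. Th17 vs Th1) over the
#' TF's targets of the given mode that are significant in that contrast.
#'
#' @param network a `regulatory_network`.
#' @param tf TF name.
#' @param mode `"ACT"` or `"REP"`.
#' @param subset_de subset-contrast DE data.frame.
#' @param alpha FDR threshold, strict.
#' @return a distribution summary as in [net_effect_summary()].
#' @export
subset_preference <- function(network, tf, mode = c("ACT", "REP"),
                              subset_de, alpha = 0.05) {
  mode <- match.arg(mode)
  if (!tf %in% network$edges$tf) stop("TF not present in network: ", tf)
  targets <- network$edges$gene_id[network$edges$tf == tf &
                                     network$edges$mode == mode]
  sig <- subset_de[subset_de$fdr < alpha, c("gene_id", "log2fc")]
  fc_distribution_summary(sig$log2fc[sig$gene_id %in% targets])
}

#' Annotate network nodes with subset-contrast differential expression
#'
#' Each gene appearing in the edge set gets its subset log2FC when it is
#' significant (FDR < alpha) in the subset contrast, and an explicit
#' not-significant marker otherwise. The edge set is never altered.
#'
#' @param network a `regulatory_network`.
#' @param subset_de subset-contrast DE data.frame.
#' @param alpha FDR threshold, strict.
#' @return the network with `nodes` filled (`gene_id`, `subset_log2fc`,
#'   `subset_significant`, `subset_contrast`).
#' @export
annotate_nodes <- function(network, subset_de, alpha = 0.05) {
  genes <- sort(unique(network$edges$gene_id))
  sig <- subset_de[subset_de$fdr < alpha, , drop = FALSE]
  idx <- match(genes, sig$gene_id)
  network$nodes <- data.frame(
    gene_id = genes,
    subset_log2fc = ifelse(is.na(idx), NA_real_, sig$log2fc[idx]),
    subset_significant = !is.na(idx),
    subset_contrast = if (nrow(subset_de)) subset_de$contrast[1L] else NA_character_,
    stringsAsFactors = FALSE)
  network
}
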