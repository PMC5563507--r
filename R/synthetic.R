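#' Specification of a planted regulatory-network benchmark
#'
#' Defines the study conditions the generator emulates: a panel of TFs,
#' each with a planted set of target genes (DIRECT at rate `frac_direct`,
#' activated at rate `frac_act`), knockout DE tables in which true
#' targets receive Beta(`target_p_shape`, 1) p-values (a < 1 concentrates
#' near 0; a = 1 is the null) and signed lognormal effect sizes, while
#' non-targets are null (p ~ Uniform(0,1), log2FC ~ Normal(0, 0.1)).
#' Gene bodies are placed with >= 2*window gaps so every generated peak
#' summit maps to at most one gene and recovery metrics stay
#' interpretable. Peaks of DIRECT edges can be dropped at rate
#' `peak_dropout`; decoy peaks land beyond the window of any gene.
#'
#' @param seed RNG seed; all outputs are byte-reproducible given it.
#' @param n_genes number of genes.
#' @param n_chroms chromosomes of `chrom_length` bases each.
#' @param chrom_length chromosome length in bases.
#' @param tf_panel TF names.
#' @param n_targets planted targets per TF.
#' @param frac_direct probability a planted edge is DIRECT.
#' @param frac_act probability a planted edge is an activation target.
#' @param effect_meanlog,effect_sdlog lognormal parameters of |log2FC|
#'   for true targets (defaults centre the magnitude near 2).
#' @param target_p_shape Beta shape `a` for true-target p-values.
#' @param peak_dropout per-peak independent drop probability.
#' @param peaks_per_edge peaks generated per DIRECT edge.
#' @param decoy_peaks_per_tf decoy peaks per TF, placed beyond the
#'   window of every gene body.
#' @param window association window (must match the analysis setting).
#' @param pair_mode_table optional data.frame (`tf_a`, `tf_b`, `mode_a`,
#'   `mode_b`, `n`) planting shared targets with fixed mode combinations.
#' @param signature_overlap fraction of ACT (REP) targets planted as
#'   subset-upregulated (-downregulated) in the subset contrasts.
#' @param gene_length_range min/max gene-body length in bases.
#' @return a `truth_spec` list.
#' @export
truth_spec <- function(seed = 42L, n_genes = 200L, n_chroms = 3L,
                       chrom_length = 3e6, tf_panel = c("JunB", "BATF", "Fosl2"),
                       n_targets = 60L, frac_direct = 0.5, frac_act = 0.5,
                       effect_meanlog = 0.7, effect_sdlog = 0.5,
                       target_p_shape = 0.01, peak_dropout = 0,
                       peaks_per_edge = 1L, decoy_peaks_per_tf = 50L,
                       window = 5000L, pair_mode_table = NULL,
                       signature_overlap = 0.8,
                       gene_length_range = c(2000L, 20000L)) {
  stopifnot(n_targets <= n_genes,
            frac_direct >= 0, frac_direct <= 1,
            frac_act >= 0, frac_act <= 1,
            peak_dropout >= 0, peak_dropout <= 1,
            signature_overlap >= 0, signature_overlap <= 1,
            target_p_shape > 0, window >= 0, peaks_per_edge >= 1)
  structure(as.list(environment()), class = "truth_spec")
}

# place gene bodies uniformly with >= 2*window inter-gene gaps
place_gene_bodies <- function(spec) {
  per_chrom <- diff(round(seq(0, spec$n_genes, length.out = spec$n_chroms + 1)))
  gap_min <- 2L * spec$window
  out <- vector("list", spec$n_chroms)
  gi <- 0L
  for (ci in seq_len(spec$n_chroms)) {
    g <- per_chrom[ci]
    if (g == 0L) next
    len <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], g,
                  replace = TRUE)
    slack <- spec$chrom_length - sum(len) - (g + 1L) * gap_min
    if (slack < 0)
      stop("genes cannot be placed at the requested density; ",
           "increase chrom_length or reduce n_genes")
    cuts <- sort(stats::runif(g + 1L))
    extra <- floor(slack * cuts / sum(cuts))
    start <- integer(g)
    x <- 0L
    for (i in seq_len(g)) {
      x <- x + gap_min + extra[i]
      start[i] <- x
      x <- x + len[i]
    }
    out[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", gi + seq_len(g)),
      chrom = sprintf("chr%d", ci),
      start = start, end = start + len,
      strand = sample(c("+", "-"), g, replace = TRUE),
      stringsAsFactors = FALSE)
    gi <- gi + g
  }
  genes <- do.call(rbind, out)
  genes$symbol <- genes$gene_id
  genes[, c("gene_id", "symbol", "chrom", "start", "end", "strand")]
}

#' Generate a planted ground-truth network
#'
#' Places non-overlapping gene bodies (gaps >= 2*window), samples each
#' TF's target set with planted directness and mode, plants optional
#' TF-pair mode combinations on fresh shared targets, and marks
#' signature members for the subset contrasts ("Th17_vs_Th0",
#' "Th17_vs_Th1"): activation targets as subset-upregulated, repression
#' targets as subset-downregulated, each at rate `signature_overlap`.
#'
#' @param spec a [truth_spec()].
#' @return a `synthetic_truth` list: `gene_models`, `edges` (planted
#'   `tf`, `gene_id`, `directness`, `mode`, `log2fc`),
#'   `signature_members` (contrast -> list(up, down)), `spec`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  withr::with_seed(as.integer(spec$seed), {
    genes <- place_gene_bodies(spec)
    taken <- character(0)
    edges <- lapply(spec$tf_panel, function(tf) {
      if (spec$n_targets == 0L) return(NULL)
      gid <- sample(genes$gene_id, spec$n_targets)
      k <- length(gid)
      data.frame(
        tf = tf, gene_id = gid,
        directness = ifelse(stats::runif(k) < spec$frac_direct,
                            "DIRECT", "INDIRECT"),
        mode = ifelse(stats::runif(k) < spec$frac_act, "ACT", "REP"),
        log2fc = NA_real_, stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, edges)
    if (is.null(edges))
      edges <- data.frame(tf = character(), gene_id = character(),
                          directness = character(), mode = character(),
                          log2fc = double(), stringsAsFactors = FALSE)
    if (!is.null(spec$pair_mode_table)) {
      pm <- spec$pair_mode_table
      for (i in seq_len(nrow(pm))) {
        pool <- setdiff(genes$gene_id, edges$gene_id)
        if (length(pool) < pm$n[i])
          stop("not enough untargeted genes to plant pair modes")
        gid <- sample(pool, pm$n[i])
        for (side in c("a", "b")) {
          k <- length(gid)
          edges <- rbind(edges, data.frame(
            tf = pm[[paste0("tf_", side)]][i], gene_id = gid,
            directness = ifelse(stats::runif(k) < spec$frac_direct,
                                "DIRECT", "INDIRECT"),
            mode = pm[[paste0("mode_", side)]][i],
            log2fc = NA_real_, stringsAsFactors = FALSE))
        }
      }
    }
    # planted knockout effect: ACT targets go down in the KO
    mag <- stats::rlnorm(nrow(edges), spec$effect_meanlog, spec$effect_sdlog)
    edges$log2fc <- ifelse(edges$mode == "ACT", -mag, mag)
    edges <- edges[order(edges$tf, edges$gene_id), , drop = FALSE]
    rownames(edges) <- NULL

    pick <- function(ids) {
      ids <- unique(ids)
      if (!length(ids)) return(character(0))
      sort(ids[stats::runif(length(ids)) < spec$signature_overlap])
    }
    sig <- list(
      Th17_vs_Th0 = list(up = pick(edges$gene_id[edges$mode == "ACT"]),
                         down = pick(edges$gene_id[edges$mode == "REP"])),
      Th17_vs_Th1 = list(up = pick(edges$gene_id[edges$mode == "ACT"]),
                         down = pick(edges$gene_id[edges$mode == "REP"])))
    structure(list(gene_models = genes, edges = edges,
                   signature_members = sig, spec = spec),
              class = "synthetic_truth")
  })
}

# uniform sample of `n` summit positions from the complement of the
# per-gene exclusion zones [start - w, end + w - 1] on each chromosome
sample_decoy_summits <- function(genes, spec, n) {
  if (n == 0L) return(NULL)
  zones <- data.frame(chrom = genes$chrom,
                      start = pmax(genes$start - spec$window, 0),
                      end = genes$end + spec$window,
                      stringsAsFactors = FALSE)
  safe <- do.call(rbind, lapply(sprintf("chr%d", seq_len(spec$n_chroms)),
    function(ch) {
      z <- merge_intervals(zones[zones$chrom == ch, , drop = FALSE])
      edges <- c(1000, rbind(z$start, z$end), spec$chrom_length - 1000)
      s <- edges[seq(1, length(edges), by = 2)]
      e <- edges[seq(2, length(edges), by = 2)]
      keep <- e - s > 600  # room for a peak interval around the summit
      data.frame(chrom = ch, start = s[keep] + 300, end = e[keep] - 300,
                 stringsAsFactors = FALSE)
    }))
  w <- safe$end - safe$start
  iv <- sample.int(nrow(safe), n, replace = TRUE, prob = w)
  data.frame(chrom = safe$chrom[iv],
             summit = safe$start[iv] + floor(stats::runif(n) * w[iv]),
             stringsAsFactors = FALSE)
}

#' Generate per-TF peak sets for a planted truth
#'
#' Every DIRECT edge receives `peaks_per_edge` peaks whose summits fall
#' uniformly in `[body.start - window, body.end + window - 1]` (so the
#' summit-association rule recovers the edge); each peak is then dropped
#' independently at rate `peak_dropout`. Decoy peaks get summits beyond
#' the window of every gene body, so they can never create a DIRECT
#' call.
#'
#' @param truth a [generate_truth()] result.
#' @param spec the same [truth_spec()].
#' @return named list (TF -> peak data.frame, narrowPeak-writable).
#' @export
generate_peaks <- function(truth, spec = truth$spec) {
  genes <- truth$gene_models
  withr::with_seed(as.integer(spec$seed) + 1L, {
    out <- lapply(spec$tf_panel, function(tf) {
      de <- truth$edges[truth$edges$tf == tf &
                          truth$edges$directness == "DIRECT", , drop = FALSE]
      rows <- de[rep(seq_len(nrow(de)), each = spec$peaks_per_edge), ,
                 drop = FALSE]
      gi <- match(rows$gene_id, genes$gene_id)
      n_true <- nrow(rows)
      if (n_true) {
        lo <- genes$start[gi] - spec$window
        hi <- genes$end[gi] + spec$window - 1L
        summit <- lo + floor(stats::runif(n_true) * (hi - lo + 1L))
        chrom <- genes$chrom[gi]
      } else {
        summit <- integer(0); chrom <- character(0)
      }
      decoys <- sample_decoy_summits(genes, spec, spec$decoy_peaks_per_tf)
      if (!is.null(decoys)) {
        chrom <- c(chrom, decoys$chrom)
        summit <- c(summit, decoys$summit)
      }
      n <- length(summit)
      if (!n) return(NULL)
      w <- sample(200:500, n, replace = TRUE)
      start <- pmax(summit - w %/% 2L, 0L)
      end <- summit + (w - w %/% 2L)
      keep <- stats::runif(n) >= spec$peak_dropout
      score <- round(stats::rlnorm(n, 2, 0.5), 3)
      peaks <- data.frame(
        chrom = chrom, start = as.integer(start), end = as.integer(end),
        peak_id = sprintf("%s_peak_%04d", tf, seq_len(n)),
        score = score, summit = as.integer(summit), source = tf,
        stringsAsFactors = FALSE)[keep, , drop = FALSE]
      rownames(peaks) <- NULL
      peaks
    })
    names(out) <- spec$tf_panel
    out
  })
}

#' Generate knockout and subset-contrast DE tables for a planted truth
#'
#' Knockout contrasts (`<TF>KO_vs_WT`): planted targets get
#' p ~ Beta(a, 1) and the planted signed log2FC; all other genes are
#' null. Subset contrasts (`Th17_vs_Th0`, `Th17_vs_Th1`): planted
#' signature members get Beta(a, 1) p-values with positive (up members)
#' or negative (down members) lognormal log2FC. Every FDR column is
#' [bh_adjust()] of the table's p column.
#'
#' @param truth a [generate_truth()] result.
#' @param spec the same [truth_spec()].
#' @return named list (contrast -> DE data.frame).
#' @export
generate_de_tables <- function(truth, spec = truth$spec) {
  genes <- truth$gene_models$gene_id
  n <- length(genes)
  withr::with_seed(as.integer(spec$seed) + 2L, {
    null_table <- function(contrast) {
      data.frame(gene_id = genes,
                 log2fc = stats::rnorm(n, 0, 0.1),
                 pvalue = stats::runif(n),
                 fdr = NA_real_, contrast = contrast,
                 stringsAsFactors = FALSE)
    }
    out <- list()
    for (tf in spec$tf_panel) {
      de <- null_table(sprintf("%sKO_vs_WT", tf))
      e <- truth$edges[truth$edges$tf == tf, , drop = FALSE]
      idx <- match(e$gene_id, genes)
      de$pvalue[idx] <- stats::rbeta(nrow(e), spec$target_p_shape, 1)
      de$log2fc[idx] <- e$log2fc
      de$fdr <- bh_adjust(de$pvalue)
      out[[de$contrast[1L]]] <- de
    }
    for (contrast in names(truth$signature_members)) {
      de <- null_table(contrast)
      sm <- truth$signature_members[[contrast]]
      for (dir in c("up", "down")) {
        idx <- match(sm[[dir]], genes)
        if (!length(idx)) next
        de$pvalue[idx] <- stats::rbeta(length(idx), spec$target_p_shape, 1)
        mag <- stats::rlnorm(length(idx), spec$effect_meanlog, spec$effect_sdlog)
        de$log2fc[idx] <- if (dir == "up") mag else -mag
      }
      de$fdr <- bh_adjust(de$pvalue)
      out[[contrast]] <- de
    }
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_truth()], [generate_peaks()]
#' and [generate_de_tables()] for one spec.
#'
#' @param spec a [truth_spec()].
#' @return list: `truth`, `peaks`, `de_tables`, `spec`.
#' @export
generate_dataset <- function(spec = truth_spec()) {
  truth <- generate_truth(spec)
  list(truth = truth, peaks = generate_peaks(truth, spec),
       de_tables = generate_de_tables(truth, spec), spec = spec)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits per-TF narrowPeak files, a BED6 gene annotation, per-contrast
#' DE TSVs, and a `truth.json` with the planted edges and signature
#' members, so the dataset can be consumed through the ordinary readers.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed6(dataset$truth$gene_models, file.path(dir, "genes.bed"))
  for (tf in names(dataset$peaks)) {
    p <- dataset$peaks[[tf]]
    if (!is.null(p))
      write_narrowpeak(p, file.path(dir, sprintf("%s.narrowPeak", tf)))
  }
  for (contrast in names(dataset$de_tables))
    write_de_table(dataset$de_tables[[contrast]],
                   file.path(dir, sprintf("de_%s.tsv", contrast)))
  jsonlite::write_json(
    list(edges = dataset$truth$edges,
         signature_members = dataset$truth$signature_members,
         seed = dataset$spec$seed),
    file.path(dir, "truth.json"), digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Edge-recovery metrics of an inferred network against planted truth
#'
#' Standard precision / recall / F1 on (tf, gene) edge presence, plus
#' mode and directness accuracy over the true-positive edges; reported
#' pooled and per TF. An empty inferred network has undefined precision,
#' reported as NaN with `degenerate = TRUE`.
#'
#' @param network a `regulatory_network`.
#' @param truth a [generate_truth()] result.
#' @return list with `pooled` and `per_tf` metric lists.
#' @export
recovery_metrics <- function(network, truth) {
  score <- function(inf, tru) {
    key_i <- paste(inf$tf, inf$gene_id)
    key_t <- paste(tru$tf, tru$gene_id)
    tp_keys <- intersect(key_i, key_t)
    tp <- length(tp_keys)
    prec <- if (nrow(inf) == 0L) NaN else tp / nrow(inf)
    rec <- if (nrow(tru) == 0L) NaN else tp / nrow(tru)
    f1 <- if (is.nan(prec) || is.nan(rec) || (prec + rec) == 0) NaN
          else 2 * prec * rec / (prec + rec)
    ii <- match(tp_keys, key_i)
    ti <- match(tp_keys, key_t)
    list(n_inferred = nrow(inf), n_truth = nrow(tru), tp = tp,
         precision = prec, recall = rec, f1 = f1,
         mode_accuracy = if (tp) mean(inf$mode[ii] == tru$mode[ti]) else NaN,
         directness_accuracy = if (tp)
           mean(inf$directness[ii] == tru$directness[ti]) else NaN,
         degenerate = nrow(inf) == 0L)
  }
  per_tf <- lapply(unique(truth$edges$tf), function(tf)
    score(network$edges[network$edges$tf == tf, , drop = FALSE],
          truth$edges[truth$edges$tf == tf, , drop = FALSE]))
  names(per_tf) <- unique(truth$edges$tf)
  list(pooled = score(network$edges, truth$edges), per_tf = per_tf)
}

#' Generate a pair of DE tables with planted sign concordance
#'
#' All genes are significant in both tables; the sign of table B's
#' log2FC agrees with table A's with probability `concordance`.
#' Benchmarks [quadrant_concordance()].
#'
#' @param n_genes co-significant genes.
#' @param concordance planted sign-agreement probability.
#' @param seed RNG seed.
#' @return list: `de_a`, `de_b`, `planted_agreement` (realized fraction).
#' @export
generate_de_pair <- function(n_genes = 1000L, concordance = 0.9, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    gid <- sprintf("g%04d", seq_len(n_genes))
    sign_a <- sample(c(-1, 1), n_genes, replace = TRUE)
    agree <- stats::runif(n_genes) < concordance
    sign_b <- ifelse(agree, sign_a, -sign_a)
    mk <- function(sgn, contrast) {
      p <- stats::runif(n_genes, 0, 1e-6)
      data.frame(gene_id = gid,
                 log2fc = sgn * stats::rlnorm(n_genes, 0.5, 0.4),
                 pvalue = p, fdr = bh_adjust(p), contrast = contrast,
                 stringsAsFactors = FALSE)
    }
    list(de_a = mk(sign_a, "A"), de_b = mk(sign_b, "B"),
         planted_agreement = mean(agree))
  })
}

#' Generate an occupancy-clustering benchmark with planted archetypes
#'
#' Eight archetype occupancy patterns over a 7-TF panel, constructed
#' from 3 pattern bits duplicated across paired columns plus a parity
#' bit (pairwise Hamming distance >= 3), replicated to `n_modules` rows
#' with independent per-bit flip noise. Benchmarks [cluster_occupancy()].
#'
#' @param n_modules rows, default 4000.
#' @param flip_rate independent bit-flip probability, default 0.05.
#' @param seed RNG seed.
#' @return list: `occ` (0/1 matrix), `labels` (planted archetype of each
#'   row), `archetypes`.
#' @export
generate_occupancy_benchmark <- function(n_modules = 4000L, flip_rate = 0.05,
                                         seed = 1L) {
  bits <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  arch <- cbind(bits[, 1], bits[, 1], bits[, 2], bits[, 2],
                bits[, 3], bits[, 3], (bits[, 1] + bits[, 2] + bits[, 3]) %% 2)
  colnames(arch) <- c("JunB", "JunD", "BATF", "Fosl2", "IRF4", "p300", "RORgt")
  withr::with_seed(as.integer(seed), {
    labels <- sample(rep_len(seq_len(nrow(arch)), n_modules))
    occ <- arch[labels, , drop = FALSE]
    flips <- matrix(stats::runif(length(occ)) < flip_rate, nrow(occ))
    occ[flips] <- 1L - occ[flips]
    rownames(occ) <- NULL
    list(occ = occ, labels = labels, archetypes = arch)
  })
}

#' Plant differential-binding statistics on a set of regions
#'
#' Emulates a DiffBind-style differential-occupancy table over given
#' regions: a planted fraction is differential (Beta(0.001, 1) p-values,
#' signed lognormal log2FC), the rest null; FDR is [bh_adjust()] of p.
#' Used to exercise [annotate_cobound()] and [diff_summary()].
#'
#' @param regions interval data.frame (`chrom`, `start`, `end`).
#' @param frac_diff fraction of regions planted as differential.
#' @param effect_meanlog,effect_sdlog lognormal |log2FC| parameters.
#' @param seed RNG seed.
#' @return `regions` with `log2fc`, `pvalue`, `fdr` columns appended.
#' @export
generate_diff_region_stats <- function(regions, frac_diff = 0.25,
                                       effect_meanlog = 0.9,
                                       effect_sdlog = 0.4, seed = 1L) {
  n <- nrow(regions)
  withr::with_seed(as.integer(seed), {
    diff <- stats::runif(n) < frac_diff
    regions$log2fc <- stats::rnorm(n, 0, 0.3)
    regions$pvalue <- stats::runif(n)
    k <- sum(diff)
    if (k) {
      regions$log2fc[diff] <- sample(c(-1, 1), k, replace = TRUE) *
        stats::rlnorm(k, effect_meanlog, effect_sdlog)
      regions$pvalue[diff] <- stats::rbeta(k, 0.001, 1)
    }
    regions$fdr <- bh_adjust(regions$pvalue)
    regions
  })
}
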