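#' Pipeline configuration
#'
#' Collects every input path and threshold of the full analysis. All
#' defaults are the analysis-wide conventions: alpha = 0.05 (strict FDR),
#' window = 5000 bp, 8 occupancy clusters, top-100 signatures, 10,000
#' gene-set permutations with the weighted statistic, and volcano p caps
#' of 1e-30 (expression) and 1e-25 (differential binding).
#'
#' @param peak_paths named character vector / list, TF -> narrowPeak path.
#' @param de_paths named character vector / list, contrast -> DE TSV path.
#' @param annotation_path gene annotation (BED6 or GTF).
#' @param annotation_dialect `"bed6"` or `"gtf"`.
#' @param ko_contrasts named character vector, TF -> knockout contrast
#'   name (must be names of `de_paths`).
#' @param subset_contrasts contrast names used for node annotation,
#'   net-effect summaries and signatures.
#' @param alpha,window,manual_direct see [network_config()].
#' @param pcrm_k,pcrm_seed occupancy clustering parameters.
#' @param signature_n signature size.
#' @param gsea_nperm,gsea_seed,gsea_weight GSEA parameters.
#' @param gsea_rank_contrast contrast ranked for GSEA (default: the
#'   first knockout contrast).
#' @param volcano_p_cap_de,volcano_p_cap_diff volcano p-value caps.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(peak_paths, de_paths, annotation_path,
                            annotation_dialect = "bed6", ko_contrasts,
                            subset_contrasts = character(0),
                            alpha = 0.05, window = 5000L,
                            manual_direct = list(JunB = c("Ifng", "Irf8", "Tbx21")),
                            pcrm_k = 8L, pcrm_seed = 1L,
                            signature_n = 100L, gsea_nperm = 10000L,
                            gsea_seed = 1L, gsea_weight = 1,
                            gsea_rank_contrast = NULL,
                            volcano_p_cap_de = 1e-30,
                            volcano_p_cap_diff = 1e-25,
                            out_dir = "results/pipeline") {
  cfg <- as.list(environment())
  if (is.null(cfg$gsea_rank_contrast))
    cfg$gsea_rank_contrast <- unname(ko_contrasts[1L])
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(unlist(config$peak_paths), unlist(config$de_paths),
             config$annotation_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("pipeline input file(s) not found: ", paste(missing, collapse = ", "))
  bad <- setdiff(unname(unlist(config$ko_contrasts)), names(config$de_paths))
  if (length(bad))
    stop("ko_contrasts name DE tables that are not configured: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(config$subset_contrasts, names(config$de_paths))
  if (length(bad))
    stop("subset_contrasts name DE tables that are not configured: ",
         paste(bad, collapse = ", "))
  invisible(config)
}

#' Plot-ready volcano export of a DE table
#'
#' One row per input gene: log2FC, -log10(p) with the p-value capped
#' (default 1e-30), and a significance flag (FDR < alpha). Trendline
#' parameters (fold change 1.5, p = 0.01) are returned as metadata for
#' the plotting layer.
#'
#' @param de_table DE data.frame.
#' @param alpha FDR threshold for the significance flag.
#' @param p_cap p-value floor before the -log10 transform.
#' @return list: `table` (`gene_id`, `log2fc`, `minus_log10_p`,
#'   `significant`), `trendlines` (`fold_change`, `pvalue`).
#' @export
make_volcano_export <- function(de_table, alpha = 0.05, p_cap = 1e-30) {
  list(table = data.frame(
         gene_id = de_table$gene_id,
         log2fc = de_table$log2fc,
         minus_log10_p = -log10(pmax(de_table$pvalue, p_cap)),
         significant = de_table$fdr < alpha,
         stringsAsFactors = FALSE),
       trendlines = list(fold_change = 1.5, pvalue = 0.01))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: peak-gene association, network construction with
#' node annotation, quadrant / pair-mode / net-effect summaries, pCRM
#' construction and occupancy clustering, signature construction with
#' pre-ranked GSEA, and volcano exports. Every output is written with
#' deterministic formatting; the returned manifest lists each file with
#' its MD5 hash, so identical inputs and configuration reproduce
#' identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest: data.frame `file`, `md5` (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  genes <- run_stage("annotation",
    read_gene_models(config$annotation_path, config$annotation_dialect))
  peaks <- run_stage("peaks", {
    p <- lapply(names(config$peak_paths), function(tf)
      read_narrowpeak(config$peak_paths[[tf]], source = tf))
    names(p) <- names(config$peak_paths)
    p
  })
  de <- run_stage("de_tables", {
    d <- lapply(names(config$de_paths), function(ct)
      read_de_table(config$de_paths[[ct]], contrast = ct))
    names(d) <- names(config$de_paths)
    d
  })

  # shared gene namespace check between annotation and DE tables
  if (!length(intersect(genes$gene_id, unique(unlist(lapply(de, `[[`, "gene_id"))))))
    stop("pipeline stage 'inputs' failed: gene annotation and DE tables share no gene ids")

  assoc <- run_stage("associations", {
    a <- lapply(names(peaks), function(tf)
      map_peaks_to_genes(peaks[[tf]], genes, window = config$window))
    names(a) <- names(peaks)
    for (tf in names(a))
      emit(write_associations(a[[tf]],
                              file.path(out, sprintf("assoc_%s.tsv", tf))))
    a
  })

  net_cfg <- network_config(alpha = config$alpha, window = config$window,
                            manual_direct = config$manual_direct)
  network <- run_stage("network", {
    ko_de <- lapply(config$ko_contrasts, function(ct) de[[ct]])
    names(ko_de) <- names(config$ko_contrasts)
    net <- build_network(ko_de, assoc[names(ko_de)], config = net_cfg)
    if (length(config$subset_contrasts))
      net <- annotate_nodes(net, de[[config$subset_contrasts[1L]]],
                            alpha = config$alpha)
    emit(write_network_table(net, file.path(out, "network_edges.tsv")))
    net
  })

  run_stage("pair_summaries", {
    tfs <- names(config$ko_contrasts)
    if (length(tfs) >= 2L && nrow(network$edges)) {
      pairs <- utils::combn(tfs, 2L, simplify = FALSE)
      summaries <- lapply(pairs, function(pr) {
        ko_a <- de[[config$ko_contrasts[[pr[1]]]]]
        ko_b <- de[[config$ko_contrasts[[pr[2]]]]]
        quad <- tryCatch(
          quadrant_concordance(ko_a, ko_b, alpha = config$alpha),
          error = function(e) list(error = conditionMessage(e)))
        groups <- pair_mode_groups(network, pr[1], pr[2])
        net_eff <- if (length(config$subset_contrasts))
          net_effect_summary(groups, de[[config$subset_contrasts[1L]]],
                             alpha = config$alpha) else NULL
        list(tf_a = pr[1], tf_b = pr[2],
             quadrant = quad[setdiff(names(quad), "genes")],
             pair_modes = as.list(table(groups$group)),
             net_effect = lapply(net_eff, function(s)
               s[c("n", "median", "q1", "q3", "empty")]))
      })
      jsonlite::write_json(summaries, file.path(out, "pair_summaries.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit(file.path(out, "pair_summaries.json"))
    }
    NULL
  })

  run_stage("pcrm", {
    nonempty <- Filter(function(p) !is.null(p) && nrow(p) > 0, peaks)
    if (length(nonempty)) {
      pcrms <- build_pcrms(nonempty)
      k <- min(config$pcrm_k, nrow(unique(
        pcrms$regions[, paste0("occ_", pcrms$tf_panel), drop = FALSE])))
      clustered <- cluster_pcrms(pcrms, k = k, seed = config$pcrm_seed)
      emit(write_pcrm_table(clustered, file.path(out, "pcrms.tsv")))
      hm <- data.frame(pcrm_id = rownames(clustered$heatmap),
                       clustered$heatmap, check.names = FALSE)
      emit(write_tsv_stable(hm, file.path(out, "pcrm_heatmap.tsv")))
    }
    NULL
  })

  run_stage("gsea", {
    if (length(config$subset_contrasts)) {
      sets <- list()
      for (ct in config$subset_contrasts)
        for (dir in c("up", "down"))
          sets[[sprintf("%s_%s", ct, dir)]] <- suppressWarnings(
            signature_from_contrast(de[[ct]], dir, n = config$signature_n))
      emit(write_gmt(sets, file.path(out, "signatures.gmt")))
      ranked <- rank_metric(de[[config$gsea_rank_contrast]])
      emit(write_rnk(ranked, file.path(out, "ranked.rnk")))
      res <- gsea_preranked(ranked, sets, nperm = config$gsea_nperm,
                            seed = config$gsea_seed, weight = config$gsea_weight)
      emit(write_tsv_stable(
        res[, c("set_name", "size", "es", "nes", "p_perm", "nperm",
                "leading_edge_size")],
        file.path(out, "enrichment.tsv")))
    }
    NULL
  })

  run_stage("volcano", {
    for (ct in names(de)) {
      v <- make_volcano_export(de[[ct]], alpha = config$alpha,
                               p_cap = config$volcano_p_cap_de)
      emit(write_tsv_stable(v$table,
                            file.path(out, sprintf("volcano_%s.tsv", ct))))
    }
    NULL
  })

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, pretty = TRUE)
  manifest
}
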