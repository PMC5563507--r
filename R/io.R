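#' Read a narrowPeak or BED peak file
#'
#' narrowPeak is BED6+4; the summit is `start + column 10` (the MACS2
#' summit offset). An offset of -1 (summit not called) and plain BED
#' input fall back to the interval midpoint, `floor((start + end) / 2)`.
#' Column 9 (-log10 q-value) is kept as the peak score; input peaks are
#' assumed pre-filtered by the caller and are not re-thresholded.
#'
#' @param path narrowPeak or BED file.
#' @param source TF / condition label attached to every peak; defaults to
#'   the file name without extension.
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score`, `summit`, `source`.
#' @export
read_narrowpeak <- function(path, source = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (is.null(source))
    source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), score = double(),
                      summit = integer(), source = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L)
    stop("fewer than 3 columns at line ", which.min(lengths(fields)))

  parse_int <- function(v, col, what) {
    out <- suppressWarnings(as.integer(v))
    bad <- which(is.na(out))
    if (length(bad))
      stop("non-integer ", what, " at line ", bad[1L])
    out
  }
  start <- parse_int(vapply(fields, `[`, "", 2L), 2L, "start")
  end <- parse_int(vapply(fields, `[`, "", 3L), 3L, "end")
  bad <- which(start >= end)
  if (length(bad)) stop("start >= end at line ", bad[1L])
  chrom <- vapply(fields, `[`, "", 1L)

  n <- length(lines)
  peak_id <- if (ncol_min >= 4L) vapply(fields, `[`, "", 4L)
             else sprintf("%s_peak_%d", source, seq_len(n))
  if (anyDuplicated(peak_id))
    stop("duplicate peak_id: ", peak_id[anyDuplicated(peak_id)])

  is_narrow <- ncol_min >= 10L
  score <- if (is_narrow)
    suppressWarnings(as.numeric(vapply(fields, `[`, "", 9L)))
  else if (ncol_min >= 5L)
    suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  else rep(NA_real_, n)

  midpoint <- (start + end) %/% 2L
  summit <- midpoint
  if (is_narrow) {
    offset <- parse_int(vapply(fields, `[`, "", 10L), 10L, "summit offset")
    has_summit <- offset != -1L
    summit[has_summit] <- start[has_summit] + offset[has_summit]
    bad <- which(has_summit & (summit < start | summit >= end))
    if (length(bad))
      stop("summit offset outside interval at line ", bad[1L])
  }

  data.frame(chrom = chrom, start = start, end = end, peak_id = peak_id,
             score = score, summit = summit, source = source,
             stringsAsFactors = FALSE)
}

#' Read gene models from BED6 or minimal GTF
#'
#' The gene body spans transcription start to transcription end. For GTF
#' input (which must carry a `gene_id` attribute) the body is the union
#' span — min start to max end — over that gene's records; a gene whose
#' records sit on more than one chromosome or strand is rejected.
#'
#' @param path annotation file.
#' @param dialect `"bed6"` or `"gtf"`.
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open bodies).
#' @export
read_gene_models <- function(path, dialect = c("bed6", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "bed6") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end",
                                           "gene_id", "score", "strand"))
    genes <- data.frame(gene_id = tab$gene_id, symbol = tab$gene_id,
                        chrom = tab$chrom, start = as.integer(tab$start),
                        end = as.integer(tab$end), strand = tab$strand,
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("empty annotation: ", path)
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 9L)) stop("GTF requires 9 tab-separated columns")
    attr9 <- vapply(f, `[`, "", 9L)
    m <- regmatches(attr9, regexpr('gene_id "[^"]+"', attr9))
    if (length(m) != length(attr9))
      stop("GTF record without gene_id attribute")
    gid <- sub('gene_id "([^"]+)"', "\\1", m)
    rec <- data.frame(gene_id = gid,
                      chrom = vapply(f, `[`, "", 1L),
                      start = as.integer(vapply(f, `[`, "", 4L)) - 1L,  # GTF is 1-based closed
                      end = as.integer(vapply(f, `[`, "", 5L)),
                      strand = vapply(f, `[`, "", 7L),
                      stringsAsFactors = FALSE)
    sp <- split(rec, rec$gene_id)
    offenders <- names(sp)[vapply(sp, function(d)
      length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L, TRUE)]
    if (length(offenders))
      stop("gene_id spanning multiple chromosomes or strands: ",
           paste(offenders, collapse = ", "))
    genes <- do.call(rbind, lapply(sp, function(d)
      data.frame(gene_id = d$gene_id[1L], symbol = d$gene_id[1L],
                 chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
                 strand = d$strand[1L], stringsAsFactors = FALSE)))
    rownames(genes) <- NULL
  }
  if (!nrow(genes)) stop("empty annotation: ", path)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[anyDuplicated(genes$gene_id)])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  validate_intervals(genes, "gene body")
  genes[order(genes$gene_id), , drop = FALSE]
}

#' Read a differential-expression table
#'
#' Accepts edgeR-style column names by default (`logFC`, `PValue`, `FDR`)
#' with a configurable alias map. Readers fail fast: duplicate gene ids,
#' missing columns, and p or FDR outside `[0, 1]` are errors.
#'
#' @param path TSV with a header.
#' @param contrast label recorded on every row, e.g. `"JunbKO_vs_WT_Th17"`.
#' @param aliases named list mapping canonical names (`gene_id`, `log2fc`,
#'   `pvalue`, `fdr`) to acceptable header names.
#' @return data.frame with columns `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `contrast`.
#' @export
read_de_table <- function(path, contrast,
                          aliases = list(
                            gene_id = c("gene_id", "gene", "genes", "GeneID", "symbol"),
                            log2fc = c("log2fc", "logFC", "log2FC", "log2FoldChange"),
                            pvalue = c("pvalue", "PValue", "p", "pval", "p.value"),
                            fdr = c("fdr", "FDR", "padj", "adj.P.Val"))) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(canon) {
    hit <- intersect(aliases[[canon]], names(tab))
    if (!length(hit))
      stop("missing required column '", canon, "' (accepted names: ",
           paste(aliases[[canon]], collapse = ", "), ")")
    tab[[hit[1L]]]
  }
  de <- data.frame(gene_id = as.character(pick("gene_id")),
                   log2fc = as.numeric(pick("log2fc")),
                   pvalue = as.numeric(pick("pvalue")),
                   fdr = as.numeric(pick("fdr")),
                   contrast = contrast, stringsAsFactors = FALSE)
  validate_de_table(de)
  de
}

validate_de_table <- function(de) {
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene_id in DE table: ",
         de$gene_id[anyDuplicated(de$gene_id)])
  if (any(is.na(de$pvalue)) || any(de$pvalue < 0 | de$pvalue > 1))
    stop("p-value outside [0, 1]")
  if (any(is.na(de$fdr)) || any(de$fdr < 0 | de$fdr > 1))
    stop("FDR outside [0, 1]")
  invisible(de)
}

# shared deterministic TSV writer: fixed column order, no quoting,
# byte-stable numeric formatting
write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.15g", v)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write a regulatory network as Cytoscape-ready flat tables
#'
#' Emits a tab-separated edge table (`tf`, `gene_id`, `directness`, `mode`,
#' `kd_log2fc`, `kd_fdr`, `n_peaks`, `manual_flag`) sorted by
#' `(tf, gene_id)`, plus a companion node-attribute table (`gene_id`,
#' `subset_log2fc`, `subset_significant`). Output is byte-stable across
#' reruns.
#'
#' @param network a `regulatory_network` (see [build_network()]).
#' @param path edge-table path; the node table goes to
#'   `sub("\\.tsv$", "", path)` + `".nodes.tsv"`.
#' @return invisibly, the two paths written.
#' @export
write_network_table <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges[order(network$edges$tf, network$edges$gene_id),
                     c("tf", "gene_id", "directness", "mode",
                       "kd_log2fc", "kd_fdr", "n_peaks", "manual_flag"),
                     drop = FALSE]
  write_tsv_stable(e, path)
  nodes <- network$nodes
  if (is.null(nodes))
    nodes <- data.frame(gene_id = character(), subset_log2fc = double(),
                        subset_significant = logical())
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  node_path <- paste0(sub("\\.tsv$", "", path), ".nodes.tsv")
  write_tsv_stable(nodes, node_path)
  invisible(c(path, node_path))
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param sets named list of character vectors (member gene ids).
#' @param path file path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a nonempty name")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    if (!length(members)) stop("gene set '", nm, "' is empty")
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("GMT line with fewer than 3 fields")
  sets <- lapply(f, function(v) v[-(1:2)])
  names(sets) <- vapply(f, `[`, "", 1L)
  sets
}

#' Write / read a pre-ranked gene list in RNK format
#'
#' Lines are `gene_id TAB score`, sorted by descending score.
#'
#' @param ranked data.frame with `gene_id` and `score` columns (a
#'   [rank_metric()] result).
#' @param path file path.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(all(c("gene_id", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id))
    stop("duplicate gene in ranked list: ",
         ranked$gene_id[anyDuplicated(ranked$gene_id)])
  ranked <- ranked[order(-ranked$score, ranked$gene_id), , drop = FALSE]
  writeLines(paste(ranked$gene_id, sprintf("%.15g", ranked$score),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "score"))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene in RNK file")
  tab[order(-tab$score, tab$gene_id), , drop = FALSE]
}

#' Write peaks as narrowPeak, gene models as BED6, DE tables as TSV
#'
#' Writers for the synthetic-data generator so its output is consumed
#' through the same readers as real data.
#'
#' @param peaks peak data.frame (see [read_narrowpeak()]).
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param de DE data.frame (see [read_de_table()]).
#' @param path output file.
#' @name raw_writers
NULL

#' @rdname raw_writers
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                 0L, ".", 0,
                 sprintf("%.15g", score), sprintf("%.15g", score),
                 peaks$summit - peaks$start, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname raw_writers
#' @export
write_bed6 <- function(genes, path) {
  lines <- paste(genes$chrom, genes$start, genes$end, genes$gene_id,
                 0L, genes$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname raw_writers
#' @export
write_de_table <- function(de, path) {
  write_tsv_stable(de[, c("gene_id", "log2fc", "pvalue", "fdr")], path)
}
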