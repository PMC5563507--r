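# Independent brute-force oracles and small random-instance generators
# shared across the suite. These stay deliberately naive: correctness by
# inspection, not speed.

# exact binomial 99% acceptance interval for an observed fraction when
# the true success probability is p0 over n trials
binom_ci99 <- function(p0, n) {
  stats::qbinom(c(0.005, 0.995), n, p0) / n
}

# all-pairs peak-gene association scan (distance <= window, summit rule):
# every (peak, gene) pair is examined, no index structure involved
brute_force_map <- function(peaks, genes, window) {
  idx <- expand.grid(i = seq_len(nrow(peaks)), j = seq_len(nrow(genes)))
  s <- peaks$summit[idx$i]
  st <- genes$start[idx$j]
  en <- genes$end[idx$j]
  d <- ifelse(s < st, st - s, ifelse(s >= en, s - en + 1L, 0L))
  keep <- peaks$chrom[idx$i] == genes$chrom[idx$j] & d <= window
  out <- data.frame(peak_id = peaks$peak_id[idx$i[keep]],
                    gene_id = genes$gene_id[idx$j[keep]],
                    tf = peaks$source[idx$i[keep]],
                    distance = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# base-wise boolean coverage length over a small genome
coverage_union_length <- function(x, genome_length) {
  total <- 0L
  for (ch in unique(x$chrom)) {
    cov <- logical(genome_length)
    sub <- x[x$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      cov[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    total <- total + sum(cov)
  }
  total
}

# direct-formula BH step-up with cummin monotonicity enforcement
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# classic unweighted KS enrichment statistic (independent of the
# weighted implementation): +1/Nh at hits, -1/(N-Nh) at misses
naive_unweighted_ks <- function(ranked, geneset) {
  hit <- ranked$gene_id %in% geneset
  nh <- sum(hit)
  n <- length(hit)
  running <- cumsum(ifelse(hit, 1 / nh, -1 / (n - nh)))
  running[which.max(abs(running))]
}

random_intervals <- function(n, genome_length, chroms = "chr1",
                             max_width = 500L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(genome_length - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

random_peaks <- function(n, genome_length, chroms = c("chr1", "chr2"),
                         source = "TFX") {
  iv <- random_intervals(n, genome_length, chroms)
  iv$peak_id <- sprintf("p%04d", seq_len(n))
  iv$score <- round(stats::runif(n, 1, 50), 2)
  iv$summit <- iv$start + floor(stats::runif(n) * (iv$end - iv$start))
  iv$source <- source
  iv
}

random_genes <- function(n, genome_length, chroms = c("chr1", "chr2")) {
  iv <- random_intervals(n, genome_length, chroms, max_width = 5000L)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), symbol = "na",
             chrom = iv$chrom, start = iv$start, end = iv$end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# minimal valid DE table
make_de <- function(gene_id, log2fc, pvalue, fdr = NULL,
                    contrast = "test") {
  if (is.null(fdr)) fdr <- naive_bh(pvalue)
  data.frame(gene_id = gene_id, log2fc = log2fc, pvalue = pvalue,
             fdr = fdr, contrast = contrast, stringsAsFactors = FALSE)
}
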