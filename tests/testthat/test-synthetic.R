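test_that("generation is fully deterministic under a seed, including write/read round-trips", {
  spec <- truth_spec(seed = 101, n_genes = 60, n_targets = 15)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$truth$edges, d2$truth$edges)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(d1$de_tables, d2$de_tables)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)

  # round-trip through the standard readers
  genes_back <- read_gene_models(file.path(dir1, "genes.bed"), "bed6")
  expect_equal(sort(genes_back$gene_id), sort(d1$truth$gene_models$gene_id))
  p_back <- read_narrowpeak(file.path(dir1, "JunB.narrowPeak"), source = "JunB")
  expect_equal(p_back$summit, d1$peaks$JunB$summit)
  de_back <- read_de_table(file.path(dir1, "de_JunBKO_vs_WT.tsv"),
                           "JunBKO_vs_WT")
  expect_equal(de_back$fdr, d1$de_tables$JunBKO_vs_WT$fdr)
})

test_that("the bundled fixture files are exactly the seed-42 dataset", {
  dir <- system.file("extdata", "fixture", package = "tfregnet")
  expect_true(nzchar(dir))
  tmp <- withr::local_tempdir()
  write_dataset(generate_dataset(truth_spec(seed = 42)), tmp)
  files <- list.files(dir)
  expect_true(length(files) >= 9)
  for (f in files)
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(tmp, f)), label = f)
})

test_that("gene bodies keep >= 2*window gaps so peak assignment is unambiguous", {
  spec <- truth_spec(seed = 7, n_genes = 100, n_chroms = 2, chrom_length = 2e6)
  truth <- generate_truth(spec)
  g <- truth$gene_models
  for (ch in unique(g$chrom)) {
    s <- g[g$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1)
      expect_true(all(s$start[-1] - s$end[-nrow(s)] >= 2 * spec$window))
  }
  # an unplaceable request errors with advice
  expect_error(generate_truth(truth_spec(seed = 1, n_genes = 500,
                                         n_chroms = 1, chrom_length = 1e6)),
               "density")
})

test_that("planted fractions realize within binomial bounds; frac_direct = 1 is exact", {
  all_direct <- generate_truth(truth_spec(seed = 3, frac_direct = 1))
  expect_true(all(all_direct$edges$directness == "DIRECT"))

  spec <- truth_spec(seed = 5, n_genes = 4000, n_chroms = 8,
                     chrom_length = 2e7, tf_panel = c("A", "B", "C"),
                     n_targets = 3400, frac_act = 0.6)
  truth <- generate_truth(spec)
  n <- nrow(truth$edges)
  ci <- binom_ci99(0.6, n)
  frac <- mean(truth$edges$mode == "ACT")
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("peaks of DIRECT edges land within the window; decoys never do", {
  spec <- truth_spec(seed = 13, n_genes = 80, n_targets = 40,
                     frac_direct = 1, decoy_peaks_per_tf = 100)
  ds <- generate_dataset(spec)
  genes <- ds$truth$gene_models
  for (tf in spec$tf_panel) {
    assoc <- map_peaks_to_genes(ds$peaks[[tf]], genes, spec$window)
    direct_genes <- ds$truth$edges$gene_id[ds$truth$edges$tf == tf &
                                             ds$truth$edges$directness == "DIRECT"]
    # every planted DIRECT edge is recoverable from the peaks
    expect_true(all(direct_genes %in% assoc$gene_id))
    # decoys (peaks not from a planted edge) associate with nothing
    n_true <- sum(ds$truth$edges$tf == tf &
                    ds$truth$edges$directness == "DIRECT")
    decoy_ids <- ds$peaks[[tf]]$peak_id[
      as.integer(sub(".*_peak_", "", ds$peaks[[tf]]$peak_id)) > n_true]
    expect_false(any(decoy_ids %in% assoc$peak_id))
  }
})

test_that("knockout DE tables encode targets and the FDR column is exactly BH", {
  spec <- truth_spec(seed = 17, n_genes = 100, n_targets = 25,
                     target_p_shape = 1e-6)
  ds <- generate_dataset(spec)
  for (tf in spec$tf_panel) {
    de <- ds$de_tables[[paste0(tf, "KO_vs_WT")]]
    expect_equal(de$fdr, bh_adjust(de$pvalue))
    e <- ds$truth$edges[ds$truth$edges$tf == tf, ]
    idx <- match(e$gene_id, de$gene_id)
    expect_equal(de$log2fc[idx], e$log2fc)
    expect_true(all(sign(de$log2fc[idx][e$mode == "ACT"]) == -1))
  }
})

test_that("a no-target table is null-calibrated and yields ~no edges", {
  spec <- truth_spec(seed = 23, n_genes = 2000, n_chroms = 4,
                     chrom_length = 1.5e7, tf_panel = "TFX", n_targets = 0,
                     decoy_peaks_per_tf = 0)
  ds <- generate_dataset(spec)
  de <- ds$de_tables$TFXKO_vs_WT
  frac <- mean(de$pvalue < 0.05)
  ci <- binom_ci99(0.05, nrow(de))
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  net <- build_network(list(TFX = de),
                       config = network_config(manual_direct = list()))
  expect_lte(nrow(net$edges), 2L)  # BH under the global null
})

test_that("recovery metrics match a set-algebra oracle and flag degenerate cases", {
  spec <- truth_spec(seed = 29, n_genes = 80, n_targets = 20,
                     tf_panel = c("A", "B"), target_p_shape = 1e-6)
  ds <- generate_dataset(spec)
  ko <- ds$de_tables[paste0(spec$tf_panel, "KO_vs_WT")]
  names(ko) <- spec$tf_panel
  assoc <- lapply(ds$peaks, map_peaks_to_genes, genes = ds$truth$gene_models)
  net <- build_network(ko, assoc, network_config(manual_direct = list()))
  m <- recovery_metrics(net, ds$truth)

  key_i <- paste(net$edges$tf, net$edges$gene_id)
  key_t <- paste(ds$truth$edges$tf, ds$truth$edges$gene_id)
  tp <- length(intersect(key_i, key_t))
  expect_equal(m$pooled$precision, tp / length(key_i))
  expect_equal(m$pooled$recall, tp / length(key_t))
  expect_equal(m$pooled$f1,
               2 * m$pooled$precision * m$pooled$recall /
                 (m$pooled$precision + m$pooled$recall))
  expect_named(m$per_tf, c("A", "B"))

  empty <- build_network(list(A = ko$A[0, ], B = ko$B[0, ]))
  me <- recovery_metrics(empty, ds$truth)
  expect_true(is.nan(me$pooled$precision))
  expect_equal(me$pooled$recall, 0)
  expect_true(me$pooled$degenerate)
})

test_that("recall degrades monotonically along dropout and p-shape grids", {
  base <- function(dropout, shape) {
    spec <- truth_spec(seed = 37, n_genes = 1000, n_chroms = 4,
                       chrom_length = 6e6, tf_panel = "TFX",
                       n_targets = 400, frac_direct = 1,
                       peak_dropout = dropout, target_p_shape = shape,
                       decoy_peaks_per_tf = 0)
    ds <- generate_dataset(spec)
    assoc <- list(TFX = map_peaks_to_genes(ds$peaks$TFX,
                                           ds$truth$gene_models))
    net <- build_network(list(TFX = ds$de_tables$TFXKO_vs_WT), assoc,
                         network_config(manual_direct = list()))
    m <- recovery_metrics(net, ds$truth)
    e <- net$edges
    list(recall = m$pooled$recall,
         direct_frac = if (nrow(e)) mean(e$directness == "DIRECT") else 0)
  }
  # directness recovery is non-increasing in peak dropout
  direct <- vapply(c(0, 0.2, 0.4, 0.6, 0.8),
                   function(d) base(d, 1e-4)$direct_frac, 0)
  expect_true(all(diff(direct) <= 0.02))  # monotone trend, small MC slack
  # edge recall is non-increasing as target p-values approach the null
  recall <- vapply(c(1e-6, 0.01, 0.1, 0.3, 1),
                   function(a) base(0, a)$recall, 0)
  expect_true(all(diff(recall) <= 0.02))
})

test_that("overlapping gene bodies are handled by multi-assignment (dedicated fixture)", {
  genes <- data.frame(gene_id = c("outer", "inner"),
                      symbol = c("outer", "inner"), chrom = "chr1",
                      start = c(1000L, 2000L), end = c(9000L, 3000L),
                      strand = "+", stringsAsFactors = FALSE)
  peak <- data.frame(chrom = "chr1", start = 2400L, end = 2600L,
                     peak_id = "p1", score = 1, summit = 2500L,
                     source = "TFX", stringsAsFactors = FALSE)
  a <- map_peaks_to_genes(peak, genes)
  expect_setequal(a$gene_id, c("outer", "inner"))
  expect_true(all(a$distance == 0L))
})
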