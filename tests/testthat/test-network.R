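test_that("target classification follows the FDR / sign / proximal-peak rules", {
  cfg <- network_config()
  e <- classify_target("JunB", "g1", log2fc = 1.4, fdr = 0.03,
                       n_proximal_peaks = 2, config = cfg)
  expect_equal(e$directness, "DIRECT")
  expect_equal(e$mode, "REP")

  # strict threshold: fdr exactly 0.05 is not significant
  expect_null(classify_target("JunB", "g1", 1.4, 0.05, 2, cfg))

  # manual curation forces DIRECT without peaks, still needs significance
  e <- classify_target("JunB", "Ifng", -2.0, 0.001, 0, cfg, manual = TRUE)
  expect_equal(e$directness, "DIRECT")
  expect_equal(e$mode, "ACT")
  expect_true(e$manual_flag)
  expect_null(classify_target("JunB", "Ifng", -2.0, 0.5, 0, cfg, manual = TRUE))

  # zero log2FC has no mode: excluded with a warning
  expect_warning(out <- classify_target("JunB", "g1", 0, 0.001, 1, cfg),
                 "mode undefined")
  expect_null(out)
})

test_that("network construction integrates DE and associations per the direct-target rule", {
  de <- make_de(c("a", "b", "c", "d"),
                log2fc = c(-2, 1.5, -0.5, 3),
                pvalue = c(1e-8, 1e-6, 0.5, 1e-4),
                fdr = c(1e-7, 1e-5, 0.6, 1e-3))
  assoc <- data.frame(peak_id = c("p1", "p2", "p3"),
                      gene_id = c("a", "a", "d"),
                      tf = "JunB", distance = 0L, stringsAsFactors = FALSE)
  net <- build_network(list(JunB = de), list(JunB = assoc),
                       network_config(manual_direct = list()))
  e <- net$edges
  expect_equal(nrow(e), 3L)  # c not significant
  expect_equal(e$directness[e$gene_id == "a"], "DIRECT")
  expect_equal(e$n_peaks[e$gene_id == "a"], 2L)
  expect_equal(e$directness[e$gene_id == "b"], "INDIRECT")
  expect_equal(e$mode[e$gene_id == "a"], "ACT")
  expect_equal(e$mode[e$gene_id == "b"], "REP")

  # empty DE -> empty network; orphan associations -> error
  empty <- build_network(list(JunB = de[0, ]))
  expect_equal(nrow(empty$edges), 0L)
  expect_error(build_network(list(JunB = de), list(BATF = assoc)),
               "without a DE table")

  # orientation flip reverses modes
  net2 <- build_network(list(JunB = de), list(JunB = assoc),
                        network_config(manual_direct = list(),
                                       ko_orientation = "wt_vs_ko"))
  expect_equal(net2$edges$mode[net2$edges$gene_id == "a"], "REP")
})

test_that("removing peaks relabels DIRECT to INDIRECT without changing genes", {
  spec <- truth_spec(seed = 9, n_genes = 100, n_targets = 30,
                     tf_panel = c("JunB", "BATF"))
  ds <- generate_dataset(spec)
  ko <- ds$de_tables[paste0(spec$tf_panel, "KO_vs_WT")]
  names(ko) <- spec$tf_panel
  assoc <- lapply(ds$peaks, map_peaks_to_genes, genes = ds$truth$gene_models)
  cfg <- network_config(manual_direct = list())
  with_peaks <- build_network(ko, assoc, cfg)
  without <- build_network(ko, config = cfg)
  expect_setequal(paste(with_peaks$edges$tf, with_peaks$edges$gene_id),
                  paste(without$edges$tf, without$edges$gene_id))
  expect_true(all(without$edges$directness == "INDIRECT"))
  expect_identical(with_peaks$edges$mode[order(with_peaks$edges$gene_id,
                                               with_peaks$edges$tf)],
                   without$edges$mode[order(without$edges$gene_id,
                                            without$edges$tf)])
})

test_that("quadrant concordance: identity, antisymmetry, and sum-to-one", {
  set.seed(21)
  de <- make_de(sprintf("g%03d", 1:100),
                log2fc = stats::rnorm(100),
                pvalue = stats::runif(100, 0, 0.01))
  q <- quadrant_concordance(de, de)
  expect_equal(q$concordance, 1.0)
  neg <- de
  neg$log2fc <- -neg$log2fc
  expect_equal(quadrant_concordance(de, neg)$concordance, 0.0)
  q2 <- quadrant_concordance(de, neg)
  expect_equal(sum(q2$fractions), 1.0)

  # only co-significant genes count
  half <- de
  half$fdr[1:50] <- 0.9
  q3 <- quadrant_concordance(de, half)
  expect_equal(q3$n, 50L)

  allns <- de
  allns$fdr <- 0.9
  expect_error(quadrant_concordance(de, allns), "no co-significant")
})

test_that("planted sign concordance is recovered within its binomial interval", {
  pair <- generate_de_pair(n_genes = 1000, concordance = 0.9, seed = 13)
  q <- quadrant_concordance(pair$de_a, pair$de_b)
  expect_equal(q$n, 1000L)
  ci <- binom_ci99(0.9, 1000)
  expect_gte(q$concordance, ci[1])
  expect_lte(q$concordance, ci[2])
  # and the estimator reproduces the realized planted agreement exactly
  expect_equal(q$concordance, pair$planted_agreement)
})

test_that("pair-mode groups recover planted cooperative modes exactly", {
  pm <- data.frame(tf_a = "JunB", tf_b = "BATF",
                   mode_a = c("ACT", "ACT", "REP", "REP"),
                   mode_b = c("ACT", "REP", "ACT", "REP"),
                   n = 5, stringsAsFactors = FALSE)
  spec <- truth_spec(seed = 31, n_genes = 150, n_targets = 20,
                     tf_panel = c("JunB", "BATF"), target_p_shape = 1e-6,
                     pair_mode_table = pm)
  ds <- generate_dataset(spec)
  ko <- ds$de_tables[paste0(spec$tf_panel, "KO_vs_WT")]
  names(ko) <- spec$tf_panel
  net <- build_network(ko, config = network_config(manual_direct = list()))
  groups <- pair_mode_groups(net, "JunB", "BATF")
  truth_e <- ds$truth$edges
  for (i in seq_len(nrow(pm))) {
    planted <- intersect(
      truth_e$gene_id[truth_e$tf == "JunB" & truth_e$mode == pm$mode_a[i]],
      truth_e$gene_id[truth_e$tf == "BATF" & truth_e$mode == pm$mode_b[i]])
    label <- paste(pm$mode_a[i], pm$mode_b[i], sep = ":")
    expect_true(all(planted %in% groups$gene_id[groups$group == label]))
  }
  expect_error(pair_mode_groups(net, "JunB", "Nope"), "not present")
})

test_that("net-effect summaries match a sort-based order-statistics oracle", {
  set.seed(77)
  groups <- data.frame(gene_id = sprintf("g%03d", 1:40),
                       mode_a = "ACT", mode_b = "ACT",
                       group = rep(c("ACT:ACT", "REP:REP"), each = 20),
                       stringsAsFactors = FALSE)
  subset_de <- make_de(sprintf("g%03d", 1:60),
                       log2fc = stats::rnorm(60, 1),
                       pvalue = stats::runif(60, 0, 0.01))
  s <- net_effect_summary(groups, subset_de)
  sig <- subset_de[subset_de$fdr < 0.05, ]
  for (g in c("ACT:ACT", "REP:REP")) {
    vals <- sort(sig$log2fc[sig$gene_id %in% groups$gene_id[groups$group == g]])
    expect_equal(s[[g]]$values, vals)
    expect_equal(s[[g]]$median, stats::median(vals))
    expect_equal(s[[g]]$q1, unname(stats::quantile(vals, 0.25)))
    expect_equal(s[[g]]$q3, unname(stats::quantile(vals, 0.75)))
  }
  expect_true(s[["ACT:REP"]]$empty)
  expect_equal(s[["ACT:REP"]]$n, 0L)
})

test_that("subset preference projects target log2FC from the subset table", {
  spec <- truth_spec(seed = 47, n_genes = 150, n_targets = 40,
                     tf_panel = c("JunB", "BATF"), target_p_shape = 1e-6,
                     signature_overlap = 1)
  ds <- generate_dataset(spec)
  ko <- ds$de_tables[paste0(spec$tf_panel, "KO_vs_WT")]
  names(ko) <- spec$tf_panel
  net <- build_network(ko, config = network_config(manual_direct = list()))
  th17_th1 <- ds$de_tables[["Th17_vs_Th1"]]
  rep_pref <- subset_preference(net, "JunB", "REP", th17_th1)
  expect_lt(rep_pref$median, 0)  # repression targets are Th1-preferential
  act_pref <- subset_preference(net, "JunB", "ACT", th17_th1)
  expect_gt(act_pref$median, 0)
  expect_true(all(rep_pref$values %in% th17_th1$log2fc))
})

test_that("node annotation marks subset significance and never alters edges", {
  de <- make_de(c("a", "b"), c(-2, 1.5), c(1e-8, 1e-6), c(1e-7, 1e-5))
  net <- build_network(list(JunB = de),
                       config = network_config(manual_direct = list()))
  subset_de <- make_de("a", 2.5, 1e-4, 1e-3, "Th17_vs_Th0")
  ann <- annotate_nodes(net, subset_de)
  expect_identical(ann$edges, net$edges)
  expect_equal(ann$nodes$subset_log2fc[ann$nodes$gene_id == "a"], 2.5)
  expect_true(ann$nodes$subset_significant[ann$nodes$gene_id == "a"])
  expect_false(ann$nodes$subset_significant[ann$nodes$gene_id == "b"])
  expect_true(is.na(ann$nodes$subset_log2fc[ann$nodes$gene_id == "b"]))
})
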