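#!/usr/bin/env Rscript
# Build the direct/indirect activation/repression network from the
# knockout DE tables plus peak associations, annotate nodes with the
# Th17-vs-Th0 contrast, score recovery against the planted truth, and
# compute the TF-pair summaries (quadrant concordance, cooperative-mode
# groups, net-effect distributions). Outputs under results/network/.

suppressMessages(library(tfregnet))

tfs <- c("JunB", "BATF", "Fosl2")
genes <- read_gene_models("results/data/genes.bed", "bed6")
ko <- lapply(tfs, function(tf)
  read_de_table(sprintf("results/data/de_%sKO_vs_WT.tsv", tf),
                contrast = sprintf("%sKO_vs_WT", tf)))
names(ko) <- tfs
assoc <- lapply(tfs, function(tf) {
  peaks <- read_narrowpeak(sprintf("results/data/%s.narrowPeak", tf),
                           source = tf)
  map_peaks_to_genes(peaks, genes, window = 5000)
})
names(assoc) <- tfs
th17_th0 <- read_de_table("results/data/de_Th17_vs_Th0.tsv", "Th17_vs_Th0")

net <- build_network(ko, assoc, network_config(manual_direct = list()))
net <- annotate_nodes(net, th17_th0)
dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
write_network_table(net, "results/network/network_edges.tsv")
print(net)

truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
m <- recovery_metrics(net, list(edges = truth$edges))$pooled
cat(sprintf("Recovery vs planted truth: precision %.3f, recall %.3f, F1 %.3f; mode acc %.3f, directness acc %.3f\n",
            m$precision, m$recall, m$f1, m$mode_accuracy,
            m$directness_accuracy))

summaries <- lapply(utils::combn(tfs, 2, simplify = FALSE), function(pr) {
  q <- quadrant_concordance(ko[[pr[1]]], ko[[pr[2]]])
  cat(sprintf("%s vs %s: %.0f%% concordant over %d co-significant genes\n",
              pr[1], pr[2], 100 * q$concordance, q$n))
  groups <- pair_mode_groups(net, pr[1], pr[2])
  eff <- net_effect_summary(groups, th17_th0)
  for (g in names(eff))
    if (!eff[[g]]$empty)
      cat(sprintf("  %s:%s %-8s n=%3d median Th17/Th0 log2FC %+.2f\n",
                  pr[1], pr[2], g, eff[[g]]$n, eff[[g]]$median))
  list(pair = pr, quadrant = q[c("fractions", "concordance", "n")],
       modes = as.list(table(groups$group)),
       net_effect = lapply(eff, function(s) s[c("n", "median", "q1", "q3")]))
})
jsonlite::write_json(summaries, "results/network/pair_summaries.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/network/\n")
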