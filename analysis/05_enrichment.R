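#!/usr/bin/env Rscript
# Build top-100 subset signatures from the Th17-vs-Th0 and Th17-vs-Th1
# contrasts, rank the JunB-knockout contrast by signed -log10(p), and run
# pre-ranked GSEA (weighted statistic, 10,000 gene-set permutations).
# Outputs under results/enrichment/.

suppressMessages(library(tfregnet))

de <- list(
  Th17_vs_Th0 = read_de_table("results/data/de_Th17_vs_Th0.tsv", "Th17_vs_Th0"),
  Th17_vs_Th1 = read_de_table("results/data/de_Th17_vs_Th1.tsv", "Th17_vs_Th1"))
junb <- read_de_table("results/data/de_JunBKO_vs_WT.tsv", "JunBKO_vs_WT")

sets <- list()
for (ct in names(de))
  for (dir in c("up", "down"))
    sets[[sprintf("%s_%s", ct, dir)]] <-
      suppressWarnings(signature_from_contrast(de[[ct]], dir, n = 100))
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)
write_gmt(sets, "results/enrichment/signatures.gmt")
cat("Signatures:", paste(sprintf("%s (%d)", names(sets), lengths(sets)),
                         collapse = ", "), "\n")

ranked <- rank_metric(junb)
write_rnk(ranked, "results/enrichment/JunBKO_vs_WT.rnk")

res <- gsea_preranked(ranked, sets, nperm = 10000, seed = 1, weight = 1)
utils::write.table(
  res[, c("set_name", "size", "es", "nes", "p_perm", "nperm",
          "leading_edge_size")],
  "results/enrichment/enrichment.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
for (i in seq_len(nrow(res)))
  cat(sprintf("  %-18s ES %+.3f NES %+.3f p %s (leading edge %d/%d)\n",
              res$set_name[i], res$es[i], res$nes[i],
              format(res$p_perm[i], digits = 3),
              res$leading_edge_size[i], res$size[i]))
cat("Wrote results/enrichment/\n")
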