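#!/usr/bin/env Rscript
# Associate each TF's peaks with genes by the summit-within-5-kb rule and
# export the association tables under results/associations/.

suppressMessages(library(tfregnet))

genes <- read_gene_models("results/data/genes.bed", "bed6")
tfs <- c("JunB", "BATF", "Fosl2")
dir.create("results/associations", recursive = TRUE, showWarnings = FALSE)

for (tf in tfs) {
  peaks <- read_narrowpeak(sprintf("results/data/%s.narrowPeak", tf),
                           source = tf)
  assoc <- map_peaks_to_genes(peaks, genes, window = 5000)
  write_associations(assoc, sprintf("results/associations/assoc_%s.tsv", tf))
  cat(sprintf("%s: %d/%d peaks associated with %d genes (median distance %d bp)\n",
              tf, length(unique(assoc$peak_id)), nrow(peaks),
              length(unique(assoc$gene_id)),
              as.integer(stats::median(assoc$distance))))
}
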