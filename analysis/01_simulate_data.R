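#!/usr/bin/env Rscript
# Generate the benchmark dataset: a planted 3-TF regulatory network over
# 200 genes (seed 42) with ChIP-seq-style peak sets, knockout DE tables,
# and two subset contrasts. Writes narrowPeak/BED6/TSV inputs plus the
# planted truth under results/data/.

suppressMessages(library(tfregnet))

spec <- truth_spec(seed = 42)
ds <- generate_dataset(spec)
write_dataset(ds, "results/data")

cat("Wrote results/data:", length(list.files("results/data")), "files\n")
cat("Planted edges:", nrow(ds$truth$edges), "over",
    length(unique(ds$truth$edges$gene_id)), "genes;",
    sum(ds$truth$edges$directness == "DIRECT"), "DIRECT,",
    sum(ds$truth$edges$mode == "ACT"), "ACT\n")
for (tf in spec$tf_panel)
  cat(sprintf("  %s: %d peaks (incl. %d decoys)\n", tf,
              nrow(ds$peaks[[tf]]), spec$decoy_peaks_per_tf))
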