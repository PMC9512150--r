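#!/usr/bin/env Rscript
# Expression-side preparation per condition: robust-expression gene filter
# (non-zero in >= 2 replicates for >= 85% of samples), TE-gene removal,
# replicate averaging, and per-gene ranking of samples.
source("analysis/00_common.R")
ensure_simulation()

genes <- attach_gene_metadata(read_gene_models(file.path(SIM_DIR, "genes.gff3")),
                              file.path(SIM_DIR, "gene_metadata.tsv"))
tr <- remove_te_genes(genes, file.path(SIM_DIR, "te.bed"))
message(sprintf("%d TE-overlapping genes removed: %s", length(tr$removed),
                paste(tr$removed, collapse = ", ")))

rows <- list()
for (cond in c("wet", "dry")) {
  em <- read_expression(file.path(SIM_DIR, sprintf("expr_%s.tsv", cond)), cond)
  robust <- robust_gene_filter(em)
  kept <- intersect(robust$genes, tr$genes$gene_id)
  ranks <- rank_samples(mean_expression(robust)[kept, , drop = FALSE], em$panel)
  rows[[cond]] <- data.frame(condition = cond, genes_input = length(em$genes),
                             genes_robust = length(robust$genes),
                             genes_analysed = length(ranks$genes))
  message(sprintf("%s: %d/%d genes robustly expressed, %d analysed after TE removal",
                  cond, length(robust$genes), length(em$genes), length(ranks$genes)))
}
write_tsv_df(do.call(rbind, rows), file.path(RESULTS_DIR, "03_gene_counts.tsv"))
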