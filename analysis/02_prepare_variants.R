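#!/usr/bin/env Rscript
# Variant-side preparation: GATK-style hard filters, SV depth/size rules,
# and rare-variant selection (MAF < 5% with the hom/3-het evidence rule for
# SNPs and indels; SV singletons allowed).
source("analysis/00_common.R")
ensure_simulation()

vt <- read_vcf(file.path(SIM_DIR, "variants.vcf"))
n0 <- n_variants(vt)
vt <- apply_hard_filters(vt)
hard_attr <- attr(vt, "attrition")
vt <- filter_sv_records(vt)
sv_attr <- attr(vt, "attrition")
vt <- suppressMessages(attach_site_scores(vt, file.path(SIM_DIR, "site_scores.tsv")))
rset <- select_rare_variants(vt)
rare_attr <- attr(rset, "attrition")

attrition <- data.frame(
  rule = c("input", names(hard_attr), names(sv_attr), names(rare_attr), "rare"),
  removed = c(0L, hard_attr, sv_attr, rare_attr, 0L),
  remaining = c(n0, rep(NA, length(hard_attr) + length(sv_attr) + length(rare_attr)),
                n_variants(rset)))
write_tsv_df(attrition, file.path(RESULTS_DIR, "02_filter_attrition.tsv"))
write_tsv_df(as.data.frame(table(vclass = rset$variants$vclass)),
             file.path(RESULTS_DIR, "02_rare_catalog.tsv"))

message(sprintf("%d/%d variants remain after QC; %d rare variants selected",
                n_variants(vt), n0, n_variants(rset)))
message(sprintf("rare catalog: %s",
                paste(names(table(rset$variants$vclass)),
                      table(rset$variants$vclass), sep = "=", collapse = ", ")))
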