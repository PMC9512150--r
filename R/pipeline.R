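#' Run the full rare-allele burden pipeline on a simulated or real dataset
#'
#' Convenience orchestration used by the analysis scripts and the
#' acceptance checks. Reads a dataset laid out as written by
#' [simulate_population()] (VCF + GFF3 + per-condition expression TSVs +
#' metadata + site scores + TE BED), applies the variant filters (hard
#' filters, SV depth/size rules, rarity + evidence rules), prepares
#' expression (robust filter, TE-gene removal, replicate averaging,
#' ranking) per condition, assigns rare variants to region bins and
#' computes the per-rank profile, quadratic fit, rank-group tests and phi.
#'
#' @param dir dataset directory.
#' @param conditions condition labels; file `expr_<condition>.tsv` must
#'   exist for each.
#' @param mode `"cis"` or `"windows"` (see [assign_variants()]).
#' @param maf_threshold rarity threshold (default 0.05).
#' @return list with `rset`, `genes` (TE-filtered gene models with
#'   metadata), and per-condition entries `expr` (robust-filtered matrix),
#'   `mean_expr`, `ranks`, `cube`, `profile`, `quad`, `groups`, `phi`.
#' @export
run_pipeline <- function(dir, conditions = c("wet", "dry"),
                         mode = c("cis", "windows"), maf_threshold = 0.05) {
  mode <- match.arg(mode)
  vt <- read_vcf(file.path(dir, "variants.vcf"))
  vt <- apply_hard_filters(vt)
  vt <- filter_sv_records(vt)
  scores_path <- file.path(dir, "site_scores.tsv")
  if (file.exists(scores_path))
    vt <- suppressMessages(attach_site_scores(vt, scores_path))
  rset <- select_rare_variants(vt, maf_threshold = maf_threshold)

  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  meta_path <- file.path(dir, "gene_metadata.tsv")
  if (file.exists(meta_path)) genes <- attach_gene_metadata(genes, meta_path)
  te_path <- file.path(dir, "te.bed")
  te_removed <- character(0)
  if (file.exists(te_path)) {
    tr <- remove_te_genes(genes, te_path)
    genes <- tr$genes
    te_removed <- tr$removed
  }

  out <- list(rset = rset, genes = genes, te_removed = te_removed,
              conditions = list())
  for (cond in conditions) {
    em <- read_expression(file.path(dir, sprintf("expr_%s.tsv", cond)), cond,
                          panel = vt$panel)
    em <- robust_gene_filter(em)
    keep <- intersect(em$genes, genes$gene_id)
    emv <- em$values[match(keep, em$genes), , , drop = FALSE]
    em <- expression_matrix(emv, cond, em$panel)
    me <- mean_expression(em)
    ranks <- rank_samples(me, em$panel)
    cond_genes <- genes[genes$gene_id %in% ranks$genes, , drop = FALSE]
    cube <- assign_variants(rset, cond_genes, mode = mode)
    profile <- per_rank_profile(cube, ranks)
    quad <- tryCatch(fit_quadratic(profile), error = function(e) NULL)
    groups <- tryCatch(rank_group_test(profile), error = function(e) NULL)
    phi <- compute_phi(cube, ranks)
    out$conditions[[cond]] <- list(expr = em, mean_expr = me, ranks = ranks,
                                   genes = cond_genes, cube = cube,
                                   profile = profile, quad = quad,
                                   groups = groups, phi = phi)
  }
  out
}
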