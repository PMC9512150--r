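#' Hand-constructed tiny fixtures with documented expected outputs
#'
#' Writes one of three deterministic miniature datasets to `dir`, in the
#' same external formats the pipeline reads. These are exact, hand-checked
#' cases used throughout the test suite:
#'
#' * `tiny5` — 5 samples, one `+` strand gene `[10001, 13000]`
#'   (TSS = 10001) with expression S1..S5 = 1..5 and three single-carrier
#'   SNPs: at TSS-500 (carrier S3), inside the gene body (carrier S5) and at
#'   TSS-2100 (carrier S1). Treating all three as rare, the cis
#'   (GENIC + 0-2 kb) per-rank profile is `(0, 0, 1, 0, 1)` and the
#'   TSS-2100 variant falls in the 2-4 kb window.
#' * `ranks10` — 10 samples, one gene, seven genic single-carrier variants
#'   placing counts `(2,0,0,0,1,1,0,0,0,3)` on ranks 1..10; the
#'   extreme-to-middle ratio is `phi = (2+3)/(1+1) = 2.5`.
#' * `merge_cases` — per-sample SV calls covering the merge boundary rules:
#'   deletions `[100,199]` (sample A) and `[150,249]` (sample B) with exactly
#'   50% reciprocal overlap (merged), deletions `[100,199]` / `[180,279]`
#'   with 20% (not merged), and breakends at identical vs off-by-one
#'   positions.
#'
#' @param name one of `"tiny5"`, `"ranks10"`, `"merge_cases"`.
#' @param dir output directory (default: fresh temp directory).
#' @return list of file paths (plus fixture-specific expected values).
#' @export
make_fixture <- function(name = c("tiny5", "ranks10", "merge_cases"),
                         dir = tempfile("fixture_")) {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         tiny5 = .fixture_tiny5(dir),
         ranks10 = .fixture_ranks10(dir),
         merge_cases = .fixture_merge_cases(dir))
}

.single_carrier_geno <- function(n_var, n_samp, carrier_idx, gt = 1L) {
  g <- matrix(0L, n_var, n_samp)
  g[cbind(seq_len(n_var), carrier_idx)] <- gt
  g
}

.flat_expression <- function(values, panel, condition = "wet", n_rep = 3L,
                             gene_ids = "g1") {
  arr <- array(rep(values, times = n_rep),
               dim = c(length(gene_ids), length(values) / length(gene_ids), n_rep),
               dimnames = list(gene_ids, as.character(panel), NULL))
  expression_matrix(arr, condition, panel)
}

.fixture_tiny5 <- function(dir) {
  panel <- sample_panel(paste0("S", 1:5))
  genes <- gene_models(data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                                  start = 10001L, end = 13000L))
  variants <- data.frame(
    variant_id = c("snp_u500", "snp_genic", "snp_u2100"),
    chrom = "chr1", pos = c(9501L, 11000L, 7901L),
    end = c(9501L, 11000L, 7901L), ref = "A", alt = "T",
    vclass = "SNP", length = 1L, stringsAsFactors = FALSE)
  vt <- variant_table(variants, .single_carrier_geno(3L, 5L, c(3L, 5L, 1L)), panel)
  em <- .flat_expression(1:5, panel)
  paths <- list(vcf = file.path(dir, "tiny5.vcf"),
                gff = file.path(dir, "tiny5.gff3"),
                expr = file.path(dir, "tiny5_expr.tsv"))
  write_vcf(vt, paths$vcf)
  write_gene_models(genes, paths$gff)
  write_expression(em, paths$expr)
  c(paths, list(expected_cis_profile = c(0, 0, 1, 0, 1),
                expected_u2100_bin = "U_2_4"))
}

.fixture_ranks10 <- function(dir) {
  panel <- sample_panel(paste0("S", 1:10))
  genes <- gene_models(data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                                  start = 10001L, end = 20000L))
  # counts by rank: (2,0,0,0,1,1,0,0,0,3); sample Sk holds rank k
  carriers <- c(1L, 1L, 5L, 6L, 10L, 10L, 10L)
  variants <- data.frame(
    variant_id = sprintf("v%d", seq_along(carriers)),
    chrom = "chr1", pos = 10000L + 100L * seq_along(carriers),
    end = 10000L + 100L * seq_along(carriers), ref = "A", alt = "T",
    vclass = "SNP", length = 1L, stringsAsFactors = FALSE)
  vt <- variant_table(variants,
                      .single_carrier_geno(length(carriers), 10L, carriers),
                      panel)
  em <- .flat_expression(1:10, panel)
  paths <- list(vcf = file.path(dir, "ranks10.vcf"),
                gff = file.path(dir, "ranks10.gff3"),
                expr = file.path(dir, "ranks10_expr.tsv"))
  write_vcf(vt, paths$vcf)
  write_gene_models(genes, paths$gff)
  write_expression(em, paths$expr)
  c(paths, list(expected_counts_by_rank = c(2, 0, 0, 0, 1, 1, 0, 0, 0, 3),
                expected_phi = 2.5))
}

.fixture_merge_cases <- function(dir) {
  calls <- data.frame(
    sample = c("A", "B",        # exactly 50% reciprocal overlap -> merged
               "A", "B",        # 20% reciprocal overlap -> not merged
               "A", "B", "C"),  # BND exact match vs off-by-one
    chrom = c("c1", "c1", "c2", "c2", "c3", "c3", "c3"),
    pos = c(100L, 150L, 100L, 180L, 5000L, 5000L, 5001L),
    end = c(199L, 249L, 199L, 279L, 5000L, 5000L, 5001L),
    vclass = c("DEL", "DEL", "DEL", "DEL", "BND", "BND", "BND"),
    length = c(100L, 100L, 100L, 100L, 0L, 0L, 0L),
    gt = c(2L, 2L, 2L, 1L, 1L, 1L, 1L),
    dhffc = c(0.4, 0.5, 0.4, 0.5, NA, NA, NA),
    dhbfc = NA_real_,
    stringsAsFactors = FALSE)
  path <- file.path(dir, "merge_cases.tsv")
  write_tsv_df(calls, path)
  list(calls = path, panel = sample_panel(c("A", "B", "C")),
       expected_n_merged = 5L)  # c1: 1 cluster; c2: 2; c3: 2
}
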