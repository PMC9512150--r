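write_mini_vcf <- function(lines, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

test_that("VCF records are classified and genotyped correctly", {
  p <- write_mini_vcf(c(
    "chr1\t100\tsnp1\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
    "chr1\t1000\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1500\tGT\t0/1\t0/0\t./.",
    "chr1\t2000\tind1\tACGT\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "chr1\t3000\tmulti\tA\tT,C\t.\tPASS\t.\tGT\t0/1\t0/2\t1/2"))
  vt <- read_vcf(p)
  v <- vt$variants
  # SNP het
  expect_equal(v$vclass[v$variant_id == "snp1"], "SNP")
  expect_equal(unname(vt$geno["snp1", ]), c(1L, 0L, 2L))
  # symbolic DEL: inclusive coordinates, length 501, missing genotype
  expect_equal(v$vclass[v$variant_id == "del1"], "DEL")
  expect_equal(v$length[v$variant_id == "del1"], 501L)
  expect_equal(unname(vt$geno["del1", ]), c(1L, 0L, NA_integer_))
  # 3-bp deletion is an INDEL
  expect_equal(v$vclass[v$variant_id == "ind1"], "INDEL")
  expect_equal(v$length[v$variant_id == "ind1"], 3L)
  # multiallelic site split into two biallelic records with per-allele counts
  multi <- v[grepl("^multi", v$variant_id), ]
  expect_equal(nrow(multi), 2L)
  expect_true(all(multi$pos == 3000L))
  expect_equal(unname(vt$geno["multi_alt1", ]), c(1L, 0L, 1L))
  expect_equal(unname(vt$geno["multi_alt2", ]), c(0L, 1L, 1L))
})

test_that("unknown SVTYPE is skipped with a warning; malformed GT errors", {
  p <- write_mini_vcf(c(
    "chr1\t100\tok\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "chr1\t200\tbad\tN\t<WEIRD>\t.\tPASS\tSVTYPE=WEIRD;END=300\tGT\t0/1\t0/0\t0/0"))
  expect_warning(vt <- read_vcf(p), "SVTYPE")
  expect_equal(n_variants(vt), 1L)
  p2 <- write_mini_vcf("chr1\t100\tx\tA\tT\t.\tPASS\t.\tGT\t0/x\t0/0\t0/0")
  expect_error(read_vcf(p2), "malformed GT")
})

test_that("variant tables round-trip through VCF field for field", {
  set.seed(7)
  panel <- sample_panel(sprintf("S%02d", 1:6))
  geno <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), 60, replace = TRUE), 10, 6)
  vt <- make_vt(geno, panel,
                vclass = c("SNP", "SNP", "INDEL", "DEL", "DUP", "INS", "INV",
                           "BND", "SNP", "INDEL"),
                QD = round(runif(10, 2, 30), 2),
                MQ = c(round(runif(9, 40, 60), 2), NA),
                dhffc = c(rep(NA, 3), 0.5, rep(NA, 6)),
                rho = c(0.25, rep(NA, 9)))
  # sequence-allele classes need consistent ref/alt for reclassification
  vt$variants$ref[vt$variants$vclass == "INDEL"] <- "ACGT"
  vt$variants$alt[vt$variants$vclass == "INDEL"] <- "A"
  vt$variants$length[vt$variants$vclass == "INDEL"] <- 3L
  vt$variants$end[vt$variants$vclass == "INDEL"] <-
    vt$variants$pos[vt$variants$vclass == "INDEL"] + 3L
  path <- tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  back <- read_vcf(path, panel)
  for (col in c("variant_id", "chrom", "pos", "end", "vclass", "length",
                "QD", "MQ", "dhffc", "rho"))
    expect_equal(back$variants[[col]], vt$variants[[col]], info = col)
  expect_equal(back$geno, vt$geno)
})

test_that("gene models read from BED and GFF3 with correct coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tg1\t0\t+", bed)
  g <- read_gene_models(bed)
  expect_equal(g$start, 1000L)   # BED 0-based half-open -> 1-based inclusive
  expect_equal(g$end, 2000L)
  expect_equal(g$tss, 1000L)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t5000\t8000\t.\t-\t.\tID=g2"), gff)
  g2 <- read_gene_models(gff)
  expect_equal(g2$tss, 8000L)    # minus strand: TSS at end

  gff_bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t5000\t8000\t.\t.\t.\tID=g3"), gff_bad)
  expect_error(read_gene_models(gff_bad), "strand")
})

test_that("gene models round-trip through GFF3", {
  genes <- gene_models(data.frame(
    gene_id = c("ga", "gb"), chrom = "chr1", strand = c("+", "-"),
    start = c(100L, 9000L), end = c(2000L, 12000L)))
  path <- tempfile(fileext = ".gff3")
  write_gene_models(genes, path)
  back <- read_gene_models(path)
  expect_equal(back[c("gene_id", "chrom", "strand", "start", "end", "tss")],
               genes[c("gene_id", "chrom", "strand", "start", "end", "tss")])
})

test_that("expression TSV reading honors shape, NA and log2p1", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tS1__rep1\tS1__rep2\tS1__rep3\tS2__rep1\tS2__rep2\tS2__rep3\tS3__rep1\tS3__rep2\tS3__rep3",
    "g1\t1\t2\t3\t4\t5\t6\t7\t8\t9",
    "g2\t0\t0\tNA\t1\t1\t1\t3\t3\t3"), path)
  em <- read_expression(path, "wet")
  expect_equal(dim(em$values), c(2L, 3L, 3L))
  expect_true(is.na(em$values["g2", "S1", 3]))
  expect_equal(em$values["g1", "S2", 2], 5)
  em2 <- read_expression(path, "wet", log2p1 = TRUE)
  expect_equal(em2$values["g1", "S1", 3], 2)   # log2(3 + 1)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1__rep1\tS1__rep2\tS2__rep1", "g1\t1\t2\t3"), bad)
  expect_error(read_expression(bad, "wet"), "replicate count")
})

test_that("site scores attach to SNPs only and validate their range", {
  vt <- make_vt(matrix(c(0L, 1L, 0L, 1L, 0L, 0L), 2, 3),
                vclass = c("SNP", "INDEL"), pos = c(500L, 600L))
  vt$variants$ref[2] <- "AT"; vt$variants$alt[2] <- "A"
  vt$variants$length[2] <- 1L; vt$variants$end[2] <- 601L
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trho", "chr1\t500\t0.25", "chr1\t600\t0.4",
               "chr1\t999\t0.1"), path)
  expect_message(vt2 <- attach_site_scores(vt, path), "no matching SNP")
  expect_equal(vt2$variants$rho[1], 0.25)
  expect_true(is.na(vt2$variants$rho[2]))   # indel never scored

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trho", "chr1\t500\t1.2"), bad)
  expect_error(read_site_scores(bad), "\\[0,1\\]")
})
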