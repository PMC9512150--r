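test_that("hard filters apply the SNP and indel quality rules", {
  g <- matrix(1L, 6, 3)
  vt <- make_vt(g, vclass = c("SNP", "SNP", "SNP", "INDEL", "INDEL", "INDEL"),
                QD = c(10, 10, NA, 10, 10, 10),
                FS = c(10, 10, NA, 150, 250, 10),
                MQ = c(60, 39, NA, NA, NA, NA),
                SOR = c(1, 1, NA, 5, 5, 11),
                MQRankSum = c(0, 0, NA, NA, NA, NA),
                ReadPosRankSum = c(0, 0, NA, NA, NA, NA),
                length = c(1L, 1L, 1L, 5L, 5L, 5L))
  vt$variants$end <- vt$variants$pos + c(0L, 0L, 0L, 5L, 5L, 5L)
  out <- apply_hard_filters(vt)
  # v001: all criteria pass; v002: MQ = 39 fails; v003: absent annotations pass
  # v004: indel FS 150 < 200 and SOR 5 < 10 pass; v005: FS 250 fails;
  # v006: SOR 11 fails
  expect_equal(out$variants$variant_id, c("v001", "v003", "v004"))

  long <- make_vt(matrix(1L, 1, 3), vclass = "INDEL", length = 25L)
  long$variants$end <- long$variants$pos + 25L
  expect_equal(n_variants(apply_hard_filters(long)), 0L)
})

test_that("hard filters are idempotent and leave SVs untouched", {
  g <- matrix(1L, 3, 3)
  vt <- make_vt(g, vclass = c("SNP", "DEL", "BND"), MQ = c(39, NA, NA),
                dhffc = c(NA, 0.9, NA))
  once <- apply_hard_filters(vt)
  twice <- apply_hard_filters(once)
  expect_equal(once$variants, twice$variants)
  expect_true(all(c("DEL", "BND") %in% once$variants$vclass))
})

test_that("SV filters enforce depth fold-change and size bounds", {
  g <- matrix(1L, 7, 3)
  vt <- make_vt(g, vclass = c("DEL", "DEL", "DUP", "DUP", "DEL", "INV", "BND"),
                length = c(300L, 300L, 300L, 300L, 250001L, 5000L, 0L),
                dhffc = c(0.60, 0.75, NA, NA, 0.5, NA, NA),
                dhbfc = c(NA, NA, 1.80, 1.20, NA, NA, NA))
  out <- filter_sv_records(vt)
  # kept: DEL dhffc .60 < .70; DUP dhbfc 1.8 > 1.3; INV (no depth rule); BND
  expect_setequal(out$variants$variant_id, c("v001", "v003", "v006", "v007"))
  expect_equal(filter_sv_records(out)$variants, out$variants)  # idempotent

  tiny <- make_vt(matrix(1L, 1, 3), vclass = "DEL", length = 20L, dhffc = 0.5)
  expect_equal(n_variants(filter_sv_records(tiny)), 0L)  # rule is strict > 20 bp
})

test_that("same-sample overlapping SV calls are excluded, across samples kept", {
  calls <- data.frame(
    sample = c("A", "A", "A", "A", "B"),
    chrom = "c1",
    pos = c(100L, 150L, 201L, 400L, 150L),
    end = c(200L, 300L, 300L, 450L, 300L),
    vclass = c("DEL", "DUP", "DEL", "DEL", "DUP"),
    length = c(101L, 151L, 100L, 51L, 151L),
    gt = 1L, stringsAsFactors = FALSE)
  out <- exclude_intra_sample_overlaps(calls)
  # A's [100,200] and [150,300] overlap -> both removed; but [201,300] also
  # overlaps [150,300] -> removed too; abutting [400,450] kept; B's kept.
  expect_equal(out$pos, c(400L, 150L))
  expect_equal(out$sample, c("A", "B"))

  abut <- data.frame(sample = "A", chrom = "c1", pos = c(100L, 201L),
                     end = c(200L, 300L), vclass = "DEL", length = c(101L, 100L),
                     gt = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(exclude_intra_sample_overlaps(abut)), 2L)
})

test_that("SV merging honors reciprocal overlap, breakend window and BND rule", {
  fx <- make_fixture("merge_cases")
  calls <- read_sv_calls(fx$calls)
  merged <- merge_svs(calls, fx$panel)
  expect_equal(n_variants(merged), fx$expected_n_merged)
  v <- merged$variants
  # c1 pair merged: representative is first member by (pos, end)
  c1 <- v[v$chrom == "c1", ]
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$pos, c1$end), c(100L, 199L))
  expect_equal(unname(merged$geno[v$chrom == "c1", ]), c(2L, 2L, 0L))
  # c2 pair (20% reciprocal) stays separate
  expect_equal(nrow(v[v$chrom == "c2", ]), 2L)
  # BNDs: exact position merges, off-by-one does not
  c3 <- v[v$chrom == "c3", ]
  expect_equal(nrow(c3), 2L)
  expect_equal(sum(merged$geno[v$chrom == "c3" & v$pos == 5000L, ] == 1L), 2L)
})

test_that("SV merging is invariant to input order", {
  fx <- make_fixture("merge_cases")
  calls <- read_sv_calls(fx$calls)
  merged1 <- merge_svs(calls, fx$panel)
  set.seed(11)
  for (i in 1:5) {
    shuffled <- calls[sample.int(nrow(calls)), , drop = FALSE]
    merged2 <- merge_svs(shuffled, fx$panel)
    expect_equal(merged2$variants[c("chrom", "pos", "end", "vclass")],
                 merged1$variants[c("chrom", "pos", "end", "vclass")])
    expect_equal(unname(merged2$geno), unname(merged1$geno))
  }
})

test_that("breakend distance also gates merging of long overlapping SVs", {
  # 90% reciprocal overlap but both breakends displaced by 1.2 kb -> no merge
  calls <- data.frame(
    sample = c("A", "B"), chrom = "c1",
    pos = c(10000L, 11200L), end = c(21999L, 23199L),
    vclass = "DEL", length = 12000L, gt = 1L, stringsAsFactors = FALSE)
  merged <- merge_svs(calls, sample_panel(c("A", "B")))
  expect_equal(n_variants(merged), 2L)
})

test_that("allele frequencies treat missing genotypes and folding correctly", {
  # 3 heterozygotes among 129 genotyped samples
  g <- matrix(0L, 1, 129); g[1, 1:3] <- 1L
  f <- compute_allele_frequency(make_vt(g))
  expect_equal(f$f_alt, 3 / 258)
  expect_equal(f$maf, 3 / 258)
  # 7 homozygous-alt among 129: f = 14/258 > 5%
  g2 <- matrix(0L, 1, 129); g2[1, 1:7] <- 2L
  f2 <- compute_allele_frequency(make_vt(g2))
  expect_equal(f2$f_alt, 14 / 258)
  expect_gt(f2$maf, 0.05)
  # missing genotypes drop out of numerator and denominator
  g3 <- matrix(c(1L, NA, 0L, 0L), 1, 4)
  expect_equal(compute_allele_frequency(make_vt(g3))$f_alt, 1 / 6)
  # high-frequency alt folds to the reference allele
  g4 <- matrix(2L, 1, 10); g4[1, 1] <- 0L
  f4 <- compute_allele_frequency(make_vt(g4))
  expect_equal(f4$minor, "ref")
  expect_equal(f4$maf, 2 / 20)
  expect_equal(f4$n_hom_minor, 1L)
})

test_that("rare selection applies the class-specific evidence rules", {
  N <- 129
  mk <- function(n_het, n_hom, vclass = "SNP") {
    g <- matrix(0L, 1, N)
    if (n_het > 0) g[1, seq_len(n_het)] <- 1L
    if (n_hom > 0) g[1, n_het + seq_len(n_hom)] <- 2L
    make_vt(g, vclass = vclass)
  }
  # 2 heterozygous SNP carriers, no homozygote -> excluded
  expect_equal(nrow(select_rare_variants(mk(2, 0))$variants), 0L)
  # 3 heterozygous carriers -> retained
  expect_equal(nrow(select_rare_variants(mk(3, 0))$variants), 1L)
  # 1 homozygous minor carrier -> retained
  expect_equal(nrow(select_rare_variants(mk(0, 1))$variants), 1L)
  # SV singleton -> retained (no evidence rule)
  expect_equal(nrow(select_rare_variants(mk(1, 0, "DEL"))$variants), 1L)
  # carrier set is every sample with >= 1 minor allele
  rs <- select_rare_variants(mk(3, 1))
  expect_equal(sum(rs$carriers), 4L)
})

test_that("rare selection matches a brute-force oracle on small panels", {
  set.seed(42)
  for (trial in 1:20) {
    S <- sample(4:8, 1)
    n <- sample(10:50, 1)
    geno <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), S * n, replace = TRUE), n, S)
    classes <- sample(c("SNP", "INDEL", "DEL", "INS"), n, replace = TRUE)
    vt <- make_vt(geno, vclass = classes)
    rs <- select_rare_variants(vt, maf_threshold = 0.3)
    # oracle: per-variant loop recounting alleles and carriers from scratch
    expected <- character(0)
    for (i in seq_len(n)) {
      gi <- geno[i, ]
      called <- !is.na(gi)
      if (!any(called)) next
      f <- sum(gi[called]) / (2 * sum(called))
      maf <- min(f, 1 - f)
      minor_is_alt <- f <= 0.5
      het <- sum(gi[called] == 1L)
      hom <- if (minor_is_alt) sum(gi[called] == 2L) else sum(gi[called] == 0L)
      carriers <- if (minor_is_alt) sum(gi[called] >= 1L) else sum(gi[called] <= 1L)
      rare <- maf < 0.3 && carriers > 0
      if (classes[i] %in% c("SNP", "INDEL")) rare <- rare && (hom >= 1 || het >= 3)
      if (rare) expected <- c(expected, vt$variants$variant_id[i])
    }
    expect_setequal(rs$variants$variant_id, expected)
  }
})

test_that("raising the MAF threshold never shrinks the rare set", {
  set.seed(9)
  geno <- matrix(sample(c(0L, 0L, 0L, 0L, 1L, 2L), 400, replace = TRUE), 50, 8)
  vt <- make_vt(geno)
  prev <- character(0)
  for (thr in c(0.05, 0.1, 0.2, 0.4)) {
    ids <- select_rare_variants(vt, maf_threshold = thr)$variants$variant_id
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})
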