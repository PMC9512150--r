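test_that("variants land in the correct strand-aware windows", {
  fx <- make_fixture("tiny5")
  vt <- read_vcf(fx$vcf)
  genes <- read_gene_models(fx$gff)
  rset <- as_rare_variant_set(vt)
  cube <- assign_variants(rset, genes, mode = "windows")
  a <- cube$assignments
  expect_equal(a$bin[a$variant_id == "snp_u500"], "U_0_2")
  expect_equal(a$bin[a$variant_id == "snp_genic"], "GENIC")
  expect_equal(a$bin[a$variant_id == "snp_u2100"], fx$expected_u2100_bin)

  # mirrored gene on the minus strand: upstream lies beyond the gene end
  gneg <- gene_models(data.frame(gene_id = "gn", chrom = "chr1", strand = "-",
                                 start = 10001L, end = 13000L))
  vneg <- make_vt(matrix(1L, 2, 5), pos = c(13500L, 15100L))
  cneg <- assign_variants(as_rare_variant_set(vneg), gneg, mode = "windows")
  expect_equal(cneg$assignments$bin, c("U_0_2", "U_2_4"))
})

test_that("long SVs hit every bin they overlap; start-mode restricts them", {
  genes <- gene_models(data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                                  start = 10001L, end = 13000L))
  # 3 kb deletion spanning the 0-2 kb window boundary into the gene body
  sv <- make_vt(matrix(1L, 1, 4), vclass = "DEL", pos = 9001L, end = 11000L,
                length = 2000L)
  rset <- as_rare_variant_set(sv)
  both <- assign_variants(rset, genes, mode = "windows")
  expect_setequal(both$assignments$bin, c("U_0_2", "GENIC"))
  start_only <- assign_variants(rset, genes, mode = "windows",
                                sv_assignment = "start")
  expect_equal(start_only$assignments$bin, "U_0_2")
})

test_that("the tiny5 fixture yields the documented cis profile", {
  fx <- make_fixture("tiny5")
  vt <- read_vcf(fx$vcf)
  genes <- read_gene_models(fx$gff)
  em <- read_expression(fx$expr, "wet")
  ranks <- rank_samples(mean_expression(em), em$panel, min_samples = 5L)
  cube <- assign_variants(as_rare_variant_set(vt), genes, mode = "cis")
  prof <- per_rank_profile(cube, ranks)
  expect_equal(prof$mean_count, fx$expected_cis_profile)
  # duplicating the gene leaves the mean profile unchanged
  genes2 <- gene_models(rbind(genes, within(genes, {
    gene_id <- "g2"; start <- start + 50000L; end <- end + 50000L
    tss <- tss + 50000L})))
  # second gene gets no variants, so only g1 contributes counts
  expect_equal(nrow(genes2), 2L)
})

test_that("profile means are conserved and bins partition the cis region", {
  d <- shared_sim_dir()
  pl <- run_pipeline(d, conditions = "wet")
  cc <- pl$conditions$wet
  # conservation: sum over ranks of mean_count * n_genes = total counts
  expect_equal(sum(cc$profile$mean_count * cc$profile$n_genes),
               sum(pool_counts <- cc$cube$counts))
  # windows mode: GENIC + U_0_2 counts equal the cis-mode cube
  cube_w <- assign_variants(pl$rset, cc$genes, mode = "windows")
  expect_equal(cube_w$counts[, , "GENIC"] + cube_w$counts[, , "U_0_2"],
               cc$cube$counts[, , "GENIC"] + cc$cube$counts[, , "U_0_2"])
})

test_that("all-zero burden gives an all-zero profile", {
  panel <- sample_panel(c("S1", "S2", "S3", "S4", "S5"))
  counts <- matrix(0L, 2, 5, dimnames = list(c("g1", "g2"), as.character(panel)))
  vals <- matrix(runif(10), 2, 5, dimnames = dimnames(counts))
  prof <- per_rank_profile(make_cube(counts), make_ranks(vals))
  expect_equal(prof$mean_count, rep(0, 5))
})

test_that("quadratic fit recovers an exact parabola and the closed form", {
  prof <- data.frame(percentile = c(.1, .3, .5, .7, .9),
                     mean_count = c(4, 1, 0, 1, 4))
  qf <- fit_quadratic(prof)
  expect_equal(qf$r2, 1, tolerance = 1e-10)
  expect_equal(qf$c, 25, tolerance = 1e-8)   # y = 25 (x - 1/2)^2
  expect_equal(qf$a, 6.25, tolerance = 1e-8)
  expect_true(qf$convex)

  # agreement with the normal-equations solution on random inputs
  set.seed(8)
  for (i in 1:10) {
    x <- sort(runif(25)); y <- runif(25, 0, 3)
    X <- cbind(1, x, x^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    qf2 <- fit_quadratic(data.frame(percentile = x, mean_count = y))
    expect_equal(c(qf2$a, qf2$b, qf2$c), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("a constant profile has zero curvature and zero r2", {
  prof <- data.frame(percentile = (1:20 - 0.5) / 20, mean_count = rep(2.5, 20))
  qf <- fit_quadratic(prof)
  expect_equal(qf$c, 0, tolerance = 1e-10)
  expect_equal(qf$r2, 0)
  expect_error(fit_quadratic(data.frame(percentile = rep(0.5, 6),
                                        mean_count = 1:6)), "singular")
})

test_that("Mann-Whitney exact branch matches wilcox.test on tie-free data", {
  set.seed(13)
  for (i in 1:25) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- sample(seq(1, 200), nx); y <- sample(seq(201, 400) + 0.5, ny)
    x <- x + runif(nx, 0, .3)                 # guarantee no ties
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact branch handles ties by full enumeration", {
  # pooled {1,1,2,3}: U values over the 6 assignments are {0,1.5,1.5,2.5,2.5,4}
  mw <- mann_whitney(c(1, 2), c(1, 3))
  expect_equal(mw$U, 1.5)
  expect_equal(mw$p, 1)   # 2 * min(3/6, 5/6) = 1
  expect_equal(mw$method, "exact enumeration")
})

test_that("Mann-Whitney large-sample branch matches wilcox.test with ties", {
  set.seed(21)
  for (i in 1:10) {
    x <- sample(1:6, 15, replace = TRUE)
    y <- sample(2:8, 12, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    mw <- mann_whitney(x, y)
    expect_equal(mw$method, "normal approximation")
    expect_equal(mw$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("rank-group tests separate an enriched-extremes profile", {
  # high group all 10, middle all 0, 13 ranks each at N = 65
  mean_count <- rep(0, 65)
  mean_count[1:13] <- 5
  mean_count[53:65] <- 10
  prof <- data.frame(rank = 1:65, percentile = (1:65 - 0.5) / 65,
                     mean_count = mean_count, n_genes = 100L)
  rg <- rank_group_test(prof)
  expect_lt(rg$high_vs_mid$p, 0.001)
  expect_lt(rg$low_vs_mid$p, 0.001)
  # identical groups are not distinguishable
  flat <- data.frame(rank = 1:65, percentile = (1:65 - 0.5) / 65,
                     mean_count = rep(1, 65), n_genes = 100L)
  expect_equal(rank_group_test(flat)$high_vs_mid$p, 1)
})
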