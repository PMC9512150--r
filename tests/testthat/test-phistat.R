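test_that("equal-mass rank bins reproduce the documented cut points", {
  pb10 <- phi_rank_bins(10)
  expect_equal(pb10$extreme, c(1L, 10L))
  expect_equal(pb10$middle, c(5L, 6L))
  pb129 <- phi_rank_bins(129)
  expect_equal(length(pb129$extreme), length(pb129$middle))  # balanced mass
  expect_equal(length(pb129$extreme), 26L)
  expect_true(all(pb129$extreme %in% c(1:13, 117:129)))
  expect_false(any(pb129$middle %in% pb129$extreme))
})

test_that("phi matches the hand-counted 10-rank example", {
  fx <- make_fixture("ranks10")
  vt <- read_vcf(fx$vcf)
  genes <- read_gene_models(fx$gff)
  em <- read_expression(fx$expr, "wet")
  ranks <- rank_samples(mean_expression(em), em$panel)
  cube <- assign_variants(as_rare_variant_set(vt), genes, mode = "cis")
  ph <- compute_phi(cube, ranks)
  expect_equal(ph$E_r, 5)
  expect_equal(ph$M_r, 2)
  expect_equal(ph$phi, fx$expected_phi)
})

test_that("uniform counts across ranks give phi exactly 1", {
  for (N in c(10L, 20L, 129L)) {
    panel <- sample_panel(sprintf("S%03d", seq_len(N)))
    counts <- matrix(3L, 4, N,
                     dimnames = list(sprintf("g%d", 1:4), as.character(panel)))
    vals <- matrix(rep(seq_len(N), each = 4) + runif(4 * N, 0, .01), 4, N,
                   dimnames = dimnames(counts))
    ph <- compute_phi(make_cube(counts), make_ranks(vals))
    expect_equal(ph$phi, 1)
  }
})

test_that("phi agrees with a brute-force double loop on random instances", {
  set.seed(31)
  for (i in 1:15) {
    G <- sample(3:20, 1); N <- sample(12:20, 1)
    panel <- sample_panel(sprintf("S%02d", seq_len(N)))
    counts <- matrix(rpois(G * N, 0.7), G, N,
                     dimnames = list(sprintf("g%02d", 1:G), as.character(panel)))
    vals <- matrix(runif(G * N), G, N, dimnames = dimnames(counts))
    ranks <- make_ranks(vals)
    ph <- compute_phi(make_cube(counts), ranks)
    ref <- brute_phi(counts, ranks$rank, ranks$n_g)
    expect_equal(ph$E_r, ref$E_r)
    expect_equal(ph$M_r, ref$M_r)
  }
})

test_that("phi handles genes ranked in fewer samples via their own bins", {
  panel <- sample_panel(sprintf("S%02d", 1:20))
  counts <- matrix(rpois(40, 1), 2, 20,
                   dimnames = list(c("full", "partial"), as.character(panel)))
  vals <- matrix(runif(40), 2, 20, dimnames = dimnames(counts))
  vals["partial", 1:6] <- NA
  ranks <- make_ranks(vals)
  ph <- compute_phi(make_cube(counts), ranks)
  counts2 <- counts; counts2["partial", 1:6] <- 0L  # unranked cells never count
  ref <- brute_phi(counts2, ranks$rank, ranks$n_g)
  expect_equal(ph$phi, ref$phi)
})

test_that("phi is undefined (flagged) when the middle bins are empty", {
  panel <- sample_panel(sprintf("S%d", 1:10))
  counts <- matrix(0L, 1, 10, dimnames = list("g", as.character(panel)))
  counts[1, 1] <- 5L
  vals <- matrix(1:10, 1, 10, dimnames = dimnames(counts))
  ph <- compute_phi(make_cube(counts), make_ranks(vals))
  expect_true(ph$undefined)
  expect_true(is.na(ph$phi))
})

test_that("the Fisher odds ratio equals the phi ratio algebraically", {
  mk <- function(E, M) structure(list(E_r = E, M_r = M, phi = E / M,
                                      undefined = FALSE), class = "phi_result")
  cmp <- fisher_compare(mk(10, 5), mk(4, 4))
  expect_equal(cmp$odds_ratio, 2)
  flat <- fisher_compare(mk(5, 5), mk(5, 5))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$fisher_p, 1)
  set.seed(17)
  for (i in 1:200) {
    a <- mk(sample(1:500, 1), sample(1:500, 1))
    b <- mk(sample(1:500, 1), sample(1:500, 1))
    expect_equal(fisher_compare(a, b)$odds_ratio, a$phi / b$phi,
                 tolerance = 1e-12)
  }
  expect_error(fisher_compare(mk(0, 0), mk(1, 1)), "zero margin")
})

test_that("relative phi increase is plain percentage arithmetic", {
  expect_equal(phi_relative_increase(1.1, 1.0), 10, tolerance = 1e-12)
  mk <- function(E, M) structure(list(E_r = E, M_r = M, phi = E / M,
                                      undefined = FALSE), class = "phi_result")
  expect_equal(phi_relative_increase(mk(12, 10), mk(10, 10)), 20)
})

test_that("permutation test returns p = 1 for identical datasets", {
  set.seed(41)
  panel <- sample_panel(sprintf("S%02d", 1:20))
  counts <- matrix(rpois(200, 1), 10, 20,
                   dimnames = list(sprintf("g%02d", 1:10), as.character(panel)))
  vals <- matrix(runif(200), 10, 20, dimnames = dimnames(counts))
  cube <- make_cube(counts); ranks <- make_ranks(vals)
  res <- permutation_test_phi(cube, ranks, cube, ranks, n_perm = 50, seed = 1)
  expect_equal(res$delta_obs, 0)
  expect_equal(res$p, 1)
})

test_that("relabeling the datasets flips the sign of the statistic", {
  set.seed(43)
  panel <- sample_panel(sprintf("S%02d", 1:20))
  mk <- function() {
    counts <- matrix(rpois(200, 1), 10, 20,
                     dimnames = list(sprintf("g%02d", 1:10), as.character(panel)))
    vals <- matrix(runif(200), 10, 20, dimnames = dimnames(counts))
    list(cube = make_cube(counts), ranks = make_ranks(vals))
  }
  A <- mk(); B <- mk()
  ab <- permutation_test_phi(A$cube, A$ranks, B$cube, B$ranks, n_perm = 400, seed = 7)
  ba <- permutation_test_phi(B$cube, B$ranks, A$cube, A$ranks, n_perm = 400, seed = 7)
  expect_equal(ba$delta_obs, -ab$delta_obs)
  # two-sided p is label-symmetric up to permutation noise
  expect_lt(abs(ab$p - ba$p), 0.12)
})

test_that("permutations are seed-reproducible", {
  set.seed(47)
  panel <- sample_panel(sprintf("S%02d", 1:15))
  counts <- matrix(rpois(150, 1), 10, 15,
                   dimnames = list(sprintf("g%02d", 1:10), as.character(panel)))
  vals <- matrix(runif(150), 10, 15, dimnames = dimnames(counts))
  counts2 <- counts; counts2[1, ] <- counts2[1, ] + 2L
  a <- permutation_test_phi(make_cube(counts), make_ranks(vals),
                            make_cube(counts2), make_ranks(vals),
                            n_perm = 100, seed = 5)
  b <- permutation_test_phi(make_cube(counts), make_ranks(vals),
                            make_cube(counts2), make_ranks(vals),
                            n_perm = 100, seed = 5)
  expect_equal(a$deltas, b$deltas)
  expect_equal(a$p, b$p)
})

test_that("the permutation null centres phi at one on exchangeable counts", {
  set.seed(53)
  panel <- sample_panel(sprintf("S%02d", 1:26))
  phis <- replicate(60, {
    counts <- matrix(rpois(30 * 26, 0.8), 30, 26,
                     dimnames = list(sprintf("g%02d", 1:30), as.character(panel)))
    vals <- matrix(runif(30 * 26), 30, 26, dimnames = dimnames(counts))
    compute_phi(make_cube(counts), make_ranks(vals))$phi
  })
  se <- sd(phis) / sqrt(length(phis))
  expect_lt(abs(mean(phis) - 1), 3 * se + 0.02)
})
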