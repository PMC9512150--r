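#' Equal-mass extreme/middle rank bins
#'
#' Given `n` ranked samples, returns the rank indices counted as expression
#' extremes (lowest and highest `extreme[1]` / `1 - extreme[2]` of ranks)
#' and as the middle block. Membership is computed on rank counts, not raw
#' percentile intervals: `k = round(n * fraction)` ranks at each extreme,
#' and — whenever the nominal extreme and middle masses are equal, as with
#' the defaults (10% + 10% vs 40-60%) — a middle block of exactly the same
#' total size centred on the median rank. This guarantees that exchangeable
#' counts give an extreme-to-middle ratio with expectation 1 for every `n`,
#' including odd panel sizes where raw percentile intervals would be
#' unbalanced.
#'
#' @param n number of ranked samples.
#' @param extreme cut points `(lo, hi)`: percentiles below `lo` or at/above
#'   `hi` are extreme (default `c(0.10, 0.90)`).
#' @param middle middle percentile interval (default `c(0.40, 0.60)`).
#' @return list with integer vectors `extreme` and `middle` of rank indices.
#' @export
phi_rank_bins <- function(n, extreme = c(0.10, 0.90), middle = c(0.40, 0.60)) {
  k_lo <- max(1L, round(n * extreme[1]))
  k_hi <- max(1L, round(n * (1 - extreme[2])))
  ext <- c(seq_len(k_lo), seq.int(n - k_hi + 1L, n))
  nominal_equal <- abs((extreme[1] + 1 - extreme[2]) - (middle[2] - middle[1])) < 1e-9
  m_mid <- if (nominal_equal) k_lo + k_hi else max(1L, round(n * (middle[2] - middle[1])))
  centre <- n * (middle[1] + middle[2]) / 2
  start <- floor(centre - m_mid / 2)
  mid <- seq.int(start + 1L, start + m_mid)
  if (any(mid %in% ext) || any(mid < 1L) || any(mid > n))
    stop("extreme and middle rank bins overlap; check cut points for n = ", n)
  list(extreme = sort(unique(ext)), middle = mid)
}

#' The extreme-to-middle rare-allele ratio phi = E_r / M_r
#'
#' `E_r` totals rare-variant carrier counts over (gene, sample) cells whose
#' expression rank falls in the extreme bins (top and bottom 10% of ranks by
#' default) and `M_r` over the middle bins (40-60%); `phi = E_r / M_r`.
#' Under no genotype-expression association phi is about 1; outlier
#' enrichment pushes it above 1. Rank-bin membership is per gene (genes
#' ranked in fewer samples use their own `n_g`), with equal-mass bins (see
#' [phi_rank_bins()]).
#'
#' @param cube a [assign_variants()] burden cube.
#' @param ranks a [rank_samples()] rank table.
#' @param bins region bins pooled before counting (default: all in cube).
#' @param extreme,middle cut points passed to [phi_rank_bins()].
#' @return list of class `phi_result`: `E_r`, `M_r`, `phi`, the cut points
#'   and the numbers of extreme/middle ranks used (at the modal `n_g`).
#' @export
compute_phi <- function(cube, ranks, bins = NULL,
                        extreme = c(0.10, 0.90), middle = c(0.40, 0.60)) {
  common <- intersect(cube$genes, ranks$genes)
  if (!length(common)) stop("cube and rank table share no genes")
  C <- pool_bins(cube, bins)[common, , drop = FALSE]
  gi <- match(common, ranks$genes)
  R <- ranks$rank[gi, , drop = FALSE]
  ng <- ranks$n_g[gi]
  E_r <- 0; M_r <- 0
  for (n in unique(ng)) {
    pb <- phi_rank_bins(n, extreme, middle)
    cls <- integer(n)                    # 0 other, 1 extreme, 2 middle
    cls[pb$extreme] <- 1L
    cls[pb$middle] <- 2L
    rows <- which(ng == n)
    Rn <- R[rows, , drop = FALSE]
    Cn <- C[rows, , drop = FALSE]
    ok <- !is.na(Rn)
    cl <- cls[Rn[ok]]
    vals <- Cn[ok]
    E_r <- E_r + sum(vals[cl == 1L])
    M_r <- M_r + sum(vals[cl == 2L])
  }
  pb0 <- phi_rank_bins(as.integer(stats::median(ng)), extreme, middle)
  phi <- if (M_r > 0) E_r / M_r else NA_real_
  structure(list(E_r = E_r, M_r = M_r, phi = phi,
                 extreme = extreme, middle = middle,
                 n_extreme_ranks = length(pb0$extreme),
                 n_middle_ranks = length(pb0$middle),
                 undefined = M_r == 0),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("phi = E_r/M_r = %d/%d = %s\n", round(x$E_r), round(x$M_r),
              if (x$undefined) "undefined (M_r = 0)" else sprintf("%.4f", x$phi)))
  invisible(x)
}

#' Relative increase between two phi values, in percent
#'
#' `100 * (phi_num / phi_den - 1)`; e.g. the stress-over-normal increase of
#' the rare-allele extreme-to-middle ratio.
#'
#' @param phi_num,phi_den phi values (or `phi_result` objects).
#' @export
phi_relative_increase <- function(phi_num, phi_den) {
  if (inherits(phi_num, "phi_result")) phi_num <- phi_num$phi
  if (inherits(phi_den, "phi_result")) phi_den <- phi_den$phi
  100 * (phi_num / phi_den - 1)
}

#' Contingency comparison of two phi results
#'
#' Builds the 2x2 table `[[E_A, M_A], [E_B, M_B]]`, computes the sample odds
#' ratio `(E_A * M_B) / (M_A * E_B)` — algebraically identical to
#' `phi_A / phi_B` — and a two-sided Fisher's exact p-value.
#'
#' @param phiA,phiB `phi_result` objects.
#' @param labels character pair naming the strata.
#' @return list of class `stratum_comparison`: `table`, `odds_ratio`,
#'   `fisher_p`, `labels`.
#' @export
fisher_compare <- function(phiA, phiB, labels = c("A", "B")) {
  cells <- c(phiA$E_r, phiA$M_r, phiB$E_r, phiB$M_r)
  if (any(!is.finite(cells))) stop("non-finite contingency cells")
  tab <- matrix(round(cells), nrow = 2, byrow = TRUE,
                dimnames = list(labels, c("extreme", "middle")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  or <- (phiA$E_r * phiB$M_r) / (phiA$M_r * phiB$E_r)
  p <- stats::fisher.test(tab)$p.value
  structure(list(table = tab, odds_ratio = or, fisher_p = p, labels = labels),
            class = "stratum_comparison")
}

#' @export
print.stratum_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: OR = %.4f, Fisher p = %.3g\n",
              x$labels[1], x$labels[2], x$odds_ratio, x$fisher_p))
  print(x$table)
  invisible(x)
}

# Run fn with a temporary RNG state seeded by `seed` (NULL = current stream).
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  fn()
}

# Flatten a (cube, ranks) pair into per-gene blocks for fast within-gene
# permutation of the rank-class assignment. Returns the count vector (block
# contiguous), a class template aligned to blocks (1 extreme, 2 middle), and
# the block id vector.
.phi_perm_layout <- function(cube, ranks, bins, extreme, middle) {
  common <- intersect(cube$genes, ranks$genes)
  C <- pool_bins(cube, bins)[common, , drop = FALSE]
  gi <- match(common, ranks$genes)
  R <- ranks$rank[gi, , drop = FALSE]
  ng <- ranks$n_g[gi]
  counts <- vector("list", length(common))
  cls <- vector("list", length(common))
  cls_by_n <- list()
  for (g in seq_along(common)) {
    n <- ng[g]
    key <- as.character(n)
    if (is.null(cls_by_n[[key]])) {
      pb <- phi_rank_bins(n, extreme, middle)
      v <- integer(n); v[pb$extreme] <- 1L; v[pb$middle] <- 2L
      cls_by_n[[key]] <- v
    }
    idx <- which(!is.na(R[g, ]))
    counts[[g]] <- C[g, idx[order(R[g, idx])]]   # position r = count at rank r
    cls[[g]] <- cls_by_n[[key]]
  }
  list(v = unlist(counts, use.names = FALSE),
       cls = unlist(cls, use.names = FALSE),
       block = rep(seq_along(common), lengths(counts)))
}

.phi_perm_em <- function(layout, o = NULL) {
  v <- if (is.null(o)) layout$v else layout$v[o]
  c(E = sum(v[layout$cls == 1L]), M = sum(v[layout$cls == 2L]))
}

#' Permutation test for a difference in phi between two datasets
#'
#' The observed statistic is `delta = phi_A - phi_B`. The null is built by
#' independently permuting, within each gene and in both datasets, the
#' assignment of samples to expression ranks (breaking any
#' genotype-expression link while preserving both marginal structures) and
#' recomputing the difference. The p-value uses the add-one finite-sampling
#' correction `(1 + #{|delta*| >= |delta|}) / (n_perm + 1)` so it is never
#' zero.
#'
#' @param cubeA,cubeB burden cubes for the two datasets (e.g. conditions).
#' @param ranksA,ranksB matching rank tables.
#' @param bins region bins pooled before counting.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param extreme,middle cut points passed to [phi_rank_bins()].
#' @return list of class `phi_permutation`: `delta_obs`, `p`, `phi_A`,
#'   `phi_B`, `n_perm`, and the permuted `delta` vector.
#' @export
permutation_test_phi <- function(cubeA, ranksA, cubeB, ranksB, bins = NULL,
                                 n_perm = 1000L, seed = NULL,
                                 extreme = c(0.10, 0.90),
                                 middle = c(0.40, 0.60)) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  layA <- .phi_perm_layout(cubeA, ranksA, bins, extreme, middle)
  layB <- .phi_perm_layout(cubeB, ranksB, bins, extreme, middle)
  emA <- .phi_perm_em(layA); emB <- .phi_perm_em(layB)
  if (emA["M"] == 0 || emB["M"] == 0) stop("undefined phi (M_r = 0)")
  phiA <- emA["E"] / emA["M"]; phiB <- emB["E"] / emB["M"]
  delta_obs <- unname(phiA - phiB)
  deltas <- with_seed(seed, function() {
    vapply(seq_len(n_perm), function(b) {
      oA <- order(layA$block, stats::runif(length(layA$v)))
      oB <- order(layB$block, stats::runif(length(layB$v)))
      eA <- .phi_perm_em(layA, oA); eB <- .phi_perm_em(layB, oB)
      pA <- if (eA["M"] > 0) eA["E"] / eA["M"] else NA_real_
      pB <- if (eB["M"] > 0) eB["E"] / eB["M"] else NA_real_
      unname(pA - pB)
    }, numeric(1))
  })
  ok <- !is.na(deltas)
  p <- (1 + sum(abs(deltas[ok]) >= abs(delta_obs) - 1e-12)) / (sum(ok) + 1)
  structure(list(delta_obs = delta_obs, p = p, phi_A = unname(phiA),
                 phi_B = unname(phiB), n_perm = n_perm, deltas = deltas),
            class = "phi_permutation")
}

#' @export
print.phi_permutation <- function(x, ...) {
  cat(sprintf("phi permutation test: phi_A = %.4f, phi_B = %.4f, delta = %.4f, p = %.4f (%d permutations)\n",
              x$phi_A, x$phi_B, x$delta_obs, x$p, x$n_perm))
  invisible(x)
}
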