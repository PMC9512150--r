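#' Region bin labels used for variant-to-gene assignment
#'
#' `GENIC` is the gene body; `U_a_b` are strand-aware windows (a, b] kb
#' upstream of the TSS; `U_GT20` covers 20-100 kb (capped to bound the
#' search).
#' @export
REGION_BINS <- c("GENIC", "U_0_2", "U_2_4", "U_4_6", "U_6_8", "U_8_10",
                 "U_10_12", "U_12_14", "U_14_16", "U_16_18", "U_18_20",
                 "U_GT20")

#' Bins pooled for the headline cis analysis (gene body + 2 kb upstream)
#' @export
CIS_BINS <- c("GENIC", "U_0_2")

.upstream_bounds_kb <- rbind(
  U_0_2 = c(0, 2),   U_2_4 = c(2, 4),   U_4_6 = c(4, 6),   U_6_8 = c(6, 8),
  U_8_10 = c(8, 10), U_10_12 = c(10, 12), U_12_14 = c(12, 14),
  U_14_16 = c(14, 16), U_16_18 = c(16, 18), U_18_20 = c(18, 20),
  U_GT20 = c(20, 100))

#' Genomic intervals of the region bins of each gene
#'
#' For a `+` strand gene, the (a, b] kb upstream window covers positions
#' `[tss - 1000 b, tss - 1000 a - 1]`; for a `-` strand gene it covers
#' `[tss + 1000 a + 1, tss + 1000 b]`. `GENIC` is `[start, end]`. Bins are
#' disjoint within a gene by construction.
#'
#' @param genes gene-model data.frame.
#' @param bins subset of [REGION_BINS] to build (default all).
#' @return data.frame with `gene_id`, `bin`, `chrom`, `start`, `end`.
#' @export
gene_bin_ranges <- function(genes, bins = REGION_BINS) {
  out <- vector("list", length(bins))
  for (bi in seq_along(bins)) {
    b <- bins[bi]
    if (b == "GENIC") {
      out[[bi]] <- data.frame(gene_id = genes$gene_id, bin = b,
                              chrom = genes$chrom,
                              start = genes$start, end = genes$end,
                              stringsAsFactors = FALSE)
    } else {
      a_bp <- .upstream_bounds_kb[b, 1] * 1000
      b_bp <- .upstream_bounds_kb[b, 2] * 1000
      plus <- genes$strand == "+"
      start <- ifelse(plus, genes$tss - b_bp, genes$tss + a_bp + 1)
      end <- ifelse(plus, genes$tss - a_bp - 1, genes$tss + b_bp)
      out[[bi]] <- data.frame(gene_id = genes$gene_id, bin = b,
                              chrom = genes$chrom,
                              start = pmax(1, start), end = end,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[res$start <= res$end, , drop = FALSE]
}

#' Assign rare variants to gene region bins and count carriers
#'
#' A variant is assigned to a gene's bin when its position lies in the bin
#' (SNP/INDEL/BND: the start position; other SVs: any overlap of the
#' variant's `[pos, end]` interval, so a long deletion can hit several
#' bins). Each carrier of the minor allele contributes one count (or its
#' allele dosage when `dosage = TRUE`) to `counts[gene, sample, bin]` per
#' assigned variant. A variant may be assigned to multiple genes.
#'
#' @param rset a `rare_variant_set` (see [select_rare_variants()] or
#'   [as_rare_variant_set()]).
#' @param genes gene-model data.frame.
#' @param mode `"cis"` (GENIC + 0-2 kb upstream) or `"windows"` (all bins).
#' @param sv_assignment `"overlap"` (default) or `"start"` to force SVs to be
#'   assigned by start position only.
#' @param dosage count allele copies instead of carrier presence.
#' @return object of class `burden_cube`: 3-d `counts` array
#'   genes x samples x bins plus `genes`, `panel`, `bins`, and an
#'   `assignments` data.frame (variant, gene, bin).
#' @export
assign_variants <- function(rset, genes, mode = c("cis", "windows"),
                            sv_assignment = c("overlap", "start"),
                            dosage = FALSE) {
  mode <- match.arg(mode)
  sv_assignment <- match.arg(sv_assignment)
  bins <- if (mode == "cis") CIS_BINS else REGION_BINS
  br <- gene_bin_ranges(genes, bins)
  v <- rset$variants
  sv_extended <- v$vclass %in% SV_CLASSES & v$vclass != "BND" &
    sv_assignment == "overlap"
  v_end <- ifelse(sv_extended, v$end, v$pos)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v_end))
  bgr <- GenomicRanges::GRanges(br$chrom, IRanges::IRanges(br$start, br$end))
  hits <- GenomicRanges::findOverlaps(vgr, bgr)
  hv <- S4Vectors::queryHits(hits)
  hb <- S4Vectors::subjectHits(hits)

  G <- nrow(genes); S <- length(rset$panel); B <- length(bins)
  gene_idx <- match(br$gene_id[hb], genes$gene_id)
  bin_idx <- match(br$bin[hb], bins)
  counts <- array(0L, dim = c(G, S, B),
                  dimnames = list(genes$gene_id, as.character(rset$panel), bins))
  if (length(hv)) {
    car_idx <- lapply(seq_len(nrow(v)), function(i) which(rset$carriers[i, ]))
    car_len <- lengths(car_idx)
    keep <- car_len[hv] > 0L
    hv2 <- hv[keep]; g2 <- gene_idx[keep]; b2 <- bin_idx[keep]
    if (length(hv2)) {
      ss <- unlist(car_idx[hv2], use.names = FALSE)
      gg <- rep(g2, car_len[hv2])
      bb <- rep(b2, car_len[hv2])
      lin <- (bb - 1L) * (G * S) + (ss - 1L) * G + gg
      if (!dosage) {
        counts[] <- tabulate(lin, nbins = G * S * B)
      } else {
        w <- rep(NA_real_, length(ss))
        vv <- rep(hv2, car_len[hv2])
        w <- ifelse(rset$freq$minor[vv] == "alt",
                    rset$geno[cbind(vv, ss)],
                    2L - rset$geno[cbind(vv, ss)])
        agg <- rowsum(w, lin)
        tmp <- numeric(G * S * B)
        tmp[as.integer(rownames(agg))] <- agg[, 1]
        counts[] <- tmp
      }
    }
  }
  assignments <- data.frame(variant_id = v$variant_id[hv],
                            gene_id = br$gene_id[hb], bin = br$bin[hb],
                            stringsAsFactors = FALSE)
  structure(list(counts = counts, genes = genes$gene_id,
                 panel = rset$panel, bins = bins, mode = mode,
                 assignments = assignments),
            class = "burden_cube")
}

#' @export
print.burden_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("burden_cube [%s]: %d genes x %d samples x %d bins; total count %d\n",
              x$mode, d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

# Pool a cube's counts over a selection of bins -> genes x samples matrix.
pool_bins <- function(cube, bins = NULL) {
  if (is.null(bins)) bins <- cube$bins
  miss <- setdiff(bins, cube$bins)
  if (length(miss)) stop("bins not in cube: ", paste(miss, collapse = ", "))
  sel <- match(bins, cube$bins)
  out <- matrix(0, dim(cube$counts)[1], dim(cube$counts)[2],
                dimnames = dimnames(cube$counts)[1:2])
  for (b in sel) out <- out + cube$counts[, , b]
  out
}

#' Mean rare-variant count per expression rank
#'
#' For each raw rank position `r` in `1..N` (N = panel size), the mean over
#' genes of the burden count of the sample holding rank `r` at that gene.
#' Genes ranked in fewer than N samples contribute through percentile
#' binning (their percentiles mapped into N equal bins), so the mean at each
#' rank is taken over the genes actually contributing there.
#'
#' @param cube a [assign_variants()] burden cube.
#' @param ranks a [rank_samples()] rank table (shared genes/panel).
#' @param bins bins pooled for the profile (default: all bins in the cube).
#' @return data.frame of class `per_rank_profile` with `rank`, `percentile`,
#'   `mean_count`, `n_genes`.
#' @export
per_rank_profile <- function(cube, ranks, bins = NULL) {
  common <- intersect(cube$genes, ranks$genes)
  if (!length(common)) stop("cube and rank table share no genes")
  C <- pool_bins(cube, bins)[common, , drop = FALSE]
  gi <- match(common, ranks$genes)
  R <- ranks$rank[gi, , drop = FALSE]
  ng <- ranks$n_g[gi]
  N <- length(cube$panel)
  G <- length(common)
  sum_r <- numeric(N); n_r <- integer(N)
  full <- ng == N
  if (any(full)) {
    Rf <- R[full, , drop = FALSE]
    Cf <- C[full, , drop = FALSE]
    ok <- !is.na(Rf)
    gidx <- row(Rf)[ok]
    ridx <- Rf[ok]
    sum_r <- sum_r + as.numeric(tapply(Cf[ok], ridx, sum, default = 0)[as.character(seq_len(N))])
    sum_r[is.na(sum_r)] <- 0
    n_r <- n_r + sum(full)
  }
  if (any(!full)) {
    for (g in which(!full)) {
      idx <- which(!is.na(R[g, ]))
      perc <- (R[g, idx] - 0.5) / ng[g]
      rbin <- pmin(N, pmax(1L, ceiling(perc * N)))
      for (j in seq_along(idx)) {
        sum_r[rbin[j]] <- sum_r[rbin[j]] + C[g, idx[j]]
      }
      contrib <- unique(rbin)
      n_r[contrib] <- n_r[contrib] + 1L
    }
  }
  mean_count <- ifelse(n_r > 0, sum_r / n_r, NA_real_)
  structure(data.frame(rank = seq_len(N), percentile = (seq_len(N) - 0.5) / N,
                       mean_count = mean_count, n_genes = n_r),
            class = c("per_rank_profile", "data.frame"))
}

#' Quadratic fit of a per-rank profile
#'
#' Ordinary least squares of the mean count on percentile and squared
#' percentile, `m(x) = a + b x + c x^2`. The U-shape diagnostic is a convex
#' fit (`c > 0`) with non-trivial `r2`. `p` is the overall F-test of the
#' model.
#'
#' @param profile a [per_rank_profile()] (or any data.frame with
#'   `percentile` and `mean_count`).
#' @return list of class `quad_fit`: `a`, `b`, `c`, `r2`, `p`, `convex`.
#' @export
fit_quadratic <- function(profile) {
  ok <- !is.na(profile$mean_count)
  x <- profile$percentile[ok]; y <- profile$mean_count[ok]
  if (length(x) < 4L) stop("need at least 4 rank points for a quadratic fit")
  if (length(unique(x)) < 3L) stop("singular design: need >= 3 distinct percentiles")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  if (sst <= .Machine$double.eps * max(1, sum(y^2))) {
    r2 <- 0; p <- NA_real_
  } else {
    r2 <- 1 - sse / sst
    fs <- suppressWarnings(summary(fit))$fstatistic  # perfect fits warn
    p <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  structure(list(a = cf[1], b = cf[2], c = cf[3], r2 = r2, p = p,
                 convex = cf[3] > 0),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("quadratic fit: m(x) = %.4g + %.4g x + %.4g x^2; r2 = %.3f, p = %.3g\n",
              x$a, x$b, x$c, x$r2, x$p))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts pairs where an `x` value exceeds a `y` value (ties count 1/2).
#' For group sizes of at most `exact_max` on both sides the null is
#' enumerated exactly over all assignments of the pooled values (valid under
#' ties); otherwise the tie-corrected normal approximation with continuity
#' correction is used, matching `stats::wilcox.test`.
#'
#' @param x,y numeric vectors.
#' @param exact_max enumeration threshold (default 8).
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty group in Mann-Whitney test")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (max(nx, ny) <= exact_max) {
    pooled <- c(x, y)
    n <- nx + ny
    combos <- utils::combn(n, nx)
    rr <- rank(pooled)
    Uvals <- apply(combos, 2L, function(idx) sum(rr[idx]) - nx * (nx + 1) / 2)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Uvals <= U + eps), mean(Uvals >= U - eps)))
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Compare extreme rank groups to the middle
#'
#' Splits the per-rank profile means into low (bottom 20% of percentiles),
#' middle (40-60%) and high (top 20%) groups (half-open `[lo, hi)`
#' intervals) and runs two-sided Mann-Whitney tests of high vs middle and
#' low vs middle.
#'
#' @param profile a [per_rank_profile()].
#' @param low,mid,high percentile intervals defining the groups.
#' @return list of class `rank_group_test` with per-comparison `U` and `p`
#'   plus the group sizes.
#' @export
rank_group_test <- function(profile, low = c(0, 0.20), mid = c(0.40, 0.60),
                            high = c(0.80, 1.0)) {
  if (nrow(profile) < 15L)
    stop("need at least 15 rank points for rank-group tests")
  p <- profile$percentile
  in_int <- function(int) !is.na(profile$mean_count) & p >= int[1] & p < int[2]
  g_low <- profile$mean_count[in_int(low)]
  g_mid <- profile$mean_count[in_int(mid)]
  g_high <- profile$mean_count[in_int(high)]
  if (!length(g_low) || !length(g_mid) || !length(g_high))
    stop("empty rank group; widen the percentile intervals")
  hm <- mann_whitney(g_high, g_mid)
  lm_ <- mann_whitney(g_low, g_mid)
  structure(list(high_vs_mid = hm, low_vs_mid = lm_,
                 n_low = length(g_low), n_mid = length(g_mid),
                 n_high = length(g_high)),
            class = "rank_group_test")
}

#' @export
print.rank_group_test <- function(x, ...) {
  cat(sprintf("rank groups (n = %d/%d/%d low/mid/high):\n", x$n_low, x$n_mid, x$n_high))
  cat(sprintf("  high vs mid: U = %.1f, p = %.3g (%s)\n",
              x$high_vs_mid$U, x$high_vs_mid$p, x$high_vs_mid$method))
  cat(sprintf("  low  vs mid: U = %.1f, p = %.3g (%s)\n",
              x$low_vs_mid$U, x$low_vs_mid$p, x$low_vs_mid$method))
  invisible(x)
}
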