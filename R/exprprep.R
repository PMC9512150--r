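#' Robust-expression gene filter
#'
#' A gene is retained when the number of samples showing non-zero expression
#' in at least `min_replicates` replicates reaches
#' `floor(min_fraction * n_samples)`. With the defaults and a 129-sample
#' panel the threshold is 109 samples (109/129 = 84.5%, i.e. the floor of
#' 85%).
#'
#' @param em an [expression_matrix()].
#' @param min_fraction minimum fraction of samples (default 0.85).
#' @param min_replicates replicates that must be non-zero (default 2).
#' @return the filtered [expression_matrix()]; attribute `kept` holds the
#'   logical mask over input genes and `threshold` the sample threshold used.
#' @export
robust_gene_filter <- function(em, min_fraction = 0.85, min_replicates = 2L) {
  d <- dim(em$values)
  if (d[2] == 0L) stop("expression matrix has zero samples")
  nz <- matrix(0L, d[1], d[2])
  for (k in seq_len(d[3])) {
    v <- em$values[, , k]
    nz <- nz + (!is.na(v) & v > 0)
  }
  thr <- floor(min_fraction * d[2])
  n_ok <- rowSums(nz >= min_replicates)
  keep <- n_ok >= thr
  out <- expression_matrix(em$values[keep, , , drop = FALSE], em$condition, em$panel)
  attr(out, "kept") <- keep
  attr(out, "threshold") <- thr
  out
}

#' Remove genes with heavy transposable-element overlap
#'
#' A gene is removed when some TE interval covers strictly more than
#' `reciprocal` of the gene *and* the gene covers strictly more than
#' `reciprocal` of that TE (reciprocal overlap, strict).
#'
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param te_intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), or a BED path (converted on ingestion).
#' @param reciprocal overlap fraction threshold (default 0.50, strict `>`).
#' @return list with `genes` (retained), `removed` (gene ids removed).
#' @export
remove_te_genes <- function(genes, te_intervals, reciprocal = 0.50) {
  if (is.character(te_intervals)) {
    gr <- rtracklayer::import(te_intervals, format = "bed")
    te_intervals <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                               start = BiocGenerics::start(gr),
                               end = BiocGenerics::end(gr))
  }
  removed <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    te <- te_intervals[te_intervals$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(te)) next
    ov <- pmax(0L, pmin(genes$end[i], te$end) - pmax(genes$start[i], te$start) + 1L)
    glen <- genes$end[i] - genes$start[i] + 1L
    tlen <- te$end - te$start + 1L
    removed[i] <- any(ov / glen > reciprocal & ov / tlen > reciprocal)
  }
  list(genes = genes[!removed, , drop = FALSE],
       removed = genes$gene_id[removed])
}

#' Replicate-averaged expression
#'
#' Arithmetic mean over non-missing replicates; a (gene, sample) cell is
#' missing only when all replicates are missing.
#'
#' @param em an [expression_matrix()].
#' @return numeric matrix genes x samples.
#' @export
mean_expression <- function(em) {
  d <- dim(em$values)
  sum_ <- matrix(0, d[1], d[2])
  nrep <- matrix(0L, d[1], d[2])
  for (k in seq_len(d[3])) {
    v <- em$values[, , k]
    ok <- !is.na(v)
    sum_[ok] <- sum_[ok] + v[ok]
    nrep <- nrep + ok
  }
  out <- sum_ / nrep
  out[nrep == 0L] <- NA_real_
  dimnames(out) <- dimnames(em$values)[1:2]
  out
}

#' Rank samples within each gene by expression
#'
#' Ascending ranks `1..n_g` (1 = lowest expression) over the samples with a
#' value for the gene. Ties are broken deterministically by canonical panel
#' order, or randomly under a seed when `tie_break = "random"`. Percentile is
#' `(rank - 0.5) / n_g`. Genes ranked in fewer than `min_samples` samples are
#' excluded (their ids are recorded in the `excluded` attribute).
#'
#' @param mexpr genes x samples matrix from [mean_expression()].
#' @param panel a [sample_panel()].
#' @param min_samples minimum ranked samples per gene (default 10).
#' @param tie_break `"panel"` (deterministic, default) or `"random"`.
#' @param seed RNG seed used only for random tie-breaking.
#' @return object of class `rank_table`: integer `rank` matrix
#'   (genes x samples, `NA` where unranked), numeric `percentile` matrix,
#'   vector `n_g`, plus `genes` and `panel`.
#' @export
rank_samples <- function(mexpr, panel, min_samples = 10L,
                         tie_break = c("panel", "random"), seed = NULL) {
  tie_break <- match.arg(tie_break)
  if (ncol(mexpr) != length(panel)) stop("matrix columns must match panel")
  n_g <- rowSums(!is.na(mexpr))
  keep <- n_g >= min_samples
  excluded <- rownames(mexpr)[!keep]
  m <- mexpr[keep, , drop = FALSE]
  G <- nrow(m); S <- ncol(m)
  rank_m <- matrix(NA_integer_, G, S, dimnames = dimnames(m))
  if (tie_break == "random" && !is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  for (g in seq_len(G)) {
    idx <- which(!is.na(m[g, ]))
    key2 <- if (tie_break == "panel") idx else sample.int(length(idx))
    ord <- idx[order(m[g, idx], key2)]
    rank_m[g, ord] <- seq_along(ord)
  }
  ng <- n_g[keep]
  perc <- sweep(rank_m - 0.5, 1L, ng, "/")
  structure(list(rank = rank_m, percentile = perc, n_g = ng,
                 genes = rownames(m), panel = panel),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("rank_table: %d genes x %d samples (n_g %d..%d)\n",
              nrow(x$rank), length(x$panel), min(x$n_g), max(x$n_g)))
  invisible(x)
}

#' Restrict a rank table to a subset of its genes
#' @param ranks a `rank_table`.
#' @param gene_ids character vector of gene ids to keep.
#' @export
subset_ranks <- function(ranks, gene_ids) {
  i <- ranks$genes %in% gene_ids
  structure(list(rank = ranks$rank[i, , drop = FALSE],
                 percentile = ranks$percentile[i, , drop = FALSE],
                 n_g = ranks$n_g[i], genes = ranks$genes[i],
                 panel = ranks$panel),
            class = "rank_table")
}
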