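#' Split genes into low/high recombination strata
#'
#' Median split on per-gene recombination rate (cM/Mb): `low` is rate at or
#' below the median, `high` strictly above (ties go to `low`). Genes without
#' a rate are labelled `excluded`, never silently dropped.
#'
#' @param genes gene-model data.frame with `recomb_rate`.
#' @return data.frame `gene_id`, `stratum`; attribute `median` holds the
#'   split point.
#' @export
split_by_recombination <- function(genes) {
  r <- genes$recomb_rate
  if (all(is.na(r))) stop("no recombination rates available")
  med <- stats::median(r, na.rm = TRUE)
  stratum <- ifelse(is.na(r), "excluded", ifelse(r <= med, "low", "high"))
  if (sum(!is.na(r)) > 1L && length(unique(r[!is.na(r)])) == 1L)
    warning("all recombination rates equal; every gene is in the 'low' stratum")
  structure(data.frame(gene_id = genes$gene_id, stratum = stratum,
                       stringsAsFactors = FALSE),
            median = med)
}

#' Split genes into low/high expression strata
#'
#' Median split on the per-gene mean of replicate-averaged expression across
#' samples, computed per condition (a gene may switch strata between
#' conditions).
#'
#' @param gene_ids character vector of gene ids.
#' @param gene_means numeric vector of per-gene mean expression, aligned.
#' @return data.frame `gene_id`, `stratum`; attribute `median`.
#' @export
split_by_expression <- function(gene_ids, gene_means) {
  ok <- !is.na(gene_means)
  if (sum(ok) < 2L) stop("need at least two genes with expression to split")
  med <- stats::median(gene_means, na.rm = TRUE)
  stratum <- ifelse(!ok, "excluded", ifelse(gene_means <= med, "low", "high"))
  structure(data.frame(gene_id = gene_ids, stratum = stratum,
                       stringsAsFactors = FALSE),
            median = med)
}

#' Split SNPs into fitness-consequence score classes
#'
#' High class: rho > 0.2; low class: rho < 0.1; scores between the
#' thresholds, missing scores, and non-SNP variants are `excluded`.
#'
#' @param rset a `rare_variant_set` (or `variant_table`).
#' @param high_min exclusive lower bound of the high class (default 0.2).
#' @param low_max exclusive upper bound of the low class (default 0.1).
#' @return data.frame `variant_id`, `stratum`.
#' @export
split_by_fitcons <- function(rset, high_min = 0.2, low_max = 0.1) {
  v <- rset$variants
  rho <- v$rho
  stratum <- rep("excluded", nrow(v))
  is_snp <- v$vclass == "SNP"
  stratum[is_snp & !is.na(rho) & rho > high_min] <- "high"
  stratum[is_snp & !is.na(rho) & rho < low_max] <- "low"
  data.frame(variant_id = v$variant_id, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Split genes into connectivity classes
#'
#' High connectivity: r in [0.80, 0.99]; low: r in [0.16, 0.77]. Values
#' outside both ranges (including r > 0.99) and missing values are
#' `excluded` rather than clamped.
#'
#' @param genes gene-model data.frame with `connectivity`.
#' @param high_range,low_range inclusive class ranges.
#' @return data.frame `gene_id`, `stratum`.
#' @export
split_by_connectivity <- function(genes, high_range = c(0.80, 0.99),
                                  low_range = c(0.16, 0.77)) {
  r <- genes$connectivity
  stratum <- rep("excluded", nrow(genes))
  stratum[!is.na(r) & r >= high_range[1] & r <= high_range[2]] <- "high"
  stratum[!is.na(r) & r >= low_range[1] & r <= low_range[2]] <- "low"
  data.frame(gene_id = genes$gene_id, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Split variants by class (SNP / INDEL / SV)
#'
#' All structural classes (DEL, DUP, INS, INV and unresolved breakends) are
#' pooled as `SV` for burden analyses.
#'
#' @param rset a `rare_variant_set` (or `variant_table`).
#' @return data.frame `variant_id`, `stratum`.
#' @export
split_by_variant_class <- function(rset) {
  v <- rset$variants
  stratum <- ifelse(v$vclass %in% SV_CLASSES, "SV", v$vclass)
  data.frame(variant_id = v$variant_id, stratum = stratum,
             stringsAsFactors = FALSE)
}

# One full burden analysis (profile, quadratic, rank-group tests, phi) on a
# rare-set/gene/rank triple. Returns NULL rows flagged if no variants land.
.analyse_stratum <- function(rset, genes, ranks, bins_mode = "cis",
                             extreme = c(0.10, 0.90), middle = c(0.40, 0.60)) {
  cube <- assign_variants(rset, genes, mode = bins_mode)
  if (sum(cube$counts) == 0)
    return(list(cube = cube, empty = TRUE))
  profile <- per_rank_profile(cube, ranks)
  qf <- tryCatch(fit_quadratic(profile), error = function(e) NULL)
  rg <- tryCatch(rank_group_test(profile), error = function(e) NULL)
  phi <- compute_phi(cube, ranks, extreme = extreme, middle = middle)
  list(cube = cube, profile = profile, quad = qf, groups = rg, phi = phi,
       empty = FALSE)
}

#' Run the full burden + phi analysis per stratum
#'
#' For one stratifying factor, runs the per-rank profile, quadratic fit,
#' rank-group tests and phi for every stratum in every condition, and a
#' Fisher contingency comparison for the low/high (or pairwise) strata
#' within each condition. Gene-level factors subset the genes; variant-level
#' factors (`variant_class`, `fitcons_rho`) subset the variants with all
#' genes retained.
#'
#' @param rset a `rare_variant_set`.
#' @param genes gene-model data.frame.
#' @param ranks_by_condition named list of [rank_samples()] rank tables.
#' @param factor one of `"variant_class"`, `"recombination"`,
#'   `"expression_level"`, `"fitcons_rho"`, `"connectivity"`.
#' @param mean_expr_by_condition named list of [mean_expression()] matrices,
#'   required for `factor = "expression_level"`.
#' @param bins_mode `"cis"` or `"windows"` (passed to [assign_variants()]).
#' @return list with `summary` (tidy per condition x stratum table) and
#'   `comparisons` (pairwise Fisher results per condition).
#' @export
run_stratified <- function(rset, genes, ranks_by_condition,
                           factor = c("variant_class", "recombination",
                                      "expression_level", "fitcons_rho",
                                      "connectivity"),
                           mean_expr_by_condition = NULL,
                           bins_mode = "cis") {
  factor <- match.arg(factor)
  summary_rows <- list()
  comp_rows <- list()
  for (cond in names(ranks_by_condition)) {
    ranks <- ranks_by_condition[[cond]]
    cond_genes <- genes[genes$gene_id %in% ranks$genes, , drop = FALSE]
    if (factor == "variant_class") {
      sv <- split_by_variant_class(rset)
      strata <- c("SNP", "INDEL", "SV")
      get_inputs <- function(s) list(
        rset = subset_rare_set(rset, sv$stratum == s),
        genes = cond_genes, ranks = ranks)
    } else if (factor == "fitcons_rho") {
      sv <- split_by_fitcons(rset)
      strata <- c("low", "high")
      get_inputs <- function(s) list(
        rset = subset_rare_set(rset, sv$stratum == s),
        genes = cond_genes, ranks = ranks)
    } else {
      sg <- switch(factor,
        recombination = split_by_recombination(cond_genes),
        connectivity = split_by_connectivity(cond_genes),
        expression_level = {
          if (is.null(mean_expr_by_condition))
            stop("expression_level stratification needs mean_expr_by_condition")
          me <- mean_expr_by_condition[[cond]]
          gm <- rowMeans(me, na.rm = TRUE)[cond_genes$gene_id]
          split_by_expression(cond_genes$gene_id, gm)
        })
      strata <- c("low", "high")
      get_inputs <- function(s) {
        ids <- sg$gene_id[sg$stratum == s]
        list(rset = rset,
             genes = cond_genes[cond_genes$gene_id %in% ids, , drop = FALSE],
             ranks = subset_ranks(ranks, ids))
      }
    }
    results <- list()
    for (s in strata) {
      inp <- get_inputs(s)
      if (nrow(inp$rset$variants) == 0L || nrow(inp$genes) == 0L) {
        res <- list(empty = TRUE)
      } else {
        res <- .analyse_stratum(inp$rset, inp$genes, inp$ranks, bins_mode)
      }
      results[[s]] <- res
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        condition = cond, factor = factor, stratum = s,
        empty = isTRUE(res$empty),
        n_genes = if (isTRUE(res$empty)) 0L else nrow(inp$genes),
        n_variants = nrow(inp$rset$variants),
        E_r = if (isTRUE(res$empty)) NA_real_ else res$phi$E_r,
        M_r = if (isTRUE(res$empty)) NA_real_ else res$phi$M_r,
        phi = if (isTRUE(res$empty)) NA_real_ else res$phi$phi,
        quad_c = if (isTRUE(res$empty) || is.null(res$quad)) NA_real_ else res$quad$c,
        quad_r2 = if (isTRUE(res$empty) || is.null(res$quad)) NA_real_ else res$quad$r2,
        quad_p = if (isTRUE(res$empty) || is.null(res$quad)) NA_real_ else res$quad$p,
        high_vs_mid_p = if (isTRUE(res$empty) || is.null(res$groups)) NA_real_ else res$groups$high_vs_mid$p,
        low_vs_mid_p = if (isTRUE(res$empty) || is.null(res$groups)) NA_real_ else res$groups$low_vs_mid$p,
        stringsAsFactors = FALSE)
    }
    pairs <- utils::combn(strata, 2, simplify = FALSE)
    for (pr in pairs) {
      a <- results[[pr[1]]]; b <- results[[pr[2]]]
      if (isTRUE(a$empty) || isTRUE(b$empty) ||
          a$phi$undefined || b$phi$undefined) next
      fc <- tryCatch(fisher_compare(a$phi, b$phi, labels = pr),
                     error = function(e) NULL)
      if (is.null(fc)) next
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        condition = cond, factor = factor,
        stratum_a = pr[1], stratum_b = pr[2],
        phi_a = a$phi$phi, phi_b = b$phi$phi,
        odds_ratio = fc$odds_ratio, fisher_p = fc$fisher_p,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summary_rows),
       comparisons = if (length(comp_rows)) do.call(rbind, comp_rows) else NULL)
}

#' Phi per region bin (linkage/window analysis)
#'
#' Computes phi separately for the gene body and each upstream distance
#' window from a `windows`-mode burden cube, the machinery behind the
#' decay of the rare-variant effect with distance from the TSS.
#'
#' @param cube a windows-mode [assign_variants()] cube.
#' @param ranks matching [rank_samples()] rank table.
#' @param extreme,middle cut points passed to [phi_rank_bins()].
#' @return data.frame `bin`, `E_r`, `M_r`, `phi`.
#' @export
phi_by_window <- function(cube, ranks, extreme = c(0.10, 0.90),
                          middle = c(0.40, 0.60)) {
  rows <- lapply(cube$bins, function(b) {
    ph <- compute_phi(cube, ranks, bins = b, extreme = extreme, middle = middle)
    data.frame(bin = b, E_r = ph$E_r, M_r = ph$M_r, phi = ph$phi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
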