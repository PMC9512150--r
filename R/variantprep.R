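#' Apply GATK-style hard filters to SNPs and indels
#'
#' SNPs are retained iff `QD > 2 & FS < 60 & MQ > 40 & SOR < 4 &
#' MQRankSum > -12.5 & ReadPosRankSum > -8`; indels iff
#' `QD > 2 & FS < 200 & SOR < 10` and length <= 20 bp. An annotation that is
#' absent from a record passes that criterion (GATK only emits the RankSum
#' annotations at heterozygous sites, so strictness would silently drop
#' homozygous-only sites). Structural-variant records pass through unchanged;
#' see [filter_sv_records()] for their rules.
#'
#' @param vt a [variant_table()].
#' @param max_indel_length maximum retained indel length in bp (default 20).
#' @return filtered [variant_table()] with an `attrition` attribute counting
#'   removals per rule.
#' @export
apply_hard_filters <- function(vt, max_indel_length = 20L) {
  v <- vt$variants
  gtn <- function(x, thr) is.na(x) | x > thr   # pass if absent
  ltn <- function(x, thr) is.na(x) | x < thr
  keep <- rep(TRUE, nrow(v))
  attrition <- c()
  snp <- v$vclass == "SNP"
  ind <- v$vclass == "INDEL"
  rules <- list(
    snp_QD  = snp & !gtn(v$QD, 2),   snp_FS  = snp & !ltn(v$FS, 60),
    snp_MQ  = snp & !gtn(v$MQ, 40),  snp_SOR = snp & !ltn(v$SOR, 4),
    snp_MQRankSum = snp & !gtn(v$MQRankSum, -12.5),
    snp_ReadPosRankSum = snp & !gtn(v$ReadPosRankSum, -8),
    indel_QD = ind & !gtn(v$QD, 2),  indel_FS = ind & !ltn(v$FS, 200),
    indel_SOR = ind & !ltn(v$SOR, 10),
    indel_length = ind & v$length > max_indel_length)
  for (r in names(rules)) {
    attrition[r] <- sum(keep & rules[[r]])
    keep <- keep & !rules[[r]]
  }
  out <- subset_variants(vt, keep)
  attr(out, "attrition") <- attrition
  out
}

#' Filter structural-variant records
#'
#' Deletions require a read-depth fold-change relative to flanking regions
#' below 0.70 and duplications a fold-change relative to similar-GC bins
#' above 1.30 (duphold annotations); insertions, inversions and breakends
#' pass the depth rules unchanged. All non-breakend SVs must satisfy
#' 20 bp < length <= 200 kb. Deletions/duplications missing their
#' fold-change annotation are removed (conservative) and counted.
#'
#' @param vt a [variant_table()] (non-SV records pass through unchanged).
#' @param dhffc_max maximum DEL depth fold-change (default 0.70).
#' @param dhbfc_min minimum DUP depth fold-change (default 1.30).
#' @param min_length minimum SV length, exclusive (default 20 bp).
#' @param max_length maximum SV length, inclusive (default 200,000 bp).
#' @return filtered [variant_table()] with an `attrition` attribute.
#' @export
filter_sv_records <- function(vt, dhffc_max = 0.70, dhbfc_min = 1.30,
                              min_length = 20L, max_length = 200000L) {
  v <- vt$variants
  is_sv <- v$vclass %in% SV_CLASSES
  keep <- rep(TRUE, nrow(v))
  attrition <- c()
  del_bad <- v$vclass == "DEL" & (is.na(v$dhffc) | v$dhffc >= dhffc_max)
  dup_bad <- v$vclass == "DUP" & (is.na(v$dhbfc) | v$dhbfc <= dhbfc_min)
  size_bad <- is_sv & v$vclass != "BND" &
    (v$length <= min_length | v$length > max_length)
  for (r in c("del_depth", "dup_depth", "sv_size")) {
    bad <- switch(r, del_depth = del_bad, dup_depth = dup_bad, sv_size = size_bad)
    attrition[r] <- sum(keep & bad)
    keep <- keep & !bad
  }
  out <- subset_variants(vt, keep)
  attr(out, "attrition") <- attrition
  out
}

.intervals_overlap <- function(p1, e1, p2, e2) p1 <= e2 & p2 <= e1

#' Exclude overlapping same-sample SV calls
#'
#' Two (or more) non-breakend SV calls from the same sample on the same
#' chromosome whose inclusive intervals overlap could represent complex
#' rearrangements and make cross-sample merging ambiguous; all members of
#' such an overlap are removed. The rule is strictly within-individual.
#'
#' @param calls per-sample SV call data.frame (see [read_sv_calls()]).
#' @return filtered call data.frame.
#' @export
exclude_intra_sample_overlaps <- function(calls) {
  drop <- rep(FALSE, nrow(calls))
  nb <- calls$vclass != "BND"
  for (key in unique(paste(calls$sample, calls$chrom))) {
    idx <- which(nb & paste(calls$sample, calls$chrom) == key)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1L):length(idx)) {
      i <- idx[a]; j <- idx[b]
      if (.intervals_overlap(calls$pos[i], calls$end[i], calls$pos[j], calls$end[j]))
        drop[c(i, j)] <- TRUE
    }
  }
  calls[!drop, , drop = FALSE]
}

#' Merge per-sample SV calls into population variants
#'
#' Single-linkage clustering over same-class, same-chromosome calls.
#' Two calls join when their intervals cover at least `reciprocal` of each
#' other and both breakends lie within `bnd_window` bp; breakend (BND)
#' records merge only on exact (chrom, pos) equality. Each cluster emits one
#' population record taking the coordinates of its first member by
#' (pos, end); its genotype vector is the union of member genotypes (a
#' sample contributing conflicting genotypes keeps the maximum alternate
#' count, with a message).
#'
#' @param calls per-sample SV call data.frame (see [read_sv_calls()]);
#'   should already be depth/size-filtered and purged of intra-sample
#'   overlaps.
#' @param panel a [sample_panel()].
#' @param reciprocal minimum reciprocal overlap (default 0.50).
#' @param bnd_window maximum breakend distance in bp (default 1000).
#' @return a [variant_table()] of merged population SVs, with a
#'   `merge_report` attribute (cluster membership table).
#' @export
merge_svs <- function(calls, panel, reciprocal = 0.50, bnd_window = 1000L) {
  calls <- calls[order(calls$chrom, calls$pos, calls$end, calls$sample), , drop = FALSE]
  n <- nrow(calls)
  if (n == 0L) stop("no SV calls to merge")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  key <- paste(calls$chrom, calls$vclass)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    is_bnd <- calls$vclass[idx[1]] == "BND"
    for (a in seq_along(idx)[-length(idx)]) {
      i <- idx[a]
      for (b in (a + 1L):length(idx)) {
        j <- idx[b]
        if (calls$pos[j] - calls$pos[i] > max(bnd_window, 0L) &&
            calls$pos[j] > calls$end[i]) break
        if (is_bnd) {
          if (calls$pos[i] == calls$pos[j]) union_(i, j)
        } else {
          ov <- min(calls$end[i], calls$end[j]) - max(calls$pos[i], calls$pos[j]) + 1L
          if (ov <= 0L) next
          li <- calls$end[i] - calls$pos[i] + 1L
          lj <- calls$end[j] - calls$pos[j] + 1L
          if (ov / li >= reciprocal && ov / lj >= reciprocal &&
              abs(calls$pos[i] - calls$pos[j]) <= bnd_window &&
              abs(calls$end[i] - calls$end[j]) <= bnd_window)
            union_(i, j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), root)
  S <- length(panel)
  out_var <- vector("list", length(clusters))
  out_gt <- matrix(0L, nrow = length(clusters), ncol = S)
  report <- vector("list", length(clusters))
  conflicts <- 0L
  for (ci in seq_along(clusters)) {
    members <- clusters[[ci]]
    ord <- members[order(calls$pos[members], calls$end[members])]
    rep_i <- ord[1]
    g <- integer(S)
    for (m in members) {
      s <- match(calls$sample[m], as.character(panel))
      if (is.na(s)) stop("SV call sample not in panel: ", calls$sample[m])
      if (g[s] != 0L && g[s] != calls$gt[m]) conflicts <- conflicts + 1L
      g[s] <- max(g[s], calls$gt[m])
    }
    out_gt[ci, ] <- g
    out_var[[ci]] <- data.frame(
      variant_id = sprintf("sv_%s_%d_%s", calls$chrom[rep_i], calls$pos[rep_i],
                           calls$vclass[rep_i]),
      chrom = calls$chrom[rep_i], pos = calls$pos[rep_i], end = calls$end[rep_i],
      ref = "N", alt = paste0("<", calls$vclass[rep_i], ">"),
      vclass = calls$vclass[rep_i], length = calls$length[rep_i],
      dhffc = if ("dhffc" %in% names(calls)) calls$dhffc[rep_i] else NA_real_,
      dhbfc = if ("dhbfc" %in% names(calls)) calls$dhbfc[rep_i] else NA_real_,
      stringsAsFactors = FALSE)
    report[[ci]] <- data.frame(
      cluster_id = ci, sample = calls$sample[ord],
      pos = calls$pos[ord], end = calls$end[ord], vclass = calls$vclass[ord],
      representative = seq_along(ord) == 1L, stringsAsFactors = FALSE)
  }
  if (conflicts > 0)
    message(conflicts, " same-sample genotype conflicts resolved by max alt count")
  variants <- do.call(rbind, out_var)
  if (anyDuplicated(variants$variant_id))
    variants$variant_id <- make.unique(variants$variant_id, sep = "_c")
  ord <- order(variants$chrom, variants$pos, variants$end)
  out <- variant_table(variants[ord, , drop = FALSE],
                       out_gt[ord, , drop = FALSE], panel)
  attr(out, "merge_report") <- do.call(rbind, report)
  out
}

#' Alternate-allele and minor-allele frequency of each variant
#'
#' The alternate-allele frequency is `sum(genotypes) / (2 * non-missing
#' samples)`; missing genotypes are excluded from numerator and denominator.
#' The minor allele is frequency-defined: `maf = min(f, 1 - f)`, and when the
#' alternate frequency exceeds 0.5 the *reference* allele is the minor
#' allele.
#'
#' @param vt a [variant_table()].
#' @return data.frame with one row per variant: `variant_id`, `f_alt`,
#'   `maf`, `minor` (`"alt"`/`"ref"`), `n_called`, `n_hom_minor`,
#'   `n_het`, `n_carriers`. Variants with all genotypes missing get `NA`
#'   frequencies.
#' @export
compute_allele_frequency <- function(vt) {
  g <- vt$geno
  n_called <- rowSums(!is.na(g))
  alt_alleles <- rowSums(g, na.rm = TRUE)
  f_alt <- ifelse(n_called > 0, alt_alleles / (2 * n_called), NA_real_)
  minor <- ifelse(is.na(f_alt), NA_character_, ifelse(f_alt > 0.5, "ref", "alt"))
  maf <- pmin(f_alt, 1 - f_alt)
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_hom_minor <- ifelse(minor == "alt", rowSums(g == 2L, na.rm = TRUE),
                        rowSums(g == 0L, na.rm = TRUE))
  carriers <- ifelse(minor == "alt", rowSums(g >= 1L, na.rm = TRUE),
                     rowSums(g <= 1L, na.rm = TRUE))
  data.frame(variant_id = vt$variants$variant_id, f_alt = f_alt, maf = maf,
             minor = minor, n_called = n_called, n_hom_minor = n_hom_minor,
             n_het = n_het, n_carriers = carriers, stringsAsFactors = FALSE)
}

#' Minor-allele carrier matrix
#'
#' Logical `variants x samples` matrix: `TRUE` where the sample carries at
#' least one copy of the (frequency-defined) minor allele. Missing genotypes
#' are never carriers.
#'
#' @param vt a [variant_table()].
#' @param freq optional precomputed [compute_allele_frequency()] result.
#' @export
carrier_matrix <- function(vt, freq = compute_allele_frequency(vt)) {
  g <- vt$geno
  alt_minor <- freq$minor == "alt"
  car <- matrix(FALSE, nrow(g), ncol(g), dimnames = dimnames(g))
  car[alt_minor, ] <- !is.na(g[alt_minor, , drop = FALSE]) &
    g[alt_minor, , drop = FALSE] >= 1L
  car[!alt_minor, ] <- !is.na(g[!alt_minor, , drop = FALSE]) &
    g[!alt_minor, , drop = FALSE] <= 1L
  car[is.na(freq$minor), ] <- FALSE
  car
}

#' Select rare variants
#'
#' Rarity is a folded minor-allele frequency below `maf_threshold` (default
#' 5%). SNPs and indels additionally need supporting evidence: at least one
#' individual homozygous for the minor allele or at least three heterozygous
#' individuals (guards against sequencing error in singleton heterozygotes).
#' SV singletons are permitted because SV calls rest on multiple signals.
#' Variants with all genotypes missing are excluded and counted.
#'
#' @param vt a [variant_table()].
#' @param maf_threshold rarity threshold on folded MAF (default 0.05,
#'   exclusive).
#' @param min_hom minimum minor-allele homozygotes for SNP/indel evidence.
#' @param min_het alternative minimum heterozygote count.
#' @return object of class `rare_variant_set`: the retained
#'   [variant_table()] plus per-variant frequencies (`$freq`) and the
#'   minor-allele `$carriers` matrix. An `attrition` attribute counts
#'   exclusions per rule.
#' @export
select_rare_variants <- function(vt, maf_threshold = 0.05,
                                 min_hom = 1L, min_het = 3L) {
  freq <- compute_allele_frequency(vt)
  all_missing <- freq$n_called == 0
  rare <- !all_missing & freq$maf < maf_threshold & freq$n_carriers > 0
  snp_indel <- vt$variants$vclass %in% c("SNP", "INDEL")
  evidence <- freq$n_hom_minor >= min_hom | freq$n_het >= min_het
  keep <- rare & (!snp_indel | evidence)
  attrition <- c(all_missing = sum(all_missing),
                 not_rare = sum(!all_missing & !rare),
                 evidence = sum(rare & snp_indel & !evidence))
  sub <- subset_variants(vt, keep)
  sub_freq <- freq[keep, , drop = FALSE]
  rownames(sub_freq) <- NULL
  out <- structure(list(variants = sub$variants, geno = sub$geno,
                        panel = vt$panel, freq = sub_freq,
                        carriers = carrier_matrix(sub, sub_freq),
                        maf_threshold = maf_threshold),
                   class = c("rare_variant_set", "variant_table"))
  attr(out, "attrition") <- attrition
  out
}

#' Treat every variant in a table as (already selected) rare
#'
#' Convenience constructor for hand-built fixtures whose carrier structure is
#' specified directly: computes frequencies and minor-allele carriers without
#' applying the MAF/evidence filters.
#'
#' @param vt a [variant_table()].
#' @export
as_rare_variant_set <- function(vt) {
  freq <- compute_allele_frequency(vt)
  structure(list(variants = vt$variants, geno = vt$geno, panel = vt$panel,
                 freq = freq, carriers = carrier_matrix(vt, freq),
                 maf_threshold = NA_real_),
            class = c("rare_variant_set", "variant_table"))
}

#' @export
print.rare_variant_set <- function(x, ...) {
  cat(sprintf("rare_variant_set: %d variants x %d samples (MAF < %s)\n",
              nrow(x$variants), length(x$panel),
              format(x$maf_threshold)))
  print(table(x$variants$vclass))
  invisible(x)
}

#' Restrict a rare-variant set to a subset of its variants
#' @param rset a `rare_variant_set`.
#' @param i integer or logical index over variants.
#' @export
subset_rare_set <- function(rset, i) {
  out <- rset
  out$variants <- rset$variants[i, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$geno <- rset$geno[i, , drop = FALSE]
  out$freq <- rset$freq[i, , drop = FALSE]
  rownames(out$freq) <- NULL
  out$carriers <- rset$carriers[i, , drop = FALSE]
  out
}
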