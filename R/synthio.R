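#' Simulation configuration
#'
#' Defines a synthetic selfing population: diploid, mostly homozygous
#' genotypes for rare and common variants of three classes (SNP, indel, SV)
#' placed in genic and upstream regions of non-overlapping genes, and
#' triplicate log2(TPM + 1) expression in two conditions, with a fraction of
#' rare variants causally shifting carrier expression away from the gene's
#' optimum. Effect probability can be coupled to fitness-consequence score,
#' recombination rate and expression level, and effect size decays with
#' distance from the TSS; the dry (stress) condition amplifies effects by
#' `kappa_dry`.
#'
#' @param n_samples panel size (default 129).
#' @param n_genes number of genes (default 2000).
#' @param gene_spacing bp between gene starts; genes are placed
#'   non-overlapping with wide spacing so upstream windows up to 100 kb stay
#'   clean (default 220 kb).
#' @param n_rare named counts of rare variants per class
#'   (`SNP`, `INDEL`, `SV`).
#' @param n_common counts of common (MAF >= 5%) variants per class.
#' @param n_low_evidence counts of low-frequency SNP/indel variants with
#'   only 1-2 heterozygous carriers, planted to exercise the evidence rule.
#' @param n_fail_qc counts of SNP/indel records failing the GATK hard
#'   filters.
#' @param n_fail_sv count of SV records failing depth/size rules.
#' @param homozygosity probability a carrier is homozygous (selfing;
#'   default 0.95).
#' @param pi causal fraction per class.
#' @param delta causal effect size in SDs of log2 expression (default 1.5).
#' @param lambda distance-decay half-length in bp for upstream effects
#'   (weight `exp(-d / lambda)`, 1 inside the gene; default 2000).
#' @param kappa_dry multiplier on effects in the dry condition (>= 1).
#' @param rho_slope,recomb_slope,expr_slope,conn_slope coupling of the
#'   causal probability to high-rho SNPs, low-recombination genes,
#'   low-expression genes and low-connectivity genes (0 = no coupling).
#' @param sv_sign_bias probability a causal SV/indel effect is negative
#'   (0.5 = symmetric).
#' @param bio_sd biological (sample-level) SD of log2 expression.
#' @param rep_noise_sd replicate technical noise SD.
#' @param n_replicates replicates per sample (default 3).
#' @param dropout fraction of (gene, sample) pairs with all-replicate zero
#'   expression.
#' @param seed RNG seed; the generator is byte-deterministic given the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 129L, n_genes = 2000L,
                       gene_spacing = 220000L,
                       n_rare = c(SNP = 20000L, INDEL = 3800L, SV = 1500L),
                       n_common = c(SNP = 800L, INDEL = 200L, SV = 80L),
                       n_low_evidence = c(SNP = 100L, INDEL = 30L),
                       n_fail_qc = c(SNP = 50L, INDEL = 10L),
                       n_fail_sv = 20L,
                       homozygosity = 0.95,
                       pi = c(SNP = 0.15, INDEL = 0.15, SV = 0.30),
                       delta = 1.5, lambda = 2000,
                       kappa_dry = 1.5,
                       rho_slope = 0.5, recomb_slope = 0.5,
                       expr_slope = 0.5, conn_slope = 0,
                       sv_sign_bias = 0.5,
                       bio_sd = 0.7, rep_noise_sd = 0.25,
                       n_replicates = 3L, dropout = 0.02,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              gene_spacing = as.integer(gene_spacing),
              n_rare = n_rare, n_common = n_common,
              n_low_evidence = n_low_evidence, n_fail_qc = n_fail_qc,
              n_fail_sv = as.integer(n_fail_sv),
              homozygosity = homozygosity, pi = pi, delta = delta,
              lambda = lambda, kappa_dry = kappa_dry,
              rho_slope = rho_slope, recomb_slope = recomb_slope,
              expr_slope = expr_slope, conn_slope = conn_slope,
              sv_sign_bias = sv_sign_bias,
              bio_sd = bio_sd, rep_noise_sd = rep_noise_sd,
              n_replicates = as.integer(n_replicates), dropout = dropout,
              seed = as.integer(seed))
  fr <- c(cfg$homozygosity, cfg$pi, cfg$dropout, cfg$sv_sign_bias)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (cfg$kappa_dry < 1) stop("kappa_dry must be >= 1")
  chrom_len <- 100000L + cfg$n_genes * cfg$gene_spacing + 200000L
  cfg$chrom_length <- chrom_len
  if (cfg$n_genes * cfg$gene_spacing > cfg$chrom_length)
    stop("infeasible gene placement: too many genes for chromosome length")
  structure(cfg, class = "sim_config")
}

# Draw the minor-allele count (in alleles) for a rare variant: support
# 1..max_alleles with weight 1/a (rare variants skew to singletons).
.draw_allele_count <- function(n, max_alleles) {
  sample.int(max_alleles, n, replace = TRUE, prob = 1 / seq_len(max_alleles))
}

# Compose hom/het carrier counts for a total allele count, respecting the
# selfing homozygosity and (for SNP/indel) the evidence rule.
.compose_carriers <- function(alleles, homozygosity, enforce_evidence) {
  hom <- 0L; het <- 0L; left <- alleles
  while (left > 0L) {
    if (left >= 2L && stats::runif(1) < homozygosity) {
      hom <- hom + 1L; left <- left - 2L
    } else {
      het <- het + 1L; left <- left - 1L
    }
  }
  if (enforce_evidence && hom == 0L && het < 3L) {
    if (alleles >= 2L) { hom <- 1L; het <- alleles - 2L }
    else { hom <- 1L; het <- 0L }     # promote singleton to one homozygote
  }
  c(hom = hom, het = het)
}

#' Generate a synthetic population and write it in the pipeline's formats
#'
#' Writes, under `dir`: `variants.vcf` (SNPs/indels/SVs with GT and
#' annotations), `genes.gff3`, `expr_wet.tsv` / `expr_dry.tsv`
#' (replicate-level expression), `gene_metadata.tsv` (recombination rate,
#' connectivity, TE overlap), `site_scores.tsv` (fitCons rho for SNP
#' positions), `te.bed`, and `truth.tsv` (per-variant ground truth: causal
#' flag, signed effect, target gene, distance to TSS). Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list with the file paths and the truth table.
#' @export
simulate_population <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, function() .simulate_impl(config, dir))
}

.simulate_impl <- function(cfg, dir) {
  N <- cfg$n_samples
  panel <- sample_panel(sprintf("S%03d", seq_len(N)))
  G <- cfg$n_genes

  ## gene models
  gene_len <- sample(1500:6000, G, replace = TRUE)
  start <- 100000L + (seq_len(G) - 1L) * cfg$gene_spacing
  strand <- sample(c("+", "-"), G, replace = TRUE)
  genes <- gene_models(data.frame(
    gene_id = sprintf("G%04d", seq_len(G)), chrom = "chr1", strand = strand,
    start = start, end = start + gene_len - 1L, stringsAsFactors = FALSE))

  ## per-gene metadata and baselines
  recomb <- round(stats::rlnorm(G, meanlog = log(4), sdlog = 0.6), 4)
  connectivity <- round(stats::runif(G, 0.16, 0.99), 4)
  connectivity[sample.int(G, max(1L, round(0.1 * G)))] <- NA
  mu <- pmax(2, stats::rnorm(G, mean = 6, sd = 1.5))
  med_rec <- stats::median(recomb)
  med_mu <- stats::median(mu)

  ## TE intervals: a few genes fully covered (removed by the TE filter),
  ## plus intergenic TEs that overlap nothing
  n_te_genes <- max(1L, round(0.004 * G))
  te_gene_idx <- sort(sample.int(G, n_te_genes))
  te <- data.frame(chrom = "chr1",
                   start = genes$start[te_gene_idx] - 50L,
                   end = genes$end[te_gene_idx] + 50L)
  te <- rbind(te, data.frame(chrom = "chr1",
                             start = genes$end[1] + 150000L + (0:4) * 9000L,
                             end = genes$end[1] + 150000L + (0:4) * 9000L + 4000L))
  te_overlap <- numeric(G)
  te_overlap[te_gene_idx] <- 1

  ## variant placement mixture over region bins
  bin_probs <- c(GENIC = 0.40, U_0_2 = 0.15, U_2_4 = 0.08, U_4_6 = 0.07,
                 U_6_8 = 0.06, U_8_10 = 0.05, U_10_12 = 0.04, U_12_14 = 0.04,
                 U_14_16 = 0.03, U_16_18 = 0.03, U_18_20 = 0.02, U_GT20 = 0.03)
  max_rare_alleles <- max(1L, as.integer(ceiling(0.05 * 2 * N)) - 1L)

  specs <- list()
  add_spec <- function(class, n, category) {
    if (n > 0L) specs[[length(specs) + 1L]] <<- list(class = class, n = as.integer(n),
                                                     category = category)
  }
  for (cl in c("SNP", "INDEL", "SV")) {
    add_spec(cl, cfg$n_rare[[cl]], "rare")
    add_spec(cl, cfg$n_common[[cl]], "common")
  }
  for (cl in c("SNP", "INDEL")) {
    add_spec(cl, cfg$n_low_evidence[[cl]], "low_evidence")
    add_spec(cl, cfg$n_fail_qc[[cl]], "fail_qc")
  }
  add_spec("SV", cfg$n_fail_sv, "fail_sv")

  n_total <- sum(vapply(specs, function(s) s$n, integer(1)))
  col_chr <- function() character(n_total)
  col_int <- function() integer(n_total)
  col_num <- function() rep(NA_real_, n_total)
  V <- list(variant_id = col_chr(), chrom = rep("chr1", n_total),
            pos = col_int(), end = col_int(), ref = col_chr(), alt = col_chr(),
            vclass = col_chr(), length = col_int(),
            QD = col_num(), FS = col_num(), MQ = col_num(), SOR = col_num(),
            MQRankSum = col_num(), ReadPosRankSum = col_num(),
            dhffc = col_num(), dhbfc = col_num(), rho = col_num())
  TR <- list(variant_id = col_chr(), vclass = col_chr(), category = col_chr(),
             gene_id = col_chr(), causal = logical(n_total),
             delta = numeric(n_total), distance = numeric(n_total),
             rho = col_num())
  geno <- matrix(0L, n_total, N)
  vid <- 0L
  sv_types <- c("DEL", "DUP", "INS", "INV", "BND")
  sv_probs <- c(0.40, 0.20, 0.20, 0.15, 0.05)
  bases <- c("A", "C", "G", "T")
  common_lo <- min(N, as.integer(ceiling(0.05 * N)) + 1L)
  common_hi <- max(common_lo, as.integer(floor(N / 3)))

  runifr <- function(n, lo, hi, dig) round(stats::runif(n, lo, hi), dig)

  for (sp in specs) {
    np <- sp$n
    at <- vid + seq_len(np)          # output slots for this block
    vid <- vid + np

    ## placement (vectorized)
    g <- sample.int(G, np, replace = TRUE)
    bin <- sample(names(bin_probs), np, replace = TRUE, prob = bin_probs)
    genic <- bin == "GENIC"
    d <- numeric(np)
    ub <- .upstream_bounds_kb[bin[!genic], , drop = FALSE] * 1000
    d[!genic] <- ub[, 1] + ceiling(stats::runif(sum(!genic)) * (ub[, 2] - ub[, 1]))
    glen <- genes$end[g] - genes$start[g] + 1L
    pos <- integer(np)
    pos[genic] <- genes$start[g[genic]] +
      as.integer(floor(stats::runif(sum(genic)) * glen[genic]))
    plus <- genes$strand[g] == "+"
    pos[!genic] <- as.integer(ifelse(plus[!genic],
                                     genes$tss[g[!genic]] - d[!genic],
                                     genes$tss[g[!genic]] + d[!genic]))

    ## alleles and class-specific fields
    vclass <- rep(sp$class, np)
    len <- rep(1L, np); end <- pos
    ref_i <- sample.int(4L, np, replace = TRUE)
    ref <- bases[ref_i]
    alt <- bases[(ref_i + sample.int(3L, np, replace = TRUE) - 1L) %% 4L + 1L]
    dhffc <- rep(NA_real_, np); dhbfc <- rep(NA_real_, np)
    if (sp$class == "INDEL") {
      len <- sample.int(20L, np, replace = TRUE)
      del_style <- stats::runif(np) < 0.5
      seqs <- vapply(len, function(l)
        paste(sample(bases, l + 1L, replace = TRUE), collapse = ""), character(1))
      ref <- ifelse(del_style, seqs, substr(seqs, 1L, 1L))
      alt <- ifelse(del_style, substr(seqs, 1L, 1L), seqs)
      end <- ifelse(del_style, pos + len, pos)
    } else if (sp$class == "SV") {
      svtype <- sample(sv_types, np, replace = TRUE, prob = sv_probs)
      len <- as.integer(round(exp(stats::runif(np, log(30), log(3000)))))
      len[svtype == "BND"] <- 0L
      dhffc <- ifelse(svtype == "DEL", runifr(np, 0.10, 0.60, 3), NA_real_)
      dhbfc <- ifelse(svtype == "DUP", runifr(np, 1.40, 2.50, 3), NA_real_)
      if (sp$category == "fail_sv") {
        kind <- sample(c("depth", "size"), np, replace = TRUE)
        bad_depth_del <- kind == "depth" & svtype == "DEL"
        bad_depth_dup <- kind == "depth" & svtype == "DUP"
        bad_size <- kind == "size" & svtype %in% c("DEL", "DUP", "INV")
        fallback <- !(bad_depth_del | bad_depth_dup | bad_size)
        dhffc[bad_depth_del] <- runifr(sum(bad_depth_del), 0.80, 1.10, 3)
        dhbfc[bad_depth_dup] <- runifr(sum(bad_depth_dup), 0.90, 1.20, 3)
        len[bad_size] <- 200000L + as.integer(ceiling(stats::runif(sum(bad_size)) * 60000))
        # INS/BND/depth-mismatch cases fall back to undersized deletions
        svtype[fallback] <- "DEL"
        len[fallback] <- sample.int(20L, sum(fallback), replace = TRUE)
        dhffc[fallback] <- runifr(sum(fallback), 0.10, 0.60, 3)
      }
      vclass <- svtype
      end <- ifelse(svtype %in% c("INS", "BND"), pos, pos + pmax(len - 1L, 0L))
      ref <- rep("N", np)
      alt <- paste0("<", svtype, ">")
    }

    ## genotypes (small per-variant loop; everything else is drawn in batch)
    if (sp$category %in% c("rare", "fail_qc", "fail_sv")) {
      alleles <- .draw_allele_count(np, max_rare_alleles)
      sv_singleton <- sp$class == "SV" & stats::runif(np) < 0.15
      for (i in seq_len(np)) {
        if (sv_singleton[i]) {
          geno[at[i], sample.int(N, 1L)] <- 1L
        } else {
          hh <- .compose_carriers(alleles[i], cfg$homozygosity,
                                  enforce_evidence = sp$class %in% c("SNP", "INDEL"))
          carriers <- sample.int(N, hh["hom"] + hh["het"])
          geno[at[i], carriers] <- c(rep(2L, hh["hom"]), rep(1L, hh["het"]))
        }
      }
    } else if (sp$category == "low_evidence") {
      n_het <- sample(1:2, np, replace = TRUE)
      for (i in seq_len(np))
        geno[at[i], sample.int(N, n_het[i])] <- 1L
    } else {  # common: homozygous carriers comfortably above the MAF cutoff
      n_hom <- if (common_hi > common_lo)
        sample(common_lo:common_hi, np, replace = TRUE) else rep(common_lo, np)
      for (i in seq_len(np))
        geno[at[i], sample.int(N, n_hom[i])] <- 2L
    }

    ## site annotations (SNP/indel only)
    has_annot <- sp$class %in% c("SNP", "INDEL")
    if (has_annot) {
      QD <- runifr(np, 5, 30, 2); FS <- runifr(np, 0, 30, 2)
      MQ <- runifr(np, 50, 60, 2); SOR <- runifr(np, 0.3, 2, 3)
      MQRankSum <- runifr(np, -2, 2, 3); ReadPosRankSum <- runifr(np, -2, 2, 3)
      if (sp$category == "fail_qc") {
        # indels are only screened on QD/FS/SOR, so MQ failures would pass
        fail_opts <- if (sp$class == "SNP") c("QD", "MQ", "FS") else c("QD", "FS")
        which_fail <- sample(fail_opts, np, replace = TRUE)
        QD[which_fail == "QD"] <- runifr(sum(which_fail == "QD"), 0.1, 1.9, 2)
        MQ[which_fail == "MQ"] <- runifr(sum(which_fail == "MQ"), 20, 39, 2)
        FS[which_fail == "FS"] <- runifr(sum(which_fail == "FS"), 250, 400, 2)
      }
      V$QD[at] <- QD; V$FS[at] <- FS; V$MQ[at] <- MQ; V$SOR[at] <- SOR
      V$MQRankSum[at] <- MQRankSum; V$ReadPosRankSum[at] <- ReadPosRankSum
    }

    ## fitCons scores: mixture populating both the low and high classes
    rho <- rep(NA_real_, np)
    if (sp$class == "SNP") {
      u <- stats::runif(np)
      rho <- round(ifelse(u < 0.45, stats::runif(np, 0, 0.099),
                   ifelse(u < 0.65, stats::runif(np, 0.1, 0.2),
                          stats::runif(np, 0.201, 0.6))), 4)
    }

    ## causal assignment (rare variants only)
    causal <- rep(FALSE, np); delta_v <- numeric(np)
    if (sp$category == "rare") {
      m <- rep(1, np)
      if (sp$class == "SNP") {
        m <- m * ifelse(rho > 0.2, 1 + cfg$rho_slope,
                        ifelse(rho < 0.1, 1 - cfg$rho_slope, 1))
      }
      m <- m * ifelse(recomb[g] <= med_rec, 1 + cfg$recomb_slope, 1 - cfg$recomb_slope)
      m <- m * ifelse(mu[g] <= med_mu, 1 + cfg$expr_slope, 1 - cfg$expr_slope)
      if (cfg$conn_slope > 0) {
        cm <- ifelse(is.na(connectivity[g]), 1,
                     ifelse(connectivity[g] <= 0.77, 1 + cfg$conn_slope,
                            1 - cfg$conn_slope))
        m <- m * cm
      }
      p_causal <- pmin(1, pmax(0, cfg$pi[[sp$class]] * m))
      causal <- stats::runif(np) < p_causal
      neg_p <- if (sp$class %in% c("INDEL", "SV")) cfg$sv_sign_bias else 0.5
      sgn <- ifelse(stats::runif(np) < neg_p, -1, 1)
      delta_v[causal] <- (sgn * cfg$delta)[causal]
    }

    V$variant_id[at] <- sprintf("v%06d", at)
    V$pos[at] <- pos; V$end[at] <- as.integer(end)
    V$ref[at] <- ref; V$alt[at] <- alt
    V$vclass[at] <- vclass; V$length[at] <- len
    V$dhffc[at] <- dhffc; V$dhbfc[at] <- dhbfc
    TR$variant_id[at] <- V$variant_id[at]; TR$vclass[at] <- vclass
    TR$category[at] <- sp$category; TR$gene_id[at] <- genes$gene_id[g]
    TR$causal[at] <- causal; TR$delta[at] <- delta_v
    TR$distance[at] <- d; TR$rho[at] <- rho
  }
  variants <- as.data.frame(V, stringsAsFactors = FALSE)
  truth <- as.data.frame(TR, stringsAsFactors = FALSE)
  ## avoid coincident positions colliding on (chrom, pos) score matching
  dup <- duplicated(paste(variants$chrom, variants$pos))
  if (any(dup)) {
    shift <- cumsum(dup) %% 7L + 1L
    variants$pos[dup] <- variants$pos[dup] + shift[dup]
    variants$end[dup] <- variants$end[dup] + shift[dup]
  }
  vt <- variant_table(variants, geno, panel)

  ## expression: per condition, carriers of causal variants are shifted by
  ## delta_v * w(d) (x kappa in dry), in units of the biological SD
  w <- exp(-truth$distance / cfg$lambda)
  w[truth$distance == 0] <- 1
  shift_base <- matrix(0, G, N)
  causal_idx <- which(truth$causal)
  for (i in causal_idx) {
    g <- match(truth$gene_id[i], genes$gene_id)
    carr <- which(geno[i, ] >= 1L)
    shift_base[g, carr] <- shift_base[g, carr] +
      truth$delta[i] * w[i] * cfg$bio_sd
  }
  make_expr <- function(condition) {
    kappa <- if (condition == "dry") cfg$kappa_dry else 1
    cond_shift <- if (condition == "dry") stats::rnorm(G, 0, 0.3) else numeric(G)
    latent <- matrix(stats::rnorm(G * N, 0, cfg$bio_sd), G, N) +
      mu + cond_shift + kappa * shift_base
    arr <- array(NA_real_, c(G, N, cfg$n_replicates),
                 dimnames = list(genes$gene_id, as.character(panel), NULL))
    for (k in seq_len(cfg$n_replicates))
      arr[, , k] <- pmax(0, latent + stats::rnorm(G * N, 0, cfg$rep_noise_sd))
    drop_mask <- matrix(stats::runif(G * N) < cfg$dropout, G, N)
    for (k in seq_len(cfg$n_replicates)) {
      slice <- arr[, , k]
      slice[drop_mask] <- 0
      arr[, , k] <- slice
    }
    expression_matrix(arr, condition, panel)
  }
  em_wet <- make_expr("wet")
  em_dry <- make_expr("dry")

  ## write everything
  paths <- list(
    vcf = file.path(dir, "variants.vcf"),
    gff = file.path(dir, "genes.gff3"),
    expr_wet = file.path(dir, "expr_wet.tsv"),
    expr_dry = file.path(dir, "expr_dry.tsv"),
    metadata = file.path(dir, "gene_metadata.tsv"),
    scores = file.path(dir, "site_scores.tsv"),
    te = file.path(dir, "te.bed"),
    truth = file.path(dir, "truth.tsv"))
  write_vcf(vt, paths$vcf)
  write_gene_models(genes, paths$gff)
  write_expression(em_wet, paths$expr_wet)
  write_expression(em_dry, paths$expr_dry)
  write_tsv_df(data.frame(gene_id = genes$gene_id,
                          recomb_rate = recomb,
                          connectivity = connectivity,
                          te_overlap = te_overlap), paths$metadata)
  snp <- truth$vclass == "SNP"
  write_tsv_df(data.frame(chrom = variants$chrom[snp], pos = variants$pos[snp],
                          rho = truth$rho[snp]), paths$scores)
  writeLines(paste(te$chrom, te$start - 1L, te$end, "TE", 0, "+", sep = "\t"),
             paths$te)
  write_tsv_df(truth, paths$truth)
  invisible(list(paths = paths, truth = truth, config = cfg))
}
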