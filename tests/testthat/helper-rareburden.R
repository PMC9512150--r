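# Shared helpers: small in-memory builders used across the test files.

# Variant table with given genotype matrix (variants x samples) and optional
# per-variant field overrides.
make_vt <- function(geno, panel = sample_panel(sprintf("S%d", seq_len(ncol(geno)))),
                    vclass = "SNP", pos = NULL, end = NULL, length = NULL, ...) {
  n <- nrow(geno)
  vclass <- rep_len(vclass, n)
  if (is.null(pos)) pos <- 1000L + 10L * seq_len(n)
  if (is.null(length)) length <- ifelse(vclass == "SNP", 1L,
                                        ifelse(vclass == "BND", 0L, 100L))
  if (is.null(end)) end <- ifelse(vclass %in% c("SNP", "INDEL", "INS", "BND"),
                                  pos, pos + length - 1L)
  df <- data.frame(variant_id = sprintf("v%03d", seq_len(n)), chrom = "chr1",
                   pos = pos, end = end, ref = "A",
                   alt = ifelse(vclass %in% SV_CLASSES & vclass != "SNP",
                                paste0("<", vclass, ">"), "T"),
                   vclass = vclass, length = length, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  variant_table(df, geno, panel)
}

# Rank table directly from a values matrix (genes x samples).
make_ranks <- function(values, panel = sample_panel(colnames(values)),
                       min_samples = 2L) {
  rank_samples(values, panel, min_samples = min_samples)
}

# Burden cube built directly from a per-(gene, sample) count matrix with a
# single pooled bin, bypassing genomic assignment.
make_cube <- function(counts, bin = "GENIC",
                      panel = sample_panel(colnames(counts))) {
  arr <- array(as.integer(counts), dim = c(nrow(counts), ncol(counts), 1L),
               dimnames = list(rownames(counts), colnames(counts), bin))
  structure(list(counts = arr, genes = rownames(counts), panel = panel,
                 bins = bin, mode = "cis",
                 assignments = data.frame()),
            class = "burden_cube")
}

# Independent brute-force phi: double loop over genes and samples.
brute_phi <- function(count_mat, rank_mat, n_g,
                      extreme = c(0.10, 0.90), middle = c(0.40, 0.60)) {
  E <- 0; M <- 0
  for (g in seq_len(nrow(count_mat))) {
    pb <- phi_rank_bins(n_g[g], extreme, middle)
    for (s in seq_len(ncol(count_mat))) {
      r <- rank_mat[g, s]
      if (is.na(r)) next
      if (r %in% pb$extreme) E <- E + count_mat[g, s]
      if (r %in% pb$middle) M <- M + count_mat[g, s]
    }
  }
  list(E_r = E, M_r = M, phi = E / M)
}

# Expression matrix with identical replicates from a genes x samples matrix.
make_expr <- function(values, condition = "wet", n_rep = 3L,
                      panel = sample_panel(colnames(values))) {
  arr <- array(rep(as.numeric(values), n_rep),
               dim = c(nrow(values), ncol(values), n_rep),
               dimnames = list(rownames(values), colnames(values), NULL))
  expression_matrix(arr, condition, panel)
}

# Small simulated dataset reused by several slow-ish tests (built once).
shared_sim_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "rareburden_shared_sim")
      if (!file.exists(file.path(dir, "variants.vcf"))) {
        cfg <- sim_config(n_genes = 250L,
                          n_rare = c(SNP = 700L, INDEL = 180L, SV = 90L),
                          n_common = c(SNP = 70L, INDEL = 20L, SV = 10L),
                          seed = 2024L)
        simulate_population(cfg, dir)
      }
    }
    dir
  }
})
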