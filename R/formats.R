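#' Construct a sample panel
#'
#' A sample panel is the canonical ordered set of individual identifiers for a
#' population. Every genotype vector, expression matrix and rank table in the
#' package is indexed against one panel; ploidy is fixed at 2 (the populations
#' analysed here are diploid, largely selfing landraces).
#'
#' @param ids character vector of unique sample identifiers.
#' @return character vector of class `sample_panel`.
#' @export
sample_panel <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("sample panel must contain at least one sample")
  if (anyDuplicated(ids)) stop("sample identifiers must be unique")
  structure(ids, class = "sample_panel")
}

#' Variant classes recognised by the package
#' @export
VARIANT_CLASSES <- c("SNP", "INDEL", "DEL", "DUP", "INS", "INV", "BND")

#' Structural-variant classes (breakends included)
#' @export
SV_CLASSES <- c("DEL", "DUP", "INS", "INV", "BND")

ANNOT_COLS <- c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum",
                "dhffc", "dhbfc", "rho")

#' Construct a variant table
#'
#' The in-memory population variant container: a per-variant data frame plus a
#' genotype matrix (variants x samples) holding alternate-allele counts
#' 0/1/2 with `NA` for missing calls. All coordinates are 1-based inclusive.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `end`, `ref`, `alt`, `vclass`, `length`, and optionally the site
#'   annotations `QD`, `FS`, `MQ`, `SOR`, `MQRankSum`, `ReadPosRankSum`,
#'   `dhffc`, `dhbfc`, `rho`.
#' @param geno integer matrix, one row per variant in the same order,
#'   one column per panel sample.
#' @param panel a [sample_panel()].
#' @return object of class `variant_table`.
#' @export
variant_table <- function(variants, geno, panel) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "end", "ref", "alt", "vclass", "length")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing columns: ", paste(miss, collapse = ", "))
  for (a in ANNOT_COLS) if (!a %in% names(variants)) variants[[a]] <- NA_real_
  if (anyDuplicated(variants$variant_id)) stop("variant_id values must be unique")
  if (!all(variants$vclass %in% VARIANT_CLASSES))
    stop("unknown variant class: ",
         paste(unique(setdiff(variants$vclass, VARIANT_CLASSES)), collapse = ", "))
  if (any(variants$pos > variants$end)) stop("variant pos must be <= end")
  bad_len <- variants$length < 1 & variants$vclass != "BND"
  if (any(bad_len)) stop("variant length must be >= 1 (0 permitted only for BND)")
  if (any(variants$vclass == "SNP" & variants$length != 1))
    stop("SNPs must have length 1")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants))
    stop("genotype matrix rows must match variant rows")
  if (ncol(geno) != length(panel))
    stop("genotype matrix columns must match panel size")
  if (any(geno < 0L | geno > 2L, na.rm = TRUE))
    stop("genotypes must be alternate-allele counts in 0..2")
  rownames(geno) <- variants$variant_id
  colnames(geno) <- as.character(panel)
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno, panel = panel),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples\n",
              nrow(x$variants), length(x$panel)))
  print(table(x$variants$vclass))
  invisible(x)
}

#' Number of variants in a variant table
#' @param vt a `variant_table`.
#' @export
n_variants <- function(vt) nrow(vt$variants)

#' Subset a variant table by row index or logical mask
#' @param vt a `variant_table`.
#' @param i integer or logical index over variants.
#' @export
subset_variants <- function(vt, i) {
  variant_table(vt$variants[i, , drop = FALSE],
                vt$geno[i, , drop = FALSE], vt$panel)
}

## ---------------------------------------------------------------------------
## VCF input/output

# Map one biallelic GT string vector to 0/1/2/NA alt-allele counts for allele k.
# Works on the unique strings only, so cost is independent of panel size.
.parse_gt <- function(gt_strings, k) {
  # fast path: hash-match the canonical diploid codes for allele k
  ks <- as.character(k)
  fast_names <- c("0/0", "0|0", paste0("0/", ks), paste0(ks, "/0"),
                  paste0("0|", ks), paste0(ks, "|0"),
                  paste0(ks, "/", ks), paste0(ks, "|", ks), "./.", ".|.", ".")
  fast_vals <- c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L,
                 NA_integer_, NA_integer_, NA_integer_)
  idx <- match(gt_strings, fast_names)
  out <- fast_vals[idx]
  rest <- which(is.na(idx) & !is.na(gt_strings))
  if (length(rest)) {
    # general path (other alleles, FORMAT suffixes): parse unique strings only
    uraw <- unique(gt_strings[rest])
    ug <- sub(":.*", "", uraw)
    parse_one <- function(g) {
      al <- strsplit(g, "[/|]", perl = TRUE)[[1]]
      if (length(al) < 1L || length(al) > 2L) return(-2L)  # malformed
      if (any(al == ".")) return(NA_integer_)
      if (!all(grepl("^[0-9]+$", al))) return(-2L)
      if (length(al) == 1L) al <- c(al, al)  # haploid treated as homozygous
      sum(al == ks)
    }
    map <- vapply(ug, parse_one, integer(1), USE.NAMES = FALSE)
    out[rest] <- map[match(gt_strings[rest], uraw)]
  }
  out
}

.parse_info <- function(info, key) {
  # returns character vector of values or NA where absent (vectorized)
  has <- grepl(paste0("(^|;)", key, "="), info)
  out <- rep(NA_character_, length(info))
  if (any(has))
    out[has] <- sub(paste0("^(?:.*;)?", key, "=([^;]*).*$"), "\\1",
                    info[has], perl = TRUE)
  out
}

.info_num <- function(info, key) suppressWarnings(as.numeric(.parse_info(info, key)))

#' Read a population VCF into a variant table
#'
#' Parses VCF 4.x with per-sample GT fields. Multiallelic sites are split into
#' one biallelic record per ALT allele (records share `pos` but get distinct
#' `variant_id`s). Variant class is inferred from allele lengths for sequence
#' alleles (SNP: both length 1; INDEL: size difference 1-20 bp; larger
#' differences become DEL/INS) and from `SVTYPE` for symbolic alleles. INFO
#' keys `SVTYPE`, `END`, `SVLEN`, `DHFFC`, `DHBFC`, `RHO` and the GATK site
#' annotations `QD`, `FS`, `MQ`, `SOR`, `MQRankSum`, `ReadPosRankSum` are
#' honored when present.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param panel optional [sample_panel()]; defaults to the VCF sample columns.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, panel = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no genotype columns")
  if (!all(startsWith(gt[, 1L], "GT")))
    stop("GT must be the first FORMAT field")
  samples <- colnames(gt)[-1L]
  if (is.null(panel)) panel <- sample_panel(samples)
  if (!setequal(samples, as.character(panel)))
    stop("VCF samples do not match the supplied panel")
  gt <- gt[, match(as.character(panel), colnames(gt)), drop = FALSE]

  info <- fix$INFO
  pos0 <- as.integer(fix$POS)
  svtype0 <- .parse_info(info, "SVTYPE")
  svend0 <- suppressWarnings(as.integer(.parse_info(info, "END")))
  svlen0 <- suppressWarnings(as.integer(.parse_info(info, "SVLEN")))

  ## expand multiallelic sites: one output record per ALT allele
  alts_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts_list)
  rec <- rep(seq_along(pos0), n_alt)
  k <- sequence(n_alt)
  alt <- unlist(alts_list, use.names = FALSE)
  ref <- fix$REF[rec]
  pos <- pos0[rec]
  svtype <- svtype0[rec]; svend <- svend0[rec]; svlen <- svlen0[rec]

  breakend_alt <- grepl("[", alt, fixed = TRUE) | grepl("]", alt, fixed = TRUE)
  symbolic <- grepl("^<.*>$", alt) | breakend_alt
  svtype[symbolic & is.na(svtype) & breakend_alt] <- "BND"

  n <- length(alt)
  vclass <- rep(NA_character_, n)
  len <- integer(n); end <- integer(n)
  drop <- logical(n)

  lr <- nchar(ref); la <- nchar(alt)
  diff <- abs(lr - la)
  seqal <- !symbolic
  snp <- seqal & lr == 1L & la == 1L
  vclass[snp] <- "SNP"; len[snp] <- 1L; end[snp] <- pos[snp]
  small <- seqal & diff >= 1L & diff <= 20L
  vclass[small] <- "INDEL"; len[small] <- diff[small]
  end[small] <- pos[small] + lr[small] - 1L
  big <- seqal & diff > 20L
  vclass[big] <- ifelse(la[big] > lr[big], "INS", "DEL")
  len[big] <- diff[big]; end[big] <- pos[big] + lr[big] - 1L
  mnp <- seqal & diff == 0L & lr > 1L   # same-length substitution block
  vclass[mnp] <- "INDEL"; len[mnp] <- 1L; end[mnp] <- pos[mnp] + lr[mnp] - 1L

  sym_ok <- symbolic & !is.na(svtype) & svtype %in% SV_CLASSES
  bad_sym <- symbolic & !sym_ok
  if (any(bad_sym)) {
    warning(sprintf("%d records with unknown SVTYPE skipped", sum(bad_sym)),
            call. = FALSE)
    drop[bad_sym] <- TRUE
  }
  bnd <- sym_ok & svtype == "BND"
  vclass[bnd] <- "BND"; len[bnd] <- 0L; end[bnd] <- pos[bnd]
  ins <- sym_ok & svtype == "INS" & !is.na(svlen)
  vclass[ins] <- "INS"; len[ins] <- abs(svlen[ins]); end[ins] <- pos[ins]
  other <- sym_ok & !bnd & !ins
  use_end <- other & !is.na(svend)
  vclass[use_end] <- svtype[use_end]
  end[use_end] <- svend[use_end]; len[use_end] <- svend[use_end] - pos[use_end] + 1L
  use_len <- other & is.na(svend) & !is.na(svlen)
  vclass[use_len] <- svtype[use_len]
  len[use_len] <- abs(svlen[use_len])
  end[use_len] <- ifelse(svtype[use_len] == "INS", pos[use_len],
                         pos[use_len] + len[use_len] - 1L)
  no_extent <- other & is.na(svend) & is.na(svlen)
  if (any(no_extent)) {
    warning(sprintf("%d SV records lack END and SVLEN; skipped", sum(no_extent)),
            call. = FALSE)
    drop[no_extent] <- TRUE
  }

  keep <- !drop
  if (!any(keep)) stop("no usable variant records in ", path)

  ## genotypes: parse per distinct alt-allele index over whole sub-matrices
  geno <- matrix(NA_integer_, n, ncol(gt))
  for (kk in unique(k)) {
    rows <- which(k == kk & keep)
    if (!length(rows)) next
    sub_gt <- gt[rec[rows], , drop = FALSE]
    g <- .parse_gt(as.vector(sub_gt), kk)
    if (any(g == -2L, na.rm = TRUE)) {
      bad <- which(matrix(g, nrow = length(rows))[, 1] == -2L |
                     apply(matrix(g == -2L, nrow = length(rows)), 1L, any))[1]
      stop(sprintf("malformed GT at VCF record %d (%s:%d)", rec[rows[bad]],
                   fix$CHROM[rec[rows[bad]]], pos0[rec[rows[bad]]]))
    }
    geno[rows, ] <- matrix(g, nrow = length(rows))
  }

  id <- fix$ID[rec]
  no_id <- is.na(id) | id == "."
  id[no_id] <- sprintf("%s_%d", fix$CHROM[rec][no_id], pos[no_id])
  multi <- n_alt[rec] > 1L
  id[multi] <- sprintf("%s_alt%d", id[multi], k[multi])

  variants <- data.frame(
    variant_id = id[keep], chrom = fix$CHROM[rec][keep], pos = pos[keep],
    end = end[keep], ref = ref[keep], alt = alt[keep], vclass = vclass[keep],
    length = len[keep],
    QD = .info_num(info, "QD")[rec][keep], FS = .info_num(info, "FS")[rec][keep],
    MQ = .info_num(info, "MQ")[rec][keep], SOR = .info_num(info, "SOR")[rec][keep],
    MQRankSum = .info_num(info, "MQRankSum")[rec][keep],
    ReadPosRankSum = .info_num(info, "ReadPosRankSum")[rec][keep],
    dhffc = .info_num(info, "DHFFC")[rec][keep],
    dhbfc = .info_num(info, "DHBFC")[rec][keep],
    rho = .info_num(info, "RHO")[rec][keep],
    stringsAsFactors = FALSE)
  if (anyDuplicated(variants$variant_id))
    variants$variant_id <- make.unique(variants$variant_id, sep = "_dup")
  variant_table(variants, geno[keep, , drop = FALSE], panel)
}

#' Write a variant table as VCF
#'
#' Emits a minimal VCF 4.2 with GT genotypes and the package's honored INFO
#' keys, suitable for re-reading with [read_vcf()] (field-for-field
#' round trip).
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @export
write_vcf <- function(vt, path) {
  v <- vt$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=DHFFC,Number=1,Type=Float,Description=\"Duphold depth fold-change vs flanks\">",
    "##INFO=<ID=DHBFC,Number=1,Type=Float,Description=\"Duphold depth fold-change vs GC bins\">",
    "##INFO=<ID=RHO,Number=1,Type=Float,Description=\"fitCons score\">",
    paste0("##INFO=<ID=", c("QD","FS","MQ","SOR","MQRankSum","ReadPosRankSum"),
           ",Number=1,Type=Float,Description=\"GATK site annotation\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            as.character(vt$panel)), collapse = "\t"))
  num <- function(x) formatC(x, format = "g", digits = 8)
  add_kv <- function(info, key, val, present = !is.na(val), fmt = num) {
    idx <- which(present)
    if (!length(idx)) return(info)
    piece <- paste0(key, "=", fmt(val[idx]))
    empty <- info[idx] == ""
    info[idx][empty] <- piece[empty]
    info[idx][!empty] <- paste(info[idx][!empty], piece[!empty], sep = ";")
    info
  }
  info <- character(nrow(v))
  sym <- v$vclass %in% SV_CLASSES & grepl("^<.*>$", v$alt)
  info <- add_kv(info, "SVTYPE", v$vclass, sym, fmt = identity)
  info <- add_kv(info, "END", v$end, sym, fmt = identity)
  info <- add_kv(info, "SVLEN", v$length, sym, fmt = identity)
  for (key in c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum"))
    info <- add_kv(info, key, v[[key]])
  info <- add_kv(info, "DHFFC", v$dhffc)
  info <- add_kv(info, "DHBFC", v$dhbfc)
  info <- add_kv(info, "RHO", v$rho)
  info[info == ""] <- "."
  gt_code <- c("0/0", "0/1", "1/1")
  gm <- matrix(gt_code[vt$geno + 1L], nrow = nrow(v))
  gm[is.na(vt$geno)] <- "./."
  body <- data.frame(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                     info, "GT", gm, stringsAsFactors = FALSE,
                     check.names = FALSE)
  writeLines(hdr, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene models

#' Read gene models from GFF3 or BED
#'
#' Coordinates are normalised to 1-based inclusive (BED's 0-based half-open
#' intervals are converted on ingestion by `rtracklayer`). The transcription
#' start site is derived from strand: `start` on `+`, `end` on `-`. Strand is
#' required because upstream windows are strand-aware.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @param format override the extension-based dialect guess.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss` and placeholder metadata columns `recomb_rate`,
#'   `connectivity`, `te_overlap`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
              else if (ext == "bed") "bed"
              else stop("cannot infer gene-model format from extension '", ext, "'")
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr))) {
    gg <- gr[as.character(gr$type) == "gene"]
    if (length(gg)) gr <- gg
  }
  if (!length(gr)) stop("no gene records in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("gene models must carry strand (+/-); found unstranded records")
  ids <- NULL
  mc <- S4Vectors::mcols(gr)
  for (cand in c("ID", "Name", "gene_id", "name")) {
    if (cand %in% names(mc) && !all(is.na(mc[[cand]]))) { ids <- as.character(mc[[cand]]); break }
  }
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(gr))
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  gene_models(data.frame(
    gene_id = ids, chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand, start = start, end = end, stringsAsFactors = FALSE))
}

#' Validate and complete a gene-model data frame
#'
#' @param df data.frame with `gene_id`, `chrom`, `strand`, `start`, `end` and
#'   optional `recomb_rate`, `connectivity`, `te_overlap`.
#' @export
gene_models <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene models missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("gene_id values must be unique")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(df$start > df$end)) stop("gene start must be <= end")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  for (m in c("recomb_rate", "connectivity", "te_overlap"))
    if (!m %in% names(df)) df[[m]] <- NA_real_
  if (any(!is.na(df$connectivity) & (df$connectivity < 0 | df$connectivity > 1)))
    stop("connectivity must lie in [0,1]")
  rownames(df) <- NULL
  df
}

#' Write gene models as GFF3
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "rareburden", "gene", genes$start, genes$end,
                   ".", genes$strand, ".", paste0("ID=", genes$gene_id),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Attach per-gene metadata (recombination rate, connectivity, TE overlap)
#'
#' @param genes gene-model data.frame.
#' @param meta data.frame or TSV path with `gene_id` plus any of
#'   `recomb_rate` (cM/Mb), `connectivity` (correlation in `[0,1]`),
#'   `te_overlap` (fraction in `[0,1]`).
#' @export
attach_gene_metadata <- function(genes, meta) {
  if (is.character(meta)) meta <- read_tsv_df(meta)
  idx <- match(genes$gene_id, meta$gene_id)
  for (m in c("recomb_rate", "connectivity", "te_overlap")) {
    if (m %in% names(meta)) {
      val <- meta[[m]][idx]
      genes[[m]] <- ifelse(is.na(val), genes[[m]], val)
    }
  }
  gene_models(genes)
}

## ---------------------------------------------------------------------------
## Expression matrices

#' Construct an expression matrix container
#'
#' Holds per (gene, sample, replicate) normalized expression values, on the
#' log2(TPM + 1) scale by convention, for one growth condition.
#'
#' @param values 3-d numeric array `genes x samples x replicates`
#'   (dimnames: gene ids, sample ids, NULL).
#' @param condition condition label (e.g. `"wet"`, `"dry"`).
#' @param panel a [sample_panel()].
#' @export
expression_matrix <- function(values, condition, panel) {
  stopifnot(length(dim(values)) == 3L)
  if (dim(values)[2] != length(panel))
    stop("expression samples must match panel size")
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be >= 0 (log2(TPM+1) scale)")
  if (is.null(dimnames(values)[[1]])) stop("expression array needs gene dimnames")
  dimnames(values)[[2]] <- as.character(panel)
  structure(list(values = values, condition = condition,
                 genes = dimnames(values)[[1]], panel = panel),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples x %d replicates\n",
              x$condition, d[1], d[2], d[3]))
  invisible(x)
}

#' Read a replicate-level expression TSV
#'
#' Expected layout: a `gene_id` column plus one column per
#' `<sample>__rep<k>` combination. Replicate counts must be identical across
#' samples. Values may be `NA`.
#'
#' @param path TSV path.
#' @param condition condition label stored on the result.
#' @param n_replicates expected replicates per sample (default 3).
#' @param log2p1 if `TRUE`, apply `log2(x + 1)` to the values on ingestion.
#' @param panel optional [sample_panel()] fixing sample order.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, condition, n_replicates = 3L, log2p1 = FALSE,
                            panel = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (!"gene_id" %in% names(dt)) stop("expression TSV must have a gene_id column")
  cols <- setdiff(names(dt), "gene_id")
  m <- regmatches(cols, regexec("^(.*)__rep([0-9]+)$", cols))
  ok <- lengths(m) == 3L
  if (!all(ok)) stop("expression columns must be named <sample>__rep<k>: ",
                     paste(cols[!ok], collapse = ", "))
  samp <- vapply(m, `[`, character(1), 2L)
  rep_k <- as.integer(vapply(m, `[`, character(1), 3L))
  reps_per <- tapply(rep_k, samp, function(x) length(unique(x)))
  if (length(unique(reps_per)) != 1L)
    stop("replicate count is inconsistent across samples")
  if (unique(reps_per) != n_replicates)
    stop(sprintf("expected %d replicates per sample, found %d",
                 n_replicates, unique(reps_per)))
  usamp <- unique(samp)
  if (is.null(panel)) panel <- sample_panel(usamp)
  if (!setequal(usamp, as.character(panel)))
    stop("expression samples do not match the supplied panel")
  genes <- as.character(dt$gene_id)
  arr <- array(NA_real_, dim = c(length(genes), length(panel), n_replicates),
               dimnames = list(genes, as.character(panel), NULL))
  for (j in seq_along(cols)) {
    v <- as.numeric(dt[[cols[j]]])
    arr[, match(samp[j], as.character(panel)), rep_k[j]] <- v
  }
  if (log2p1) arr <- log2(arr + 1)
  expression_matrix(arr, condition, panel)
}

#' Write an expression matrix as replicate-level TSV
#' @param em an [expression_matrix()].
#' @param path output path.
#' @param digits decimal places used for values (fixed for determinism).
#' @export
write_expression <- function(em, path, digits = 4L) {
  d <- dim(em$values)
  cols <- list(gene_id = em$genes)
  for (s in seq_len(d[2])) for (k in seq_len(d[3])) {
    nm <- sprintf("%s__rep%d", as.character(em$panel)[s], k)
    cols[[nm]] <- round(em$values[, s, k], digits)
  }
  data.table::fwrite(as.data.frame(cols, check.names = FALSE), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Site fitness-consequence scores

#' Read per-site fitness-consequence (fitCons) scores
#'
#' @param path TSV with columns `chrom`, `pos`, `rho`; `rho` is the
#'   probability (in `[0,1]`) that a mutation at the site has a fitness
#'   consequence.
#' @return data.frame of scores.
#' @export
read_site_scores <- function(path) {
  df <- read_tsv_df(path)
  req <- c("chrom", "pos", "rho")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("site-score TSV missing columns: ", paste(miss, collapse = ", "))
  if (any(df$rho < 0 | df$rho > 1, na.rm = TRUE))
    stop("rho scores must lie in [0,1]")
  df
}

#' Attach fitCons scores to SNP records
#'
#' Scores are matched to SNPs by exact (chrom, pos); unmatched SNPs keep
#' `rho = NA`, and unmatched score rows are counted in a message.
#'
#' @param vt a [variant_table()].
#' @param scores data.frame from [read_site_scores()] (or a path).
#' @export
attach_site_scores <- function(vt, scores) {
  if (is.character(scores)) scores <- read_site_scores(scores)
  key_v <- paste(vt$variants$chrom, vt$variants$pos)
  key_s <- paste(scores$chrom, scores$pos)
  is_snp <- vt$variants$vclass == "SNP"
  idx <- match(key_v, key_s)
  hit <- is_snp & !is.na(idx)
  vt$variants$rho[hit] <- scores$rho[idx[hit]]
  unmatched <- sum(!key_s %in% key_v[is_snp])
  if (unmatched > 0)
    message(unmatched, " site-score rows had no matching SNP and were ignored")
  vt
}

## ---------------------------------------------------------------------------
## Small TSV helpers

#' Read a TSV into a plain data frame
#' @param path TSV path.
#' @export
read_tsv_df <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a plain data frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv_df <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read per-sample SV calls from TSV
#'
#' Layout used by the SV merge machinery: one row per call with columns
#' `sample`, `chrom`, `pos`, `end`, `vclass`, `length`, `gt` (alt-allele
#' count) and optional `dhffc`, `dhbfc`.
#'
#' @param path TSV path.
#' @export
read_sv_calls <- function(path) {
  df <- read_tsv_df(path)
  req <- c("sample", "chrom", "pos", "end", "vclass", "length", "gt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("SV call TSV missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$vclass %in% SV_CLASSES)) stop("SV calls must have SV classes")
  df
}
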