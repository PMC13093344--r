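#' Pooled allele-count container
#'
#' The raw observable of a Pool-Seq experiment: per-SNP, per-stand reference
#' and alternate read depths, plus the haploid size of each pool.
#'
#' @param snp Tibble with one row per SNP: `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param ref_depth,alt_depth SNPs x stands non-negative integer matrices.
#' @param haploid_size Named integer vector of per-pool haploid sample sizes
#'   (>= 2), or a single value recycled to all stands.
#' @param stand_ids Character vector of stand ids (column order of the depth
#'   matrices).
#'
#' @return An object of class `pool_counts`.
#' @export
pool_counts <- function(snp, ref_depth, alt_depth, haploid_size, stand_ids) {
  ref_depth <- as.matrix(ref_depth)
  alt_depth <- as.matrix(alt_depth)
  if (!all(dim(ref_depth) == dim(alt_depth))) {
    abort("`ref_depth` and `alt_depth` must have identical dimensions")
  }
  if (nrow(ref_depth) != nrow(snp)) {
    abort("depth matrices must have one row per SNP")
  }
  if (ncol(ref_depth) != length(stand_ids)) {
    abort("depth matrices must have one column per stand")
  }
  if (any(ref_depth < 0) || any(alt_depth < 0)) {
    abort("read depths must be non-negative")
  }
  if (length(haploid_size) == 1) {
    haploid_size <- stats::setNames(rep(haploid_size, length(stand_ids)),
                                    stand_ids)
  }
  haploid_size <- haploid_size[stand_ids]
  if (any(is.na(haploid_size)) || any(haploid_size < 2)) {
    abort("`haploid_size` must cover every stand and be >= 2")
  }
  storage.mode(ref_depth) <- "integer"
  storage.mode(alt_depth) <- "integer"
  dimnames(ref_depth) <- dimnames(alt_depth) <- list(snp$snp_id, stand_ids)
  structure(
    list(snp = tibble::as_tibble(snp), ref_depth = ref_depth,
         alt_depth = alt_depth,
         haploid_size = stats::setNames(as.integer(haploid_size), stand_ids),
         stand_ids = stand_ids),
    class = "pool_counts"
  )
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> %d SNPs x %d pools (haploid sizes %s)\n",
              nrow(x$snp), length(x$stand_ids),
              paste(range(x$haploid_size), collapse = "-")))
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat("filtered; removal per rule:",
        paste(sprintf("%s=%d", rep$rule, rep$n_removed), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.pool_counts <- function(x) dim(x$ref_depth)

# Subset SNPs (rows) and/or stands (columns) of a pool_counts object.
subset_pool_counts <- function(pc, snps = NULL, stands = NULL) {
  i <- if (is.null(snps)) seq_len(nrow(pc$snp)) else snps
  j <- if (is.null(stands)) pc$stand_ids else stands
  pool_counts(pc$snp[i, , drop = FALSE],
              pc$ref_depth[i, j, drop = FALSE],
              pc$alt_depth[i, j, drop = FALSE],
              pc$haploid_size[j], j)
}

total_depth <- function(pc) pc$ref_depth + pc$alt_depth

#' Read pooled variant calls from a VCF file
#'
#' Reads a VCF with one sample per pool and per-sample allelic depths (the
#' `AD` FORMAT field), retaining biallelic SNP records only. Multiallelic and
#' indel records are dropped and counted. Pool haploid sizes are taken from a
#' `##poolscape_haploid_size=` header line when present (as written by
#' [write_pool_vcf()]) or from the `haploid_sizes` argument.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param haploid_sizes Named integer vector (or single value) of per-pool
#'   haploid sizes; required when the header carries none.
#'
#' @return A [pool_counts] object with attribute `n_dropped`, the number of
#'   non-biallelic-SNP records removed.
#' @export
read_pool_vcf <- function(path, haploid_sizes = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(haploid_sizes)) {
    meta <- grep("^##poolscape_haploid_size=", v@meta, value = TRUE)
    if (length(meta) == 1) {
      spec <- sub("^##poolscape_haploid_size=", "", meta)
      parts <- strsplit(strsplit(spec, ",")[[1]], ":")
      haploid_sizes <- stats::setNames(
        as.integer(vapply(parts, `[`, "", 2)),
        vapply(parts, `[`, "", 1))
    } else {
      abort("no haploid sizes in VCF header; supply `haploid_sizes`")
    }
  }
  keep <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$ALT %in% c("A", "C", "G", "T") & fix$REF %in% c("A", "C", "G", "T")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d non-biallelic-SNP record(s)", n_dropped))
  }
  fmt <- unique(unlist(strsplit(v@gt[, 1], ":")))
  if (!"AD" %in% fmt) {
    abort(sprintf("record %s:%s has no AD field in FORMAT",
                  fix$CHROM[1], fix$POS[1]))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (any(is.na(ad[keep, , drop = FALSE]))) {
    bad <- which(is.na(ad) & keep)[1]
    i <- (bad - 1) %% nrow(ad) + 1
    abort(sprintf("missing AD depths at record %s:%s",
                  fix$CHROM[i], fix$POS[i]))
  }
  ad <- ad[keep, , drop = FALSE]
  split_ad <- function(k) {
    matrix(as.integer(vapply(strsplit(ad, ",", fixed = TRUE), `[`, "", k)),
           nrow = nrow(ad))
  }
  ref_depth <- split_ad(1)
  alt_depth <- split_ad(2)
  snp <- tibble(
    snp_id = if (all(is.na(fix$ID[keep])) || all(fix$ID[keep] == "."))
      sprintf("%s_%s", fix$CHROM[keep], fix$POS[keep]) else fix$ID[keep],
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  out <- pool_counts(snp, ref_depth, alt_depth, haploid_sizes,
                     colnames(v@gt)[-1])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write pooled counts as a minimal VCF with per-sample allelic depths
#'
#' @param pc A [pool_counts] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(pc, path) {
  hap <- paste(sprintf("%s:%d", names(pc$haploid_size), pc$haploid_size),
               collapse = ",")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolscape",
    sprintf("##poolscape_haploid_size=%s", hap),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pc$stand_ids), collapse = "\t")
  )
  ad <- matrix(paste0(pc$ref_depth, ",", pc$alt_depth), nrow = nrow(pc$snp))
  body <- cbind(pc$snp$chrom, pc$snp$pos, pc$snp$snp_id, pc$snp$ref,
                pc$snp$alt, ".", "PASS", ".", "AD", ad)
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

sync_base_order <- function() c("A", "T", "C", "G", "N", "del")

#' Read pooled counts from a sync file
#'
#' Parses the tab-separated sync interchange format
#' (`chr pos ref A:T:C:G:N:del` count strings, one column per pool). The
#' stated reference base defines the reference allele; the most frequent
#' other nucleotide (summed over pools) defines the alternate.
#'
#' @param path Path to a sync file.
#' @param haploid_sizes Named integer vector (or single value) of per-pool
#'   haploid sizes; names default to `pool1`, `pool2`, ... when the value is
#'   unnamed.
#' @return A [pool_counts] object.
#' @export
read_sync <- function(path, haploid_sizes) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (length(unique(n_col)) != 1 || n_col[1] < 4) {
    abort(sprintf("malformed sync line %d: expected >= 4 tab-separated fields",
                  which(n_col != n_col[1])[1] %||% 1))
  }
  n_pools <- n_col[1] - 3
  chrom <- vapply(fields, `[`, "", 1)
  pos <- as.integer(vapply(fields, `[`, "", 2))
  ref <- toupper(vapply(fields, `[`, "", 3))
  counts <- array(NA_integer_, c(length(lines), 6, n_pools))
  for (k in seq_len(n_pools)) {
    cell <- vapply(fields, `[`, "", 3 + k)
    parts <- strsplit(cell, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 6)
    if (length(bad) > 0) {
      abort(sprintf("malformed count string on line %d: '%s'",
                    bad[1], cell[bad[1]]))
    }
    mat <- suppressWarnings(
      matrix(as.integer(unlist(parts)), ncol = 6, byrow = TRUE))
    if (any(is.na(mat))) {
      abort(sprintf("malformed count string on line %d",
                    which(rowSums(is.na(mat)) > 0)[1]))
    }
    counts[, , k] <- mat
  }
  bases <- sync_base_order()
  totals <- apply(counts, c(1, 2), sum)            # SNPs x 6
  ref_idx <- match(ref, bases)
  if (any(is.na(ref_idx))) {
    abort(sprintf("unknown reference base on line %d",
                  which(is.na(ref_idx))[1]))
  }
  nt_tot <- totals[, 1:4, drop = FALSE]
  nt_tot[cbind(seq_along(ref_idx), ref_idx)] <- -1L   # exclude ref
  alt_idx <- max.col(nt_tot, ties.method = "first")
  ref_depth <- t(vapply(seq_along(ref_idx), function(i) {
    counts[i, ref_idx[i], ]
  }, numeric(n_pools)))
  alt_depth <- t(vapply(seq_along(alt_idx), function(i) {
    counts[i, alt_idx[i], ]
  }, numeric(n_pools)))
  if (n_pools == 1) {
    ref_depth <- matrix(ref_depth, ncol = 1)
    alt_depth <- matrix(alt_depth, ncol = 1)
  }
  stand_ids <- names(haploid_sizes) %||% sprintf("pool%d", seq_len(n_pools))
  if (length(haploid_sizes) == 1 && n_pools > 1 && is.null(names(haploid_sizes))) {
    stand_ids <- sprintf("pool%d", seq_len(n_pools))
  }
  snp <- tibble(snp_id = sprintf("%s_%d", chrom, pos), chrom = chrom,
                pos = pos, ref = ref, alt = bases[alt_idx])
  pool_counts(snp, ref_depth, alt_depth,
              if (is.null(names(haploid_sizes)))
                stats::setNames(rep(haploid_sizes, length.out = n_pools),
                                stand_ids)
              else haploid_sizes,
              stand_ids)
}

#' Write pooled counts in sync format
#'
#' @inheritParams write_pool_vcf
#' @return `path`, invisibly.
#' @export
write_sync <- function(pc, path) {
  bases <- sync_base_order()
  ref_idx <- match(pc$snp$ref, bases)
  alt_idx <- match(pc$snp$alt, bases)
  n_pools <- length(pc$stand_ids)
  cols <- vapply(seq_len(n_pools), function(k) {
    m <- matrix(0L, nrow(pc$snp), 6)
    m[cbind(seq_len(nrow(m)), ref_idx)] <- pc$ref_depth[, k]
    m[cbind(seq_len(nrow(m)), alt_idx)] <- pc$alt_depth[, k]
    apply(m, 1, paste, collapse = ":")
  }, character(nrow(pc$snp)))
  if (nrow(pc$snp) == 1) cols <- matrix(cols, nrow = 1)
  body <- cbind(pc$snp$chrom, pc$snp$pos, pc$snp$ref, cols)
  writeLines(apply(body, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Apply coverage and minor-allele-frequency SNP filters
#'
#' Three rules, applied in order: (a) every pool's total depth at the SNP is
#' at least `min_cov` reads (1x per haplotype for pools of 60); (b) every
#' pool's depth lies within that pool's own
#' `[cov_quantile_lo, cov_quantile_hi]` depth quantiles (computed across the
#' SNPs entering this rule); (c) the overall minor-allele frequency, pooled
#' across stands with depth weighting, is at least `maf_min`. A per-pool MAF
#' mode (`maf_scope = "per_pool"`: keep a SNP when any single pool reaches
#' `maf_min`) and a global coverage-quantile mode are available.
#'
#' @param pc A [pool_counts] object.
#' @param min_cov Minimum per-pool total depth.
#' @param cov_quantile_lo,cov_quantile_hi Depth quantile bounds.
#' @param maf_min Minimum minor-allele frequency.
#' @param maf_scope `"global"` (default, depth-weighted across all pools) or
#'   `"per_pool"`.
#' @param cov_scope `"per_pool"` (default; each pool's own depth distribution)
#'   or `"global"` (quantiles of all depths jointly).
#' @param cov_bounds Optional explicit depth band: a list with numeric
#'   vectors `lo` and `hi` (one entry per pool), used instead of recomputing
#'   quantiles. The realised band of a run is stored as attribute
#'   `cov_bounds`; re-filtering with that band is exactly idempotent, whereas
#'   recomputing quantiles on an already-trimmed depth distribution can shave
#'   a few further SNPs.
#'
#' @return A filtered [pool_counts] with attributes `filter_report` (tibble
#'   of SNPs removed per rule) and `cov_bounds` (the depth band applied).
#' @export
filter_snps <- function(pc, min_cov = 60, cov_quantile_lo = 0.001,
                        cov_quantile_hi = 0.999, maf_min = 0.008,
                        maf_scope = c("global", "per_pool"),
                        cov_scope = c("per_pool", "global"),
                        cov_bounds = NULL) {
  maf_scope <- match.arg(maf_scope)
  cov_scope <- match.arg(cov_scope)
  if (nrow(pc$snp) == 0) abort("`pc` contains no SNPs")
  depth <- total_depth(pc)
  n0 <- nrow(depth)

  keep_a <- rowSums(depth >= min_cov) == ncol(depth)
  n_a <- sum(!keep_a)
  depth_b <- depth[keep_a, , drop = FALSE]

  if (nrow(depth_b) > 0) {
    if (!is.null(cov_bounds)) {
      lo <- cov_bounds$lo
      hi <- cov_bounds$hi
    } else if (cov_scope == "per_pool") {
      lo <- apply(depth_b, 2, stats::quantile, probs = cov_quantile_lo)
      hi <- apply(depth_b, 2, stats::quantile, probs = cov_quantile_hi)
    } else {
      q <- stats::quantile(depth_b, probs = c(cov_quantile_lo, cov_quantile_hi))
      lo <- rep(q[1], ncol(depth_b))
      hi <- rep(q[2], ncol(depth_b))
    }
    in_band <- sweep(depth_b, 2, lo, ">=") & sweep(depth_b, 2, hi, "<=")
    keep_b <- rowSums(in_band) == ncol(depth_b)
  } else {
    lo <- hi <- rep(NA_real_, ncol(depth_b))
    keep_b <- logical(0)
  }
  n_b <- sum(!keep_b)

  idx_ab <- which(keep_a)[keep_b]
  alt <- pc$alt_depth[idx_ab, , drop = FALSE]
  tot <- depth[idx_ab, , drop = FALSE]
  if (maf_scope == "global") {
    p <- rowSums(alt) / rowSums(tot)
    maf <- pmin(p, 1 - p)
  } else {
    pp <- alt / tot
    maf <- apply(pmin(pp, 1 - pp), 1, max, na.rm = TRUE)
  }
  keep_c <- maf >= maf_min
  n_c <- sum(!keep_c)

  idx <- idx_ab[keep_c]
  if (length(idx) == 0) {
    warn("all SNPs removed by filtering")
  }
  out <- subset_pool_counts(pc, snps = idx)
  attr(out, "filter_report") <- tibble(
    rule = c("min_cov", "cov_quantile", "maf"),
    n_removed = c(n_a, n_b, n_c),
    n_remaining = c(n0 - n_a, n0 - n_a - n_b, length(idx))
  )
  attr(out, "cov_bounds") <- list(lo = lo, hi = hi)
  out
}

#' Estimate per-stand allele frequencies from read proportions
#'
#' The raw read-proportion estimator `alt / (ref + alt)` per SNP and stand,
#' the standard Pool-Seq frequency estimate.
#'
#' @param pc A [pool_counts] object in which every SNP has depth >= 1 in
#'   every pool (run [filter_snps()] first).
#'
#' @return A stands x SNPs numeric matrix with values in `[0, 1]`.
#' @export
estimate_frequencies <- function(pc) {
  depth <- total_depth(pc)
  if (any(depth == 0)) {
    abort("zero depth encountered; apply filter_snps() before estimating")
  }
  t(pc$alt_depth / depth)
}
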