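# Pool-Seq ANOVA FST (Hivert et al. 2018 style).
#
# Model per locus: pool i holds n_i haplotypes sampled from its population
# (allele frequency p_i), and c_i reads each drawn uniformly with replacement
# from those haplotypes. Writing phat_i for the read proportion,
#   E[c_i phat_i (1 - phat_i)]            = (c_i - D2_i) (1-F) pi (1-pi)
#   E[sum_i c_i (phat_i - pbar)^2]        = pi(1-pi) [F a1 + (1-F) a2]
# with D2_i = (n_i + c_i - 1)/n_i (the read-duplication correction),
# C1 = sum c_i, C2 = sum c_i^2, a1 = C1 - C2/C1 (= (n_d - 1) n_c),
# a2 = sum D2_i - sum(c_i D2_i)/C1, b = sum(c_i - D2_i). The method-of-moments
# estimator pairs an unbiased numerator (proportional to F) with an unbiased
# denominator (proportional to the total variance), combined across loci as a
# ratio of sums:
#   FST = sum_l [SSP - (a2/b) SSI] / sum_l [SSP + ((a1 - a2)/b) SSI].
# For two pools this is the pairwise ANOVA estimator of Hivert et al.; at
# c -> Inf it reduces to the classical Weir-Cockerham-type moment estimator.

# Per-locus numerator/denominator components for one pool pair (vectors over
# loci). y* = alt depth, c* = total depth, n* = haploid pool size.
fst_pair_components <- function(y1, c1, y2, c2, n1, n2) {
  usable <- c1 >= 1 & c2 >= 1
  p1 <- y1 / c1
  p2 <- y2 / c2
  C1 <- c1 + c2
  C2 <- c1^2 + c2^2
  d1 <- (n1 + c1 - 1) / n1
  d2 <- (n2 + c2 - 1) / n2
  a1 <- C1 - C2 / C1
  a2 <- (d1 + d2) - (c1 * d1 + c2 * d2) / C1
  b <- (c1 - d1) + (c2 - d2)
  usable <- usable & b > 0
  pbar <- (y1 + y2) / C1
  ssp <- c1 * (p1 - pbar)^2 + c2 * (p2 - pbar)^2
  ssi <- c1 * p1 * (1 - p1) + c2 * p2 * (1 - p2)
  num <- ssp - (a2 / b) * ssi
  den <- ssp + ((a1 - a2) / b) * ssi
  list(num = num[usable], den = den[usable], n_usable = sum(usable))
}

fst_pair <- function(pc, i, j) {
  comp <- fst_pair_components(
    pc$alt_depth[, i], total_depth(pc)[, i],
    pc$alt_depth[, j], total_depth(pc)[, j],
    pc$haploid_size[[i]], pc$haploid_size[[j]])
  if (comp$n_usable == 0) {
    abort(sprintf("no usable loci for pair %s / %s", i, j))
  }
  sum(comp$num) / sum(comp$den)
}

#' Pairwise Pool-Seq FST between all stands
#'
#' Multilocus pairwise FST using the ANOVA Pool-Seq estimator of Hivert et
#' al. (2018): per locus, between-pool and within-pool sums of squares from
#' read counts with the effective-sample-size correction for pool haploid
#' size and read depth, combined across loci as a ratio of sums. Slightly
#' negative estimates are reported as-is (estimator noise); clamping would
#' bias downstream Mantel statistics.
#'
#' @param pc A [pool_counts] object with at least two stands.
#'
#' @return A symmetric stands x stands matrix with zero diagonal and
#'   attribute `kind = "fst"`.
#' @export
pairwise_fst <- function(pc) {
  ids <- pc$stand_ids
  if (length(ids) < 2) abort("need at least two stands")
  if (nrow(pc$snp) < 1) abort("need at least one SNP")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in seq_along(ids)[-length(ids)]) {
    for (b in seq((a + 1), length(ids))) {
      f <- fst_pair(pc, ids[a], ids[b])
      m[a, b] <- m[b, a] <- f
    }
  }
  attr(m, "kind") <- "fst"
  m
}

#' Split pairwise FST into outlier and background matrices
#'
#' Partitions the SNPs of `pc` into the outlier set (SNPs passing in
#' `outliers`) and all remaining SNPs, and computes a pairwise FST matrix
#' from each disjoint set -- the dependent and control matrices of the
#' isolation-by-environment partial Mantel design.
#'
#' @param pc A [pool_counts] object.
#' @param outliers An outlier report (from [corr_outliers()] or
#'   [lfmm_associations()]), or a character vector of SNP ids.
#'
#' @return A list with `fst_outlier` and `fst_background` matrices (attributes
#'   `kind = "fst_outlier"` / `"fst_background"`).
#' @export
split_fst <- function(pc, outliers) {
  ids <- outlier_snp_ids(outliers)
  ids <- intersect(ids, pc$snp$snp_id)
  if (length(ids) == 0) {
    abort("empty outlier set; run a gene-environment association scan first")
  }
  if (length(ids) >= nrow(pc$snp)) {
    abort("outlier set must be a proper subset of the SNPs")
  }
  is_out <- pc$snp$snp_id %in% ids
  f_out <- pairwise_fst(subset_pool_counts(pc, snps = which(is_out)))
  f_bg <- pairwise_fst(subset_pool_counts(pc, snps = which(!is_out)))
  attr(f_out, "kind") <- "fst_outlier"
  attr(f_bg, "kind") <- "fst_background"
  list(fst_outlier = f_out, fst_background = f_bg)
}

outlier_snp_ids <- function(outliers) {
  if (is.character(outliers)) return(unique(outliers))
  if (is.data.frame(outliers)) {
    return(unique(outliers$snp_id[outliers$passes]))
  }
  abort("`outliers` must be an outlier report or a character vector of ids")
}
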