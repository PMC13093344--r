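#' Per-stand diversity summaries from pooled counts
#'
#' For each stand: the number of invariant sites (within-stand read frequency
#' exactly 0 or 1), the proportion of polymorphic-in-stand SNPs whose minor
#' allele frequency is below `rare_threshold`, and mean expected
#' heterozygosity `2 p (1 - p)`, by default with the small-sample correction
#' `n_h / (n_h - 1)` for the haploid pool size. Run on counts that have not
#' been MAF-filtered if invariant-site counts are of interest.
#'
#' @param pc A [pool_counts] object.
#' @param rare_threshold Minor-allele frequency below which a polymorphic SNP
#'   counts as rare.
#' @param corrected Apply the `n_h / (n_h - 1)` bias correction to
#'   heterozygosity (default) or report raw `2 p (1 - p)`.
#'
#' @return A tibble with one row per stand: `stand_id`, `n_invariant`,
#'   `prop_rare`, `heterozygosity`.
#' @export
diversity_stats <- function(pc, rare_threshold = 0.05, corrected = TRUE) {
  depth <- total_depth(pc)
  rows <- lapply(pc$stand_ids, function(s) {
    d <- depth[, s]
    ok <- d > 0
    p <- pc$alt_depth[ok, s] / d[ok]
    invariant <- p == 0 | p == 1
    maf <- pmin(p, 1 - p)
    nh <- pc$haploid_size[[s]]
    het <- 2 * p * (1 - p) * if (corrected) nh / (nh - 1) else 1
    tibble(
      stand_id = s,
      n_invariant = sum(invariant),
      prop_rare = if (any(!invariant)) mean(maf[!invariant] < rare_threshold)
                  else NA_real_,
      heterozygosity = mean(het)
    )
  })
  dplyr::bind_rows(rows)
}
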