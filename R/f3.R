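# Outgroup f3 statistics from pooled read counts.

#' Outgroup f3 shared-drift statistic for one stand trio
#'
#' Estimates `f3(outgroup; source1, source2) = E[(p_out - p_1)(p_out - p_2)]`
#' over loci, the shared genetic drift of the two source stands relative to
#' the outgroup: larger values mean the sources are more similar to each
#' other relative to the outgroup. Because the outgroup frequency appears in
#' both factors, its squared sampling noise inflates the product; the
#' estimator subtracts an unbiased estimate of that noise,
#' `phat_o (1 - phat_o) (n_o + c_o - 1) / ((c_o - 1)(n_o - 1))`,
#' which accounts for both the finite haploid pool size `n_o` and the read
#' depth `c_o`. Standard errors come from a delete-one block jackknife over
#' contiguous SNP blocks.
#'
#' @param pc A [pool_counts] object.
#' @param source1,source2,outgroup Stand ids (three distinct stands).
#' @param block_size Number of contiguous SNPs per jackknife block.
#'
#' @return A one-row tibble: `outgroup`, `source1`, `source2`, `f3`,
#'   `jackknife_se`, `z`, `n_loci`, `n_blocks`.
#' @export
outgroup_f3 <- function(pc, source1, source2, outgroup, block_size = 500) {
  if (outgroup %in% c(source1, source2)) {
    abort("the outgroup must be distinct from both sources")
  }
  depth <- total_depth(pc)
  c1 <- depth[, source1]; c2 <- depth[, source2]; co <- depth[, outgroup]
  usable <- c1 >= 1 & c2 >= 1 & co >= 2
  if (sum(usable) < 2) abort("fewer than two usable loci")
  p1 <- (pc$alt_depth[, source1] / c1)[usable]
  p2 <- (pc$alt_depth[, source2] / c2)[usable]
  po <- (pc$alt_depth[, outgroup] / co)[usable]
  co <- co[usable]
  no <- pc$haploid_size[[outgroup]]
  h_o <- po * (1 - po) * (no + co - 1) / ((co - 1) * (no - 1))
  f3_l <- (po - p1) * (po - p2) - h_o

  n <- length(f3_l)
  block <- ceiling(seq_len(n) / block_size)
  n_blocks <- max(block)
  if (n_blocks < 2) abort("fewer than 2 jackknife blocks; reduce block_size")
  tot <- sum(f3_l)
  block_sum <- tapply(f3_l, block, sum)
  block_n <- tabulate(block)
  theta_jack <- (tot - block_sum) / (n - block_n)   # delete-one-block means
  f3 <- tot / n
  se <- sqrt((n_blocks - 1) / n_blocks *
               sum((theta_jack - mean(theta_jack))^2))
  tibble(outgroup = outgroup, source1 = source1, source2 = source2,
         f3 = f3, jackknife_se = se, z = f3 / se,
         n_loci = n, n_blocks = n_blocks)
}

#' Outgroup f3 scan over localities, cycling the outgroup role
#'
#' For every locality holding one old and two planted stands, computes the
#' three outgroup f3 statistics obtained by cycling which stand plays the
#' outgroup: with the old stand as outgroup the two planted stands are the
#' sources (comparison class `"P vs. P"`); with either planted stand as
#' outgroup the sources are the old stand and the other planted stand
#' (`"O vs. P"`).
#'
#' @param pc A [pool_counts] object.
#' @param stands Stand table with `stand_id`, `stand_type`, `locality`.
#' @param block_size Jackknife block size, see [outgroup_f3()].
#'
#' @return A tibble of f3 results with `locality` and `class` columns; three
#'   rows per complete locality. Localities without one old and two planted
#'   stands are skipped with a warning.
#' @export
f3_locality_scan <- function(pc, stands, block_size = 500) {
  stands <- stands[stands$stand_id %in% pc$stand_ids, ]
  out <- list()
  for (loc in sort(unique(stands$locality))) {
    s <- stands[stands$locality == loc, ]
    old <- s$stand_id[s$stand_type == "old"]
    pl <- s$stand_id[s$stand_type == "planted"]
    if (length(old) != 1 || length(pl) != 2) {
      warn(sprintf("locality %s lacks the 1 old + 2 planted structure; skipped",
                   loc))
      next
    }
    trio <- dplyr::bind_rows(
      dplyr::mutate(outgroup_f3(pc, pl[1], pl[2], old, block_size),
                    class = "P vs. P"),
      dplyr::mutate(outgroup_f3(pc, old, pl[2], pl[1], block_size),
                    class = "O vs. P"),
      dplyr::mutate(outgroup_f3(pc, old, pl[1], pl[2], block_size),
                    class = "O vs. P")
    )
    trio$locality <- loc
    out[[length(out) + 1]] <- trio
  }
  dplyr::relocate(dplyr::bind_rows(out), "locality")
}
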