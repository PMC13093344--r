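test_that("VCF round-trip reproduces pooled counts exactly", {
  f <- bn_freqs(40, 0.1, n_pools = 3)
  pc <- pc_from_freq(f, depth = 80, seed = 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_pool_vcf(pc, path)
  back <- read_pool_vcf(path)
  expect_identical(back$ref_depth, pc$ref_depth)
  expect_identical(back$alt_depth, pc$alt_depth)
  expect_identical(back$haploid_size, pc$haploid_size)
  expect_identical(back$snp$ref, pc$snp$ref)
})

test_that("non-biallelic records are dropped with a count; missing AD errors", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##poolscape_haploid_size=p1:60,p2:60",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "p1", "p2"), collapse = "\t"),
    "chr1\t10\tsnp1\tA\tC\t.\tPASS\t.\tAD\t10,5\t8,2",
    "chr1\t20\tsnp2\tA\tC,G\t.\tPASS\t.\tAD\t10,5,1\t8,2,0",  # multiallelic
    "chr1\t30\tsnp3\tAT\tA\t.\tPASS\t.\tAD\t10,5\t8,2",       # indel
    "chr1\t40\tsnp4\tG\tT\t.\tPASS\t.\tAD\t3,3\t4,4")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  pc <- read_pool_vcf(path)
  expect_equal(nrow(pc$snp), 2)
  expect_equal(attr(pc, "n_dropped"), 2)
  expect_equal(unname(pc$alt_depth[, "p2"]), c(2, 4))

  bad <- sub("AD\t10,5\t8,2", "DP\t15\t10", lines[c(1:5)])
  writeLines(bad, path)
  expect_error(suppressWarnings(read_pool_vcf(path)), "AD")
})

test_that("sync lines parse with ref from the stated base, alt by majority", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("chr1\t5\tA\t10:0:2:0:0:0\t8:0:4:0:0:0",
               "chr1\t9\tC\t0:3:7:0:0:0\t0:5:9:0:0:0"), path)
  pc <- read_sync(path, haploid_sizes = c(p1 = 60, p2 = 60))
  expect_equal(pc$snp$ref, c("A", "C"))
  expect_equal(pc$snp$alt, c("C", "T"))
  expect_equal(unname(pc$ref_depth[1, ]), c(10, 8))
  expect_equal(unname(pc$alt_depth[1, ]), c(2, 4))
  # all-zero pool retained at depth 0
  writeLines("chr1\t5\tA\t10:0:2:0:0:0\t0:0:0:0:0:0", path)
  pc0 <- read_sync(path, haploid_sizes = 60)
  expect_equal(unname(pc0$ref_depth[1, 2] + pc0$alt_depth[1, 2]), 0)
  # malformed count string names the line
  writeLines(c("chr1\t5\tA\t10:0:2:0:0:0\t8:0:4:0:0:0",
               "chr1\t6\tA\t10:0:2:0\t8:0:4:0:0:0"), path)
  expect_error(read_sync(path, 60), "line 2")
})

test_that("sync writer and reader are inverse on a 100-SNP fixture", {
  f <- bn_freqs(100, 0.08, n_pools = 4)
  pc <- pc_from_freq(f, depth = 120, seed = 5)
  path <- withr::local_tempfile(fileext = ".sync")
  write_sync(pc, path)
  back <- read_sync(path, haploid_sizes = pc$haploid_size)
  expect_equal(unname(back$ref_depth), unname(pc$ref_depth))
  expect_equal(unname(back$alt_depth), unname(pc$alt_depth))
  expect_identical(back$snp$ref, pc$snp$ref)
  expect_identical(back$snp$alt, pc$snp$alt)
})

test_that("filters implement the three rules in order and match a brute force", {
  set.seed(11)
  f <- bn_freqs(1000, 0.1, n_pools = 5)
  pc <- simulate_pool_reads(f, haploids_per_pool = 60, mean_depth = 120,
                            depth_dispersion = 3, error_rate = 0, seed = 6)
  out <- filter_snps(pc, min_cov = 60, cov_quantile_lo = 0.01,
                     cov_quantile_hi = 0.99, maf_min = 0.008)
  # independent brute-force re-application
  depth <- pc$ref_depth + pc$alt_depth
  keep_a <- apply(depth >= 60, 1, all)
  d2 <- depth[keep_a, ]
  lo <- apply(d2, 2, quantile, 0.01); hi <- apply(d2, 2, quantile, 0.99)
  keep_b <- sapply(seq_len(nrow(d2)), function(i)
    all(d2[i, ] >= lo & d2[i, ] <= hi))
  alt <- pc$alt_depth[keep_a, ][keep_b, ]
  tot <- d2[keep_b, ]
  p <- rowSums(alt) / rowSums(tot)
  keep_c <- pmin(p, 1 - p) >= 0.008
  expect_equal(nrow(out$snp), sum(keep_c))
  expect_identical(out$snp$snp_id,
                   pc$snp$snp_id[keep_a][keep_b][keep_c])

  # a SNP with one pool at depth 59 is removed by rule (a)
  pc2 <- pc
  pc2$ref_depth[1, 1] <- 59L
  pc2$alt_depth[1, 1] <- 0L
  out2 <- filter_snps(pc2, min_cov = 60, cov_quantile_lo = 0,
                      cov_quantile_hi = 1, maf_min = 0)
  expect_false(pc$snp$snp_id[1] %in% out2$snp$snp_id)

  # pooled alt fraction 0.004 is removed by the MAF rule
  pc3 <- pool_counts(tibble::tibble(snp_id = "s1", chrom = "c", pos = 1L,
                                    ref = "A", alt = "C"),
                     matrix(996, 1, 2), matrix(4, 1, 2), 60, c("p1", "p2"))
  out3 <- suppressWarnings(filter_snps(pc3, min_cov = 0, cov_quantile_lo = 0,
                                       cov_quantile_hi = 1))
  expect_equal(nrow(out3$snp), 0)
})

test_that("filtering is idempotent at a fixed depth band", {
  f <- bn_freqs(500, 0.05, n_pools = 4)
  pc <- simulate_pool_reads(f, mean_depth = 150, depth_dispersion = 4,
                            seed = 8)
  once <- filter_snps(pc)
  # exactly idempotent when the realised depth band is reapplied
  twice <- filter_snps(once, cov_bounds = attr(once, "cov_bounds"))
  expect_identical(twice$snp$snp_id, once$snp$snp_id)
  expect_identical(twice$alt_depth, once$alt_depth)
  # recomputing quantiles on the trimmed distribution shaves at most a
  # sliver (the 0.1%/99.9% band of an already-trimmed sample)
  naive <- filter_snps(once)
  expect_gte(nrow(naive$snp), 0.98 * nrow(once$snp))
})

test_that("frequency estimation is the read proportion, flip-symmetric", {
  pc <- pool_counts(tibble::tibble(snp_id = c("s1", "s2"), chrom = "c",
                                   pos = 1:2, ref = "A", alt = "C"),
                    ref_depth = matrix(c(30, 10), 2, 1),
                    alt_depth = matrix(c(30, 0), 2, 1),
                    haploid_size = 60, stand_ids = "p1")
  fr <- estimate_frequencies(pc)
  expect_equal(unname(fr["p1", ]), c(0.5, 0))
  # swapping ref/alt labels maps p to 1 - p
  pc_sw <- pool_counts(pc$snp, pc$alt_depth, pc$ref_depth, 60, "p1")
  expect_equal(unname(estimate_frequencies(pc_sw)), unname(1 - fr))
  # zero depth is an error
  pc0 <- pool_counts(pc$snp[1, ], matrix(0, 1, 1), matrix(0, 1, 1), 60, "p1")
  expect_error(estimate_frequencies(pc0), "depth")
})

test_that("estimated frequencies track simulated truth within binomial error", {
  st <- make_stands(4, seed = 2)
  cc <- simulate_climate(st, seed = 2)
  sim <- simulate_frequencies(st, cc, n_neutral = 2000, n_adaptive = 0,
                              n_factors = 0, seed = 3)
  pc <- simulate_pool_reads(sim$freq, mean_depth = 1850, seed = 4)
  fl <- filter_snps(pc)
  fr <- estimate_frequencies(fl)
  truth <- sim$freq[, colnames(fr)]
  expect_lt(mean(abs(fr - truth)), 2 / sqrt(1850))
})
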