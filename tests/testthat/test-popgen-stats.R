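test_that("pairwise FST behaves at its limits", {
  # identical frequencies, very high depth -> FST ~ 0
  f <- bn_freqs(3000, 0.2, n_pools = 1)
  f2 <- rbind(f, f)
  rownames(f2) <- c("a", "b")
  pc <- pc_from_freq(f2, depth = 2000, seed = 2)
  expect_lt(abs(pairwise_fst(pc)[1, 2]), 0.005)

  # opposite fixation, deep reads -> FST -> 1
  fx <- matrix(rep(c(0, 1), 300), nrow = 2,
               dimnames = list(c("a", "b"), sprintf("s%d", 1:300)))
  pcx <- pc_from_freq(fx, depth = 5000, seed = 3)
  expect_gt(pairwise_fst(pcx)[1, 2], 0.99)
})

test_that("multilocus FST is a ratio of sums and order-invariant", {
  f <- bn_freqs(200, 0.1, n_pools = 3)
  pc <- pc_from_freq(f, depth = 150, seed = 4)
  m <- pairwise_fst(pc)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
  # single locus: multilocus estimate equals the single-locus estimate
  pc1 <- poolscape:::subset_pool_counts(pc, snps = 5)
  comp <- poolscape:::fst_pair_components(
    pc1$alt_depth[, 1], pc1$ref_depth[, 1] + pc1$alt_depth[, 1],
    pc1$alt_depth[, 2], pc1$ref_depth[, 2] + pc1$alt_depth[, 2], 60, 60)
  expect_equal(pairwise_fst(pc1)[1, 2], comp$num / comp$den)
  # SNP order and stand order invariance
  perm <- sample(nrow(pc$snp))
  pc_s <- poolscape:::subset_pool_counts(pc, snps = perm)
  expect_equal(pairwise_fst(pc_s), m)
  pc_p <- poolscape:::subset_pool_counts(pc, stands = c("pool3", "pool1",
                                                        "pool2"))
  m2 <- pairwise_fst(pc_p)
  expect_equal(m2[rownames(m), colnames(m)], m, ignore_attr = TRUE)
})

test_that("outgroup f3 is symmetric, non-negative when degenerate, and scans", {
  set.seed(5)
  f <- bn_freqs(2000, 0.05, n_pools = 4)
  pc <- pc_from_freq(f, depth = 300, seed = 6)
  a <- outgroup_f3(pc, "pool1", "pool2", "pool3", block_size = 200)
  b <- outgroup_f3(pc, "pool2", "pool1", "pool3", block_size = 200)
  expect_equal(a$f3, b$f3)
  expect_equal(a$z, a$f3 / a$jackknife_se)
  # degenerate trio: f3(O; S, S) is the squared drift distance, positive
  d <- outgroup_f3(pc, "pool1", "pool1", "pool3", block_size = 200)
  expect_gt(d$f3, 0)
  expect_error(outgroup_f3(pc, "pool1", "pool2", "pool1"), "distinct")
  expect_error(outgroup_f3(pc, "pool1", "pool2", "pool3", block_size = 2000),
               "blocks")
})

test_that("jackknife SE shrinks roughly as 1/sqrt(number of blocks)", {
  set.seed(7)
  f <- bn_freqs(8000, 0.05, n_pools = 3)
  pc <- pc_from_freq(f, depth = 300, seed = 8)
  se_full <- outgroup_f3(pc, "pool1", "pool2", "pool3", block_size = 200)$jackknife_se
  pc_q <- poolscape:::subset_pool_counts(pc, snps = 1:2000)
  se_quarter <- outgroup_f3(pc_q, "pool1", "pool2", "pool3",
                            block_size = 200)$jackknife_se
  expect_gt(se_quarter / se_full, 1.3)   # ideal ratio 2
  expect_lt(se_quarter / se_full, 3)
})

test_that("a shared planted drift branch raises f3 with the old outgroup", {
  set.seed(9)
  wins <- replicate(20, {
    L <- 2000
    pi0 <- runif(L, 0.1, 0.9)
    th <- function(fst) (1 - fst) / fst
    panc <- rbeta(L, pi0 * th(0.05), (1 - pi0) * th(0.05))
    f <- rbind(O = rbeta(L, pi0 * th(0.05), (1 - pi0) * th(0.05)),
               P1 = rbeta(L, panc * th(0.03), (1 - panc) * th(0.03)),
               P2 = rbeta(L, panc * th(0.03), (1 - panc) * th(0.03)))
    colnames(f) <- sprintf("s%d", seq_len(L))
    pc <- simulate_pool_reads(f, mean_depth = 300)
    outgroup_f3(pc, "P1", "P2", "O", 200)$f3 >
      outgroup_f3(pc, "O", "P2", "P1", 200)$f3
  })
  expect_gte(sum(wins), 18)
})

test_that("locality scan cycles the outgroup and labels comparison classes", {
  sim <- simulate_poolseq(seed = 3, n_localities = 4, n_neutral = 400,
                          n_adaptive = 14, mean_depth = 200)
  f3 <- f3_locality_scan(sim$counts, sim$stands, block_size = 100)
  expect_equal(nrow(f3), 12)              # 3 per locality
  old_ids <- sim$stands$stand_id[sim$stands$stand_type == "old"]
  expect_true(all(f3$class[f3$outgroup %in% old_ids] == "P vs. P"))
  expect_true(all(f3$class[!f3$outgroup %in% old_ids] == "O vs. P"))
  # incomplete locality skipped with a warning
  st2 <- sim$stands[-1, ]
  expect_warning(f3_locality_scan(sim$counts, st2, block_size = 100),
                 "skipped")
})

test_that("provenance decoupling makes planted stands mutually more similar", {
  sim <- simulate_poolseq(seed = 5, n_neutral = 8000, n_adaptive = 280,
                          n_factors = 0, mean_depth = 500)
  f3 <- f3_locality_scan(sim$counts, sim$stands, block_size = 400)
  med <- tapply(f3$f3, f3$class, median)
  expect_gt(med[["P vs. P"]], med[["O vs. P"]])
})

test_that("diversity summaries match closed forms and the negative control", {
  # all SNPs fixed in a stand
  pc <- pool_counts(tibble::tibble(snp_id = sprintf("s%d", 1:3), chrom = "c",
                                   pos = 1:3, ref = "A", alt = "C"),
                    ref_depth = matrix(c(50, 50, 0), 3, 1),
                    alt_depth = matrix(c(0, 0, 50), 3, 1),
                    haploid_size = 60, stand_ids = "p1")
  d <- diversity_stats(pc)
  expect_equal(d$n_invariant, 3)
  expect_equal(d$heterozygosity, 0)
  # p = 0.5, n_h = 60 -> per-SNP heterozygosity 0.5 * 60/59
  pc2 <- pool_counts(pc$snp[1, ], matrix(30, 1, 1), matrix(30, 1, 1),
                     60, "p1")
  expect_equal(diversity_stats(pc2)$heterozygosity, 0.5 * 60 / 59)
  expect_equal(diversity_stats(pc2, corrected = FALSE)$heterozygosity, 0.5)

  # negative control: with no decoupling, old and planted diversity agree
  set.seed(31)
  fails <- replicate(5, {
    sim <- simulate_poolseq(seed = sample.int(1e6, 1), n_localities = 15,
                            n_neutral = 3000, n_adaptive = 100,
                            source_decoupling = 0, mean_depth = 300)
    dv <- diversity_stats(sim$counts)
    type <- sim$stands$stand_type[match(dv$stand_id, sim$stands$stand_id)]
    p <- sapply(c("n_invariant", "prop_rare", "heterozygosity"), function(v)
      suppressWarnings(wilcox.test(dv[[v]][type == "old"],
                                   dv[[v]][type == "planted"])$p.value))
    any(p < 0.05)
  })
  expect_lte(sum(fails), 2)
})

test_that("haversine distance matches closed forms and an independent formula", {
  expect_equal(haversine_km(63, 14, 63, 14), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  # spherical law of cosines oracle
  slc <- function(lat1, lon1, lat2, lon2) {
    r <- 6371.0088
    p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
    dl <- (lon2 - lon1) * pi / 180
    r * acos(sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))
  }
  expect_equal(haversine_km(63, 14, 64, 20), slc(63, 14, 64, 20),
               tolerance = 0.1 / 300)
  skip_if_not_installed("geosphere")
  expect_equal(haversine_km(63, 14, 64, 20),
               geosphere::distHaversine(c(14, 63), c(20, 64),
                                        r = 6371008.8) / 1000,
               tolerance = 1e-8)
})
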