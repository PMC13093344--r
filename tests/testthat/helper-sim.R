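# Shared fixtures, built in code.

# Tiny pool_counts from an explicit frequency matrix, deep reads, no error.
pc_from_freq <- function(freq, depth = 1000, haploids = 60, seed = 1) {
  simulate_pool_reads(freq, haploids_per_pool = haploids, mean_depth = depth,
                      depth_dispersion = 50, error_rate = 0, seed = seed)
}

# Balding-Nichols two-pool frequency matrix.
bn_freqs <- function(n_loci, fst, n_pools = 2, pi = NULL) {
  pi <- pi %||% stats::runif(n_loci, 0.05, 0.95)
  theta <- (1 - fst) / fst
  f <- matrix(stats::rbeta(n_pools * n_loci, rep(pi, each = n_pools) * theta,
                           rep(1 - pi, each = n_pools) * theta),
              nrow = n_pools)
  dimnames(f) <- list(paste0("pool", seq_len(n_pools)),
                      sprintf("s%05d", seq_len(n_loci)))
  f
}

`%||%` <- rlang::`%||%`

# Random symmetric "distance" matrix with zero diagonal.
random_dist <- function(n, seed = NULL) {
  g <- function() {
    m <- matrix(stats::runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
    m
  }
  if (is.null(seed)) g() else withr::with_seed(seed, g())
}

# The default synthetic landscape at study scale, built once and shared by
# the acceptance tests (simulation, filtering, frequencies, associations).
.acc_cache <- new.env(parent = emptyenv())

default_landscape_run <- function() {
  if (!is.null(.acc_cache$run)) return(.acc_cache$run)
  sim <- simulate_poolseq(seed = 20260920)
  pc <- filter_snps(sim$counts)
  freq <- estimate_frequencies(pc)
  st <- sim$stands
  sets <- list(old = st$stand_id[st$stand_type == "old"],
               planted = st$stand_id[st$stand_type == "planted"])
  cc <- sim$climate_current
  thr <- corr_null_threshold(length(sets$old), cc, n_draws = 1e6, seed = 1)
  assoc <- dplyr::bind_rows(lapply(names(sets), function(s) {
    fs <- freq[sets[[s]], , drop = FALSE]
    clim <- cc[match(sets[[s]], cc$stand_id), ]
    dplyr::bind_rows(
      corr_outliers(fs, clim, threshold = thr, stand_set = s),
      lfmm_associations(fs, clim, stand_set = s))
  }))
  attr(assoc, "variables") <- c("AIT", "CMT", "CONT", "DegD0", "DegD5",
                                "MTC", "PCQ")
  .acc_cache$run <- list(sim = sim, pc = pc, freq = freq, sets = sets,
                         threshold = thr, assoc = assoc)
  .acc_cache$run
}
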