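test_that("correlation null threshold matches the Student-t closed form", {
  st <- make_stands(15, seed = 1)
  cc <- simulate_climate(st, seed = 2)
  t999 <- qt(0.999, 13)
  closed <- t999 / sqrt(t999^2 + 13)
  thr <- corr_null_threshold(15, cc, n_draws = 1e5, seed = 3)
  expect_lt(abs(thr - closed), 0.01)
  # the median of the symmetric null is ~ 0
  med <- corr_null_threshold(15, cc, n_draws = 5e4, quantile = 0.5, seed = 4)
  expect_lt(abs(med), 0.01)
  # constant climate variable excluded with a warning
  cc2 <- cc
  cc2$AIT <- 1
  expect_warning(corr_null_threshold(15, cc2, n_draws = 1e4, seed = 5),
                 "constant")
  expect_error(corr_null_threshold(3, cc), "n_stands")
})

test_that("the far-tail null is shape-sensitive: uniform draws vs smooth partners", {
  # against smooth ramp-like climate vectors at n = 15, Uniform draws put the
  # 0.999 quantile visibly above the Gaussian closed form; this documents why
  # Gaussian is the default.
  st <- make_stands(15, seed = 1)
  cc <- simulate_climate(st, seed = 2)
  thr_u <- corr_null_threshold(15, cc, n_draws = 2e5, seed = 6,
                               distribution = "uniform")
  thr_g <- corr_null_threshold(15, cc, n_draws = 2e5, seed = 6)
  expect_gt(thr_u, thr_g)
  expect_lt(abs(thr_g - 0.7301), 0.006)
})

test_that("correlation outliers pass on exact clines and never on constants", {
  st <- make_stands(5, seed = 1)
  cc <- simulate_climate(st, seed = 2)
  freqs <- cbind(lin = 0.2 + 0.001 * (cc$AIT - min(cc$AIT)),
                 const = rep(0.4, nrow(cc)),
                 noise = c(0.2, 0.8, 0.4, 0.6, 0.1, 0.5, 0.3, 0.7, 0.45,
                           0.55, 0.25, 0.75, 0.35, 0.65, 0.5))
  rownames(freqs) <- cc$stand_id
  rep <- corr_outliers(freqs, cc, threshold = 0.9)
  lin <- rep[rep$snp_id == "lin" & rep$variable == "AIT", ]
  expect_equal(lin$statistic, 1)
  expect_true(lin$passes)
  cons <- rep[rep$snp_id == "const", ]
  expect_true(all(!cons$passes))
  expect_true(all(is.na(cons$statistic)))
  # Pearson r is invariant to affine transforms of the climate variable
  cc2 <- cc
  cc2$AIT <- 3 * cc$AIT + 100
  rep2 <- corr_outliers(freqs, cc2, threshold = 0.9)
  expect_equal(rep2$statistic[rep2$variable == "AIT"],
               rep$statistic[rep$variable == "AIT"])
})

test_that("PCA structure summary has ordered eigenvalues and finds clusters", {
  set.seed(8)
  f <- matrix(runif(8 * 50), 8, 50,
              dimnames = list(paste0("s", 1:8), paste0("x", 1:50)))
  f2 <- rbind(f, f[1, , drop = FALSE])
  rownames(f2)[9] <- "dup"
  p <- pca_structure(f2)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(sum(p$prop_variance), 1)
  dup <- unlist(p$scores[p$scores$stand_id == "dup", -1])
  one <- unlist(p$scores[p$scores$stand_id == "s1", -1])
  expect_equal(dup, one, ignore_attr = TRUE)
  # two well-separated clusters: PC1 separates them with silhouette > 0.5
  cl <- matrix(runif(12 * 200), 12, 200)
  cl[1:6, 1:100] <- cl[1:6, 1:100] + 1.5
  rownames(cl) <- paste0("s", 1:12); colnames(cl) <- paste0("x", 1:200)
  pc1 <- pca_structure(cl)$scores$PC1
  lab <- rep(1:2, each = 6)
  sil <- sapply(1:12, function(i) {
    a <- mean(abs(pc1[i] - pc1[lab == lab[i]][-which(which(lab == lab[i]) == i)]))
    b <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)
})

test_that("latent-factor associations calibrate the null and keep ranks", {
  set.seed(10)
  n <- 15
  f <- matrix(runif(n * 10000), n, 10000,
              dimnames = list(paste0("s", 1:n), sprintf("x%d", 1:10000)))
  st <- make_stands(5, seed = 1)
  cc <- simulate_climate(st, seed = 2)
  cc <- cc[1:n, ]
  cc$stand_id <- rownames(f)
  rep <- lfmm_associations(f, cc, k_latent = 4)
  expect_equal(unique(rep$threshold), 0.05 / 10000)
  # frequencies orthogonal to climate: the report holds 7 x 10,000 tests at
  # the 5e-6 threshold, so ~0.35 chance passes are expected; a handful is
  # still a calibrated null
  expect_lte(sum(rep$passes), 3)
  # GIF recalibration leaves p-value ranks unchanged within a variable
  one <- rep[rep$variable == "AIT", ]
  expect_equal(order(one$p), order(-abs(one$statistic)))
  expect_error(lfmm_associations(f[1:5, ], cc[1:5, ], k_latent = 4), "k_latent")
})

test_that("the Bonferroni threshold reproduces the printed study value", {
  # 0.05 / 47,552 as produced by the code path
  n <- 12
  f <- matrix(runif(n * 300), n, 300,
              dimnames = list(paste0("s", 1:n), sprintf("x%d", 1:300)))
  st <- make_stands(4, seed = 1)
  cc <- simulate_climate(st, seed = 2)
  cc$stand_id <- rownames(f)
  rep <- lfmm_associations(f, cc, k_latent = 2, alpha = 0.05)
  expect_equal(unique(rep$threshold), 0.05 / 300)
  expect_equal(signif(0.05 / 47552, 3), 1.05e-06)
})

test_that("latent factors control structure confounding better than raw correlation", {
  # climate collinear with a structure gradient loaded on many neutral SNPs:
  # the correlation scan fires, the factor-corrected scan mostly does not.
  set.seed(12)
  n <- 20
  grad <- seq(-1, 1, length.out = n)
  n_snps <- 2000
  load <- rnorm(n_snps, 0, 0.35)
  f <- plogis(outer(grad, load) +
                matrix(qlogis(runif(n_snps, 0.2, 0.8)), n, n_snps,
                       byrow = TRUE) + matrix(rnorm(n * n_snps, 0, 0.2), n))
  dimnames(f) <- list(paste0("s", 1:n), sprintf("x%d", 1:n_snps))
  clim <- tibble::tibble(stand_id = rownames(f),
                         AIT = 10 + 5 * grad + rnorm(n, 0, 0.3),
                         CMT = 1 + grad, CONT = 20 - 2 * grad,
                         DegD0 = 100 + 10 * grad, DegD5 = 80 + 8 * grad,
                         MTC = -40 - 4 * grad, PCQ = 8 - grad)
  thr <- qt(0.999, n - 2) / sqrt(qt(0.999, n - 2)^2 + n - 2)
  n_corr <- sum(corr_outliers(f, clim, thr)$passes)
  # the deliberate structure-climate collinearity triggers the flag warning
  n_lfmm <- sum(suppressWarnings(
    lfmm_associations(f, clim, k_latent = 4))$passes)
  expect_gt(n_corr, 20)
  expect_lt(n_lfmm, n_corr / 4)
})

test_that("association counting is consistent and completes zeros", {
  st <- make_stands(5, seed = 1)
  cc <- simulate_climate(st, seed = 2)
  f <- matrix(runif(15 * 20), 15, 20,
              dimnames = list(cc$stand_id, sprintf("x%d", 1:20)))
  rep <- corr_outliers(f, cc, threshold = 0.99)
  counts <- count_associations(rep)
  expect_equal(sum(counts$n), sum(rep$passes))
  empty <- rep[0, ]
  attr(empty, "variables") <- c("AIT", "CMT")
  ce <- count_associations(empty)
  expect_true(all(ce$n == 0))
})
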