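# Gene-environment association: Monte-Carlo correlation null and
# latent-factor-corrected regression.

#' Monte-Carlo null threshold for allele-frequency--climate correlations
#'
#' Draws `n_draws` random allele-frequency vectors of length `n_stands`,
#' pairs each with a climate variable selected uniformly at random, computes
#' the Pearson correlation, and returns the requested quantile of the
#' resulting null distribution. For 15 stands and the 0.999 quantile the
#' Gaussian-draw threshold is r = 0.730, matching the exact closed form
#' `t / sqrt(t^2 + df)` with `t = qt(0.999, 13)`.
#'
#' The null is *not* distribution-free in the far tail at small n: the
#' closed form is exact for spherically symmetric draws, and the quantile
#' for other iid laws depends on the shape of the fixed partner vector
#' (Uniform draws against smooth, ramp-like climate vectors sit near
#' r = 0.74 for n = 15). Gaussian draws are therefore the default, matching
#' the standard printed threshold; `distribution = "uniform"` is available.
#'
#' @param n_stands Length of the frequency vectors (>= 4).
#' @param climate Climate table (the variables only supply fixed partners for
#'   the draws; constant variables are excluded with a warning).
#' @param n_draws Number of Monte-Carlo draws (>= 10,000).
#' @param quantile Quantile of the signed correlation null to return.
#' @param seed Optional integer seed.
#' @param mode `"signed"` (quantile of r, the default) or `"absolute"`
#'   (quantile of |r|).
#' @param distribution Law of the iid null frequency vectors.
#'
#' @return The threshold, a single numeric value.
#' @export
corr_null_threshold <- function(n_stands, climate, n_draws = 1e6,
                                quantile = 0.999, seed = NULL,
                                mode = c("signed", "absolute"),
                                distribution = c("gaussian", "uniform")) {
  mode <- match.arg(mode)
  distribution <- match.arg(distribution)
  rdraw <- switch(distribution, gaussian = stats::rnorm, uniform = stats::runif)
  if (n_stands < 4) abort("`n_stands` must be >= 4")
  if (n_draws < 1e4) abort("`n_draws` must be >= 10,000")
  cm <- if (is.matrix(climate)) climate else
    as.matrix(climate[, setdiff(names(climate), "stand_id"), drop = FALSE])
  sds <- apply(cm, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste("excluding constant climate variable(s):",
               paste(colnames(cm)[sds == 0], collapse = ", ")))
    cm <- cm[, sds > 0, drop = FALSE]
  }
  if (nrow(cm) != n_stands) {
    # Null partners need only be fixed non-constant vectors of the right
    # length; resample positions if the table has a different stand count.
    cm <- apply(cm, 2, function(x) rep_len(x, n_stands))
  }
  z <- scale(cm)
  z <- sweep(z, 2, sqrt(colSums(z^2)), "/")       # centred, unit norm
  n_vars <- ncol(z)

  with_seed_maybe(seed, {
    pick <- sample.int(n_vars, n_draws, replace = TRUE)
    r <- numeric(n_draws)
    batch <- 50000L
    done <- 0L
    while (done < n_draws) {
      take <- min(batch, n_draws - done)
      idx <- seq(done + 1L, done + take)
      x <- matrix(rdraw(n_stands * take), n_stands, take)
      x <- sweep(x, 2, colMeans(x))
      xn <- sqrt(colSums(x^2))
      num <- colSums(x * z[, pick[idx], drop = FALSE])
      r[idx] <- num / xn
      done <- done + take
    }
    if (mode == "absolute") r <- abs(r)
    unname(stats::quantile(r, probs = quantile))
  })
}

#' Correlation-based outlier scan of SNPs against climate variables
#'
#' Pearson correlation between per-stand allele frequencies and each climate
#' variable, for every SNP x variable pair. A pair passes when the signed
#' correlation strictly exceeds `threshold` (use `mode = "absolute"` for
#' two-tailed exceedance). SNPs with zero variance across stands are recorded
#' as non-significant with an `NA` statistic.
#'
#' @param freqs Stands x SNPs frequency matrix.
#' @param climate Climate table matching the rows of `freqs`.
#' @param threshold Correlation threshold, e.g. from [corr_null_threshold()].
#' @param stand_set Optional label (`"old"` / `"planted"`) recorded in the
#'   report.
#' @param mode Signed (`r > threshold`) or absolute (`|r| > threshold`)
#'   exceedance.
#'
#' @return An outlier report: a tibble with `snp_id`, `variable`, `statistic`
#'   (r), `passes`, plus `method`, `stand_set` and `threshold` columns.
#' @export
corr_outliers <- function(freqs, climate, threshold,
                          stand_set = NA_character_,
                          mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  cm <- climate_matrix(climate)
  if (!is.null(rownames(cm)) && !is.null(rownames(freqs))) {
    if (!setequal(rownames(cm), rownames(freqs))) {
      abort("stands of `freqs` do not match the climate table")
    }
    cm <- cm[rownames(freqs), , drop = FALSE]
  }
  r <- suppressWarnings(stats::cor(freqs, cm))     # SNPs x variables
  stat <- if (mode == "absolute") abs(r) else r
  passes <- !is.na(stat) & stat > threshold
  out <- tibble(
    snp_id = rep(rownames(r), times = ncol(r)),
    variable = rep(colnames(r), each = nrow(r)),
    statistic = as.vector(r),
    passes = as.vector(passes),
    method = "correlation",
    stand_set = stand_set,
    threshold = threshold
  )
  attr(out, "variables") <- colnames(r)
  out
}

#' Principal-component summary of population structure
#'
#' PCA of the column-centred stands x SNPs frequency matrix; the scores are
#' the standard population-structure summary and supply the latent factors
#' of [lfmm_associations()].
#'
#' @param freqs Stands x SNPs frequency matrix (>= 3 stands).
#'
#' @return A list with `scores` (tibble: `stand_id` plus PC columns),
#'   `variance_explained` (eigenvalues; sums to the total column variance)
#'   and `prop_variance`.
#' @export
pca_structure <- function(freqs) {
  if (nrow(freqs) < 3) abort("need at least 3 stands")
  p <- stats::prcomp(freqs, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2
  scores <- tibble::as_tibble(p$x)
  scores <- dplyr::bind_cols(
    tibble(stand_id = rownames(freqs) %||% as.character(seq_len(nrow(freqs)))),
    scores)
  list(scores = scores, variance_explained = ve,
       prop_variance = ve / sum(ve))
}

#' Latent-factor-corrected gene-environment association
#'
#' Per climate variable, fits the per-SNP linear model
#' `frequency ~ variable + K latent factors`, the latent factors being the
#' first `k_latent` principal components of the frequency matrix. The
#' variable's t statistic is converted to a z-score, z-scores are
#' recalibrated by the genomic inflation factor (median of `z^2` divided by
#' the chi-square(1) median), and a SNP passes when the recalibrated p-value
#' is below the Bonferroni threshold `alpha / n_snps`.
#'
#' @param freqs Stands x SNPs frequency matrix.
#' @param climate Climate table matching the rows of `freqs`.
#' @param k_latent Number of latent factors (must satisfy
#'   `k_latent < n_stands - 2`).
#' @param alpha Familywise error rate for the Bonferroni threshold.
#' @param stand_set Optional label recorded in the report.
#'
#' @return An outlier report tibble with `snp_id`, `variable`, `statistic`
#'   (calibrated z), `p` (calibrated), `gif`, `passes`, `method`,
#'   `stand_set`, `threshold`. Variables nearly collinear with the latent
#'   factors are flagged with a warning.
#' @export
lfmm_associations <- function(freqs, climate, k_latent = 4, alpha = 0.05,
                              stand_set = NA_character_) {
  n <- nrow(freqs)
  if (k_latent >= n - 2) abort("`k_latent` must be < n_stands - 2")
  cm <- climate_matrix(climate)
  if (!is.null(rownames(cm)) && !is.null(rownames(freqs))) {
    cm <- cm[rownames(freqs), , drop = FALSE]
  }
  n_snps <- ncol(freqs)
  bonf <- alpha / n_snps
  factors <- stats::prcomp(freqs, center = TRUE)$x[, seq_len(k_latent),
                                                   drop = FALSE]
  out <- vector("list", ncol(cm))
  for (k in seq_len(ncol(cm))) {
    env <- cm[, k]
    # Collinearity of the variable with the factor span.
    r2_env <- summary(stats::lm(env ~ factors))$r.squared
    if (r2_env > 0.98) {
      warn(sprintf("variable %s is nearly collinear with the latent factors",
                   colnames(cm)[k]))
    }
    x <- cbind(1, env, factors)
    qx <- qr(x)
    df <- n - ncol(x)
    coefs <- qr.coef(qx, freqs)
    res <- qr.resid(qx, freqs)
    sigma2 <- colSums(res^2) / df
    xtx_inv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    tval <- coefs[2, ] / se
    p_t <- 2 * stats::pt(-abs(tval), df)
    z2 <- stats::qchisq(p_t, df = 1, lower.tail = FALSE)
    gif <- stats::median(z2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
    p_cal <- stats::pchisq(z2 / gif, df = 1, lower.tail = FALSE)
    out[[k]] <- tibble(
      snp_id = colnames(freqs),
      variable = colnames(cm)[k],
      statistic = sign(tval) * sqrt(z2 / gif),
      p = p_cal,
      gif = gif,
      passes = !is.na(p_cal) & p_cal < bonf,
      method = "lfmm",
      stand_set = stand_set,
      threshold = bonf
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "variables") <- colnames(cm)
  res
}

#' Count significant associations per climate variable
#'
#' @param report An outlier report (rows may mix methods and stand sets).
#'
#' @return A tibble of counts of passing SNPs per `variable` (and per
#'   `method` / `stand_set` where those columns vary), with explicit zeros
#'   for variables present in the report but never passing.
#' @export
count_associations <- function(report) {
  if (nrow(report) == 0) {
    return(tibble(variable = attr(report, "variables") %||% character(0),
                  n = 0L))
  }
  keys <- intersect(c("method", "stand_set", "variable"), names(report))
  report |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n = sum(.data$passes, na.rm = TRUE), .groups = "drop")
}
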