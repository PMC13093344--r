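#' Lay out old-growth and planted stands along a west--east climate axis
#'
#' Generates a synthetic sampling design mimicking a survey of boreal conifer
#' stands: `n_localities` localities spaced along a one-dimensional west--east
#' axis (embedded in latitude/longitude over northern Scandinavia), each
#' holding one old-growth stand and two nearby planted stands.
#'
#' @param n_localities Number of localities (>= 2); each contributes three
#'   stands, so the default design of 15 localities yields 45 stands.
#' @param jitter_deg Standard deviation, in degrees, of the coordinate jitter
#'   of stands around their locality centre.
#' @param seed Optional integer seed; fixing it fixes the whole table.
#'
#' @return A tibble with one row per stand: `stand_id`, `stand_type`
#'   (`"old"` or `"planted"`), `locality` (integer), `latitude`, `longitude`,
#'   and `axis`, the standardised west--east position that drives the climate
#'   model (negative towards the coast, positive towards the mountains).
#' @export
make_stands <- function(n_localities = 15, jitter_deg = 0.02, seed = NULL) {
  if (!is.numeric(n_localities) || length(n_localities) != 1 ||
      n_localities < 2) {
    abort("`n_localities` must be a single integer >= 2")
  }
  n_localities <- as.integer(n_localities)
  with_seed_maybe(seed, {
    u <- seq(0, 1, length.out = n_localities)       # 0 = coast, 1 = mountains
    loc_lon <- 20.8 - 6.8 * u
    loc_lat <- 63.0 + 1.8 * u
    per_loc <- function(i, type, tag) {
      tibble(
        stand_id  = sprintf("L%02d_%s", i, tag),
        stand_type = type,
        locality  = i,
        latitude  = loc_lat[i] + stats::rnorm(1, 0, jitter_deg),
        longitude = loc_lon[i] + stats::rnorm(1, 0, jitter_deg)
      )
    }
    rows <- lapply(seq_len(n_localities), function(i) {
      dplyr::bind_rows(per_loc(i, "old", "O"),
                       per_loc(i, "planted", "P1"),
                       per_loc(i, "planted", "P2"))
    })
    stands <- dplyr::bind_rows(rows)
    # Axis position recovered from longitude so that co-located stands share
    # (almost exactly) the same climate.
    u_stand <- (20.8 - stands$longitude) / 6.8
    stands$axis <- as.numeric(scale(u_stand))
    stands
  })
}

# Baseline level and west-east gradient of each climate variable, loosely
# calibrated to a coast-to-mountain transect of northern Sweden (units as in
# the ENVIREM variables: degree-day variables in 10*degC, MTC in 10*degC).
climate_model <- function() {
  tibble(
    variable  = climate_variables(),
    intercept = c(35, 0.35, 24, 120, 85, -45, 9),
    coef      = c(8, 0.15, 3, -25, -20, -10, -3)
  )
}

#' Default future-scenario climate shift
#'
#' A warming-consistent displacement of each of the seven climate variables,
#' sized at one quarter of the variable's spatial gradient coefficient:
#' across a region spanning a steep coast-to-mountain gradient, an
#' end-of-century mid-range emissions scenario moves local climate by a
#' modest fraction of the spatial spread.
#'
#' @return Named numeric vector of length 7 (one entry per climate variable).
#' @export
climate_shift_default <- function() {
  cm <- climate_model()
  shift <- 0.25 * abs(cm$coef)
  # Warming signs: more degree days, milder coldest month, higher winter PET,
  # slightly less continental, wetter-index down (drier growing season).
  sign <- c(AIT = -1, CMT = -1, CONT = -1, DegD0 = 1, DegD5 = 1,
            MTC = 1, PCQ = 1)
  stats::setNames(shift * sign[cm$variable], cm$variable)
}

#' Simulate a stand-by-variable climate table
#'
#' Each of the seven climate variables is a linear (hence monotone) function
#' of the shared west--east axis plus independent Gaussian noise, so the
#' variables are mutually correlated through the axis, mimicking the strong
#' collinearity of real ENVIREM extractions. A future scenario is obtained by
#' adding `scenario_shift` to each variable after the noise, so a zero shift
#' reproduces the current table exactly under the same seed.
#'
#' @param stands Stand table from [make_stands()].
#' @param scenario_shift Named numeric vector of length 7 added per variable
#'   (`NULL` or zeros for the current scenario); see
#'   [climate_shift_default()].
#' @param noise_sd Noise standard deviation, expressed as a fraction of each
#'   variable's axis gradient coefficient (0.15 keeps the axis--variable
#'   correlation above 0.97).
#' @param seed Optional integer seed.
#'
#' @return A tibble with `stand_id` plus the seven variable columns, and a
#'   `scenario` attribute (`"current"` or `"future"`).
#' @export
simulate_climate <- function(stands, scenario_shift = NULL, noise_sd = 0.15,
                             seed = NULL) {
  if (nrow(stands) == 0) abort("`stands` must be non-empty")
  cm <- climate_model()
  shift <- rep(0, 7)
  names(shift) <- cm$variable
  if (!is.null(scenario_shift)) {
    if (is.null(names(scenario_shift))) {
      stopifnot(length(scenario_shift) == 7)
      names(scenario_shift) <- cm$variable
    }
    shift[names(scenario_shift)] <- scenario_shift
  }
  out <- with_seed_maybe(seed, {
    vals <- lapply(seq_len(nrow(cm)), function(k) {
      base <- cm$intercept[k] + cm$coef[k] * stands$axis
      noise <- stats::rnorm(nrow(stands), 0, noise_sd * abs(cm$coef[k]))
      base + noise + shift[cm$variable[k]]
    })
    names(vals) <- cm$variable
    dplyr::bind_cols(tibble(stand_id = stands$stand_id), tibble::as_tibble(vals))
  })
  attr(out, "scenario") <- if (all(shift == 0)) "current" else "future"
  out
}

#' Simulate stand allele frequencies with known neutral and adaptive structure
#'
#' Neutral SNPs follow a Balding--Nichols model: ancestral frequency
#' `pi ~ Uniform(0.05, 0.95)` and per-stand frequencies Beta-distributed with
#' mean `pi` and variance `pi (1 - pi) fst_background`. Optionally,
#' `n_factors` latent structure factors (random stand loadings, logit-scale
#' SNP loadings on neutral SNPs) add population structure that is not
#' collinear with climate, as a stand-in for the ancestry/batch structure
#' that latent-factor association methods are built to absorb.
#'
#' Adaptive SNPs are each assigned one driver climate variable (round-robin
#' over the seven variables). Old-growth stands sit on a logistic cline in
#' the standardised driver: mean `plogis(qlogis(pi) + slope_logit * z)`.
#' Each planted stand draws a single source position
#' `z_src ~ N(0, source_sd^2)` on the climate axis -- one seed lot per stand,
#' with orchard material climatically close to the range centre -- and its
#' adaptive mean is the convex combination
#' `(1 - d) * cline(z_local) + d * cline(z_src)` with `d = source_decoupling`.
#' With `source_decoupling = 0` planted stands are indistinguishable from old
#' stands (negative control); with `d = 1` their adaptive frequencies are
#' decoupled from the local climate.
#'
#' @param stands Stand table from [make_stands()].
#' @param climate Current-scenario climate table from [simulate_climate()].
#' @param n_neutral,n_adaptive Numbers of neutral and adaptive SNPs
#'   (adaptive default 700 = 100 per variable).
#' @param fst_background Balding--Nichols drift parameter in (0, 1).
#' @param slope_logit Cline steepness on the logit scale per standard
#'   deviation of the driver.
#' @param source_decoupling Fraction `d` in `[0, 1]` by which planted-stand
#'   adaptive frequencies track their source rather than local climate.
#' @param source_sd Standard deviation of planted-source axis positions
#'   (local positions have standard deviation 1).
#' @param n_factors,factor_sd Number and logit-scale loading standard
#'   deviation of latent neutral-structure factors (0 disables them); stand
#'   scores are orthogonalised against the climate axis within each stand
#'   type.
#' @param seed Optional integer seed.
#'
#' @return A list with `freq`, a stands x SNPs matrix of alternate-allele
#'   frequencies, and `truth`, a tibble recording per SNP whether it is
#'   adaptive, its driver variable, cline slope, decoupling, and ancestral
#'   frequency.
#' @export
simulate_frequencies <- function(stands, climate,
                                 n_neutral = 20000, n_adaptive = 700,
                                 fst_background = 0.05, slope_logit = 1.5,
                                 source_decoupling = 0.8, source_sd = 0.5,
                                 n_factors = 4, factor_sd = 0.6,
                                 seed = NULL) {
  if (fst_background <= 0 || fst_background >= 1) {
    abort("`fst_background` must lie strictly between 0 and 1")
  }
  if (source_decoupling < 0 || source_decoupling > 1) {
    abort("`source_decoupling` must lie in [0, 1]")
  }
  n_stands <- nrow(stands)
  n_snps <- n_neutral + n_adaptive
  vars <- climate_variables()
  zmat <- scale(climate_matrix(climate))           # stands x 7, standardised
  planted <- stands$stand_type == "planted"

  with_seed_maybe(seed, {
    pi0 <- stats::runif(n_snps, 0.05, 0.95)
    snp_id <- sprintf("snp%06d", seq_len(n_snps))
    is_adaptive <- c(rep(FALSE, n_neutral), rep(TRUE, n_adaptive))
    driver <- rep(NA_character_, n_snps)
    if (n_adaptive > 0) {
      driver[is_adaptive] <- rep(vars, length.out = n_adaptive)
    }

    alpha <- stats::qlogis(pi0)
    m <- matrix(rep(pi0, each = n_stands), nrow = n_stands)  # stands x SNPs

    # Latent neutral structure: logit-scale factor loadings on neutral SNPs.
    # Stand scores are residualised against the climate axis within each
    # stand type, so this structure is population structure *orthogonal* to
    # the climate gradient (recolonisation routes, provenance blocks) -- the
    # kind a latent-factor correction is meant to absorb without eating the
    # climate signal itself.
    if (n_factors > 0 && n_neutral > 0) {
      u <- matrix(stats::rnorm(n_stands * n_factors), n_stands, n_factors)
      ax_old <- stands$axis * (stands$stand_type == "old")
      ax_pl <- stands$axis * (stands$stand_type == "planted")
      u <- stats::resid(stats::lm(u ~ ax_old + ax_pl))
      u <- scale(u)
      lam <- matrix(stats::rnorm(n_neutral * n_factors, 0, factor_sd),
                    n_neutral, n_factors)
      idx <- which(!is_adaptive)
      m[, idx] <- stats::plogis(
        sweep(u %*% t(lam), 2, alpha[idx], "+")
      )
    }

    # One source position per planted stand, shared across SNPs.
    z_src <- rep(0, n_stands)
    z_src[planted] <- stats::rnorm(sum(planted), 0, source_sd)

    if (n_adaptive > 0) {
      for (v in vars) {
        jv <- which(is_adaptive & driver == v)
        if (length(jv) == 0) next
        zl <- zmat[, v]
        cline_local <- stats::plogis(outer(zl, alpha[jv], function(z, a) {
          a + slope_logit * z
        }))
        cline_src <- stats::plogis(outer(z_src, alpha[jv], function(z, a) {
          a + slope_logit * z
        }))
        mv <- cline_local
        d <- source_decoupling
        mv[planted, ] <- (1 - d) * cline_local[planted, , drop = FALSE] +
          d * cline_src[planted, , drop = FALSE]
        m[, jv] <- mv
      }
    }

    # Balding-Nichols drift noise around the mean surface.
    m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
    theta <- (1 - fst_background) / fst_background
    freq <- matrix(stats::rbeta(length(m), m * theta, (1 - m) * theta),
                   nrow = n_stands,
                   dimnames = list(stands$stand_id, snp_id))

    truth <- tibble(
      snp_id = snp_id,
      is_adaptive = is_adaptive,
      driver_variable = driver,
      slope_logit = ifelse(is_adaptive, slope_logit, 0),
      source_decoupling = ifelse(is_adaptive, source_decoupling, 0),
      ancestral_freq = pi0
    )
    list(freq = freq, truth = truth)
  })
}

#' Simulate pooled sequencing read counts from stand allele frequencies
#'
#' For each SNP and stand: the number of alternate haplotypes in the pool is
#' `k ~ Binomial(haploids_per_pool, freq)`; read depth is negative-binomial
#' with the given mean and dispersion; alternate read counts are
#' `Binomial(depth, p')` where `p' = (k/n)(1 - e) + (1 - k/n) e` applies a
#' symmetric per-read error `e`.
#'
#' @param freqs Stands x SNPs frequency matrix (e.g. from
#'   [simulate_frequencies()]).
#' @param haploids_per_pool Haploid pool size (60 = 30 diploid trees).
#' @param mean_depth Mean read depth per SNP and pool.
#' @param depth_dispersion Negative-binomial `size`; smaller is more
#'   overdispersed.
#' @param error_rate Symmetric per-read error probability.
#' @param seed Optional integer seed.
#'
#' @return A [pool_counts] object.
#' @export
simulate_pool_reads <- function(freqs, haploids_per_pool = 60,
                                mean_depth = 1850, depth_dispersion = 5,
                                error_rate = 0.001, seed = NULL) {
  if (haploids_per_pool < 2) abort("`haploids_per_pool` must be >= 2")
  if (mean_depth <= 0) abort("`mean_depth` must be positive")
  n_stands <- nrow(freqs)
  n_snps <- ncol(freqs)
  with_seed_maybe(seed, {
    k <- matrix(stats::rbinom(length(freqs), haploids_per_pool, freqs),
                nrow = n_stands)
    depth <- matrix(stats::rnbinom(length(freqs), mu = mean_depth,
                                   size = depth_dispersion),
                    nrow = n_stands)
    p_read <- (k / haploids_per_pool) * (1 - error_rate) +
      (1 - k / haploids_per_pool) * error_rate
    alt <- matrix(stats::rbinom(length(freqs), depth, p_read),
                  nrow = n_stands)
    ref <- depth - alt

    bases <- c("A", "C", "G", "T")
    ref_base <- sample(bases, n_snps, replace = TRUE)
    alt_base <- vapply(ref_base, function(b) sample(setdiff(bases, b), 1), "")
    snp <- tibble(
      snp_id = colnames(freqs) %||% sprintf("snp%06d", seq_len(n_snps)),
      chrom = "chr1",
      pos = seq_len(n_snps) * 10L,
      ref = ref_base,
      alt = unname(alt_base)
    )
    pool_counts(
      snp = snp,
      ref_depth = t(ref), alt_depth = t(alt),
      haploid_size = stats::setNames(rep(haploids_per_pool, n_stands),
                                     rownames(freqs)),
      stand_ids = rownames(freqs)
    )
  })
}

#' Simulate a complete pooled-sequencing landscape
#'
#' Convenience wrapper chaining [make_stands()], [simulate_climate()] (current
#' and future scenarios), [simulate_frequencies()] and
#' [simulate_pool_reads()], with per-stage seeds derived deterministically
#' from a single master seed.
#'
#' @param n_localities Number of localities.
#' @param seed Master seed (required, for full reproducibility).
#' @param scenario_shift Future-scenario climate displacement; defaults to
#'   [climate_shift_default()].
#' @param ... Passed on to [simulate_frequencies()].
#' @inheritParams simulate_pool_reads
#'
#' @return A list with `stands`, `climate_current`, `climate_future`, `freq`,
#'   `truth` and `counts`.
#' @export
simulate_poolseq <- function(n_localities = 15, seed = 1,
                             scenario_shift = climate_shift_default(),
                             haploids_per_pool = 60, mean_depth = 1850,
                             depth_dispersion = 5, error_rate = 0.001, ...) {
  stands <- make_stands(n_localities, seed = derive_seed(seed, 1))
  clim_cur <- simulate_climate(stands, seed = derive_seed(seed, 2))
  clim_fut <- simulate_climate(stands, scenario_shift = scenario_shift,
                               seed = derive_seed(seed, 2))
  sim <- simulate_frequencies(stands, clim_cur, seed = derive_seed(seed, 3),
                              ...)
  counts <- simulate_pool_reads(sim$freq, haploids_per_pool = haploids_per_pool,
                                mean_depth = mean_depth,
                                depth_dispersion = depth_dispersion,
                                error_rate = error_rate,
                                seed = derive_seed(seed, 4))
  list(stands = stands, climate_current = clim_cur, climate_future = clim_fut,
       freq = sim$freq, truth = sim$truth, counts = counts)
}
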