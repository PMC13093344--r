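# Risk of non-adaptedness (RONA): expected allele-frequency shifts required
# to track a projected climate, weighted by regression fit.

#' Per-SNP linear regression of allele frequency on a climate variable
#'
#' Ordinary least squares of per-stand frequency on the raw (unstandardised)
#' climate variable, so slopes carry per-unit meaning. SNPs with zero
#' variance get slope 0 and r-squared 0.
#'
#' @param freqs Stands x SNPs frequency matrix (>= 3 stands).
#' @param env Numeric vector, the climate variable at each stand.
#'
#' @return A tibble with `snp_id`, `intercept`, `slope`, `r_squared`.
#' @export
snp_env_regression <- function(freqs, env) {
  if (nrow(freqs) < 3) abort("need at least 3 stands")
  if (stats::sd(env) == 0) abort("`env` must not be constant")
  xc <- env - mean(env)
  sxx <- sum(xc^2)
  ybar <- colMeans(freqs)
  sxy <- colSums(xc * freqs)
  slope <- unname(sxy / sxx)
  intercept <- unname(ybar - slope * mean(env))
  syy <- unname(colSums(sweep(freqs, 2, ybar)^2))
  r2 <- ifelse(syy > 0, (sxy^2 / sxx) / syy, 0)
  r2 <- unname(r2)
  slope[syy == 0] <- 0
  tibble(snp_id = colnames(freqs) %||% as.character(seq_along(slope)),
         intercept = intercept, slope = slope, r_squared = r2)
}

#' Risk of non-adaptedness per stand for one climate variable
#'
#' For each stand, the average allele-frequency change at climate-associated
#' SNPs required to match the projected climate, weighted per SNP by the
#' r-squared of the frequency--environment regression (fitted on the stands
#' of `freqs`, current climate). Two forms of the per-SNP shift are
#' available:
#' \describe{
#'   \item{`"observed"` (default)}{`|(a + b e_future) - p_observed|`, the
#'     distance from the stand's current observed frequency to the fitted
#'     future expectation. This carries any mismatch already present under
#'     the current climate, which is what makes maladapted stands score
#'     high.}
#'   \item{`"predicted"`}{`|b| |e_future - e_current|`, the difference of
#'     fitted values -- a pure climate-displacement term that is zero under a
#'     zero shift and exactly linear in the shift.}
#' }
#'
#' @param freqs Stands x SNPs frequency matrix for the stand set being
#'   scored.
#' @param env_current,env_future The climate variable at those stands under
#'   the two scenarios (same order as the rows of `freqs`).
#' @param assoc_snps Outlier report (or character vector of SNP ids) giving
#'   the associated SNPs; restricted to `variable` when a report is given.
#' @param variable Climate variable name (used to filter the report and
#'   label the output).
#' @param form Per-SNP shift form, see Details.
#' @param method,stand_set Optional labels carried into the output.
#'
#' @return A tibble with one row per stand: `stand_id`, `stand_set`,
#'   `variable`, `method`, `rona`, `n_snps_used`.
#' @export
rona_per_stand <- function(freqs, env_current, env_future, assoc_snps,
                           variable, form = c("observed", "predicted"),
                           method = NA_character_,
                           stand_set = NA_character_) {
  form <- match.arg(form)
  if (is.data.frame(assoc_snps)) {
    sel <- assoc_snps[assoc_snps$variable == variable & assoc_snps$passes, ]
    ids <- unique(sel$snp_id)
    if (is.na(method) && nrow(sel) > 0 && "method" %in% names(sel)) {
      method <- paste(unique(sel$method), collapse = "+")
    }
  } else {
    ids <- unique(assoc_snps)
  }
  ids <- intersect(ids, colnames(freqs))
  if (length(ids) == 0) {
    abort(sprintf("no associated SNPs for variable %s", variable))
  }
  f <- freqs[, ids, drop = FALSE]
  reg <- snp_env_regression(f, env_current)
  w <- reg$r_squared
  if (sum(w) == 0) abort("all regression weights are zero")

  n_stands <- nrow(f)
  shift <- matrix(NA_real_, n_stands, length(ids))
  if (form == "predicted") {
    de <- abs(env_future - env_current)
    shift <- outer(de, abs(reg$slope))
  } else {
    pred_fut <- outer(env_future, reg$slope) +
      matrix(reg$intercept, n_stands, length(ids), byrow = TRUE)
    shift <- abs(pred_fut - f)
  }
  rona <- as.vector(shift %*% w) / sum(w)
  tibble(stand_id = rownames(f) %||% as.character(seq_len(n_stands)),
         stand_set = stand_set, variable = variable, method = method,
         rona = rona, n_snps_used = length(ids))
}

#' Contrast RONA between old and planted stand sets
#'
#' Per climate variable (and method, when present): mean RONA in each stand
#' set, their difference (planted minus old), and a two-sided Wilcoxon
#' rank-sum p-value.
#'
#' @param results RONA tibble (rows from [rona_per_stand()]) containing both
#'   stand sets.
#'
#' @return A tibble with one row per variable (x method): `mean_old`,
#'   `mean_planted`, `difference`, `p_wilcoxon`.
#' @export
rona_contrast <- function(results) {
  if (!all(c("old", "planted") %in% results$stand_set)) {
    abort("`results` must contain both stand sets")
  }
  keys <- intersect(c("method", "variable"), names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_old = mean(.data$rona[.data$stand_set == "old"]),
      mean_planted = mean(.data$rona[.data$stand_set == "planted"]),
      difference = .data$mean_planted - .data$mean_old,
      p_wilcoxon = {
        p <- tryCatch(
          suppressWarnings(stats::wilcox.test(
            .data$rona[.data$stand_set == "planted"],
            .data$rona[.data$stand_set == "old"])$p.value),
          error = function(e) NA_real_)
        if (is.nan(p)) 1 else p   # fully tied samples carry no evidence
      },
      .groups = "drop"
    )
}
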