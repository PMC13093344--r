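# Climate distances and (partial) Mantel tests for isolation by
# distance/environment.

#' Euclidean climate distance between stands
#'
#' Standardises each climate variable to zero mean and unit variance across
#' stands, then computes pairwise Euclidean distances in the standardised
#' multi-dimensional climate space. With a single variable this reduces to
#' the absolute standardised difference, the per-variable environmental
#' distance of the isolation-by-environment tables; with all seven variables
#' it is the overall climate distance.
#'
#' @param climate Climate table (`stand_id` plus variable columns).
#' @param variables Variables to use; default all seven.
#'
#' @return A symmetric stands x stands matrix with attribute
#'   `kind = "climate"`. Zero-variance variables are excluded with a warning.
#' @export
climate_distance <- function(climate, variables = NULL) {
  cm <- climate_matrix(climate, variables %||% intersect(
    climate_variables(), names(climate)))
  if (nrow(cm) < 2) abort("need at least 2 stands")
  sds <- apply(cm, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste("excluding zero-variance variable(s):",
               paste(colnames(cm)[sds == 0], collapse = ", ")))
    cm <- cm[, sds > 0, drop = FALSE]
  }
  m <- as.matrix(stats::dist(scale(cm)))
  attr(m, "kind") <- "climate"
  m
}

new_mantel_result <- function(r, p, n_perm, partial, matrices) {
  structure(list(r = r, p = p, n_perm = n_perm, partial = partial,
                 matrices = matrices),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel test: r = %.4f, p = %.4g (%d permutations)\n",
              if (x$partial) "Partial " else "", x$r, x$p, x$n_perm))
  invisible(x)
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return A one-row tibble with `r`, `p`, `n_perm` and `partial`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm, partial = x$partial)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x)

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries, with a
#' one-sided upper-tail permutation p-value obtained by simultaneously
#' relabelling the rows and columns of `d1`:
#' `p = (number of permuted r >= observed r + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 Symmetric distance matrices with matching labels.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutations.
#'
#' @return A `mantel_result` (see [tidy.mantel_result()]).
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  if (n_perm < 99) abort("`n_perm` must be >= 99")
  d2 <- align_dist(d1, d2)
  v2 <- lower_tri(d2)
  r_obs <- stats::cor(lower_tri(d1), v2)
  n <- nrow(d1)
  r_perm <- with_seed_maybe(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(lower_tri(d1[p, p]), v2)
    }, numeric(1))
  })
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  new_mantel_result(r_obs, p, n_perm, FALSE,
                    c(attr(d1, "kind") %||% "d1", attr(d2, "kind") %||% "d2"))
}

partial_r <- function(r12, r13, r23) {
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

#' Partial Mantel test controlling for a third distance matrix
#'
#' First-order partial Pearson correlation of `d1` and `d2` given `d3` over
#' the strictly-lower-triangle entries, with a one-sided upper-tail
#' permutation p-value obtained by relabelling `d1` and recomputing the
#' partial correlation for each permutation (the convention of vegan's
#' `mantel.partial`).
#'
#' @param d1,d2,d3 Symmetric distance matrices with matching labels;
#'   conventionally `d1` the genetic distances, `d2` the predictor and `d3`
#'   the control.
#' @inheritParams mantel_test
#'
#' @return A `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel <- function(d1, d2, d3, n_perm = 9999, seed = NULL) {
  if (n_perm < 99) abort("`n_perm` must be >= 99")
  d2 <- align_dist(d1, d2)
  d3 <- align_dist(d1, d3, arg = "d3")
  v2 <- lower_tri(d2)
  v3 <- lower_tri(d3)
  r23 <- stats::cor(v2, v3)
  v1 <- lower_tri(d1)
  r12 <- stats::cor(v1, v2)
  r13 <- stats::cor(v1, v3)
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12) {
    abort("partial correlation undefined: control matrix collinear")
  }
  r_obs <- partial_r(r12, r13, r23)
  n <- nrow(d1)
  r_perm <- with_seed_maybe(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      vp <- lower_tri(d1[p, p])
      partial_r(stats::cor(vp, v2), stats::cor(vp, v3), r23)
    }, numeric(1))
  })
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  new_mantel_result(r_obs, p, n_perm, TRUE,
                    c(attr(d1, "kind") %||% "d1", attr(d2, "kind") %||% "d2",
                      attr(d3, "kind") %||% "d3"))
}

#' Isolation-by-distance / isolation-by-environment summary
#'
#' Reproduces the layout of the stand-type contrast tables: for every
#' method present in `outliers`, every climate variable, stand set and
#' scenario, a partial Mantel test of the outlier-SNP FST matrix against the
#' single-variable climate distance, controlling for the background FST
#' matrix computed from all remaining SNPs. The per-variable outlier set is
#' the union of SNPs passing in either stand set (the old-stand detections
#' dominate), scored within each stand set separately. Plain Mantel tests of
#' isolation by distance (all-SNP FST vs geographic distance) and of the
#' geography--climate association are attached as attribute `"ibd"`.
#'
#' @param stands Stand table (`stand_id`, `stand_type`, `locality`,
#'   coordinates).
#' @param pc A filtered [pool_counts] object.
#' @param outliers Combined outlier report (rows from [corr_outliers()]
#'   and/or [lfmm_associations()], both stand sets).
#' @param climate_current,climate_future Climate tables for the two
#'   scenarios.
#' @param n_perm Permutations per Mantel test.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per method x variable x stand set x
#'   scenario: `n_outlier_snps`, `partial_r`, `p`.
#' @export
ibd_ibe_report <- function(stands, pc, outliers, climate_current,
                           climate_future, n_perm = 9999, seed = NULL) {
  vars <- attr(outliers, "variables") %||% unique(outliers$variable)
  methods <- unique(outliers$method)
  sets <- list(old = stands$stand_id[stands$stand_type == "old"],
               planted = stands$stand_id[stands$stand_type == "planted"])
  scen <- list(current = climate_current, future = climate_future)
  seed_i <- 0
  rows <- list()
  for (m in methods) {
    rep_m <- outliers[outliers$method == m, ]
    for (v in vars) {
      ids <- unique(rep_m$snp_id[rep_m$variable == v & rep_m$passes])
      for (s in names(sets)) {
        members <- intersect(sets[[s]], pc$stand_ids)
        pcs <- subset_pool_counts(pc, stands = members)
        fsts <- tryCatch(split_fst(pcs, ids), error = function(e) NULL)
        for (sc in names(scen)) {
          seed_i <- seed_i + 1
          clim <- scen[[sc]]
          clim <- clim[match(members, clim$stand_id), ]
          res <- if (is.null(fsts)) NULL else {
            cd <- climate_distance(clim, variables = v)
            partial_mantel(fsts$fst_outlier, cd, fsts$fst_background,
                           n_perm = n_perm,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, seed_i))
          }
          rows[[length(rows) + 1]] <- tibble(
            method = m, variable = v, stand_set = s, scenario = sc,
            n_outlier_snps = length(ids),
            partial_r = if (is.null(res)) NA_real_ else res$r,
            p = if (is.null(res)) NA_real_ else res$p
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)

  # Plain Mantel: isolation by distance and geography-vs-climate, per set.
  ibd <- list()
  fst_all <- NULL
  for (s in names(sets)) {
    members <- intersect(sets[[s]], pc$stand_ids)
    st <- stands[match(members, stands$stand_id), ]
    geo <- geo_distance(st)
    fst_s <- pairwise_fst(subset_pool_counts(pc, stands = members))
    cd <- climate_distance(climate_current[
      match(members, climate_current$stand_id), ])
    seed_i <- seed_i + 1
    m1 <- mantel_test(fst_s, geo, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, seed_i))
    seed_i <- seed_i + 1
    m2 <- mantel_test(cd, geo, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, seed_i))
    ibd[[length(ibd) + 1]] <- tibble(
      stand_set = s,
      comparison = c("fst_vs_geography", "climate_vs_geography"),
      r = c(m1$r, m2$r), p = c(m1$p, m2$p))
  }
  attr(out, "ibd") <- dplyr::bind_rows(ibd)
  out
}
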