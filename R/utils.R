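# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider complete
NULL

# Run `expr` under a fixed seed when `seed` is non-NULL, otherwise use the
# current RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a per-stage seed from a master seed; kept strictly below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.double(seed) * 48271 + 131 * stage) %% 2147483647
}

# Strictly-lower-triangle vectorisation of a square symmetric matrix.
lower_tri <- function(m) m[lower.tri(m)]

# Validate that two labelled square matrices refer to the same entities, and
# reorder the second to match the first.
align_dist <- function(d1, d2, arg = "d2") {
  if (!all(dim(d1) == dim(d2))) {
    abort(sprintf("dimension mismatch: %dx%d vs %dx%d",
                  nrow(d1), ncol(d1), nrow(d2), ncol(d2)))
  }
  l1 <- rownames(d1)
  l2 <- rownames(d2)
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) {
      abort(sprintf("labels of `%s` do not match those of `d1`", arg))
    }
    d2 <- d2[l1, l1, drop = FALSE]
  }
  d2
}

# The seven climate variable abbreviations, in canonical order.
climate_variables <- function() {
  c("AIT", "CMT", "CONT", "DegD0", "DegD5", "MTC", "PCQ")
}

climate_matrix <- function(climate, variables = climate_variables()) {
  missing <- setdiff(variables, names(climate))
  if (length(missing) > 0) {
    abort(paste0("climate table is missing variable(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(climate[, variables, drop = FALSE])
  if (!is.null(climate[["stand_id"]])) rownames(m) <- climate[["stand_id"]]
  storage.mode(m) <- "double"
  m
}
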