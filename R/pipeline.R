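# End-to-end orchestration: simulate or ingest, filter, estimate, test,
# report.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with every
#' threshold at its standard value (minimum coverage 60, coverage quantiles
#' 0.001/0.999, MAF 0.008, one million correlation-null draws at the 0.999
#' quantile, K = 4 latent factors, alpha = 0.05) and the simulation block at
#' the default study design (15 localities, pools of 60 haplotypes, 20,000
#' neutral + 700 adaptive SNPs). Supply `input` (a list with `counts`,
#' `stands`, `climate_current`, `climate_future`) instead of `simulation` to
#' run on real data.
#'
#' @param seed Master seed (mandatory for a run).
#' @param out_dir Output directory.
#' @param ... Overrides merged into the defaults (e.g. `n_perm = 999`,
#'   `simulation = list(n_neutral = 2000)`).
#'
#' @return A named list.
#' @export
default_config <- function(seed, out_dir = tempfile("poolscape_run"), ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    simulation = list(n_localities = 15, n_neutral = 20000, n_adaptive = 700,
                      fst_background = 0.05, slope_logit = 1.5,
                      source_decoupling = 0.8, source_sd = 0.5,
                      n_factors = 4, factor_sd = 0.6,
                      haploids_per_pool = 60, mean_depth = 1850,
                      depth_dispersion = 5, error_rate = 0.001),
    input = NULL,
    filter = list(min_cov = 60, cov_quantile_lo = 0.001,
                  cov_quantile_hi = 0.999, maf_min = 0.008),
    gea = list(n_draws = 1e6, quantile = 0.999, null_n = NULL,
               k_latent = 4, alpha = 0.05),
    n_perm = 9999,
    f3_block_size = 500,
    rona_form = "observed"
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Cross-check pipeline inputs for consistency
#'
#' Verifies that stand ids agree across the count data, metadata and both
#' climate tables, that the seven climate variables are present, and that
#' each locality has the one-old-plus-two-planted structure. Findings are
#' returned, not raised.
#'
#' @param inputs A list with `stands`, `counts` (a [pool_counts]),
#'   `climate_current` and `climate_future`.
#'
#' @return A tibble of findings (`level`, `message`); zero rows when clean.
#' @export
validate_inputs <- function(inputs) {
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1]] <<- tibble(level = level, message = msg)
  }
  stands <- inputs$stands
  ids <- stands$stand_id
  for (what in c("climate_current", "climate_future")) {
    tab <- inputs[[what]]
    missing <- setdiff(ids, tab$stand_id)
    for (m in missing) {
      add("error", sprintf("stand %s absent from %s", m,
                           sub("climate_", "climate:", what)))
    }
    absent_vars <- setdiff(climate_variables(), names(tab))
    if (length(absent_vars) > 0) {
      add("error", sprintf("%s lacks variable(s): %s", what,
                           paste(absent_vars, collapse = ", ")))
    }
    extra <- setdiff(names(tab), c("stand_id", climate_variables()))
    if (length(extra) > 0) {
      add("warning", sprintf("%s has extra column(s) ignored: %s", what,
                             paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(inputs$counts)) {
    missing <- setdiff(ids, inputs$counts$stand_ids)
    for (m in missing) add("error", sprintf("stand %s absent from counts", m))
  }
  for (loc in unique(stands$locality)) {
    s <- stands[stands$locality == loc, ]
    if (sum(s$stand_type == "old") != 1 || sum(s$stand_type == "planted") != 2) {
      add("warning", sprintf(
        "locality %s lacks the 1 old + 2 planted structure", loc))
    }
  }
  if (length(findings) == 0) {
    return(tibble(level = character(0), message = character(0)))
  }
  dplyr::bind_rows(findings)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(stand_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Executes, with per-stage seeds derived from the master seed:
#' simulate (or ingest) -> filter -> allele frequencies -> pairwise FST, f3
#' locality scan and diversity summaries -> PCA -> gene-environment
#' association by both the correlation-null and latent-factor methods, for
#' old and planted stand sets separately -> the isolation-by-
#' distance/environment Mantel suite for current and future climates -> RONA
#' (current to future). Writes TSV tables, a JSON summary and a log to
#' `config$out_dir` and returns the results invisibly.
#'
#' @param config Configuration list, see [default_config()].
#'
#' @return (Invisibly) a list with all intermediate and final objects:
#'   `stands`, `counts`, `filter_report`, `freq`, `fst_all`, `f3`,
#'   `diversity`, `pca`, `threshold`, `associations`, `association_counts`,
#'   `ibe`, `ibd`, `rona`, `rona_contrast`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) abort("`config$seed` is mandatory")
  seed <- config$seed
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(config$input)) {
    inp <- config$input
    stands <- inp$stands
    counts_raw <- inp$counts
    clim_cur <- inp$climate_current
    clim_fut <- inp$climate_future
    truth <- NULL
    say("ingested %d SNPs x %d stands", nrow(counts_raw$snp),
        length(counts_raw$stand_ids))
  } else {
    sim_args <- config$simulation
    sim <- stage("simulate", do.call(simulate_poolseq, c(
      list(n_localities = sim_args$n_localities, seed = derive_seed(seed, 10)),
      sim_args[setdiff(names(sim_args), "n_localities")])))
    stands <- sim$stands
    counts_raw <- sim$counts
    clim_cur <- sim$climate_current
    clim_fut <- sim$climate_future
    truth <- sim$truth
    say("simulated %d SNPs x %d stands (seed %d)", nrow(counts_raw$snp),
        length(counts_raw$stand_ids), as.integer(seed))
  }
  findings <- validate_inputs(list(stands = stands, counts = counts_raw,
                                   climate_current = clim_cur,
                                   climate_future = clim_fut))
  for (i in seq_len(nrow(findings))) {
    say("[%s] %s", findings$level[i], findings$message[i])
  }
  if (any(findings$level == "error")) {
    abort("pipeline stage 'validate' failed: inconsistent inputs")
  }

  # --- filter + frequencies ----------------------------------------------
  flt <- config$filter
  counts <- stage("filter", filter_snps(
    counts_raw, min_cov = flt$min_cov, cov_quantile_lo = flt$cov_quantile_lo,
    cov_quantile_hi = flt$cov_quantile_hi, maf_min = flt$maf_min))
  filter_report <- attr(counts, "filter_report")
  for (i in seq_len(nrow(filter_report))) {
    say("filter rule %-12s removed %6d (remaining %d)",
        filter_report$rule[i], filter_report$n_removed[i],
        filter_report$n_remaining[i])
  }
  freq <- stage("frequencies", estimate_frequencies(counts))

  # --- neutral statistics -------------------------------------------------
  fst_all <- stage("fst", pairwise_fst(counts))
  f3_tab <- stage("f3", f3_locality_scan(counts, stands,
                                         block_size = config$f3_block_size))
  div <- stage("diversity", diversity_stats(counts))
  pca <- stage("pca", pca_structure(freq))

  # --- gene-environment association ---------------------------------------
  gea <- config$gea
  sets <- list(old = stands$stand_id[stands$stand_type == "old"],
               planted = stands$stand_id[stands$stand_type == "planted"])
  null_n <- gea$null_n %||% length(sets$old)
  thr <- stage("corr_null", corr_null_threshold(
    null_n, clim_cur, n_draws = gea$n_draws, quantile = gea$quantile,
    seed = derive_seed(seed, 20)))
  say("correlation null threshold (n = %d, %g draws): r* = %.3f",
      null_n, gea$n_draws, thr)
  assoc <- stage("gea", dplyr::bind_rows(lapply(names(sets), function(s) {
    fs <- freq[sets[[s]], , drop = FALSE]
    cc <- clim_cur[match(sets[[s]], clim_cur$stand_id), ]
    dplyr::bind_rows(
      corr_outliers(fs, cc, threshold = thr, stand_set = s),
      lfmm_associations(fs, cc, k_latent = gea$k_latent, alpha = gea$alpha,
                        stand_set = s))
  })))
  attr(assoc, "variables") <- climate_variables()
  counts_tab <- count_associations(assoc)

  # --- IBD / IBE ----------------------------------------------------------
  ibe <- stage("ibe", ibd_ibe_report(stands, counts, assoc, clim_cur,
                                     clim_fut, n_perm = config$n_perm,
                                     seed = derive_seed(seed, 30)))
  ibd <- attr(ibe, "ibd")

  # --- RONA ---------------------------------------------------------------
  rona_tab <- stage("rona", {
    rows <- list()
    for (m in unique(assoc$method)) {
      rep_m <- assoc[assoc$method == m, ]
      for (v in climate_variables()) {
        ids <- unique(rep_m$snp_id[rep_m$variable == v & rep_m$passes])
        if (length(ids) == 0) next
        for (s in names(sets)) {
          members <- sets[[s]]
          rows[[length(rows) + 1]] <- rona_per_stand(
            freq[members, , drop = FALSE],
            env_current = clim_cur[[v]][match(members, clim_cur$stand_id)],
            env_future = clim_fut[[v]][match(members, clim_fut$stand_id)],
            assoc_snps = ids, variable = v, form = config$rona_form,
            method = m, stand_set = s)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  rona_sum <- if (nrow(rona_tab) > 0) rona_contrast(rona_tab) else tibble()

  # --- outputs ------------------------------------------------------------
  files <- c(
    stands = "stands.tsv", climate_current = "climate_current.tsv",
    climate_future = "climate_future.tsv", filter_report = "filter_report.tsv",
    fst_all = "fst_all.tsv", f3 = "f3.tsv", diversity = "diversity.tsv",
    associations = "associations.tsv",
    association_counts = "association_counts.tsv",
    ibe_report = "ibe_report.tsv", rona = "rona.tsv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_tsv(stands, paths["stands"])
  write_tsv(clim_cur, paths["climate_current"])
  write_tsv(clim_fut, paths["climate_future"])
  write_tsv(filter_report, paths["filter_report"])
  write_matrix_tsv(fst_all, paths["fst_all"])
  write_tsv(f3_tab, paths["f3"])
  write_tsv(div, paths["diversity"])
  write_tsv(assoc, paths["associations"])
  write_tsv(counts_tab, paths["association_counts"])
  write_tsv(ibe, paths["ibe_report"])
  write_tsv(rona_tab, paths["rona"])

  summary <- list(
    seed = as.integer(seed),
    n_snps_input = nrow(counts_raw$snp),
    n_snps_retained = nrow(counts$snp),
    corr_null_threshold = thr,
    bonferroni_threshold = gea$alpha / nrow(counts$snp),
    association_counts = counts_tab,
    ibd = ibd,
    rona_contrast = rona_sum
  )
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(log_lines, log_path)
  say("wrote %d output files to %s", length(paths) + 2, out_dir)

  invisible(list(stands = stands, counts = counts,
                 filter_report = filter_report, freq = freq, truth = truth,
                 fst_all = fst_all, f3 = f3_tab, diversity = div, pca = pca,
                 threshold = thr, associations = assoc,
                 association_counts = counts_tab, ibe = ibe, ibd = ibd,
                 rona = rona_tab, rona_contrast = rona_sum,
                 files = c(paths, summary = json_path, log = log_path)))
}
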