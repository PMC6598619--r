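#' Pipeline configuration
#'
#' All tunable parameters of the three-stage pipeline, with defaults at the
#' study settings: 20-TR window and adjustment block, 250 bootstrap
#' replicates, 95% bands, 40 spline terms, Benjamini-Yekutieli FDR at 0.05,
#' null coverage proportions 0.5 (condition curves) and 0.14 (difference),
#' and difference tests gated on reference-condition significance.
#'
#' @param window_trs,block_trs,n_boot,band_level,use_bootstrap see
#'   [subject_dfc_config()].
#' @param knots number of spline terms K for the population model.
#' @param alpha significance threshold.
#' @param fdr_method `"BY"`, `"bonferroni"` or `"BH"`.
#' @param null_prop_condition,null_prop_difference design-informed null
#'   coverage proportions.
#' @param gate_on_reference gate difference tests on reference-condition
#'   significance.
#' @param seed master seed; per-(subject, scan, pair) streams are derived
#'   from it, so per-pair results are order-independent.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_trs = 20L, block_trs = 20L,
                            n_boot = 250L, band_level = 0.95,
                            knots = 40L, alpha = 0.05, fdr_method = "BY",
                            null_prop_condition = 0.5,
                            null_prop_difference = 0.14,
                            gate_on_reference = TRUE, use_bootstrap = TRUE,
                            seed = 1L) {
  cfg <- list(window_trs = as.integer(window_trs),
              block_trs = as.integer(block_trs),
              n_boot = as.integer(n_boot), band_level = band_level,
              knots = as.integer(knots), alpha = alpha,
              fdr_method = fdr_method,
              null_prop_condition = null_prop_condition,
              null_prop_difference = null_prop_difference,
              gate_on_reference = isTRUE(gate_on_reference),
              use_bootstrap = isTRUE(use_bootstrap),
              seed = as.integer(seed))
  subject_dfc_config(window_trs = cfg$window_trs, block_trs = cfg$block_trs,
                     n_boot = cfg$n_boot, band_level = cfg$band_level,
                     use_bootstrap = cfg$use_bootstrap)  # validate stage-1 part
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  sprintf("%08x", derive_seed(0L, paste(
    names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                          character(1L)),
    collapse = ";")))
}

#' Window duration in seconds
#'
#' @param window_trs window length in TRs.
#' @param tr_seconds repetition time in seconds.
#' @return `window_trs * tr_seconds` (20 TRs at 2.25 s give 45 s).
#' @export
report_window_seconds <- function(window_trs, tr_seconds) {
  stopifnot(window_trs > 0, tr_seconds > 0)
  window_trs * tr_seconds
}

write_tsv_stamped <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full dFC pipeline over a study
#'
#' For every region pair: (1) subject-level dFC per scan (MLPB bootstrap +
#' sliding window + Fisher z, median summarization); (2) the population
#' dFCM fit and condition/difference curves with pointwise bands; (3)
#' non-zero coverage with design-informed proportion tests.  Across pairs,
#' multiplicity is corrected per curve family and the difference family is
#' gated on reference-condition significance.  Per-pair failures are
#' recorded and skipped, never fatal.  All results are written as TSV to
#' `out_dir` (each file stamped with the config hash) together with a
#' key-value copy of the configuration and a run log; the run is
#' deterministic given `config$seed`.
#'
#' @param manifest manifest data frame (see [read_manifest()]) or a path to
#'   a manifest TSV.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param network_map optional named region-to-network vector; adds
#'   network-block matrices to the outputs.
#' @param pairs optional subset of pairs (data frame `region_a`,
#'   `region_b`); default all pairs of the manifest's regions.
#' @param keep_fits return the per-pair `dfcm_fit` objects (memory-heavy at
#'   scale). Default `FALSE`.
#' @return Invisibly, a list with `coverage` (per pair and kind:
#'   proportions, raw/adjusted p, significance), `curves` (long data frame),
#'   `sfcm` (static-model coefficient tables), `failures`, `out_dir`, and
#'   optionally `fits`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir,
                         network_map = NULL, pairs = NULL,
                         keep_fits = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("# pipeline run, config_hash %s\n", hash), file = logf)

  scans <- lapply(seq_len(nrow(manifest)), function(i)
    read_timeseries(manifest$path[i], manifest$subject_id[i],
                    manifest$scan_index[i], manifest$condition[i]))
  region_ids <- scans[[1L]]$region_ids
  n_time <- nrow(scans[[1L]]$values)
  if (is.null(pairs)) pairs <- enumerate_pairs(region_ids)
  grid <- dfc_grid(n_time, config$window_trs)
  logline("%d scans, %d regions, %d time points; %d pairs; window %d TRs (%g s at TR %g s); grid %d..%d (%d points); seed %d",
          length(scans), length(region_ids), n_time, nrow(pairs),
          config$window_trs,
          report_window_seconds(config$window_trs, scans[[1L]]$tr_seconds),
          scans[[1L]]$tr_seconds, min(grid), max(grid), length(grid),
          config$seed)

  coverage <- list(); curves <- list(); sfcm_rows <- list()
  failures <- list(); fits <- list()
  for (pi in seq_len(nrow(pairs))) {
    ra <- pairs$region_a[pi]; rb <- pairs$region_b[pi]
    res <- tryCatch({
      rows <- lapply(scans, function(sc) {
        cfg <- subject_dfc_config(
          window_trs = config$window_trs, block_trs = config$block_trs,
          n_boot = config$n_boot, band_level = config$band_level,
          use_bootstrap = config$use_bootstrap,
          seed = derive_seed(config$seed, sc$subject_id, sc$scan_index,
                             sc$condition, ra, rb))
        sd <- estimate_subject_dfc(sc$values[, ra], sc$values[, rb], cfg,
                                   sc$subject_id, sc$scan_index,
                                   sc$condition)
        data.frame(subject_id = sc$subject_id, scan_index = sc$scan_index,
                   condition = sc$condition, t = sd$grid, z = sd$z_median,
                   stringsAsFactors = FALSE)
      })
      dat <- do.call(rbind, rows)
      fit <- fit_dfcm(dat, K = config$knots)
      cb <- predict_curves(fit, level = config$band_level)
      sm <- summarize_pair_curves(cb, config$null_prop_condition,
                                  config$null_prop_difference)
      sf <- fit_sfcm(dat)
      list(fit = fit, cb = cb, sm = sm, sf = sf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(region_a = ra, region_b = rb,
                   message = conditionMessage(res))
      logline("pair %s-%s FAILED: %s", ra, rb, conditionMessage(res))
      next
    }
    res$sm$region_a <- ra; res$sm$region_b <- rb
    coverage[[length(coverage) + 1L]] <- res$sm
    curves[[length(curves) + 1L]] <- do.call(rbind, lapply(
      names(res$cb), function(k)
        data.frame(region_a = ra, region_b = rb, kind = k,
                   t = res$cb[[k]]$grid, estimate = res$cb[[k]]$estimate,
                   lower = res$cb[[k]]$lower, upper = res$cb[[k]]$upper,
                   stringsAsFactors = FALSE)))
    sfcm_rows[[length(sfcm_rows) + 1L]] <-
      data.frame(region_a = ra, region_b = rb,
                 term = rownames(res$sf$coef), res$sf$coef,
                 row.names = NULL)
    if (keep_fits) fits[[paste(ra, rb, sep = "~")]] <- res$fit
  }

  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(region_a = character(), region_b = character(),
                              message = character())
  out <- list(out_dir = out_dir, failures = failures)
  if (length(coverage)) {
    cov <- do.call(rbind, coverage)
    kinds <- unique(cov$kind)
    cov$p_adjusted <- NA_real_; cov$significant <- FALSE
    for (k in setdiff(kinds, "diff")) {
      i <- cov$kind == k
      adj <- adjust_multiplicity(cov$p_value[i], config$fdr_method,
                                 config$alpha)
      cov$p_adjusted[i] <- adj$p_adjusted
      cov$significant[i] <- adj$significant
    }
    refk <- kinds[1L]   # predict_curves lists the reference condition first
    idiff <- cov$kind == "diff"
    pair_key <- paste(cov$region_a, cov$region_b)
    ref_sig <- cov$significant[cov$kind == refk][
      match(pair_key[idiff], pair_key[cov$kind == refk])]
    if (config$gate_on_reference) {
      g <- gate_difference(ref_sig, cov$p_value[idiff],
                           config$fdr_method, config$alpha)
    } else {
      a <- adjust_multiplicity(cov$p_value[idiff], config$fdr_method,
                               config$alpha)
      g <- data.frame(p_adjusted = a$p_adjusted, significant = a$significant)
    }
    cov$p_adjusted[idiff] <- g$p_adjusted
    cov$significant[idiff] <- g$significant
    cov$method <- config$fdr_method
    cov <- cov[, c("region_a", "region_b", "kind", "prop_nonzero",
                   "prop_positive", "prop_negative", "direction_class",
                   "p_value", "p_adjusted", "method", "significant")]
    names(cov)[names(cov) == "p_value"] <- "p_raw"
    out$coverage <- cov
    out$curves <- do.call(rbind, curves)
    out$sfcm <- do.call(rbind, sfcm_rows)
    write_tsv_stamped(out$coverage, file.path(out_dir, "coverage.tsv"), hash)
    write_tsv_stamped(out$curves, file.path(out_dir, "curves.tsv"), hash)
    write_tsv_stamped(out$sfcm, file.path(out_dir, "sfcm.tsv"), hash)
    if (!is.null(network_map)) {
      for (k in kinds) {
        i <- cov$kind == k
        nb <- network_summary(cov[i, c("region_a", "region_b")],
                              cov$significant[i], network_map)
        write_tsv_stamped(
          data.frame(network = rownames(nb$percent_significant),
                     nb$percent_significant, check.names = FALSE),
          file.path(out_dir, sprintf("network_%s.tsv", k)), hash)
      }
    }
  }
  if (nrow(failures))
    write_tsv_stamped(failures, file.path(out_dir, "failures.tsv"), hash)
  writeLines(c(sprintf("config_hash: %s", hash),
               paste0(names(unclass(config)), ": ",
                      vapply(unclass(config), function(v)
                        paste(format(v), collapse = ","), character(1L)))),
             file.path(out_dir, "config.txt"))
  logline("done: %d pairs succeeded, %d failed",
          length(coverage), nrow(failures))
  if (keep_fits) out$fits <- fits
  invisible(out)
}
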