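#' Specification of a synthetic two-condition dFC study
#'
#' Describes a simulated study with the structure the population model
#' assumes: `n_subjects` subjects, `scans_per_condition` scans under each of
#' two conditions, `n_time` time points per scan, a smooth condition-specific
#' true association on the Fisher-z scale, and additive subject and
#' (subject, scan, condition) random shifts on that scale.  Defaults mirror
#' a 24-subject two-condition task design: 3 scans per condition, 125 TRs at
#' TR = 2.25 s, `z_B(t) = 0.4 + 0.3 sin(2 pi t)` for the reference condition
#' and constant `z_G(t) = 0.4` for the alternative, with random-shift SDs
#' 0.1 (subject) and 0.05 (scan).
#'
#' @param n_subjects number of subjects. Default 24.
#' @param scans_per_condition scans per subject per condition. Default 3.
#' @param n_time time points per scan. Default 125.
#' @param tr_seconds repetition time. Default 2.25.
#' @param z_curve_reference,z_curve_alternative functions of rescaled time
#'   `t in [0, 1]` giving the true condition association (Fisher-z scale).
#' @param sigma_b0,sigma_a0 SDs of the subject and scan random shifts on the
#'   z scale. Defaults 0.1 and 0.05.
#' @param conditions two condition labels, reference first. Default
#'   `c("B", "G")`.
#' @param seed master seed; every scan's series and every random effect is
#'   derived deterministically from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 24L, scans_per_condition = 3L,
                           n_time = 125L, tr_seconds = 2.25,
                           z_curve_reference = function(t) 0.4 + 0.3 * sin(2 * pi * t),
                           z_curve_alternative = function(t) rep(0.4, length(t)),
                           sigma_b0 = 0.1, sigma_a0 = 0.05,
                           conditions = c("B", "G"), seed = 1L) {
  stopifnot(n_subjects >= 1L, scans_per_condition >= 1L, n_time >= 4L,
            sigma_b0 >= 0, sigma_a0 >= 0, length(conditions) == 2L)
  structure(list(n_subjects = as.integer(n_subjects),
                 scans_per_condition = as.integer(scans_per_condition),
                 n_time = as.integer(n_time), tr_seconds = tr_seconds,
                 z_curve_reference = z_curve_reference,
                 z_curve_alternative = z_curve_alternative,
                 sigma_b0 = sigma_b0, sigma_a0 = sigma_a0,
                 conditions = as.character(conditions),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# rescale original 1-based time indices to [0, 1]
time01 <- function(t, n_time) (t - 1) / (n_time - 1)

# deterministic random effects per subject / per scan cell
synthetic_effects <- function(spec, subject, scan = NULL, condition = NULL) {
  b <- local({
    set.seed(derive_seed(spec$seed, "b", subject))
    stats::rnorm(1L, 0, spec$sigma_b0)
  })
  a <- if (is.null(scan)) 0 else local({
    set.seed(derive_seed(spec$seed, "a", subject, scan, condition))
    stats::rnorm(1L, 0, spec$sigma_a0)
  })
  c(b = b, a = a)
}

#' Simulate one scan's bivariate series with known time-varying correlation
#'
#' Draws the subject shift `b_i ~ N(0, sigma_b0^2)` (once per subject: the
#' same subject always gets the same shift) and the scan shift
#' `a_is ~ N(0, sigma_a0^2)` per (scan, condition) cell, sets the true
#' correlation `rho(t) = tanh(z_d(t) + b_i + a_is)` (clipped to
#' `[-0.99, 0.99]`), and generates
#' `x_t ~ N(0,1)`, `y_t = rho(t) x_t + sqrt(1 - rho(t)^2) e_t`,
#' `e_t ~ N(0,1)`, so both series have marginal variance ~1 and
#' time-t correlation `rho(t)`.
#'
#' @param spec a [synthetic_spec()].
#' @param subject subject index (1-based).
#' @param scan scan index within condition (1-based).
#' @param condition one of `spec$conditions`.
#' @return List with `x`, `y` (length `n_time`), the true `rho` path, and
#'   the drawn effects `b`, `a`.
#' @export
simulate_pair_scan <- function(spec, subject, scan, condition) {
  stopifnot(inherits(spec, "synthetic_spec"),
            condition %in% spec$conditions)
  eff <- synthetic_effects(spec, subject, scan, condition)
  t01 <- time01(seq_len(spec$n_time), spec$n_time)
  zf <- if (condition == spec$conditions[1L]) spec$z_curve_reference
        else spec$z_curve_alternative
  rho <- tanh(zf(t01) + eff[["b"]] + eff[["a"]])
  rho <- pmin(0.99, pmax(-0.99, rho))
  set.seed(derive_seed(spec$seed, "xy", subject, scan, condition))
  x <- stats::rnorm(spec$n_time)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(spec$n_time)
  list(x = x, y = y, rho = rho, b = eff[["b"]], a = eff[["a"]])
}

#' Simulate a full study to disk
#'
#' Writes one two-region TSV per (subject, scan, condition) — the formats of
#' the core readers — plus the study manifest and a key-value file recording
#' all generation parameters and the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return The manifest data frame (invisibly readable back with
#'   [read_manifest()]); its `path` column holds absolute file paths.
#' @export
simulate_study <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- expand.grid(scan_index = seq_len(spec$scans_per_condition),
                     condition = spec$conditions,
                     subject_id = sprintf("s%02d", seq_len(spec$n_subjects)),
                     stringsAsFactors = FALSE)
  rec <- rec[, c("subject_id", "scan_index", "condition")]
  rec$path <- file.path(normalizePath(dir), sprintf(
    "%s_%s_scan%d.tsv", rec$subject_id, rec$condition, rec$scan_index))
  for (i in seq_len(nrow(rec))) {
    subj <- as.integer(sub("^s", "", rec$subject_id[i]))
    sim <- simulate_pair_scan(spec, subj, rec$scan_index[i], rec$condition[i])
    ts <- roi_timeseries(cbind(sim$x, sim$y), c("r1", "r2"),
                         rec$subject_id[i], rec$scan_index[i],
                         rec$condition[i], spec$tr_seconds)
    write_timeseries(ts, rec$path[i])
  }
  utils::write.table(rec, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  par <- c(n_subjects = spec$n_subjects,
           scans_per_condition = spec$scans_per_condition,
           n_time = spec$n_time, tr_seconds = spec$tr_seconds,
           sigma_b0 = spec$sigma_b0, sigma_a0 = spec$sigma_a0,
           reference = spec$conditions[1L], alternative = spec$conditions[2L],
           seed = spec$seed)
  writeLines(paste0(names(par), ": ", par), file.path(dir, "spec.txt"))
  invisible(rec)
}

#' True condition curves on a dFC grid
#'
#' Evaluates the generating curves `z_B`, `z_G` and their difference on the
#' dFC grid (1-based window-center indices), for scoring recovered curves.
#'
#' @param spec a [synthetic_spec()].
#' @param grid 1-based time indices within `[1, n_time]` (e.g.
#'   [dfc_grid()]).
#' @return Data frame with columns `t`, `z_reference`, `z_alternative`,
#'   `z_diff`.
#' @export
true_dfc_on_grid <- function(spec, grid) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(grid < 1 | grid > spec$n_time))
    stop("grid must lie within [1, n_time]")
  t01 <- time01(grid, spec$n_time)
  zb <- spec$z_curve_reference(t01)
  zg <- spec$z_curve_alternative(t01)
  data.frame(t = grid, z_reference = zb, z_alternative = zg,
             z_diff = zg - zb)
}

#' Draw population-model responses directly (no time series)
#'
#' Generates Fisher-z responses straight from the population model
#' `z = z_d(t) + b_i + a_isd + eps` on a given dFC grid — the generating
#' process the dFCM assumes — bypassing the subject-level estimation stage.
#' Used to study the population stage in isolation (band calibration,
#' null-difference control).
#'
#' @param spec a [synthetic_spec()].
#' @param grid 1-based time indices (default the 20-TR dFC grid of the
#'   spec's scan length).
#' @param sigma_eps residual SD on the z scale. Default 0.2, the order of
#'   the sampling noise of a Fisher-z correlation from a 20-TR window.
#' @return Data frame with columns `subject_id`, `scan_index`, `condition`,
#'   `t`, `z` — directly fittable by [fit_dfcm()].
#' @export
simulate_dfcm_data <- function(spec, grid = dfc_grid(spec$n_time, 20L),
                               sigma_eps = 0.2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tr <- true_dfc_on_grid(spec, grid)
  J <- length(grid)
  rec <- expand.grid(scan_index = seq_len(spec$scans_per_condition),
                     condition = spec$conditions,
                     subject = seq_len(spec$n_subjects),
                     stringsAsFactors = FALSE)
  set.seed(derive_seed(spec$seed, "dfcm-data"))
  out <- vector("list", nrow(rec))
  b <- stats::rnorm(spec$n_subjects, 0, spec$sigma_b0)
  for (i in seq_len(nrow(rec))) {
    mu <- if (rec$condition[i] == spec$conditions[1L]) tr$z_reference
          else tr$z_alternative
    a <- stats::rnorm(1L, 0, spec$sigma_a0)
    out[[i]] <- data.frame(
      subject_id = sprintf("s%02d", rec$subject[i]),
      scan_index = rec$scan_index[i], condition = rec$condition[i],
      t = grid,
      z = mu + b[rec$subject[i]] + a + stats::rnorm(J, 0, sigma_eps),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
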