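#' Configuration for subject-level dFC estimation
#'
#' @param window_trs sliding-window length in TRs; even and >= 4.
#'   Default 20 (45 s at TR = 2.25 s).
#' @param block_trs width of the adjacent bootstrap adjustment blocks in
#'   TRs; must be >= `window_trs / 2`. Default 20.
#' @param n_boot number of bootstrap replicates B. Default 250.
#' @param band_level level of the pointwise percentile band. Default 0.95.
#' @param use_bootstrap when `FALSE`, the supplementary sliding-window-only
#'   mode: the Fisher-z trajectory of the raw series, no band.
#' @param seed integer seed for the bootstrap resampling; `NULL` leaves the
#'   RNG state alone.
#' @param clip_r correlations are clipped to `[-clip_r, clip_r]` before the
#'   Fisher z-transform so it stays finite. Default `1 - 1e-6`.
#' @param taper_bandwidth bandwidth (in lags) of the flat-top taper used to
#'   band the stacked covariance in the MLPB step; `NULL` means
#'   `ceiling(L^(1/3))` for a block of length L.
#' @param eig_floor eigenvalues of the banded covariance are floored at
#'   `eig_floor` times the largest eigenvalue. Default 1e-6.
#' @return A list of class `subject_dfc_config`.
#' @export
subject_dfc_config <- function(window_trs = 20L, block_trs = 20L,
                               n_boot = 250L, band_level = 0.95,
                               use_bootstrap = TRUE, seed = NULL,
                               clip_r = 1 - 1e-6, taper_bandwidth = NULL,
                               eig_floor = 1e-6) {
  window_trs <- as.integer(window_trs)
  block_trs <- as.integer(block_trs)
  n_boot <- as.integer(n_boot)
  if (window_trs < 4L || window_trs %% 2L != 0L)
    stop("window_trs must be even and >= 4")
  if (block_trs < window_trs / 2L)
    stop("block_trs must be >= window_trs / 2")
  if (use_bootstrap && n_boot < 2L)
    stop("n_boot must be >= 2 when the bootstrap is on")
  if (!(band_level > 0 && band_level < 1))
    stop("band_level must be in (0, 1)")
  if (!(clip_r > 0 && clip_r < 1))
    stop("clip_r must be in (0, 1)")
  structure(list(window_trs = window_trs, block_trs = block_trs,
                 n_boot = n_boot, band_level = band_level,
                 use_bootstrap = isTRUE(use_bootstrap),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 clip_r = clip_r, taper_bandwidth = taper_bandwidth,
                 eig_floor = eig_floor),
            class = "subject_dfc_config")
}

#' dFC time grid for a scan
#'
#' Centers of the valid sliding windows, as 1-based original-time indices
#' `w/2 + 1, ..., T - w/2` — exactly `T - w` points, excluding the first and
#' last `w/2` scan time points (125 TRs with a 20-TR window give the 105-point
#' grid 11..115).
#'
#' @param n_time number of time points T in the scan.
#' @param window_trs window length w (even).
#' @return Integer vector of window-center indices.
#' @export
dfc_grid <- function(n_time, window_trs) {
  if (n_time <= window_trs) stop("need T > window_trs")
  h <- window_trs %/% 2L
  seq.int(h + 1L, n_time - h)
}

#' Sliding-window Pearson correlation
#'
#' The correlation at grid center t is computed over the w points
#' `[t - w/2, t + w/2 - 1]`; valid centers are `w/2 + 1, ..., T - w/2`, so
#' the trajectory has `T - w` points.
#'
#' @param x,y numeric series of common length T > `window_trs`.
#' @param window_trs window length w (even, >= 4).
#' @return Numeric vector of length `T - window_trs` of correlations in
#'   `[-1, 1]`, named by the 1-based window-center index.
#' @export
sliding_window_correlation <- function(x, y, window_trs = 20L) {
  w <- as.integer(window_trs)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= w) stop("need length(x) > window_trs")
  if (w < 4L || w %% 2L != 0L) stop("window_trs must be even and >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  # rolling sums over window starts 1..T-w (center = start + w/2)
  x <- x - mean(x); y <- y - mean(y)   # guard against cancellation
  cx <- c(0, cumsum(x));  cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cyy <- c(0, cumsum(y * y))
  cxy <- c(0, cumsum(x * y))
  s <- seq_len(n - w); e <- s + w
  sx <- cx[e] - cx[s];  sy <- cy[e] - cy[s]
  vx <- (cxx[e] - cxx[s]) - sx * sx / w
  vy <- (cyy[e] - cyy[s]) - sy * sy / w
  tol <- 1e-12 * w * max(1, max(x * x), max(y * y))
  if (any(vx <= tol) || any(vy <= tol)) {
    j <- which(vx <= tol | vy <= tol)[1L]
    stop(sprintf(
      "correlation undefined: zero variance within the window centered at t = %d",
      j + w %/% 2L))
  }
  r <- ((cxy[e] - cxy[s]) - sx * sy / w) / sqrt(vx * vy)
  r <- pmin(1, pmax(-1, r))
  names(r) <- dfc_grid(n, w)
  r
}

#' Fisher z-transformation with clipping
#'
#' `z = atanh(r)` after clipping r into `[-clip_r, clip_r]`, so the transform
#' is finite even at |r| = 1.  Strictly increasing and odd.
#'
#' @param r correlations in `[-1, 1]`.
#' @param clip_r clip bound in (0, 1). Default `1 - 1e-6`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, clip_r = 1 - 1e-6) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(clip_r, pmax(-clip_r, r)))
}

# Precompute the MLPB machinery for one block: banded stacked covariance,
# its Cholesky factor, and the standardized whitened residuals.
mlpb_prep <- function(block, taper_bandwidth = NULL, eig_floor = 1e-6) {
  block <- as.matrix(block)
  if (ncol(block) != 2L) stop("block must have 2 columns")
  L <- nrow(block)
  if (L < 4L) stop("block too short (L >= 4 required)")
  if (any(!is.finite(block))) stop("block must be finite")
  mu <- colMeans(block)
  c1 <- block[, 1L] - mu[1L]; c2 <- block[, 2L] - mu[2L]
  if (stats::var(c1) == 0 || stats::var(c2) == 0)
    stop("degenerate block: constant column")
  l <- if (is.null(taper_bandwidth)) ceiling(L^(1 / 3)) else taper_bandwidth
  # flat-top taper weight for lag h at bandwidth l
  kap <- function(h) {
    u <- abs(h) / l
    ifelse(u <= 0.5, 1, ifelse(u <= 1, 2 * (1 - u), 0))
  }
  acov <- function(a, b, h) {           # (1/L) sum_t a[t+h] b[t], h >= 0
    if (h >= L) return(0)
    sum(a[(1L + h):L] * b[seq_len(L - h)]) / L
  }
  lagmat <- outer(seq_len(L), seq_len(L), "-")   # i - j
  fill <- function(a, b) {
    g <- vapply(-(L - 1L):(L - 1L), function(h)
      if (h >= 0L) acov(a, b, h) else acov(b, a, -h), numeric(1L))
    matrix(g[lagmat + L] * kap(lagmat), L, L)
  }
  Sigma <- rbind(cbind(fill(c1, c1), fill(c1, c2)),
                 cbind(fill(c2, c1), fill(c2, c2)))
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE)
  if (any(!is.finite(ev$values))) stop("non-finite covariance estimate")
  lam <- pmax(ev$values, eig_floor * max(ev$values))
  Sigma <- ev$vectors %*% (lam * t(ev$vectors))
  R <- chol((Sigma + t(Sigma)) / 2)
  e <- forwardsolve(t(R), c(c1, c2))
  e <- (e - mean(e)) / stats::sd(e)
  list(R = R, resid = e, mu = mu, L = L)
}

mlpb_draw <- function(prep) {
  L <- prep$L
  idx <- sample.int(2L * L, 2L * L, replace = TRUE)
  v <- drop(crossprod(prep$R, prep$resid[idx]))
  cbind(v[seq_len(L)] + prep$mu[1L], v[L + seq_len(L)] + prep$mu[2L])
}

#' One multivariate linear process bootstrap (MLPB) resample of a block
#'
#' Resamples an L x 2 bivariate block while preserving its second-order
#' structure: the two centered columns are stacked into a 2L vector whose
#' 2L x 2L covariance is estimated from sample auto- and cross-covariances
#' with a banded flat-top taper, floored to positive definiteness, and
#' Cholesky-factored; the whitened coordinates are standardized, resampled
#' i.i.d. with replacement, recolored and the column means re-added.
#'
#' Uses the current RNG state; seed the session (or use
#' [estimate_subject_dfc()]) for reproducibility.
#'
#' @param block numeric L x 2 matrix, L >= 4, both columns non-constant.
#' @param taper_bandwidth,eig_floor see [subject_dfc_config()].
#' @return An L x 2 resampled block.
#' @export
mlpb_resample_block <- function(block, taper_bandwidth = NULL,
                                eig_floor = 1e-6) {
  mlpb_draw(mlpb_prep(block, taper_bandwidth, eig_floor))
}

# Adjacent block boundaries: blocks of block_trs, remainder absorbed into
# the final block (125 with block 20 -> 20,20,20,20,20,25).
block_bounds <- function(n_time, block_trs) {
  nb <- n_time %/% block_trs
  if (nb < 1L) stop("block_trs exceeds the series length")
  starts <- (seq_len(nb) - 1L) * block_trs + 1L
  ends <- c(starts[-1L] - 1L, n_time)
  cbind(start = starts, end = ends)
}

#' Subject-level dFC for one region pair and scan
#'
#' Implements the bootstrap dFC estimator: the series is split into adjacent
#' blocks of `block_trs` TRs (remainder merged into the final block), each
#' block is resampled by the MLPB, the resampled blocks are concatenated into
#' a full-length bootstrap series, and sliding-window correlation followed by
#' the Fisher z-transform gives one bootstrapped dFC trajectory.  Repeating
#' `n_boot` times, the subject-level dFC estimate is the pointwise median
#' and the band the pointwise `(1-level)/2` and `1-(1-level)/2` percentiles.
#' With `use_bootstrap = FALSE` the estimate is the Fisher-z trajectory of
#' the raw series and the band is absent.
#'
#' @param x,y numeric series of common length T > `window_trs`.
#' @param cfg a [subject_dfc_config()].
#' @param subject_id,scan_index,condition metadata carried into the result.
#' @param return_ensemble keep the B x J matrix of bootstrap trajectories.
#' @return An object of class `subject_dfc`: fields `grid` (1-based window
#'   centers), `z_median`, `z_lower`, `z_upper` (NULL without bootstrap),
#'   metadata, and optionally `ensemble`.
#' @export
estimate_subject_dfc <- function(x, y, cfg = subject_dfc_config(),
                                 subject_id = NA_character_,
                                 scan_index = NA_integer_,
                                 condition = NA_character_,
                                 return_ensemble = FALSE) {
  stopifnot(inherits(cfg, "subject_dfc_config"))
  n <- length(x)
  grid <- dfc_grid(n, cfg$window_trs)
  J <- length(grid)
  if (!cfg$use_bootstrap) {
    z <- fisher_z(sliding_window_correlation(x, y, cfg$window_trs), cfg$clip_r)
    return(structure(list(subject_id = as.character(subject_id),
                          scan_index = as.integer(scan_index),
                          condition = as.character(condition),
                          grid = grid, z_median = unname(z),
                          z_lower = NULL, z_upper = NULL,
                          n_boot = 0L, band_level = NA_real_,
                          window_trs = cfg$window_trs),
                     class = "subject_dfc"))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bb <- block_bounds(n, cfg$block_trs)
  preps <- lapply(seq_len(nrow(bb)), function(k) {
    tryCatch(
      mlpb_prep(cbind(x, y)[bb[k, 1L]:bb[k, 2L], , drop = FALSE],
                cfg$taper_bandwidth, cfg$eig_floor),
      error = function(e) stop(sprintf(
        "subject %s scan %s block %d [%d..%d]: %s",
        subject_id, scan_index, k, bb[k, 1L], bb[k, 2L],
        conditionMessage(e)), call. = FALSE))
  })
  Z <- matrix(NA_real_, cfg$n_boot, J)
  for (b in seq_len(cfg$n_boot)) {
    star <- do.call(rbind, lapply(preps, mlpb_draw))
    r <- tryCatch(
      sliding_window_correlation(star[, 1L], star[, 2L], cfg$window_trs),
      error = function(e) stop(sprintf(
        "bootstrap replicate %d: %s", b, conditionMessage(e)), call. = FALSE))
    Z[b, ] <- fisher_z(r, cfg$clip_r)
  }
  a <- (1 - cfg$band_level) / 2
  qs <- apply(Z, 2L, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  out <- structure(list(subject_id = as.character(subject_id),
                        scan_index = as.integer(scan_index),
                        condition = as.character(condition),
                        grid = grid, z_median = qs[2L, ],
                        z_lower = qs[1L, ], z_upper = qs[3L, ],
                        n_boot = cfg$n_boot, band_level = cfg$band_level,
                        window_trs = cfg$window_trs),
                   class = "subject_dfc")
  if (return_ensemble) out$ensemble <- Z
  out
}

#' @export
print.subject_dfc <- function(x, ...) {
  cat(sprintf("<subject_dfc> subject %s scan %s condition %s: %d grid points (centers %d..%d), %s\n",
              x$subject_id, x$scan_index, x$condition, length(x$grid),
              min(x$grid), max(x$grid),
              if (x$n_boot > 0L)
                sprintf("median of %d bootstrap trajectories, %g%% band",
                        x$n_boot, 100 * x$band_level)
              else "sliding-window only (no band)"))
  invisible(x)
}

#' Derive a reproducible stream seed from a master seed and identifiers
#'
#' Deterministic 31-bit hash used to give every (subject, scan, pair)
#' unit its own RNG stream, so per-pair results are order-independent.
#'
#' @param master integer master seed.
#' @param ... identifiers (coerced to character) of the work unit.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(paste(..., sep = "\r")))
    h <- (h * 31 + ch) %% m
  as.integer(h + 1)
}
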