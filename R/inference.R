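#' Non-zero coverage of a confidence band
#'
#' The summary statistic of a dFC curve: the proportion of the time grid at
#' which the pointwise confidence band excludes zero, split by side.  A
#' non-zero coverage of 0.8 means the whole band is above or below zero for
#' 80% of the scan time.
#'
#' @param band a [curve_band()].
#' @return A list of class `coverage_summary`: `prop_positive` (fraction of
#'   grid points with lower limit > 0), `prop_negative` (upper limit < 0),
#'   `prop_nonzero` (their sum), `n_grid`, `kind`, and `direction_class`
#'   (one of `"positive-only"`, `"negative-only"`, `"mixed"`, `"none"`).
#' @export
nonzero_coverage <- function(band) {
  stopifnot(inherits(band, "curve_band"))
  J <- length(band$grid)
  npos <- sum(band$lower > 0)
  nneg <- sum(band$upper < 0)
  dir <- if (npos > 0 && nneg > 0) "mixed"
         else if (npos > 0) "positive-only"
         else if (nneg > 0) "negative-only"
         else "none"
  structure(list(prop_positive = npos / J, prop_negative = nneg / J,
                 prop_nonzero = (npos + nneg) / J, n_grid = J,
                 kind = band$kind, direction_class = dir),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> kind '%s': non-zero %.3f (positive %.3f, negative %.3f) over %d points [%s]\n",
              x$kind, x$prop_nonzero, x$prop_positive, x$prop_negative,
              x$n_grid, x$direction_class))
  invisible(x)
}

#' One-sided exact binomial test of a coverage proportion
#'
#' Tests whether an observed non-zero-coverage proportion over `J` grid
#' points exceeds a design-informed null proportion `p0`, via the exact
#' binomial upper tail `P(X >= k)` with `X ~ Binomial(J, p0)` and
#' `k = ceiling(prop * J)` (the smallest count consistent with the observed
#' proportion).  Grid points are treated as exchangeable trials; temporal
#' dependence of the underlying curve makes the test approximate, which the
#' returned object records.
#'
#' @param prop observed proportion in `[0, 1]` (a multiple of `1/J` when it
#'   comes from [nonzero_coverage()]).
#' @param J number of grid points.
#' @param p0 null proportion in (0, 1); 0.5 for the condition curves of a
#'   half-on/half-off block design, 0.14 for the condition difference.
#' @return The one-sided p-value, with attribute `"note"` flagging the
#'   independence approximation.
#' @export
proportion_test <- function(prop, J, p0) {
  if (!is.finite(prop) || prop < 0 || prop > 1)
    stop("prop must lie in [0, 1]")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie in (0, 1)")
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1")
  k <- ceiling(prop * J - 1e-9)
  p <- if (k <= 0L) 1 else stats::pbinom(k - 1L, J, p0, lower.tail = FALSE)
  attr(p, "note") <- "exact binomial over grid points; temporal dependence makes this approximate"
  p
}

#' Multiplicity correction with significance flags
#'
#' Benjamini-Yekutieli step-up false-discovery-rate control (valid under
#' dependence) or the Bonferroni family-wise-error bound; the
#' Benjamini-Hochberg step-up is available as an option.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param method `"BY"` (default), `"bonferroni"`, or `"BH"`.
#' @param alpha significance threshold. Default 0.05.
#' @return Data frame with columns `p_raw`, `p_adjusted`, `significant`
#'   and attribute `method`.
#' @export
adjust_multiplicity <- function(p_values, method = c("BY", "bonferroni", "BH"),
                                alpha = 0.05) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values,
                         method = c(BY = "BY", bonferroni = "bonferroni",
                                    BH = "BH")[[method]])
  sig <- if (method == "bonferroni") p_values < alpha / length(p_values)
         else adj <= alpha
  out <- data.frame(p_raw = p_values, p_adjusted = adj, significant = sig)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}

#' Gate difference tests on reference-condition significance
#'
#' Condition-difference significance is evaluated only for region pairs that
#' already show a significant association under the reference condition:
#' pairs failing the gate are excluded from the difference multiplicity
#' family before correction (default), or flagged after a full-family
#' correction when `gate_before = FALSE`.
#'
#' @param reference_significant logical vector: per-pair significance of the
#'   reference-condition curve.
#' @param diff_pvalues raw difference p-values, aligned with
#'   `reference_significant`.
#' @param method,alpha passed to [adjust_multiplicity()].
#' @param gate_before restrict the family before correction (default) or
#'   gate the flags after a full-family correction.
#' @return Data frame with `p_raw`, `p_adjusted` (NA for gated-out pairs
#'   when `gate_before`), `gated` and `significant`.
#' @export
gate_difference <- function(reference_significant, diff_pvalues,
                            method = "BY", alpha = 0.05,
                            gate_before = TRUE) {
  if (length(reference_significant) != length(diff_pvalues))
    stop("misaligned inputs: reference flags and difference p-values differ in length")
  m <- length(diff_pvalues)
  gated <- as.logical(reference_significant)
  out <- data.frame(p_raw = diff_pvalues, p_adjusted = NA_real_,
                    gated = gated, significant = FALSE)
  if (gate_before) {
    if (any(gated)) {
      adj <- adjust_multiplicity(diff_pvalues[gated], method, alpha)
      out$p_adjusted[gated] <- adj$p_adjusted
      out$significant[gated] <- adj$significant
    }
  } else {
    adj <- adjust_multiplicity(diff_pvalues, method, alpha)
    out$p_adjusted <- adj$p_adjusted
    out$significant <- adj$significant & gated
  }
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  out
}

#' Network-block summary of per-pair significance
#'
#' Aggregates per-pair significance flags into a symmetric network-by-network
#' matrix whose entry (p, q) is the percentage of significant pairs among all
#' pairs with one region in network p and the other in network q (the
#' diagonal holds within-network percentages).
#'
#' @param pairs data frame with columns `region_a`, `region_b` (as from
#'   [enumerate_pairs()]).
#' @param significant logical vector aligned with `pairs`.
#' @param network_map named character vector mapping every region to one
#'   network (see [read_network_map()]).
#' @return A list of class `network_block_matrix` with `percent_significant`
#'   (square matrix), `n_pairs` and `n_significant` count matrices.
#' @export
network_summary <- function(pairs, significant, network_map) {
  if (nrow(pairs) != length(significant))
    stop("pairs and significance flags differ in length")
  regs <- unique(c(pairs$region_a, pairs$region_b))
  unmapped <- setdiff(regs, names(network_map))
  if (length(unmapped))
    stop("region(s) without a network assignment: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  nets <- sort(unique(unname(network_map[regs])))
  na_ <- factor(network_map[pairs$region_a], levels = nets)
  nb_ <- factor(network_map[pairs$region_b], levels = nets)
  lo <- pmin(as.integer(na_), as.integer(nb_))
  hi <- pmax(as.integer(na_), as.integer(nb_))
  k <- length(nets)
  n_pairs <- n_sig <- matrix(0L, k, k, dimnames = list(nets, nets))
  for (i in seq_along(lo)) {
    n_pairs[lo[i], hi[i]] <- n_pairs[lo[i], hi[i]] + 1L
    if (significant[i]) n_sig[lo[i], hi[i]] <- n_sig[lo[i], hi[i]] + 1L
  }
  n_pairs <- n_pairs + t(n_pairs) - diag(diag(n_pairs))
  n_sig <- n_sig + t(n_sig) - diag(diag(n_sig))
  pct <- ifelse(n_pairs > 0, 100 * n_sig / n_pairs, NA_real_)
  structure(list(networks = nets, percent_significant = pct,
                 n_pairs = n_pairs, n_significant = n_sig),
            class = "network_block_matrix")
}

#' @export
print.network_block_matrix <- function(x, ...) {
  cat("<network_block_matrix> percent significant pairs per network block:\n")
  print(round(x$percent_significant, 1))
  invisible(x)
}

#' Coverage summary and tests for one pair's curve set
#'
#' Convenience wrapper: non-zero coverage and the design-informed one-sided
#' binomial p-value for each of the three curves of one region pair.  For
#' the condition curves the coverage is tested against `null_condition`; for
#' the difference curve the positive and negative coverages are tested
#' separately against `null_difference` and combined as twice the smaller
#' one-sided p, capped at 1 (signed difference classes are reported).
#'
#' @param curves named list of three [curve_band()]s as returned by
#'   [predict_curves()].
#' @param null_condition null coverage proportion for the condition curves.
#'   Default 0.5.
#' @param null_difference null coverage proportion for the difference curve.
#'   Default 0.14.
#' @return Data frame with one row per curve: `kind`, `prop_nonzero`,
#'   `prop_positive`, `prop_negative`, `direction_class`, `p_value`.
#' @export
summarize_pair_curves <- function(curves, null_condition = 0.5,
                                  null_difference = 0.14) {
  rows <- lapply(names(curves), function(kind) {
    cv <- nonzero_coverage(curves[[kind]])
    if (kind == "diff") {
      pp <- proportion_test(cv$prop_positive, cv$n_grid, null_difference)
      pn <- proportion_test(cv$prop_negative, cv$n_grid, null_difference)
      p <- min(1, 2 * min(pp, pn))
    } else {
      p <- proportion_test(cv$prop_nonzero, cv$n_grid, null_condition)
    }
    data.frame(kind = kind, prop_nonzero = cv$prop_nonzero,
               prop_positive = cv$prop_positive,
               prop_negative = cv$prop_negative,
               direction_class = cv$direction_class,
               p_value = as.numeric(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
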