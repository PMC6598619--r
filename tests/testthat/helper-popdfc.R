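# Shared fixtures, all built in code.

# band on J points: whole band above zero at the first n_pos points, below
# zero at the next n_neg, straddling zero elsewhere
make_band <- function(J, n_pos, n_neg = 0L, kind = "B") {
  lower <- rep(-0.1, J); upper <- rep(0.1, J)
  if (n_pos > 0L) { lower[seq_len(n_pos)] <- 0.05; upper[seq_len(n_pos)] <- 0.3 }
  if (n_neg > 0L) {
    i <- n_pos + seq_len(n_neg)
    lower[i] <- -0.3; upper[i] <- -0.05
  }
  curve_band(seq_len(J), (lower + upper) / 2, lower, upper, kind = kind)
}

# flat-curve synthetic spec (identical conditions unless stated)
flat_spec <- function(seed, level = 0.3, n_subjects = 8L, ...) {
  f <- local({ lv <- level; function(t) rep(lv, length(t)) })
  synthetic_spec(n_subjects = n_subjects, seed = seed,
                 z_curve_reference = f, z_curve_alternative = f, ...)
}

# balanced population-model frame on an explicit grid with given cell means
balanced_frame <- function(grid, n_subj = 3L, n_scan = 2L,
                           mean_ref = 0.2, mean_alt = 0.5) {
  d <- expand.grid(subject_id = paste0("s", seq_len(n_subj)),
                   scan_index = seq_len(n_scan),
                   condition = c("B", "G"), t = grid,
                   stringsAsFactors = FALSE)
  d$z <- ifelse(d$condition == "B", mean_ref, mean_alt)
  d
}
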