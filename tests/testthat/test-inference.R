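test_that("non-zero coverage splits the grid by band side", {
  J <- 105L
  b_all <- make_band(J, J)
  cv <- nonzero_coverage(b_all)
  expect_equal(cv$prop_nonzero, 1.0)
  expect_equal(cv$direction_class, "positive-only")

  cv0 <- nonzero_coverage(make_band(J, 0L))
  expect_equal(cv0$prop_nonzero, 0.0)
  expect_equal(cv0$direction_class, "none")

  # the definitional worked example: 84 of 105 points excluded -> 0.8
  cv84 <- nonzero_coverage(make_band(J, 84L))
  expect_equal(cv84$prop_nonzero, 0.8)

  # signed split and the partition invariant
  cvm <- nonzero_coverage(make_band(J, 40L, 20L))
  expect_equal(cvm$direction_class, "mixed")
  expect_equal(cvm$prop_positive + cvm$prop_negative, cvm$prop_nonzero)
  straddle <- 1 - cvm$prop_nonzero
  expect_equal(cvm$prop_positive + cvm$prop_negative + straddle, 1,
               tolerance = 1e-15)
})

test_that("proportion test equals brute-force binomial enumeration for small grids", {
  brute <- function(k, J, p0) sum(dbinom(k:J, J, p0))
  for (J in c(5L, 12L, 30L)) {
    for (p0 in c(0.14, 0.5, 0.8)) {
      for (k in c(0L, 1L, J %/% 2L, J)) {
        p <- proportion_test(k / J, J, p0)
        expect_equal(as.numeric(p),
                     if (k == 0L) 1 else brute(k, J, p0),
                     tolerance = 1e-12)
      }
    }
  }
  # closed-form tail at full coverage
  expect_equal(as.numeric(proportion_test(1, 105, 0.5)), 0.5^105)
  # full tail at zero coverage
  expect_equal(as.numeric(proportion_test(0, 105, 0.14)), 1)
  # observed proportion at the null itself sits near the tail median
  expect_gte(as.numeric(proportion_test(0.14, 105, 0.14)), 0.4)
  expect_error(proportion_test(1.2, 105, 0.5), "\\[0, 1\\]")
  expect_error(proportion_test(0.5, 105, 0), "p0")
})

test_that("multiplicity correction: thresholds, monotonicity and method relations", {
  # m = 1: both methods flag iff p < alpha
  for (m in c("BY", "bonferroni"))
    expect_identical(adjust_multiplicity(0.04, m)$significant, TRUE)
  expect_identical(adjust_multiplicity(0.06, "BY")$significant, FALSE)

  # Bonferroni threshold arithmetic at the full pair count
  m <- 30628L
  p <- c(1e-6, rep(0.5, 9))
  expect_true(adjust_multiplicity(c(p, numeric(0)), "bonferroni",
                                  alpha = 0.05)$significant[1] ||
                1e-6 >= 0.05 / m)  # guard in case family is length 10
  # direct threshold: within a family of m tests, p = 1e-6 < .05/30628
  pv <- c(1e-6, runif(m - 1L, 0.2, 1))
  out <- adjust_multiplicity(pv, "bonferroni")
  expect_true(out$significant[1])
  pv2 <- pv; pv2[1] <- 1.7e-6  # just above .05/30628 ~ 1.63e-6
  expect_false(adjust_multiplicity(pv2, "bonferroni")$significant[1])

  # adjusted values monotone in raw p
  set.seed(12)
  pr <- runif(100)
  adj <- adjust_multiplicity(pr, "BY")$p_adjusted
  expect_true(all(diff(adj[order(pr)]) >= -1e-12))

  # step-up dominance relations on random p-value sets: BH flags contain
  # Bonferroni flags, and BY flags contain Bonferroni flags taken at the
  # harmonic-corrected level alpha / c(m)
  set.seed(13)
  ok_bh <- ok_by <- TRUE
  for (i in 1:1000) {
    m_ <- sample(5:80, 1)
    pv <- runif(m_)^sample(1:3, 1)
    bh <- adjust_multiplicity(pv, "BH")$significant
    by <- adjust_multiplicity(pv, "BY")$significant
    bf <- adjust_multiplicity(pv, "bonferroni")$significant
    cm <- sum(1 / seq_len(m_))
    bf_harm <- pv < 0.05 / (m_ * cm)
    ok_bh <- ok_bh && all(bh[bf])
    ok_by <- ok_by && all(by[bf_harm])
  }
  expect_true(ok_bh)
  expect_true(ok_by)
})

test_that("reference-condition gating restricts the difference family", {
  set.seed(14)
  p <- runif(40)
  # reference flag false -> difference flag false regardless of p
  g <- gate_difference(rep(FALSE, 40), p)
  expect_false(any(g$significant))
  # all reference flags true -> gating is the identity on the family
  g2 <- gate_difference(rep(TRUE, 40), p)
  a2 <- adjust_multiplicity(p, "BY")
  expect_identical(g2$significant, a2$significant)
  expect_equal(g2$p_adjusted, a2$p_adjusted)
  # restricting the family weakly increases the BY-significant set
  for (i in 1:50) {
    pv <- runif(60)^2
    keep <- runif(60) < 0.5
    gated <- gate_difference(keep, pv)
    full <- adjust_multiplicity(pv, "BY")
    expect_gte(sum(gated$significant),
               sum(full$significant & keep))
  }
  expect_error(gate_difference(c(TRUE, FALSE), runif(3)), "misaligned")
})

test_that("network block matrix counts pairs per block", {
  nm <- c(a1 = "N1", a2 = "N1", b1 = "N2", b2 = "N2")
  pairs <- enumerate_pairs(names(nm))
  # one of the four between-network pairs significant -> 25%
  sig <- pairs$region_a == "a1" & pairs$region_b == "b1"
  nb <- network_summary(pairs, sig, nm)
  expect_equal(nb$percent_significant["N1", "N2"], 25.0)
  expect_equal(nb$n_pairs["N1", "N2"], 4L)
  expect_equal(nb$percent_significant["N1", "N1"], 0.0)
  # all / none significant
  expect_true(all(network_summary(pairs, rep(TRUE, nrow(pairs)),
                                  nm)$percent_significant == 100))
  expect_true(all(network_summary(pairs, rep(FALSE, nrow(pairs)),
                                  nm)$percent_significant == 0))
  expect_error(network_summary(pairs, sig, nm[-1]), "without a network")
})

test_that("per-pair curve summaries use the design-informed nulls", {
  J <- 105L
  curves <- list(B = make_band(J, 84L, kind = "B"),
                 G = make_band(J, 0L, kind = "G"),
                 diff = make_band(J, 10L, 20L, kind = "diff"))
  sm <- summarize_pair_curves(curves)
  expect_equal(sm$prop_nonzero, c(0.8, 0, 30 / 105))
  # condition curves tested against 0.5
  expect_equal(sm$p_value[1],
               as.numeric(proportion_test(0.8, J, 0.5)))
  # difference: two one-sided tests at 0.14, smaller doubled, capped at 1
  pp <- as.numeric(proportion_test(10 / J, J, 0.14))
  pn <- as.numeric(proportion_test(20 / J, J, 0.14))
  expect_equal(sm$p_value[3], min(1, 2 * min(pp, pn)))
})
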