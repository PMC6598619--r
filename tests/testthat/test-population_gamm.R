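test_that("O'Sullivan basis has the stated dimensions and spans cubic splines", {
  grid <- dfc_grid(125, 20)
  b <- build_osullivan_basis(grid, 40)
  expect_equal(dim(b$Z), c(105L, 40L))
  expect_error(build_osullivan_basis(1:20, 40), "under-determined")

  # a straight line lies in the penalty null space: projecting it on
  # [1, t, Z] leaves residual < 1e-8 and its Z-part carries nothing
  t01 <- b$t01
  C <- cbind(1, t01, b$Z)
  line <- 2 - 3 * t01
  res <- line - C %*% solve(crossprod(C), crossprod(C, line))
  expect_lt(max(abs(res)), 1e-8)

  # an arbitrary cubic spline on the knots is reproduced exactly
  set.seed(5)
  spl <- splines::splineDesign(b$all_knots, t01, ord = 4) %*% rnorm(42)
  res2 <- spl - C %*% solve(crossprod(C), crossprod(C, spl))
  expect_lt(max(abs(res2)), 1e-8)

  # penalized fit of sin(2*pi*t) at small lambda: max error < 0.01
  y <- sin(2 * pi * t01)
  lam <- 1e-8
  pen <- diag(c(0, 0, rep(lam, 40)))
  co <- solve(crossprod(C) + pen, crossprod(C, y))
  expect_lt(max(abs(C %*% co - y)), 0.01)
})

test_that("dFCM coefficients at fixed variance components equal the penalized normal equations", {
  # tiny instance: 2 subjects, J = 20, K = 5; oracle = direct dense solve
  grid <- 1:20
  basis <- build_osullivan_basis(grid, 5)
  dat <- expand.grid(subject_id = c("s1", "s2"), scan_index = 1:2,
                     condition = c("B", "G"), t = grid,
                     stringsAsFactors = FALSE)
  set.seed(77)
  dat$z <- rnorm(nrow(dat), 0.3, 0.3)
  vc <- list(eps = 0.04, u = 0.5, w = 0.3, b = 0.01, a = 0.005)
  fit <- fit_dfcm(dat, basis = basis, var_comp = vc)

  t01 <- (dat$t - 1) / 19
  d <- as.numeric(dat$condition == "G")
  Z <- evaluate_basis(basis, dat$t)$Z
  X <- cbind(1, t01, d, d * t01)
  ind <- function(f) {
    lev <- sort(unique(f))
    m <- 1 * outer(f, lev, "==")
    colnames(m) <- lev
    m
  }
  Zb <- ind(dat$subject_id)
  Za <- ind(paste(dat$subject_id, dat$scan_index, dat$condition, sep = "."))
  C <- cbind(X, Z, Z * d, Zb, Za)
  pen <- c(rep(0, 4), rep(vc$eps / vc$u, 5), rep(vc$eps / vc$w, 5),
           rep(vc$eps / vc$b, ncol(Zb)), rep(vc$eps / vc$a, ncol(Za)))
  co <- solve(crossprod(C) + diag(pen), crossprod(C, dat$z))

  expect_equal(c(fit$beta0, fit$beta1, fit$gamma0, fit$gamma1),
               co[1:4], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(fit$u), co[5:9], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(fit$w), co[10:14], tolerance = 1e-8,
               ignore_attr = TRUE)
  # fitted values agree too (covers the random intercepts regardless of
  # level ordering)
  fitted_pkg <- X %*% c(fit$beta0, fit$beta1, fit$gamma0, fit$gamma1) +
    Z %*% fit$u + (Z * d) %*% fit$w +
    Zb %*% fit$b[colnames(Zb)] + Za %*% fit$a[colnames(Za)]
  expect_equal(drop(fitted_pkg), drop(C %*% co), tolerance = 1e-8)
})

test_that("REML is invariant to a constant response shift absorbed by the intercept", {
  sp <- flat_spec(21, n_subjects = 4L)
  dat <- simulate_dfcm_data(sp, grid = dfc_grid(60, 20), sigma_eps = 0.2)
  f1 <- fit_dfcm(dat, K = 10)
  dat2 <- dat; dat2$z <- dat$z + 0.7
  f2 <- fit_dfcm(dat2, K = 10)
  expect_equal(f2$beta0 - f1$beta0, 0.7, tolerance = 1e-8)
  expect_equal(f2$beta1, f1$beta1, tolerance = 1e-8)
  expect_equal(f2$u, f1$u, tolerance = 1e-8)
  expect_equal(f2$sigma2, f1$sigma2, tolerance = 1e-8)
  expect_equal(f2$reml_value, f1$reml_value, tolerance = 1e-6)
})

test_that("lambda is the stored ratio of error to smooth variance", {
  sp <- synthetic_spec(n_subjects = 6, seed = 33)
  dat <- simulate_dfcm_data(sp, grid = dfc_grid(70, 20), sigma_eps = 0.2)
  fit <- fit_dfcm(dat, K = 20)
  expect_true(fit$converged)
  if (is.finite(fit$lambda))
    expect_equal(fit$lambda, fit$sigma2[["eps"]] / fit$sigma2[["u"]],
                 tolerance = 1e-10)
})

test_that("degenerate constant truth is recovered without spurious wiggle", {
  sp <- flat_spec(44, level = 0.3, n_subjects = 8L,
                  sigma_b0 = 0, sigma_a0 = 0)
  dat <- simulate_dfcm_data(sp, grid = dfc_grid(70, 20), sigma_eps = 0.15)
  fit <- fit_dfcm(dat, K = 20)
  cb <- predict_curves(fit)
  expect_lt(abs(fit$beta0 - 0.3), 0.05)
  for (k in c("B", "G"))
    expect_lt(max(abs(cb[[k]]$estimate - mean(cb[[k]]$estimate))), 0.05)
})

test_that("static model matches the dynamic model with smooth and slope removed", {
  sp <- synthetic_spec(n_subjects = 5, seed = 55)
  dat <- simulate_dfcm_data(sp, grid = dfc_grid(60, 20), sigma_eps = 0.25)
  sf <- fit_sfcm(dat)
  nested <- fit_dfcm(dat, include_smooth = FALSE, include_slope = FALSE)
  expect_equal(sf$coef["beta0", "estimate"], nested$beta0, tolerance = 1e-6)
  expect_equal(sf$coef["gamma0", "estimate"], nested$gamma0,
               tolerance = 1e-6)
})

test_that("static model REML agrees with the independent lme4 fit", {
  sp <- synthetic_spec(n_subjects = 6, seed = 66)
  dat <- simulate_dfcm_data(sp, grid = dfc_grid(60, 20), sigma_eps = 0.25)
  sf <- fit_sfcm(dat)
  dat$cell <- interaction(dat$subject_id, dat$scan_index, dat$condition)
  lf <- lme4::lmer(z ~ condition + (1 | subject_id) + (1 | cell),
                   data = dat, REML = TRUE)
  co <- summary(lf)$coefficients
  expect_equal(sf$coef$estimate, unname(co[, "Estimate"]),
               tolerance = 1e-4)
  expect_equal(sf$coef$se, unname(co[, "Std. Error"]), tolerance = 1e-3)
  expect_equal(unname(sf$sigma2[["eps"]]), lme4::getME(lf, "sigma")^2,
               tolerance = 1e-3)
})

test_that("balanced noiseless data give the cell means exactly", {
  dat <- balanced_frame(dfc_grid(70, 20), mean_ref = 0.2, mean_alt = 0.5)
  sf <- fit_sfcm(dat)
  expect_equal(sf$coef["beta0", "estimate"], 0.2, tolerance = 1e-6)
  expect_equal(sf$coef["gamma0", "estimate"], 0.3, tolerance = 1e-6)
})

test_that("static-model test of a null condition effect holds its size", {
  # gamma0 = 0 truth: two-sided test at alpha = .05 rejects in 5% +/- 3%
  rej <- vapply(1:200, function(i) {
    sp <- flat_spec(7000 + i, n_subjects = 12L)
    dat <- simulate_dfcm_data(sp, grid = dfc_grid(50, 20), sigma_eps = 0.2)
    fit_sfcm(dat)$coef["gamma0", "p"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("predicted curves obey the difference identity and band algebra", {
  sp <- synthetic_spec(n_subjects = 5, seed = 88)
  dat <- simulate_dfcm_data(sp, grid = dfc_grid(60, 20), sigma_eps = 0.2)
  fit <- fit_dfcm(dat, K = 15)
  cb95 <- predict_curves(fit, level = 0.95)
  # c(t) = f_G(t) - f_B(t) exactly
  expect_equal(cb95$diff$estimate, cb95$G$estimate - cb95$B$estimate,
               tolerance = 1e-12)
  expect_true(all(cb95$B$lower <= cb95$B$estimate &
                    cb95$B$estimate <= cb95$B$upper))
  # 95% band everywhere at least as wide as the 80% band
  cb80 <- predict_curves(fit, level = 0.80)
  for (k in names(cb95))
    expect_true(all(cb95[[k]]$upper - cb95[[k]]$lower >=
                      cb80[[k]]$upper - cb80[[k]]$lower - 1e-12))
  # refusal on a non-converged fit
  bad <- fit; bad$converged <- FALSE
  expect_error(predict_curves(bad), "non-converged")
})

test_that("difference band covers zero under a null difference at its measured rate", {
  # oracle value 0.93 (100-sim Monte-Carlo at these conditions); 50 sims
  # here, tolerance 3 MC standard errors (sd per sim ~ 0.20)
  cz <- vapply(1:50, function(i) {
    sp <- flat_spec(5000 + i, level = 0.4)
    dat <- simulate_dfcm_data(sp, grid = dfc_grid(70, 20), sigma_eps = 0.2)
    cb <- predict_curves(fit_dfcm(dat, K = 40))
    mean(cb$diff$lower <= 0 & 0 <= cb$diff$upper)
  }, numeric(1))
  expect_lt(abs(mean(cz) - 0.93), 3 * 0.20 / sqrt(50))
})
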