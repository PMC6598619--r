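#' O'Sullivan penalized-spline basis in mixed-model form
#'
#' Builds a cubic B-spline basis on quantile knots over the (rescaled) dFC
#' time grid with the integrated-squared-second-derivative roughness penalty,
#' then rotates it to the mixed-model parameterization: the penalty null
#' space (constant and linear trend) is carried by the fixed part `[1, t]`,
#' and the random part `Z` is whitened so the roughness penalty on its
#' coefficients is the identity.  `K` counts the spline terms, i.e. the
#' number of columns of `Z`; `K - 2` interior knots are placed at quantiles
#' of the grid so that the cubic basis dimension is `K + 2` and removing the
#' 2-dimensional null space leaves exactly `K` penalized directions.
#'
#' @param grid numeric vector of J distinct time points (the dFC grid);
#'   rescaled internally to `[0, 1]`.
#' @param K number of spline terms (default 40); requires `J > K + 4`.
#' @return An object of class `osullivan_basis` with elements `grid`, `t01`
#'   (rescaled grid), `Z` (J x K), `K`, `knots` (interior, rescaled), and
#'   the rotation needed to evaluate the basis at new points.
#' @export
build_osullivan_basis <- function(grid, K = 40L) {
  K <- as.integer(K)
  grid <- sort(unique(as.numeric(grid)))
  J <- length(grid)
  if (K < 3L) stop("K must be >= 3")
  if (J <= K + 4L)
    stop(sprintf("under-determined basis: need J > K + 4 (J = %d, K = %d)",
                 J, K))
  rng <- range(grid)
  t01 <- (grid - rng[1L]) / diff(rng)
  int_knots <- stats::quantile(t01, probs = seq_len(K - 2L) / (K - 1L),
                               names = FALSE, type = 7)
  all_knots <- c(rep(0, 4L), int_knots, rep(1, 4L))
  B <- splines::splineDesign(all_knots, t01, ord = 4L)
  # exact roughness penalty: 3-point Gauss-Legendre per inter-knot interval
  # (B'' products are quartic, degree-5-exact quadrature suffices)
  brk <- unique(all_knots)
  h <- diff(brk)
  gl_x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gl_w <- c(5, 8, 5) / 9
  qx <- as.vector(outer(gl_x, rep(1, length(h))) *
                    rep(h / 2, each = 3L) + rep((brk[-1L] + brk[-length(brk)]) / 2, each = 3L))
  qw <- as.vector(outer(gl_w, h / 2))
  D2 <- splines::splineDesign(all_knots, qx, ord = 4L, derivs = 2L)
  Omega <- crossprod(D2, qw * D2)
  ev <- eigen((Omega + t(Omega)) / 2, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  if (sum(pos) != K)
    stop(sprintf("penalty rank %d != K = %d", sum(pos), K))
  U <- ev$vectors[, pos, drop = FALSE]
  dinv <- 1 / sqrt(ev$values[pos])
  Z <- B %*% U %*% diag(dinv, K)
  structure(list(grid = grid, t01 = t01, Z = Z, K = K,
                 knots = int_knots, all_knots = all_knots,
                 rotation = U %*% diag(dinv, K), range = rng),
            class = "osullivan_basis")
}

#' Evaluate an O'Sullivan basis at new time points
#'
#' @param basis an [build_osullivan_basis()] object.
#' @param t new time points on the original grid scale.
#' @return List with `t01` (rescaled points) and `Z` (length(t) x K).
#' @export
evaluate_basis <- function(basis, t) {
  t01 <- (as.numeric(t) - basis$range[1L]) / diff(basis$range)
  if (any(t01 < -1e-9 | t01 > 1 + 1e-9))
    stop("evaluation points outside the basis range")
  t01 <- pmin(1, pmax(0, t01))
  B <- splines::splineDesign(basis$all_knots, t01, ord = 4L)
  list(t01 = t01, Z = B %*% basis$rotation)
}

#' @export
print.osullivan_basis <- function(x, ...) {
  cat(sprintf("<osullivan_basis> %d grid points, %d spline terms, %d interior knots on [%g, %g]\n",
              length(x$grid), x$K, length(x$knots), x$range[1L], x$range[2L]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# REML engine for Gaussian mixed models with isotropic random-effect blocks:
#   y = X beta + sum_g Z_g u_g + eps,  u_g ~ N(0, sigma_g^2 I),
#   eps ~ N(0, sigma_eps^2 I).
# The restricted likelihood is profiled over sigma_eps^2 and optimized over
# the log variance ratios lambda_g = sigma_g^2 / sigma_eps^2 (quasi-Newton,
# bounded so boundary solutions sigma_g^2 -> 0 are representable).
# All objective evaluations work from fixed crossproducts via Woodbury.
# ---------------------------------------------------------------------------
reml_engine <- function(y, X, blocks, log_ratio = NULL,
                        lower = -25, upper = 15, reltol = 1e-8) {
  N <- length(y); p <- ncol(X)
  Z <- do.call(cbind, blocks)
  qg <- vapply(blocks, ncol, integer(1L))
  G <- length(qg); q <- sum(qg)
  gidx <- rep.int(seq_len(G), qg)
  XtX <- crossprod(X); Xty <- drop(crossprod(X, y))
  ZtZ <- crossprod(Z); ZtX <- crossprod(Z, X); Zty <- drop(crossprod(Z, y))
  yty <- sum(y * y)

  eval_at <- function(th) {
    s <- exp(th[gidx] / 2)                       # D^{1/2} diagonal
    A <- (s %o% s) * ZtZ
    diag(A) <- diag(A) + 1
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    WX <- s * ZtX; Wy <- s * Zty
    AiWX <- backsolve(cA, forwardsolve(t(cA), WX))
    AiWy <- backsolve(cA, forwardsolve(t(cA), Wy))
    XtViX <- XtX - crossprod(WX, AiWX)
    XtViy <- Xty - drop(crossprod(WX, AiWy))
    ytViy <- yty - sum(Wy * AiWy)
    cXX <- tryCatch(chol((XtViX + t(XtViX)) / 2), error = function(e) NULL)
    if (is.null(cXX)) return(NULL)
    beta <- backsolve(cXX, forwardsolve(t(cXX), XtViy))
    rss <- ytViy - sum(XtViy * beta)
    if (!is.finite(rss)) return(NULL)
    # exact-fit degeneracy: floor the profiled residual sum of squares so
    # interpolating data (rss -> 0) stays evaluable
    rss <- max(rss, 1e-12 * (yty / N + 1))
    list(m2reml = 2 * sum(log(diag(cA))) + 2 * sum(log(diag(cXX))) +
           (N - p) * log(rss),
         rss = rss)
  }
  obj <- function(th) {
    e <- eval_at(th)
    if (is.null(e)) 1e10 else e$m2reml
  }

  if (is.null(log_ratio)) {
    # derivative-free search first (the profiled surface can be flat near a
    # variance boundary and trap a gradient method there), then a bounded
    # quasi-Newton polish
    if (G >= 2L) {
      nm <- stats::optim(rep(0, G), obj, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
      start <- pmin(pmax(nm$par, lower), upper)
    } else {
      nm <- NULL
      start <- 0
    }
    opt <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = reltol / .Machine$double.eps))
    th <- opt$par
    converged <- opt$convergence == 0L
    if (!is.null(nm) && nm$value < opt$value) {
      th <- pmin(pmax(nm$par, lower), upper)
      converged <- nm$convergence == 0L
    }
  } else {
    th <- log_ratio
    converged <- TRUE
  }
  fin <- eval_at(th)
  if (is.null(fin))
    stop("restricted likelihood not evaluable at the chosen variance components (singular design?)")
  sigma_eps2 <- fin$rss / (N - p)
  lambda_g <- exp(th)
  sigma_g2 <- lambda_g * sigma_eps2

  # mixed-model equations at the optimum: coefficients, BLUPs, and the
  # empirical-Bayes ("Bayesian") coefficient covariance
  M <- rbind(cbind(XtX, t(ZtX)),
             cbind(ZtX, ZtZ + diag(1 / lambda_g[gidx], q)))
  cM <- chol((M + t(M)) / 2)
  coef <- backsolve(cM, forwardsolve(t(cM), c(Xty, Zty)))
  coef_cov <- sigma_eps2 * chol2inv(cM)
  names(sigma_g2) <- names(blocks)
  ublocks <- split(coef[p + seq_len(q)], gidx)
  names(ublocks) <- names(blocks)
  for (g in seq_len(G))
    names(ublocks[[g]]) <- colnames(blocks[[g]])
  list(beta = coef[seq_len(p)], u = ublocks,
       sigma_eps2 = sigma_eps2, sigma_g2 = sigma_g2,
       log_ratio = th, at_lower = th <= lower + 1e-6,
       coef_cov = coef_cov, converged = converged,
       reml_value = -0.5 * fin$m2reml, n_obs = N, p = p, qg = qg)
}

# Assemble the model frame shared by dFCM and sFCM fits.
dfcm_frame <- function(data, reference = NULL) {
  need <- c("subject_id", "scan_index", "condition", "t", "z")
  if (!all(need %in% colnames(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(data$z))) stop("responses must be finite")
  conds <- sort(unique(as.character(data$condition)))
  if (length(conds) != 2L)
    stop("exactly two conditions are required, got: ",
         paste(conds, collapse = ", "))
  if (is.null(reference))
    reference <- if ("B" %in% conds) "B" else conds[1L]
  if (!reference %in% conds)
    stop("reference condition '", reference, "' not present")
  alternative <- setdiff(conds, reference)
  subj <- factor(data$subject_id)
  if (nlevels(subj) < 2L) stop("at least 2 subjects are required")
  cell <- factor(paste(data$subject_id, data$scan_index, data$condition,
                       sep = "."))
  grid <- sort(unique(data$t))
  list(d = as.numeric(data$condition == alternative),
       subj = subj, cell = cell, grid = grid,
       reference = reference, alternative = alternative)
}

indicator_matrix <- function(f) {
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Fit the dynamic functional connectivity mixed model (dFCM)
#'
#' Pools the subject-level Fisher-z dFC estimates of one region pair across
#' subjects, scans and both conditions, and fits
#' \deqn{z_{isd}(t) = \beta_0 + \beta_1 t + \sum_k u_k z_k(t)
#'   + d\,[\gamma_0 + \gamma_1 t + \sum_k w_k z_k(t)] + b_{i0} + a_{is0}
#'   + \varepsilon,}
#' where `d` indicates the alternative condition, `z_k` are the O'Sullivan
#' basis functions, `u_k ~ N(0, sigma_u^2)` is the shared smooth,
#' `w_k ~ N(0, sigma_w^2)` the condition-difference smooth, `b_i0` a subject
#' intercept and `a_is0` a nested (subject, scan, condition) intercept.  The
#' five variance components are estimated by REML (profiled restricted
#' log-likelihood over log variance ratios, quasi-Newton); coefficients are
#' the penalized generalized-least-squares solution at the optimum and the
#' random effects their BLUPs.  The smoothing parameter is
#' `lambda = sigma_eps^2 / sigma_u^2`.
#'
#' @param data data frame with columns `subject_id`, `scan_index`,
#'   `condition`, `t` (grid time), `z` (Fisher-z dFC response); each
#'   (subject, scan, condition) must contribute the full grid.
#' @param basis optional [build_osullivan_basis()] on the data's grid; built
#'   with `K` terms when `NULL`.
#' @param K number of spline terms when `basis` is `NULL`. Default 40.
#' @param reference reference condition label; defaults to `"B"` when
#'   present, else the lexicographically first label.
#' @param var_comp optional named list fixing the variance components
#'   (`eps`, `u`, `w`, `b`, `a`): skips REML and solves the penalized
#'   normal equations at those values.
#' @param include_smooth,include_slope internal switches that drop the
#'   spline terms / linear-trend columns, reducing the model to the static
#'   sFCM; used for nesting checks.
#' @return An object of class `dfcm_fit` with fixed effects `beta0`,
#'   `beta1`, `gamma0`, `gamma1`, spline coefficients `u`, `w`, random
#'   intercepts `b`, `a`, variance components `sigma2`, `lambda`,
#'   `coef_cov`, `converged`, `reml_value`, the basis and the grid.
#' @export
fit_dfcm <- function(data, basis = NULL, K = 40L, reference = NULL,
                     var_comp = NULL, include_smooth = TRUE,
                     include_slope = TRUE) {
  fr <- dfcm_frame(data, reference)
  tab <- table(fr$cell)
  if (length(unique(tab)) != 1L)
    stop("unbalanced grids: every (subject, scan, condition) must contribute the same number of rows")
  if (include_smooth) {
    if (is.null(basis)) basis <- build_osullivan_basis(fr$grid, K)
    if (!isTRUE(all.equal(basis$grid, fr$grid)))
      stop("basis grid does not match the data grid")
    ev <- evaluate_basis(basis, data$t)
    t01 <- ev$t01
    Zs <- ev$Z
  } else {
    rng <- range(fr$grid)
    t01 <- if (diff(rng) > 0) (data$t - rng[1L]) / diff(rng) else rep(0, nrow(data))
    Zs <- NULL
  }
  X <- if (include_slope) cbind(`(Intercept)` = 1, t = t01, d = fr$d,
                                `d:t` = fr$d * t01)
       else cbind(`(Intercept)` = 1, d = fr$d)
  blocks <- list()
  if (include_smooth) {
    colnames(Zs) <- paste0("z", seq_len(ncol(Zs)))
    blocks$u <- Zs
    blocks$w <- Zs * fr$d
  }
  blocks$b <- indicator_matrix(fr$subj)
  blocks$a <- indicator_matrix(fr$cell)

  log_ratio <- NULL
  if (!is.null(var_comp)) {
    want <- c(if (include_smooth) c("u", "w"), "b", "a")
    if (!all(c(want, "eps") %in% names(var_comp)))
      stop("var_comp must name: eps, ", paste(want, collapse = ", "))
    log_ratio <- log(pmax(unlist(var_comp[want]) / var_comp$eps, 1e-12))
  }
  fit <- reml_engine(data$z, X, blocks, log_ratio = log_ratio)
  if (!is.null(var_comp)) fit$sigma_eps2 <- var_comp$eps

  sg <- fit$sigma_g2
  sigma2 <- c(eps = fit$sigma_eps2,
              u = if (include_smooth) unname(sg["u"]) else 0,
              w = if (include_smooth) unname(sg["w"]) else 0,
              b0 = unname(sg["b"]), a0 = unname(sg["a"]))
  lambda <- if (include_smooth && !fit$at_lower[match("u", names(blocks))])
    sigma2[["eps"]] / sigma2[["u"]] else Inf
  structure(list(
    beta0 = unname(fit$beta[1L]),
    beta1 = if (include_slope) unname(fit$beta[2L]) else 0,
    gamma0 = unname(fit$beta[if (include_slope) 3L else 2L]),
    gamma1 = if (include_slope) unname(fit$beta[4L]) else 0,
    u = if (include_smooth) fit$u$u else numeric(0),
    w = if (include_smooth) fit$u$w else numeric(0),
    b = fit$u$b, a = fit$u$a,
    sigma2 = sigma2, lambda = lambda,
    coef_cov = fit$coef_cov, converged = fit$converged,
    reml_value = fit$reml_value, n_obs = fit$n_obs,
    p = fit$p, qg = fit$qg,
    include_smooth = include_smooth, include_slope = include_slope,
    basis = basis, grid = fr$grid,
    reference = fr$reference, alternative = fr$alternative),
    class = "dfcm_fit")
}

#' @export
print.dfcm_fit <- function(x, ...) {
  cat(sprintf("<dfcm_fit> %d obs, %d grid points, reference '%s' vs '%s'%s\n",
              x$n_obs, length(x$grid), x$reference, x$alternative,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  beta0 = %.4f, beta1 = %.4f, gamma0 = %.4f, gamma1 = %.4f\n",
              x$beta0, x$beta1, x$gamma0, x$gamma1))
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(x$sigma2), x$sigma2), collapse = ", "),
      sprintf("\n  lambda = %s\n",
              if (is.finite(x$lambda)) format(x$lambda, digits = 5) else "Inf"))
  invisible(x)
}

#' Fit the static functional connectivity mixed model (sFCM)
#'
#' The constant-connectivity counterpart of [fit_dfcm()]:
#' `z = beta0 + gamma0 d + b_i0 + a_is0 + eps`, REML variance components,
#' with Wald t statistics (`estimate / SE`) and two-sided p-values from the
#' large-sample normal reference for `beta0` and `gamma0`.
#'
#' @inheritParams fit_dfcm
#' @return An object of class `sfcm_fit` with a `coef` table (estimate,
#'   se, t, p), variance components, `converged` and `reml_value`.
#' @export
fit_sfcm <- function(data, reference = NULL) {
  fit <- fit_dfcm(data, reference = reference,
                  include_smooth = FALSE, include_slope = FALSE)
  est <- c(beta0 = fit$beta0, gamma0 = fit$gamma0)
  se <- sqrt(diag(fit$coef_cov)[1:2])
  tval <- est / se
  coef <- data.frame(estimate = est, se = se, t = tval,
                     p = 2 * stats::pnorm(-abs(tval)),
                     row.names = c("beta0", "gamma0"))
  structure(list(coef = coef, sigma2 = fit$sigma2[c("eps", "b0", "a0")],
                 b = fit$b, a = fit$a, converged = fit$converged,
                 reml_value = fit$reml_value,
                 reference = fit$reference, alternative = fit$alternative),
            class = "sfcm_fit")
}

#' @export
print.sfcm_fit <- function(x, ...) {
  cat(sprintf("<sfcm_fit> reference '%s' vs '%s'%s\n", x$reference,
              x$alternative, if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$coef, 5))
  invisible(x)
}

#' Construct a curve with a pointwise confidence band
#'
#' @param grid time grid.
#' @param estimate,lower,upper numeric vectors on the grid with
#'   `lower <= estimate <= upper` pointwise.
#' @param level band level in (0, 1).
#' @param kind label: the condition (e.g. `"B"`, `"G"`) or `"diff"`.
#' @return An object of class `curve_band`.
#' @export
curve_band <- function(grid, estimate, lower, upper, level = 0.95,
                       kind = "curve") {
  stopifnot(length(grid) == length(estimate),
            length(lower) == length(estimate),
            length(upper) == length(estimate))
  if (any(lower > estimate + 1e-12) || any(upper < estimate - 1e-12))
    stop("band must bracket the estimate pointwise")
  structure(list(grid = grid, estimate = estimate, lower = lower,
                 upper = upper, level = level, kind = kind),
            class = "curve_band")
}

#' @export
print.curve_band <- function(x, ...) {
  cat(sprintf("<curve_band> kind '%s', %d grid points, %g%% pointwise band\n",
              x$kind, length(x$grid), 100 * x$level))
  invisible(x)
}

#' Condition curves and their difference, with pointwise bands
#'
#' From a converged dFCM fit, computes the reference-condition curve
#' `f_B(t) = beta0 + beta1 t + sum u_k z_k(t)`, the alternative-condition
#' curve `f_G(t) = f_B(t) + gamma0 + gamma1 t + sum w_k z_k(t)` and the
#' difference `c(t) = f_G(t) - f_B(t)`, each with pointwise bands
#' `estimate +/- z_{1-(1-level)/2} SE`, where the SEs come from the
#' empirical-Bayes coefficient covariance conditional on the plugged-in
#' variance components.  The identity `c(t) = f_G(t) - f_B(t)` holds exactly
#' at every grid point.
#'
#' @param fit a converged [fit_dfcm()] object.
#' @param level pointwise band level. Default 0.95.
#' @return Named list of three [curve_band()]s: the reference condition,
#'   the alternative condition, and `diff`.
#' @export
predict_curves <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dfcm_fit"))
  if (!fit$converged)
    stop("refusing to predict from a non-converged fit; inspect variance components")
  J <- length(fit$grid)
  if (fit$include_smooth) {
    ev <- evaluate_basis(fit$basis, fit$grid)
    t01 <- ev$t01; Zs <- ev$Z
    Kq <- ncol(Zs)
  } else {
    rng <- range(fit$grid)
    t01 <- if (diff(rng) > 0) (fit$grid - rng[1L]) / diff(rng) else rep(0, J)
    Zs <- matrix(0, J, 0); Kq <- 0L
  }
  z0 <- matrix(0, J, Kq)
  if (fit$include_slope) {
    CB <- cbind(1, t01, 0, 0 * t01, Zs, z0)
    CG <- cbind(1, t01, 1, t01, Zs, Zs)
    Cc <- cbind(0, 0 * t01, 1, t01, z0, Zs)
  } else {
    CB <- cbind(1, 0, Zs, z0)
    CG <- cbind(1, 1, Zs, Zs)
    Cc <- cbind(0, 1, z0, Zs)
  }
  # coefficient covariance block for (fixed, u, w)
  nfu <- fit$p + 2L * Kq
  V <- fit$coef_cov[seq_len(nfu), seq_len(nfu), drop = FALSE]
  theta <- c(if (fit$include_slope) c(fit$beta0, fit$beta1, fit$gamma0, fit$gamma1)
             else c(fit$beta0, fit$gamma0),
             fit$u, fit$w)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  mk <- function(C, kind) {
    est <- drop(C %*% theta)
    se <- sqrt(pmax(0, rowSums((C %*% V) * C)))
    curve_band(fit$grid, est, est - zq * se, est + zq * se, level, kind)
  }
  out <- list(mk(CB, fit$reference), mk(CG, fit$alternative), mk(Cc, "diff"))
  names(out) <- c(fit$reference, fit$alternative, "diff")
  out
}
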