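## L0-penalized joint fit: closed-form per-gene solutions, keep/kill
## thresholding, and global search over the shared parameter delta.

#' Per-gene ordinary least squares coefficients on centered data
#'
#' \eqn{\beta_i^{(ols)} = (\tilde{X}^T\tilde{X})^{-1}\tilde{X}^T\tilde{y}_i
#' + \delta}: the unpenalized minimizer of each gene's quadratic given the
#' shared parameter. The delta-free part does not depend on \eqn{\delta}.
#'
#' @param cd centered data from [center_data()].
#' @param delta length-p numeric vector.
#' @return m x p matrix of coefficients.
#' @export
ols_betas <- function(cd, delta) {
  base <- ols_base(cd)
  sweep(base, 2L, delta, "+")
}

# delta-free part of the per-gene OLS solution (m x p)
ols_base <- function(cd) {
  (cd$y_tilde %*% cd$x_tilde) %*% xtx_inverse(cd$x_tilde)
}

# ||X~ beta||^2 per gene via the Cholesky factor of X~'X~
xb_sqnorm <- function(betas, x_tilde) {
  R <- chol(crossprod(x_tilde))
  rowSums((betas %*% t(R))^2)
}

#' Type-I keep-or-kill rule
#'
#' A gene keeps its OLS coefficient vector iff
#' \eqn{\frac{1}{2\sigma_i^2}\|\tilde{X}\beta_i^{(ols)}\|^2 \ge \lambda_i};
#' otherwise the whole vector is set to zero. Ties (statistic exactly equal
#' to the penalty) keep the gene: killing requires a strict inequality.
#'
#' @inheritParams ols_betas
#' @param variances length-m positive vector.
#' @param lambdas length-m penalties (a scalar is broadcast).
#' @return list with \code{selected} (logical m) and \code{beta} (m x p).
#' @export
type1_keep_rule <- function(cd, variances, lambdas, delta) {
  betas <- ols_betas(cd, delta)
  lambdas <- rep_len(lambdas, nrow(betas))
  stat <- xb_sqnorm(betas, cd$x_tilde) / (2 * variances)
  selected <- !(stat < lambdas)
  betas[!selected, ] <- 0
  list(selected = selected, beta = betas)
}

#' Profiled type-I objective as a function of delta
#'
#' \eqn{\sum_i \min\{\frac{1}{2\sigma_i^2}\|\tilde{X}\beta_i^{(ols)}(\delta)
#' \|^2,\ \lambda_i\}}: each gene contributes its quadratic while alive and
#' a flat \eqn{\lambda_i} once killed, making the objective piecewise
#' quadratic in \eqn{\delta}.
#'
#' @inheritParams type1_keep_rule
#' @return scalar objective value.
#' @export
type1_delta_objective <- function(cd, variances, lambdas, delta) {
  betas <- ols_betas(cd, delta)
  lambdas <- rep_len(lambdas, nrow(betas))
  stat <- xb_sqnorm(betas, cd$x_tilde) / (2 * variances)
  sum(pmin(stat, lambdas))
}

## One-dimensional piecewise-quadratic minimizer shared by both penalty
## types: minimize sum_i min(a_i (b_i + delta)^2, lambda_i).
## Grid over the span of the per-gene candidate minimizers {-b_i}, padded
## 10%, then golden-section refinement inside the best grid cell.
## Tie-break: a flat objective returns 0.
optimize_piecewise_1d <- function(a, b, lambdas, n_grid = 2001L) {
  obj <- function(d) sum(pmin(a * (b + d)^2, lambdas))
  lo <- min(-b); hi <- max(-b)
  width <- hi - lo
  if (width == 0) {
    cand <- lo
  } else {
    pad <- 0.1 * width
    grid <- seq(lo - pad, hi + pad, length.out = n_grid)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    bracket <- c(grid[max(1L, k - 1L)], grid[min(n_grid, k + 1L)])
    ref <- stats::optimize(obj, interval = bracket, tol = 1e-10)
    cand <- if (ref$objective < vals[k]) ref$minimum else grid[k]
  }
  best <- obj(cand)
  if (obj(0) <= best + 1e-12 * max(1, abs(best))) return(0)
  cand
}

#' Optimize the shared parameter for the type-I penalty
#'
#' Minimizes the profiled piecewise-quadratic objective over \eqn{\delta}.
#' For p = 1 an exhaustive grid (2001 points over the span of the per-gene
#' candidate minimizers, padded 10%) is refined by golden-section search;
#' for p = 2 a 201 x 201 tensor grid with a local Nelder-Mead polish; for
#' p > 2, seeded multi-start local optimization from per-gene candidates
#' (best objective wins, ties broken by smallest norm).
#'
#' @inheritParams type1_keep_rule
#' @param seed seed for the multi-start draws used when p > 2 (default 1).
#' @return length-p numeric delta.
#' @export
optimize_delta_type1 <- function(cd, variances, lambdas, seed = 1L) {
  base <- ols_base(cd)
  m <- nrow(base); p <- ncol(base)
  if (m < 1L) jde_stop_validation("empty gene set")
  lambdas <- rep_len(lambdas, m)
  if (p == 1L) {
    a <- drop(crossprod(cd$x_tilde))[1L] / (2 * variances)
    return(optimize_piecewise_1d(a, drop(base), lambdas))
  }
  xtx <- crossprod(cd$x_tilde)
  R <- chol(xtx)
  obj <- function(d) {
    stat <- rowSums((sweep(base, 2L, d, "+") %*% t(R))^2) / (2 * variances)
    sum(pmin(stat, lambdas))
  }
  cands <- -base
  if (p == 2L) {
    rng1 <- range(cands[, 1L]); rng2 <- range(cands[, 2L])
    pad1 <- 0.1 * max(diff(rng1), 1e-8)
    pad2 <- 0.1 * max(diff(rng2), 1e-8)
    g1 <- seq(rng1[1L] - pad1, rng1[2L] + pad1, length.out = 201L)
    g2 <- seq(rng2[1L] - pad2, rng2[2L] + pad2, length.out = 201L)
    best <- NULL; best_val <- Inf
    for (d2 in g2) {
      vals <- vapply(g1, function(d1) obj(c(d1, d2)), numeric(1))
      k <- which.min(vals)
      if (vals[k] < best_val) { best_val <- vals[k]; best <- c(g1[k], d2) }
    }
    pol <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000L))
    if (pol$value < best_val) { best <- pol$par; best_val <- pol$value }
  } else {
    set.seed(as.integer(seed))
    idx <- sample.int(m, min(10L, m))
    starts <- rbind(cands[idx, , drop = FALSE], colMeans(cands))
    best <- NULL; best_val <- Inf
    for (k in seq_len(nrow(starts))) {
      pol <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 5000L))
      better <- pol$value < best_val - 1e-12 ||
        (abs(pol$value - best_val) <= 1e-12 &&
           sum(pol$par^2) < sum(best^2))
      if (is.null(best) || better) { best <- pol$par; best_val <- pol$value }
    }
  }
  if (obj(rep(0, p)) <= best_val + 1e-12 * max(1, abs(best_val)))
    return(rep(0, p))
  best
}

#' Recover normalization offsets and intercepts from fitted coefficients
#'
#' Given final (thresholded) coefficients, recomputes the weighted mean
#' \eqn{\bar\beta^{(w)}} and returns the sample offsets
#' \eqn{d_j = (\bar{y}_{\cdot j}^{(w)} - \bar{y}_{\cdot 1}^{(w)}) -
#' (x_j - x_1)^T \bar\beta^{(w)}} (so \eqn{d_1 = 0} exactly) and intercepts
#' \eqn{\alpha_i = \bar{y}_{i\cdot} + \bar{y}_{\cdot 1}^{(w)} -
#' \bar{y}^{(w)} + (\bar{x} - x_1)^T\bar\beta^{(w)} - \bar{x}^T\beta_i}.
#'
#' @inheritParams type1_keep_rule
#' @param beta m x p matrix of final coefficients.
#' @return list with \code{d} (length n, first element 0) and \code{alpha}
#'   (length m).
#' @export
recover_normalization <- function(cd, beta, variances) {
  beta <- as.matrix(beta)
  beta_bar <- weighted_beta_mean(beta, variances)
  xt <- cd$x_tilde
  d <- (cd$weighted_col_means - cd$weighted_col_means[1L]) -
    as.numeric(sweep(xt, 2L, xt[1L, ], "-") %*% beta_bar)
  d[1L] <- 0  # exact, not up to rounding
  alpha <- cd$row_means + cd$weighted_col_means[1L] - cd$grand_weighted_mean -
    sum(xt[1L, ] * beta_bar) - as.numeric(beta %*% cd$covariate_means)
  list(d = d, alpha = alpha)
}

# assemble a fit-result object shared by both algorithms
build_fit_result <- function(cd, variances, lambdas, sel, delta_opt,
                             objective, penalty) {
  delta <- weighted_beta_mean(sel$beta, variances)
  rec <- recover_normalization(cd, sel$beta, variances)
  structure(list(
    beta = sel$beta, delta = delta, delta_opt = delta_opt,
    alpha = rec$alpha, d = rec$d, selected = sel$selected,
    objective = objective, beta_ols = sel$beta_ols,
    penalty = penalty, lambdas = lambdas, variances = variances,
    centered = cd
  ), class = "jde_fit")
}

# sum_i ||(I - H) y~_i||^2 / (2 sigma_i^2): the delta-independent residual
# part of the joint objective.
residual_objective <- function(cd, variances) {
  base <- ols_base(cd)
  resid <- cd$y_tilde - tcrossprod(base, cd$x_tilde)
  sum(rowSums(resid^2) / (2 * variances))
}

#' Fit the joint model with the type-I penalty (all covariates of interest)
#'
#' Centers the data with precision weights, globally optimizes the shared
#' parameter \eqn{\delta}, applies the exact keep-or-kill rule to the
#' per-gene OLS solutions, and recovers the normalization offsets and
#' intercepts. The reported \code{delta} is recomputed from the final
#' thresholded coefficients so the recovery equations are internally
#' consistent; \code{delta_opt} is the profiled optimizer and
#' \code{objective} the attained minimum of the penalized joint objective.
#'
#' @param y m x n matrix of log-expression values.
#' @param x n x p covariate matrix (or length-n vector).
#' @param variances length-m positive gene-wise noise variances.
#' @param lambdas per-gene penalties (scalar broadcast).
#' @return object of class \code{"jde_fit"} with elements \code{beta},
#'   \code{delta}, \code{delta_opt}, \code{alpha}, \code{d},
#'   \code{selected}, \code{objective}, \code{beta_ols}, \code{penalty}.
#' @seealso [fit_type2()], [jointde()] for the count-level front end.
#' @export
fit_type1 <- function(y, x, variances, lambdas) {
  cd <- center_data(y, x, variances)
  m <- nrow(cd$y_tilde)
  lambdas <- rep_len(lambdas, m)
  delta_opt <- optimize_delta_type1(cd, variances, lambdas)
  sel <- type1_keep_rule(cd, variances, lambdas, delta_opt)
  sel$beta_ols <- ols_betas(cd, delta_opt)
  objective <- residual_objective(cd, variances) +
    type1_delta_objective(cd, variances, lambdas, delta_opt)
  build_fit_result(cd, variances, lambdas, sel, delta_opt, objective, "type1")
}

## ---- type II: only the p-th covariate is penalized -----------------------

# residualize the target covariate on the adjustment covariates
residualized_target <- function(x_tilde) {
  p <- ncol(x_tilde)
  xp <- x_tilde[, p]
  if (p == 1L) {
    r <- xp
  } else {
    xm <- x_tilde[, -p, drop = FALSE]
    r <- xp - xm %*% solve_qr(crossprod(xm), crossprod(xm, xp))
    r <- as.numeric(r)
  }
  s <- sum(r^2)
  if (s < 1e-12 * max(1, sum(xp^2)))
    jde_stop_numeric("target covariate is collinear with the adjustment covariates")
  list(r = r, s = s)
}

#' Target-covariate OLS coefficient via the partitioned-inverse form
#'
#' The p-th coordinate of the per-gene OLS solution, written with the
#' target covariate residualized on the adjustment covariates
#' (Frisch-Waugh): \eqn{\beta_{ip}^{(ols)} = \tilde{y}_i^T r / (r^T r) +
#' \delta_p}, where \eqn{r = (I - H^-)\tilde{x}^p}. For p = 1 the
#' projector is the identity and this equals the plain OLS slope.
#'
#' @inheritParams ols_betas
#' @param delta_p scalar shared parameter for the target covariate.
#' @return length-m numeric vector.
#' @export
beta_p_ols <- function(cd, delta_p) {
  rt <- residualized_target(cd$x_tilde)
  as.numeric(cd$y_tilde %*% rt$r) / rt$s + delta_p
}

#' Type-II keep-or-kill rule
#'
#' Kills the target coefficient of gene i iff
#' \eqn{\frac{s}{2\sigma_i^2}|\beta_{ip}^{(ols)}|^2 < \lambda_i}, where s
#' is the squared norm of the residualized target covariate; ties keep.
#' Killed genes get \eqn{\beta_{ip} = 0} with the adjustment coefficients
#' refit under the reduced model (including the \eqn{\tilde{x}^p\delta_p}
#' correction); kept genes get the full OLS vector. The non-target part of
#' the shared parameter is a gauge freedom (absorbed by the offsets) and is
#' fixed at zero.
#'
#' @inheritParams type1_keep_rule
#' @param delta_p scalar shared parameter for the target covariate.
#' @return list with \code{selected} and \code{beta}.
#' @export
type2_keep_rule <- function(cd, variances, lambdas, delta_p) {
  xt <- cd$x_tilde
  p <- ncol(xt)
  m <- nrow(cd$y_tilde)
  lambdas <- rep_len(lambdas, m)
  rt <- residualized_target(xt)
  bp <- beta_p_ols(cd, delta_p)
  stat <- rt$s * bp^2 / (2 * variances)
  selected <- !(stat < lambdas)

  delta_full <- c(rep(0, p - 1L), delta_p)
  betas <- ols_betas(cd, delta_full)
  if (any(!selected)) {
    if (p == 1L) {
      betas[!selected, 1L] <- 0
    } else {
      xm <- xt[, -p, drop = FALSE]
      yk <- cd$y_tilde[!selected, , drop = FALSE]
      ## reduced-model OLS of (y~ + x~^p delta_p) on the adjustment block
      rhs <- yk + matrix(xt[, p] * delta_p, nrow(yk), ncol(yk), byrow = TRUE)
      bm <- t(solve_qr(crossprod(xm), crossprod(xm, t(rhs))))
      betas[!selected, ] <- cbind(bm, 0)
    }
  }
  list(selected = selected, beta = betas)
}

#' Fit the joint model with the type-II penalty (one covariate of interest)
#'
#' Optimizes the scalar shared parameter \eqn{\delta_p} of the profiled
#' piecewise-quadratic objective by the same grid-plus-refinement scheme as
#' the type-I p = 1 case, applies the type-II keep-or-kill rule, and
#' recovers offsets and intercepts. For p = 1 the two algorithms coincide
#' exactly.
#'
#' @inheritParams fit_type1
#' @return object of class \code{"jde_fit"} (see [fit_type1()]); for
#'   type II, \code{selected} flags genes whose target coefficient is
#'   nonzero and \code{delta_opt} is the scalar optimizer.
#' @export
fit_type2 <- function(y, x, variances, lambdas) {
  cd <- center_data(y, x, variances)
  m <- nrow(cd$y_tilde)
  p <- ncol(cd$x_tilde)
  lambdas <- rep_len(lambdas, m)
  rt <- residualized_target(cd$x_tilde)
  b_base <- as.numeric(cd$y_tilde %*% rt$r) / rt$s
  a <- rt$s / (2 * variances)
  delta_p <- optimize_piecewise_1d(a, b_base, lambdas)
  sel <- type2_keep_rule(cd, variances, lambdas, delta_p)
  sel$beta_ols <- ols_betas(cd, c(rep(0, p - 1L), delta_p))
  objective <- residual_objective(cd, variances) +
    sum(pmin(a * (b_base + delta_p)^2, lambdas))
  res <- build_fit_result(cd, variances, lambdas, sel, delta_p, objective,
                          "type2")
  res
}
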