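#' Gene-wise noise variances by alternating maximum likelihood
#'
#' Estimates \eqn{\sigma_i^2} under the joint model by alternating three
#' closed-form updates until convergence: (a) the per-gene coefficients
#' given the current weighted column means and weighted mean coefficient,
#' \deqn{\beta_i = (\tilde{X}^T\tilde{X})^{-1} \sum_j \tilde{x}_j
#'       (y_{ij} - \bar{y}_{\cdot j}^{(w)}) + \bar{\beta}^{(w)};}
#' (b) the weighted mean \eqn{\bar{\beta}^{(w)}} with the current weights;
#' (c) the per-gene MLE of the variance (divisor n),
#' \deqn{\sigma_i^2 = \frac{1}{n}\sum_j \big(\tilde{y}_{ij}
#'       - \tilde{x}_j^T(\beta_i - \bar{\beta}^{(w)})\big)^2.}
#' The sigma-dependent weighted means are recomputed every cycle.
#'
#' Initialization: per-gene sample variance of the unweighted doubly
#' centered data and \eqn{\bar{\beta}^{(w)} = 0}. Each \eqn{\sigma_i^2} is
#' floored at \code{1e-8} so constant genes keep finite weights.
#'
#' @param y m x n matrix of log-expression values.
#' @param x n x p covariate matrix (or vector).
#' @param tol relative convergence tolerance on the variances (default 1e-6).
#' @param max_iter maximum number of alternating cycles (default 100); a
#'   warning is raised and the last iterate returned if not converged.
#' @return list with \code{raw} (length-m variance vector),
#'   \code{beta_bar}, \code{iterations} and \code{converged}.
#' @seealso [shrink_variances()] for the robustified estimates.
#' @export
estimate_variances <- function(y, x, tol = 1e-6, max_iter = 100L) {
  y <- as.matrix(y); x <- as.matrix(x)
  m <- nrow(y); n <- ncol(y); p <- ncol(x)
  if (n <= p + 1L)
    jde_stop_validation("need n > p + 1 for positive residual degrees of freedom")
  floor_ <- 1e-8
  x_tilde <- sweep(x, 2L, colMeans(x))
  xtx_inv <- xtx_inverse(x_tilde)
  row_means <- rowMeans(y)

  ## init: unweighted double centering
  y0 <- y - row_means
  y0 <- sweep(y0, 2L, colMeans(y0))
  sigma2 <- pmax(rowSums(y0^2) / (n - 1L), floor_)
  beta_bar <- rep(0, p)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- 1 / sigma2
    sw <- sum(w)
    wcm <- as.numeric(crossprod(w, y)) / sw
    gw <- sum(w * row_means) / sw
    yc <- sweep(y, 2L, wcm)                       # y - weighted col means
    B <- (yc %*% x_tilde) %*% xtx_inv             # delta-free part
    B <- sweep(B, 2L, beta_bar, "+")
    beta_bar <- as.numeric(crossprod(w, B)) / sw
    y_tilde <- (yc - row_means) + gw
    resid <- y_tilde - tcrossprod(sweep(B, 2L, beta_bar), x_tilde)
    sigma2_new <- pmax(rowSums(resid^2) / n, floor_)
    delta_rel <- max(abs(sigma2_new - sigma2) / sigma2)
    sigma2 <- sigma2_new
    if (delta_rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("variance estimation did not converge in ", max_iter,
            " iterations; returning last iterate")
  list(raw = sigma2, beta_bar = beta_bar,
       iterations = iter, converged = converged)
}

#' Shrink gene-wise variance estimates toward their mean
#'
#' Robustifies raw variance MLEs by a shrinkage-toward-the-mean scheme:
#' \deqn{\hat{\hat{\sigma}}_i^2 = (1-w)\hat\sigma_i^2 +
#'       w\,\overline{\hat\sigma^2},}
#' with
#' \deqn{w = \frac{2(m-1)}{n-p+1}\left(\frac{1}{m} +
#'       \frac{(\overline{\hat\sigma^2})^2}
#'            {\sum_i (\hat\sigma_i^2-\overline{\hat\sigma^2})^2}\right),}
#' clamped to \[0, 1\] so the result stays a convex combination (the formula
#' can exceed 1 for small n or nearly homogeneous variances). When all raw
#' values are identical the formula divides by zero; the input is returned
#' unchanged with \code{shrink_weight = 1}.
#'
#' Shrinkage preserves the mean: \code{mean(shrunk) == mean(raw)}.
#'
#' @param raw length-m vector of positive raw variance estimates.
#' @param n number of samples the estimates are based on.
#' @param p number of covariates in the model.
#' @return list with \code{raw}, \code{shrunk}, \code{shrink_weight}
#'   (the clamped w) and \code{mean_raw}.
#' @export
shrink_variances <- function(raw, n, p) {
  m <- length(raw)
  if (m < 2L) jde_stop_validation("need at least two genes to shrink")
  if (n <= p - 1L) jde_stop_validation("need n > p - 1")
  if (any(raw <= 0)) jde_stop_validation("raw variances must be positive")
  mean_raw <- mean(raw)
  ss <- sum((raw - mean_raw)^2)
  if (ss == 0) {
    return(list(raw = raw, shrunk = raw, shrink_weight = 1, mean_raw = mean_raw))
  }
  w <- 2 * (m - 1) / (n - p + 1) * (1 / m + mean_raw^2 / ss)
  w <- min(max(w, 0), 1)
  list(raw = raw, shrunk = (1 - w) * raw + w * mean_raw,
       shrink_weight = w, mean_raw = mean_raw)
}
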