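#' Doubly center expression data, profiling out gene and sample effects
#'
#' Removes from each log-expression value the plain gene (row) mean, the
#' precision-weighted sample (column) mean and adds back the weighted grand
#' mean:
#' \deqn{\tilde{y}_{ij} = y_{ij} - \bar{y}_{i\cdot} - \bar{y}_{\cdot j}^{(w)}
#'       + \bar{y}^{(w)},}
#' where the column means and the grand mean are weighted by
#' \eqn{1/\sigma_i^2}. Covariates are centered at their sample mean,
#' \eqn{\tilde{x}_j = x_j - \bar{x}}. This is the profiling step that
#' eliminates the per-gene intercepts and the sample normalization offsets
#' from the joint objective, leaving the per-gene coefficients (and their
#' weighted mean) as the only free parameters.
#'
#' The centered values satisfy
#' \eqn{\sum_i \tilde{y}_{ij}/\sigma_i^2 = 0} for every sample and
#' \eqn{\sum_j \tilde{y}_{ij} = 0} for every gene.
#'
#' @param y m x n matrix of log-expression values (genes in rows).
#' @param x n x p matrix (or length-n vector) of covariates.
#' @param variances length-m vector of positive gene-wise noise variances
#'   defining the weights \eqn{1/\sigma_i^2}.
#' @return An object of class \code{"jde_centered"}: a list with
#'   \code{y_tilde}, \code{x_tilde}, \code{weighted_col_means},
#'   \code{row_means}, \code{grand_weighted_mean}, \code{covariate_means}
#'   and \code{variances}.
#' @export
center_data <- function(y, x, variances) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  m <- nrow(y); n <- ncol(y)
  if (nrow(x) != n)
    jde_stop_validation("covariate rows must match expression columns")
  if (length(variances) != m || any(!is.finite(variances)) || any(variances <= 0))
    jde_stop_validation("variances must be finite, positive and one per gene")
  w <- 1 / variances
  sw <- sum(w)
  wcm <- as.numeric(crossprod(w, y)) / sw       # weighted column means
  rm_ <- rowMeans(y)                            # plain row means
  gw <- sum(w * rm_) / sw                       # weighted grand mean
  y_tilde <- y - rm_                            # recycles down columns
  y_tilde <- sweep(y_tilde, 2L, wcm) + gw
  xbar <- colMeans(x)
  x_tilde <- sweep(x, 2L, xbar)
  if (qr(x_tilde)$rank < ncol(x_tilde))
    jde_stop_numeric("centered covariate matrix is rank deficient")
  structure(list(
    y_tilde = y_tilde, x_tilde = x_tilde,
    weighted_col_means = wcm, row_means = rm_,
    grand_weighted_mean = gw, covariate_means = xbar,
    variances = variances
  ), class = "jde_centered")
}

#' Precision-weighted mean of per-gene coefficient vectors
#'
#' Computes \eqn{\bar{\beta}^{(w)} = \sum_i \beta_i/\sigma_i^2 \big/
#' \sum_i 1/\sigma_i^2}, the shared parameter (also written \eqn{\delta})
#' that couples all genes through the normalization offsets.
#'
#' @param betas m x p matrix (or length-m vector when p = 1).
#' @param variances length-m vector of positive variances.
#' @return numeric vector of length p.
#' @export
weighted_beta_mean <- function(betas, variances) {
  betas <- as.matrix(betas)
  if (length(variances) != nrow(betas) || any(variances <= 0))
    jde_stop_validation("variances must be positive, one per gene")
  w <- 1 / variances
  as.numeric(crossprod(w, betas)) / sum(w)
}
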