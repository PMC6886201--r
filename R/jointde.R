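#' Joint between-sample normalization and differential expression detection
#'
#' Fits the log-linear model
#' \deqn{y_{ij} = \alpha_i + \beta_i^T x_j + d_j + \varepsilon_{ij},
#'       \quad \varepsilon_{ij} \sim N(0, \sigma_i^2),}
#' to a genes-by-samples matrix of read counts (or pre-log-transformed
#' expression values), where \eqn{d_j} are sample-specific normalization
#' offsets estimated jointly with the per-gene coefficients under an L0
#' penalty that selects differentially expressed genes. The penalty is
#' either on the whole coefficient vector (\code{"type1"}: is the gene
#' associated with any covariate?) or only on the last covariate
#' (\code{"type2"}: is it associated with the covariate of interest after
#' adjusting for the others?).
#'
#' The pipeline is: log-transform (unless \code{log_input}), estimate
#' gene-wise noise variances by alternating maximum likelihood and
#' optionally shrink them toward their mean, derive the penalty from the
#' significance level \code{q} (chi-squared quantile for type I, Gaussian
#' for type II), fit by [fit_type1()] or [fit_type2()], and compute
#' gene-wise p-values after substituting the estimated offsets.
#'
#' @param counts m x n matrix of non-negative read counts (genes in rows),
#'   or of log-expression values when \code{log_input = TRUE}.
#' @param covariates n x p matrix (or length-n vector) of continuous
#'   experimental conditions.
#' @param penalty \code{"type1"} or \code{"type2"}.
#' @param q significance level in (0, 1) from which the penalty is derived;
#'   default 0.01.
#' @param pseudocount constant added to counts before the log; default 1.
#' @param variance \code{"shrunk"} (default) for shrinkage-robustified
#'   estimates, \code{"mle"} for the raw alternating-MLE estimates, or
#'   \code{"fixed"} to supply \code{sigma2}.
#' @param sigma2 fixed variance(s), required when \code{variance = "fixed"}.
#' @param lambda optional explicit penalty value(s), overriding \code{q}.
#' @param log_input set \code{TRUE} if \code{counts} is already on the log
#'   scale.
#' @param pvalue_method method for the post-fit gene-wise tests; see
#'   [gene_pvalues()].
#' @param tol,max_iter convergence controls for [estimate_variances()].
#'
#' @return An object of class \code{"jointde"}: a list with \code{beta},
#'   \code{alpha}, \code{d} (normalization offsets, \code{d[1] == 0}),
#'   \code{delta} (weighted mean coefficient), \code{selected},
#'   \code{pvalues}, \code{objective}, \code{variances} (raw and shrunk),
#'   \code{lambda}, \code{settings} and the internal \code{fit}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{fitted},
#'   \code{residuals}, \code{predict}, \code{plot}.
#'
#' @examples
#' sim <- simulate_counts(m = 300, n = 12, de_fraction = 0.1, seed = 7)
#' fit <- jointde(sim$counts, sim$covariates)
#' fit
#' head(coef(fit))
#' @export
jointde <- function(counts, covariates,
                    penalty = c("type1", "type2"),
                    q = 0.01, pseudocount = 1,
                    variance = c("shrunk", "mle", "fixed"),
                    sigma2 = NULL, lambda = NULL,
                    log_input = FALSE,
                    pvalue_method = c("ols_f", "chisq_known_var"),
                    tol = 1e-6, max_iter = 100L) {
  penalty <- match.arg(penalty)
  variance <- match.arg(variance)
  pvalue_method <- match.arg(pvalue_method)
  if (q <= 0 || q >= 1) jde_stop_validation("q must lie in (0, 1)")
  counts <- as.matrix(counts)
  x <- as.matrix(covariates)
  y <- if (log_input) counts else log_transform(counts, pseudocount)
  m <- nrow(y); p <- ncol(x)

  vres <- NULL
  if (variance == "fixed") {
    if (is.null(sigma2)) jde_stop_validation("variance = 'fixed' requires sigma2")
    sig2 <- rep_len(sigma2, m)
  } else {
    vres <- estimate_variances(y, x, tol = tol, max_iter = max_iter)
    sig2 <- if (variance == "shrunk") {
      shrink_variances(vres$raw, n = ncol(y), p = p)$shrunk
    } else vres$raw
  }
  lam <- if (is.null(lambda)) select_lambda(q, p, penalty) else lambda
  fit <- if (penalty == "type1") fit_type1(y, x, sig2, lam)
         else fit_type2(y, x, sig2, lam)
  pv <- gene_pvalues(y, x, fit, method = pvalue_method)

  structure(list(
    beta = fit$beta, alpha = fit$alpha, d = fit$d,
    delta = fit$delta, selected = fit$selected,
    pvalues = pv, objective = fit$objective,
    variances = list(used = sig2, raw = if (is.null(vres)) sig2 else vres$raw),
    lambda = lam,
    settings = list(penalty = penalty, q = q, pseudocount = pseudocount,
                    variance = variance, pvalue_method = pvalue_method,
                    log_input = log_input),
    y = y, covariates = x, fit = fit,
    gene_ids = rownames(y) %||% sprintf("gene_%d", seq_len(m)),
    sample_ids = colnames(y) %||% sprintf("sample_%d", seq_len(ncol(y)))
  ), class = "jointde")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.jointde <- function(x, ...) {
  s <- x$settings
  cat("Joint normalization / differential expression fit (L0 penalty)\n")
  cat(sprintf("  %d genes x %d samples, %d covariate(s), penalty %s\n",
              nrow(x$beta), length(x$d), ncol(x$beta), s$penalty))
  cat(sprintf("  lambda = %.4f (q = %g, %s variances)\n",
              x$lambda[1L], s$q, s$variance))
  cat(sprintf("  selected genes: %d (%.2f%%)\n",
              sum(x$selected), 100 * mean(x$selected)))
  cat(sprintf("  shared slope delta = %s\n",
              paste(signif(x$delta, 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.jointde <- function(object, n_top = 10L, ...) {
  ord <- order(object$pvalues)
  top <- data.frame(
    gene_id = object$gene_ids[ord[seq_len(min(n_top, length(ord)))]],
    beta = object$beta[ord[seq_len(min(n_top, length(ord)))], 1L],
    p_value = object$pvalues[ord[seq_len(min(n_top, length(ord)))]],
    selected = object$selected[ord[seq_len(min(n_top, length(ord)))]]
  )
  structure(list(fit = object, top = top), class = "summary.jointde")
}

#' @export
print.summary.jointde <- function(x, ...) {
  print(x$fit)
  cat("\nTop genes by p-value:\n")
  print(x$top, row.names = FALSE, digits = 4)
  d <- x$fit$d
  cat(sprintf("\nNormalization offsets d: range [%.3f, %.3f] (d[1] = 0)\n",
              min(d), max(d)))
  invisible(x)
}

#' @export
coef.jointde <- function(object, ...) {
  b <- object$beta
  rownames(b) <- object$gene_ids
  b
}

#' @export
fitted.jointde <- function(object, ...) {
  f <- object$alpha + tcrossprod(object$beta, object$covariates)
  f <- sweep(f, 2L, object$d, "+")
  dimnames(f) <- list(object$gene_ids, object$sample_ids)
  f
}

#' @export
residuals.jointde <- function(object, ...) object$y - fitted(object)

#' Predict log expression for new covariate values
#'
#' Returns \eqn{\alpha_i + \beta_i^T x} for each gene at the supplied
#' covariate rows. Sample offsets \eqn{d_j} are sample-specific and do not
#' transfer to new samples, so they are not included.
#'
#' @param object a \code{jointde} fit.
#' @param newdata matrix (or vector) of covariate rows; defaults to the
#'   training covariates.
#' @param ... unused.
#' @return genes x new-samples matrix of predicted log expression.
#' @export
predict.jointde <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$covariates else as.matrix(newdata)
  object$alpha + tcrossprod(object$beta, x)
}

#' @export
plot.jointde <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$pvalues, breaks = 30, main = "Gene-wise p-values",
                 xlab = "p-value", col = "grey80", border = "white")
  graphics::plot(x$d, type = "h", main = "Normalization offsets",
                 xlab = "sample", ylab = expression(hat(d)[j]))
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
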