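#' Simulate an RNA-seq count matrix with known differential expression
#'
#' Generates a genes-by-samples matrix of read counts from a log-linear
#' model with gene effects, sample normalization offsets and continuous
#' covariates, together with the ground-truth coefficients. The mean count
#' of gene \eqn{i} in sample \eqn{j} is
#' \deqn{\mu_{ij} = N_j \frac{\ell_i}{\sum_i \ell_i}
#'       e^{\alpha_i + \beta_i^T x_j + d_j},}
#' where gene lengths \eqn{\ell_i \sim e^{U(5,10)}}, gene offsets
#' \eqn{\alpha_i \sim N(0,1)}, covariates \eqn{x_j \sim N(0,1)}, library
#' sizes \eqn{N_j \sim U(2,3)\times 10^6} and sample offsets
#' \eqn{d_j \sim N(0,1)}. A fraction \code{de_fraction} of genes is
#' differentially expressed: each coordinate of their \eqn{\beta_i} is drawn
#' from \eqn{N(2,1)} (up-regulated) or \eqn{N(-2,1)} (down-regulated); all
#' other genes have \eqn{\beta_i = 0}.
#'
#' Counts are drawn either as
#' \eqn{c_{ij} = \lceil e^{N(\log\mu_{ij},\sigma_i^2)} \rceil}
#' (log-normal noise) or as negative binomial with mean \eqn{\mu_{ij}} and
#' variance \eqn{\mu_{ij} + \phi_i \mu_{ij}^2} (gamma-Poisson mixture;
#' \code{dispersion = 0} degenerates to Poisson).
#'
#' The RNG stream is split into named substreams (gene-level draws,
#' sample-level draws, count noise) so that changing \code{n} does not
#' perturb the gene-level draws for a given seed.
#'
#' @param m number of genes.
#' @param n number of samples (at least 2).
#' @param p number of covariates (default 1).
#' @param de_fraction fraction of genes that are differentially expressed,
#'   in \[0, 1\].
#' @param up_fraction fraction of DE genes that are up-regulated, in \[0, 1\].
#' @param noise count noise model, \code{"lognormal"} or \code{"negbinom"}.
#' @param sigma2 log-normal noise variance; scalar or per-gene vector.
#' @param dispersion negative-binomial dispersion \eqn{\phi}; scalar or
#'   per-gene vector. Ignored under log-normal noise.
#' @param seed integer RNG seed; if \code{NULL} the current RNG state is used.
#' @param gene_offsets optional length-\code{m} vector overriding the drawn
#'   \eqn{\alpha_i} (useful for diagnostics).
#' @param sample_offsets optional length-\code{n} vector overriding the drawn
#'   \eqn{d_j}.
#'
#' @return An object of class \code{"jde_sim"}: a list with elements
#'   \code{counts} (m x n integer matrix), \code{truth_beta} (m x p),
#'   \code{de_labels} (logical m), \code{covariates} (n x p),
#'   \code{library_sizes}, \code{gene_lengths}, \code{sample_offsets},
#'   \code{gene_offsets}, \code{mean_counts} and \code{config}.
#'
#' @examples
#' sim <- simulate_counts(m = 200, n = 8, de_fraction = 0.1, seed = 1)
#' table(sim$de_labels)
#' @export
simulate_counts <- function(m, n, p = 1L,
                            de_fraction = 0.1, up_fraction = 0.5,
                            noise = c("lognormal", "negbinom"),
                            sigma2 = 0.01, dispersion = 0.25,
                            seed = NULL,
                            gene_offsets = NULL, sample_offsets = NULL) {
  noise <- match.arg(noise)
  m <- as.integer(m); n <- as.integer(n); p <- as.integer(p)
  if (m < 1L || n < 2L || p < 1L)
    jde_stop_validation("need m >= 1, n >= 2, p >= 1")
  if (de_fraction < 0 || de_fraction > 1 || up_fraction < 0 || up_fraction > 1)
    jde_stop_validation("de_fraction and up_fraction must lie in [0, 1]")
  if (any(sigma2 <= 0)) jde_stop_validation("sigma2 must be positive")
  if (any(dispersion < 0)) jde_stop_validation("dispersion must be non-negative")
  n_de <- round(de_fraction * m)
  if (n_de > m) jde_stop_validation("de_fraction implies more DE genes than genes")

  if (!is.null(seed)) set.seed(as.integer(seed))
  substream <- sample.int(.Machine$integer.max, 3L)

  ## gene-level draws
  set.seed(substream[1L])
  gene_lengths <- exp(stats::runif(m, 5, 10))
  alpha <- stats::rnorm(m)
  perm <- sample.int(m)
  de_idx <- perm[seq_len(n_de)]
  n_up <- round(up_fraction * n_de)
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- setdiff(de_idx, up_idx)
  beta <- matrix(0, m, p)
  if (length(up_idx))
    beta[up_idx, ] <- stats::rnorm(length(up_idx) * p, mean = 2, sd = 1)
  if (length(down_idx))
    beta[down_idx, ] <- stats::rnorm(length(down_idx) * p, mean = -2, sd = 1)
  if (!is.null(gene_offsets)) {
    stopifnot(length(gene_offsets) == m)
    alpha <- as.numeric(gene_offsets)
  }

  ## sample-level draws
  set.seed(substream[2L])
  x <- matrix(stats::rnorm(n * p), n, p)
  lib_sizes <- stats::runif(n, 2e6, 3e6)
  d <- stats::rnorm(n)
  if (!is.null(sample_offsets)) {
    stopifnot(length(sample_offsets) == n)
    d <- as.numeric(sample_offsets)
  }

  eta <- outer(alpha, d, "+") + beta %*% t(x)
  mu <- (gene_lengths / sum(gene_lengths)) * exp(eta)
  mu <- sweep(mu, 2L, lib_sizes, "*")

  ## count noise
  set.seed(substream[3L])
  counts <- switch(noise,
    lognormal = {
      sd_mat <- sqrt(rep_len(sigma2, m))  # recycled per gene, column-major
      ceiling(exp(stats::rnorm(m * n, mean = as.vector(log(mu)),
                               sd = rep(sd_mat, times = n))))
    },
    negbinom = {
      phi <- rep_len(dispersion, m)
      if (all(phi == 0)) {
        stats::rpois(m * n, lambda = as.vector(mu))
      } else {
        stats::rnbinom(m * n, mu = as.vector(mu),
                       size = rep(1 / phi, times = n))
      }
    })
  counts <- matrix(as.numeric(counts), m, n)
  gene_ids <- sprintf("gene_%d", seq_len(m))
  sample_ids <- sprintf("sample_%d", seq_len(n))
  dimnames(counts) <- list(gene_ids, sample_ids)
  dimnames(mu) <- dimnames(counts)
  rownames(x) <- sample_ids
  colnames(x) <- sprintf("x%d", seq_len(p))
  de_labels <- rowSums(beta != 0) > 0
  ## by construction exactly the drawn DE set
  de_labels[de_idx] <- TRUE

  structure(list(
    counts = counts,
    truth_beta = beta,
    de_labels = de_labels,
    covariates = x,
    library_sizes = lib_sizes,
    gene_lengths = gene_lengths,
    sample_offsets = d,
    gene_offsets = alpha,
    mean_counts = mu,
    config = list(m = m, n = n, p = p, de_fraction = de_fraction,
                  up_fraction = up_fraction, noise = noise,
                  sigma2 = sigma2, dispersion = dispersion, seed = seed)
  ), class = "jde_sim")
}

#' @export
print.jde_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated RNA-seq dataset: %d genes x %d samples (%s noise)\n",
              cfg$m, cfg$n, cfg$noise))
  cat(sprintf("  DE genes: %d (%.1f%%), up-regulated: %.0f%% of DE\n",
              sum(x$de_labels), 100 * mean(x$de_labels),
              100 * cfg$up_fraction))
  invisible(x)
}

#' Log-transform a count matrix
#'
#' Computes \eqn{y_{ij} = \log(c_{ij} + \mathrm{pseudocount})} (natural
#' log). A pseudocount of 0 is only allowed when all counts are positive.
#'
#' @param counts non-negative numeric matrix, genes in rows.
#' @param pseudocount non-negative constant added before the log; default 1.
#' @return numeric matrix of the same shape (dimnames preserved).
#' @export
log_transform <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) jde_stop_validation("counts must be non-negative")
  if (pseudocount < 0) jde_stop_validation("pseudocount must be non-negative")
  if (pseudocount == 0 && any(counts == 0))
    jde_stop_validation("zero counts require a positive pseudocount")
  log(counts + pseudocount)
}
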