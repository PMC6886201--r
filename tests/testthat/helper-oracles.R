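# Independent oracles and fixture builders. Everything here is written as
# straight-line/brute-force code, deliberately not reusing the package's
# vectorized implementations.

# small random model instance: y from the joint model with Gaussian noise
random_instance <- function(m, n, p = 1L, seed = 1L, sigma = 0.3,
                            de_fraction = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  alpha <- rnorm(m)
  d <- c(0, rnorm(n - 1))
  beta <- matrix(0, m, p)
  nde <- round(de_fraction * m)
  if (nde > 0) beta[seq_len(nde), ] <- rnorm(nde * p, 2)
  y <- alpha + beta %*% t(x) + matrix(d, m, n, byrow = TRUE) +
    matrix(rnorm(m * n, sd = sigma), m, n)
  variances <- runif(m, 0.05, 0.5)
  list(y = y, x = x, variances = variances, beta = beta, d = d,
       alpha = alpha)
}

# centering by definition, scalar loops
oracle_center <- function(y, x, variances) {
  m <- nrow(y); n <- ncol(y)
  w <- 1 / variances
  wcm <- numeric(n)
  for (j in seq_len(n)) wcm[j] <- sum(w * y[, j]) / sum(w)
  rm_ <- numeric(m)
  for (i in seq_len(m)) rm_[i] <- mean(y[i, ])
  gw <- sum(w * rm_) / sum(w)
  yt <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n))
    yt[i, j] <- y[i, j] - rm_[i] - wcm[j] + gw
  xt <- x
  for (k in seq_len(ncol(x))) xt[, k] <- x[, k] - mean(x[, k])
  list(y_tilde = yt, x_tilde = xt, wcm = wcm, rm = rm_, gw = gw)
}

# exhaustive support enumeration for the type-I problem: each support
# pattern solved in closed form with its own optimal shared parameter
oracle_type1_optimum <- function(y, x, variances, lambdas) {
  oc <- oracle_center(y, x, variances)
  xt <- oc$x_tilde
  xtx <- t(xt) %*% xt
  m <- nrow(y)
  lambdas <- rep_len(lambdas, m)
  w <- 1 / (2 * variances)
  b <- matrix(0, m, ncol(xt))
  sse <- numeric(m)
  for (i in seq_len(m)) {
    bi <- solve(xtx, t(xt) %*% oc$y_tilde[i, ])
    b[i, ] <- bi
    sse[i] <- sum((oc$y_tilde[i, ] - xt %*% bi)^2)
  }
  best <- Inf
  for (s in 0:(2^m - 1)) {
    keep <- as.logical(bitwAnd(s, 2^(seq_len(m) - 1)))
    val <- sum(w * sse) + sum(lambdas[keep])
    if (any(!keep)) {
      wk <- w[!keep]
      bk <- b[!keep, , drop = FALSE]
      dstar <- -colSums(wk * bk) / sum(wk)
      for (i in seq_len(nrow(bk))) {
        v <- bk[i, ] + dstar
        val <- val + wk[i] * sum(v * (xtx %*% v))
      }
    }
    if (val < best) best <- val
  }
  best
}

# exhaustive enumeration over {beta_ip = 0 / free} for the type-II problem
oracle_type2_optimum <- function(y, x, variances, lambdas) {
  oc <- oracle_center(y, x, variances)
  xt <- oc$x_tilde
  p <- ncol(xt)
  m <- nrow(y)
  lambdas <- rep_len(lambdas, m)
  w <- 1 / (2 * variances)
  xp <- xt[, p]
  if (p == 1L) {
    r <- xp
  } else {
    xm <- xt[, -p, drop = FALSE]
    r <- xp - xm %*% solve(t(xm) %*% xm, t(xm) %*% xp)
  }
  s <- sum(r^2)
  xtx <- t(xt) %*% xt
  btil <- numeric(m)
  sse_full <- numeric(m)
  for (i in seq_len(m)) {
    btil[i] <- sum(oc$y_tilde[i, ] * r) / s
    bi <- solve(xtx, t(xt) %*% oc$y_tilde[i, ])
    sse_full[i] <- sum((oc$y_tilde[i, ] - xt %*% bi)^2)
  }
  best <- Inf
  for (pat in 0:(2^m - 1)) {
    keep <- as.logical(bitwAnd(pat, 2^(seq_len(m) - 1)))
    val <- sum(w * sse_full) + sum(lambdas[keep])
    if (any(!keep)) {
      wk <- w[!keep]; bk <- btil[!keep]
      dstar <- -sum(wk * bk) / sum(wk)
      val <- val + sum(wk * s * (bk + dstar)^2)
    }
    if (val < best) best <- val
  }
  best
}

# one alternating variance-update cycle coded from the update equations
# with explicit loops (same initialization convention as the package)
oracle_variance_step <- function(y, x) {
  m <- nrow(y); n <- ncol(y); p <- ncol(x)
  xt <- x
  for (k in seq_len(p)) xt[, k] <- x[, k] - mean(x[, k])
  y0 <- y
  for (i in seq_len(m)) y0[i, ] <- y0[i, ] - mean(y0[i, ])
  for (j in seq_len(n)) y0[, j] <- y0[, j] - mean(y0[, j])
  sigma2 <- pmax(apply(y0, 1, function(r) sum(r^2)) / (n - 1), 1e-8)
  beta_bar <- rep(0, p)

  w <- 1 / sigma2
  wcm <- numeric(n)
  for (j in seq_len(n)) wcm[j] <- sum(w * y[, j]) / sum(w)
  rm_ <- apply(y, 1, mean)
  gw <- sum(w * rm_) / sum(w)
  xtx <- t(xt) %*% xt
  B <- matrix(0, m, p)
  for (i in seq_len(m)) {
    acc <- rep(0, p)
    for (j in seq_len(n)) acc <- acc + xt[j, ] * (y[i, j] - wcm[j])
    B[i, ] <- solve(xtx, acc) + beta_bar
  }
  bb_new <- rep(0, p)
  for (i in seq_len(m)) bb_new <- bb_new + w[i] * B[i, ]
  bb_new <- bb_new / sum(w)
  s2 <- numeric(m)
  for (i in seq_len(m)) {
    acc <- 0
    for (j in seq_len(n)) {
      yt <- y[i, j] - rm_[i] - wcm[j] + gw
      acc <- acc + (yt - sum(xt[j, ] * (B[i, ] - bb_new)))^2
    }
    s2[i] <- max(acc / n, 1e-8)
  }
  list(sigma2 = s2, beta_bar = bb_new)
}

# AUC by all-pairs counting with half-credit ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
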