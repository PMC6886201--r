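make_cd <- function(inst) center_data(inst$y, inst$x, inst$variances)

test_that("per-gene OLS solutions behave as closed forms", {
  inst <- random_instance(m = 6, n = 9, p = 1, seed = 2)
  cd <- make_cd(inst)
  # zero response gives delta itself
  cd0 <- cd
  cd0$y_tilde <- cd$y_tilde * 0
  expect_equal(unname(ols_betas(cd0, 0)), matrix(0, 6, 1))
  expect_equal(unname(ols_betas(cd0, 1.7)), matrix(1.7, 6, 1))
  # textbook slopes: x = (-1,0,1), y = (-2,0,2) -> slope 2 (a mirrored
  # second gene keeps the column means at zero so y passes through
  # centering unchanged)
  y <- rbind(c(-2, 0, 2), c(2, 0, -2))
  x <- matrix(c(-1, 0, 1), 3, 1)
  cd1 <- center_data(y, x, variances = c(1, 1))
  expect_equal(unname(drop(ols_betas(cd1, 0))), c(2, -2))
  # matches lm() on the centered data, gene by gene
  b <- ols_betas(cd, 0)
  for (i in 1:6) {
    ref <- unname(coef(lm(cd$y_tilde[i, ] ~ cd$x_tilde - 1)))
    expect_equal(unname(b[i, ]), ref, tolerance = 1e-10)
  }
})

test_that("type-I keep rule kills small effects and keeps boundary ties", {
  inst <- random_instance(m = 5, n = 8, p = 1, seed = 3)
  cd <- make_cd(inst)
  keep_all <- type1_keep_rule(cd, inst$variances, lambdas = 0, delta = 0)
  expect_true(all(keep_all$selected))
  kill_all <- type1_keep_rule(cd, inst$variances, lambdas = Inf, delta = 0)
  expect_false(any(kill_all$selected))
  expect_true(all(kill_all$beta == 0))
  # set each lambda exactly at the statistic: ties keep
  b <- ols_betas(cd, 0)
  stat <- rowSums((b %*% t(chol(crossprod(cd$x_tilde))))^2) /
    (2 * inst$variances)
  tie <- type1_keep_rule(cd, inst$variances, lambdas = stat, delta = 0)
  expect_true(all(tie$selected))
})

test_that("profiled delta objective matches a term-by-term loop oracle", {
  inst <- random_instance(m = 20, n = 10, p = 2, seed = 4)
  cd <- make_cd(inst)
  lam <- runif(20, 0.5, 3)
  xtx <- crossprod(cd$x_tilde)
  base <- t(apply(cd$y_tilde, 1, function(yi)
    solve(xtx, crossprod(cd$x_tilde, yi))))
  set.seed(5)
  for (k in 1:50) {
    delta <- rnorm(2)
    ref <- 0
    for (i in 1:20) {
      v <- base[i, ] + delta
      ref <- ref + min(sum(v * (xtx %*% v)) / (2 * inst$variances[i]), lam[i])
    }
    expect_equal(type1_delta_objective(cd, inst$variances, lam, delta), ref,
                 tolerance = 1e-10)
  }
  # zero data: zero objective at zero delta
  cd0 <- cd; cd0$y_tilde <- cd$y_tilde * 0
  expect_equal(type1_delta_objective(cd0, inst$variances, lam, c(0, 0)), 0)
})

test_that("delta optimization beats a dense brute-force grid", {
  inst <- random_instance(m = 50, n = 12, p = 1, seed = 6)
  cd <- make_cd(inst)
  lam <- runif(50, 0.2, 2)
  dhat <- optimize_delta_type1(cd, inst$variances, lam)
  grid <- seq(-8, 8, length.out = 1e5)
  a <- drop(crossprod(cd$x_tilde)) / (2 * inst$variances)
  b <- drop(ols_betas(cd, 0))
  objv <- vapply(grid, function(d) sum(pmin(a * (b + d)^2, lam)), numeric(1))
  ours <- type1_delta_objective(cd, inst$variances, lam, dhat)
  expect_lte(ours, min(objv) + 1e-8)
})

test_that("single-gene and flat-objective delta cases resolve as documented", {
  inst <- random_instance(m = 1, n = 6, p = 1, seed = 8)
  cd <- make_cd(inst)
  b1 <- drop(ols_betas(cd, 0))
  dhat <- optimize_delta_type1(cd, inst$variances, lambdas = Inf)
  expect_equal(drop(dhat), -b1, tolerance = 1e-6)
  # all-zero penalties: flat objective, tie-break at zero
  expect_equal(drop(optimize_delta_type1(cd, inst$variances, lambdas = 0)), 0)
})

test_that("null data yields an all-killed fit with offset-only normalization", {
  set.seed(10)
  alpha <- rnorm(7); d <- c(0, rnorm(5))
  y <- outer(alpha, d, "+") + matrix(rnorm(42, sd = 0.1), 7, 6)
  x <- matrix(rnorm(6), 6, 1)
  sig <- rep(0.01, 7)
  fit <- fit_type1(y, x, sig, lambdas = select_lambda(0.01, 1, "type1"))
  cd <- center_data(y, x, sig)
  # with beta = 0 the offsets reduce to differences of weighted column means
  if (!any(fit$selected)) {
    expect_equal(fit$d, cd$weighted_col_means - cd$weighted_col_means[1])
  }
  expect_identical(fit$d[1], 0)
})

test_that("fit attains the exhaustive support-enumeration optimum", {
  for (k in 1:10) {
    inst <- random_instance(m = 6, n = 8, p = 1, seed = 100 + k)
    lam <- runif(6, 0.3, 3)
    fit <- fit_type1(inst$y, inst$x, inst$variances, lam)
    ref <- oracle_type1_optimum(inst$y, inst$x, inst$variances, lam)
    expect_equal(fit$objective, ref, tolerance = 1e-6)
  }
})

test_that("reported objective equals direct evaluation of the joint objective", {
  inst <- random_instance(m = 12, n = 9, p = 2, seed = 33)
  lam <- runif(12, 0.3, 2)
  fit <- fit_type1(inst$y, inst$x, inst$variances, lam)
  cd <- fit$centered
  delta <- fit$delta_opt
  direct <- 0
  for (i in 1:12) {
    r <- cd$y_tilde[i, ] + drop(cd$x_tilde %*% delta) -
      drop(cd$x_tilde %*% fit$beta[i, ])
    direct <- direct + sum(r^2) / (2 * inst$variances[i]) +
      lam[i] * any(fit$beta[i, ] != 0)
  }
  expect_equal(fit$objective, direct, tolerance = 1e-8)
})

test_that("selection is monotone in a shared penalty ladder", {
  inst <- random_instance(m = 60, n = 10, p = 1, seed = 12)
  ladder <- c(0.01, 0.1, 0.5, 1, 2, 5, 20, 1e3)
  nsel <- vapply(ladder, function(l)
    sum(fit_type1(inst$y, inst$x, inst$variances, l)$selected), numeric(1))
  expect_true(all(diff(nsel) <= 0))
})

test_that("uniform-variance fits match the rescaled-penalty fit", {
  inst <- random_instance(m = 15, n = 8, p = 1, seed = 14)
  s2 <- 0.37
  lam <- 1.3
  f1 <- fit_type1(inst$y, inst$x, rep(s2, 15), lam)
  f2 <- fit_type1(inst$y, inst$x, rep(1, 15), lam * s2)
  expect_identical(f1$selected, f2$selected)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$d, f2$d, tolerance = 1e-9)
})

test_that("normalization recovery reproduces the closed-form sum and shifts", {
  inst <- random_instance(m = 9, n = 7, p = 2, seed = 16)
  cd <- make_cd(inst)
  lam <- 1
  fit <- fit_type1(inst$y, inst$x, inst$variances, lam)
  bb <- weighted_beta_mean(fit$beta, inst$variances)
  xt <- cd$x_tilde
  for (i in c(1, 5, 9)) for (j in c(1, 4, 7)) {
    ref <- cd$row_means[i] + cd$weighted_col_means[j] -
      cd$grand_weighted_mean -
      sum(xt[j, ] * bb) - sum(cd$covariate_means * fit$beta[i, ])
    expect_equal(fit$alpha[i] + fit$d[j], ref, tolerance = 1e-10)
  }
  # adding a constant shifts intercepts, not offsets
  fit2 <- fit_type1(inst$y + 3.2, inst$x, inst$variances, lam)
  expect_equal(fit2$d, fit$d, tolerance = 1e-9)
  expect_equal(fit2$alpha, fit$alpha + 3.2, tolerance = 1e-9)
})

test_that("target-coefficient OLS agrees with full regression (p = 2)", {
  inst <- random_instance(m = 7, n = 10, p = 2, seed = 18)
  cd <- make_cd(inst)
  bp <- beta_p_ols(cd, delta_p = 0.4)
  for (i in 1:7) {
    ref <- unname(coef(lm(cd$y_tilde[i, ] ~ cd$x_tilde - 1))[2]) + 0.4
    expect_equal(bp[i], ref, tolerance = 1e-10)
  }
  # p = 1 reduces to the plain OLS coordinate
  inst1 <- random_instance(m = 5, n = 8, p = 1, seed = 19)
  cd1 <- make_cd(inst1)
  expect_equal(beta_p_ols(cd1, 0.2), drop(ols_betas(cd1, 0.2)),
               tolerance = 1e-12)
})

test_that("type-II keep rule refits killed genes under the reduced model", {
  inst <- random_instance(m = 6, n = 9, p = 2, seed = 21)
  cd <- make_cd(inst)
  res <- type2_keep_rule(cd, inst$variances, lambdas = Inf, delta_p = 0.7)
  expect_false(any(res$selected))
  expect_true(all(res$beta[, 2] == 0))
  xm <- cd$x_tilde[, 1, drop = FALSE]
  for (i in 1:6) {
    rhs <- cd$y_tilde[i, ] + cd$x_tilde[, 2] * 0.7
    ref <- drop(solve(crossprod(xm), crossprod(xm, rhs)))
    expect_equal(res$beta[i, 1], ref, tolerance = 1e-10)
  }
  keep <- type2_keep_rule(cd, inst$variances, lambdas = 0, delta_p = 0.7)
  expect_true(all(keep$selected))
})

test_that("type-II fit attains its exhaustive enumeration optimum", {
  for (k in 1:10) {
    inst <- random_instance(m = 5, n = 8, p = 2, seed = 200 + k)
    lam <- runif(5, 0.3, 3)
    fit <- fit_type2(inst$y, inst$x, inst$variances, lam)
    ref <- oracle_type2_optimum(inst$y, inst$x, inst$variances, lam)
    expect_equal(fit$objective, ref, tolerance = 1e-6)
  }
})

test_that("type-I and type-II fits coincide for a single covariate", {
  for (k in 1:10) {
    inst <- random_instance(m = 12, n = 9, p = 1, seed = 300 + k)
    lam <- select_lambda(0.05, 1, "type1")
    f1 <- fit_type1(inst$y, inst$x, inst$variances, lam)
    f2 <- fit_type2(inst$y, inst$x, inst$variances, lam)
    expect_identical(f1$selected, f2$selected)
    # estimates agree to the resolution of the shared-parameter refinement
    expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
    expect_equal(f1$d, f2$d, tolerance = 1e-6)
    expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
  }
})

test_that("multi-start optimization for p > 2 is deterministic and sane", {
  inst <- random_instance(m = 30, n = 12, p = 3, seed = 55)
  lam <- runif(30, 0.3, 2)
  d1 <- optimize_delta_type1(center_data(inst$y, inst$x, inst$variances),
                             inst$variances, lam, seed = 1)
  d2 <- optimize_delta_type1(center_data(inst$y, inst$x, inst$variances),
                             inst$variances, lam, seed = 1)
  expect_identical(d1, d2)
  cd <- center_data(inst$y, inst$x, inst$variances)
  ours <- type1_delta_objective(cd, inst$variances, lam, d1)
  set.seed(77)
  probes <- matrix(rnorm(3000, sd = 2), ncol = 3)
  vals <- apply(probes, 1, function(d)
    type1_delta_objective(cd, inst$variances, lam, d))
  expect_lte(ours, min(vals))
})
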