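test_that("intercept-only null fit equals the sample mean", {
  nul <- fit_null_model(c(0, 0, 1, 1))
  expect_equal(nul$yhat, rep(0.5, 4))
  expect_equal(fit_null_model(c(0, 1))$yhat, c(0.5, 0.5))
  nul2 <- fit_null_model(c(0, 1, 1, 1, 0, 1))
  expect_equal(nul2$yhat, rep(4 / 6, 6))
  expect_equal(nul2$v, nul2$yhat * (1 - nul2$yhat))
})

test_that("null fit satisfies the score equations with covariates", {
  set.seed(10)
  n <- 80
  Z <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * Z[, 1]))
  nul <- fit_null_model(y, Z)
  Zt <- cbind(1, Z)
  expect_lt(max(abs(crossprod(Zt, y - nul$yhat))), 1e-6)
  expect_true(all(nul$yhat > 0 & nul$yhat < 1))
})

test_that("null fit rejects degenerate inputs", {
  expect_error(fit_null_model(c(1, 1, 1)), "constant")
  # perfect separation
  y <- c(rep(0, 10), rep(1, 10))
  Z <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
  expect_error(fit_null_model(y, Z), "separation|converge")
  # rank-deficient covariates
  Z2 <- cbind(a = rep(1, 6), b = rep(2, 6))
  expect_error(fit_null_model(c(0, 1, 0, 1, 0, 1), Z2), "rank")
})

test_that("score statistic equals the direct triple-loop quadratic form", {
  set.seed(11)
  y <- rbinom(20, 1, 0.5); y[1] <- 0; y[2] <- 1
  nul <- fit_null_model(y)
  A <- matrix(rnorm(400), 20); K <- crossprod(A) / 20
  Q <- score_statistic(y, nul, K)
  r <- y - nul$yhat
  brute <- 0
  for (i in 1:20) for (j in 1:20) brute <- brute + r[i] * K[i, j] * r[j]
  expect_equal(Q, brute, tolerance = 1e-12)
  expect_equal(score_statistic(y, nul, matrix(0, 20, 20)), 0)
  # K = identity, balanced y: Q = n * 0.25
  yb <- rep(c(0, 1), 10)
  expect_equal(score_statistic(yb, fit_null_model(yb), diag(20)), 20 * 0.25)
})

test_that("mixture weights reproduce the closed-form projection for K = I", {
  yb <- rep(c(0, 1), 8)                       # balanced, intercept-only
  nul <- fit_null_model(yb)
  w <- mixture_weights(diag(16), nul)
  expect_length(w$lambdas, 15)                # n - 1
  expect_equal(w$lambdas, rep(0.25, 15), tolerance = 1e-10)
  # K = 0: degenerate, empty weights
  w0 <- mixture_weights(matrix(0, 16, 16), nul)
  expect_length(w0$lambdas, 0)
  expect_equal(mixture_pvalue(0, w0)$method, "degenerate")
})

test_that("mixture weights satisfy the trace identity on random instances", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 30
    Z <- matrix(rnorm(n * 2), n)
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    nul <- fit_null_model(y, Z)
    A <- matrix(rnorm(n * n), n); K <- crossprod(A) / n
    w <- mixture_weights(K, nul)
    # sum of retained eigenvalues = tr(P0 K), P0 built independently here
    v <- nul$v; Zt <- cbind(1, Z)
    P0 <- diag(v) - (v * Zt) %*% solve(t(Zt) %*% (v * Zt)) %*% t(v * Zt)
    expect_equal(sum(w$lambdas), sum(diag(P0 %*% K)), tolerance = 1e-8)
    expect_false(is.unsorted(rev(w$lambdas)))
  }
})

test_that("covariate-adjusted mixture matches a Gaussian Monte-Carlo tail", {
  # r ~ N(0, P0) makes Q = r'Kr an exact lambda-chi-square mixture; the
  # Davies tail must match the empirical tail of simulated draws
  set.seed(13)
  n <- 25
  Z <- matrix(rnorm(n), n)
  y <- rbinom(n, 1, 0.6); y[1:2] <- 0:1
  nul <- fit_null_model(y, Z)
  A <- matrix(rnorm(n * n), n); K <- crossprod(A) / n
  w <- mixture_weights(K, nul)
  v <- nul$v; Zt <- cbind(1, Z)
  P0 <- diag(v) - (v * Zt) %*% solve(t(Zt) %*% (v * Zt)) %*% t(v * Zt)
  ch <- chol(P0 + 1e-12 * diag(n))
  B <- 200000
  R <- matrix(rnorm(B * n), B) %*% ch
  Qs <- rowSums((R %*% K) * R)
  for (pt in c(0.5, 0.1, 0.02)) {
    qq <- quantile(Qs, 1 - pt)
    pd <- mixture_pvalue(qq, w)$p
    se <- sqrt(pt * (1 - pt) / B)
    expect_lt(abs(pd - pt), 4 * se)
  }
})

test_that("mixture p-value matches chi-square closed forms", {
  # single weight: chi2_1 survival
  expect_equal(mixture_pvalue(3.841459, 1)$p, 0.05, tolerance = 1e-6)
  # equal weights: chi2_k survival, across k and tail depths
  for (k in c(2, 5, 10)) for (pt in c(0.5, 0.05, 1e-6)) {
    q <- qchisq(pt, df = k, lower.tail = FALSE)
    res <- mixture_pvalue(q, rep(1, k))
    expect_equal(res$method, "davies")
    expect_equal(res$p, pt, tolerance = 1e-9)
  }
  # scaled equal weights
  expect_equal(mixture_pvalue(2 * qchisq(0.01, 3, lower.tail = FALSE),
                              rep(2, 3))$p, 0.01, tolerance = 1e-9)
  expect_equal(mixture_pvalue(0, c(2, 1))$p, 1)
  expect_error(mixture_pvalue(NaN, c(1)), "non-finite")
})

test_that("moment-matching fallback approximates the mixture tail", {
  lam <- c(3, 1.5, 0.7, 0.2)
  for (pt in c(0.2, 0.05, 0.01)) {
    q <- quantile_of <- {
      # invert the Davies tail by root finding to get the exact quantile
      uniroot(function(x) mckat:::davies_pvalue(x, lam)$p - pt,
              c(1e-6, 200))$root
    }
    expect_equal(mckat:::liu_pvalue(q, lam), pt, tolerance = 0.25)
  }
})

test_that("test_region composes the pipeline and flags degenerate regions", {
  set.seed(14)
  ps <- random_profile_set(30)
  y <- rbinom(30, 1, 0.5); y[1:2] <- 0:1
  ph <- phenotype_table(ps$subjects, y)
  res <- test_region(ps, ph, "1")
  expect_s3_class(res, "mckat_result")
  expect_gte(res$Q, 0)
  expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
  expect_equal(res$n_cnvs, sum(ps$cnv$chrom == "1"))
  # empty region
  res0 <- test_region(ps, ph, "9")
  expect_equal(res0$p_value, 1)
  expect_equal(res0$Q, 0)
  expect_equal(res0$method, "degenerate")
  expect_match(res0$note, "degenerate")
  # misaligned cohort is rejected
  ph2 <- phenotype_table(rev(ps$subjects), y)
  expect_error(test_region(ps, ph2, "1"), "align")
})

test_that("permutation moments of Q match the mixture moments", {
  # E[Q] under label permutation equals the sum of mixture weights
  # (validates both the weights and the statistic); the variance is
  # bounded above by the Gaussian mixture variance for binary traits
  set.seed(15)
  ps <- random_profile_set(60)
  y <- rep(c(0, 1), 30)
  ph <- phenotype_table(ps$subjects, y)
  km <- kernel_matrix(ps, "1")
  nul <- fit_null_model(ph$y)
  w <- mixture_weights(km, nul)
  B <- 4000
  r0 <- ph$y - mean(ph$y)
  Qs <- replicate(B, {
    r <- sample(r0)
    drop(crossprod(r, km$K %*% r))
  })
  se <- sd(Qs) / sqrt(B)
  expect_lt(abs(mean(Qs) - sum(w$lambdas)), 4 * se)
  expect_lte(var(Qs), 2 * sum(w$lambdas^2) * 1.1)
})
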