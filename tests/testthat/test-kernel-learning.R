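test_that("projected Gram matches closed forms and the dense oracle", {
  # residuals orthogonal to every genotype column -> zero component scores
  d <- make_dataset(30, n = 50, p = 3, m = 1)
  f <- fit_null(d)
  f0 <- f
  Gq <- qr.Q(qr(cbind(1, d$G)))
  f0$r <- rnorm(50)
  f0$r <- f0$r - Gq %*% crossprod(Gq, f0$r)
  expect_lt(max(projected_gram(f0, d$G)$s), 1e-18)

  # intercept-only continuous: B = sigma0^2 * Gc'Gc
  d2 <- make_dataset(31, n = 40, p = 3, m = 0)
  f2 <- fit_null(d2)
  Gc <- sweep(d2$G, 2, colMeans(d2$G))
  pg2 <- projected_gram(f2, d2$G)
  expect_equal(pg2$B, f2$phi0 * crossprod(Gc), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(pg2$b, diag(pg2$B))

  # dense oracle, with covariates and both traits
  for (trait in c("continuous", "binary")) {
    d3 <- make_dataset(32, n = 30, p = 3, m = 2, trait = trait)
    f3 <- fit_null(d3)
    P0 <- dense_p0_oracle(f3$v, d3$X)
    pg3 <- projected_gram(f3, d3$G)
    expect_equal(pg3$B, t(d3$G) %*% P0 %*% d3$G, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(pg3$s, as.numeric(crossprod(d3$G, f3$r))^2, tolerance = 1e-12)
  }
})

test_that("objective reduces on coordinate vectors and via the eigen route", {
  d <- make_dataset(33, n = 60, p = 4, m = 1)
  f <- fit_null(d)
  pg <- projected_gram(f, d$G)
  for (j in 1:4) {
    ej <- weight_vector(as.numeric(seq_len(4) == j))
    expect_equal(kernel_objective(pg, ej), pg$s[j] / pg$B[j, j],
                 tolerance = 1e-10)
    expect_equal(kernel_objective(pg, ej, centered = TRUE),
                 (pg$s[j] - pg$b[j]) / pg$B[j, j], tolerance = 1e-10)
  }
  # ratio identity: J(w) = Q(w) / ||lambda0(w)||_2, dispersion cancelling
  for (trait in c("continuous", "binary")) {
    dt <- make_dataset(34, n = 150, p = 6, m = 2, trait = trait)
    ft <- fit_null(dt)
    pgt <- projected_gram(ft, dt$G)
    for (k in 1:5) {
      w <- weight_vector(runif(6))
      J <- kernel_objective(pgt, w)
      Q <- skat_statistic(ft, dt$G, w)
      lam <- null_eigenvalues(ft, dt$G, w)$lambdas
      expect_equal(J, Q / sqrt(sum(lam^2)), tolerance = 1e-8)
    }
  }
})

test_that("QP solution is optimal: separable case, KKT, and simplex grid", {
  # identity quadratic: solution proportional to the positive part of c
  pg_id <- structure(list(B = diag(3), s = c(2, 0.5, 1), b = rep(1, 3),
                          phi0 = 1), class = "ecskat_gram")
  w <- solve_weights(pg_id)
  expect_equal(w$w, c(2, 0.5, 1) / 3.5, tolerance = 1e-8)
  expect_false(attr(w, "no_signal"))
  # centered: c = s - b = (1, -0.5, 0): negative part clipped
  wc <- solve_weights(pg_id, centered = TRUE)
  expect_equal(wc$w, c(1, 0, 0), tolerance = 1e-8)
  # no learnable signal -> uniform fallback, flagged
  pg0 <- structure(list(B = diag(3), s = rep(0, 3), b = rep(1, 3), phi0 = 1),
                   class = "ecskat_gram")
  w0 <- solve_weights(pg0)
  expect_true(attr(w0, "no_signal"))
  expect_equal(w0$w, rep(1 / 3, 3))

  # random instances: optimum over a fine simplex grid, KKT residual small
  grid <- simplex_grid3(0.02)
  set.seed(44)
  for (k in 1:5) {
    d <- make_dataset(50 + k, n = 80, p = 3, m = 1,
                      beta = c(0.5, 0, 0) * (k %% 2))
    f <- fit_null(d)
    pg <- projected_gram(f, d$G)
    ws <- solve_weights(pg)
    expect_lt(attr(ws, "kkt_residual"), 1e-6 * max(1, max(pg$s)))
    Jstar <- kernel_objective(pg, ws)
    Jgrid <- apply(grid, 1, function(g) {
      if (sum(g) == 0) return(-Inf)
      kernel_objective(pg, weight_vector(g))
    })
    expect_gte(Jstar, max(Jgrid) - 1e-6)
  }
})

test_that("bound and certification formulas are correct and monotone", {
  expect_equal(pvalue_bound(8), exp(-1))
  expect_equal(pvalue_bound(0), 1)
  expect_equal(pvalue_bound(0.5), exp(-0.25 / 8))
  expect_equal(pvalue_bound(-3), 1)
  expect_equal(certified_level(0), 0)
  expect_equal(certified_level(8 * log(10)), 1)
  js <- seq(-2, 20, by = 0.25)
  expect_true(all(diff(vapply(js, certified_level, numeric(1))) >= 0))
  expect_true(all(diff(vapply(js, pvalue_bound, numeric(1))) <= 0))
  # bound and certificate are consistent: bound <= 10^-certified
  for (j in js) expect_lte(pvalue_bound(j), 10^-certified_level(j) + 1e-12)
})

test_that("null p-value never exceeds the exponential bound", {
  set.seed(77)
  for (k in 1:10) {
    trait <- if (k %% 2) "continuous" else "binary"
    d <- make_dataset(60 + k, n = 120, p = 5, m = 2, trait = trait)
    f <- fit_null(d)
    pg <- projected_gram(f, d$G)
    ws <- list(solve_weights(pg), weight_vector(runif(5)))
    for (w in ws) {
      Q <- skat_statistic(f, d$G, w)
      p <- as.numeric(mixchisq_survival(null_eigenvalues(f, d$G, w), Q))
      Jm <- kernel_objective(pg, w, centered = TRUE)
      expect_lte(p, pvalue_bound(Jm) + 1e-9)
    }
  }
})

test_that("ecskat split-learn-test is deterministic and honors its contract", {
  d <- make_dataset(70, n = 240, p = 6, m = 2, beta = c(0.6, -0.4, 0, 0, 0, 0))
  r1 <- ecskat_test(d, seed = 5)
  r2 <- ecskat_test(d, seed = 5)
  expect_identical(r1$weights$w, r2$weights$w)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$train_idx, r2$train_idx)
  # split partitions the samples
  expect_length(intersect(r1$train_idx, r1$test_idx), 0)
  expect_setequal(c(r1$train_idx, r1$test_idx), seq_len(240))
  expect_equal(length(r1$train_idx), round(0.3 * 240))
  expect_equal(r1$bound, pvalue_bound(r1$J_mod))
  # stratified split for binary traits preserves both classes
  db <- make_dataset(71, n = 200, p = 4, m = 1, trait = "binary")
  rb <- ecskat_test(db, seed = 9)
  expect_gt(length(unique(db$y[rb$train_idx])), 1)
  expect_gt(length(unique(db$y[rb$test_idx])), 1)
  expect_error(ecskat_test(d, train_ratio = 0.005, seed = 1), "small")
})

test_that("weights and p-value are invariant to genotype column scaling", {
  d <- make_dataset(72, n = 150, p = 4, m = 1, beta = c(0.5, 0, 0, 0))
  f <- fit_null(d)
  pg1 <- projected_gram(f, d$G)
  pg2 <- projected_gram(f, 3 * d$G)
  w1 <- solve_weights(pg1); w2 <- solve_weights(pg2)
  expect_equal(w1$w, w2$w, tolerance = 1e-6)
  wfix <- weight_vector(runif(4))
  p1 <- mixchisq_survival(null_eigenvalues(f, d$G, wfix),
                          skat_statistic(f, d$G, wfix))
  p2 <- mixchisq_survival(null_eigenvalues(f, 3 * d$G, wfix),
                          skat_statistic(f, 3 * d$G, wfix))
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-8)
})

test_that("multi-kernel statistics reduce to the per-variant sufficient statistics", {
  d <- make_dataset(73, n = 50, p = 4, m = 1)
  f <- fit_null(d)
  pg <- projected_gram(f, d$G)
  # per-variant rank-one kernels
  feats <- lapply(1:4, function(j) d$G[, j, drop = FALSE])
  mk <- multi_kernel_stats(f, feats, is_feature = rep(TRUE, 4))
  expect_equal(mk$s, pg$s, tolerance = 1e-10)
  expect_equal(mk$M, pg$B * pg$B, tolerance = 1e-8, ignore_attr = TRUE)
  # same result from dense n x n kernel matrices
  kerns <- lapply(feats, function(fm) fm %*% t(fm))
  mk2 <- multi_kernel_stats(f, kerns, is_feature = rep(FALSE, 4))
  expect_equal(mk2$s, pg$s, tolerance = 1e-6)
  expect_equal(mk2$M, pg$B * pg$B, tolerance = 1e-4, ignore_attr = TRUE)
  # L = 1: M11 = ||lambda0||^2 phi0^2 and s1 = Q phi0
  w <- weight_vector(rep(1, 4))
  Kw <- d$G %*% diag(w$w) %*% t(d$G)
  mk3 <- multi_kernel_stats(f, list(d$G %*% diag(sqrt(w$w))),
                            is_feature = TRUE)
  lam <- null_eigenvalues(f, d$G, w)$lambdas
  expect_equal(mk3$M[1, 1], sum(lam^2) * f$phi0^2, tolerance = 1e-8)
  expect_equal(mk3$s[1], skat_statistic(f, d$G, w) * f$phi0, tolerance = 1e-10)
  # annotation-style kernels G diag(phi(a)) G' with phi(x) = x^2
  a <- runif(4)
  Fl <- d$G %*% diag(a)                    # feature map with D = diag(a^2)...
  mk4 <- multi_kernel_stats(f, list(Fl), is_feature = TRUE)
  Kann <- d$G %*% diag(a^2) %*% t(d$G)
  expect_equal(mk4$s[1], as.numeric(t(f$r) %*% Kann %*% f$r), tolerance = 1e-8)
})
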