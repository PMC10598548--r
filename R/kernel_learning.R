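#' Sufficient statistics for kernel learning
#'
#' Everything the weight-learning objective needs, condensed to p-by-p:
#' the projected Gram matrix \eqn{B = G^\top P_0 G}, the component score
#' vector \eqn{s = (G^\top r)^2} (square taken elementwise), its centering
#' counterpart \eqn{b = \mathrm{diag}(B)}, and the dispersion carried along
#' for eigenvalue use. B is built in operator form, cost O(np^2 + nmp).
#'
#' @param fit an `ecskat_null` from [fit_null()].
#' @param G genotype (or feature) matrix with one row per sample.
#' @return An object of class `ecskat_gram`: list with `B`, `s`, `b`,
#'   `phi0`.
#' @export
projected_gram <- function(fit, G) {
  stopifnot(inherits(fit, "ecskat_null"))
  G <- as.matrix(G)
  B <- unname(crossprod(G, projection_apply(fit, G)))
  B <- (B + t(B)) / 2
  s <- as.numeric(crossprod(G, fit$r))^2
  structure(list(B = B, s = s, b = unname(diag(B)), phi0 = fit$phi0),
            class = "ecskat_gram")
}

#' Kernel-alignment objective for simplex weights
#'
#' The criterion maximized by the weight learner:
#' \deqn{J(w) = \frac{w^\top s}{\sqrt{w^\top (B \odot B) w}}}
#' (\eqn{\odot} the elementwise product), which equals the SKAT statistic
#' divided by the Euclidean norm of its null eigen-spectrum — large J means
#' the observed score sits far out in its own null distribution. The
#' centered form replaces the numerator by \eqn{w^\top(s - b)}, subtracting
#' the null mean of each component score; it is the quantity the p-value
#' upper bound ([pvalue_bound()]) is driven by.
#'
#' @param pg an `ecskat_gram` from [projected_gram()].
#' @param weights an `ecskat_weights`.
#' @param centered use the centered numerator \eqn{w^\top(s-b)}.
#' @return scalar objective value.
#' @export
kernel_objective <- function(pg, weights, centered = FALSE) {
  stopifnot(inherits(pg, "ecskat_gram"), inherits(weights, "ecskat_weights"))
  w <- weights$w
  num <- if (centered) sum(w * (pg$s - pg$b)) else sum(w * pg$s)
  den2 <- sum(w * ((pg$B * pg$B) %*% w))
  if (den2 <= 0)
    stop("zero denominator: weights are supported on variants annihilated by P0")
  num / sqrt(den2)
}

#' Learn kernel weights by quadratic programming
#'
#' Solves \deqn{\min_{z \ge 0}\; z^\top (B \odot B) z - 2 z^\top c} with
#' \eqn{c = s} (or \eqn{s - b} when `centered`) and returns the normalized
#' maximizer \eqn{w^* = z^*/\sum z^*} of the scale-invariant objective
#' [kernel_objective()] over the simplex. \eqn{B \odot B} is positive
#' semi-definite (Schur product of PSD matrices); a small ridge retry
#' handles semi-definite cases. When the solution is identically zero there
#' is no learnable signal and uniform weights are returned with
#' `no_signal = TRUE`.
#'
#' @inheritParams kernel_objective
#' @return An `ecskat_weights` with source `"learned"` and attributes
#'   `no_signal` (logical) and `kkt_residual` (max KKT violation of the
#'   returned z*).
#' @export
solve_weights <- function(pg, centered = FALSE) {
  stopifnot(inherits(pg, "ecskat_gram"))
  M <- pg$B * pg$B
  cvec <- if (centered) pg$s - pg$b else pg$s
  p <- length(cvec)
  if (all(cvec <= 0)) {
    w <- weight_vector(rep(1, p), source = "learned")
    attr(w, "no_signal") <- TRUE
    attr(w, "kkt_residual") <- 0
    return(w)
  }
  ridge0 <- 1e-8 * sum(diag(M)) / p
  kkt_of <- function(z) {
    grad <- 2 * (M %*% z - cvec)
    act <- z > 1e-10
    max(0, if (any(act)) max(abs(grad[act])) else 0,
        if (any(!act)) max(-grad[!act]) else 0)
  }
  scale <- max(abs(cvec))
  z <- NULL; kkt <- Inf
  for (ridge in c(0, ridge0, 100 * ridge0)) {
    sol <- tryCatch(suppressWarnings(
      pracma::quadprog(2 * (M + ridge * diag(p)), -2 * cvec, lb = rep(0, p))),
      error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol$xmin))) next
    zc <- pmax(sol$xmin, 0)
    kc <- kkt_of(zc)
    if (kc < kkt) { z <- zc; kkt <- kc }
    if (kkt <= 1e-8 * max(scale, 1)) break
  }
  if (is.null(z)) stop("QP solver failed even after ridge retries")
  if (sum(z) <= 0) {
    w <- weight_vector(rep(1, p), source = "learned")
    attr(w, "no_signal") <- TRUE
  } else {
    w <- weight_vector(z, source = "learned")
    attr(w, "no_signal") <- FALSE
  }
  attr(w, "kkt_residual") <- kkt
  w
}

#' Exponential upper bound on the null p-value
#'
#' For the centered objective value \eqn{\tilde J} the asymptotic null
#' p-value of the corresponding SKAT statistic satisfies
#' \deqn{p \le \exp\{-\min(\tilde J, \tilde J^2)/8\},}
#' a sub-exponential (Bernstein-type) tail bound for convex combinations of
#' independent \eqn{\chi^2_1} variables. Nonpositive \eqn{\tilde J} gives
#' the vacuous bound 1.
#'
#' @param J_mod centered objective value (finite scalar).
#' @return bound in `[0, 1]`.
#' @examples
#' pvalue_bound(8)    # exp(-1)
#' pvalue_bound(0)    # 1
#' @export
pvalue_bound <- function(J_mod) {
  stopifnot(is.finite(J_mod))
  min(1, exp(-min(J_mod, J_mod^2) / 8))
}

#' Certified significance exponent
#'
#' The largest \eqn{a \ge 0} such that the p-value upper bound certifies
#' \eqn{p \le 10^{-a}}: \eqn{a = \min(\tilde J, \tilde J^2)/(8 \ln 10)} when
#' positive, else 0.
#'
#' @inheritParams pvalue_bound
#' @return nonnegative scalar.
#' @export
certified_level <- function(J_mod) {
  stopifnot(is.finite(J_mod))
  max(0, min(J_mod, J_mod^2) / (8 * log(10)))
}

#' ecSKAT: learn kernel weights on a split, test on the rest
#'
#' The full data-driven procedure: (1) randomly split the samples with the
#' given learning fraction (stratified by case/control for binary traits);
#' (2) on the learning split, fit the null model, form the sufficient
#' statistics and solve the QP for the simplex weights; (3) on the held-out
#' split, refit the null model independently and run the SKAT score test
#' with the learned weights held fixed. Only the held-out split contributes
#' to the reported p-value, which is what keeps the test valid despite the
#' weights being data-dependent. The centered objective on the learning
#' split yields the certified p-value upper bound.
#'
#' @param dataset an [ecskat_dataset].
#' @param train_ratio fraction of samples used for weight learning, in
#'   (0, 1). Default 0.3.
#' @param seed optional integer seed controlling the split.
#' @param centered learn with the centered objective instead of the plain
#'   one (the bound always uses the centered value).
#' @return An object of class `ecskat_learned`: list with `weights`
#'   (`ecskat_weights`), `J` (plain objective at w*), `J_mod` (centered
#'   objective at w*), `bound` (p-value upper bound from `J_mod`),
#'   `certified` (exponent from [certified_level()]), `train_idx`,
#'   `test_idx`, `result` (the held-out `ecskat_result`), and `p_value`
#'   (shortcut to `result$p_value`).
#' @examples
#' set.seed(7)
#' G <- matrix(rbinom(3000, 2, 0.05), 500, 6)
#' d <- ecskat_dataset(rnorm(500) + G[, 1], NULL, G, "continuous")
#' ecskat_test(d, seed = 1)
#' @export
ecskat_test <- function(dataset, train_ratio = 0.3, seed = NULL,
                        centered = FALSE) {
  stopifnot(inherits(dataset, "ecskat_dataset"),
            train_ratio > 0, train_ratio < 1)
  n <- length(dataset$y)
  m <- ncol(dataset$X)
  if (!is.null(seed)) set.seed(seed)

  if (dataset$trait_type == "binary") {
    idx1 <- which(dataset$y == 1)
    idx0 <- which(dataset$y == 0)
    tr <- c(sample(idx1, max(1L, round(train_ratio * length(idx1)))),
            sample(idx0, max(1L, round(train_ratio * length(idx0)))))
  } else {
    tr <- sample.int(n, round(train_ratio * n))
  }
  tr <- sort(tr)
  ts <- setdiff(seq_len(n), tr)
  if (length(tr) < m + 2L || length(ts) < m + 2L)
    stop("split too small to fit the null model on both parts")

  subset_ds <- function(idx) {
    ecskat_dataset(dataset$y[idx], dataset$X[idx, , drop = FALSE],
                   dataset$G[idx, , drop = FALSE], dataset$trait_type,
                   sample_ids = dataset$sample_ids[idx],
                   variant_ids = dataset$variant_ids)
  }
  d_tr <- subset_ds(tr)
  d_ts <- subset_ds(ts)

  fit_tr <- fit_null(d_tr)
  pg <- projected_gram(fit_tr, d_tr$G)
  w <- solve_weights(pg, centered = centered)
  J <- kernel_objective(pg, w, centered = FALSE)
  J_mod <- kernel_objective(pg, w, centered = TRUE)

  fit_ts <- fit_null(d_ts)
  res <- skat_test(d_ts, fit_ts, w)
  res$method <- "ecskat"

  structure(list(weights = w, J = J, J_mod = J_mod,
                 bound = pvalue_bound(J_mod),
                 certified = certified_level(J_mod),
                 train_idx = tr, test_idx = ts,
                 result = res, p_value = res$p_value),
            class = "ecskat_learned")
}

#' @export
print.ecskat_learned <- function(x, ...) {
  cat(sprintf("ecskat: p = %.4g (held-out n = %d), J = %.4g, bound = %.4g\n",
              x$p_value, length(x$test_idx), x$J, x$bound))
  nz <- sum(x$weights$w > 1e-6)
  cat(sprintf("learned weights: %d of %d above 1e-6%s\n", nz,
              length(x$weights$w),
              if (isTRUE(attr(x$weights, "no_signal"))) " [no-signal fallback]" else ""))
  invisible(x)
}

#' Sufficient statistics for arbitrary base kernels
#'
#' Generalizes [projected_gram()] from per-variant rank-one kernels to any
#' list of positive semi-definite base kernels: returns
#' \eqn{s_l = r^\top K_l r} and \eqn{M_{lm} = \mathrm{tr}(P_0 K_l P_0 K_m)},
#' the quantities that drive the same QP over kernel-combination weights.
#' Each base kernel is given either as an n-by-n PSD matrix or as an
#' n-by-d feature matrix \eqn{F_l} (then \eqn{K_l = F_l F_l^\top}; this path
#' never forms an n-by-n matrix). With the per-variant feature columns of G
#' this reduces exactly to `(s, B * B)` from [projected_gram()].
#'
#' @param fit an `ecskat_null`.
#' @param base_kernels list; each element an n-by-n symmetric PSD matrix or
#'   an n-by-d feature matrix (disambiguated by `is_feature`).
#' @param is_feature logical vector (recycled) marking feature-matrix
#'   entries; defaults to treating square matrices as kernels.
#' @return list with `s` (length-L numeric) and `M` (L-by-L PSD matrix).
#' @export
multi_kernel_stats <- function(fit, base_kernels, is_feature = NULL) {
  stopifnot(inherits(fit, "ecskat_null"), is.list(base_kernels))
  n <- length(fit$r)
  L <- length(base_kernels)
  if (is.null(is_feature))
    is_feature <- vapply(base_kernels, function(K) !(nrow(as.matrix(K)) == n && ncol(as.matrix(K)) == n), logical(1))
  is_feature <- rep_len(is_feature, L)

  # Factor every kernel as K_l = F_l F_l' and keep F_l plus P0 F_l; then
  # s_l = ||F_l' r||^2 and tr(P0 K_l P0 K_m) = ||F_l' (P0 F_m)||_F^2.
  fac <- vector("list", L)
  pf <- vector("list", L)
  s <- numeric(L)
  for (l in seq_len(L)) {
    K <- as.matrix(base_kernels[[l]])
    if (is_feature[l]) {
      Fl <- K
    } else {
      if (nrow(K) != n || ncol(K) != n) stop("kernel ", l, " has wrong dimensions")
      K <- (K + t(K)) / 2
      ch <- tryCatch(chol(K + 1e-10 * mean(diag(K)) * diag(n)),
                     error = function(e) NULL)
      if (is.null(ch)) stop("kernel ", l, " is not positive semi-definite")
      Fl <- t(ch)
    }
    if (nrow(Fl) != n) stop("kernel ", l, " has wrong number of rows")
    fac[[l]] <- Fl
    s[l] <- sum(as.numeric(crossprod(Fl, fit$r))^2)
    pf[[l]] <- projection_apply(fit, Fl)
  }
  M <- matrix(0, L, L)
  for (l in seq_len(L)) {
    for (mm in l:L) {
      M[l, mm] <- M[mm, l] <- sum(crossprod(fac[[l]], pf[[mm]])^2)
    }
  }
  list(s = s, M = M)
}
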