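#' Fit the null generalized linear model
#'
#' Regresses the trait on the intercept plus the non-genetic covariates only
#' (no genotypes), by maximum likelihood: ordinary least squares under the
#' identity link for continuous traits, logistic regression (IRLS) for
#' binary traits. The fit carries everything the score tests need — fitted
#' means, raw residuals, the dispersion estimate and the conditional
#' variances that define the projection \eqn{P_0}.
#'
#' The continuous dispersion is the maximum-likelihood estimate
#' \eqn{\hat\sigma_0^2 = \sum r_i^2 / n}; set `dispersion = "unbiased"` for
#' the \eqn{n - m - 1} denominator used by some implementations. Binary
#' dispersion is fixed at 1 and the conditional variances are
#' \eqn{\hat\mu_i(1-\hat\mu_i)}.
#'
#' @param dataset an [ecskat_dataset] (only `y`, `X`, `trait_type` are used).
#' @param dispersion `"ml"` (divide by n, default) or `"unbiased"`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step (binary traits only).
#' @return An object of class `ecskat_null`: list with `alpha0` (intercept),
#'   `alpha` (covariate coefficients), `mu0` (fitted means), `r` (raw
#'   residuals `y - mu0`), `phi0` (dispersion), `v` (conditional variances),
#'   `trait_type`, and `X` (the covariate matrix, kept for projections).
#' @examples
#' d <- ecskat_dataset(c(1, 2, 3), NULL, matrix(0:2, 3, 1), "continuous")
#' f <- fit_null(d)
#' f$mu0  # all equal to mean(y)
#' @export
fit_null <- function(dataset, dispersion = c("ml", "unbiased"),
                     maxit = 100L, tol = 1e-8) {
  stopifnot(inherits(dataset, "ecskat_dataset"))
  dispersion <- match.arg(dispersion)
  y <- dataset$y
  X <- dataset$X
  n <- length(y)
  m <- ncol(X)
  Xt <- cbind(`(Intercept)` = 1, X)
  if (n <= m + 1L) stop("need n > m + 1 samples to fit the null model")
  if (qr(Xt)$rank < ncol(Xt)) stop("null design [1 | X] is rank-deficient")

  if (dataset$trait_type == "continuous") {
    fit <- lm.fit(Xt, y)
    mu0 <- as.numeric(fit$fitted.values)
    r <- y - mu0
    denom <- if (dispersion == "ml") n else n - m - 1L
    phi0 <- sum(r^2) / denom
    if (phi0 <= 0) stop("residual variance is zero; trait is exactly linear in X")
    v <- rep(phi0, n)
    coefs <- fit$coefficients
  } else {
    # convergence and separation are checked explicitly below
    fit <- suppressWarnings(glm.fit(Xt, y, family = binomial(),
                                    control = list(maxit = maxit, epsilon = tol)))
    if (!fit$converged)
      stop("logistic null model did not converge (possible separation)")
    mu0 <- as.numeric(fit$fitted.values)
    eps <- .Machine$double.eps
    if (any(mu0 < eps) || any(mu0 > 1 - eps))
      stop("fitted probabilities at machine bounds (separation)")
    r <- y - mu0
    phi0 <- 1
    v <- mu0 * (1 - mu0)
    coefs <- fit$coefficients
  }
  structure(list(alpha0 = unname(coefs[1]), alpha = unname(coefs[-1]),
                 mu0 = mu0, r = r, phi0 = phi0, v = v,
                 trait_type = dataset$trait_type, X = X),
            class = "ecskat_null")
}

#' Apply the null-model projection P0 to a matrix
#'
#' Computes \eqn{P_0 M} where
#' \eqn{P_0 = V - V\tilde X(\tilde X^\top V \tilde X)^{-1}\tilde X^\top V},
#' \eqn{V = \mathrm{diag}(v)} holds the null conditional variances and
#' \eqn{\tilde X = [1\,|\,X]} is the intercept-augmented design. The n-by-n
#' matrix is never formed: the cost is two solves against the (m+1)-by-(m+1)
#' weighted Gram matrix, O(nmk) for an n-by-k input.
#'
#' @param fit an `ecskat_null` from [fit_null()].
#' @param M numeric matrix (or vector) with one row per sample.
#' @return `P0 %*% M`, same shape as `M`.
#' @export
projection_apply <- function(fit, M) {
  stopifnot(inherits(fit, "ecskat_null"))
  M <- as.matrix(M)
  v <- fit$v
  if (nrow(M) != length(v)) stop("M has the wrong number of rows")
  Xt <- cbind(1, fit$X)
  VX <- v * Xt
  A <- crossprod(Xt, VX)                 # X~' V X~
  VM <- v * M
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) stop("X~' V X~ is singular")
  VM - VX %*% backsolve(ch, forwardsolve(t(ch), crossprod(Xt, VM)))
}

#' Dense P0 matrix (small-n testing path)
#'
#' Materializes the projection of [projection_apply()] as an n-by-n matrix.
#' Intended for oracles and small problems; refuses n > 2000.
#'
#' @param fit an `ecskat_null`.
#' @return n-by-n symmetric positive semi-definite matrix.
#' @export
p0_matrix <- function(fit) {
  n <- length(fit$v)
  if (n > 2000L) stop("dense P0 is only for small n; use projection_apply()")
  projection_apply(fit, diag(n))
}
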