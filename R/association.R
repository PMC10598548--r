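#' Construct a kernel weight vector on the simplex
#'
#' @param w nonnegative numeric vector with at least one positive entry;
#'   normalized to sum to one.
#' @param source label recording where the weights came from.
#' @return An object of class `ecskat_weights`.
#' @export
weight_vector <- function(w, source = c("custom", "uniform", "beta_pdf", "learned")) {
  source <- match.arg(source)
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and nonnegative")
  tot <- sum(w)
  if (tot <= 0) stop("weights must have a positive sum")
  structure(list(w = w / tot, source = source), class = "ecskat_weights")
}

#' Minor-allele-frequency keyed Beta-density weights
#'
#' The classical SKAT weighting: each variant's weight is the Beta(a, b)
#' density evaluated at its sample minor-allele frequency
#' \eqn{\hat m_j = \mathrm{mean}(G_{\cdot j})/2}, squared by default (the
#' original convention) and normalized onto the simplex. With `a = b = 1`
#' the weights are uniform. Beta(1, 25) up-weights rare variants sharply.
#'
#' @param G genotype matrix of minor-allele counts.
#' @param a,b positive Beta shape parameters.
#' @param squared square the density before normalizing (default `TRUE`).
#' @return An [weight_vector()] with source `"beta_pdf"` (or `"uniform"`
#'   when `a = b = 1`).
#' @export
maf_weights <- function(G, a = 1, b = 25, squared = TRUE) {
  stopifnot(a > 0, b > 0)
  maf <- colMeans(as.matrix(G)) / 2
  if (any(maf == 0))
    warning(sprintf("%d monomorphic variant(s); weight taken at the density value", sum(maf == 0)))
  raw <- dbeta(maf, a, b)
  if (squared) raw <- raw^2
  weight_vector(raw, source = if (a == 1 && b == 1) "uniform" else "beta_pdf")
}

#' SKAT variance-component score statistic
#'
#' \eqn{Q = r^\top K r / \hat\phi_0} for the weighted linear kernel
#' \eqn{K = G\,\mathrm{diag}(w)\,G^\top}, computed in factored form
#' \eqn{\sum_j w_j (g_j^\top r)^2 / \hat\phi_0} without building K.
#'
#' @param fit an `ecskat_null` from [fit_null()].
#' @param G genotype matrix.
#' @param weights an `ecskat_weights`.
#' @return nonnegative scalar.
#' @export
skat_statistic <- function(fit, G, weights) {
  stopifnot(inherits(fit, "ecskat_null"), inherits(weights, "ecskat_weights"))
  gr <- crossprod(as.matrix(G), fit$r)
  sum(weights$w * gr^2) / fit$phi0
}

#' Null eigen-spectrum of the SKAT statistic
#'
#' Under the null, Q is distributed as \eqn{\sum_j \lambda_j \chi^2_1} where
#' the \eqn{\lambda_j} are the nonzero eigenvalues of
#' \eqn{A = P_0^{1/2} K P_0^{1/2} / \hat\phi_0}. These coincide with the
#' eigenvalues of the p-by-p matrix
#' \eqn{\mathrm{diag}(\sqrt w)\, G^\top P_0 G\, \mathrm{diag}(\sqrt w)/\hat\phi_0}
#' (similar matrices), which is the path used here since p is typically far
#' smaller than n. Small negative eigenvalues from round-off are clipped.
#'
#' @inheritParams skat_statistic
#' @param B optional precomputed `crossprod(G, projection_apply(fit, G))`;
#'   pass it when testing many weight vectors against one fit.
#' @return A [mixture_spec()] of the nonzero eigenvalues.
#' @export
null_eigenvalues <- function(fit, G, weights, B = NULL) {
  stopifnot(inherits(fit, "ecskat_null"), inherits(weights, "ecskat_weights"))
  G <- as.matrix(G)
  if (is.null(B)) B <- crossprod(G, projection_apply(fit, G))
  sw <- sqrt(weights$w)
  Ap <- (sw * t(sw * B)) / fit$phi0   # diag(sw) B diag(sw) / phi0, symmetric
  ev <- eigen((Ap + t(Ap)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  if (mx <= 0)
    stop("all null eigenvalues are zero: genotypes lie in the span of the null design (untestable set)")
  ev <- pmax(ev, 0)
  mixture_spec(ev)
}

#' Build a test-result record
#' @noRd
new_test_result <- function(Q, lambdas, p_value, method, metadata = list()) {
  structure(list(Q = Q, lambdas = lambdas, p_value = as.numeric(p_value),
                 method = method, metadata = metadata),
            class = "ecskat_result")
}

#' @export
print.ecskat_result <- function(x, ...) {
  cat(sprintf("%s: Q = %.6g, p = %.4g\n", x$method, x$Q, x$p_value))
  invisible(x)
}

#' SKAT test with fixed kernel weights
#'
#' The variance-component score test of no association between the variant
#' set and the trait, given the null-model fit and a fixed weight vector:
#' statistic from [skat_statistic()], null spectrum from
#' [null_eigenvalues()], p-value from [mixchisq_survival()].
#'
#' @param dataset an [ecskat_dataset].
#' @param fit an `ecskat_null` fitted on the same data; fitted internally
#'   when `NULL`.
#' @param weights an `ecskat_weights`; uniform when `NULL`.
#' @return An `ecskat_result` with fields `Q`, `lambdas`, `p_value`,
#'   `method`, `metadata` (includes which tail method was used).
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(600, 2, 0.05), 200, 3)
#' d <- ecskat_dataset(rnorm(200), NULL, G, "continuous")
#' skat_test(d, weights = maf_weights(d$G, 1, 25))
#' @export
skat_test <- function(dataset, fit = NULL, weights = NULL) {
  stopifnot(inherits(dataset, "ecskat_dataset"))
  if (is.null(fit)) fit <- fit_null(dataset)
  if (is.null(weights))
    weights <- weight_vector(rep(1, ncol(dataset$G)), source = "uniform")
  Q <- skat_statistic(fit, dataset$G, weights)
  spec <- null_eigenvalues(fit, dataset$G, weights)
  p <- mixchisq_survival(spec, Q)
  label <- switch(weights$source,
                  uniform = "skat(uniform)",
                  beta_pdf = "skat(beta)",
                  learned = "skat(learned)",
                  "skat")
  new_test_result(Q, spec$lambdas, p, label,
                  metadata = list(tail_method = attr(p, "method"),
                                  weight_source = weights$source))
}

#' Collapse a variant set to one scalar per sample
#'
#' @param G genotype matrix.
#' @param agg `"sum"` (total minor-allele count) or `"max"` (largest
#'   single-variant count).
#' @return numeric n-vector.
#' @export
burden_aggregate <- function(G, agg = c("sum", "max")) {
  agg <- match.arg(agg)
  G <- as.matrix(G)
  if (agg == "sum") rowSums(G) else apply(G, 1, max)
}

#' Burden test (collapsing score test)
#'
#' Collapses the variant set into one scalar \eqn{c_i} per sample
#' ([burden_aggregate()]) and score-tests its coefficient in the GLM given
#' the null fit: the statistic \eqn{(c^\top r)^2 / (c^\top P_0 c)} is
#' referred to \eqn{\chi^2_1}. For a single variant this coincides exactly
#' with the SKAT p-value.
#'
#' @inheritParams skat_test
#' @param agg aggregation rule, `"sum"` or `"max"`.
#' @return An `ecskat_result` (the `lambdas` field is empty).
#' @export
burden_test <- function(dataset, fit = NULL, agg = c("sum", "max")) {
  agg <- match.arg(agg)
  stopifnot(inherits(dataset, "ecskat_dataset"))
  if (is.null(fit)) fit <- fit_null(dataset)
  cvec <- burden_aggregate(dataset$G, agg)
  denom <- sum(cvec * projection_apply(fit, cvec))
  if (denom <= 0)
    stop("burden vector is constant after projection; untestable set")
  stat <- sum(cvec * fit$r)^2 / denom
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result(stat, numeric(0), p, paste0("burden(", agg, ")"),
                  metadata = list(agg = agg))
}
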