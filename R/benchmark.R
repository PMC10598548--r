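#' Run a method on a dataset, returning its p-value
#' @noRd
run_method <- function(method, dataset, fit, seed, train_ratio) {
  switch(method,
    "ecskat" = ecskat_test(dataset, train_ratio = train_ratio, seed = seed)$p_value,
    "skat_uniform" = skat_test(dataset, fit,
                               weight_vector(rep(1, ncol(dataset$G)), "uniform"))$p_value,
    "skat_beta" = skat_test(dataset, fit,
                            suppressWarnings(maf_weights(dataset$G, 1, 25)))$p_value,
    "burden_sum" = burden_test(dataset, fit, "sum")$p_value,
    "burden_max" = burden_test(dataset, fit, "max")$p_value,
    stop("unknown method: ", method))
}

#' Type-I-error / power benchmarking harness
#'
#' Repeatedly simulates datasets from a configuration, runs every requested
#' method on each replicate, and tabulates rejection fractions at each
#' significance level with Wilson 95% confidence intervals. Replicate
#' seeds are derived independently from the base seed (`bitwXor(seed, i)`)
#' so any subset of replicates is reproducible on its own and replicate
#' order is immaterial. A method failing on a replicate is counted in
#' `n_error` for that method, never silently dropped.
#'
#' Method labels: `"ecskat"`, `"skat_uniform"`, `"skat_beta"` (Beta(1,25)
#' MAF weights), `"burden_sum"`, `"burden_max"`.
#'
#' @param cfg an [sim_config()]; `causal_fraction = 0` gives the null
#'   (type-I-error) setting, positive values the power setting, and
#'   `interaction_scale > 0` the misspecified setting.
#' @param methods character vector of method labels.
#' @param alphas numeric vector of significance levels.
#' @param reps number of simulation replicates.
#' @param seed base integer seed.
#' @param train_ratio learning fraction passed to [ecskat_test()].
#' @return data.frame with one row per method-by-alpha combination:
#'   `method`, `alpha`, `n`, `setting`, `reps`, `n_error`, `rejections`,
#'   `estimate`, `ci_lo`, `ci_hi`.
#' @export
run_benchmark <- function(cfg, methods = c("ecskat", "skat_uniform", "skat_beta", "burden_sum"),
                          alphas = c(0.1, 0.01), reps = 200, seed = 1,
                          train_ratio = 0.3) {
  stopifnot(inherits(cfg, "ecskat_simconfig"), reps >= 1)
  setting <- if (cfg$causal_fraction == 0) "null"
             else if (cfg$interaction_scale == 0) "causal_correct"
             else "causal_misspecified"
  pvals <- matrix(NA_real_, nrow = reps, ncol = length(methods),
                  dimnames = list(NULL, methods))
  for (i in seq_len(reps)) {
    rep_seed <- bitwXor(as.integer(seed), i)
    truth <- simulate_dataset(cfg, seed = rep_seed)
    ds <- truth$dataset
    fit <- tryCatch(fit_null(ds), error = function(e) NULL)
    for (meth in methods) {
      if (is.null(fit) && meth != "ecskat") next
      pvals[i, meth] <- tryCatch(
        run_method(meth, ds, fit, seed = rep_seed + 1L, train_ratio = train_ratio),
        error = function(e) NA_real_)
    }
  }
  out <- expand.grid(method = methods, alpha = alphas,
                     stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(out)), function(k) {
    meth <- out$method[k]; a <- out$alpha[k]
    pv <- pvals[, meth]
    ok <- !is.na(pv)
    rej <- sum(pv[ok] <= a)
    ntest <- sum(ok)
    ci <- if (ntest > 0) {
      suppressWarnings(prop.test(rej, ntest, correct = FALSE)$conf.int)
    } else c(NA_real_, NA_real_)
    data.frame(method = meth, alpha = a, n = cfg$n, setting = setting,
               reps = ntest, n_error = reps - ntest, rejections = rej,
               estimate = if (ntest > 0) rej / ntest else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, rows)
}

#' Summarize how well learned weights recover the causal set
#'
#' Reports the total learned-weight mass sitting on the truly causal
#' variants, plus support precision and recall where the learned support is
#' the smallest set of indices covering `mass_threshold` of the weight
#' mass. With a null generator (no causal variants) the mass is reported
#' as `NA`.
#'
#' @param truth an `ecskat_simtruth` from [simulate_dataset()].
#' @param learned an `ecskat_learned` from [ecskat_test()] on the same
#'   dataset.
#' @param mass_threshold fraction of weight mass defining the learned
#'   support (default 0.95).
#' @return list with `causal_mass`, `precision`, `recall`,
#'   `support` (indices), and `comparison` (data.frame of `beta` and `w`
#'   per variant, for plotting).
#' @export
weight_recovery_report <- function(truth, learned, mass_threshold = 0.95) {
  stopifnot(inherits(truth, "ecskat_simtruth"),
            inherits(learned, "ecskat_learned"))
  w <- learned$weights$w
  causal <- truth$causal_idx
  ord <- order(w, decreasing = TRUE)
  cum <- cumsum(w[ord])
  support <- sort(ord[seq_len(which(cum >= mass_threshold)[1])])
  if (length(causal) == 0) {
    return(list(causal_mass = NA_real_, precision = NA_real_,
                recall = NA_real_, support = support,
                comparison = data.frame(beta = truth$beta, w = w)))
  }
  list(causal_mass = sum(w[causal]),
       precision = mean(support %in% causal),
       recall = mean(causal %in% support),
       support = support,
       comparison = data.frame(beta = truth$beta, w = w))
}
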