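#' Simulation configuration
#'
#' Study conditions for the synthetic generator: genotypes are independent
#' variants drawn under Hardy-Weinberg equilibrium with minor-allele
#' frequencies following a truncated power law; genetic effects are sparse,
#' of mixed sign, and grow in magnitude as the MAF shrinks
#' (\eqn{|\beta_j| = c\,|\log_{10} m_j| / 2} on causal variants); an
#' optional symmetric pairwise-interaction term on causal pairs induces
#' model misspecification. Non-genetic covariates default to one
#' Bernoulli(0.5) and one standard-normal column with coefficients 0.5.
#'
#' Defaults: `p = 50` variants, MAF power-law exponent 1 on
#' (5e-4, 0.05), 10% causal fraction, effect scale 0.6 for continuous
#' traits and 1 for binary, mixed signs on, no interaction, unit noise;
#' binary intercepts are solved for 20% prevalence.
#'
#' @param n,p samples and variants.
#' @param maf_range MAF truncation interval inside (0, 0.5).
#' @param maf_exponent power-law shape (density proportional to
#'   `m^-maf_exponent`); 0 gives uniform.
#' @param causal_fraction fraction of variants carrying effects.
#' @param effect_scale magnitude multiplier c; `NULL` picks 0.6
#'   (continuous) or 1 (binary).
#' @param mixed_signs random +/- signs on causal effects.
#' @param interaction_scale magnitude of the pairwise interaction term
#'   (0 disables misspecification).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param alpha0 intercept; `NULL` means 0 for continuous traits and
#'   solved for `prevalence` for binary traits.
#' @param alpha covariate coefficients (length 2 by default).
#' @param prevalence target binary trait prevalence used when `alpha0` is
#'   solved.
#' @param noise_sd residual standard deviation (continuous only).
#' @return list of class `ecskat_simconfig`.
#' @export
sim_config <- function(n = 1000, p = 50,
                       maf_range = c(5e-4, 0.05), maf_exponent = 1,
                       causal_fraction = 0.1, effect_scale = NULL,
                       mixed_signs = TRUE, interaction_scale = 0,
                       trait_type = c("continuous", "binary"),
                       alpha0 = NULL, alpha = c(0.5, 0.5),
                       prevalence = 0.2, noise_sd = 1) {
  trait_type <- match.arg(trait_type)
  stopifnot(n >= 2, p >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 0.5,
            maf_range[1] < maf_range[2],
            causal_fraction >= 0, causal_fraction <= 1,
            interaction_scale >= 0, noise_sd > 0)
  if (is.null(effect_scale))
    effect_scale <- if (trait_type == "continuous") 0.6 else 1
  structure(list(n = n, p = p, maf_range = maf_range,
                 maf_exponent = maf_exponent,
                 causal_fraction = causal_fraction,
                 effect_scale = effect_scale, mixed_signs = mixed_signs,
                 interaction_scale = interaction_scale,
                 trait_type = trait_type, alpha0 = alpha0, alpha = alpha,
                 prevalence = prevalence, noise_sd = noise_sd),
            class = "ecskat_simconfig")
}

#' Draw minor-allele frequencies from a truncated power law
#'
#' i.i.d. draws from the density proportional to \eqn{m^{-e}} on
#' `maf_range`, by inverse-CDF sampling (closed form for every exponent;
#' exponent 0 is uniform on the range).
#'
#' @param cfg an [sim_config()].
#' @return numeric p-vector inside `maf_range`.
#' @export
draw_mafs <- function(cfg) {
  stopifnot(inherits(cfg, "ecskat_simconfig"))
  lo <- cfg$maf_range[1]; hi <- cfg$maf_range[2]
  e <- cfg$maf_exponent
  u <- runif(cfg$p)
  if (abs(e - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a <- 1 - e
    (lo^a + u * (hi^a - lo^a))^(1 / a)
  }
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Independent variants: \eqn{G_{ij} \sim \mathrm{Binomial}(2, m_j)}.
#'
#' @param mafs p-vector of minor-allele frequencies.
#' @param n sample count.
#' @return n-by-p matrix in \{0, 1, 2\}.
#' @export
draw_genotypes <- function(mafs, n) {
  p <- length(mafs)
  matrix(rbinom(n * p, 2L, rep(mafs, each = n)), nrow = n, ncol = p)
}

#' Draw sparse mixed-sign effects and the interaction term
#'
#' A random subset of `ceiling(causal_fraction * p)` variants is causal;
#' each causal effect has magnitude \eqn{c\,|\log_{10} m_j|/2} (rarer
#' variants get larger effects) and, when `mixed_signs`, an independent
#' random sign. The interaction matrix is symmetric with zero diagonal,
#' nonzero only on causal-by-causal off-diagonal pairs, entries
#' `interaction_scale` times standard normals.
#'
#' @param mafs p-vector of minor-allele frequencies.
#' @param cfg an [sim_config()].
#' @return list with `beta` (p-vector), `Gamma` (p-by-p), `causal_idx`.
#' @export
draw_effects <- function(mafs, cfg) {
  stopifnot(inherits(cfg, "ecskat_simconfig"))
  p <- length(mafs)
  beta <- numeric(p)
  Gamma <- matrix(0, p, p)
  n_causal <- if (cfg$causal_fraction > 0) ceiling(cfg$causal_fraction * p) else 0L
  causal <- integer(0)
  if (n_causal > 0) {
    causal <- sort(sample.int(p, n_causal))
    mag <- cfg$effect_scale * abs(log10(mafs[causal])) / 2
    sgn <- if (cfg$mixed_signs) sample(c(-1, 1), n_causal, replace = TRUE) else rep(1, n_causal)
    beta[causal] <- sgn * mag
    if (cfg$interaction_scale > 0 && n_causal >= 2) {
      for (a in seq_len(n_causal - 1)) {
        for (b in (a + 1):n_causal) {
          val <- cfg$interaction_scale * rnorm(1)
          Gamma[causal[a], causal[b]] <- val
          Gamma[causal[b], causal[a]] <- val
        }
      }
    }
  }
  list(beta = beta, Gamma = Gamma, causal_idx = causal)
}

#' Simulate a dataset from the generative GLM
#'
#' Linear predictor
#' \eqn{\eta_i = \alpha_0 + \alpha^\top x_i + \beta^\top g_i + g_i^\top \Gamma g_i};
#' continuous traits add Gaussian noise, binary traits are Bernoulli with
#' logistic link (the intercept solved so the population prevalence matches
#' `cfg$prevalence` unless given). Covariates are one Bernoulli(0.5) and
#' one standard-normal column.
#'
#' @param cfg an [sim_config()].
#' @param seed optional integer seed (all randomness flows from it).
#' @return list of class `ecskat_simtruth`: `dataset` (an
#'   [ecskat_dataset]), `mafs`, `beta`, `Gamma`, `causal_idx`, `alpha0`,
#'   `eta` (the linear predictor used).
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "ecskat_simconfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  mafs <- draw_mafs(cfg)
  G <- draw_genotypes(mafs, n)
  eff <- draw_effects(mafs, cfg)
  X <- cbind(x1 = rbinom(n, 1L, 0.5), x2 = rnorm(n))
  # constant-column guard for tiny n: re-draw the Bernoulli column if degenerate
  tries <- 0L
  while (max(X[, 1]) == min(X[, 1]) && tries < 10L) {
    X[, 1] <- rbinom(n, 1L, 0.5); tries <- tries + 1L
  }
  gbeta <- as.numeric(G %*% eff$beta)
  ginter <- if (cfg$interaction_scale > 0) rowSums((G %*% eff$Gamma) * G) else numeric(n)
  core <- as.numeric(X %*% cfg$alpha) + gbeta + ginter

  if (cfg$trait_type == "continuous") {
    alpha0 <- if (is.null(cfg$alpha0)) 0 else cfg$alpha0
    eta <- alpha0 + core
    y <- eta + rnorm(n, sd = cfg$noise_sd)
  } else {
    if (is.null(cfg$alpha0)) {
      f <- function(a0) mean(plogis(a0 + core)) - cfg$prevalence
      alpha0 <- uniroot(f, c(-50, 50))$root
    } else {
      alpha0 <- cfg$alpha0
    }
    eta <- alpha0 + core
    y <- rbinom(n, 1L, plogis(eta))
    attempts <- 0L
    while (length(unique(y)) < 2L && attempts < 10L) {
      y <- rbinom(n, 1L, plogis(eta))
      attempts <- attempts + 1L
    }
    if (length(unique(y)) < 2L)
      stop("binary simulation produced a single class after 10 attempts")
  }
  ds <- suppressWarnings(
    ecskat_dataset(y, X, G, cfg$trait_type))
  structure(list(dataset = ds, mafs = mafs, beta = eff$beta,
                 Gamma = eff$Gamma, causal_idx = eff$causal_idx,
                 alpha0 = alpha0, eta = eta),
            class = "ecskat_simtruth")
}

#' Subsample an existing dataset without replacement
#'
#' Semi-empirical resampling: draws `n` rows without replacement from a
#' source dataset (for example one built from real genotypes), preserving
#' row alignment across trait, covariates and genotypes.
#'
#' @param source an [ecskat_dataset].
#' @param n subsample size, at most the source size.
#' @param seed optional integer seed.
#' @return An [ecskat_dataset] with `n` samples.
#' @export
resample_semiempirical <- function(source, n, seed = NULL) {
  stopifnot(inherits(source, "ecskat_dataset"))
  N <- length(source$y)
  if (n > N) stop("requested subsample exceeds the source size")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(N, n)
  suppressWarnings(ecskat_dataset(
    source$y[idx], source$X[idx, , drop = FALSE],
    source$G[idx, , drop = FALSE], source$trait_type,
    sample_ids = source$sample_ids[idx], variant_ids = source$variant_ids))
}
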