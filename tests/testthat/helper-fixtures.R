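# Shared fixtures: small random instances built in code.

# A random dataset with common-enough variants that every column is
# polymorphic with overwhelming probability.
make_dataset <- function(seed, n = 120, p = 5, m = 2,
                         trait = c("continuous", "binary"),
                         maf = NULL, beta = NULL) {
  trait <- match.arg(trait)
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.1, 0.4)
  G <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  # guard against the rare monomorphic column
  for (j in seq_len(p)) {
    while (max(G[, j]) == min(G[, j])) G[, j] <- rbinom(n, 2L, maf[j])
  }
  X <- if (m > 0) matrix(rnorm(n * m), n, m) else NULL
  eta <- if (m > 0) as.numeric(X %*% rep(0.5, m)) else numeric(n)
  if (!is.null(beta)) eta <- eta + as.numeric(G %*% beta)
  y <- if (trait == "continuous") eta + rnorm(n) else {
    yy <- rbinom(n, 1L, plogis(eta))
    while (length(unique(yy)) < 2L) yy <- rbinom(n, 1L, plogis(eta))
    yy
  }
  suppressWarnings(ecskat_dataset(y, X, G, trait))
}

# Dense P0 built from first principles (independent of projection_apply).
dense_p0_oracle <- function(v, X) {
  Xt <- cbind(1, X)
  V <- diag(v)
  V - V %*% Xt %*% solve(t(Xt) %*% V %*% Xt) %*% t(Xt) %*% V
}

# Monte-Carlo tail of sum(lambda_j chi2_1) with standard error.
mc_mixchisq_tail <- function(lambdas, q, ndraw, seed) {
  set.seed(seed)
  tot <- numeric(ndraw)
  for (lam in lambdas) tot <- tot + lam * rchisq(ndraw, 1)
  p <- mean(tot >= q)
  list(p = p, se = sqrt(max(p * (1 - p), 1 / ndraw) / ndraw))
}

# All simplex grid points with the given step, p = 3.
simplex_grid3 <- function(step = 0.01) {
  k <- round(1 / step)
  pts <- list()
  idx <- 1
  for (i in 0:k) for (j in 0:(k - i)) {
    pts[[idx]] <- c(i, j, k - i - j) / k
    idx <- idx + 1
  }
  do.call(rbind, pts)
}

# A tiny valid VCF written to a temp file; 3 samples, one site per GT column
# spec given in `gts` (list of character vectors of GT strings per site).
write_test_vcf <- function(gts, path = tempfile(fileext = ".vcf"),
                           samples = c("s1", "s2", "s3"), alts = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (is.null(alts)) alts <- rep("T", length(gts))
  body <- vapply(seq_along(gts), function(i) {
    paste(c("1", as.character(100 * i), paste0("rs", i), "A", alts[i], ".",
            "PASS", ".", "GT", gts[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
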