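#' Assemble a phenotype/covariate/genotype dataset
#'
#' Bundles the three pieces every test in this package consumes: a trait
#' vector `y`, a matrix `X` of non-genetic covariates (no intercept column;
#' the intercept is always added internally by the null model), and a
#' genotype matrix `G` of minor-allele counts in \{0, 1, 2\}.
#'
#' Variants whose sample allele frequency exceeds 0.5 are flipped
#' (`g -> 2 - g`) with a warning so that `G` always counts minor alleles;
#' weights keyed to minor-allele frequency assume this orientation.
#'
#' @param y numeric trait vector; for `trait_type = "binary"` it must be
#'   coded 0/1 and contain both classes.
#' @param X numeric covariate matrix with `length(y)` rows, or `NULL` for no
#'   covariates. Must not contain a constant column.
#' @param G numeric genotype matrix with `length(y)` rows, entries in
#'   \{0, 1, 2\}.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param sample_ids,variant_ids optional label vectors; defaults are
#'   positional.
#' @return An object of class `ecskat_dataset`: a list with elements `y`,
#'   `X`, `G`, `trait_type`, `sample_ids`, `variant_ids`.
#' @examples
#' G <- matrix(rbinom(40, 2, 0.2), 20, 2)
#' d <- ecskat_dataset(rnorm(20), NULL, G, "continuous")
#' dim(d$G)
#' @export
ecskat_dataset <- function(y, X, G, trait_type = c("continuous", "binary"),
                           sample_ids = NULL, variant_ids = NULL) {
  trait_type <- match.arg(trait_type)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (nrow(X) != n || nrow(G) != n)
    stop("y, X and G must have the same number of samples")
  if (anyNA(y) || anyNA(X) || anyNA(G))
    stop("missing values are not allowed; impute genotypes first (impute_missing)")
  if (!all(G %in% c(0, 1, 2)))
    stop("G entries must be in {0, 1, 2}")
  if (trait_type == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary trait must be coded 0/1")
    if (length(unique(y)) < 2L) stop("binary trait contains a single class")
  }
  if (ncol(X) > 0 && any(apply(X, 2, function(col) max(col) == min(col))))
    stop("X contains a constant column; the intercept is handled internally")
  # minor-allele orientation
  af <- colMeans(G) / 2
  flip <- af > 0.5
  if (any(flip)) {
    warning(sprintf("%d variant(s) with allele frequency > 0.5 flipped to minor-allele coding", sum(flip)))
    G[, flip] <- 2 - G[, flip]
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(G)))
  rownames(G) <- sample_ids
  if (ncol(X) > 0) rownames(X) <- sample_ids
  colnames(G) <- variant_ids
  structure(list(y = y, X = X, G = G, trait_type = trait_type,
                 sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids)),
            class = "ecskat_dataset")
}

#' @export
print.ecskat_dataset <- function(x, ...) {
  cat(sprintf("ecskat_dataset: n = %d samples, m = %d covariates, p = %d variants (%s trait)\n",
              length(x$y), ncol(x$X), ncol(x$G), x$trait_type))
  invisible(x)
}

#' Impute missing genotype entries
#'
#' Replaces missing minor-allele counts by the per-variant rounded mean
#' (default) or mode of the observed entries, keeping the \{0, 1, 2\} domain.
#'
#' @param G_raw numeric matrix with missing entries coded `NA`.
#' @param method `"mean"` (round the observed per-variant mean, half away
#'   from zero rounds up) or `"mode"` (most frequent observed count).
#' @return Matrix of the same shape with entries in \{0, 1, 2\}.
#' @examples
#' impute_missing(matrix(c(0, NA, 2), 3, 1))
#' @export
impute_missing <- function(G_raw, method = c("mean", "mode")) {
  method <- match.arg(method)
  G <- as.matrix(G_raw)
  storage.mode(G) <- "double"
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (!any(miss)) next
    obs <- G[!miss, j]
    if (length(obs) == 0L)
      stop(sprintf("variant %d has all entries missing", j))
    fill <- if (method == "mean") {
      floor(mean(obs) + 0.5)
    } else {
      tab <- tabulate(obs + 1L, nbins = 3L)
      which.max(tab) - 1
    }
    G[miss, j] <- fill
  }
  if (!all(G %in% c(0, 1, 2)))
    stop("imputed genotypes fall outside {0, 1, 2}")
  G
}

#' Read a dataset from delimited text or VCF
#'
#' Phenotype and covariates are tab-separated files whose first column holds
#' the sample id (header row required); the phenotype file has one value
#' column and the covariate file `m` columns. Genotypes come either from a
#' TSV of the same layout (p variant columns) or from a VCF 4.x file, from
#' which only the GT field of diploid calls is used; multi-allelic sites are
#' skipped with a warning and counts are oriented to the minor allele.
#'
#' The three sources are intersected on sample id and row-aligned; rows
#' present in only some files are dropped.
#'
#' @param pheno_path path to the phenotype TSV.
#' @param covar_path path to the covariate TSV, or `NULL` for no covariates.
#' @param geno_path path to the genotype TSV or VCF.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param format `"tsv"` or `"vcf"` for the genotype file.
#' @return An [ecskat_dataset].
#' @export
read_dataset <- function(pheno_path, covar_path, geno_path,
                         trait_type = c("continuous", "binary"),
                         format = c("tsv", "vcf")) {
  trait_type <- match.arg(trait_type)
  format <- match.arg(format)
  for (f in c(pheno_path, covar_path, geno_path))
    if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)

  ph <- read.delim(pheno_path, check.names = FALSE, colClasses = c("character", "numeric"))
  if (ncol(ph) != 2L) stop("phenotype file must have exactly one value column")
  pheno_ids <- ph[[1]]

  if (!is.null(covar_path)) {
    cv <- read.delim(covar_path, check.names = FALSE)
    covar_ids <- as.character(cv[[1]])
    Xall <- as.matrix(cv[, -1, drop = FALSE])
  } else {
    covar_ids <- pheno_ids
    Xall <- matrix(numeric(0), nrow = length(pheno_ids), ncol = 0)
  }

  if (format == "tsv") {
    gt <- read.delim(geno_path, check.names = FALSE)
    geno_ids <- as.character(gt[[1]])
    Gall <- as.matrix(gt[, -1, drop = FALSE])
  } else {
    vg <- read_vcf_genotypes(geno_path)
    geno_ids <- rownames(vg)
    Gall <- vg
  }

  ids <- intersect(intersect(pheno_ids, covar_ids), geno_ids)
  if (length(ids) == 0L) stop("no overlapping sample ids across input files")

  y <- ph[[2]][match(ids, pheno_ids)]
  X <- Xall[match(ids, covar_ids), , drop = FALSE]
  G <- Gall[match(ids, geno_ids), , drop = FALSE]
  if (anyNA(G)) G <- impute_missing(G)
  ecskat_dataset(y, X, G, trait_type, sample_ids = ids,
                 variant_ids = colnames(G))
}

#' Write a dataset to delimited text
#'
#' Inverse of [read_dataset()] for the TSV layout: writes phenotype,
#' covariate (when present) and genotype files with sample ids in the first
#' column.
#'
#' @param dataset an [ecskat_dataset].
#' @param pheno_path,covar_path,geno_path output paths; `covar_path` may be
#'   `NULL` when the dataset has no covariates.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, pheno_path, covar_path, geno_path) {
  stopifnot(inherits(dataset, "ecskat_dataset"))
  tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(data.frame(sample_id = dataset$sample_ids, y = dataset$y), pheno_path)
  if (ncol(dataset$X) > 0) {
    if (is.null(covar_path)) stop("dataset has covariates but covar_path is NULL")
    cn <- colnames(dataset$X)
    if (is.null(cn)) cn <- paste0("x", seq_len(ncol(dataset$X)))
    cv <- data.frame(sample_id = dataset$sample_ids, dataset$X)
    names(cv) <- c("sample_id", cn)
    tsv(cv, covar_path)
  }
  gt <- data.frame(sample_id = dataset$sample_ids, dataset$G, check.names = FALSE)
  tsv(gt, geno_path)
  invisible(dataset)
}

#' Extract minor-allele counts from a VCF
#'
#' GT-field parsing only: diploid calls against the first ALT allele.
#' Multi-allelic records are skipped with a warning; missing calls become
#' `NA` (impute downstream). Columns whose ALT frequency exceeds 0.5 are
#' flipped to minor-allele counts with a warning.
#'
#' @param path a VCF 4.x file (plain or bgzipped).
#' @return numeric samples-by-variants matrix in \{0, 1, 2, NA\}.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  if (is.null(ids) || anyNA(ids))
    ids <- paste(vcfR::getCHROM(vcf), vcfR::getPOS(vcf), sep = ":")
  count_alt <- function(cell) {
    if (is.na(cell) || cell %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(cell, "[/|]")[[1]]
    if (length(alleles) != 2L || !all(alleles %in% c("0", "1")))
      stop("unsupported GT call: ", cell)
    sum(alleles == "1")
  }
  G <- matrix(vapply(as.vector(gt), count_alt, numeric(1)),
              nrow = nrow(gt), ncol = ncol(gt))   # variants x samples
  G <- t(G)
  rownames(G) <- colnames(gt)
  colnames(G) <- ids
  af <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) {
    warning(sprintf("%d variant(s) flipped to minor-allele coding", sum(flip)))
    G[, flip] <- 2 - G[, flip]
  }
  G
}
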