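#' Principal components from a genetic relationship matrix
#'
#' Dosages are mean-imputed per SNP, centred at `2p` and standardised by
#' `sqrt(2 p (1 - p))` (monomorphic SNPs are skipped); the GRM is
#' `X X' / L` and its leading eigenvectors, scaled by the square root of
#' their eigenvalues, give the sample scores. Each component's sign is fixed
#' so its largest-magnitude entry is positive.
#'
#' @param ds A [geno_dataset()] with at least `n_components + 1` samples.
#' @param n_components Number of leading components (default 4).
#' @return List with `scores` (tibble: `sample`, `population`, `PC1`...),
#'   `explained_variance` (eigenvalue share per component) and `grm`.
#' @export
pca_genotypes <- function(ds, n_components = 4) {
  if (n_samples(ds) < n_components + 1L) {
    abort("need at least n_components + 1 samples")
  }
  d <- ds$dosages
  called <- colSums(!is.na(d))
  p <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("all variants are monomorphic; PCA undefined")
  x <- d[, poly, drop = FALSE]
  p <- p[poly]
  mu <- matrix(2 * p, nrow(x), ncol(x), byrow = TRUE)
  x[is.na(x)] <- mu[is.na(x)]                     # per-SNP mean imputation
  x <- (x - mu) / matrix(sqrt(2 * p * (1 - p)), nrow(x), ncol(x), byrow = TRUE)
  grm <- tcrossprod(x) / ncol(x)
  eig <- eigen(grm, symmetric = TRUE)
  k <- seq_len(n_components)
  vals <- pmax(eig$values, 0)
  scores <- eig$vectors[, k, drop = FALSE] %*% diag(sqrt(vals[k]), n_components)
  for (j in k) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", k)
  list(
    scores = bind_cols(
      tibble(sample = ds$samples$id, population = ds$samples$population),
      as_tibble(scores)
    ),
    explained_variance = vals[k] / sum(vals),
    grm = grm
  )
}
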