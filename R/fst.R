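#' Per-SNP Fst between two sample groups
#'
#' Two estimators are provided. `weir_cockerham` is the two-population theta
#' from the 1984 variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals), with
#' per-SNP `theta = a / (a + b + c)`. `hudson` is the Bhatia et al. ratio
#' `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] /
#' [p1(1-p2) + p2(1-p1)]` with `n` counted in alleles. A SNP is defined only
#' when both groups have at least 2 called alleles and the union is
#' polymorphic; undefined SNPs carry `NA` and are excluded from means.
#'
#' The default `mean_fst` is the ratio-of-sums ("weighted") average:
#' `sum(numerators) / sum(denominators)` over defined SNPs; the per-SNP
#' arithmetic mean is also reported.
#'
#' @param ds A [geno_dataset()].
#' @param group_a,group_b Character vectors of sample ids.
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`.
#' @return An object of class `fst_result`: list with `per_snp` tibble
#'   (`id`, `chrom`, `pos`, `fst`, `defined`), `mean_fst` (ratio of sums),
#'   `mean_fst_per_snp`, `estimator`, `pair`.
#' @export
fst_per_snp <- function(ds, group_a, group_b,
                        estimator = c("weir_cockerham", "hudson")) {
  estimator <- arg_match(estimator)
  if (length(intersect(group_a, group_b))) {
    abort("groups must be disjoint")
  }
  da <- subset_samples(ds, group_a)$dosages
  db <- subset_samples(ds, group_b)$dosages
  comp <- switch(estimator,
    weir_cockerham = fst_wc_components(da, db),
    hudson = fst_hudson_components(da, db)
  )
  defined <- unname(comp$defined)
  fst <- unname(ifelse(defined, comp$num / comp$den, NA_real_))
  structure(
    list(
      per_snp = tibble(
        id = ds$variants$id, chrom = ds$variants$chrom,
        pos = ds$variants$pos, fst = fst, defined = defined
      ),
      mean_fst = sum(comp$num[defined]) / sum(comp$den[defined]),
      mean_fst_per_snp = mean(fst[defined]),
      estimator = estimator,
      pair = c(a = paste(group_a, collapse = ","),
               b = paste(group_b, collapse = ","))
    ),
    class = "fst_result"
  )
}

# Weir & Cockerham (1984) two-population variance components per SNP,
# vectorised over SNPs. Returns num = a, den = a + b + c.
fst_wc_components <- function(da, db) {
  stats_of <- function(d) {
    n <- colSums(!is.na(d))                      # genotyped individuals
    p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- stats_of(da); B <- stats_of(db)
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1
  defined <- A$n >= 1 & B$n >= 1 & nbar > 1 & poly
  list(num = a, den = a + b + cc, defined = defined)
}

# Bhatia/Hudson per-SNP components: num and den as in the ratio estimator.
fst_hudson_components <- function(da, db) {
  freq_of <- function(d) {
    n <- 2 * colSums(!is.na(d))                  # called alleles
    p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p)
  }
  A <- freq_of(da); B <- freq_of(db)
  num <- (A$p - B$p)^2 -
    A$p * (1 - A$p) / (A$n - 1) - B$p * (1 - B$p) / (B$n - 1)
  den <- A$p * (1 - B$p) + B$p * (1 - A$p)
  defined <- A$n >= 2 & B$n >= 2 & !is.na(den) & den > 0
  list(num = num, den = den, defined = defined)
}

#' @exportS3Method base::print
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "<fst_result> %s: %d SNPs (%d defined), mean Fst (ratio of sums) = %.4f\n",
    x$estimator, nrow(x$per_snp), sum(x$per_snp$defined), x$mean_fst
  ))
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_snp

#' @export
glance.fst_result <- function(x, ...) {
  tibble(
    estimator = x$estimator, n_snps = nrow(x$per_snp),
    n_defined = sum(x$per_snp$defined),
    mean_fst = x$mean_fst, mean_fst_per_snp = x$mean_fst_per_snp
  )
}

#' Average pairwise Fst matrix over populations
#'
#' Entry (i, j) is the ratio-of-sums mean Fst for the pair; negative means
#' are clamped to 0 so the matrix can serve as a distance matrix (raw values
#' are available through [fst_per_snp()]).
#'
#' @param ds A [geno_dataset()].
#' @param groups Named list of sample-id vectors, or `NULL` for the dataset's
#'   populations. Every group needs >= 2 samples.
#' @param estimator Passed to [fst_per_snp()].
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
pairwise_fst_matrix <- function(ds, groups = NULL,
                                estimator = c("weir_cockerham", "hudson")) {
  estimator <- arg_match(estimator)
  if (is.null(groups)) groups <- split(ds$samples$id, ds$samples$population)
  if (length(groups) < 2L) abort("need at least 2 groups")
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    abort(paste0("groups with < 2 samples: ", paste(small, collapse = ", ")))
  }
  labs <- names(groups)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_len(i - 1L)) {
      f <- fst_per_snp(ds, groups[[i]], groups[[j]], estimator)$mean_fst
      m[i, j] <- m[j, i] <- max(0, f)
    }
  }
  m
}
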