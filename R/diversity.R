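#' Per-SNP alternate-allele frequencies within a sample group
#'
#' Frequencies are computed over non-missing alleles only; SNPs with zero
#' called alleles get `NA` frequency.
#'
#' @param ds A [geno_dataset()].
#' @param group Character vector of sample ids (default: all samples).
#' @return Tibble with `id`, `chrom`, `pos`, `alt_count`, `total_alleles`,
#'   `freq`.
#' @export
allele_frequency <- function(ds, group = ds$samples$id) {
  if (length(group) == 0L) abort("group must be non-empty")
  d <- subset_samples(ds, group)$dosages
  alt <- unname(colSums(d, na.rm = TRUE))
  tot <- 2 * unname(colSums(!is.na(d)))
  tibble(
    id = ds$variants$id, chrom = ds$variants$chrom, pos = ds$variants$pos,
    alt_count = as.integer(alt), total_alleles = as.integer(tot),
    freq = ifelse(tot > 0, alt / tot, NA_real_)
  )
}

#' Allele frequency from raw allele counts, as a whole percent
#'
#' Convenience formatter for reporting carrier/allele counts the way breed
#' surveys print them (e.g. 134 of 178 alleles -> 75).
#' @param count Alternate (or focal) allele count.
#' @param total Total called alleles.
#' @return Percentage rounded to the nearest whole percent.
#' @export
allele_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  round(100 * count / total)
}

#' Per-population genetic diversity statistics
#'
#' For each group computes, over the same assayed SNP set:
#' * `pn`: proportion of SNPs at which both alleles are observed in the group
#'   (denominator = all assayed SNPs, including ones entirely missing here);
#' * `ho`: observed heterozygosity, the fraction of called genotypes that are
#'   heterozygous, averaged over SNPs with at least one called genotype;
#' * `pi`: mean per-site nucleotide diversity, with the unbiased pairwise
#'   estimator `pi_s = n/(n-1) * (1 - p^2 - q^2)` at each SNP (`n` = called
#'   alleles), monomorphic SNPs contributing 0 and entirely-missing SNPs
#'   excluded from the denominator.
#'
#' @param ds A [geno_dataset()].
#' @param groups Named list of sample-id vectors, or `NULL` to use the
#'   dataset's populations. Each group needs at least 2 samples.
#' @return Tibble with one row per group: `population`, `n_samples`,
#'   `n_snp_polymorphic`, `pn`, `ho`, `pi`.
#' @export
diversity_stats <- function(ds, groups = NULL) {
  if (is.null(groups)) {
    groups <- split(ds$samples$id, ds$samples$population)
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- map(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) < 2L) {
      abort(sprintf("group '%s' has < 2 samples; pi is undefined", g))
    }
    d <- subset_samples(ds, ids)$dosages
    called_gt <- colSums(!is.na(d))
    n_alleles <- 2 * called_gt
    alt <- colSums(d, na.rm = TRUE)
    p <- ifelse(n_alleles > 0, alt / n_alleles, NA_real_)
    poly <- !is.na(p) & alt > 0 & alt < n_alleles
    het <- colSums(d == 1L, na.rm = TRUE)
    ho_s <- ifelse(called_gt > 0, het / called_gt, NA_real_)
    pi_s <- ifelse(n_alleles >= 2,
                   n_alleles / (n_alleles - 1) * (1 - p^2 - (1 - p)^2),
                   NA_real_)
    tibble(
      population = g, n_samples = length(ids),
      n_snp_polymorphic = sum(poly),
      pn = sum(poly) / n_variants(ds),
      ho = mean(ho_s, na.rm = TRUE),
      pi = mean(pi_s, na.rm = TRUE)
    )
  })
  bind_rows(rows)
}
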