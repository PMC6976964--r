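#' Per-variant minor-allele-frequency and call-rate filter
#'
#' Removes a SNP iff its minor allele frequency is strictly below `maf_min`
#' (a SNP at exactly `maf_min` is kept) or its genotype call rate is strictly
#' below `call_rate_min`. A per-rule removal report is attached to the result
#' and retrievable with [filter_report()].
#'
#' @param ds A [geno_dataset()].
#' @param maf_min Minimum minor allele frequency in `[0, 0.5]` (default 0.05).
#' @param call_rate_min Minimum fraction of called genotypes in `[0, 1]`
#'   (default 0.9).
#' @return A filtered `geno_dataset`; `attr(, "filter_report")` holds the
#'   counts (`removed_maf`, `removed_callrate`, `removed_both`, `kept`,
#'   `n_input`).
#' @export
filter_variants <- function(ds, maf_min = 0.05, call_rate_min = 0.9) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            call_rate_min >= 0, call_rate_min <= 1)
  d <- ds$dosages
  called <- colSums(!is.na(d))
  call_rate <- called / nrow(d)
  alt <- colSums(d, na.rm = TRUE)
  tot <- 2 * called
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  maf <- pmin(p, 1 - p)
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_cr <- call_rate < call_rate_min
  keep <- !(fail_maf | fail_cr)
  report <- tibble(
    n_input = n_variants(ds),
    removed_maf = sum(fail_maf),
    removed_callrate = sum(fail_cr),
    removed_both = sum(fail_maf & fail_cr),
    kept = sum(keep)
  )
  if (report$kept == 0L) {
    warn("no variants survive filtering")
    out <- structure(
      list(
        variants = ds$variants[0, ], samples = ds$samples,
        dosages = ds$dosages[, 0, drop = FALSE],
        haplotypes = if (ds$phased) ds$haplotypes[, 0, drop = FALSE],
        phased = ds$phased
      ),
      class = "geno_dataset"
    )
  } else {
    out <- subset_variants(ds, keep)
  }
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_variants
#' @param x A dataset returned by [filter_variants()].
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Write a filter report as TSV
#' @param report Tibble from [filter_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
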