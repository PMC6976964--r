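#' Window-based LD pruning of variants
#'
#' Greedy left-to-right pass mirroring PLINK's `--indep-pairwise`: within
#' each window of `window_snps` consecutive (still kept) variants, while any
#' pair has squared dosage correlation above `r2_max`, the member of the
#' worst pair with the lower minor allele frequency is dropped (ties drop the
#' later position); windows advance by `step_snps`. Chromosomes are pruned
#' independently.
#'
#' @param ds A [geno_dataset()].
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Window step in SNPs (default 10). Must be < `window_snps`.
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.1).
#' @return Integer vector of kept variant indices (into `ds$variants`).
#' @export
ld_prune <- function(ds, window_snps = 50, step_snps = 10, r2_max = 0.1) {
  stopifnot(window_snps > step_snps, step_snps >= 1)
  d <- ds$dosages
  maf <- {
    called <- colSums(!is.na(d))
    p <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
    pmin(p, 1 - p)
  }
  keep <- rep(TRUE, n_variants(ds))
  for (chrom in unique(ds$variants$chrom)) {
    idx <- which(ds$variants$chrom == chrom)
    for (start in seq(1L, max(1L, length(idx)), by = step_snps)) {
      win_all <- idx[start:min(start + window_snps - 1L, length(idx))]
      repeat {
        win <- win_all[keep[win_all]]
        if (length(win) < 2L) break
        r2 <- suppressWarnings(
          cor(d[, win, drop = FALSE], use = "pairwise.complete.obs")^2
        )
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        worst <- max(r2)
        if (worst <= r2_max) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1L, ]
        a <- win[hit[1L]]; b <- win[hit[2L]]
        drop <- if (isTRUE(maf[a] < maf[b])) a
                else if (isTRUE(maf[b] < maf[a])) b
                else max(a, b)                    # tie: later position
        keep[drop] <- FALSE
      }
      if (start + window_snps - 1L >= length(idx)) break
    }
  }
  which(keep)
}
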