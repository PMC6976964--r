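#' Carrier versus noncarrier quantitative-trait association
#'
#' Two-step test as used for haplotype-trait association: a two-sided F-test
#' of variance homogeneity first; if its p-value is >= `var_alpha` the mean
#' difference is tested with a pooled-variance two-sample t-test, otherwise
#' with Welch's t-test. Group summaries are reported in "mean +/- sd" form.
#'
#' @param carrier Logical vector (TRUE = carrier), one entry per sample.
#' @param trait Numeric trait values aligned with `carrier`; pairs with NA
#'   in either are dropped.
#' @param var_alpha Gate level for the variance test (default 0.05).
#' @return Object of class `carrier_assoc` with group summaries
#'   (`n`, `mean`, `sd` for carriers and noncarriers), `f_p` (variance-test
#'   p), `t_p` (mean-test p), `t_stat` and `test` (`"pooled"` or `"welch"`).
#'   With zero variance in both groups and equal means the t-test is
#'   undefined and reported as NA.
#' @export
carrier_association <- function(carrier, trait, var_alpha = 0.05) {
  stopifnot(length(carrier) == length(trait))
  ok <- !is.na(carrier) & !is.na(trait) & is.finite(trait)
  carrier <- carrier[ok]; trait <- trait[ok]
  x <- trait[carrier]; y <- trait[!carrier]
  if (length(x) < 2L || length(y) < 2L) {
    abort("both carrier and noncarrier groups need >= 2 phenotyped samples")
  }
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    f_p <- NA_real_
    if (mean(x) == mean(y)) {
      t_stat <- NA_real_; t_p <- NA_real_; test <- "pooled"
    } else {
      t_stat <- sign(mean(x) - mean(y)) * Inf; t_p <- 0; test <- "pooled"
    }
  } else {
    f_p <- var.test(x, y)$p.value
    test <- if (!is.na(f_p) && f_p < var_alpha) "welch" else "pooled"
    tt <- t.test(x, y, var.equal = (test == "pooled"))
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  structure(
    list(
      carrier = list(n = length(x), mean = mean(x), sd = sqrt(vx)),
      noncarrier = list(n = length(y), mean = mean(y), sd = sqrt(vy)),
      f_p = f_p, t_p = t_p, t_stat = t_stat, test = test
    ),
    class = "carrier_assoc"
  )
}

fmt_mean_sd <- function(g) sprintf("%.2f ± %.2f", g$mean, g$sd)

#' @exportS3Method base::print
print.carrier_assoc <- function(x, ...) {
  cat(sprintf(
    "<carrier_assoc> carriers (n=%d) %s versus noncarriers (n=%d) %s, p = %s (%s t-test; variance-test p = %s)\n",
    x$carrier$n, fmt_mean_sd(x$carrier),
    x$noncarrier$n, fmt_mean_sd(x$noncarrier),
    format(signif(x$t_p, 2)), x$test, format(signif(x$f_p, 2))
  ))
  invisible(x)
}

#' @export
tidy.carrier_assoc <- function(x, ...) {
  tibble(
    group = c("carrier", "noncarrier"),
    n = c(x$carrier$n, x$noncarrier$n),
    mean = c(x$carrier$mean, x$noncarrier$mean),
    sd = c(x$carrier$sd, x$noncarrier$sd),
    summary = c(fmt_mean_sd(x$carrier), fmt_mean_sd(x$noncarrier))
  )
}

#' @export
glance.carrier_assoc <- function(x, ...) {
  tibble(
    n_carrier = x$carrier$n, n_noncarrier = x$noncarrier$n,
    mean_diff = x$carrier$mean - x$noncarrier$mean,
    f_p = x$f_p, t_stat = x$t_stat, t_p = x$t_p, test = x$test
  )
}

#' Carrier status for a reference haplotype
#'
#' Dominant coding: a sample is a carrier when at least one of its two
#' phased haplotypes matches `reference_hap` over the region's SNPs.
#'
#' @param ds A phased [geno_dataset()].
#' @param chrom,start_bp,end_bp Region.
#' @param reference_hap 0/1 allele string over the region SNPs.
#' @return Tibble `sample_id`, `population`, `carrier` (NA when both
#'   haplotypes have missing alleles in the region).
#' @export
haplotype_carriers <- function(ds, chrom, start_bp, end_bp, reference_hap) {
  if (!ds$phased) abort("dataset must be phased")
  idx <- region_variant_idx(ds, chrom, start_bp, end_bp)
  if (nchar(reference_hap) != length(idx)) {
    abort("reference_hap length must equal the number of region SNPs")
  }
  h <- ds$haplotypes[, idx, drop = FALSE]
  strings <- apply(h, 1L, function(r) {
    if (anyNA(r)) NA_character_ else paste(r, collapse = "")
  })
  h1 <- strings[seq(1L, length(strings), 2L)]
  h2 <- strings[seq(2L, length(strings), 2L)]
  match1 <- !is.na(h1) & h1 == reference_hap
  match2 <- !is.na(h2) & h2 == reference_hap
  carrier <- unname(match1 | match2)
  # a non-matching sample with a missing haplotype cannot be ruled out
  carrier[!carrier & (is.na(h1) | is.na(h2))] <- NA
  tibble(
    sample_id = ds$samples$id, population = ds$samples$population,
    carrier = carrier
  )
}
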