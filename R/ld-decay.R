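#' Pairwise genotype r-squared within a distance window
#'
#' Within one group, keeps SNPs with minor allele frequency strictly above
#' `maf_min` and call rate strictly above `call_rate_min` (the within-breed
#' LD filter), then computes, for every within-chromosome pair at most
#' `max_window_kb` apart, the squared Pearson correlation of dosage vectors
#' over samples called at both SNPs. Zero-variance SNPs are excluded.
#'
#' @param ds A [geno_dataset()].
#' @param group Character vector of sample ids (default all); >= 2 samples.
#' @param maf_min MAF must exceed this to enter (default 0.1).
#' @param call_rate_min Call rate must exceed this to enter (default 0.9).
#' @param max_window_kb Maximum pair distance in kb (default 1000).
#' @param report_r2_min Pairs below this r-squared are suppressed from the
#'   output (default 0, keeping all pairs for curve fitting; 0.3 reproduces
#'   tool-style reports).
#' @return Tibble with `chrom`, `id_a`, `id_b`, `pos_a`, `pos_b`, `dist_bp`,
#'   `r2`.
#' @export
compute_ld_pairs <- function(ds, group = ds$samples$id, maf_min = 0.1,
                             call_rate_min = 0.9, max_window_kb = 1000,
                             report_r2_min = 0) {
  if (length(group) < 2L) abort("group needs at least 2 samples")
  sub <- subset_samples(ds, group)
  d <- sub$dosages
  called <- colSums(!is.na(d))
  cr <- called / nrow(d)
  p <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
  maf <- pmin(p, 1 - p)
  vr <- apply(d, 2L, var, na.rm = TRUE)
  keep <- !is.na(maf) & maf > maf_min & cr > call_rate_min &
    !is.na(vr) & vr > 0
  v <- sub$variants[keep, , drop = FALSE]
  d <- d[, keep, drop = FALSE]
  out <- list()
  max_bp <- max_window_kb * 1000
  for (chrom in unique(v$chrom)) {
    ci <- which(v$chrom == chrom)
    if (length(ci) < 2L) next
    r2 <- suppressWarnings(
      cor(d[, ci, drop = FALSE], use = "pairwise.complete.obs")^2
    )
    pr <- which(upper.tri(r2), arr.ind = TRUE)
    dist_bp <- v$pos[ci[pr[, 2L]]] - v$pos[ci[pr[, 1L]]]
    ok <- dist_bp <= max_bp & !is.na(r2[pr])
    pr <- pr[ok, , drop = FALSE]
    out[[length(out) + 1L]] <- tibble(
      chrom = chrom,
      id_a = v$id[ci[pr[, 1L]]], id_b = v$id[ci[pr[, 2L]]],
      pos_a = v$pos[ci[pr[, 1L]]], pos_b = v$pos[ci[pr[, 2L]]],
      dist_bp = dist_bp[ok], r2 = r2[pr]
    )
  }
  pairs <- if (length(out)) bind_rows(out) else {
    tibble(chrom = character(), id_a = character(), id_b = character(),
           pos_a = integer(), pos_b = integer(), dist_bp = integer(),
           r2 = double())
  }
  filter(pairs, .data$r2 >= report_r2_min)
}

#' Fit an LD decay curve and the r2 = 0.3 extent
#'
#' Nonlinear least squares of `r2 ~ 1 / (1 + rate * dist_kb)` (the
#' Sved/Heifetz expectation for genotype correlations under drift and
#' recombination), with `rate > 0` in per-kb units. The LD extent
#' `r03_kb = (1/0.3 - 1)/rate` is the distance at which the fitted curve
#' crosses 0.3; a degenerate fit (rate ~ 0, no decay inside the window)
#' reports `r03_kb = Inf` with a warning.
#'
#' @param pairs Tibble from [compute_ld_pairs()] with >= 10 pairs spanning
#'   >= 2 distinct distances.
#' @return Object of class `ld_decay_fit` with `rate`, `r03_kb`, `n_pairs`.
#' @export
fit_ld_decay <- function(pairs) {
  if (nrow(pairs) < 10L || length(unique(pairs$dist_bp)) < 2L) {
    abort("need >= 10 pairs spanning >= 2 distinct distances")
  }
  dist_kb <- pairs$dist_bp / 1000
  r2 <- pairs$r2
  fit <- minpack.lm::nlsLM(
    r2 ~ 1 / (1 + rate * dist_kb),
    start = list(rate = 1 / stats::median(dist_kb)),
    lower = 0, upper = Inf,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  rate <- unname(coef(fit)[["rate"]])
  if (rate < 1e-10) {
    warn("no detectable LD decay inside the window; r03_kb is infinite")
    r03 <- Inf
  } else {
    r03 <- (1 / 0.3 - 1) / rate
  }
  structure(
    list(rate = rate, r03_kb = r03, n_pairs = nrow(pairs), pairs = pairs),
    class = "ld_decay_fit"
  )
}

#' @exportS3Method base::print
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> rate = %.5g /kb, r0.3^2 extent = %.2f kb (%d pairs)\n",
              x$rate, x$r03_kb, x$n_pairs))
  invisible(x)
}

#' @export
tidy.ld_decay_fit <- function(x, ...) {
  tibble(term = c("rate", "r03_kb"), estimate = c(x$rate, x$r03_kb))
}

#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble(rate = x$rate, r03_kb = x$r03_kb, n_pairs = x$n_pairs)
}

#' LD extent read from binned mean r-squared
#'
#' Alternative reporting mode: pairs are binned by distance, and the extent
#' is the linearly interpolated distance at which the binned mean first
#' drops below 0.3 (`Inf` if it never does).
#'
#' @param pairs Tibble from [compute_ld_pairs()].
#' @param bin_kb Bin width in kb (default 10).
#' @return Distance in kb.
#' @export
ld_r03_binned <- function(pairs, bin_kb = 10) {
  b <- pairs %>%
    mutate(bin = floor(.data$dist_bp / 1000 / bin_kb)) %>%
    group_by(.data$bin) %>%
    summarise(mid_kb = (.data$bin[1] + 0.5) * bin_kb,
              mean_r2 = mean(.data$r2), .groups = "drop") %>%
    arrange(.data$mid_kb)
  below <- which(b$mean_r2 < 0.3)
  if (!length(below)) return(Inf)
  i <- below[1L]
  if (i == 1L) return(b$mid_kb[1L])
  x0 <- b$mid_kb[i - 1L]; y0 <- b$mean_r2[i - 1L]
  x1 <- b$mid_kb[i]; y1 <- b$mean_r2[i]
  x0 + (0.3 - y0) * (x1 - x0) / (y1 - y0)
}

#' @export
autoplot.ld_decay_fit <- function(object, bin_kb = 10, ...) {
  b <- object$pairs %>%
    mutate(bin = floor(.data$dist_bp / 1000 / bin_kb)) %>%
    group_by(.data$bin) %>%
    summarise(mid_kb = (.data$bin[1] + 0.5) * bin_kb,
              mean_r2 = mean(.data$r2), .groups = "drop")
  curve <- tibble(
    dist_kb = seq(min(b$mid_kb), max(b$mid_kb), length.out = 200)
  ) %>%
    mutate(r2 = 1 / (1 + object$rate * .data$dist_kb))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid_kb, y = .data$mean_r2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$dist_kb, y = .data$r2),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.3, linetype = "dashed") +
    ggplot2::labs(x = "distance (kb)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
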