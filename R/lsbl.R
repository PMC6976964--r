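#' Locus-specific branch length from three pairwise Fst vectors
#'
#' `x = (Fst_AB + Fst_AC - Fst_BC) / 2` elementwise: the branch of focal
#' population A in the three-population tree. Undefined (NA) inputs
#' propagate; negative values are legitimate and not clamped.
#'
#' @param fst_ab,fst_ac,fst_bc Numeric per-SNP Fst vectors aligned on the
#'   same SNP index.
#' @return Numeric vector of branch lengths.
#' @export
lsbl <- function(fst_ab, fst_ac, fst_bc) {
  if (length(fst_ab) != length(fst_ac) || length(fst_ab) != length(fst_bc)) {
    abort("Fst vectors must have equal length")
  }
  (fst_ab + fst_ac - fst_bc) / 2
}

#' Three-population LSBL selection scan
#'
#' Computes the three pairwise per-SNP Fst vectors among disjoint groups A
#' (focal), B and C, the branch length `x` per SNP, and flags outliers.
#' The threshold is the empirical `(1 - top_fraction)` quantile of defined
#' `x` values (type-1 / order-statistic quantile, so with `n` defined SNPs
#' exactly `floor(n * top_fraction)` values lie strictly above it, more only
#' on exact ties), unless an absolute cutoff is supplied, in which case that
#' cutoff is the threshold. Undefined-Fst SNPs are excluded from the
#' quantile and are never outliers.
#'
#' @param ds A [geno_dataset()].
#' @param group_a,group_b,group_c Disjoint sample-id vectors (focal = A),
#'   each with >= 2 samples.
#' @param estimator Fst estimator, see [fst_per_snp()].
#' @param top_fraction Empirical outlier fraction (default 0.0002, i.e. the
#'   top 0.02%).
#' @param abs_cutoff Optional absolute threshold on `x` overriding the
#'   empirical quantile.
#' @return Object of class `lsbl_result`: `per_snp` tibble (`id`, `chrom`,
#'   `pos`, `fst_ab`, `fst_ac`, `fst_bc`, `lsbl`, `outlier`), plus
#'   `threshold_value`, `top_fraction`, `abs_cutoff`, `n_outliers`,
#'   `estimator`, `focal_group`.
#' @export
run_lsbl_scan <- function(ds, group_a, group_b, group_c,
                          estimator = c("weir_cockerham", "hudson"),
                          top_fraction = 0.0002, abs_cutoff = NULL,
                          focal_label = "A") {
  estimator <- arg_match(estimator)
  groups <- list(A = group_a, B = group_b, C = group_c)
  if (any(lengths(groups) < 2L)) abort("each group needs >= 2 samples")
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(groups[[i]], groups[[j]])
    if (length(ov)) {
      abort(paste0("groups overlap: ", paste(head(ov, 5), collapse = ", ")))
    }
  }
  f_ab <- fst_per_snp(ds, group_a, group_b, estimator)$per_snp$fst
  f_ac <- fst_per_snp(ds, group_a, group_c, estimator)$per_snp$fst
  f_bc <- fst_per_snp(ds, group_b, group_c, estimator)$per_snp$fst
  x <- lsbl(f_ab, f_ac, f_bc)
  defined <- !is.na(x)
  threshold <- if (!is.null(abs_cutoff)) {
    abs_cutoff
  } else {
    unname(quantile(x[defined], 1 - top_fraction, type = 1))
  }
  outlier <- defined & x > threshold
  structure(
    list(
      per_snp = tibble(
        id = ds$variants$id, chrom = ds$variants$chrom,
        pos = ds$variants$pos,
        fst_ab = f_ab, fst_ac = f_ac, fst_bc = f_bc,
        lsbl = x, outlier = outlier
      ),
      threshold_value = threshold,
      top_fraction = top_fraction,
      abs_cutoff = abs_cutoff,
      n_outliers = sum(outlier),
      estimator = estimator,
      focal_group = focal_label
    ),
    class = "lsbl_result"
  )
}

#' @exportS3Method base::print
print.lsbl_result <- function(x, ...) {
  cat(sprintf(
    "<lsbl_result> focal %s, %d SNPs, threshold %.4f (%s), %d outliers [%s]\n",
    x$focal_group, nrow(x$per_snp), x$threshold_value,
    if (is.null(x$abs_cutoff)) sprintf("top %.4g fraction", x$top_fraction)
    else "absolute cutoff",
    x$n_outliers, x$estimator
  ))
  invisible(x)
}

#' @export
tidy.lsbl_result <- function(x, ...) x$per_snp

#' @export
glance.lsbl_result <- function(x, ...) {
  tibble(
    focal_group = x$focal_group, estimator = x$estimator,
    n_snps = nrow(x$per_snp), n_defined = sum(!is.na(x$per_snp$lsbl)),
    threshold_value = x$threshold_value, top_fraction = x$top_fraction,
    n_outliers = x$n_outliers
  )
}

#' Manhattan plot of an LSBL scan
#' @param object An `lsbl_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lsbl_result <- function(object, ...) {
  d <- filter(object$per_snp, !is.na(.data$lsbl))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = .data$lsbl,
                                  colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = object$threshold_value,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = "LSBL") +
    ggplot2::theme_minimal()
}

#' Annotate LSBL outliers with nearby genes
#'
#' A gene is a candidate iff some outlier SNP lies inside its span
#' (inclusive) or strictly less than `flank_bp` away from either edge - so a
#' SNP exactly `flank_bp` from a gene does not qualify. Genes are
#' deduplicated by `gene_id`.
#'
#' @param result An `lsbl_result`.
#' @param genes Tibble with `gene_id`, `name`, `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive; see [read_gene_annotation()]).
#' @param flank_bp Flanking distance in bp (default 10000).
#' @return Tibble with one row per (gene, supporting outlier SNP):
#'   `gene_id`, `name`, `chrom`, `start_bp`, `end_bp`, `snp_id`, `pos`,
#'   `lsbl`, `distance_bp` (0 inside the gene).
#' @export
annotate_candidates <- function(result, genes, flank_bp = 10000) {
  outliers <- filter(result$per_snp, .data$outlier)
  if (!nrow(outliers)) {
    return(tibble(gene_id = character(), name = character(),
                  chrom = character(), start_bp = integer(),
                  end_bp = integer(), snp_id = character(), pos = integer(),
                  lsbl = double(), distance_bp = integer()))
  }
  if (!length(intersect(unique(outliers$chrom), unique(genes$chrom)))) {
    abort(paste0(
      "no annotation chromosome matches the outlier SNPs; SNP chroms: ",
      paste(unique(outliers$chrom), collapse = ", ")
    ))
  }
  hits <- outliers %>%
    dplyr::inner_join(genes, by = "chrom", relationship = "many-to-many") %>%
    mutate(distance_bp = pmax(0L, pmax(.data$start_bp - .data$pos,
                                       .data$pos - .data$end_bp))) %>%
    filter(.data$distance_bp < flank_bp) %>%
    select(gene_id = "gene_id", name = "name", chrom = "chrom",
           start_bp = "start_bp", end_bp = "end_bp", snp_id = "id",
           pos = "pos", lsbl = "lsbl", distance_bp = "distance_bp") %>%
    distinct(.data$gene_id, .data$snp_id, .keep_all = TRUE) %>%
    arrange(.data$gene_id, .data$pos)
  hits
}
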