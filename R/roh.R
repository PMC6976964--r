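#' Parameters for the sliding-window ROH caller
#'
#' The four window parameters mirror the PLINK command
#' `--homozyg --homozyg-window-snp 50 --homozyg-window-het 1
#' --homozyg-window-missing 5 --homozyg-kb 500`; the companion parameters
#' (`min_snps`, `window_hit_threshold`, `max_gap_kb`,
#' `min_density_kb_per_snp`) default to that tool's conventional defaults and
#' are exposed here so their sensitivity can be examined.
#'
#' @param window_snps SNPs per sliding window (default 50).
#' @param window_het_max Maximum heterozygous calls tolerated per window
#'   (default 1).
#' @param window_missing_max Maximum missing calls tolerated per window
#'   (default 5).
#' @param min_length_kb Minimum segment length in kb (default 500).
#' @param min_snps Minimum SNPs per segment (default 100).
#' @param window_hit_threshold Minimum fraction of homozygous windows
#'   covering a SNP for it to be ROH-candidate (default 0.05).
#' @param max_gap_kb Maximum gap between consecutive SNPs inside a segment
#'   (default 1000).
#' @param min_density_kb_per_snp Maximum kb per SNP inside a segment
#'   (default 50).
#' @return List of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_het_max = 1,
                       window_missing_max = 5, min_length_kb = 500,
                       min_snps = 100, window_hit_threshold = 0.05,
                       max_gap_kb = 1000, min_density_kb_per_snp = 50) {
  p <- list(
    window_snps = window_snps, window_het_max = window_het_max,
    window_missing_max = window_missing_max, min_length_kb = min_length_kb,
    min_snps = min_snps, window_hit_threshold = window_hit_threshold,
    max_gap_kb = max_gap_kb, min_density_kb_per_snp = min_density_kb_per_snp
  )
  stopifnot(all(unlist(p) >= 0),
            window_snps >= window_het_max + window_missing_max)
  structure(p, class = "roh_params")
}

#' Call runs of homozygosity per individual
#'
#' Per individual and chromosome, windows of `window_snps` consecutive SNPs
#' slide one SNP at a time; a window is homozygous when it has at most
#' `window_het_max` heterozygous and `window_missing_max` missing calls.
#' Each SNP's hit rate is the fraction of windows covering it that are
#' homozygous; SNPs at or above `window_hit_threshold` are ROH candidates.
#' Maximal candidate runs are split at inter-SNP gaps above `max_gap_kb`,
#' trimmed to their outermost homozygous non-missing SNPs, and reported when
#' they satisfy the length, SNP-count and density constraints. Segment
#' length is `(end - start + 1)/1000` kb on 1-based inclusive coordinates.
#'
#' @param ds A [geno_dataset()] (variants must be position-sorted, which the
#'   container enforces).
#' @param params A [roh_params()].
#' @return Tibble with `sample`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_kb`, ordered by (sample, chrom, start).
#' @export
call_roh <- function(ds, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  out <- list()
  for (chrom in unique(ds$variants$chrom)) {
    idx <- which(ds$variants$chrom == chrom)
    pos <- ds$variants$pos[idx]
    for (s in seq_len(n_samples(ds))) {
      g <- ds$dosages[s, idx]
      segs <- roh_one(g, pos, params)
      if (nrow(segs)) {
        segs$sample <- ds$samples$id[s]
        segs$chrom <- chrom
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(tibble(
      sample = character(), chrom = character(), start_bp = integer(),
      end_bp = integer(), n_snps = integer(), length_kb = double()
    ))
  }
  bind_rows(out) %>%
    select("sample", "chrom", "start_bp", "end_bp", "n_snps", "length_kb") %>%
    arrange(.data$sample, .data$chrom, .data$start_bp)
}

# Single genotype vector on one chromosome -> candidate segments.
roh_one <- function(g, pos, p) {
  L <- length(g)
  w <- p$window_snps
  empty <- tibble(start_bp = integer(), end_bp = integer(),
                  n_snps = integer(), length_kb = double())
  if (L < w) return(empty)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  csh <- c(0L, cumsum(het))
  csm <- c(0L, cumsum(mis))
  starts <- 1:(L - w + 1L)
  hom_win <- (csh[starts + w] - csh[starts]) <= p$window_het_max &
    (csm[starts + w] - csm[starts]) <= p$window_missing_max
  # windows covering SNP j start in [j - w + 1, j], clipped to valid range
  csw <- c(0L, cumsum(as.integer(hom_win)))
  j <- seq_len(L)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, L - w + 1L)
  n_cov <- hi - lo + 1L
  n_hom <- csw[hi + 1L] - csw[lo]
  candidate <- n_cov > 0L & (n_hom / n_cov) >= p$window_hit_threshold
  runs <- split_runs(which(candidate), pos, p$max_gap_kb * 1000)
  segs <- list()
  for (run in runs) {
    # trim to outermost homozygous, non-missing SNPs
    ok <- !is.na(g[run]) & g[run] != 1L
    if (!any(ok)) next
    run <- run[min(which(ok)):max(which(ok))]
    n_snp <- length(run)
    start_bp <- pos[run[1L]]
    end_bp <- pos[run[n_snp]]
    len_kb <- (end_bp - start_bp + 1) / 1000
    if (n_snp >= p$min_snps && len_kb >= p$min_length_kb &&
        len_kb / n_snp <= p$min_density_kb_per_snp) {
      segs[[length(segs) + 1L]] <- tibble(
        start_bp = start_bp, end_bp = end_bp,
        n_snps = n_snp, length_kb = len_kb
      )
    }
  }
  if (!length(segs)) empty else bind_rows(segs)
}

# Maximal runs of consecutive indices, additionally split where the physical
# gap between neighbouring SNPs exceeds max_gap_bp.
split_runs <- function(idx, pos, max_gap_bp) {
  if (!length(idx)) return(list())
  brk <- diff(idx) > 1L | diff(pos[idx]) > max_gap_bp
  unname(split(idx, cumsum(c(0L, as.integer(brk)))))
}

#' Classify ROH segments into length bins
#'
#' Bins are half-open: 0.5-1 Mb, 1-5 Mb and >= 5 Mb (`[0.5,1)`, `[1,5)`,
#' `[5,Inf)`); segments below 0.5 Mb are ignored.
#'
#' @param segments Tibble from [call_roh()].
#' @return Tibble with one row per sample and bin: `sample`, `bin`,
#'   `n_segments`, `total_kb`.
#' @export
classify_roh <- function(segments) {
  bins <- c("0.5-1Mb", "1-5Mb", ">5Mb")
  if (!nrow(segments)) {
    return(tibble(sample = character(), bin = character(),
                  n_segments = integer(), total_kb = double()))
  }
  segments %>%
    mutate(bin = dplyr::case_when(
      .data$length_kb >= 5000 ~ bins[3],
      .data$length_kb >= 1000 ~ bins[2],
      .data$length_kb >= 500 ~ bins[1],
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$sample, .data$bin) %>%
    summarise(n_segments = dplyr::n(), total_kb = sum(.data$length_kb),
              .groups = "drop")
}

#' Per-sample ROH totals
#' @param segments Tibble from [call_roh()].
#' @return Tibble `sample`, `n_segments`, `total_kb`.
#' @export
roh_summary <- function(segments) {
  if (!nrow(segments)) {
    return(tibble(sample = character(), n_segments = integer(),
                  total_kb = double()))
  }
  segments %>%
    group_by(.data$sample) %>%
    summarise(n_segments = dplyr::n(), total_kb = sum(.data$length_kb),
              .groups = "drop")
}
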