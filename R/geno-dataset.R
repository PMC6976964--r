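#' Genotype dataset container
#'
#' Bundles a samples-by-variants dosage matrix with its variant metadata,
#' sample/population map and, for phased data, the underlying haplotype
#' matrix. Dosages count copies of the alternate allele (0, 1, 2) and missing
#' genotypes are `NA`, never 0. Coordinates are 1-based inclusive throughout
#' the package.
#'
#' @param variants Tibble with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` (single-base allele strings). Within each chromosome,
#'   positions must be strictly increasing.
#' @param samples Tibble with columns `id`, `population` and optionally
#'   `ecotype`. Sample ids must be unique and populations non-empty.
#' @param dosages Integer matrix `[n_samples x n_variants]` with entries in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names variant ids.
#' @param haplotypes Optional integer matrix `[2*n_samples x n_variants]`
#'   with entries in `{0, 1, NA}`; rows `2i-1`, `2i` are the two haplotypes of
#'   sample `i`. Supplying it marks the dataset as phased.
#'
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(variants, samples, dosages, haplotypes = NULL) {
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  stopifnot(
    all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
    all(c("id", "population") %in% names(samples))
  )
  if (!"ecotype" %in% names(samples)) samples$ecotype <- NA_character_
  if (anyDuplicated(samples$id) > 0) {
    abort("sample ids must be unique")
  }
  if (any(!nzchar(samples$population)) || anyNA(samples$population)) {
    abort("every sample needs a non-empty population label")
  }
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    abort("ref and alt allele must differ at every variant")
  }
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(samples) || ncol(dosages) != nrow(variants)) {
    abort("dosage matrix shape does not match sample/variant tables")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  rownames(dosages) <- samples$id
  colnames(dosages) <- variants$id
  # positions sorted within chromosome; a coordinate may repeat only for
  # distinct alt alleles (split multiallelic records)
  by_chrom <- split(variants$pos, variants$chrom)
  if (any(vapply(by_chrom, is.unsorted, logical(1)))) {
    abort("variants must be sorted by pos within chrom")
  }
  if (anyDuplicated(variants[, c("chrom", "pos", "alt")])) {
    abort("duplicate (chrom, pos, alt) variants; deduplicate on read")
  }
  phased <- !is.null(haplotypes)
  if (phased) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (nrow(haplotypes) != 2L * nrow(samples) ||
        ncol(haplotypes) != nrow(variants)) {
      abort("haplotype matrix must be [2*n_samples x n_variants]")
    }
    hb <- haplotypes[!is.na(haplotypes)]
    if (length(hb) && (min(hb) < 0L || max(hb) > 1L)) {
      abort("haplotype entries must be 0, 1 or NA")
    }
    hsum <- haplotypes[seq(1L, nrow(haplotypes), by = 2L), , drop = FALSE] +
      haplotypes[seq(2L, nrow(haplotypes), by = 2L), , drop = FALSE]
    both <- !is.na(hsum) & !is.na(dosages)
    if (any(hsum[both] != dosages[both])) {
      abort("dosages disagree with haplotype sums")
    }
    rownames(haplotypes) <- paste0(rep(samples$id, each = 2L), c("_h1", "_h2"))
    colnames(haplotypes) <- variants$id
  }
  structure(
    list(
      variants = variants, samples = samples,
      dosages = dosages, haplotypes = haplotypes, phased = phased
    ),
    class = "geno_dataset"
  )
}

#' @exportS3Method base::print
print.geno_dataset <- function(x, ...) {
  cat(sprintf(
    "<geno_dataset> %d samples x %d variants (%s), %d populations\n",
    n_samples(x), n_variants(x),
    if (x$phased) "phased" else "unphased",
    length(unique(x$samples$population))
  ))
  invisible(x)
}

#' Number of samples / variants in a genotype dataset
#' @param ds A [geno_dataset()].
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' @rdname n_samples
#' @export
n_variants <- function(ds) nrow(ds$variants)

#' Subset a genotype dataset
#'
#' @param ds A [geno_dataset()].
#' @param variant_idx Integer or logical index into the variant table.
#' @param sample_ids Character vector of sample ids to keep.
#' @return A new `geno_dataset`.
#' @export
subset_variants <- function(ds, variant_idx) {
  hap <- if (ds$phased) ds$haplotypes[, variant_idx, drop = FALSE] else NULL
  geno_dataset(
    ds$variants[variant_idx, , drop = FALSE], ds$samples,
    ds$dosages[, variant_idx, drop = FALSE], hap
  )
}

#' @rdname subset_variants
#' @export
subset_samples <- function(ds, sample_ids) {
  keep <- match(sample_ids, ds$samples$id)
  if (anyNA(keep)) {
    abort(paste0(
      "unknown sample ids: ",
      paste(sample_ids[is.na(keep)], collapse = ", ")
    ))
  }
  hap <- NULL
  if (ds$phased) {
    hrows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
    hap <- ds$haplotypes[hrows, , drop = FALSE]
  }
  geno_dataset(
    ds$variants, ds$samples[keep, , drop = FALSE],
    ds$dosages[keep, , drop = FALSE], hap
  )
}

#' Indices of variants falling in a genomic region (1-based inclusive)
#' @param ds A [geno_dataset()].
#' @param chrom Chromosome name.
#' @param start_bp,end_bp Region bounds in bp, both included.
#' @return Integer vector of variant indices.
#' @export
region_variant_idx <- function(ds, chrom, start_bp, end_bp) {
  which(ds$variants$chrom == chrom &
          ds$variants$pos >= start_bp & ds$variants$pos <= end_bp)
}

#' Span of a 1-based inclusive region in kilobases
#'
#' `(end - start + 1) / 1000`, the convention used for ROH lengths and
#' haplotype-region spans throughout.
#' @param start_bp,end_bp Region bounds in bp.
#' @return Span in kb.
#' @export
region_span_kb <- function(start_bp, end_bp) {
  stopifnot(end_bp >= start_bp)
  (end_bp - start_bp + 1) / 1000
}

#' Sample ids belonging to given populations
#' @param ds A [geno_dataset()].
#' @param populations Character vector of population labels.
#' @return Character vector of sample ids.
#' @export
population_samples <- function(ds, populations) {
  miss <- setdiff(populations, ds$samples$population)
  if (length(miss)) {
    abort(paste0("unknown populations: ", paste(miss, collapse = ", ")))
  }
  ds$samples$id[ds$samples$population %in% populations]
}
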