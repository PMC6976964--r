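#' Identity-by-state distance matrix between individuals
#'
#' Similarity between two individuals is the mean, over SNPs called in both,
#' of `(2 - |dosage_i - dosage_j|) / 2`; the distance is `1 - similarity`.
#'
#' @param ds A [geno_dataset()] with at least 2 samples.
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
ibs_distance_matrix <- function(ds) {
  if (n_samples(ds) < 2L) abort("need at least 2 samples")
  d <- ds$dosages
  n <- nrow(d)
  m <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      diff <- abs(d[i, ] - d[j, ])
      if (all(is.na(diff))) {
        abort(sprintf(
          "samples %s and %s share no called SNPs; IBS undefined",
          rownames(d)[i], rownames(d)[j]
        ))
      }
      m[i, j] <- m[j, i] <- mean(diff, na.rm = TRUE) / 2
    }
  }
  m
}

#' Nei standard genetic distance between two allele-frequency vectors
#'
#' `D = -ln( sum_ij x_ij y_ij / sqrt(sum_ij x_ij^2 * sum_ij y_ij^2) )`, the
#' sums running over loci and over both alleles of each biallelic SNP.
#' `freq_a`/`freq_b` give the alternate-allele frequency per SNP; the
#' reference-allele terms are filled in as `1 - freq`. SNPs with a missing
#' frequency in either vector are dropped pairwise.
#'
#' @param freq_a,freq_b Numeric vectors of alternate-allele frequencies,
#'   aligned on the same SNP set.
#' @return Non-negative distance; `+Inf` (with a warning) when the two
#'   vectors share no alleles anywhere.
#' @export
nei_standard_distance <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b)) {
    abort("frequency vectors must be aligned on the same SNP set")
  }
  ok <- !is.na(freq_a) & !is.na(freq_b)
  x <- freq_a[ok]; y <- freq_b[ok]
  if (!length(x)) abort("no jointly defined SNPs")
  jxy <- sum(x * y + (1 - x) * (1 - y))
  jx <- sum(x^2 + (1 - x)^2)
  jy <- sum(y^2 + (1 - y)^2)
  if (jxy == 0) {
    warn("no shared alleles at any locus; Nei distance is infinite")
    return(Inf)
  }
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' Pairwise Nei standard distance matrix over populations
#' @param ds A [geno_dataset()].
#' @param groups Named list of sample-id vectors, or `NULL` for the dataset's
#'   populations.
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
nei_distance_matrix <- function(ds, groups = NULL) {
  if (is.null(groups)) groups <- split(ds$samples$id, ds$samples$population)
  freqs <- map(groups, function(ids) allele_frequency(ds, ids)$freq)
  labs <- names(groups)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- nei_standard_distance(freqs[[i]], freqs[[j]])
    }
  }
  m
}

#' Write / read a square distance matrix as TSV
#'
#' Square layout with header labels; row names in the first column.
#' @param m Labelled symmetric matrix.
#' @param path Output path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
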