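# Fixture builders and independent oracles shared across the test files.

# Quick dataset from a samples x variants dosage matrix.
make_ds <- function(dosages, populations = rep("popA", nrow(dosages)),
                    pos = NULL, chrom = "chr1", haplotypes = NULL,
                    ids = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  L <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  geno_dataset(
    variants = tibble::tibble(
      id = sprintf("v%03d", seq_len(L)), chrom = chrom,
      pos = as.integer(pos), ref = "A", alt = "G"
    ),
    samples = tibble::tibble(id = ids, population = populations),
    dosages = dosages, haplotypes = haplotypes
  )
}

# Phased dataset from a 2n x L haplotype matrix.
make_phased_ds <- function(hap, populations, pos = NULL, chrom = "chr1") {
  hap <- as.matrix(hap)
  d <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  make_ds(d, populations, pos = pos, chrom = chrom, haplotypes = hap)
}

write_mini_vcf <- function(path, samples, records, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(records, function(r) {
    gts <- gsub("/", sep, r$gt, fixed = TRUE)
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", ".", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

write_popmap <- function(path, ids, pops) {
  readr::write_tsv(tibble::tibble(sample_id = ids, population = pops), path)
  path
}

# Scalar transcription of the Weir & Cockerham (1984) two-population
# variance components for one SNP; the production code is vectorised and
# shares no code with this.
wc_fst_oracle <- function(ga, gb) {
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  n1 <- length(ga); n2 <- length(gb)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return(NA_real_)
  p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
  h1 <- mean(ga == 1); h2 <- mean(gb == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  if (pbar == 0 || pbar == 1) return(NA_real_)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Plain-loop re-implementation of the window ROH definition, for small
# inputs only; shares no code with call_roh().
roh_oracle <- function(g, pos, p) {
  L <- length(g)
  w <- p$window_snps
  if (L < w) return(data.frame())
  hom_win <- logical(L - w + 1)
  for (s in seq_len(L - w + 1)) {
    win <- g[s:(s + w - 1)]
    hom_win[s] <- sum(win == 1, na.rm = TRUE) <= p$window_het_max &&
      sum(is.na(win)) <= p$window_missing_max
  }
  cand <- logical(L)
  for (j in seq_len(L)) {
    starts <- max(1, j - w + 1):min(j, L - w + 1)
    if (length(starts) == 0 || min(starts) > L - w + 1) next
    cand[j] <- mean(hom_win[starts]) >= p$window_hit_threshold
  }
  segs <- list()
  run <- integer()
  flush <- function(run, segs) {
    if (!length(run)) return(segs)
    ok <- which(!is.na(g[run]) & g[run] != 1)
    if (!length(ok)) return(segs)
    run <- run[min(ok):max(ok)]
    len_kb <- (pos[run[length(run)]] - pos[run[1]] + 1) / 1000
    if (length(run) >= p$min_snps && len_kb >= p$min_length_kb &&
        len_kb / length(run) <= p$min_density_kb_per_snp) {
      segs[[length(segs) + 1]] <- data.frame(
        start_bp = pos[run[1]], end_bp = pos[run[length(run)]],
        n_snps = length(run), length_kb = len_kb
      )
    }
    segs
  }
  for (j in seq_len(L)) {
    if (cand[j]) {
      if (length(run) &&
          (pos[j] - pos[run[length(run)]]) > p$max_gap_kb * 1000) {
        segs <- flush(run, segs)
        run <- integer()
      }
      run <- c(run, j)
    } else {
      segs <- flush(run, segs)
      run <- integer()
    }
  }
  segs <- flush(run, segs)
  if (!length(segs)) data.frame() else do.call(rbind, segs)
}

# Random additive distance matrix from a random topology; returns the tree
# and its cophenetic matrix.
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.5, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
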