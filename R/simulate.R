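#' Simulate multi-population SNP genotypes under the Balding-Nichols model
#'
#' Per SNP an ancestral frequency `p` is drawn from `Uniform(0.05, 0.95)`
#' (the ascertainment window of a common-variant SNP chip); each
#' population's frequency is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so
#' the drift coefficient `F` equals the expected Fst to the ancestor.
#' Genotypes are then binomial draws per individual. In `mosaic` mode each
#' population first realises `n_founders` founder haplotypes from its
#' frequencies and every sample haplotype is a Markov copying mosaic of
#' them, switching founders between adjacent SNPs with probability
#' `1 - exp(-recomb_rate * gap_bp)`, which yields distance-decaying LD.
#' `selected_loci` overrides the focal population's frequency at chosen
#' SNPs, planting selection outliers. SNP spacing defaults to the chip-like
#' 2,689 bp average; positions are drawn uniformly on one chromosome and
#' sorted.
#'
#' Everything is a pure function of the arguments and `seed`.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Diploid individuals per population (scalar or vector).
#' @param n_snps Number of biallelic SNPs.
#' @param fst Per-population drift coefficient `F` in (0, 1) (scalar or
#'   vector); 0 and 1 are degenerate and rejected.
#' @param seed Integer seed (mandatory).
#' @param mode `"independent"` (no LD) or `"mosaic"` (founder-copying LD).
#' @param phased Keep the haplotype matrix (TRUE for mosaic mode).
#' @param selected_loci Optional tibble `snp` (index), `pop` (label or
#'   index), `freq` (target frequency in `[0,1]`) overriding drifted
#'   frequencies; an optional `ancestral` column pins the locus's ancestral
#'   frequency (and hence the other populations' drift centre).
#' @param n_founders Founder haplotypes per population in mosaic mode
#'   (default 8).
#' @param recomb_rate Per-bp founder-switch intensity in mosaic mode
#'   (default 1e-6).
#' @param chrom Chromosome name (default `"chr1"`).
#' @param spacing_bp Mean inter-SNP distance (default 2689).
#' @param pop_names Population labels (default `pop1..popK`).
#' @return A [geno_dataset()].
#' @export
simulate_populations <- function(n_pops, n_per_pop, n_snps, fst, seed,
                                 mode = c("independent", "mosaic"),
                                 phased = (mode == "mosaic"),
                                 selected_loci = NULL, n_founders = 8,
                                 recomb_rate = 1e-6, chrom = "chr1",
                                 spacing_bp = 2689,
                                 pop_names = paste0("pop", seq_len(n_pops))) {
  mode <- arg_match(mode)
  force(phased)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (any(fst <= 0) || any(fst >= 1)) {
    abort("fst must lie strictly inside (0, 1); the Beta model degenerates")
  }
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst <- rep_len(fst, n_pops)
  withr_seed(seed)
  pos <- sort(sample.int(n_snps * spacing_bp, n_snps))
  p_anc <- runif(n_snps, 0.05, 0.95)
  if (!is.null(selected_loci) && "ancestral" %in% names(selected_loci)) {
    p_anc[selected_loci$snp] <- selected_loci$ancestral
  }
  pop_freq <- sapply(seq_len(n_pops), function(k) {
    f <- fst[k]
    rbeta(n_snps, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  })
  if (!is.null(selected_loci)) {
    for (r in seq_len(nrow(selected_loci))) {
      kp <- selected_loci$pop[r]
      if (is.character(kp)) kp <- match(kp, pop_names)
      pop_freq[selected_loci$snp[r], kp] <- selected_loci$freq[r]
    }
  }
  samples <- tibble(
    id = unlist(map(seq_len(n_pops), function(k) {
      sprintf("%s_ind%02d", pop_names[k], seq_len(n_per_pop[k]))
    })),
    population = rep(pop_names, n_per_pop)
  )
  n_total <- sum(n_per_pop)
  hap <- matrix(NA_integer_, 2L * n_total, n_snps)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    n_hap <- 2L * n_per_pop[k]
    if (mode == "independent") {
      hk <- matrix(
        rbinom(n_hap * n_snps, 1L, rep(pop_freq[, k], each = n_hap)),
        nrow = n_hap
      )
    } else {
      founders <- matrix(
        rbinom(n_founders * n_snps, 1L, rep(pop_freq[, k], each = n_founders)),
        nrow = n_founders
      )
      hk <- mosaic_haplotypes(founders, n_hap, pos, recomb_rate)
    }
    hap[row0 + seq_len(n_hap), ] <- hk
    row0 <- row0 + n_hap
  }
  variants <- tibble(
    id = sprintf("snp%06d", seq_len(n_snps)), chrom = chrom,
    pos = as.integer(pos), ref = "A", alt = "G"
  )
  dosages <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
    hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  geno_dataset(variants, samples, dosages, if (phased) hap else NULL)
}

# Each row of the result copies from `founders`, switching founder between
# adjacent SNPs with probability 1 - exp(-rate * gap).
mosaic_haplotypes <- function(founders, n_hap, pos, rate) {
  n_snps <- ncol(founders)
  switch_p <- 1 - exp(-rate * diff(pos))
  out <- matrix(NA_integer_, n_hap, n_snps)
  for (h in seq_len(n_hap)) {
    src <- integer(n_snps)
    src[1L] <- sample.int(nrow(founders), 1L)
    sw <- runif(n_snps - 1L) < switch_p
    for (j in seq_len(n_snps - 1L)) {
      src[j + 1L] <- if (sw[j]) sample.int(nrow(founders), 1L) else src[j]
    }
    out[h, ] <- founders[cbind(src, seq_len(n_snps))]
  }
  out
}

# local, dependency-free equivalent of withr::with_seed semantics: the
# generators own their RNG stream entirely, so a plain set.seed is enough.
withr_seed <- function(seed) set.seed(as.integer(seed))

#' Simulate a phased haplotype region with planted founder blocks
#'
#' Generates a phased region where every sample haplotype is a copy of one
#' of a small set of founder haplotypes, the discrete structure that
#' haplotype networks, sharing matrices and shared-block detection assume.
#' A designated block (a run of SNP indices) can be planted so that a
#' reference haplotype reaches a requested frequency in chosen target
#' populations: carriers match the reference exactly inside the block.
#' Frequencies are realised as exact counts (`round(freq * 2n)` copies, any
#' rounding is reported), spread over distinct individuals first so that
#' dominant-coded carrier counts are predictable. At the SNPs immediately flanking a planted block
#' each target population is forced to stay visibly polymorphic (about 20%
#' minor-allele haplotypes), so the planted block terminates at its stated
#' boundaries rather than extending by chance.
#'
#' @param n_pops,n_per_pop,seed As in [simulate_populations()].
#' @param n_snps SNPs in the region.
#' @param founders Optional 0/1 matrix `[n_founders x n_snps]` of founder
#'   haplotypes; drawn at random (frequency 0.5 per SNP) when NULL, in which
#'   case the panel is forced to stay polymorphic at every SNP so that no
#'   locus is trivially fixed in all populations.
#' @param founder_freqs Optional `[n_founders x n_pops]` matrix of founder
#'   sampling weights per population; uniform when NULL.
#' @param planted_block Optional list with `start_snp`, `end_snp` (indices),
#'   `target_pops` (labels), `freq` in `[0, 1]`, and optionally `haplotype`
#'   (0/1 string over the block; defaults to all 1s).
#' @param n_founders Number of founders when `founders` is NULL (default 6).
#' @param chrom Chromosome name (default `"chr3"`).
#' @param start_bp First SNP position (default 100000).
#' @param spacing_bp Inter-SNP spacing (default 1500, a dense genic region).
#' @param pop_names Population labels.
#' @return A phased [geno_dataset()].
#' @export
simulate_haplotype_region <- function(n_pops, n_per_pop, n_snps, seed,
                                      founders = NULL, founder_freqs = NULL,
                                      planted_block = NULL, n_founders = 6,
                                      chrom = "chr3", start_bp = 100000,
                                      spacing_bp = 1500,
                                      pop_names = paste0("pop", seq_len(n_pops))) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  withr_seed(seed)
  if (is.null(founders)) {
    founders <- matrix(rbinom(n_founders * n_snps, 1L, 0.5),
                       nrow = n_founders)
    # the founder panel must be polymorphic at every SNP, otherwise a SNP is
    # trivially "fixed" in every population regardless of planted structure
    mono <- which(colSums(founders) %in% c(0L, nrow(founders)))
    if (length(mono)) {
      flip <- sample.int(nrow(founders), length(mono), replace = TRUE)
      founders[cbind(flip, mono)] <- 1L - founders[cbind(flip, mono)]
    }
  }
  n_founders <- nrow(founders)
  if (is.null(founder_freqs)) {
    founder_freqs <- matrix(1 / n_founders, n_founders, n_pops)
  }
  pos <- as.integer(start_bp + spacing_bp * (seq_len(n_snps) - 1L))
  block <- NULL
  if (!is.null(planted_block)) {
    block <- planted_block
    block$idx <- block$start_snp:block$end_snp
    block$hap <- if (!is.null(block$haplotype)) {
      as.integer(strsplit(block$haplotype, "")[[1]])
    } else {
      rep(1L, length(block$idx))
    }
    stopifnot(length(block$hap) == length(block$idx))
  }
  hap <- matrix(NA_integer_, 2L * sum(n_per_pop), n_snps)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    n_hap <- 2L * n_per_pop[k]
    src <- sample.int(n_founders, n_hap, replace = TRUE,
                      prob = founder_freqs[, k])
    hk <- founders[src, , drop = FALSE]
    if (!is.null(block) && pop_names[k] %in% block$target_pops) {
      n_carrier <- round(block$freq * n_hap)
      if (abs(n_carrier - block$freq * n_hap) > 1e-9) {
        inform(sprintf(
          "population %s: planted frequency %.3f rounded to %d/%d haplotypes",
          pop_names[k], block$freq, n_carrier, n_hap
        ))
      }
      if (n_carrier > 0L) {
        # spread copies over distinct individuals first (heterozygous
        # carriers), so dominant-coded carrier counts are predictable
        ord <- c(seq(1L, n_hap, 2L), seq(2L, n_hap, 2L))
        carrier_rows <- ord[seq_len(n_carrier)]
        hk[carrier_rows, block$idx] <-
          matrix(block$hap, n_carrier, length(block$idx), byrow = TRUE)
      }
      # keep flanking SNPs polymorphic so the block ends where stated
      for (fl in c(block$start_snp - 1L, block$end_snp + 1L)) {
        if (fl >= 1L && fl <= n_snps) {
          m <- max(1L, ceiling(0.2 * n_hap))
          major <- as.integer(mean(hk[, fl]) >= 0.5)
          flip <- tail(seq_len(n_hap), m)
          hk[flip, fl] <- 1L - major
        }
      }
    }
    hap[row0 + seq_len(n_hap), ] <- hk
    row0 <- row0 + n_hap
  }
  samples <- tibble(
    id = unlist(map(seq_len(n_pops), function(k) {
      sprintf("%s_ind%02d", pop_names[k], seq_len(n_per_pop[k]))
    })),
    population = rep(pop_names, n_per_pop)
  )
  variants <- tibble(
    id = sprintf("rsnp%04d", seq_len(n_snps)), chrom = chrom, pos = pos,
    ref = "A", alt = "G"
  )
  dosages <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
    hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  geno_dataset(variants, samples, dosages, hap)
}

#' Plant runs of homozygosity into a phased dataset
#'
#' Within each tract the individual's second haplotype is overwritten by the
#' first, producing full homozygosity there; everything outside the tracts
#' is untouched. Overlapping tracts for one sample are merged (with a
#' message).
#'
#' @param ds A phased [geno_dataset()].
#' @param tracts Tibble with `sample`, `chrom`, `start_bp`, `end_bp`.
#' @return A new phased `geno_dataset`.
#' @export
plant_roh <- function(ds, tracts) {
  if (!ds$phased) abort("plant_roh needs a phased dataset")
  merged <- tracts %>%
    arrange(.data$sample, .data$chrom, .data$start_bp) %>%
    group_by(.data$sample, .data$chrom) %>%
    mutate(grp = cumsum(c(TRUE, .data$start_bp[-1] >
                            cummax(.data$end_bp[-dplyr::n()])))) %>%
    group_by(.data$sample, .data$chrom, .data$grp) %>%
    summarise(start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
              .groups = "drop")
  if (nrow(merged) < nrow(tracts)) {
    inform(sprintf("merged %d overlapping tracts", nrow(tracts) - nrow(merged)))
  }
  hap <- ds$haplotypes
  for (r in seq_len(nrow(merged))) {
    s <- match(merged$sample[r], ds$samples$id)
    if (is.na(s)) abort(paste0("unknown sample in tracts: ", merged$sample[r]))
    idx <- region_variant_idx(ds, merged$chrom[r], merged$start_bp[r],
                              merged$end_bp[r])
    hap[2L * s, idx] <- hap[2L * s - 1L, idx]
  }
  dosages <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
    hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  geno_dataset(ds$variants, ds$samples, dosages, hap)
}

#' Simulate a quantitative trait with an additive haplotype-carrier effect
#'
#' `y = mu + beta * carrier + Normal(0, residual_sd)` with dominant carrier
#' coding for a reference haplotype over a region (see
#' [haplotype_carriers()]). Defaults emulate a hemoglobin-like blood trait
#' (baseline 138 g/L, residual sd 14.5 g/L).
#'
#' @param ds A phased [geno_dataset()].
#' @param chrom,start_bp,end_bp,reference_hap Region and reference haplotype.
#' @param beta Carrier effect in trait units.
#' @param residual_sd Residual standard deviation (default 14.5).
#' @param mu Baseline mean (default 138).
#' @param seed Integer seed (mandatory).
#' @return Tibble `sample_id`, `population`, `carrier`, `trait`.
#' @export
simulate_trait <- function(ds, chrom, start_bp, end_bp, reference_hap,
                           beta, residual_sd = 14.5, mu = 138, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  carriers <- haplotype_carriers(ds, chrom, start_bp, end_bp, reference_hap)
  withr_seed(seed)
  carriers %>%
    mutate(trait = mu + beta * as.numeric(.data$carrier) +
             rnorm(dplyr::n(), 0, residual_sd))
}

#' Write the planted-signal truth of a simulation as JSON
#' @param truth Named list describing planted signals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
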