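#' Read genotypes plus a population map
#'
#' Reads diploid biallelic SNP genotypes from a VCF (plain or gzipped, via
#' vcfR) or a PLINK-text PED/MAP pair, attaches population labels from a
#' tab-separated popmap, and returns a [geno_dataset()]. The dataset is
#' flagged phased only when every genotype separator in the file is `|`.
#'
#' @param path Path to the VCF, or to either member of a PED/MAP pair.
#' @param popmap_path Path to a TSV with header columns `sample_id`,
#'   `population` and optionally `ecotype`. Every genotyped sample must
#'   appear; unknown samples are an error.
#' @param format `"vcf"` or `"plink_text"`.
#' @param split_multiallelic Split multiallelic VCF records into biallelic
#'   ones instead of rejecting them.
#' @param dedup Keep the first of several variants sharing a (chrom, pos)
#'   coordinate instead of erroring.
#' @return A [geno_dataset()] with variants sorted by (chrom, pos).
#' @export
read_genotypes <- function(path, popmap_path,
                           format = c("vcf", "plink_text"),
                           split_multiallelic = FALSE, dedup = FALSE) {
  format <- arg_match(format)
  popmap <- read_popmap(popmap_path)
  parsed <- switch(format,
    vcf = parse_vcf(path, split_multiallelic),
    plink_text = parse_plink_text(path)
  )
  missing_ids <- setdiff(parsed$samples, popmap$sample_id)
  if (length(missing_ids)) {
    abort(paste0(
      "samples absent from popmap: ", paste(missing_ids, collapse = ", ")
    ))
  }
  pm <- popmap[match(parsed$samples, popmap$sample_id), ]
  samples <- tibble(
    id = parsed$samples, population = pm$population,
    ecotype = if ("ecotype" %in% names(pm)) pm$ecotype else NA_character_
  )
  v <- parsed$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, ]
  dos <- parsed$dosages[, ord, drop = FALSE]
  hap <- if (!is.null(parsed$haplotypes)) {
    parsed$haplotypes[, ord, drop = FALSE]
  }
  # split multiallelic records legitimately share a coordinate (they differ
  # in alt allele); everything else at a seen coordinate is a duplicate
  from_split <- if ("from_split" %in% names(v)) v$from_split else rep(FALSE, nrow(v))
  v <- v[setdiff(names(v), "from_split")]
  dup <- duplicated(v[, c("chrom", "pos")]) & !from_split
  if (any(dup)) {
    if (!dedup) {
      abort(sprintf(
        "%d duplicate variant coordinates (e.g. %s:%d); use dedup = TRUE",
        sum(dup), v$chrom[dup][1], v$pos[dup][1]
      ))
    }
    inform(sprintf("dedup: dropping %d duplicate-position variants", sum(dup)))
    v <- v[!dup, ]
    dos <- dos[, !dup, drop = FALSE]
    if (!is.null(hap)) hap <- hap[, !dup, drop = FALSE]
  }
  geno_dataset(v, samples, dos, hap)
}

#' Read a sample-to-population map
#' @param path TSV with header columns `sample_id`, `population`
#'   and optionally `ecotype`.
#' @return Tibble.
#' @export
read_popmap <- function(path) {
  pm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "population") %in% names(pm))) {
    abort("popmap needs header columns sample_id, population")
  }
  pm
}

parse_vcf <- function(path, split_multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  multi <- grepl(",", fix$ALT)
  if (any(multi) && !split_multiallelic) {
    abort(sprintf(
      "%d multiallelic records (e.g. %s:%s); use split_multiallelic = TRUE",
      sum(multi), fix$CHROM[multi][1], fix$POS[multi][1]
    ))
  }
  sep <- regmatches(gt, regexpr("[/|]", gt))
  phased <- length(sep) > 0 && all(sep == "|")
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", gt)
  a1[a1 %in% c(".", "")] <- NA
  a2[a2 %in% c(".", "") | a2 == gt] <- NA  # haploid/missing entries
  a1 <- matrix(suppressWarnings(as.integer(a1)), nrow = nrow(gt))
  a2 <- matrix(suppressWarnings(as.integer(a2)), nrow = nrow(gt))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(
    fix$CHROM[is.na(ids) | ids == "."], "_", fix$POS[is.na(ids) | ids == "."]
  )
  rec <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      h1 <- ifelse(is.na(a1[i, ]), NA_integer_, as.integer(a1[i, ] == k))
      h2 <- ifelse(is.na(a2[i, ]), NA_integer_, as.integer(a2[i, ] == k))
      rec[[length(rec) + 1L]] <- list(
        id = if (length(alts) > 1L) paste0(ids[i], "_alt", k) else ids[i],
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], h1 = h1, h2 = h2,
        from_split = length(alts) > 1L && k > 1L
      )
    }
  }
  variants <- tibble(
    id = map_chr(rec, "id"), chrom = map_chr(rec, "chrom"),
    pos = map_int(rec, "pos"), ref = map_chr(rec, "ref"),
    alt = map_chr(rec, "alt"), from_split = map_lgl(rec, "from_split")
  )
  h1 <- t(vapply(rec, function(r) r$h1, integer(length(samples))))
  h2 <- t(vapply(rec, function(r) r$h2, integer(length(samples))))
  if (length(samples) == 1L) {
    h1 <- matrix(unlist(map(rec, "h1")), ncol = 1L)
    h2 <- matrix(unlist(map(rec, "h2")), ncol = 1L)
  }
  dosages <- t(h1 + h2)  # samples x variants after transpose
  haplotypes <- NULL
  if (phased) {
    haplotypes <- matrix(NA_integer_, 2L * length(samples), nrow(variants))
    haplotypes[seq(1L, nrow(haplotypes), 2L), ] <- t(h1)
    haplotypes[seq(2L, nrow(haplotypes), 2L), ] <- t(h2)
  }
  list(
    variants = variants, samples = samples,
    dosages = dosages, haplotypes = haplotypes
  )
}

# PLINK text: .ped (fam id pat mat sex pheno + 2 allele columns per SNP) and
# .map (chrom id cM pos). Alleles are recoded with the alphabetically first
# observed allele as ref; 0 means missing.
parse_plink_text <- function(path) {
  base <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(base, ".ped")
  map_path <- paste0(base, ".map")
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  n_snps <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snps) {
    abort("PED column count does not match 2 alleles per MAP variant")
  }
  samples <- ped[[2L]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  al[al == "0"] <- NA
  dosages <- matrix(NA_integer_, nrow(ped), n_snps)
  ref <- alt <- character(n_snps)
  for (j in seq_len(n_snps)) {
    pair <- al[, c(2L * j - 1L, 2L * j), drop = FALSE]
    obs <- sort(unique(stats::na.omit(as.vector(pair))))
    if (length(obs) > 2L) {
      abort(sprintf("variant %s has >2 alleles in PED", map$id[j]))
    }
    ref[j] <- obs[1]
    alt[j] <- if (length(obs) == 2L) obs[2] else "N"
    d <- (pair[, 1L] == alt[j]) + (pair[, 2L] == alt[j])
    dosages[, j] <- as.integer(d)
  }
  variants <- tibble(
    id = map$id, chrom = map$chrom, pos = map$pos, ref = ref, alt = alt
  )
  list(
    variants = variants, samples = samples,
    dosages = dosages, haplotypes = NULL
  )
}

#' Write a genotype dataset as VCF (+ optional popmap)
#'
#' Emits a minimal VCF 4.2 with GT fields; phased datasets use `|`
#' separators so the phase bit round-trips through [read_genotypes()].
#'
#' @param ds A [geno_dataset()].
#' @param path Output VCF path (plain text).
#' @param popmap_path Optional path for a companion popmap TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, popmap_path = NULL) {
  v <- ds$variants
  sep <- if (ds$phased) "|" else "/"
  if (ds$phased) {
    h1 <- ds$haplotypes[seq(1L, 2L * n_samples(ds), 2L), , drop = FALSE]
    h2 <- ds$haplotypes[seq(2L, 2L * n_samples(ds), 2L), , drop = FALSE]
    g1 <- ifelse(is.na(h1), ".", h1)
    g2 <- ifelse(is.na(h2), ".", h2)
  } else {
    d <- ds$dosages
    g1 <- ifelse(is.na(d), ".", ifelse(d >= 1L, "1", "0"))
    g2 <- ifelse(is.na(d), ".", ifelse(d == 2L, "1", "0"))
  }
  gt <- matrix(paste0(g1, sep, g2), nrow = n_samples(ds))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples$id), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  if (!is.null(popmap_path)) {
    readr::write_tsv(
      tibble(sample_id = ds$samples$id, population = ds$samples$population,
             ecotype = ds$samples$ecotype),
      popmap_path, progress = FALSE
    )
  }
  invisible(path)
}

#' Read a quantitative-trait table
#' @param path TSV with a `sample_id` column plus one column per trait.
#' @return Tibble.
#' @export
read_trait_table <- function(path) {
  tt <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tt)) abort("trait table needs a sample_id column")
  tt
}

#' Read gene annotation from GFF3 or BED
#'
#' BED half-open 0-based intervals are converted to the package's 1-based
#' inclusive convention on read. Requires the rtracklayer package.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @return Tibble with columns `gene_id`, `name`, `chrom`, `start_bp`,
#'   `end_bp`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gene_annotation requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  pick <- function(cols, fallback) {
    for (cl in cols) if (cl %in% names(md)) return(as.character(md[[cl]]))
    fallback
  }
  ids <- pick(c("gene_id", "ID", "Name", "name"),
              paste0("gene", seq_along(gr)))
  tibble(
    gene_id = ids,
    name = pick(c("Name", "name", "gene_name"), ids),
    chrom = as.character(md$seqnames),
    start_bp = as.integer(md$start),
    end_bp = as.integer(md$end),
    strand = as.character(md$strand)
  )
}
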