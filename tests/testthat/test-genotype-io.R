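test_that("a minimal unphased VCF parses with correct dosages and phase flag", {
  vcf <- write_mini_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    samples = c("s1", "s2"),
    records = list(
      list(chrom = "chr1", pos = 100, id = "a", ref = "A", alt = "G",
           gt = c("0/1", "1/1")),
      list(chrom = "chr1", pos = 200, id = "b", ref = "C", alt = "T",
           gt = c("0/0", "0/1")),
      list(chrom = "chr1", pos = 300, id = "c", ref = "G", alt = "A",
           gt = c("./.", "0/0"))
    )
  )
  pm <- write_popmap(withr::local_tempfile(fileext = ".tsv"),
                     c("s1", "s2"), c("p1", "p2"))
  ds <- read_genotypes(vcf, pm, format = "vcf")
  expect_false(ds$phased)
  expect_equal(unname(ds$dosages),
               matrix(c(1L, 2L, 0L, 1L, NA, 0L), nrow = 2))
  expect_equal(ds$variants$pos, c(100L, 200L, 300L))
  expect_equal(ds$samples$population, c("p1", "p2"))
})

test_that("pipe separators set the phase flag and populate haplotypes", {
  vcf <- write_mini_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    samples = c("s1", "s2"),
    records = list(
      list(chrom = "chr1", pos = 100, id = "a", ref = "A", alt = "G",
           gt = c("0/1", "1/0"))
    ),
    phased = TRUE
  )
  pm <- write_popmap(withr::local_tempfile(fileext = ".tsv"),
                     c("s1", "s2"), c("p1", "p1"))
  ds <- read_genotypes(vcf, pm, format = "vcf")
  expect_true(ds$phased)
  expect_equal(unname(ds$haplotypes[, 1]), c(0L, 1L, 1L, 0L))
  expect_equal(unname(ds$dosages[, 1]), c(1L, 1L))
})

test_that("a VCF sample missing from the popmap raises an error naming it", {
  vcf <- write_mini_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    samples = c("s1", "s_orphan"),
    records = list(list(chrom = "chr1", pos = 100, id = "a", ref = "A",
                        alt = "G", gt = c("0/1", "0/0")))
  )
  pm <- write_popmap(withr::local_tempfile(fileext = ".tsv"), "s1", "p1")
  expect_error(read_genotypes(vcf, pm, format = "vcf"), "s_orphan")
})

test_that("multiallelic records are rejected by default and split on request", {
  vcf <- write_mini_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    samples = c("s1", "s2"),
    records = list(
      list(chrom = "chr1", pos = 100, id = "m", ref = "A", alt = "G,T",
           gt = c("1/2", "0/1"))
    )
  )
  pm <- write_popmap(withr::local_tempfile(fileext = ".tsv"),
                     c("s1", "s2"), c("p1", "p1"))
  expect_error(read_genotypes(vcf, pm, format = "vcf"), "multiallelic")
  ds <- read_genotypes(vcf, pm, format = "vcf", split_multiallelic = TRUE)
  expect_equal(n_variants(ds), 2L)
  expect_equal(unname(ds$dosages[, 1]), c(1L, 1L))  # allele G
  expect_equal(unname(ds$dosages[, 2]), c(1L, 0L))  # allele T
})

test_that("duplicate coordinates error unless dedup keeps the first record", {
  vcf <- write_mini_vcf(
    withr::local_tempfile(fileext = ".vcf"),
    samples = "s1",
    records = list(
      list(chrom = "chr1", pos = 100, id = "a", ref = "A", alt = "G",
           gt = "0/1"),
      list(chrom = "chr1", pos = 100, id = "b", ref = "A", alt = "T",
           gt = "1/1")
    )
  )
  pm <- write_popmap(withr::local_tempfile(fileext = ".tsv"), "s1", "p1")
  expect_error(read_genotypes(vcf, pm, format = "vcf"), "duplicate")
  expect_message(
    ds <- read_genotypes(vcf, pm, format = "vcf", dedup = TRUE),
    "dedup"
  )
  expect_equal(ds$variants$id, "a")
})

test_that("write/read round-trip preserves dosages, coordinates and phase", {
  for (phased in c(FALSE, TRUE)) {
    ds <- simulate_populations(2, 6, 40, 0.1, seed = 5, mode = "independent",
                               phased = phased)
    if (!phased) {  # punch a missing value in to exercise the NA path
      d <- ds$dosages; d[1, 1] <- NA
      ds <- geno_dataset(ds$variants, ds$samples, d)
    }
    vcf <- withr::local_tempfile(fileext = ".vcf")
    pm <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(ds, vcf, pm)
    back <- read_genotypes(vcf, pm, format = "vcf")
    expect_equal(back$phased, phased)
    expect_equal(unname(back$dosages), unname(ds$dosages))
    expect_equal(back$variants$pos, ds$variants$pos)
    expect_equal(back$variants$chrom, ds$variants$chrom)
    if (phased) {
      expect_equal(unname(back$haplotypes), unname(ds$haplotypes))
    }
  }
})

test_that("PLINK-text PED/MAP reads to the same dosages as the matching VCF", {
  base <- withr::local_tempfile()
  # 3 samples x 2 SNPs; alleles recoded with alphabetical ref
  writeLines(c(
    "chr1\tsnpA\t0\t500",
    "chr1\tsnpB\t0\t900"
  ), paste0(base, ".map"))
  writeLines(c(
    "f1 s1 0 0 0 -9 A G C C",
    "f1 s2 0 0 0 -9 G G C T",
    "f1 s3 0 0 0 -9 0 0 T T"
  ), paste0(base, ".ped"))
  pm <- write_popmap(withr::local_tempfile(fileext = ".tsv"),
                     c("s1", "s2", "s3"), rep("p1", 3))
  ds <- read_genotypes(paste0(base, ".ped"), pm, format = "plink_text")
  expect_false(ds$phased)
  # snpA: ref A, alt G -> dosages 1, 2, NA; snpB: ref C, alt T -> 0, 1, 2
  expect_equal(unname(ds$dosages[, 1]), c(1L, 2L, NA))
  expect_equal(unname(ds$dosages[, 2]), c(0L, 1L, 2L))
})

test_that("region helpers use 1-based inclusive spans", {
  expect_equal(region_span_kb(100173669, 100212129), 38.461)
  expect_equal(region_span_kb(54611837, 54777019), 165.183)
  ds <- make_ds(matrix(0L, 2, 3), pos = c(10L, 20L, 30L))
  expect_equal(region_variant_idx(ds, "chr1", 10, 20), c(1L, 2L))
  expect_equal(region_variant_idx(ds, "chr2", 10, 20), integer(0))
})
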