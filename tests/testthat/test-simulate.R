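test_that("generators are pure functions of their seed", {
  a <- simulate_populations(2, 8, 100, 0.1, seed = 111, mode = "mosaic")
  b <- simulate_populations(2, 8, 100, 0.1, seed = 111, mode = "mosaic")
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$variants, b$variants)
  c_ <- simulate_populations(2, 8, 100, 0.1, seed = 112, mode = "mosaic")
  expect_false(identical(a$dosages, c_$dosages))

  r1 <- simulate_haplotype_region(2, 6, 20, seed = 113)
  r2 <- simulate_haplotype_region(2, 6, 20, seed = 113)
  expect_identical(r1$haplotypes, r2$haplotypes)
})

test_that("degenerate drift parameters are rejected", {
  expect_error(simulate_populations(2, 5, 10, 0, seed = 1), "strictly inside")
  expect_error(simulate_populations(2, 5, 10, 1, seed = 1), "strictly inside")
})

test_that("Balding-Nichols drift is recovered by the ratio-of-sums estimator", {
  ds <- simulate_populations(2, 50, 20000, 0.1, seed = 114,
                             mode = "independent")
  f <- fst_per_snp(ds, population_samples(ds, "pop1"),
                   population_samples(ds, "pop2"))
  expect_lt(abs(f$mean_fst - 0.1) / 0.1, 0.15)
})

test_that("a selected locus overrides the focal population's frequency", {
  ds <- simulate_populations(
    2, 200, 50, 0.05, seed = 115, mode = "independent",
    selected_loci = tibble::tibble(snp = 10L, pop = "pop1", freq = 0.99,
                                   ancestral = 0.2)
  )
  af1 <- allele_frequency(ds, population_samples(ds, "pop1"))$freq[10]
  af2 <- allele_frequency(ds, population_samples(ds, "pop2"))$freq[10]
  expect_gt(af1, 0.95)
  expect_lt(af2, 0.6)
})

test_that("independent mode has no LD structure while mosaic mode decays with distance", {
  ds_ind <- simulate_populations(1, 100, 60, 0.1, seed = 116,
                                 mode = "independent")
  pairs_ind <- compute_ld_pairs(ds_ind, maf_min = 0.1, call_rate_min = 0,
                                max_window_kb = 1e6)
  expect_lt(mean(pairs_ind$r2), 3 / (2 * 100))  # ~ sampling noise only

  ds_mos <- simulate_populations(1, 100, 300, 0.1, seed = 117,
                                 mode = "mosaic", n_founders = 6,
                                 recomb_rate = 2e-6, spacing_bp = 2689)
  pairs_mos <- compute_ld_pairs(ds_mos, maf_min = 0.1, call_rate_min = 0)
  bins <- tapply(pairs_mos$r2,
                 cut(pairs_mos$dist_bp, c(0, 1e5, 3e5, 8e5)), mean)
  expect_true(all(diff(bins) < 0))  # binned mean r2 decreases with distance
})

test_that("planted haplotype blocks are realised at the requested frequency", {
  ds <- simulate_haplotype_region(
    3, 10, 40, seed = 118,
    planted_block = list(start_snp = 5L, end_snp = 30L,
                         target_pops = "pop2", freq = 0.6,
                         haplotype = strrep("10", 13))
  )
  pos <- ds$variants$pos
  tbl <- extract_haplotypes(ds, "chr3", pos[5], pos[30])
  cnt <- tbl$counts$count[tbl$counts$hap == strrep("10", 13) &
                            tbl$counts$population == "pop2"]
  expect_equal(cnt, round(0.6 * 20))
})

test_that("three chain founders reproduce a chain network", {
  founders <- rbind(
    c(0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 0L),
    c(1L, 1L, 0L, 0L)
  )
  ds <- simulate_haplotype_region(1, 30, 4, seed = 119, founders = founders)
  tbl <- extract_haplotypes(ds, "chr3", 1, 1e7)
  net <- haplotype_network(tbl, min_count = 10)
  mst <- net$edges[!net$edges$alternative, ]
  expect_equal(nrow(mst), 2L)
  expect_equal(sort(mst$weight), c(1L, 1L))
  # chain topology: the middle founder joins the two ends
  expect_equal(sum(c(mst$from, mst$to) == "1000"), 2L)
})

test_that("planted ROH tracts are recovered and short tracts are not called", {
  set.seed(120)
  hits <- overlaps <- logical(8)
  for (r in 1:8) {
    ds <- simulate_populations(1, 4, 2400, 0.1, seed = 1200 + r,
                               mode = "independent", phased = TRUE,
                               spacing_bp = 2500)
    tract <- tibble::tibble(sample = ds$samples$id[1], chrom = "chr1",
                            start_bp = 1000000L, end_bp = 2500000L)
    planted <- plant_roh(ds, tract)
    segs <- call_roh(planted)
    mine <- segs[segs$sample == ds$samples$id[1] &
                   segs$end_bp > tract$start_bp &
                   segs$start_bp < tract$end_bp, ]
    hits[r] <- nrow(mine) >= 1
    if (hits[r]) {
      ov <- min(mine$end_bp, tract$end_bp) - max(mine$start_bp, tract$start_bp)
      overlaps[r] <- ov >= 0.95 * (tract$end_bp - tract$start_bp)
    }
  }
  expect_true(all(hits))
  expect_gte(sum(overlaps), 7)

  # a 300-kb tract stays below the 500-kb minimum
  ds <- simulate_populations(1, 2, 2000, 0.1, seed = 121,
                             mode = "independent", phased = TRUE,
                             spacing_bp = 1000)
  short <- plant_roh(ds, tibble::tibble(sample = ds$samples$id[1],
                                        chrom = "chr1",
                                        start_bp = 500000L,
                                        end_bp = 800000L))
  segs <- call_roh(short)
  expect_equal(nrow(segs[segs$sample == ds$samples$id[1], ]), 0L)

  # no tracts + high heterozygosity -> no segments at all
  expect_equal(nrow(call_roh(ds)), 0L)
})

test_that("overlapping tracts are merged with a message", {
  ds <- simulate_populations(1, 2, 500, 0.1, seed = 122,
                             mode = "independent", phased = TRUE)
  tr <- tibble::tibble(sample = rep(ds$samples$id[1], 2), chrom = "chr1",
                       start_bp = c(1L, 50000L), end_bp = c(100000L, 200000L))
  expect_message(out <- plant_roh(ds, tr), "merged")
  idx <- region_variant_idx(out, "chr1", 1, 200000)
  g <- out$dosages[1, idx]
  expect_true(all(g != 1L, na.rm = TRUE))  # fully homozygous inside the union
})

test_that("simulated traits have the planted carrier architecture", {
  ds <- simulate_haplotype_region(
    1, 54, 14, seed = 123,
    planted_block = list(start_snp = 1L, end_snp = 14L,
                         target_pops = "pop1", freq = 0.3)
  )
  ref <- strrep("1", 14)
  pos <- ds$variants$pos
  tt <- simulate_trait(ds, "chr3", pos[1], pos[14], ref,
                       beta = 9.6, seed = 124)
  t2 <- simulate_trait(ds, "chr3", pos[1], pos[14], ref,
                       beta = 9.6, seed = 124)
  expect_identical(tt$trait, t2$trait)
  expect_true(any(tt$carrier) && any(!tt$carrier))

  # null effect: mean-test p-values are uniform (KS not rejected at 0.01)
  pvals <- vapply(1:200, function(r) {
    y <- simulate_trait(ds, "chr3", pos[1], pos[14], ref,
                        beta = 0, seed = 10000 + r)
    carrier_association(y$carrier, y$trait)$t_p
  }, double(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
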