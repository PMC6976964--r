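test_that("haplotype extraction counts distinct strings and conserves totals", {
  hap <- rbind(c(0L, 0L),  # s1 h1 -> "00"
               c(0L, 0L),  # s1 h2 -> "00"
               c(0L, 1L),  # s2 h1 -> "01"
               c(1L, 1L))  # s2 h2 -> "11"
  ds <- make_phased_ds(hap, populations = c("p1", "p2"))
  tbl <- extract_haplotypes(ds, "chr1", 1000, 2000)
  expect_equal(nrow(tbl$totals), 3L)
  expect_equal(tbl$totals$total[tbl$totals$hap == "00"], 2L)
  expect_equal(sort(tbl$totals$total), c(1L, 1L, 2L))
  expect_equal(sum(tbl$counts$count) + tbl$n_dropped, 4L)
})

test_that("haplotypes with missing alleles are dropped and counted", {
  hap <- rbind(c(0L, 0L), c(0L, NA), c(1L, 1L), c(1L, 1L))
  ds <- make_phased_ds(hap, populations = c("p1", "p1"))
  tbl <- extract_haplotypes(ds, "chr1", 1000, 2000)
  expect_equal(tbl$n_dropped, 1L)
  expect_equal(sum(tbl$counts$count), 3L)
})

test_that("unphased input is rejected with phasing advice", {
  ds <- make_ds(matrix(0L, 2, 2))
  expect_error(extract_haplotypes(ds, "chr1", 1000, 2000), "phase")
})

test_that("region haplotype counts match a string-tally oracle on a fixture", {
  set.seed(91)
  hap <- matrix(rbinom(20 * 6, 1, 0.5), nrow = 20)
  pops <- rep(c("p1", "p2"), each = 5)
  ds <- make_phased_ds(hap, populations = pops)
  tbl <- extract_haplotypes(ds, "chr1", 1000, 6000)
  strings <- apply(hap, 1, paste, collapse = "")
  oracle <- table(strings, rep(pops, each = 2))
  for (k in seq_len(nrow(tbl$counts))) {
    expect_equal(tbl$counts$count[k],
                 unname(oracle[tbl$counts$hap[k], tbl$counts$population[k]]))
  }
  expect_equal(nrow(tbl$totals), length(unique(strings)))
})

test_that("the MST network links single-step neighbours and filters strictly", {
  counts <- tibble::tibble(
    hap = c("00", "01", "11"), population = "p1", count = c(20L, 20L, 20L)
  )
  tbl <- structure(list(
    region = list(chrom = "chr1", start_bp = 1, end_bp = 2, span_kb = 0.002),
    snps = tibble::tibble(id = c("a", "b"), chrom = "chr1", pos = 1:2,
                          ref = "A", alt = "G"),
    counts = counts,
    totals = dplyr::summarise(dplyr::group_by(counts, hap),
                              total = sum(count), .groups = "drop"),
    n_dropped = 0L
  ), class = "hap_table")
  net <- haplotype_network(tbl, min_count = 10)
  mst <- net$edges[!net$edges$alternative, ]
  expect_equal(nrow(mst), 2L)
  expect_setequal(paste(mst$from, mst$to), c("00 01", "01 11"))
  expect_equal(mst$weight, c(1L, 1L))

  # a haplotype with count exactly min_count is excluded (strict >)
  tbl$counts$count <- c(20L, 10L, 20L)
  tbl$totals$total <- c(20L, 10L, 20L)
  net2 <- haplotype_network(tbl, min_count = 10)
  expect_setequal(net2$nodes$hap, c("00", "11"))
})

test_that("the MST weight equals the independent igraph minimum", {
  skip_if_not_installed("igraph")
  set.seed(92)
  for (r in 1:5) {
    haps <- unique(apply(matrix(rbinom(8 * 10, 1, 0.5), 8), 1,
                         paste, collapse = ""))
    if (length(haps) < 3) next
    counts <- tibble::tibble(hap = haps, population = "p1", count = 20L)
    tbl <- structure(list(
      region = list(chrom = "c", start_bp = 1, end_bp = 10, span_kb = 0.01),
      snps = NULL, counts = counts,
      totals = tibble::tibble(hap = haps, total = 20L), n_dropped = 0L
    ), class = "hap_table")
    net <- haplotype_network(tbl, min_count = 10)
    got <- sum(net$edges$weight[!net$edges$alternative])

    n <- length(haps)
    w <- outer(haps, haps, Vectorize(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }))
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    want <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(got, want)
  }
})

test_that("shared fixed blocks: planted block, strictness, and degenerate bounds", {
  # 3 populations x 10 diploids, 30 SNPs; block at SNPs 11..20 fixed to 1
  # in p1 and p2 only
  set.seed(93)
  ds <- simulate_haplotype_region(
    3, 10, 30, seed = 94,
    planted_block = list(start_snp = 11L, end_snp = 20L,
                         target_pops = c("pop1", "pop2"), freq = 1)
  )
  blocks <- shared_fixed_blocks(ds, "chr3", 1, 1e7, c("pop1", "pop2"),
                                fixation_min = 0.95)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$snp_start_index, 11L)
  expect_equal(blocks$snp_end_index, 20L)
  expect_equal(blocks$n_snps, 10L)
  expect_equal(blocks$allele_string, strrep("1", 10))
  expect_equal(blocks$min_freq, 1)

  # fixation_min above the realised frequency: block vanishes
  half <- simulate_haplotype_region(
    3, 10, 30, seed = 95,
    planted_block = list(start_snp = 11L, end_snp = 20L,
                         target_pops = c("pop1", "pop2"), freq = 0.5)
  )
  none <- shared_fixed_blocks(half, "chr3", 1, 1e7, c("pop1", "pop2"),
                              fixation_min = 0.95)
  expect_true(all(none$n_snps < 10) || nrow(none) == 0)

  # fixation_min = 0 spans the whole region in one block
  all_block <- shared_fixed_blocks(ds, "chr3", 1, 1e7, c("pop1", "pop2"),
                                   fixation_min = 0)
  expect_equal(nrow(all_block), 1L)
  expect_equal(all_block$n_snps, 30L)

  # one discordant haplotype at fixation_min = 1 splits the run
  hap <- ds$haplotypes
  col <- 15L
  pop1_rows <- which(rep(ds$samples$population, each = 2) == "pop1")
  hap[pop1_rows[1], col] <- 1L - hap[pop1_rows[1], col]
  ds_split <- geno_dataset(ds$variants, ds$samples,
                           hap[seq(1, nrow(hap), 2), ] +
                             hap[seq(2, nrow(hap), 2), ], hap)
  split_blocks <- shared_fixed_blocks(ds_split, "chr3", 1, 1e7,
                                      c("pop1", "pop2"), fixation_min = 1)
  expect_true(all(split_blocks$snp_end_index != 20 |
                    split_blocks$snp_start_index > 15) ||
                nrow(split_blocks) >= 2)
  expect_false(any(split_blocks$snp_start_index <= 15 &
                     split_blocks$snp_end_index >= 15))

  expect_error(shared_fixed_blocks(ds, "chr3", 1, 1e7, character(0)),
               "non-empty")
})

test_that("the sharing matrix is column-normalised with NA for empty populations", {
  hap <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 1L))
  ds <- make_phased_ds(hap, populations = c("p1", "p2"))
  tbl <- extract_haplotypes(ds, "chr1", 1000, 2000)
  m <- haplotype_sharing_matrix(tbl)
  expect_equal(colSums(m), c(p1 = 1, p2 = 1))
  expect_equal(m["00", "p1"], 1)
  expect_warning(
    m2 <- haplotype_sharing_matrix(tbl, populations = c("p1", "p2", "p3")),
    "p3"
  )
  expect_true(all(is.na(m2[, "p3"])))
})

test_that("tag-SNP selection distinguishes haplotypes greedily and verifiably", {
  mk_tbl <- function(haps) {
    L <- nchar(haps[1])
    structure(list(
      region = list(chrom = "c", start_bp = 1, end_bp = L, span_kb = L / 1000),
      snps = tibble::tibble(id = paste0("s", 1:L), chrom = "c",
                            pos = 1:L * 100L, ref = "A", alt = "G"),
      counts = tibble::tibble(hap = haps, population = "p", count = 2L),
      totals = tibble::tibble(hap = haps, total = 2L),
      n_dropped = 0L
    ), class = "hap_table")
  }
  one <- tag_snp_reduction(mk_tbl(c("000", "010")))
  expect_equal(nrow(one$snps), 1L)
  expect_equal(one$snps$id, "s2")
  expect_equal(one$residual_ambiguous_pairs, 0L)

  two <- tag_snp_reduction(mk_tbl(c("00", "01", "10", "11")))
  expect_equal(sort(two$snps$id), c("s1", "s2"))
  expect_equal(two$residual_ambiguous_pairs, 0L)

  set.seed(96)
  haps <- unique(apply(matrix(rbinom(10 * 12, 1, 0.5), 10), 1,
                       paste, collapse = ""))
  res <- tag_snp_reduction(mk_tbl(haps))
  idx <- match(res$snps$id, paste0("s", 1:12))
  short <- substring(
    vapply(haps, function(h) paste(strsplit(h, "")[[1]][idx], collapse = ""),
           character(1)), 1
  )
  expect_equal(anyDuplicated(short), 0L)  # chosen set distinguishes all pairs
  expect_equal(res$residual_ambiguous_pairs, 0L)
})
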