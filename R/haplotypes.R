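#' Extract region haplotypes from phased genotypes
#'
#' Restricts the phased haplotype matrix to the SNPs of a 1-based inclusive
#' region, encodes each haplotype as a 0/1 allele string, drops haplotypes
#' containing missing alleles (their number is recorded), and tallies
#' haplotype counts per population.
#'
#' @param ds A phased [geno_dataset()].
#' @param chrom,start_bp,end_bp Region (must contain >= 1 SNP).
#' @return Object of class `hap_table`: `region` (chrom/start/end/span_kb),
#'   `snps` (variant tibble), `counts` (tibble `hap`, `population`, `count`),
#'   `totals` (tibble `hap`, `total`), `n_dropped` haplotypes with missing
#'   alleles.
#' @export
extract_haplotypes <- function(ds, chrom, start_bp, end_bp) {
  if (!ds$phased) {
    abort("dataset is unphased; phase it externally (or simulate phased data)")
  }
  idx <- region_variant_idx(ds, chrom, start_bp, end_bp)
  if (!length(idx)) abort("region contains no SNPs")
  h <- ds$haplotypes[, idx, drop = FALSE]
  pops <- rep(ds$samples$population, each = 2L)
  complete <- !apply(is.na(h), 1L, any)
  strings <- apply(h[complete, , drop = FALSE], 1L, paste, collapse = "")
  counts <- tibble(hap = strings, population = pops[complete]) %>%
    dplyr::count(.data$hap, .data$population, name = "count")
  totals <- counts %>%
    group_by(.data$hap) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total), .data$hap)
  out <- structure(
    list(
      region = list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                    span_kb = region_span_kb(start_bp, end_bp)),
      snps = ds$variants[idx, , drop = FALSE],
      counts = counts, totals = totals,
      n_dropped = sum(!complete)
    ),
    class = "hap_table"
  )
  stopifnot(sum(counts$count) + out$n_dropped == nrow(h))
  out
}

#' @exportS3Method base::print
print.hap_table <- function(x, ...) {
  cat(sprintf(
    "<hap_table> %s:%d-%d (%.2f kb), %d SNPs, %d distinct haplotypes (%d dropped for missingness)\n",
    x$region$chrom, x$region$start_bp, x$region$end_bp, x$region$span_kb,
    nrow(x$snps), nrow(x$totals), x$n_dropped
  ))
  invisible(x)
}

#' @export
tidy.hap_table <- function(x, ...) x$counts

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Haplotype network as a deterministic minimum spanning tree
#'
#' Keeps haplotypes with total count strictly greater than `min_count`, then
#' builds a Kruskal minimum spanning tree on the complete graph weighted by
#' Hamming distance. Edges are considered in (weight, lexicographic endpoint
#' pair) order, making the tree deterministic; rejected edges whose weight
#' equals that of an accepted edge joining the same two components are kept
#' as `alternative` annotations.
#'
#' @param tbl A [extract_haplotypes()] table.
#' @param min_count Frequency filter; survivors have `total > min_count`
#'   (default 10, i.e. count >= 11).
#' @return Object of class `hap_network`: `nodes` (tibble `hap`, `total`),
#'   `edges` (tibble `from`, `to`, `weight`, `alternative`), `counts`
#'   (per-population breakdown of surviving haplotypes).
#' @export
haplotype_network <- function(tbl, min_count = 10) {
  keep <- tbl$totals %>% filter(.data$total > min_count)
  if (nrow(keep) < 2L) {
    abort("fewer than 2 haplotypes survive the frequency filter")
  }
  haps <- sort(keep$hap)
  n <- length(haps)
  cand <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) %>%
    filter(.data$i < .data$j) %>%
    mutate(
      from = haps[.data$i], to = haps[.data$j],
      weight = map2_int_local(.data$from, .data$to)
    ) %>%
    arrange(.data$weight, .data$from, .data$to)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  chosen <- logical(nrow(cand))
  comp_at_choice <- list()
  for (e in seq_len(nrow(cand))) {
    ra <- find(cand$i[e]); rb <- find(cand$j[e])
    if (ra != rb) {
      chosen[e] <- TRUE
      comp_at_choice[[e]] <- c(sort(c(ra, rb)), cand$weight[e])
      parent[ra] <- rb
    }
  }
  # re-run to mark equal-weight alternatives: an unchosen edge is an
  # alternative if, replayed at its sorted position, it would have merged
  # the same components at the same weight as some chosen edge
  parent <- seq_len(n)
  alternative <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    ra <- find(cand$i[e]); rb <- find(cand$j[e])
    if (chosen[e]) {
      parent[ra] <- rb
    } else if (ra != rb) {
      key <- c(sort(c(ra, rb)), cand$weight[e])
      alternative[e] <- any(map_lgl(comp_at_choice[!vapply(
        comp_at_choice, is.null, logical(1))],
        function(k) identical(k, key)))
    }
  }
  edges <- cand %>%
    filter(chosen | alternative) %>%
    mutate(alternative = alternative[chosen | alternative]) %>%
    select("from", "to", "weight", "alternative")
  structure(
    list(
      nodes = keep %>% arrange(dplyr::desc(.data$total), .data$hap),
      edges = edges,
      counts = tbl$counts %>% filter(.data$hap %in% haps)
    ),
    class = "hap_network"
  )
}

map2_int_local <- function(a, b) {
  vapply(seq_along(a), function(k) hamming(a[k], b[k]), integer(1))
}

#' @exportS3Method base::print
print.hap_network <- function(x, ...) {
  cat(sprintf(
    "<hap_network> %d haplotypes, %d MST edges (total weight %d), %d alternative edges\n",
    nrow(x$nodes), sum(!x$edges$alternative),
    sum(x$edges$weight[!x$edges$alternative]), sum(x$edges$alternative)
  ))
  invisible(x)
}

#' @export
tidy.hap_network <- function(x, ...) x$edges

#' Write a haplotype network as edge-list TSV and GraphML
#' @param net A `hap_network`.
#' @param edge_path TSV output path.
#' @param graphml_path Optional GraphML output path.
#' @return `edge_path`, invisibly.
#' @export
write_hap_network <- function(net, edge_path, graphml_path = NULL) {
  readr::write_tsv(net$edges, edge_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    nodes <- net$nodes
    esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "<key id=\"total\" for=\"node\" attr.name=\"total\" attr.type=\"int\"/>",
      "<key id=\"w\" for=\"edge\" attr.name=\"weight\" attr.type=\"int\"/>",
      "<graph edgedefault=\"undirected\">",
      sprintf("<node id=\"%s\"><data key=\"total\">%d</data></node>",
              esc(nodes$hap), nodes$total),
      sprintf("<edge source=\"%s\" target=\"%s\"><data key=\"w\">%d</data></edge>",
              esc(net$edges$from), esc(net$edges$to), net$edges$weight),
      "</graph>", "</graphml>"
    )
    writeLines(lines, graphml_path)
  }
  invisible(edge_path)
}

#' Detect shared (nearly) fixed haplotype blocks across populations
#'
#' For every SNP of a region and every target population, computes the
#' major-allele frequency over called haplotypes. A SNP is block-eligible
#' iff all target populations have frequency at least `fixation_min` for the
#' same allele. Maximal runs of consecutive eligible SNPs are returned; each
#' run is maximal in the sense that extending it by one SNP in either
#' direction breaks the criterion in some target population.
#'
#' @param ds A phased [geno_dataset()].
#' @param chrom,start_bp,end_bp Region to scan.
#' @param target_pops Character vector of population labels (non-empty);
#'   each must contribute >= 4 called haplotypes in the region.
#' @param fixation_min Minimum shared major-allele frequency (default 0.95).
#' @return Tibble with one row per block: `snp_start_index`,
#'   `snp_end_index` (into the region SNP list), `start_bp`, `end_bp`,
#'   `n_snps`, `span_kb`, `allele_string` (shared allele per SNP) and
#'   `min_freq` (the smallest per-SNP, per-population shared-allele
#'   frequency inside the block).
#' @export
shared_fixed_blocks <- function(ds, chrom, start_bp, end_bp, target_pops,
                                fixation_min = 0.95) {
  if (!length(target_pops)) abort("target_pops must be non-empty")
  if (!ds$phased) abort("dataset must be phased")
  idx <- region_variant_idx(ds, chrom, start_bp, end_bp)
  if (!length(idx)) abort("region contains no SNPs")
  pops <- rep(ds$samples$population, each = 2L)
  freq_alt <- sapply(target_pops, function(p) {
    hp <- ds$haplotypes[pops == p, idx, drop = FALSE]
    if (nrow(hp) < 4L) {
      abort(sprintf("population %s has < 4 haplotypes in region", p))
    }
    colMeans(hp, na.rm = TRUE)
  })
  freq_alt <- matrix(freq_alt, nrow = length(idx),
                     dimnames = list(NULL, target_pops))
  ok_alt <- apply(freq_alt >= fixation_min, 1L, all)          # all fixed for 1
  ok_ref <- apply((1 - freq_alt) >= fixation_min, 1L, all)    # all fixed for 0
  eligible <- (ok_alt | ok_ref) & !apply(is.na(freq_alt), 1L, any)
  allele <- ifelse(ok_alt, "1", "0")
  pos <- ds$variants$pos[idx]
  runs <- split(which(eligible),
                cumsum(c(0L, diff(which(eligible)) > 1L))[seq_len(sum(eligible))])
  if (!sum(eligible)) {
    return(tibble(
      snp_start_index = integer(), snp_end_index = integer(),
      start_bp = integer(), end_bp = integer(), n_snps = integer(),
      span_kb = double(), allele_string = character(), min_freq = double()
    ))
  }
  bind_rows(map(unname(runs), function(run) {
    shared <- ifelse(allele[run] == "1", freq_alt[run, , drop = FALSE],
                     1 - freq_alt[run, , drop = FALSE])
    tibble(
      snp_start_index = run[1L], snp_end_index = run[length(run)],
      start_bp = pos[run[1L]], end_bp = pos[run[length(run)]],
      n_snps = length(run),
      span_kb = region_span_kb(pos[run[1L]], pos[run[length(run)]]),
      allele_string = paste(allele[run], collapse = ""),
      min_freq = min(shared)
    )
  }))
}

#' Haplotype-sharing matrix (per-population haplotype frequencies)
#'
#' Column-normalised: within each population the frequencies over called
#' haplotypes sum to 1. Populations without any called haplotype get an NA
#' column and a warning.
#'
#' @param tbl A [extract_haplotypes()] table.
#' @param populations Optional population order; defaults to populations
#'   present in the table.
#' @return Matrix `[haplotype x population]` of frequencies.
#' @export
haplotype_sharing_matrix <- function(tbl, populations = NULL) {
  if (!nrow(tbl$counts)) abort("empty haplotype table")
  if (is.null(populations)) populations <- sort(unique(tbl$counts$population))
  haps <- tbl$totals$hap
  m <- matrix(0, length(haps), length(populations),
              dimnames = list(haps, populations))
  for (k in seq_len(nrow(tbl$counts))) {
    m[tbl$counts$hap[k], tbl$counts$population[k]] <- tbl$counts$count[k]
  }
  sums <- colSums(m)
  empty <- sums == 0
  if (any(empty)) {
    warn(paste0("populations with no called haplotypes: ",
                paste(populations[empty], collapse = ", ")))
  }
  sweep(m, 2L, ifelse(empty, NA_real_, sums), "/")
}

#' Greedy tag-SNP selection distinguishing region haplotypes
#'
#' Greedy set cover over haplotype pairs: repeatedly pick the SNP separating
#' the largest number of still-confounded haplotype pairs (ties broken by
#' smaller position), until all pairs are distinguished or `k` SNPs are
#' chosen.
#'
#' @param tbl A [extract_haplotypes()] table with >= 2 haplotypes.
#' @param k Optional maximum number of tag SNPs (default: unlimited).
#' @return List with `snps` (tibble of chosen SNPs in choice order) and
#'   `residual_ambiguous_pairs` (0 when the set fully distinguishes all
#'   haplotypes).
#' @export
tag_snp_reduction <- function(tbl, k = Inf) {
  haps <- tbl$totals$hap
  if (length(haps) < 2L) abort("need >= 2 haplotypes")
  alle <- do.call(rbind, strsplit(haps, ""))
  pairs <- which(upper.tri(matrix(0, length(haps), length(haps))),
                 arr.ind = TRUE)
  unresolved <- rep(TRUE, nrow(pairs))
  chosen <- integer()
  while (any(unresolved) && length(chosen) < k) {
    gain <- vapply(seq_len(ncol(alle)), function(s) {
      if (s %in% chosen) return(-1L)
      sum(unresolved &
            alle[pairs[, 1L], s] != alle[pairs[, 2L], s])
    }, integer(1))
    if (max(gain) <= 0L) break
    best <- which(gain == max(gain))
    best <- best[which.min(tbl$snps$pos[best])]
    chosen <- c(chosen, best)
    unresolved <- unresolved &
      alle[pairs[, 1L], best] == alle[pairs[, 2L], best]
  }
  list(
    snps = tbl$snps[chosen, , drop = FALSE],
    residual_ambiguous_pairs = sum(unresolved)
  )
}
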