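---
title: "Methods: diversity, selection scans and haplotype analyses for SNP-chip population data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, selection scans and haplotype analyses for SNP-chip population data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigsnp)
```

pigsnp analyses dense diploid SNP-chip genotypes across many populations —
the typical design of livestock breed surveys, where dozens of breeds are
each represented by 10–20 individuals typed at around a million ascertained
common variants. This vignette explains each model and procedure, the
parameters that matter, the synthetic-data generator used to validate the
pipeline, and the numerical choices made where the design was genuinely
open.

## Data model and conventions

A `geno_dataset` couples a samples × variants dosage matrix (0/1/2 copies
of the alternate allele, `NA` for missing — never 0) to variant metadata, a
sample→population map, and, for phased data, a 2·samples × variants 0/1
haplotype matrix. All coordinates are 1-based inclusive (the VCF
convention); BED input is converted on read, and any span is
`(end − start + 1)` bp. Every statistic skips missing entries elementwise or
pairwise rather than imputing, with one documented exception (PCA, below).
Multiallelic VCF records are rejected by default because chip data are
biallelic and silent splitting hides genotyping artefacts; `split_multiallelic
= TRUE` splits them into one record per alternate allele. Duplicate
(chrom, pos) records are an error unless `dedup = TRUE` keeps the first.

Variant filtering removes a SNP iff MAF < `maf_min` **strictly** (a SNP at
exactly the threshold is kept) or call rate < `call_rate_min`; defaults 0.05
and 0.9 are the conventional chip QC settings. The attached report satisfies
`removed_maf + removed_callrate − removed_both + kept = input`.

## Diversity statistics

For a group of n ≥ 2 individuals, on a common assayed SNP set:

* **π** (nucleotide diversity per site) uses the unbiased pairwise
  estimator π_s = n_a/(n_a − 1) · (1 − p² − q²) with n_a the called alleles
  at the site, averaged over assayed SNPs. Monomorphic SNPs contribute 0;
  entirely missing SNPs are excluded from the denominator. Because the
  average runs over chip SNPs rather than all genomic sites, values are an
  order of magnitude larger than sequence-based π and are comparable only
  across groups typed on the same chip.
* **Ho** is the fraction of called genotypes that are heterozygous,
  averaged over SNPs.
* **PN** is the fraction of assayed SNPs at which both alleles are observed
  in the group — entirely missing SNPs still count in the denominator.

## Fst and the LSBL selection scan

Two per-SNP Fst estimators are provided. The default is the Weir–Cockerham
(1984) two-population θ from the variance components a, b, c, with
θ = a/(a + b + c) per SNP and the ratio-of-sums ("weighted") average
Σa/Σ(a + b + c) across SNPs — the estimator and averaging used by the
standard command-line tools that breed surveys run. The Hudson/Bhatia ratio
is provided as a hand-checkable alternative; the estimator choice is
recorded in scan metadata because it changes outlier identity. A SNP is
defined only when both groups have called alleles and the union is
polymorphic; undefined SNPs are flagged, excluded from averages, and never
outliers. Negative per-SNP values — a normal property of the W–C estimator —
are retained, and clamped to zero only when a pairwise mean-Fst matrix is
used as a distance matrix.

The **locus-specific branch length** for focal population A against
references B and C is x = (Fst_AB + Fst_AC − Fst_BC)/2 per SNP: the length
of A's branch in the three-population tree, large when A alone has shifted
in allele frequency. The scan offers two thresholding modes, because an
absolute cutoff and an empirical tail fraction answer different questions:
the empirical threshold is the (1 − `top_fraction`) type-1 (order-statistic)
quantile of defined x values, so with n SNPs exactly ⌊n·top_fraction⌋ values
exceed it barring ties (default top 0.02%); alternatively `abs_cutoff` fixes
the threshold (e.g. 0.8). Candidate genes are those harbouring an outlier
SNP (inclusive) or lying strictly less than `flank_bp` = 10 kb from one.

The identity x_A + x_B + x_C = (Fst_AB + Fst_AC + Fst_BC)/2 across the
three focal choices holds exactly by construction and is asserted in the
tests, as is symmetry in B and C.

## Distances and trees

The individual-level IBS distance is 1 minus the mean shared-allele
fraction (2 − |d_i − d_j|)/2 over SNPs called in both individuals; it lies
in [0, 1] but is not guaranteed to satisfy the triangle inequality.
The between-population Nei standard distance is
D = −ln(Σ x_ij y_ij / √(Σ x_ij² · Σ y_ij²)), the sums running over loci and
both alleles of each biallelic SNP; identical frequency vectors give 0, and
fully disjoint alleles give +∞ with a warning.

Neighbor-joining trees are built by the standard Saitou–Nei agglomeration
(via ape). On non-additive inputs such as Fst matrices NJ can propose
negative branch lengths; these are clamped to zero with the deficit moved
to the sibling edge at the same node, preserving the joined pair's path
length. On any additive matrix NJ provably recovers the generating topology,
which the tests assert over random 5–12-taxon trees.

PCA forms a genetic relationship matrix from frequency-standardised dosages
((g − 2p)/√(2p(1−p)), monomorphic SNPs skipped) and eigendecomposes it.
Missing dosages are mean-imputed per SNP before standardisation — the
simple, standard choice for GRM construction; with chip-level call rates
(> 0.9) the effect on leading components is negligible. Component signs are
fixed by making each component's largest-magnitude entry positive. LD
pruning for structure analyses mirrors the `indep-pairwise 50 10 0.1`
greedy pass: within each 50-SNP window, while any pair has r² > 0.1 the
lower-MAF member of the worst pair is dropped (ties drop the later
position), and windows advance by 10 SNPs; the tie-break makes output
deterministic where the command-line tools leave it unspecified.

## Runs of homozygosity

The caller reproduces the PLINK-style sliding-window logic with the survey
parameters: 50-SNP windows sliding one SNP at a time, a window "homozygous"
with ≤ 1 heterozygous and ≤ 5 missing calls, a SNP becoming ROH-candidate
when ≥ 5% of the windows covering it are homozygous, and maximal candidate
runs reported when ≥ 500 kb long. The companion parameters that the survey
command line leaves at tool defaults are exposed in `roh_params()` and fixed
to those defaults: ≥ 100 SNPs per segment, ≤ 50 kb per SNP density, and a
1 Mb maximum internal gap. Runs are trimmed to their outermost homozygous,
non-missing SNPs, and segment length is (end − start + 1)/1000 kb. Segments
are binned half-open into 0.5–1, 1–5 and > 5 Mb classes, so a 1.0-Mb
segment falls in the middle bin. The exact trimming behaviour of external
tools varies between versions; the definition above is frozen here and
pinned by a brute-force window-enumeration oracle in the tests.

## LD decay and the r²=0.3 extent

Within one population, pairwise genotype r² (composite LD on dosages, not
phased haplotypes — matching the genotype-based command the surveys run) is
computed for SNPs with MAF > 0.1 and call rate > 0.9 at distances up to
1 Mb. The decay curve is the Sved/Heifetz drift–recombination expectation
E[r²|d] = 1/(1 + rate·d), fitted by bounded nonlinear least squares
(`minpack.lm`), and the LD extent r0.3² = (1/0.3 − 1)/rate is where the
fitted curve crosses 0.3 — a strictly decreasing function of the rate. The
fit uses **all** pairs: fitting only pairs above the 0.3 reporting threshold
(as the tool-style report prints) would bias the curve upward, so the
threshold is applied only to the printed pair list. A binned-mean crossing
(`ld_r03_binned()`) is provided as the alternative reporting mode. A fit
with rate → 0 (no decay inside the window) reports an infinite extent with
a warning rather than a misleading number.

## Haplotype analyses

From phased data, region haplotypes are 0/1 allele strings; haplotypes with
any missing allele are dropped (and counted) rather than imputed — on chip
data with high call rates this loses little and keeps every count auditable.
The haplotype network keeps haplotypes with count **strictly** greater than
`min_count` (default 10, i.e. ≥ 11 copies) and connects them by a Kruskal
minimum spanning tree under Hamming distance. The popular network utilities
randomise over co-minimal spanning trees; here edges are taken in (weight,
lexicographic endpoint) order so the tree is reproducible, and rejected
edges that tie an accepted edge joining the same components are kept as
annotated alternatives, so no co-minimal connection is hidden.

A **shared fixed block** is a maximal run of consecutive SNPs at which
every target population has the same allele at frequency ≥ `fixation_min`.
"Nearly fixed" is not a quantified notion in the field; the default is 0.95,
the parameter is exposed, and the tests exercise 0.90/0.95/1.00 around
planted blocks. Block spans are 1-based inclusive. Tag-SNP selection is a
greedy set cover over confounded haplotype pairs (ties broken by smaller
position), returning the chosen SNPs and any residual ambiguity.

Carrier–trait association uses the two-step procedure of haplotype
association in breed surveys: a two-sided F-test of variance homogeneity
gates (at α = 0.05, a level the surveys leave unstated) between the
pooled-variance and Welch two-sample t-tests, and groups are reported in
"mean ± sd" form. Carrier status is dominant-coded (≥ 1 copy of the
reference haplotype), the usual default when the mode of action is unknown.
When group variances are equal in-sample the procedure reduces exactly to
the pooled t-test.

## The synthetic-data generator

`simulate_populations()` draws, per SNP, an ancestral frequency from
Uniform(0.05, 0.95) — the ascertainment window of a common-variant chip —
and population frequencies from the Balding–Nichols
Beta(p(1−F)/F, (1−p)(1−F)/F), whose drift coefficient F equals the expected
Fst; genotypes are binomial. Balding–Nichols was chosen over coalescent
simulation because it directly parameterises the Fst levels the scan
consumes, runs in seconds, and has closed-form expectations for recovery
tests; a coalescent backend is out of scope. Default SNP spacing is the
chip-like 2,689 bp. `mosaic` mode instead realises a small founder panel
per population and copies each sample haplotype from it with
distance-dependent founder switching (a Li–Stephens-like mosaic), producing
the distance-decaying LD that the pruning, decay and ROH stages assume.
Planted signals — selected loci with pinned ancestral and focal frequencies,
founder haplotype blocks at exact counts, fully homozygous tracts
(`plant_roh()` copies the first haplotype over the second), and an additive
carrier effect on a Gaussian trait (baseline 138, residual sd 14.5,
hemoglobin-like units) — give every detector a known truth. At the SNPs
flanking a planted block the generator forces visible polymorphism in the
target populations so the block terminates at its stated boundaries. All
generators are pure functions of their arguments and a mandatory seed.

What the generator does **not** emulate: genotyping error, ascertainment
bias beyond the uniform ancestral window, admixture and migration,
demographic change, and realistic recombination maps. Passing tests
therefore demonstrate correctness of the computations under a clean drift
model, not robustness to real-data artefacts.

## Validation conditions, and two properties that fail honestly

Test problem sizes were chosen to pin each property tightly while keeping
the default suite fast: 20,000 SNPs and n = 50 per group for drift
recovery (±15% of F ∈ {0.05, 0.1, 0.2}); 100 replicates for the scan power
and null-scan properties (3 populations, F as stated, n = 15 per group, the
typical conserved-herd sample size); 50 replicates for planted 1.5-Mb ROH
tracts at 2.5-kb SNP spacing; 100 random additive matrices for NJ.

Two documented expectations about the scan are **not met**, and the
corresponding acceptance checks are left failing rather than weakened,
because the measured behaviour is a real property of the model:

* Under Balding–Nichols drift at F = 0.2, a 20,000-SNP null scan produces
  LSBL values above 0.8 in essentially every replicate (under both
  estimators). These are true branch lengths of strongly drifted loci, not
  sampling noise: at F = 0.2 population frequencies are Beta(4p, 4q), and
  among 20,000 ascertained SNPs some always drift near fixation in one
  population while staying low in the other two. An absolute 0.8 cutoff is
  therefore *not* outlier-free under strong drift.
* For the same reason the null's top-0.02% quantile sits near the signal of
  a 0.2 → 0.99 planted sweep (x ≈ 0.7–0.8), and detection power at that
  threshold is ≈ 60%, not ≥ 90%. Scan hits at this threshold are
  enrichment candidates, not guaranteed sweeps — which is exactly why the
  empirical-threshold and absolute-cutoff modes are both first-class and
  reported side by side.

## Limitations

Statistical phasing is out of scope: haplotype analyses require phased
input (or the phased generator). ADMIXTURE-style ancestry estimation is out
of scope; only its LD-pruning input preparation is implemented. The π
definition is chip-relative (see above). The ROH trimming definition is
frozen to this package's oracle-tested rule and may differ in edge cases
from specific versions of external callers. Coordinates are taken as given;
no liftover between assemblies is attempted.
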