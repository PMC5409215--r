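# slafpop

Population genomics for SLAF-seq studies of amphidiploid crops.

SLAF-seq (specific-locus amplified fragment sequencing) genotypes large
diversity panels by sequencing restriction fragments from a chosen size
window. Studies built on it — typified by *Brassica napus* panels on the
Darmor-bzh reference (10 A + 9 C chromosomes) — share one analysis
backbone, which this package implements end to end for R users:

* **Library design** — in-silico double digestion (`digest_genome()`, RsaI
  GT^AC + HaeIII GG^CC by default), size selection of SLAF tags
  (`select_tags()`, 314–414 bp closed interval), per-chromosome tag
  spacing (`tag_spacing()`) and enzyme-scheme scoring on the four design
  criteria (`evaluate_scheme()`).
* **SNP panel statistics** — MAF/call-rate filtering with strict
  thresholds (`filter_markers()`, MAF > 0.05, integrity > 0.8), mutation
  frequency and SNP hotspots (`call_hotspots()`, frequency > 0.8), SNP
  counts in 100-kb windows (`windowed_snp_counts()`), top-1% SNP-rich
  regions (`snp_rich_regions()`) and their per-ecotype contrast
  (`compare_rich_regions_by_ecotype()`).
* **Relatedness** — Loiselle kinship with negative-to-zero truncation
  (`kinship_matrix()`), dosage-space p-distance (`p_distance()`),
  neighbour-joining trees (`neighbor_joining()`) and genotype PCA
  (`pca_genotypes()`).
* **Population structure** — admixture-model maximum likelihood by EM
  (`admixture_em()`; binomial likelihood `g_il ~ Bin(2, Σ_k q_ik f_kl)`,
  compiled core) with 5-fold genotype-masking cross-validation for the
  choice of K (`choose_k()`, K = 1..10 by default).
* **LD and haplotype blocks** — composite r² between dosage vectors
  (`pairwise_r2()`), distance-binned decay curves anchored at (0, 1) with
  the r² = 0.1 decay distance per chromosome/subgenome/genome
  (`ld_decay()`, `ld_decay_scopes()`), Gabriel D′ confidence-interval
  haplotype blocks (`dprime_ci()`, `gabriel_blocks()`) and per-subgenome
  block summaries (`block_summary()`).
* **Synthetic data** — a seeded generator for genomes with planted
  restriction sites (`simulate_genome()`), structured panels with
  Balding–Nichols divergence and subgenome-differential LD
  (`simulate_population()`), and paired reads (`simulate_reads()`), so the
  whole pipeline is testable offline.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods for
fitted objects and `autoplot()` for decay curves, CV curves, ancestry bar
charts and PCA scores. `run_pipeline()` chains all stages and writes
BED/TSV/JSON/Newick outputs plus a provenance record; one integer seed
drives every stochastic stage via `derive_seed()`.

## Worked example

Simulate a small two-subgenome genome, digest it, build a structured panel
and measure the A/C LD contrast:

```r
library(slafpop)

plan <- tibble::tibble(chrom = c("A01", "C01"),
                       subgenome = c("A", "C"),
                       length = c(2e6, 2e6))
genome <- simulate_genome(sim_genome_spec(
  plan, site_rates = c(RsaI = 1/2000, HaeIII = 1/2000), seed = 7))

tags <- select_tags(digest_genome(genome))
tag_spacing(tags, genome_info(genome))
#> # A tibble: 3 × 4
#>   chrom  length n_tags spacing_bp
#>   <chr>   <int>  <int>      <dbl>
#> 1 A01   2000000    156      12821
#> 2 C01   2000000    160      12500
#> 3 Total 4000000    316      12658

sim <- simulate_population(genome, sim_pop_spec(
  n_accessions = 80, n_markers_per_chrom = 300, k_true = 9, fst = 0.25,
  switch_rate_a = 2.7e-5, switch_rate_c = 2.7e-6, missing_rate = 0.05,
  seed = 1))
pairs <- pairwise_r2(sim$genotypes, max_distance_bp = 1.5e6)
ld_decay_scopes(pairs, genome_info(genome), bin_width_bp = 10000)[3:5, ]
#> # A tibble: 3 × 4
#>   scope_type scope n_pairs decay_bp
#>   <chr>      <chr>   <int>    <dbl>
#> 1 subgenome  A       37168    4865.
#> 2 subgenome  C       36427   16624.
#> 3 genome     all     73595    4953.
```

The A subgenome's r² = 0.1 decay distance (~4.9 kb here) is far shorter
than the C subgenome's (~16.6 kb), reflecting the ten-fold higher haplotype
switch rate given to A — the qualitative signature such panels show when
one subgenome has seen much more recombination and introgression than the
other. The packaged reference tables reproduce the published worked
arithmetic directly:

```r
tags <- ref_panel_table("tags")
average_spacing(tags$n_expected_tags, tags$length_bp)[c(1, 20)]
#> [1] 4302 4267   # A01 spacing; genome-wide spacing

snp_density_per_100kb(63307, 238.69e6)
#> [1] 27           # A-subgenome SNPs per 100 kb
```

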