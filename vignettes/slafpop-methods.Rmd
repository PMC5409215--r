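---
title: "Models and methods behind slafpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slafpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slafpop)
```

slafpop implements the computational backbone of a SLAF-seq (specific-locus
amplified fragment sequencing) population-genomics study in an amphidiploid
crop such as *Brassica napus* (AACC, 10 A + 9 C chromosomes): designing the
reduced-representation library by in-silico digestion, filtering a genotype
panel, mapping SNP hotspots and SNP-rich regions, quantifying relatedness and
population structure, and contrasting linkage disequilibrium (LD) between the
two subgenomes. This vignette records the models, the parameters that matter,
and the design decisions made where the design was genuinely open.

## In-silico digestion and enzyme-scheme scoring

`digest_genome()` cuts each chromosome at the union, over the supplied
enzymes, of `site_start + cut_offset` for every exact forward-strand
occurrence of a recognition word. Only forward-strand matching is performed:
both default enzymes (RsaI, GT^AC; HaeIII, GG^CC) are palindromic, so
forward-strand occurrences are exactly the double-strand cut sites. A
non-palindromic enzyme would need double-strand scanning and is out of scope.
Ambiguity codes (N) never match. Fragments tile the chromosome: their lengths
sum to the chromosome length, and their concatenation reproduces the input
sequence — properties the test suite asserts.

SLAF tags are fragments inside the size-selection window, read as a *closed*
interval: the conventional 314–414 bp window retains fragments of exactly
314 and exactly 414 bp. Average tag spacing is `round(length / count)` with
halves rounded away from zero; this is the arithmetic that maps, for
example, a 52,457,410 bp chromosome with 12,193 predicted tags to a spacing
of 4,302 bp, and 281,218 tags on a 1.2 Gb genome to 4,267 bp.

`evaluate_scheme()` scores the four library-design criteria. Two required
operationalisation choices. "Repeat content" is measured as exact duplicate
tag sequences (a tag counts as repeat-derived when its sequence or reverse
complement equals another tag's), because no external repeat annotation is
assumed. "Unique alignment" is approximated by tag-sequence uniqueness: on a
synthetic genome the two coincide, and a read-mapping check would drag in an
aligner for no testable gain. Evenness is the coefficient of variation of
tag counts in fixed tiling windows pooled genome-wide.

## SNP panel statistics

All panel statistics work on alternate-allele dosages (0/1/2, `NA`
missing). The filters use *strict* inequalities, exactly as such thresholds
are conventionally printed: MAF > 0.05 and integrity (call rate) > 0.8, so
boundary markers are removed. Mutation frequency is the fraction of
non-missing accessions carrying any non-reference allele; we read "most
accessions differ from the reference" as an accession-level property, not an
allele-frequency one (an allele-frequency reading would halve the score of
heterozygotes, which does not match the "hotspot" idea of a position where
the reference allele is rare among accessions). A hotspot requires mutation
frequency strictly above 0.8. The denominator is non-missing accessions; a
missing genotype carries no evidence either way.

Density windows are anchored at coordinate 0, 0-based half-open, width
100 kb by default with a truncated final window; a marker at 1-based
position `p` falls in window `(p - 1) %/% window_bp`. This convention makes
window boundaries multiples of 10^5, the form in which such regions are
conventionally named. SNP-rich regions are the top `ceil(0.01 × n_windows)`
windows by SNP count — ties broken in genomic order, earlier windows first,
a rule that had to be fixed because a count sort alone is not a total
order — merged when adjacent. The per-ecotype contrast recomputes windows
and top-fraction selection inside each ecotype subset, using only markers
polymorphic within that subset, and asks which full-panel regions overlap
each ecotype's selected windows.

## Relatedness

Kinship uses the Loiselle et al. (1995) moment estimator, the common
default of SPAGeDi-style analyses of inbred crop panels:
`f_ij = Σ_l (x_il − p_l)(x_jl − p_l) / Σ_l p_l(1 − p_l)` with `x` the
individual allele frequency (dosage/2) and `p` the panel frequency, summed
over markers non-missing in both accessions (pairwise deletion). Negative
estimates mean "less related than random draws from the panel" and are
truncated to zero off the diagonal, the usual convention for downstream
mixed-model use. The estimator name is recorded in the result for
transparency.

The p-distance is adapted from sequence space to dosage space — the
proportion of pairwise non-missing markers at which two accessions carry
different dosage calls — because the pipeline input is a genotype matrix,
not aligned sequences. Trees are built by Saitou–Nei neighbour joining
(`ape::nj`, Studier–Keppler criterion); NJ can emit negative branch lengths
on non-additive inputs, which we clamp to zero while transferring the
deficit to the sibling branch so total tree length is preserved. PCA
mean-imputes missing dosages (kinship and distance deliberately do not:
imputation would shrink pairwise contrasts), centres by marker mean, does
not scale, and reports eigenvalue shares as variance explained.

## Admixture model and the choice of K

`admixture_em()` fits the standard unsupervised admixture likelihood — the
genotype of accession *i* at marker *l* is Binomial(2, Σ_k q_ik f_kl) — by
plain EM over allele-origin latent variables. Plain EM rather than a
quasi-Newton acceleration is a deliberate choice: the stationary points are
identical and at desk scale (hundreds of accessions, thousands of markers)
the compiled EM converges in seconds. The log-likelihood is non-decreasing
every iteration (asserted in the tests to a 1e-9 relative tolerance).
Initialisation draws each ancestry row from a symmetric Dirichlet(1) and
jitters observed allele frequencies by ±0.05, clipped to [1e-6, 1 − 1e-6];
all randomness flows from one integer seed via `derive_seed()`.

`choose_k()` uses genotype-masking cross-validation: non-missing entries are
partitioned into five folds, each fold is masked in turn, the model is
refitted, and masked genotypes are predicted as `2 p_il`. The held-out loss
is `(g − 2p)² / 2`, a squared-error loss chosen because only an "error
rate" is conventionally reported for this procedure without a stated loss;
the argmin over K (ties to the smaller K) is returned. Two practical notes,
both visible in the tests: the CV minimum identifies the true K reliably
only when markers are close to unlinked — strong LD lets larger K explain
held-out genotypes through haplotype structure, the same reason ADMIXTURE
manuals recommend LD pruning before structure analysis — and CV fits use a
slightly looser tolerance (1e-5, ≤500 iterations) than final fits, which
does not move the argmin in our checks.

## Linkage disequilibrium and haplotype blocks

Pairwise LD is the squared Pearson correlation of dosage vectors (composite
LD), pairwise-complete over missingness, with markers pre-filtered at
MAF > 0.05 and pairs skipped below four shared calls. Phase is unknown in a
genotype panel, so the dosage correlation — what PLINK computes on unphased
data — is the honest statistic; EM-phased haplotype r² is deliberately not
used for decay curves and appears only inside the D′ machinery.

The decay curve averages r² in 1-kb distance bins (bin width is a
parameter), anchors the curve at (0 bp, r² = 1) — the conventional
assumption for a marker distance of zero — and reports the first
linear-interpolated
crossing of the threshold r² = 0.1 as the decay distance, per chromosome,
per subgenome (pooling that subgenome's pairs) and genome-wide. A curve
that never reaches the threshold yields an undefined (NA) decay distance
rather than a clamped number.

D′ confidence intervals follow the Gabriel et al. (2002) construction:
allele frequencies fixed at their sample estimates, the sign of D taken
from the dosage covariance, and the likelihood of the 3×3 genotype table
(haplotype pairs under Hardy–Weinberg, both phases for the double
heterozygote) profiled over a |D′| grid of step 0.001; the 90% interval is
read off the normalised likelihood mass, and the point estimate is the grid
maximum. Blocks use the Gabriel defaults — strong LD when the CI is
[≥0.70, ≥0.98], strong recombination when the upper bound is < 0.90 — and a
candidate interval qualifies when its outermost pair is in strong LD and
≥95% of its informative pairs are. Non-overlapping blocks are selected
greedily by descending bp span, and block length is the first-to-last
marker span (the Haploview convention).

Per-chromosome block summaries report count, total length, and frequency
(total block length over chromosome length, two decimals). The subgenome
row aggregates as the *mean of per-chromosome percentages*, not the pooled
ratio: the two disagree whenever chromosome lengths differ, and only the
mean-of-percentages reading reproduces the reference table shipped with
the package (A 10.28%, C 14.20%) from its own per-chromosome rows, so that
is the aggregation implemented.

## The synthetic-data generator

The generator exists so every stage is testable without external data. It
emulates: an amphidiploid genome with labelled A and C chromosomes; planted
restriction sites at chosen per-bp rates on a background scrubbed of
incidental recognition words (so site counts are checkable by direct
scanning); repeat families inserted as exact copies; a structured
population with `k_true` ancestral groups whose allele frequencies follow
the Balding–Nichols distribution around ancestral frequencies drawn
uniformly on (0.05, 0.95); mostly-pure ancestry rows (Dirichlet with a
dominant component, concentration 8 against a 0.2 baseline — a diversity
panel of inbred lines, not an F2); subgenome-differential LD; and uniform
entrywise missingness.

Within-chromosome LD is produced by a latent Gaussian copula per haplotype:
a standard-normal AR(1) process with autocorrelation `exp(−switch_rate ×
gap_bp)` between adjacent markers, thresholded at the group allele
frequency. We first implemented the textbook alternative — each haplotype
copying one of a small set of founder haplotypes per group with
exponential-rate switching — and rejected it on measurement: with
group-private founders the pooled panel r² is capped near the 0.1 decay
threshold at *any* distance (with two founders the within-group LD phase is
random per group and cancels when pooled; coupling the founder draws across
groups still dilutes r² to ~0.08 because a group is informative at both
members of a marker pair only a quarter of the time), making decay-distance
estimation degenerate. The copula keeps the one-parameter exponential decay
and exact Balding–Nichols marginals, so divergence recovery works on raw
data as well as on the recorded truth. Default switch rates (A 2.7e-5/bp,
C 8e-7/bp) were set once from the decay distances such a panel should
exhibit — tens of kb in A versus upwards of a Mb in C — via
`distance ≈ ln(10) / (2 × rate)`.

Ecotype labels (winter / semi-winter / spring, default mix 27/257/16 out of
300) are assigned by mapping ancestral groups onto ecotypes in the requested
proportions and labelling each accession with its majority-ancestry group's
ecotype, reproducing the imperfect ecotype-versus-cluster correspondence of
real panels. Read simulation emits Poisson-depth paired reads with rounded
normal Phred qualities, sufficient for Q30/GC bookkeeping and nothing more.

What the generator does *not* emulate — and therefore what green tests do
not show about real data: coalescent genealogies, selection and demography,
sequencing-error-driven genotype error, allele-frequency spectra of real
panels, non-uniform missingness, and reference bias. Parameter-recovery
results on these simulations certify the estimators against their own
generative assumptions, nothing stronger.

## Numerical choices and problem sizes

All randomness flows from a single integer seed through `derive_seed()`, a
small multiplicative hash of the stage label modulo 2^31 − 1, so any stage
reproduces in isolation. EM stops on a relative log-likelihood change below
1e-6 (1e-5 inside CV) or 2,000 iterations; ancestral frequencies are clipped
to [1e-6, 1 − 1e-6]; ancestry rows are renormalised every iteration.
Admixture fits are label-switching-invariant, so comparisons permute columns
first (`match_columns()`, exhaustive for K ≤ 8). The D′ grid step is 0.001.
Degenerate inputs return typed NA markers (undefined spacing at zero tags,
undefined decay when the curve never crosses, NA D′ below four informative
accessions) rather than sentinel zeros.

The shipped tests and the acceptance script run simulations at desk scale —
panels of 50–100 accessions, 500–1,000 markers, chromosomes of a few Mb,
ten to twenty seeded replicates per stochastic property — sizes chosen so
the full suite exercises every stage, including 5-fold cross-validation
over K = 1..10, in minutes on one core while leaving the statistical
conclusions (recovery of `k_true`, the A/C decay ordering, oracle
agreement) stable across seeds.

## Known limitations

Digestion models complete double digestion; partial digestion, methylation
sensitivity and isoschizomers are out of scope. The enzyme-scheme
"uniqueness" criterion is sequence-level, not alignment-level. Kinship
offers the Loiselle estimator only. NJ trees carry no bootstrap support.
The admixture model ignores linkage; on dense maps its CV curve will
prefer larger K unless markers are thinned. Block detection is the Gabriel
CI rule only (no four-gamete or solid-spine definitions), and phased input
is not supported.
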