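#' Plan a structured synthetic genotype panel
#'
#' Specification for [simulate_population()]. Defaults emulate a rapeseed
#' diversity panel: 300 inbred accessions in ecotype proportions
#' 257 semi-winter / 27 winter / 16 spring, structured into `k_true`
#' ancestral groups with Balding-Nichols divergence `fst`, and with
#' faster-decaying linkage disequilibrium in the A subgenome than in the C
#' subgenome (per-bp haplotype switch rates chosen so the r2 = 0.1 decay
#' distances are of order 40 kb and 1.5 Mb respectively).
#'
#' @param n_accessions number of diploid accessions (>= 2).
#' @param n_markers_per_chrom markers simulated per chromosome.
#' @param k_true number of ancestral groups (>= 1).
#' @param fst Balding-Nichols divergence of group allele frequencies, in
#'   (0, 1).
#' @param ecotype_mix named proportions over winter / semi_winter / spring,
#'   summing to 1.
#' @param switch_rate_a,switch_rate_c per-bp probability rate of switching
#'   founder haplotypes between adjacent markers in the A and C subgenomes;
#'   `switch_rate_a > switch_rate_c` yields shorter LD in A.
#' @param missing_rate fraction of genotype entries masked missing, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @return an object of class `sim_pop_spec`.
#' @export
sim_pop_spec <- function(n_accessions = 300L,
                         n_markers_per_chrom = 500L,
                         k_true = 9L,
                         fst = 0.25,
                         ecotype_mix = c(winter = 27 / 300,
                                         semi_winter = 257 / 300,
                                         spring = 16 / 300),
                         switch_rate_a = 2.7e-5,
                         switch_rate_c = 8e-7,
                         missing_rate = 0.1,
                         seed = 1L) {
  if (n_accessions < 2) abort_slaf("n_accessions must be >= 2")
  if (k_true < 1) abort_slaf("k_true must be >= 1")
  if (fst <= 0 || fst >= 1) abort_slaf("fst must be in (0, 1)")
  if (abs(sum(ecotype_mix) - 1) > 1e-9) {
    abort_slaf("ecotype_mix must sum to 1")
  }
  if (!all(names(ecotype_mix) %in% c("winter", "semi_winter", "spring"))) {
    abort_slaf("ecotype_mix names must be winter, semi_winter, spring")
  }
  for (r in c(switch_rate_a, switch_rate_c)) {
    if (r <= 0 || r >= 1) abort_slaf("switch rates must be in (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_slaf("missing_rate must be in [0, 1)")
  }
  structure(
    list(n_accessions = as.integer(n_accessions),
         n_markers_per_chrom = as.integer(n_markers_per_chrom),
         k_true = as.integer(k_true), fst = fst, ecotype_mix = ecotype_mix,
         switch_rate_a = switch_rate_a, switch_rate_c = switch_rate_c,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_pop_spec"
  )
}

#' Simulate a structured genotype panel over a genome
#'
#' Generative model: per marker an ancestral allele frequency is drawn
#' uniformly on (0.05, 0.95); group frequencies follow the Balding-Nichols
#' distribution with divergence `fst`. Every accession receives two
#' haplotypes; each haplotype draws its group per chromosome from the
#' accession's true ancestry and its alleles from a latent Gaussian
#' copula: a standard-normal AR(1) process along the chromosome with
#' correlation `exp(-switch_rate * gap_bp)` between adjacent markers
#' (subgenome-specific rate), thresholded at the group allele frequency.
#' Group frequencies are therefore exact and haplotype linkage decays
#' exponentially with physical distance, faster in the A subgenome than
#' in C. Dosages are the haplotype sums; entries are then masked missing
#' at `missing_rate`.
#' Ecotype labels are assigned by mapping ancestral groups onto ecotypes in
#' the requested proportions and labelling each accession with the ecotype
#' of its majority-ancestry group, which reproduces the imperfect
#' correspondence between ecotype and genetic cluster seen in real panels.
#'
#' @param genome a `slaf_genome` whose chromosomes carry subgenome labels.
#' @param spec a [sim_pop_spec()].
#' @return list with `genotypes` (a [slaf_geno()]) and `truth` (list:
#'   `true_q` accession x group ancestry, `true_f` group x marker
#'   frequencies, `true_group` majority group, `true_labels` ecotype per
#'   accession, `group_ecotype` the group-to-ecotype map).
#' @export
simulate_population <- function(genome, spec) {
  stopifnot(inherits(genome, "slaf_genome"), inherits(spec, "sim_pop_spec"))
  info <- genome_info(genome)
  n <- spec$n_accessions
  K <- spec$k_true
  m_chr <- pmin(spec$n_markers_per_chrom, info$length)
  set.seed(derive_seed(spec$seed, "population"))

  # marker map
  marker_list <- lapply(seq_len(nrow(info)), function(i) {
    pos <- sort(sample.int(info$length[i], m_chr[i]))
    tibble(chrom = info$chrom[i], pos = pos,
           subgenome = info$subgenome[i])
  })
  map <- bind_rows(marker_list)
  m <- nrow(map)

  # ancestral and group allele frequencies (Balding-Nichols)
  p_anc <- runif(m, 0.05, 0.95)
  if (spec$fst < 1e-6) {
    true_f <- matrix(rep(p_anc, each = K), nrow = K)
  } else {
    shape <- (1 - spec$fst) / spec$fst
    true_f <- matrix(rbeta(K * m, rep(p_anc, each = K) * shape,
                           rep(1 - p_anc, each = K) * shape), nrow = K)
  }

  # true ancestry: mostly-pure accessions with light admixture
  g_primary <- sample.int(K, n, replace = TRUE)
  alpha0 <- 0.2
  purity <- 8
  true_q <- matrix(rgamma_dirichlet(n, K, alpha0, purity, g_primary),
                   nrow = n, ncol = K)

  # haplotypes: group per haplotype per chromosome ~ Cat(true_q). LD along
  # a chromosome comes from a latent Gaussian copula per haplotype: a
  # standard-normal AR(1) process with autocorrelation exp(-rate * gap_bp)
  # between adjacent markers (rate = the subgenome's switch rate); the
  # allele at marker l is 1{pnorm(z_l) < f_kl} for the haplotype's group k.
  # Marginal group frequencies are exactly the Balding-Nichols draws and
  # haplotype correlation decays exponentially with distance, so the A/C
  # switch-rate contrast translates into shorter LD in A than in C.
  H <- 2L * n
  hap_alleles <- matrix(0L, nrow = H, ncol = m)
  col0 <- 0L
  for (ci in seq_len(nrow(info))) {
    mk <- marker_list[[ci]]
    mc <- nrow(mk)
    rate <- if (info$subgenome[ci] == "A") spec$switch_rate_a else spec$switch_rate_c
    z <- apply(true_q, 1, function(q) sample.int(K, 2, replace = TRUE, prob = q))
    z <- as.vector(z) # length H, groups of the two haplotypes per accession
    rho <- exp(-rate * diff(mk$pos))
    lat <- rnorm(H)
    for (j in seq_len(mc)) {
      if (j > 1) {
        lat <- rho[j - 1] * lat + sqrt(1 - rho[j - 1]^2) * rnorm(H)
      }
      thr <- true_f[cbind(z, col0 + j)]
      hap_alleles[, col0 + j] <- (stats::pnorm(lat) < thr) * 1L
    }
    col0 <- col0 + mc
  }
  dosage <- hap_alleles[seq(1, H, by = 2), , drop = FALSE] +
    hap_alleles[seq(2, H, by = 2), , drop = FALSE]

  if (spec$missing_rate > 0) {
    mask <- matrix(runif(n * m) < spec$missing_rate, nrow = n)
    dosage[mask] <- NA_integer_
  }

  # group -> ecotype map in roughly the requested proportions
  mix <- spec$ecotype_mix[order(-spec$ecotype_mix)]
  n_groups <- pmax(round(mix * K), ifelse(mix > 0 & K >= length(mix), 1L, 0L))
  while (sum(n_groups) > K) n_groups[which.max(n_groups)] <- n_groups[which.max(n_groups)] - 1L
  while (sum(n_groups) < K) n_groups[which.max(mix)] <- n_groups[which.max(mix)] + 1L
  group_ecotype <- rep(names(mix), times = n_groups)[seq_len(K)]
  true_labels <- group_ecotype[g_primary]

  accession <- sprintf("acc%03d", seq_len(n))
  markers <- tibble(
    marker = paste0(map$chrom, "_", map$pos),
    chrom = map$chrom, pos = map$pos, ref = "A", alt = "G"
  )
  samples <- tibble(accession = accession, ecotype = true_labels,
                    origin = "synthetic")
  gm <- slaf_geno(dosage, markers, samples)
  truth <- list(true_q = true_q, true_f = true_f, true_group = g_primary,
                true_labels = true_labels, group_ecotype = group_ecotype,
                marker_subgenome = map$subgenome)
  list(genotypes = gm, truth = truth)
}

# internal: rows ~ Dirichlet(alpha0 + purity * e_{g_i})
rgamma_dirichlet <- function(n, K, alpha0, purity, primary) {
  alpha <- matrix(alpha0, nrow = n, ncol = K)
  alpha[cbind(seq_len(n), primary)] <- alpha0 + purity
  g <- matrix(stats::rgamma(n * K, shape = alpha), nrow = n)
  g / rowSums(g)
}

#' Hudson-style Fst between two groups of accessions
#'
#' Ratio-of-averages Hudson estimator with sample-size correction: per
#' marker the numerator is `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' (allele-count denominators) and the denominator `p1(1-p2) + p2(1-p1)`;
#' the estimate is `mean(num) / mean(den)` over markers with data in both
#' groups.
#'
#' @param gm a [slaf_geno()].
#' @param groups vector assigning each accession to a group; exactly two
#'   distinct groups are compared.
#' @return a single Fst estimate.
#' @export
hudson_fst <- function(gm, groups) {
  stopifnot(inherits(gm, "slaf_geno"))
  lv <- unique(groups)
  if (length(lv) != 2) abort_slaf("groups must have exactly two levels")
  d1 <- gm$dosage[groups == lv[1], , drop = FALSE]
  d2 <- gm$dosage[groups == lv[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / n1
  p2 <- colSums(d2, na.rm = TRUE) / n2
  keep <- n1 >= 4 & n2 >= 4
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

#' @rdname hudson_fst
#' @param f1,f2 vectors of true group allele frequencies (no sampling
#'   correction applied); used as the population-level oracle.
#' @export
fst_from_freqs <- function(f1, f2) {
  mean((f1 - f2)^2) / mean(f1 * (1 - f2) + f2 * (1 - f1))
}
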