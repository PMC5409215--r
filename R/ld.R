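#' Pairwise r2 between markers
#'
#' Composite LD for unphased diploids: the squared Pearson correlation of
#' dosage vectors, pairwise-complete over missing entries. Markers are
#' pre-filtered to MAF > `maf_min`; pairs with fewer than 4 shared
#' non-missing accessions, or monomorphic within the shared set, are
#' skipped.
#'
#' @param gm a [slaf_geno()].
#' @param chrom chromosome name (default: every chromosome in turn).
#' @param max_distance_bp only pairs at most this far apart are returned.
#' @param maf_min MAF filter applied before pairing (default 0.05).
#' @return tibble of pairs: `chrom`, `pos_i`, `pos_j`, `distance`, `r2`.
#' @export
pairwise_r2 <- function(gm, chrom = NULL, max_distance_bp = Inf,
                        maf_min = 0.05) {
  stopifnot(inherits(gm, "slaf_geno"))
  st <- marker_stats(gm)
  keep <- !is.na(st$maf) & st$maf > maf_min
  gm <- subset_markers(gm, keep)
  chroms <- if (is.null(chrom)) unique(gm$markers$chrom) else chrom
  out <- lapply(chroms, function(ch) {
    idx <- which(gm$markers$chrom == ch)
    if (length(idx) < 2) return(NULL)
    d <- gm$dosage[, idx, drop = FALSE]
    pos <- gm$markers$pos[idx]
    suppressWarnings(cc <- cor(d, use = "pairwise.complete.obs"))
    shared <- crossprod((!is.na(d)) * 1)
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dist <- abs(pos[pr[, 2]] - pos[pr[, 1]])
    r2 <- cc[pr]^2
    ok <- dist <= max_distance_bp & shared[pr] >= 4 & !is.na(r2)
    tibble(chrom = ch, pos_i = pos[pr[ok, 1]], pos_j = pos[pr[ok, 2]],
           distance = dist[ok], r2 = r2[ok])
  })
  bind_rows(out)
}

#' Decay distance from a binned r2 curve
#'
#' The decay curve is piecewise linear through the fixed anchor
#' (0 bp, r2 = 1) and the bin centres in distance order; the decay
#' distance is the first linearly interpolated crossing of `threshold`.
#'
#' @param centers bin-centre distances in bp, increasing.
#' @param means mean r2 per bin.
#' @param threshold r2 threshold (default 0.1).
#' @return crossing distance in bp, or `NA` if the curve never reaches
#'   the threshold.
#' @examples
#' decay_distance_from_curve(c(10000, 50000), c(0.5, 0.08)) # ~48095
#' @export
decay_distance_from_curve <- function(centers, means, threshold = 0.1) {
  x <- c(0, centers)
  y <- c(1, means)
  for (i in seq_len(length(x) - 1)) {
    y1 <- y[i]; y2 <- y[i + 1]
    if (y1 > threshold && y2 <= threshold) {
      return(x[i] + (x[i + 1] - x[i]) * (y1 - threshold) / (y1 - y2))
    }
    if (y1 <= threshold) return(x[i]) # crossed at or before this point
  }
  NA_real_
}

#' LD decay curve and decay distance
#'
#' Bins pair distances into `bin_width_bp` bins, takes the mean r2 per bin
#' at the bin centre, anchors the curve at (0, 1) and reports the first
#' interpolated crossing of `threshold` as the decay distance.
#'
#' @param pairs pair tibble from [pairwise_r2()].
#' @param threshold r2 decay threshold (default 0.1).
#' @param bin_width_bp distance bin width in bp (default 1000).
#' @return object of class `slaf_decay`: list with `bins` (tibble:
#'   `center`, `mean_r2`, `n_pairs`), `threshold`, `decay_distance`.
#' @export
ld_decay <- function(pairs, threshold = 0.1, bin_width_bp = 1000L) {
  if (nrow(pairs) == 0) abort_slaf("no pairs")
  bin <- pairs$distance %/% bin_width_bp
  agg <- tibble(bin = bin, r2 = pairs$r2) |>
    group_by(.data$bin) |>
    summarise(mean_r2 = mean(.data$r2), n_pairs = n(), .groups = "drop") |>
    arrange(.data$bin)
  bins <- tibble(center = (agg$bin + 0.5) * bin_width_bp,
                 mean_r2 = agg$mean_r2, n_pairs = agg$n_pairs)
  dd <- decay_distance_from_curve(bins$center, bins$mean_r2, threshold)
  structure(list(bins = bins, threshold = threshold,
                 decay_distance = dd, bin_width_bp = bin_width_bp),
            class = "slaf_decay")
}

#' @export
print.slaf_decay <- function(x, ...) {
  cat("<slaf_decay> ", nrow(x$bins), " bins; decay (r2 = ", x$threshold,
      ") at ", if (is.na(x$decay_distance)) "undefined" else
        sprintf("%.2f kb", x$decay_distance / 1000), "\n", sep = "")
  invisible(x)
}

#' Per-chromosome, per-subgenome and genome-wide LD decay
#'
#' Computes [ld_decay()] for each chromosome, for each subgenome (pooling
#' pairs across that subgenome's chromosomes) and for the whole genome.
#'
#' @param pairs pair tibble from [pairwise_r2()].
#' @param chrom_info tibble mapping `chrom` to `subgenome`.
#' @inheritParams ld_decay
#' @return tibble: `scope_type` (chromosome / subgenome / genome),
#'   `scope`, `n_pairs`, `decay_bp`.
#' @export
ld_decay_scopes <- function(pairs, chrom_info, threshold = 0.1,
                            bin_width_bp = 1000L) {
  chrom_info <- as_tibble(chrom_info)
  pairs <- left_join(pairs, chrom_info[, c("chrom", "subgenome")], by = "chrom")
  one <- function(p, type, scope) {
    dd <- if (nrow(p)) ld_decay(p, threshold, bin_width_bp)$decay_distance else NA_real_
    tibble(scope_type = type, scope = scope, n_pairs = nrow(p), decay_bp = dd)
  }
  per_chr <- bind_rows(lapply(unique(pairs$chrom), function(ch) {
    one(pairs[pairs$chrom == ch, ], "chromosome", ch)
  }))
  per_sub <- bind_rows(lapply(unique(pairs$subgenome), function(sg) {
    one(pairs[pairs$subgenome == sg, ], "subgenome", sg)
  }))
  bind_rows(per_chr, per_sub, one(pairs, "genome", "all"))
}

#' D-prime point estimate and likelihood confidence interval
#'
#' Gabriel-style profile likelihood for |D'| between two unphased
#' biallelic markers: allele frequencies are fixed at their sample
#' estimates, the sign of D is taken from the sample covariance of
#' dosages, and the likelihood of the 3 x 3 genotype table (haplotype
#' pairs under Hardy-Weinberg, double heterozygotes summed over both
#' phases) is evaluated on a |D'| grid. The point estimate is the grid
#' maximum-likelihood value; the confidence bounds are the 5% and 95%
#' points of the normalised likelihood mass (a 90% interval, the Gabriel
#' default).
#'
#' @param col_i,col_j dosage vectors in `{0, 1, 2, NA}`.
#' @param resolution |D'| grid step (default 0.001).
#' @param conf central mass of the interval (default 0.9).
#' @return named numeric: `dprime`, `ci_low`, `ci_high` (all in `[0, 1]`),
#'   or all `NA` when fewer than 4 informative accessions or a marker is
#'   monomorphic.
#' @export
dprime_ci <- function(col_i, col_j, resolution = 0.001, conf = 0.9) {
  ok <- !is.na(col_i) & !is.na(col_j)
  x <- col_i[ok]; y <- col_j[ok]
  na_out <- c(dprime = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  if (length(x) < 4) return(na_out)
  pa <- mean(x) / 2
  pb <- mean(y) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(na_out)
  counts <- table(factor(x, 0:2), factor(y, 0:2))
  sgn <- sign(stats::cov(x, y))
  if (sgn == 0) sgn <- 1
  dmax <- if (sgn > 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  grid <- seq(0, 1, by = resolution)
  ll <- profile_loglik_dprime(counts, pa, pb, sgn * grid * dmax)
  point <- grid[which.max(ll)]
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  lo_q <- (1 - conf) / 2
  c(dprime = point,
    ci_low = grid[min(which(cdf >= lo_q))],
    ci_high = grid[min(which(cdf >= 1 - lo_q))])
}

# internal: log-likelihood of a 3x3 genotype count table (rows = dosage at
# marker 1, cols = dosage at marker 2) for a vector of D values, with
# allele frequencies fixed. Haplotype pairs under HWE; the double
# heterozygote sums both phases. Vectorised over D.
profile_loglik_dprime <- function(counts, pa, pb, D) {
  h00 <- pmax((1 - pa) * (1 - pb) + D, 0) # ref-ref
  h01 <- pmax((1 - pa) * pb - D, 0)       # ref-alt
  h10 <- pmax(pa * (1 - pb) - D, 0)       # alt-ref
  h11 <- pmax(pa * pb + D, 0)             # alt-alt
  gp <- list(
    `00` = h00^2,           `01` = 2 * h00 * h01,       `02` = h01^2,
    `10` = 2 * h00 * h10,   `11` = 2 * (h00 * h11 + h01 * h10),
    `12` = 2 * h01 * h11,
    `20` = h10^2,           `21` = 2 * h10 * h11,       `22` = h11^2)
  ll <- numeric(length(D))
  for (g1 in 0:2) for (g2 in 0:2) {
    n_cell <- counts[g1 + 1, g2 + 1]
    if (n_cell > 0) {
      p_cell <- gp[[paste0(g1, g2)]]
      ll <- ll + ifelse(p_cell > 0, n_cell * log(p_cell), -Inf)
    }
  }
  ll
}
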