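#' Per-marker panel statistics
#'
#' For every marker: minor allele frequency (`maf`), call rate
#' (`integrity`) and mutation frequency (`mutation_freq`).
#' MAF is `min(p, 1 - p)` with `p` the alternate-allele frequency among
#' non-missing calls; integrity is the fraction of accessions with a
#' non-missing call; mutation frequency is the fraction of non-missing
#' accessions carrying any non-reference allele (dosage >= 1), i.e. how
#' many accessions differ from the reference genome at that position.
#' Markers with no calls get `NA` for MAF and mutation frequency.
#'
#' @param gm a [slaf_geno()].
#' @return tibble with `marker`, `chrom`, `pos`, `maf`, `integrity`,
#'   `mutation_freq`.
#' @export
marker_stats <- function(gm) {
  stopifnot(inherits(gm, "slaf_geno"))
  d <- gm$dosage
  n <- nrow(d)
  called <- colSums(!is.na(d))
  p <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
  maf <- pmin(p, 1 - p)
  mut <- ifelse(called > 0, colSums(d >= 1, na.rm = TRUE) / called, NA_real_)
  tibble(marker = gm$markers$marker, chrom = gm$markers$chrom,
         pos = gm$markers$pos, maf = unname(maf),
         integrity = unname(called) / n, mutation_freq = unname(mut))
}

#' Minor allele frequency of a dosage vector
#'
#' @param column dosages in `{0, 1, 2, NA}` with at least one call.
#' @return fraction in `[0, 0.5]` (`NA` if all missing).
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2)) # 0.375
#' @export
minor_allele_frequency <- function(column) {
  called <- sum(!is.na(column))
  if (called == 0) return(NA_real_)
  p <- sum(column, na.rm = TRUE) / (2 * called)
  min(p, 1 - p)
}

#' Call rate (integrity) of a dosage vector
#'
#' @param column dosages with `NA` marking missing calls.
#' @return fraction of non-missing calls in `[0, 1]`.
#' @export
integrity <- function(column) {
  mean(!is.na(column))
}

#' Mutation frequency of a dosage vector
#'
#' Fraction of non-missing accessions with any non-reference allele.
#' @param column dosages in `{0, 1, 2, NA}`.
#' @return fraction in `[0, 1]` (`NA` if all missing).
#' @export
mutation_frequency <- function(column) {
  called <- sum(!is.na(column))
  if (called == 0) return(NA_real_)
  sum(column >= 1, na.rm = TRUE) / called
}

#' Filter markers by MAF and integrity
#'
#' Retains exactly the markers with MAF strictly above `maf_min` and
#' integrity strictly above `integrity_min` (boundary values are removed),
#' the selection rule used for high-confidence SNP panels; marker order is
#' preserved.
#'
#' @param gm a [slaf_geno()].
#' @param maf_min MAF threshold (default 0.05).
#' @param integrity_min call-rate threshold (default 0.8).
#' @return the filtered [slaf_geno()].
#' @export
filter_markers <- function(gm, maf_min = 0.05, integrity_min = 0.8) {
  st <- marker_stats(gm)
  keep <- !is.na(st$maf) & st$maf > maf_min & st$integrity > integrity_min
  subset_markers(gm, keep)
}

#' Call SNP hotspots
#'
#' Hotspots are markers whose mutation frequency strictly exceeds the
#' threshold (default 0.8): positions where most accessions differ from
#' the reference genome.
#'
#' @param gm a [slaf_geno()].
#' @param threshold mutation-frequency threshold.
#' @return tibble of hotspot markers (`marker`, `chrom`, `pos`,
#'   `mutation_freq`).
#' @export
call_hotspots <- function(gm, threshold = 0.8) {
  st <- marker_stats(gm)
  out <- st[!is.na(st$mutation_freq) & st$mutation_freq > threshold,
            c("marker", "chrom", "pos", "mutation_freq")]
  as_tibble(out)
}

#' SNP counts in tiling windows
#'
#' Windows are anchored at coordinate 0, 0-based half-open, of width
#' `window_bp` except possibly a truncated last window per chromosome;
#' each marker falls in exactly one window by `(pos - 1) %/% window_bp`.
#' The per-window density column is SNPs per 100 kb rounded to the nearest
#' integer (halves away from zero), the convention used for published
#' per-chromosome SNP density tables.
#'
#' @param gm a [slaf_geno()].
#' @param chrom_lengths tibble with `chrom` and `length` covering every
#'   chromosome in the panel.
#' @param window_bp window width in bp (default 100 kb).
#' @return tibble: `chrom`, `start`, `end`, `n_snps`, `density_per_100kb`.
#' @export
windowed_snp_counts <- function(gm, chrom_lengths, window_bp = 100000L) {
  stopifnot(inherits(gm, "slaf_geno"))
  chrom_lengths <- as_tibble(chrom_lengths)
  mk <- gm$markers
  missing_chr <- setdiff(mk$chrom, chrom_lengths$chrom)
  if (length(missing_chr)) {
    abort_slaf("no length for chromosome(s): ", paste(missing_chr, collapse = ", "))
  }
  len <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  if (any(mk$pos > len[mk$chrom])) {
    abort_slaf("marker position beyond chromosome length")
  }
  out <- lapply(seq_len(nrow(chrom_lengths)), function(i) {
    ch <- chrom_lengths$chrom[i]
    L <- chrom_lengths$length[i]
    n_win <- ceiling(L / window_bp)
    start <- (seq_len(n_win) - 1) * window_bp
    end <- pmin(start + window_bp, L)
    pos <- mk$pos[mk$chrom == ch]
    cnt <- tabulate((pos - 1) %/% window_bp + 1, nbins = n_win)
    tibble(chrom = ch, start = start, end = end, n_snps = cnt)
  })
  wc <- bind_rows(out)
  wc$density_per_100kb <- round_half_away(wc$n_snps / (wc$end - wc$start) * 1e5)
  wc
}

#' SNP density per 100 kb
#'
#' The published-table arithmetic: SNP count divided by length, scaled to
#' 100 kb and rounded to the nearest integer.
#'
#' @param n_snps SNP counts.
#' @param length_bp region lengths in bp.
#' @return rounded densities.
#' @examples
#' snp_density_per_100kb(63307, 238.69e6) # 27
#' @export
snp_density_per_100kb <- function(n_snps, length_bp) {
  round_half_away(n_snps / length_bp * 1e5)
}

#' SNP-rich regions from windowed counts
#'
#' Selects the `ceiling(top_fraction * n_windows)` windows with the largest
#' SNP counts (ties broken by genomic order, earlier windows first) and
#' merges runs of adjacent selected windows on the same chromosome into
#' regions.
#'
#' @param wc window tibble from [windowed_snp_counts()].
#' @param top_fraction fraction of windows to select (default 0.01).
#' @return tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `snp_count`.
#' @export
snp_rich_regions <- function(wc, top_fraction = 0.01) {
  if (nrow(wc) == 0) abort_slaf("no windows")
  k <- ceiling(top_fraction * nrow(wc))
  ord <- order(-wc$n_snps, wc$chrom, wc$start)
  sel <- wc[sort(ord[seq_len(k)]), ]
  merge_windows(sel)
}

# internal: merge adjacent selected windows (same chrom, end == next start)
merge_windows <- function(sel) {
  if (nrow(sel) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), snp_count = integer()))
  }
  sel <- sel[order(sel$chrom, sel$start), ]
  new_run <- c(TRUE, sel$chrom[-1] != sel$chrom[-nrow(sel)] |
                 sel$start[-1] != sel$end[-nrow(sel)])
  run <- cumsum(new_run)
  sel |>
    mutate(run = run) |>
    group_by(run) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), n_windows = n(),
              snp_count = sum(.data$n_snps), .groups = "drop") |>
    select(-"run")
}

#' Presence of SNP-rich regions across ecotypes
#'
#' Recomputes windowed counts and top-fraction windows within each ecotype
#' subset separately, keeping only markers polymorphic within that subset;
#' a region (computed on the full panel) is "present" in an ecotype iff it
#' overlaps any of that ecotype's selected windows. Ecotypes with fewer
#' than two accessions are dropped with a warning.
#'
#' @param gm a [slaf_geno()] whose sample table carries ecotype labels.
#' @param chrom_lengths tibble with `chrom`, `length`.
#' @param window_bp window width (default 100 kb).
#' @param top_fraction top fraction of windows (default 0.01).
#' @return tibble of full-panel rich regions with one logical presence
#'   column per ecotype.
#' @export
compare_rich_regions_by_ecotype <- function(gm, chrom_lengths,
                                            window_bp = 100000L,
                                            top_fraction = 0.01) {
  eco <- gm$samples$ecotype
  lv <- unique(eco[!is.na(eco)])
  if (length(lv) < 2) abort_slaf("need at least two ecotype labels")
  regions <- snp_rich_regions(
    windowed_snp_counts(gm, chrom_lengths, window_bp), top_fraction)
  for (e in lv) {
    idx <- which(!is.na(eco) & eco == e)
    if (length(idx) < 2) {
      warning("ecotype '", e, "' has < 2 accessions; skipped", call. = FALSE)
      next
    }
    sub <- subset_samples(gm, idx)
    st <- marker_stats(sub)
    poly <- !is.na(st$maf) & st$maf > 0
    sub <- subset_markers(sub, poly)
    wc_e <- windowed_snp_counts(sub, chrom_lengths, window_bp)
    k <- ceiling(top_fraction * nrow(wc_e))
    ord <- order(-wc_e$n_snps, wc_e$chrom, wc_e$start)
    sel <- wc_e[sort(ord[seq_len(k)]), ]
    present <- vapply(seq_len(nrow(regions)), function(r) {
      any(sel$chrom == regions$chrom[r] &
            sel$start < regions$end[r] & sel$end > regions$start[r])
    }, logical(1))
    regions[[e]] <- present
  }
  regions
}
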