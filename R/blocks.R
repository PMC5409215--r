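#' Gabriel-style haplotype blocks
#'
#' Applies the Gabriel et al. (2002) confidence-interval rules to the |D'|
#' intervals of [dprime_ci()]: a pair is in "strong LD" when its CI lower
#' bound is >= `strong_low` (0.70) and upper bound >= `strong_high`
#' (0.98); it shows "strong recombination" when the upper bound is
#' < `recomb_high` (0.90); other pairs are uninformative. A candidate
#' block is a marker interval whose outermost pair is in strong LD and in
#' which at least `informative_frac` (95%) of informative pairs are in
#' strong LD. Non-overlapping blocks are then chosen greedily by
#' descending bp span.
#'
#' @param gm a [slaf_geno()].
#' @param chrom chromosome to analyse (default: every chromosome).
#' @param maf_min MAF filter applied before pairing (default 0.05).
#' @param strong_low,strong_high,recomb_high CI rule thresholds.
#' @param informative_frac minimum strong-LD fraction among informative
#'   pairs inside a block.
#' @param resolution |D'| grid step passed to [dprime_ci()].
#' @return a `slaf_blocks` tibble: `chrom`, `first_marker`, `last_marker`
#'   (indices within the chromosome's filtered markers), `n_markers`,
#'   `start_bp`, `end_bp`, `length_bp` (first-to-last marker span).
#' @export
gabriel_blocks <- function(gm, chrom = NULL, maf_min = 0.05,
                           strong_low = 0.70, strong_high = 0.98,
                           recomb_high = 0.90, informative_frac = 0.95,
                           resolution = 0.001) {
  stopifnot(inherits(gm, "slaf_geno"))
  st <- marker_stats(gm)
  gm <- subset_markers(gm, !is.na(st$maf) & st$maf > maf_min)
  chroms <- if (is.null(chrom)) unique(gm$markers$chrom) else chrom
  out <- lapply(chroms, function(ch) {
    idx <- which(gm$markers$chrom == ch)
    m <- length(idx)
    if (m < 2) return(NULL)
    d <- gm$dosage[, idx, drop = FALSE]
    pos <- gm$markers$pos[idx]
    # pairwise classification: 1 strong LD, -1 strong recombination,
    # 0 uninformative
    cls <- matrix(0L, m, m)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        ci <- dprime_ci(d[, i], d[, j], resolution = resolution)
        cls[i, j] <- classify_pair(ci, strong_low, strong_high, recomb_high)
      }
    }
    cand <- find_candidate_blocks(cls, informative_frac)
    if (!nrow(cand)) return(NULL)
    cand$span <- pos[cand$last] - pos[cand$first]
    cand <- cand[order(-cand$span, cand$first), ]
    taken <- rep(FALSE, m)
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      rng <- cand$first[r]:cand$last[r]
      if (!any(taken[rng])) {
        keep[r] <- TRUE
        taken[rng] <- TRUE
      }
    }
    cand <- cand[keep, ]
    cand <- cand[order(cand$first), ]
    tibble(chrom = ch, first_marker = cand$first, last_marker = cand$last,
           n_markers = cand$last - cand$first + 1L,
           start_bp = pos[cand$first], end_bp = pos[cand$last],
           length_bp = pos[cand$last] - pos[cand$first])
  })
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(chrom = character(), first_marker = integer(),
                  last_marker = integer(), n_markers = integer(),
                  start_bp = numeric(), end_bp = numeric(),
                  length_bp = numeric())
  }
  structure(res, class = c("slaf_blocks", class(res)))
}

# internal: Gabriel pair classification from a dprime_ci() result
classify_pair <- function(ci, strong_low, strong_high, recomb_high) {
  if (any(is.na(ci))) return(0L)
  if (ci[["ci_low"]] >= strong_low && ci[["ci_high"]] >= strong_high) return(1L)
  if (ci[["ci_high"]] < recomb_high) return(-1L)
  0L
}

# internal: all intervals [i, j] whose outermost pair is strong LD and in
# which >= frac of informative pairs are strong LD
find_candidate_blocks <- function(cls, frac) {
  m <- nrow(cls)
  first <- integer(0); last <- integer(0)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (cls[i, j] != 1L) next
      sub <- cls[i:j, i:j]
      vals <- sub[upper.tri(sub)]
      n_inf <- sum(vals != 0L)
      if (n_inf == 0) next
      if (sum(vals == 1L) / n_inf >= frac) {
        first <- c(first, i); last <- c(last, j)
      }
    }
  }
  tibble(first = first, last = last)
}

#' Summarise haplotype blocks per chromosome and subgenome
#'
#' Per chromosome: block count, total block length and frequency
#' (total block length / chromosome length x 100, 2 decimals). Per
#' subgenome: the mean per-chromosome block count, mean total block
#' length, and the mean of the per-chromosome frequency percentages
#' (not the pooled ratio). The genome row pools counts and lengths and
#' reports total length / total chromosome length.
#'
#' @param per_chrom tibble with `chrom`, `n_blocks`, `total_length`; build
#'   it from a block tibble with [summarise_blocks()].
#' @param chrom_lengths tibble with `chrom`, `length` and optionally
#'   `subgenome` (defaults to the first letter of the chromosome name).
#' @return tibble with `scope_type` (chromosome / subgenome / genome),
#'   `scope`, `n_blocks`, `total_length`, `frequency_pct`.
#' @export
block_summary <- function(per_chrom, chrom_lengths) {
  per_chrom <- as_tibble(per_chrom)
  chrom_lengths <- as_tibble(chrom_lengths)
  if (!"subgenome" %in% names(chrom_lengths)) {
    chrom_lengths$subgenome <- substr(chrom_lengths$chrom, 1, 1)
  }
  tab <- left_join(chrom_lengths, per_chrom, by = "chrom")
  tab$n_blocks[is.na(tab$n_blocks)] <- 0L
  tab$total_length[is.na(tab$total_length)] <- 0
  tab$frequency_pct <- round(tab$total_length / tab$length * 100, 2)
  chr_rows <- tibble(scope_type = "chromosome", scope = tab$chrom,
                     n_blocks = as.numeric(tab$n_blocks),
                     total_length = tab$total_length,
                     frequency_pct = tab$frequency_pct)
  sub_rows <- tab |>
    group_by(.data$subgenome) |>
    summarise(n_blocks = mean(.data$n_blocks),
              total_length = mean(.data$total_length),
              frequency_pct = round(mean(.data$frequency_pct), 2),
              .groups = "drop") |>
    mutate(scope_type = "subgenome") |>
    dplyr::rename(scope = "subgenome") |>
    select("scope_type", "scope", "n_blocks", "total_length", "frequency_pct")
  gen_row <- tibble(scope_type = "genome", scope = "all",
                    n_blocks = sum(tab$n_blocks),
                    total_length = sum(tab$total_length),
                    frequency_pct = round(sum(tab$total_length) /
                                            sum(tab$length) * 100, 2))
  bind_rows(chr_rows, sub_rows, gen_row)
}

#' @rdname block_summary
#' @param blocks a block tibble from [gabriel_blocks()].
#' @export
summarise_blocks <- function(blocks) {
  as_tibble(blocks) |>
    group_by(.data$chrom) |>
    summarise(n_blocks = n(), total_length = sum(.data$length_bp),
              .groups = "drop")
}

#' Block size-class histogram
#'
#' Counts blocks in the conventional size classes 0-1 kb, 1-10 kb,
#' 10-100 kb and > 100 kb.
#'
#' @param blocks a block tibble with `length_bp`.
#' @return tibble with `size_class`, `n_blocks`, `fraction`.
#' @export
block_size_classes <- function(blocks) {
  br <- c(-Inf, 1e3, 1e4, 1e5, Inf)
  lab <- c("0-1 kb", "1-10 kb", "10-100 kb", ">100 kb")
  cl <- cut(blocks$length_bp, breaks = br, labels = lab, right = TRUE)
  cnt <- as.integer(table(cl))
  tibble(size_class = lab, n_blocks = cnt,
         fraction = if (sum(cnt) > 0) cnt / sum(cnt) else rep(NA_real_, 4))
}
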