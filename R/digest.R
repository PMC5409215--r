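#' Restriction enzymes
#'
#' A restriction enzyme is described by its recognition word and the offset
#' of the cut point from the start of the recognition site on the forward
#' strand. Only unambiguous A/C/G/T words are supported, and matching is
#' forward-strand only, which is exact for palindromic enzymes such as the
#' two used for SLAF library design in *B. napus* (RsaI, GT^AC, and HaeIII,
#' GG^CC — both blunt cutters with palindromic sites).
#'
#' @param name enzyme name.
#' @param recognition recognition word (A/C/G/T only).
#' @param cut_offset bases from the recognition start to the cut point,
#'   in `[0, nchar(recognition)]`.
#' @return an object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("RsaI", "GTAC", 2)
#' enzyme_catalog("HaeIII")
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition)) {
    abort_slaf("recognition word must be a non-empty A/C/G/T string")
  }
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    abort_slaf("cut_offset must lie within the recognition word")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
enzyme_catalog <- function(name) {
  cat_ <- list(
    RsaI   = c("GTAC", 2),
    HaeIII = c("GGCC", 2),
    AluI   = c("AGCT", 2),
    HpyCH4IV = c("ACGT", 1)
  )
  if (!name %in% names(cat_)) {
    abort_slaf("unknown enzyme '", name, "'; supply a restriction_enzyme()")
  }
  restriction_enzyme(name, cat_[[name]][1], as.integer(cat_[[name]][2]))
}

#' In-silico digestion of a genome
#'
#' Cuts every chromosome at the union, over the supplied enzymes, of
#' positions `site_start + cut_offset` for each exact forward-strand
#' occurrence of the recognition word. Fragments are the maximal intervals
#' between consecutive cut points, including both chromosome ends, so the
#' fragments tile each chromosome exactly. Ambiguity codes (e.g. N) never
#' match a recognition word.
#'
#' @param genome a `slaf_genome` (or [Biostrings::DNAStringSet]).
#' @param enzymes list of [restriction_enzyme()] objects (or enzyme names).
#' @param keep_seq keep fragment sequences in the result (default TRUE).
#' @return tibble of fragments: `chrom`, `start`, `end` (0-based half-open),
#'   `length`, and `seq` when requested.
#' @export
digest_genome <- function(genome, enzymes = list("RsaI", "HaeIII"),
                          keep_seq = TRUE) {
  if (inherits(genome, "slaf_genome")) {
    seqs <- genome$seqs
  } else if (methods::is(genome, "DNAStringSet")) {
    seqs <- genome
  } else {
    abort_slaf("genome must be a slaf_genome or DNAStringSet")
  }
  if (!length(enzymes)) abort_slaf("at least one enzyme is required")
  enzymes <- lapply(enzymes, function(e) {
    if (inherits(e, "restriction_enzyme")) e else enzyme_catalog(e)
  })
  if (!length(seqs)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), seq = character()))
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    len <- Biostrings::width(seqs)[i]
    cuts <- integer(0)
    for (e in enzymes) {
      m <- Biostrings::matchPattern(e$recognition, seqs[[i]], fixed = TRUE)
      if (length(m)) {
        cuts <- c(cuts, IRanges::start(m) - 1L + e$cut_offset)
      }
    }
    cuts <- sort(unique(cuts))
    cuts <- cuts[cuts > 0 & cuts < len]
    bounds <- c(0L, cuts, len)
    out[[i]] <- tibble(
      chrom = names(seqs)[i],
      start = bounds[-length(bounds)],
      end = bounds[-1]
    )
  }
  frags <- bind_rows(out)
  frags$length <- frags$end - frags$start
  if (keep_seq) {
    frags$seq <- unlist(lapply(seq_along(seqs), function(i) {
      f <- frags[frags$chrom == names(seqs)[i], ]
      as.character(Biostrings::extractAt(
        seqs[[i]], IRanges::IRanges(f$start + 1L, f$end)))
    }), use.names = FALSE)
  }
  frags
}

#' Select SLAF tags from digestion fragments
#'
#' A SLAF tag is a restriction fragment whose length falls inside the
#' library size-selection window; the bounds are inclusive, with the
#' standard window being 314-414 bp.
#'
#' @param fragments fragment tibble from [digest_genome()].
#' @param min_len,max_len inclusive length bounds in bp.
#' @return the retained fragments (a `slaf_tags` tibble, sorted by
#'   chromosome and start, carrying the bounds as attributes).
#' @export
select_tags <- function(fragments, min_len = 314L, max_len = 414L) {
  if (min_len > max_len) abort_slaf("min_len must be <= max_len")
  tags <- fragments[fragments$length >= min_len & fragments$length <= max_len, ]
  tags <- tags[order(tags$chrom, tags$start), ]
  structure(tags, min_len = min_len, max_len = max_len,
            class = c("slaf_tags", class(tags)))
}

#' Average tag spacing
#'
#' `average_spacing()` is the worked arithmetic: chromosome length divided
#' by tag count, rounded to the nearest integer with halves away from zero
#' (so 52,457,410 bp / 12,193 tags gives 4,302 bp). `tag_spacing()` applies
#' it per chromosome to a tag set and appends a genome-wide `Total` row
#' computed from the pooled length and count.
#'
#' @param count tag counts.
#' @param length_bp chromosome lengths in bp.
#' @return `average_spacing()`: numeric spacing in bp (`NA` where count is
#'   0). `tag_spacing()`: tibble with `chrom`, `length`, `n_tags`,
#'   `spacing_bp`.
#' @export
average_spacing <- function(count, length_bp) {
  ifelse(count > 0, round_half_away(length_bp / count), NA_real_)
}

#' @rdname average_spacing
#' @param tags a tag tibble from [select_tags()].
#' @param chrom_lengths tibble with `chrom` and `length` (bp), e.g.
#'   [genome_info()].
#' @export
tag_spacing <- function(tags, chrom_lengths) {
  chrom_lengths <- as_tibble(chrom_lengths)
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  counts <- dplyr::count(as_tibble(tags), .data$chrom, name = "n_tags")
  per <- left_join(chrom_lengths[, c("chrom", "length")], counts, by = "chrom")
  per$n_tags[is.na(per$n_tags)] <- 0L
  per$spacing_bp <- average_spacing(per$n_tags, per$length)
  total <- tibble(chrom = "Total",
                  length = sum(per$length),
                  n_tags = sum(per$n_tags),
                  spacing_bp = average_spacing(sum(per$n_tags), sum(per$length)))
  bind_rows(per, total)
}

#' Score an enzyme scheme against the SLAF design criteria
#'
#' Scores a predicted tag set on the library-design criteria: few tags made
#' of repeated sequence, even distribution along chromosomes, unique tag
#' sequences, and a high tag count. Repeat content is operationalised as
#' exact duplicate tag sequences (a tag counts as repeat-derived when its
#' sequence, or its reverse complement, equals another tag's sequence).
#' Evenness is the coefficient of variation of tag counts in fixed tiling
#' windows pooled over the whole genome.
#'
#' @param tags tag tibble from [select_tags()] (must carry `seq`).
#' @param genome the digested `slaf_genome`.
#' @param window_bp tiling window width in bp (> 0).
#' @return one-row tibble: `tag_count`, `repeat_fraction`,
#'   `uniqueness_fraction`, `evenness_cv`, plus a nested `per_chrom` tibble
#'   of counts and spacing.
#' @export
evaluate_scheme <- function(tags, genome, window_bp = 100000L) {
  if (window_bp <= 0) abort_slaf("window_bp must be > 0")
  info <- genome_info(genome)
  per <- tag_spacing(tags, info)
  n <- nrow(tags)
  if (n == 0) {
    return(tibble(tag_count = 0L, repeat_fraction = NA_real_,
                  uniqueness_fraction = NA_real_, evenness_cv = NA_real_,
                  per_chrom = list(per)))
  }
  if (is.null(tags$seq)) abort_slaf("tags must carry sequences (keep_seq = TRUE)")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(tags$seq)))
  canon <- pmin(tags$seq, rc)
  tab <- table(canon)
  repeat_fraction <- sum(tab[tab > 1]) / n
  # pooled per-window counts over fixed tiling windows
  win_counts <- unlist(lapply(seq_len(nrow(info)), function(i) {
    n_win <- ceiling(info$length[i] / window_bp)
    t_i <- tags[tags$chrom == info$chrom[i], ]
    tabulate(t_i$start %/% window_bp + 1L, nbins = n_win)
  }))
  evenness_cv <- if (mean(win_counts) > 0) {
    stats::sd(win_counts) / mean(win_counts)
  } else NA_real_
  tibble(tag_count = n,
         repeat_fraction = repeat_fraction,
         uniqueness_fraction = 1 - repeat_fraction,
         evenness_cv = evenness_cv,
         per_chrom = list(per))
}

#' Write tags as BED
#'
#' 0-based half-open intervals, one per tag.
#' @param tags tag tibble.
#' @param path output path.
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.frame(tags$chrom, tags$start, tags$end,
                    paste0("tag", seq_len(nrow(tags))))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
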