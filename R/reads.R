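#' Simulate paired-end reads from a tag set
#'
#' Emits paired reads from predicted SLAF tags for read-level QC: the
#' number of pairs per tag is Poisson with mean `depth`, mate 1 is the
#' first `read_len` bases of the tag and mate 2 the reverse complement of
#' the last `read_len` bases, and per-base Phred qualities are drawn from a
#' rounded normal `quality_model = c(mean, sd)` clamped to `[2, 41]`.
#'
#' @param tags tag tibble from [select_tags()] carrying `seq`.
#' @param depth mean fold-coverage (> 0).
#' @param quality_model numeric `c(mean, sd)` of per-base Phred quality.
#' @param read_len read length in bp.
#' @param seed integer seed.
#' @return list of two tibbles `r1`, `r2` with columns `id`, `seq`, `qual`
#'   (Phred+33 encoded string).
#' @export
simulate_reads <- function(tags, depth, quality_model = c(40, 0),
                           read_len = 100L, seed = 1L) {
  if (nrow(tags) == 0) abort_slaf("tag set is empty")
  if (depth <= 0) abort_slaf("depth must be > 0")
  if (is.null(tags$seq)) abort_slaf("tags must carry sequences")
  set.seed(derive_seed(seed, "reads"))
  n_pairs <- rpois(nrow(tags), depth)
  idx <- rep(seq_len(nrow(tags)), n_pairs)
  if (!length(idx)) {
    empty <- tibble(id = character(), seq = character(), qual = character())
    return(list(r1 = empty, r2 = empty))
  }
  tag_seq <- tags$seq[idx]
  L <- pmin(read_len, nchar(tag_seq))
  fwd <- substr(tag_seq, 1, L)
  rev_part <- substr(tag_seq, nchar(tag_seq) - L + 1, nchar(tag_seq))
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev_part)))
  ids <- paste0("tag", idx, ":", stats::ave(idx, idx, FUN = seq_along))
  qual_string <- function(lens) {
    q <- round_half_away(rnorm(sum(lens), quality_model[1], quality_model[2]))
    q <- pmin(pmax(q, 2), 41)
    vapply(split(q, rep(seq_along(lens), lens)),
           function(v) rawToChar(as.raw(v + 33L)), character(1),
           USE.NAMES = FALSE)
  }
  list(
    r1 = tibble(id = paste0(ids, "/1"), seq = fwd, qual = qual_string(nchar(fwd))),
    r2 = tibble(id = paste0(ids, "/2"), seq = rev, qual = qual_string(nchar(rev)))
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a tibble with `id`, `seq`, `qual` (one mate).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::PhredQuality(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a reads tibble
#'
#' @param path FASTQ path (Phred+33).
#' @return tibble with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(id = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Q30 fraction of a read set
#'
#' Fraction of sequenced bases with Phred quality >= 30 (error probability
#' <= 0.001), the standard short-read quality summary.
#'
#' @param reads a reads tibble (from [simulate_reads()] or [read_fastq()]),
#'   or a path to a FASTQ file.
#' @return fraction in `[0, 1]`.
#' @export
q30_fraction <- function(reads) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  if (any(nchar(reads$qual) != nchar(reads$seq))) {
    abort_slaf("quality and sequence lengths differ")
  }
  q <- utf8ToInt(paste(reads$qual, collapse = "")) - 33L
  if (!length(q)) return(NA_real_)
  mean(q >= 30)
}
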