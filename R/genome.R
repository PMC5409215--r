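#' Plan a synthetic amphidiploid genome
#'
#' Builds the specification for [simulate_genome()]. The default chromosome
#' plan emulates a small amphidiploid genome with an "A" and a "C"
#' subgenome, the situation in *Brassica napus* (10 A + 9 C chromosomes);
#' tests and examples typically use a handful of short chromosomes.
#'
#' @param chrom_plan data frame with columns `chrom` (name), `subgenome`
#'   ("A" or "C") and `length` (bp, > 0).
#' @param gc_target target GC fraction in `[0, 1]`.
#' @param site_rates named numeric vector: expected planted restriction
#'   recognition sites per bp, named by enzyme (must be known to
#'   [enzyme_catalog()] or supplied via `enzymes`).
#' @param repeat_plan optional list with elements `n_families`,
#'   `family_length` (bp) and `copies` (>= 1): repeat families inserted as
#'   exact copies.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @param enzymes optional list of [restriction_enzyme()] objects resolving
#'   the names of `site_rates`.
#' @return an object of class `sim_genome_spec`.
#' @export
sim_genome_spec <- function(chrom_plan,
                            gc_target = 0.4,
                            site_rates = c(RsaI = 1 / 2000, HaeIII = 1 / 2000),
                            repeat_plan = NULL,
                            seed = 1L,
                            enzymes = NULL) {
  chrom_plan <- as_tibble(chrom_plan)
  stopifnot(all(c("chrom", "subgenome", "length") %in% names(chrom_plan)))
  if (any(chrom_plan$length <= 0)) {
    abort_slaf("all chromosome lengths must be > 0")
  }
  if (!all(chrom_plan$subgenome %in% c("A", "C"))) {
    abort_slaf("subgenome labels must be 'A' or 'C'")
  }
  check_fraction(gc_target, "gc_target")
  if (length(site_rates) && any(site_rates < 0)) {
    abort_slaf("site_rates must be non-negative")
  }
  if (!is.null(repeat_plan)) {
    stopifnot(all(c("n_families", "family_length", "copies") %in% names(repeat_plan)))
    if (repeat_plan$copies < 1) abort_slaf("repeat copies must be >= 1")
  }
  if (is.null(enzymes)) {
    enzymes <- lapply(names(site_rates), enzyme_catalog)
  }
  structure(
    list(chrom_plan = chrom_plan, gc_target = gc_target,
         site_rates = site_rates, repeat_plan = repeat_plan,
         seed = as.integer(seed), enzymes = enzymes),
    class = "sim_genome_spec"
  )
}

#' Simulate a genome with planted restriction sites
#'
#' Draws background sequence at the target GC content, scrubs it of
#' incidental occurrences of the planted enzymes' recognition words (so the
#' only exact sites present are the planted ones), inserts repeat families
#' as exact copies, and plants recognition sites at the requested per-bp
#' rates. Deterministic given the spec's seed.
#'
#' @param spec a [sim_genome_spec()].
#' @return an object of class `slaf_genome`: a list with `seqs`
#'   (a [Biostrings::DNAStringSet] named by chromosome) and `info`
#'   (tibble of chromosome, subgenome, length).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  words <- vapply(spec$enzymes, function(e) e$recognition, character(1))
  set.seed(spec$seed)
  plan <- spec$chrom_plan

  seqs <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    len <- plan$length[i]
    base_probs <- c(A = (1 - spec$gc_target) / 2, C = spec$gc_target / 2,
                    G = spec$gc_target / 2, T = (1 - spec$gc_target) / 2)
    x <- sample(names(base_probs), len, replace = TRUE, prob = base_probs)
    x <- scrub_words(x, words)
    repeat_mask <- rep(FALSE, len)
    if (!is.null(spec$repeat_plan)) {
      rp <- spec$repeat_plan
      for (f in seq_len(rp$n_families)) {
        fam <- sample(names(base_probs), rp$family_length, replace = TRUE,
                      prob = base_probs)
        fam <- scrub_words(fam, words)
        for (cp in seq_len(rp$copies)) {
          if (rp$family_length >= len) break
          pos <- sample.int(len - rp$family_length, 1)
          x[pos:(pos + rp$family_length - 1)] <- fam
          repeat_mask[pos:(pos + rp$family_length - 1)] <- TRUE
        }
      }
    }
    # plant recognition sites outside repeats, keeping words separated
    for (k in seq_along(spec$site_rates)) {
      rate <- spec$site_rates[k]
      if (rate <= 0) next
      w <- strsplit(words[k], "")[[1]]
      wl <- length(w)
      n_sites <- rbinom(1, len, min(rate, 1))
      if (n_sites == 0) next
      max_w <- max(nchar(words))
      ok <- which(!repeat_mask)
      ok <- ok[ok <= len - wl + 1]
      placed <- 0L
      guard <- rep(FALSE, len)
      tries <- 0L
      while (placed < n_sites && length(ok) && tries < 50 * n_sites) {
        tries <- tries + 1L
        pos <- ok[sample.int(length(ok), 1)]
        span <- max(1, pos - max_w):min(len, pos + wl - 1 + max_w)
        if (any(guard[span])) next
        x[pos:(pos + wl - 1)] <- w
        guard[span] <- TRUE
        placed <- placed + 1L
      }
    }
    seqs[i] <- paste(x, collapse = "")
  }
  dss <- Biostrings::DNAStringSet(setNames(seqs, plan$chrom))
  new_slaf_genome(dss, plan[, c("chrom", "subgenome")])
}

# internal: disrupt every exact occurrence of the given words by swapping a
# middle base; iterates because a swap can create a new occurrence.
scrub_words <- function(x, words) {
  if (!length(words)) return(x)
  bases <- c("A", "C", "G", "T")
  for (pass in 1:20) {
    s <- paste(x, collapse = "")
    hit <- FALSE
    for (w in words) {
      m <- gregexpr(w, s, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      hit <- TRUE
      mid <- as.integer(m) + nchar(w) %/% 2L
      for (p in mid) {
        x[p] <- sample(setdiff(bases, x[p]), 1)
      }
    }
    if (!hit) return(x)
  }
  x
}

# internal constructor for the genome container
new_slaf_genome <- function(seqs, info) {
  stopifnot(methods::is(seqs, "DNAStringSet"))
  info <- as_tibble(info)
  info$length <- Biostrings::width(seqs)[match(info$chrom, names(seqs))]
  structure(list(seqs = seqs, info = info), class = "slaf_genome")
}

#' @export
print.slaf_genome <- function(x, ...) {
  cat("<slaf_genome> ", nrow(x$info), " chromosomes, ",
      format(sum(x$info$length), big.mark = ","), " bp (",
      sum(x$info$subgenome == "A"), " A / ",
      sum(x$info$subgenome == "C"), " C)\n", sep = "")
  invisible(x)
}

#' Chromosome table of a genome
#'
#' @param genome a `slaf_genome`.
#' @return tibble with `chrom`, `subgenome`, `length`.
#' @export
genome_info <- function(genome) {
  stopifnot(inherits(genome, "slaf_genome"))
  genome$info
}

#' Write / read a genome as FASTA
#'
#' Subgenome labels are carried in the FASTA description line
#' (`>chrom subgenome=A`), so a round trip preserves them.
#'
#' @param genome a `slaf_genome`.
#' @param path file path.
#' @return `read_genome_fasta()` returns a `slaf_genome`;
#'   `write_genome_fasta()` returns `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "slaf_genome"))
  out <- genome$seqs
  names(out) <- paste0(genome$info$chrom, " subgenome=", genome$info$subgenome)
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  full <- names(dss)
  chrom <- sub("\\s.*$", "", full)
  sub_lab <- ifelse(grepl("subgenome=([AC])", full),
                    sub(".*subgenome=([AC]).*", "\\1", full),
                    substr(chrom, 1, 1))
  if (!all(sub_lab %in% c("A", "C"))) {
    abort_slaf("cannot infer subgenome labels from FASTA names")
  }
  names(dss) <- chrom
  new_slaf_genome(dss, tibble(chrom = chrom, subgenome = sub_lab))
}

#' GC content of sequences
#'
#' Fraction (G + C) / (A + C + G + T); ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param x a `slaf_genome`, [Biostrings::DNAStringSet], or character vector
#'   of sequences.
#' @return a single fraction, or `NA_real_` for empty input.
#' @examples
#' gc_content("GGCCAATT")
#' @export
gc_content <- function(x) {
  if (inherits(x, "slaf_genome")) x <- x$seqs
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  counts <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  gc <- sum(counts[, c("C", "G")])
  acgt <- sum(counts)
  if (acgt == 0) return(NA_real_)
  gc / acgt
}
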