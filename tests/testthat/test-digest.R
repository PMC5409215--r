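rsai <- restriction_enzyme("RsaI", "GTAC", 2)
haeiii <- restriction_enzyme("HaeIII", "GGCC", 2)

as_genome <- function(seqs, subgenome = NULL) {
  dss <- Biostrings::DNAStringSet(seqs)
  if (is.null(subgenome)) subgenome <- rep("A", length(seqs))
  slafpop:::new_slaf_genome(dss, tibble::tibble(chrom = names(seqs),
                                                subgenome = subgenome))
}

test_that("double digestion cuts at both enzymes' offsets", {
  g <- as_genome(c(A01 = "AAAGTACCCGGCCTTT"))
  fr <- digest_genome(g, list(rsai, haeiii))
  expect_equal(fr$start, c(0L, 5L, 11L))
  expect_equal(fr$end, c(5L, 11L, 16L))
  expect_equal(fr$seq, c("AAAGT", "ACCCGG", "CCTTT"))
})

test_that("a chromosome with no sites yields one spanning fragment", {
  g <- as_genome(c(A01 = "AAAATTTTAAAATTTT"))
  fr <- digest_genome(g, list(rsai, haeiii))
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 0L)
  expect_equal(fr$end, 16L)
})

test_that("digestion agrees with a brute-force scan oracle on random 50-kb sequence", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE), collapse = "")
  g <- as_genome(c(A01 = s))
  fr <- digest_genome(g, list(rsai, haeiii), keep_seq = FALSE)
  or <- oracle_digest(s, list(rsai, haeiii))
  expect_equal(fr$start, or$start)
  expect_equal(fr$end, or$end)
  # conservation: fragments tile the chromosome
  expect_equal(sum(fr$length), 50000L)
  expect_equal(fr$start[-1], fr$end[-nrow(fr)])
})

test_that("fragment sequences concatenate back to the chromosome", {
  g <- two_chrom_genome(20000L, seed = 13,
                        site_rates = c(RsaI = 1 / 800, HaeIII = 1 / 800))
  fr <- digest_genome(g)
  for (ch in c("A01", "C01")) {
    expect_equal(paste(fr$seq[fr$chrom == ch], collapse = ""),
                 as.character(g$seqs[[ch]]))
  }
})

test_that("digesting the reverse complement of a palindromic-site chromosome reverses the fragment lengths", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  f1 <- digest_genome(as_genome(c(A01 = s)), list(rsai, haeiii), keep_seq = FALSE)
  f2 <- digest_genome(as_genome(c(A01 = rc)), list(rsai, haeiii), keep_seq = FALSE)
  expect_equal(f2$length, rev(f1$length))
})

test_that("tag selection uses inclusive bounds and matches a predicate oracle", {
  lens <- c(313L, 314L, 414L, 415L)
  fr <- tibble::tibble(chrom = "A01", start = cumsum(c(0L, lens[-4])),
                       end = cumsum(lens), length = lens,
                       seq = strrep("A", lens))
  tags <- select_tags(fr)
  expect_equal(tags$length, c(314L, 414L))
  expect_equal(nrow(select_tags(fr[0, ])), 0L)

  set.seed(4)
  lens <- sample(100:600, 1000, replace = TRUE)
  fr <- tibble::tibble(chrom = "A01", start = cumsum(c(0L, lens[-1000])),
                       end = cumsum(lens), length = lens)
  tags <- select_tags(fr, 314, 414)
  expect_equal(tags$length, lens[lens >= 314 & lens <= 414])

  # monotonicity: widening the window never loses tags
  wider <- select_tags(fr, 300, 450)
  expect_gte(nrow(wider), nrow(tags))
  expect_error(select_tags(fr, 400, 300), "min_len")
})

test_that("average tag spacing reproduces the published per-chromosome arithmetic", {
  expect_equal(average_spacing(12193, 52457410), 4302)
  expect_equal(average_spacing(281218, 1200000000), 4267)
  expect_equal(average_spacing(1, 12345), 12345)
  expect_true(is.na(average_spacing(0, 100)))
})

test_that("tag_spacing summarises per chromosome with a pooled Total row", {
  tags <- tibble::tibble(chrom = c("A01", "A01", "C01"),
                         start = c(0L, 1000L, 0L), end = c(350L, 1350L, 350L),
                         length = 350L)
  sp <- tag_spacing(tags, tibble::tibble(chrom = c("A01", "C01"),
                                         length = c(10000L, 7000L)))
  expect_equal(sp$n_tags, c(2L, 1L, 3L))
  expect_equal(sp$spacing_bp, c(5000, 7000, round(17000 / 3)))
  expect_equal(sp$chrom[3], "Total")
})

test_that("scheme evaluation scores uniqueness, repeats and evenness", {
  g <- two_chrom_genome(50000L, seed = 17,
                        site_rates = c(RsaI = 1 / 700, HaeIII = 1 / 700))
  tags <- select_tags(digest_genome(g), 200, 500)
  rep_ <- evaluate_scheme(tags, g, window_bp = 10000)
  expect_equal(rep_$tag_count, nrow(tags))
  # scrubbed random sequence: tags should be unique
  expect_equal(rep_$repeat_fraction, 0)
  expect_equal(rep_$uniqueness_fraction, 1)

  # constructed duplicates (incl. reverse complements) vs all-pairs oracle
  set.seed(8)
  base <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- c(base, base[1:10],
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAStringSet(base[11:15]))))
  tg <- tibble::tibble(chrom = "A01", start = (seq_along(seqs) - 1) * 100L,
                       end = (seq_along(seqs) - 1) * 100L + 40L,
                       length = 40L, seq = seqs)
  gg <- as_genome(c(A01 = strrep("A", 20000)))
  rep2 <- evaluate_scheme(tg, gg, window_bp = 5000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  dup_oracle <- vapply(seq_along(seqs), function(i) {
    any(seqs[-i] == seqs[i] | seqs[-i] == rc[i])
  }, logical(1))
  expect_equal(rep2$repeat_fraction, mean(dup_oracle))

  # evenness: equal window counts give CV 0
  tg3 <- tibble::tibble(chrom = "A01", start = c(100L, 5100L, 10100L),
                        end = c(500L, 5500L, 10500L), length = 400L,
                        seq = c("AC", "GT", "TT"))
  gg3 <- as_genome(c(A01 = strrep("A", 15000)))
  expect_equal(evaluate_scheme(tg3, gg3, window_bp = 5000)$evenness_cv, 0)

  # empty tag set: undefined metrics rather than zeros
  empty <- evaluate_scheme(tg3[0, ], gg3, window_bp = 5000)
  expect_true(is.na(empty$repeat_fraction))
  expect_true(is.na(empty$evenness_cv))
})

test_that("enzyme validation rejects malformed definitions", {
  expect_error(restriction_enzyme("X", "GTNC", 2), "A/C/G/T")
  expect_error(restriction_enzyme("X", "GTAC", 5), "cut_offset")
  expect_error(enzyme_catalog("NotAnEnzyme"), "unknown enzyme")
  expect_error(digest_genome(two_chrom_genome(1000L), list()), "at least one")
})
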