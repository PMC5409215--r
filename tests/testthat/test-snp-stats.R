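test_that("MAF, integrity and mutation frequency match direct counting", {
  expect_equal(minor_allele_frequency(c(0, 0, 1, 2)), 0.375)
  expect_equal(minor_allele_frequency(c(0, 0, 0, 0)), 0)
  expect_true(is.na(minor_allele_frequency(c(NA, NA))))
  expect_equal(integrity(c(0, 1, NA, 2, NA, 0, 1, 1, 2, 0)), 0.8)
  expect_equal(mutation_frequency(c(1, 2, 2, 2, 0)), 0.8)
  expect_equal(mutation_frequency(c(2, 2, 2, 2, 2)), 1)

  # 500 random columns against an explicit enumeration oracle
  set.seed(31)
  for (i in 1:500) {
    col <- sample(c(0:2, NA), 20, replace = TRUE)
    if (all(is.na(col))) next
    called <- col[!is.na(col)]
    p <- sum(called) / (2 * length(called))
    expect_equal(minor_allele_frequency(col), min(p, 1 - p))
    expect_equal(integrity(col), length(called) / 20)
    expect_equal(mutation_frequency(col), mean(called >= 1))
  }
})

test_that("marker_stats vectorises the per-column definitions", {
  gm <- random_panel(40, 200, miss = 0.15, seed = 7)
  st <- marker_stats(gm)
  for (j in c(1, 50, 123, 200)) {
    expect_equal(st$maf[j], minor_allele_frequency(gm$dosage[, j]))
    expect_equal(st$integrity[j], integrity(gm$dosage[, j]))
    expect_equal(st$mutation_freq[j], mutation_frequency(gm$dosage[, j]))
  }
})

test_that("filtering uses strict thresholds and matches a per-marker predicate oracle", {
  # integrity exactly 0.8 and MAF exactly 0.05 are removed
  d <- cbind(c(rep(1L, 8), NA, NA),   # integrity exactly 0.8
             c(1L, rep(0L, 9)),       # MAF exactly 0.05
             rep(c(0L, 1L), 5))       # clean marker
  gm <- make_geno(d)
  kept <- filter_markers(gm)
  expect_equal(n_markers(kept), 1L)
  expect_equal(marker_table(kept)$marker, "m3")

  gm2 <- random_panel(30, 1000, miss = 0.2, seed = 12)
  kept2 <- filter_markers(gm2, 0.05, 0.8)
  oracle <- vapply(seq_len(1000), function(j) {
    col <- gm2$dosage[, j]
    maf <- minor_allele_frequency(col)
    !is.na(maf) && maf > 0.05 && mean(!is.na(col)) > 0.8
  }, logical(1))
  expect_equal(marker_table(kept2)$marker, marker_table(gm2)$marker[oracle])

  # monotonicity: raising either threshold never increases retention
  expect_lte(n_markers(filter_markers(gm2, 0.1, 0.8)), n_markers(kept2))
  expect_lte(n_markers(filter_markers(gm2, 0.05, 0.9)), n_markers(kept2))
})

test_that("hotspot calls respect the strict 0.8 boundary", {
  d <- cbind(c(1L, 2L, 2L, 2L, 0L),  # frequency exactly 0.8: not a hotspot
             c(2L, 2L, 2L, 2L, 2L),  # frequency 1: hotspot
             c(0L, 0L, 1L, 0L, 0L))
  gm <- make_geno(d)
  hs <- call_hotspots(gm)
  expect_equal(hs$marker, "m2")
  # threshold 0 picks up every marker with any non-reference call
  expect_equal(call_hotspots(gm, 0)$marker, c("m1", "m2", "m3"))
  # all-moderate panel yields none
  gm2 <- make_geno(matrix(rep(c(0L, 1L), 10), ncol = 4))
  expect_equal(nrow(call_hotspots(gm2)), 0L)
})

test_that("window counts tile chromosomes, conserve totals and round density like the published tables", {
  gm <- make_geno(matrix(0:2, nrow = 3, ncol = 3),
                  pos = c(5L, 150000L, 150050L))
  wc <- windowed_snp_counts(gm, tibble::tibble(chrom = "A01", length = 200000L))
  expect_equal(wc$n_snps, c(1L, 2L))
  expect_equal(wc$start, c(0, 100000))
  expect_equal(wc$end, c(100000, 200000))

  gm2 <- random_panel(10, 400, miss = 0, seed = 3)
  lens <- tibble::tibble(chrom = c("A01", "C01"), length = c(400000L, 400000L))
  wc2 <- windowed_snp_counts(gm2, lens, 50000L)
  expect_equal(sum(wc2$n_snps), 400L)
  expect_equal(wc2$density_per_100kb,
               round_half_away(wc2$n_snps / (wc2$end - wc2$start) * 1e5))

  expect_equal(snp_density_per_100kb(63307, 238.69e6), 27)
  expect_equal(snp_density_per_100kb(5352, 17.40e6), 31)

  bad <- make_geno(matrix(0L, 2, 1), pos = 500000L)
  expect_error(windowed_snp_counts(bad, tibble::tibble(chrom = "A01",
                                                       length = 100000L)),
               "beyond chromosome length")
})

test_that("top-fraction windows are selected by ceil with genomic tie-breaks and merged when adjacent", {
  wc <- tibble::tibble(chrom = rep("A01", 300), start = (0:299) * 1e5,
                       end = (1:300) * 1e5, n_snps = rep(1L, 300))
  wc$n_snps[c(10, 11, 50)] <- c(90L, 80L, 95L)
  rr <- snp_rich_regions(wc, 0.01)  # ceil(3) = 3 windows
  expect_equal(sum(rr$n_windows), 3L)
  # windows 10 and 11 are adjacent: merged into one region
  expect_equal(nrow(rr), 2L)
  expect_equal(rr$snp_count[rr$start == 9e5], 170L)

  # random counts vs a full-sort oracle
  set.seed(9)
  wc2 <- tibble::tibble(chrom = rep(c("A01", "C01"), each = 100),
                        start = rep((0:99) * 1e5, 2),
                        end = rep((1:100) * 1e5, 2),
                        n_snps = sample(0:50, 200, replace = TRUE))
  rr2 <- snp_rich_regions(wc2, 0.05)
  k <- ceiling(0.05 * 200)
  ord <- order(-wc2$n_snps, wc2$chrom, wc2$start)
  sel <- wc2[sort(ord[1:k]), ]
  expect_equal(sum(rr2$n_windows), k)
  expect_equal(sum(rr2$snp_count), sum(sel$n_snps))

  # tie-break: equal counts select earlier windows first
  wc3 <- tibble::tibble(chrom = "A01", start = (0:9) * 1e5, end = (1:10) * 1e5,
                        n_snps = rep(5L, 10))
  rr3 <- snp_rich_regions(wc3, 0.1)
  expect_equal(rr3$start, 0)
})

test_that("statistics are invariant to accession order", {
  gm <- random_panel(25, 120, miss = 0.1, seed = 15)
  set.seed(1)
  perm <- sample(25)
  gm_p <- slaf_geno(gm$dosage[perm, ], gm$markers, gm$samples[perm, ])
  expect_equal(marker_stats(gm_p)$maf, marker_stats(gm)$maf)
  expect_equal(marker_stats(gm_p)$mutation_freq, marker_stats(gm)$mutation_freq)
  expect_equal(call_hotspots(gm_p), call_hotspots(gm))
  lens <- tibble::tibble(chrom = c("A01", "C01"), length = c(100000L, 100000L))
  expect_equal(windowed_snp_counts(gm_p, lens), windowed_snp_counts(gm, lens))
})

test_that("ecotype-restricted rich regions reflect subset-private variation", {
  # winter accessions polymorphic everywhere; spring monomorphic except in a
  # private hot window
  set.seed(22)
  n_w <- 20; n_s <- 20
  m <- 60
  pos <- seq(5000, by = 10000, length.out = m)  # 60 markers over 600 kb
  d_w <- matrix(rbinom(n_w * m, 2, 0.4), nrow = n_w)
  d_s <- matrix(0L, nrow = n_s, ncol = m)
  hot <- which(pos >= 300000 & pos < 400000)
  d_s[, hot] <- rbinom(n_s * length(hot), 2, 0.5)
  gm <- make_geno(rbind(d_w, d_s), pos = as.integer(pos),
                  ecotype = rep(c("winter", "spring"), c(n_w, n_s)))
  lens <- tibble::tibble(chrom = "A01", length = 600000L)
  tab <- compare_rich_regions_by_ecotype(gm, lens, window_bp = 100000L,
                                         top_fraction = 0.2)
  expect_true(all(c("winter", "spring") %in% names(tab)))
  # spring's only polymorphic window is the private one, so any region
  # overlapping [300k, 400k) is present in spring
  ov <- tab$start < 400000 & tab$end > 300000
  if (any(ov)) expect_true(all(tab$spring[ov]))

  # identical subsets produce identical presence patterns
  gm2 <- make_geno(rbind(d_w, d_w), pos = as.integer(pos),
                   ecotype = rep(c("winter", "spring"), each = n_w))
  tab2 <- compare_rich_regions_by_ecotype(gm2, lens, window_bp = 100000L,
                                          top_fraction = 0.2)
  expect_equal(tab2$winter, tab2$spring)

  # an ecotype with < 2 accessions is dropped with a warning
  gm3 <- make_geno(rbind(d_w, d_w[1, , drop = FALSE]), pos = as.integer(pos),
                   ecotype = c(rep("winter", n_w), "spring"))
  expect_warning(tab3 <- compare_rich_regions_by_ecotype(
    gm3, lens, window_bp = 100000L, top_fraction = 0.2), "spring")
  expect_false("spring" %in% names(tab3))
})
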