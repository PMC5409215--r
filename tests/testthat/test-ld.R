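test_that("pairwise r2 matches the covariance formula computed by explicit loops", {
  # identical columns: r2 = 1; orthogonal columns: r2 = 0
  d <- cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L), c(0L, 2L, 0L, 2L))
  gm <- make_geno(d, pos = c(100L, 200L, 300L))
  pr <- pairwise_r2(gm, maf_min = 0)
  expect_equal(pr$r2[pr$pos_i == 100 & pr$pos_j == 200], 1)
  expect_equal(pr$r2[pr$pos_i == 100 & pr$pos_j == 300], 0)

  gm2 <- random_panel(30, 60, miss = 0.15, seed = 11)
  pr2 <- pairwise_r2(gm2, chrom = "A01", maf_min = 0.05)
  st <- marker_stats(gm2)
  keep <- which(st$chrom == "A01" & st$maf > 0.05)
  for (r in sample(nrow(pr2), 25)) {
    i <- keep[match(pr2$pos_i[r], st$pos[keep])]
    j <- keep[match(pr2$pos_j[r], st$pos[keep])]
    x <- unname(gm2$dosage[, i]); y <- unname(gm2$dosage[, j])
    ok <- !is.na(x) & !is.na(y)
    num <- 0; sx <- 0; sy <- 0
    mx <- mean(x[ok]); my <- mean(y[ok])
    for (a in which(ok)) {
      num <- num + (x[a] - mx) * (y[a] - my)
      sx <- sx + (x[a] - mx)^2
      sy <- sy + (y[a] - my)^2
    }
    expect_equal(pr2$r2[r], num^2 / (sx * sy), tolerance = 1e-12)
  }
})

test_that("r2 is invariant under dosage flips and distance windows are honoured", {
  gm <- random_panel(25, 40, miss = 0.1, seed = 4)
  pr <- pairwise_r2(gm, chrom = "A01")
  flipped <- gm
  flipped$dosage[, 3] <- 2L - flipped$dosage[, 3]
  pr_f <- pairwise_r2(flipped, chrom = "A01")
  expect_equal(pr_f$r2, pr$r2, tolerance = 1e-12)

  pr_win <- pairwise_r2(gm, chrom = "A01", max_distance_bp = 3000)
  expect_true(all(pr_win$distance <= 3000))
})

test_that("the decay distance interpolates the anchored curve", {
  # bins (10 kb, 0.5) and (50 kb, 0.08): crossing at ~48.095 kb
  expect_equal(decay_distance_from_curve(c(10000, 50000), c(0.5, 0.08), 0.1),
               10000 + 40000 * (0.5 - 0.1) / (0.5 - 0.08))
  # a curve that never reaches the threshold is undefined
  expect_true(is.na(decay_distance_from_curve(c(1000, 2000), c(1, 1), 0.1)))
  # crossing before the first bin interpolates from the (0, 1) anchor
  expect_equal(decay_distance_from_curve(5000, 0.05, 0.1),
               5000 * 0.9 / 0.95)
})

test_that("ld_decay bins pairs and lowering the threshold never shortens the decay distance", {
  pairs <- tibble::tibble(chrom = "A01",
                          pos_i = 0, pos_j = c(500, 1500, 2500, 3500),
                          distance = c(500, 1500, 2500, 3500),
                          r2 = c(0.9, 0.5, 0.15, 0.05))
  dec <- ld_decay(pairs, threshold = 0.1, bin_width_bp = 1000)
  expect_equal(dec$bins$center, c(500, 1500, 2500, 3500))
  d_strict <- ld_decay(pairs, threshold = 0.05, bin_width_bp = 1000)$decay_distance
  d_loose <- ld_decay(pairs, threshold = 0.3, bin_width_bp = 1000)$decay_distance
  expect_gte(d_strict, dec$decay_distance)
  expect_lte(d_loose, dec$decay_distance)
})

test_that("decay scopes pool chromosome pairs into subgenome and genome curves", {
  gm <- random_panel(30, 80, miss = 0.05, seed = 8)
  pr <- pairwise_r2(gm)
  info <- tibble::tibble(chrom = c("A01", "C01"), subgenome = c("A", "C"))
  sc <- ld_decay_scopes(pr, info, threshold = 0.1, bin_width_bp = 2000)
  expect_setequal(sc$scope[sc$scope_type == "chromosome"], c("A01", "C01"))
  expect_setequal(sc$scope[sc$scope_type == "subgenome"], c("A", "C"))
  expect_equal(sc$n_pairs[sc$scope_type == "genome"], nrow(pr))
})

test_that("D-prime hits the complete-LD and independence limits", {
  # haplotypes AB and ab only (n = 100): D' = 1
  x <- rep(c(0L, 1L, 2L), c(25, 50, 25))
  ci <- dprime_ci(x, x)
  expect_equal(ci[["dprime"]], 1)
  expect_gte(ci[["ci_low"]], 0.9)
  expect_equal(ci[["ci_high"]], 1)

  # independent equifrequent columns at large n: point and CI low near 0
  set.seed(12)
  a <- rbinom(800, 2, 0.5); b <- rbinom(800, 2, 0.5)
  ci2 <- dprime_ci(a, b)
  expect_lt(ci2[["dprime"]], 0.1)
  expect_lt(ci2[["ci_low"]], 0.1)

  # degenerate inputs are undefined
  expect_true(all(is.na(dprime_ci(c(0, 1, NA), c(1, NA, 0)))))
  expect_true(all(is.na(dprime_ci(rep(0L, 10), rbinom(10, 2, 0.5)))))
})

test_that("D-prime CIs equal the exhaustive grid-search oracle on fixed genotype tables", {
  tables <- list(
    list(x = rep(c(0L, 1L, 2L, 0L), c(10, 12, 8, 5)),
         y = rep(c(0L, 1L, 2L, 2L), c(10, 12, 8, 5))),
    list(x = c(rep(0L, 15), rep(1L, 10), rep(2L, 10)),
         y = c(rep(0L, 5), rep(1L, 12), rep(2L, 8), rep(0L, 10))),
    list(x = rep(c(0L, 2L, 1L), c(12, 12, 6)),
         y = rep(c(2L, 0L, 1L), c(12, 12, 6))))
  for (tb in tables) {
    got <- dprime_ci(tb$x, tb$y, resolution = 0.001)
    want <- oracle_dprime_ci(tb$x, tb$y, resolution = 0.001)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("gabriel_blocks finds the forced extremes", {
  set.seed(7)
  col <- rbinom(100, 2, 0.4)
  gm <- make_geno(matrix(rep(col, 5), ncol = 5),
                  pos = c(100L, 300L, 600L, 900L, 1200L))
  bl <- gabriel_blocks(gm)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$first_marker, 1L)
  expect_equal(bl$last_marker, 5L)
  expect_equal(bl$length_bp, 1100)

  ind <- make_geno(matrix(rbinom(100 * 6, 2, 0.5), ncol = 6),
                   pos = as.integer(seq(100, 600, by = 100)))
  expect_equal(nrow(gabriel_blocks(ind)), 0L)

  one <- make_geno(matrix(rbinom(40, 2, 0.5), ncol = 1), pos = 50L)
  expect_equal(nrow(gabriel_blocks(one)), 0L)
})

test_that("blocks never cross chromosomes and stay within the chromosome span", {
  g <- two_chrom_genome(200000L, seed = 5)
  spec <- sim_pop_spec(n_accessions = 50, n_markers_per_chrom = 15,
                       k_true = 2, fst = 0.15,
                       switch_rate_a = 1e-4, switch_rate_c = 1e-5,
                       missing_rate = 0.05, seed = 6)
  sim <- simulate_population(g, spec)
  bl <- gabriel_blocks(sim$genotypes)
  if (nrow(bl)) {
    expect_true(all(bl$length_bp >= 0))
    per <- summarise_blocks(bl)
    expect_true(all(per$total_length <= 200000))
    # non-overlap within chromosome
    for (ch in unique(bl$chrom)) {
      b <- bl[bl$chrom == ch, ]
      if (nrow(b) > 1) {
        expect_true(all(b$first_marker[-1] > b$last_marker[-nrow(b)]))
      }
    }
  }
  expect_s3_class(bl, "slaf_blocks")
})

test_that("block summaries reproduce the published per-chromosome arithmetic", {
  tab <- ref_panel_table("hap_blocks")
  per <- tab[tab$chrom != "Total",
             c("chrom", "n_blocks", "block_length_bp")]
  names(per) <- c("chrom", "n_blocks", "total_length")
  lens <- tab[tab$chrom != "Total", c("chrom", "length_bp")]
  names(lens) <- c("chrom", "length")
  summ <- block_summary(per, lens)
  chr <- summ[summ$scope_type == "chromosome", ]
  expect_equal(chr$frequency_pct[chr$scope == "C01"], 22.57)
  expect_equal(chr$frequency_pct, tab$frequency_pct[tab$chrom != "Total"])
  sub <- summ[summ$scope_type == "subgenome", ]
  expect_equal(sub$n_blocks[sub$scope == "A"], 1208.5)
  expect_equal(sub$frequency_pct[sub$scope == "A"], 10.28)
  expect_equal(sub$frequency_pct[sub$scope == "C"], 14.20)
  gen <- summ[summ$scope_type == "genome", ]
  expect_equal(gen$frequency_pct, 12.53)

  # a single chromosome fully covered by one block is at 100%
  one <- block_summary(tibble::tibble(chrom = "A01", n_blocks = 1,
                                      total_length = 5000),
                       tibble::tibble(chrom = "A01", length = 5000,
                                      subgenome = "A"))
  expect_equal(one$frequency_pct[one$scope_type == "chromosome"], 100)

  sizes <- block_size_classes(tibble::tibble(length_bp = c(500, 900, 5e3,
                                                           5e4, 2e5)))
  expect_equal(sizes$n_blocks, c(2L, 1L, 1L, 1L))
})
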