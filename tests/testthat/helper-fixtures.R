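# shared builders and independent oracles for the test suite

make_geno <- function(dosage, chrom = NULL, pos = NULL, ecotype = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("A01", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  samples <- tibble::tibble(accession = sprintf("a%03d", seq_len(n)))
  if (!is.null(ecotype)) samples$ecotype <- ecotype
  slaf_geno(dosage,
            tibble::tibble(marker = paste0("m", seq_len(m)),
                           chrom = chrom, pos = pos),
            samples)
}

# unstructured random panel over two chromosomes
random_panel <- function(n, m, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.02, 0.98)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n, byrow = FALSE)
  if (miss > 0) d[matrix(runif(n * m) < miss, nrow = n)] <- NA
  chrom <- rep(c("A01", "C01"), each = ceiling(m / 2))[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), chrom), seq_along))[order(order(chrom))]
  # positions restart per chromosome, spaced 1 kb
  pos <- as.integer(ave(seq_len(m), chrom, FUN = seq_along) * 1000L)
  make_geno(d, chrom = chrom, pos = pos)
}

two_chrom_genome <- function(len = 500000L, seed = 1, site_rates = c(RsaI = 0, HaeIII = 0)) {
  plan <- tibble::tibble(chrom = c("A01", "C01"), subgenome = c("A", "C"),
                         length = c(len, len))
  simulate_genome(sim_genome_spec(plan, site_rates = site_rates, seed = seed))
}

# oracle: digestion by naive substring scanning
oracle_digest <- function(seqstr, enzymes) {
  len <- nchar(seqstr)
  cuts <- integer(0)
  for (e in enzymes) {
    w <- e$recognition
    wl <- nchar(w)
    for (i in seq_len(len - wl + 1)) {
      if (substr(seqstr, i, i + wl - 1) == w) {
        cuts <- c(cuts, i - 1L + e$cut_offset)
      }
    }
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0 & cuts < len]
  bounds <- c(0L, cuts, len)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# oracle: D' profile-likelihood CI by explicit per-genotype-cell loops
oracle_dprime_ci <- function(x, y, resolution = 0.001, conf = 0.9) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pa <- mean(x) / 2
  pb <- mean(y) / 2
  sgn <- sign(cov(x, y)); if (sgn == 0) sgn <- 1
  dmax <- if (sgn > 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  grid <- seq(0, 1, by = resolution)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    h <- c(rr = (1 - pa) * (1 - pb) + D, ra = (1 - pa) * pb - D,
           ar = pa * (1 - pb) - D, aa = pa * pb + D)
    h <- pmax(h, 0)
    tot <- 0
    for (i in seq_along(x)) {
      g1 <- x[i]; g2 <- y[i]
      p <- 0
      for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
        if (a1 + a2 == g1 && b1 + b2 == g2) {
          h1 <- h[[c("rr", "ra", "ar", "aa")[a1 * 2 + b1 + 1]]]
          h2 <- h[[c("rr", "ra", "ar", "aa")[a2 * 2 + b2 + 1]]]
          p <- p + h1 * h2
        }
      }
      tot <- tot + if (p > 0) log(p) else -Inf
    }
    tot
  }, numeric(1))
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  lo_q <- (1 - conf) / 2
  c(dprime = grid[which.max(ll)],
    ci_low = grid[min(which(cdf >= lo_q))],
    ci_high = grid[min(which(cdf >= 1 - lo_q))])
}

# oracle: exhaustive Gabriel-rule block finder on a small chromosome,
# built on the oracle D' CI and a literal reading of the rule set
oracle_gabriel_blocks <- function(d, pos, frac = 0.95) {
  m <- ncol(d)
  cls <- matrix(0L, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      if (sum(ok) < 4) next
      pa <- mean(d[ok, i]) / 2; pb <- mean(d[ok, j]) / 2
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) next
      ci <- oracle_dprime_ci(d[, i], d[, j])
      if (ci[["ci_low"]] >= 0.70 && ci[["ci_high"]] >= 0.98) {
        cls[i, j] <- 1L
      } else if (ci[["ci_high"]] < 0.90) {
        cls[i, j] <- -1L
      }
    }
  }
  cand <- NULL
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (cls[i, j] != 1L) next
      sub <- cls[i:j, i:j]
      v <- sub[upper.tri(sub)]
      if (sum(v != 0) == 0) next
      if (sum(v == 1) / sum(v != 0) >= frac) {
        cand <- rbind(cand, c(i, j, pos[j] - pos[i]))
      }
    }
  }
  if (is.null(cand)) return(data.frame(first = integer(), last = integer()))
  cand <- cand[order(-cand[, 3], cand[, 1]), , drop = FALSE]
  taken <- rep(FALSE, m)
  keep <- NULL
  for (r in seq_len(nrow(cand))) {
    rng <- cand[r, 1]:cand[r, 2]
    if (!any(taken[rng])) {
      keep <- rbind(keep, cand[r, 1:2])
      taken[rng] <- TRUE
    }
  }
  keep <- keep[order(keep[, 1]), , drop = FALSE]
  data.frame(first = keep[, 1], last = keep[, 2])
}

# oracle: best 6-taxon topology by ordinary-least-squares fit over all
# unrooted topologies
ls_best_topology <- function(dm) {
  n <- nrow(dm)
  labs <- rownames(dm)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pair_idx <- which(upper.tri(dm), arr.ind = TRUE)
  dvec <- dm[upper.tri(dm)]
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]  # [[ restores the compressed tip labels
    ne <- nrow(tr$edge)
    # pair (i, j) crosses edge e iff exactly one of i, j lies in the tip
    # set below e (edge bipartition), so the design matrix needs no path
    # search
    below <- phangorn::Descendants(tr, tr$edge[, 2], "tips")
    X <- matrix(0, nrow(pair_idx), ne)
    for (e in seq_len(ne)) {
      in_e <- pair_idx[, 1] %in% below[[e]]
      jn_e <- pair_idx[, 2] %in% below[[e]]
      X[xor(in_e, jn_e), e] <- 1
    }
    fit <- lm.fit(X, dvec)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- tr
    }
  }
  best
}

expect_same_topology <- function(t1, t2) {
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
}
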