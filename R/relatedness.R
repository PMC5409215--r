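#' Marker-based kinship matrix (Loiselle estimator)
#'
#' Pairwise kinship from genotype dosages using the Loiselle et al. (1995)
#' estimator: with `x_il` individual *i*'s allele frequency at marker *l*
#' (dosage / 2) and `p_l` the panel frequency,
#' `f_ij = sum_l (x_il - p_l)(x_jl - p_l) / sum_l p_l (1 - p_l)`,
#' where both sums run over the markers non-missing in *both* accessions
#' (pairwise deletion). Negative estimates indicate less relationship than
#' random expectation and are truncated to 0 off the diagonal.
#'
#' @param gm a [slaf_geno()] with >= 2 accessions and >= 1 polymorphic
#'   marker.
#' @param truncate_negative truncate negative off-diagonal values to 0
#'   (default TRUE).
#' @return a symmetric accession x accession matrix of class
#'   `slaf_kinship` with attribute `estimator_name = "Loiselle"`.
#' @export
kinship_matrix <- function(gm, truncate_negative = TRUE) {
  stopifnot(inherits(gm, "slaf_geno"))
  d <- gm$dosage
  if (nrow(d) < 2) abort_slaf("need >= 2 accessions")
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(called, 1))
  pq <- p * (1 - p)
  if (all(pq == 0)) abort_slaf("need >= 1 polymorphic marker")
  x <- d / 2
  xc <- sweep(x, 2, p)
  m_obs <- !is.na(d)
  xc[!m_obs] <- 0
  num <- tcrossprod(xc)
  den <- tcrossprod(sweep(m_obs * 1, 2, pq, "*"), m_obs * 1)
  k <- num / den
  if (any(den == 0)) {
    warning("some accession pairs share no polymorphic markers", call. = FALSE)
    k[den == 0] <- NA_real_
  }
  if (truncate_negative) {
    off <- row(k) != col(k)
    k[off & !is.na(k) & k < 0] <- 0
  }
  dimnames(k) <- list(gm$samples$accession, gm$samples$accession)
  structure(k, estimator_name = "Loiselle", class = c("slaf_kinship", "matrix"))
}

#' Fraction of accession pairs below a kinship cutoff
#'
#' Summary used to describe how unrelated a diversity panel is: the
#' fraction of unordered accession pairs with kinship below `cutoff`.
#'
#' @param km a kinship matrix from [kinship_matrix()].
#' @param cutoff kinship cutoff (default 0.05).
#' @return fraction in `[0, 1]`.
#' @export
kinship_fraction_below <- function(km, cutoff = 0.05) {
  v <- km[upper.tri(km)]
  mean(v < cutoff, na.rm = TRUE)
}

#' p-distance matrix from genotype calls
#'
#' Proportion of compared markers at which two accessions carry different
#' dosage calls, over the markers non-missing in both (pairwise deletion).
#' This adapts the sequence-space p-distance to dosage space, as the input
#' is a genotype matrix rather than aligned sequences.
#'
#' @param gm a [slaf_geno()] with >= 2 accessions.
#' @return symmetric accession x accession matrix of class `slaf_dist`
#'   with zero diagonal and entries in `[0, 1]`.
#' @export
p_distance <- function(gm) {
  stopifnot(inherits(gm, "slaf_geno"))
  d <- gm$dosage
  if (nrow(d) < 2) abort_slaf("need >= 2 accessions")
  m_obs <- (!is.na(d)) * 1
  shared <- tcrossprod(m_obs)
  matches <- matrix(0, nrow(d), nrow(d))
  for (v in 0:2) {
    iv <- (!is.na(d) & d == v) * 1
    matches <- matches + tcrossprod(iv)
  }
  pd <- (shared - matches) / shared
  if (any(shared == 0)) {
    warning("some accession pairs share no markers", call. = FALSE)
    pd[shared == 0] <- NA_real_
  }
  diag(pd) <- 0
  dimnames(pd) <- list(gm$samples$accession, gm$samples$accession)
  structure(pd, method = "p-distance", class = c("slaf_dist", "matrix"))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (Studier-Keppler criterion, as implemented
#' in [ape::nj()]) on a symmetric distance matrix, returning an unrooted
#' binary tree. Negative branch lengths, which NJ can produce on
#' non-additive data, are clamped to 0 with the deficit transferred to the
#' sibling branch so the total tree length is preserved.
#'
#' @param dm symmetric distance matrix (e.g. from [p_distance()]) over at
#'   least 3 taxa.
#' @return an [ape] `phylo` tree; serialise with [ape::write.tree()] for
#'   Newick text.
#' @export
neighbor_joining <- function(dm) {
  dm <- unclass(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    abort_slaf("distance matrix must be symmetric")
  }
  if (nrow(dm) < 3) abort_slaf("need >= 3 taxa")
  if (any(!is.finite(dm))) abort_slaf("distances must be finite")
  tr <- ape::nj(dm)
  for (pass in 1:20) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      if (tr$edge.length[e] >= 0) next
      parent <- tr$edge[e, 1]
      sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge[, 1]) != e)
      if (length(sib)) {
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr
}

#' Principal components analysis of a genotype panel
#'
#' Missing dosages are imputed to the marker mean, columns are centred by
#' marker mean (no variance scaling), and scores are taken from the
#' eigen-decomposition of the accession covariance. The variance explained
#' by component *k* is its eigenvalue over the eigenvalue total.
#'
#' @param gm a [slaf_geno()] with >= 2 accessions.
#' @param n_components number of components to return.
#' @return object of class `slaf_pca`: list with `scores` (tibble:
#'   accession, ecotype, PC1..PCk) and `variance_explained`.
#' @export
pca_genotypes <- function(gm, n_components = 3L) {
  stopifnot(inherits(gm, "slaf_geno"))
  d <- gm$dosage
  if (nrow(d) < 2) abort_slaf("need >= 2 accessions")
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  x <- d
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  ve <- if (total > 0) ev / total else rep(0, length(ev))
  k <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble(accession = gm$samples$accession, ecotype = gm$samples$ecotype),
    scores)
  structure(list(scores = scores, variance_explained = ve,
                 n_components = k),
            class = "slaf_pca")
}

#' @export
print.slaf_pca <- function(x, ...) {
  cat("<slaf_pca> first components explain ",
      paste(sprintf("%.2f%%", 100 * head(x$variance_explained, x$n_components)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
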