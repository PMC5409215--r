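#' Admixture-model ancestry estimation by EM
#'
#' Fits the unsupervised admixture model: accession *i*'s genotype at
#' marker *l* is Binomial(2, `p_il`) with `p_il = sum_k q_ik f_kl`, where
#' `q` are per-accession ancestry proportions over `k` ancestral groups
#' and `f` the ancestral allele frequencies. Maximum-likelihood estimates
#' are found by plain EM over the allele-origin latent variables (the same
#' stationary points as quasi-Newton accelerations of this likelihood);
#' missing genotypes are skipped. The log-likelihood is non-decreasing
#' across iterations.
#'
#' Initialisation: `q` rows from a symmetric Dirichlet(1); `f` from the
#' observed allele frequencies jittered by seeded uniform (+/- 0.05),
#' clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param gm a [slaf_geno()].
#' @param k number of ancestral groups, `1 <= k <= n_accessions`.
#' @param seed integer seed for the initialisation.
#' @param tol relative log-likelihood change below which EM stops.
#' @param max_iter iteration cap.
#' @return object of class `slaf_admixture`: list with `q` (accession x k),
#'   `f` (k x marker), `loglik`, `loglik_trace`, `n_iter`, `k`, `seed`.
#' @export
admixture_em <- function(gm, k, seed = 1L, tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(gm, "slaf_geno"))
  n <- n_accessions(gm)
  if (k < 1 || k > n) abort_slaf("k must be in [1, n_accessions]")
  d <- gm$dosage
  called <- colSums(!is.na(d))
  p_obs <- colSums(d, na.rm = TRUE) / (2 * pmax(called, 1))
  if (all(p_obs %in% c(0, 1))) abort_slaf("need >= 1 polymorphic marker")
  eps <- 1e-6
  set.seed(derive_seed(seed, paste0("admixture_k", k)))
  q0 <- matrix(stats::rgamma(n * k, 1), nrow = n)
  q0 <- q0 / rowSums(q0)
  f0 <- matrix(rep(p_obs, each = k) + runif(k * length(p_obs), -0.05, 0.05),
               nrow = k)
  f0 <- pmin(pmax(f0, eps), 1 - eps)
  g <- d
  g[is.na(g)] <- -1L
  fit <- .em_admixture(g, q0, f0, tol, as.integer(max_iter), eps)
  dimnames(fit$q) <- list(gm$samples$accession, paste0("Q", seq_len(k)))
  dimnames(fit$f) <- list(paste0("Q", seq_len(k)), gm$markers$marker)
  structure(
    list(q = fit$q, f = fit$f,
         loglik = fit$loglik_trace[length(fit$loglik_trace)],
         loglik_trace = fit$loglik_trace, n_iter = fit$n_iter,
         k = as.integer(k), seed = as.integer(seed)),
    class = "slaf_admixture")
}

#' @export
print.slaf_admixture <- function(x, ...) {
  cat("<slaf_admixture> K = ", x$k, ", loglik = ", format(x$loglik),
      " after ", x$n_iter, " EM iterations\n", sep = "")
  invisible(x)
}

#' Choose the number of ancestral groups by cross-validation
#'
#' Non-missing genotype entries are partitioned into `folds` folds by
#' seeded assignment; for each fold the entries are masked, the model is
#' fitted on the remainder for every K in `k_range`, and the masked
#' entries are predicted as `2 * p_il`. The held-out error is the mean of
#' `(g - 2 p)^2 / 2` over masked entries, averaged over folds; the chosen
#' K is the arg-min (ties going to the smaller K), following the standard
#' genotype-masking cross-validation for admixture models.
#'
#' @param gm a [slaf_geno()].
#' @param k_range candidate K values (default 1..10).
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling fold assignment and fits.
#' @param tol,max_iter EM settings passed to [admixture_em()].
#' @return object of class `slaf_cv`: tibble with `k`, `cv_error`, and
#'   attribute `best_k`.
#' @export
choose_k <- function(gm, k_range = 1:10, folds = 5L, seed = 1L,
                     tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(gm, "slaf_geno"))
  d <- gm$dosage
  nm_idx <- which(!is.na(d))
  if (length(nm_idx) < folds) abort_slaf("not enough non-missing entries")
  set.seed(derive_seed(seed, "cv_folds"))
  fold_of <- sample(rep(seq_len(folds), length.out = length(nm_idx)))
  err <- matrix(NA_real_, nrow = length(k_range), ncol = folds)
  for (fo in seq_len(folds)) {
    mask <- nm_idx[fold_of == fo]
    if (!length(mask)) abort_slaf("a fold has zero masked entries")
    d_train <- d
    d_train[mask] <- NA_integer_
    gm_train <- gm
    gm_train$dosage <- d_train
    for (ki in seq_along(k_range)) {
      fit <- admixture_em(gm_train, k_range[ki],
                          seed = derive_seed(seed, paste0("cv_f", fo)),
                          tol = tol, max_iter = max_iter)
      p_hat <- fit$q %*% fit$f
      err[ki, fo] <- mean((d[mask] - 2 * p_hat[mask])^2 / 2)
    }
  }
  curve <- tibble(k = as.integer(k_range), cv_error = rowMeans(err))
  best <- curve$k[which.min(curve$cv_error)]
  structure(curve, best_k = best, class = c("slaf_cv", class(curve)))
}

#' Best K of a cross-validation curve
#' @param cv a `slaf_cv` from [choose_k()].
#' @return integer K at the error minimum.
#' @export
best_k <- function(cv) attr(cv, "best_k")

#' Match ancestry columns between two fits
#'
#' Admixture fits are identified only up to a permutation of group labels.
#' Finds the column permutation of `q_est` minimising the mean absolute
#' difference to `q_ref` (exhaustive over permutations, so intended for
#' small K) and returns `q_est` with its columns permuted accordingly.
#'
#' @param q_est,q_ref accession x K ancestry matrices.
#' @return the permuted `q_est`.
#' @export
match_columns <- function(q_est, q_ref) {
  K <- ncol(q_est)
  stopifnot(ncol(q_ref) == K, K <= 8)
  perms <- permutations_of(K)
  costs <- vapply(perms, function(p) mean(abs(q_est[, p] - q_ref)), numeric(1))
  q_est[, perms[[which.min(costs)]], drop = FALSE]
}

# internal: all permutations of 1..K
permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (p in permutations_of(K - 1L)) {
      rest <- setdiff(seq_len(K), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
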