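#' Tidy methods for slafpop results
#'
#' Broom-style accessors. `tidy()` returns one row per elementary result
#' (ancestry proportion, pair, component); `glance()` returns a one-row
#' model summary.
#'
#' @param x a fitted slafpop object.
#' @param ... unused.
#' @return a tibble.
#' @name slafpop-tidiers
NULL

#' @rdname slafpop-tidiers
#' @export
tidy.slaf_admixture <- function(x, ...) {
  as_tibble(x$q, rownames = "accession") |>
    tidyr::pivot_longer(-"accession", names_to = "group",
                        values_to = "ancestry")
}

#' @rdname slafpop-tidiers
#' @export
glance.slaf_admixture <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, n_iter = x$n_iter, seed = x$seed)
}

#' @rdname slafpop-tidiers
#' @export
tidy.slaf_cv <- function(x, ...) {
  tibble(k = x$k, cv_error = x$cv_error)
}

#' @rdname slafpop-tidiers
#' @export
glance.slaf_cv <- function(x, ...) {
  tibble(best_k = best_k(x), min_cv_error = min(x$cv_error),
         n_k = nrow(x))
}

#' @rdname slafpop-tidiers
#' @export
tidy.slaf_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "component",
                        values_to = "score")
}

#' @rdname slafpop-tidiers
#' @export
glance.slaf_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_len(x$n_components)),
         variance_explained = x$variance_explained[seq_len(x$n_components)])
}

#' @rdname slafpop-tidiers
#' @export
tidy.slaf_kinship <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(accession_i = rownames(m)[idx[, 1]],
         accession_j = colnames(m)[idx[, 2]],
         kinship = m[idx])
}

#' @rdname slafpop-tidiers
#' @export
tidy.slaf_decay <- function(x, ...) {
  x$bins
}

#' @rdname slafpop-tidiers
#' @export
glance.slaf_decay <- function(x, ...) {
  tibble(decay_bp = x$decay_distance, threshold = x$threshold,
         n_bins = nrow(x$bins), n_pairs = sum(x$bins$n_pairs))
}
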