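#' Genotype panel container
#'
#' A `slaf_geno` holds a panel of diploid biallelic genotypes as
#' alternate-allele dosages: an accession x marker integer matrix with
#' entries 0, 1, 2 or `NA` (missing), a marker table sorted by chromosome
#' and 1-based position, and a sample table carrying the ecotype label
#' (winter / semi-winter / spring) and origin of each accession.
#'
#' @param dosage integer matrix, accessions in rows, markers in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param markers data frame with `marker`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param samples data frame with `accession` and optionally `ecotype`,
#'   `origin`.
#' @return an object of class `slaf_geno`.
#' @export
slaf_geno <- function(dosage, markers, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  markers <- as_tibble(markers)
  samples <- as_tibble(samples)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(markers)),
            "accession" %in% names(samples))
  if (!"ref" %in% names(markers)) markers$ref <- "A"
  if (!"alt" %in% names(markers)) markers$alt <- "G"
  if (!"ecotype" %in% names(samples)) samples$ecotype <- NA_character_
  if (!"origin" %in% names(samples)) samples$origin <- NA_character_
  if (nrow(samples) != nrow(dosage) || nrow(markers) != ncol(dosage)) {
    abort_slaf("dosage dimensions do not match marker/sample tables")
  }
  if (any(markers$pos < 1)) abort_slaf("marker positions must be >= 1")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) abort_slaf("dosages must be 0, 1, 2 or NA")
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, ]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(dosage) <- samples$accession
  colnames(dosage) <- markers$marker
  structure(list(dosage = dosage, markers = markers, samples = samples),
            class = "slaf_geno")
}

#' @export
print.slaf_geno <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat("<slaf_geno> ", nrow(x$dosage), " accessions x ", ncol(x$dosage),
      " markers (", sprintf("%.1f%%", 100 * miss), " missing)\n", sep = "")
  invisible(x)
}

#' @rdname slaf_geno
#' @param gm a `slaf_geno`.
#' @export
n_accessions <- function(gm) nrow(gm$dosage)

#' @rdname slaf_geno
#' @export
n_markers <- function(gm) ncol(gm$dosage)

#' @rdname slaf_geno
#' @export
marker_table <- function(gm) gm$markers

#' @rdname slaf_geno
#' @export
sample_table <- function(gm) gm$samples

# internal: subset by logical/integer marker index, preserving order
subset_markers <- function(gm, idx) {
  slaf_geno(gm$dosage[, idx, drop = FALSE], gm$markers[idx, ], gm$samples)
}

# internal: subset accessions
subset_samples <- function(gm, idx) {
  slaf_geno(gm$dosage[idx, , drop = FALSE], gm$markers, gm$samples[idx, ])
}
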