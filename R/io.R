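#' Read a genotype panel from VCF
#'
#' Parses a VCF (v4.2) of biallelic diploid SNPs into a [slaf_geno()].
#' GT values map 0/0 -> 0, 0/1 -> 1, 1/1 -> 2 and ./. -> missing; phased
#' separators are accepted and treated as unphased. Multiallelic records
#' are dropped with a message reporting the count.
#'
#' @param path VCF path (plain or gzipped).
#' @param metadata optional path to a tab-separated sample table with
#'   columns `accession`, `ecotype`, `origin`, matched by accession id.
#' @return a [slaf_geno()].
#' @export
read_vcf <- function(path, metadata = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    message("dropped ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gtc <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gtc), ncol = ncol(gtc))
  dos[gtc == "0/0"] <- 0L
  dos[gtc %in% c("0/1", "1/0")] <- 1L
  dos[gtc == "1/1"] <- 2L
  markers <- tibble(
    marker = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT)
  samples <- tibble(accession = colnames(gtc))
  if (!is.null(metadata)) {
    meta <- as_tibble(read.delim(metadata, stringsAsFactors = FALSE))
    samples <- left_join(samples, meta, by = "accession")
  }
  slaf_geno(t(dos), markers, samples)
}

#' Write a genotype panel as VCF v4.2
#'
#' Minimal GT-only records, 1-based positions, "./." for missing.
#'
#' @param gm a [slaf_geno()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "slaf_geno"))
  mk <- gm$markers
  gt_code <- c("0/0", "0/1", "1/1")
  d <- t(gm$dosage)
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  for (v in 0:2) gt[!is.na(d) & d == v] <- gt_code[v + 1]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=slafpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$accession), collapse = "\t"))
  body <- paste(mk$chrom, mk$pos, mk$marker, mk$ref, mk$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample metadata table
#'
#' Tab-separated `accession`, `ecotype`, `origin`.
#' @param gm a [slaf_geno()].
#' @param path output path.
#' @export
write_sample_metadata <- function(gm, path) {
  write.table(gm$samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published reference summaries of a B. napus SLAF panel
#'
#' Worked-example inputs shipped with the package: per-chromosome
#' summaries from a published *Brassica napus* SLAF-seq diversity panel on
#' the Darmor-bzh reference (19 chromosomes, 10 A + 9 C). Three tables are
#' available: `"tags"` (chromosome lengths, predicted SLAF tag counts and
#' average spacing), `"snp_density"` (filtered SNP counts, surveyed
#' lengths, SNP/gene densities per 100 kb and mean pairwise r2) and
#' `"hap_blocks"` (haplotype block counts, total block length and genome
#' frequency). They drive the worked examples and the package's
#' arithmetic checks.
#'
#' @param name one of `"tags"`, `"snp_density"`, `"hap_blocks"`.
#' @return a tibble.
#' @export
ref_panel_table <- function(name = c("tags", "snp_density", "hap_blocks")) {
  name <- match.arg(name)
  file <- c(tags = "bnapus_slaf_tags.tsv",
            snp_density = "bnapus_snp_density.tsv",
            hap_blocks = "bnapus_hap_blocks.tsv")[[name]]
  path <- system.file("extdata", file, package = "slafpop", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
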