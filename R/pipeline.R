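#' Pipeline configuration
#'
#' Bundles every threshold the pipeline applies, with the standard
#' defaults: RsaI + HaeIII digestion, 314-414 bp tag window, 100-kb
#' density windows, top 1% SNP-rich windows, MAF > 0.05 and
#' integrity > 0.8 filters, hotspot threshold 0.8, LD decay threshold
#' r2 = 0.1 with 1-kb bins, K from 1 to 10 with 5-fold cross-validation.
#' A seed is mandatory: every stochastic stage derives its own seed from
#' it via [derive_seed()].
#'
#' @param enzymes enzyme names or [restriction_enzyme()] objects.
#' @param min_len,max_len tag size-selection bounds (bp).
#' @param window_bp density window width (bp).
#' @param top_fraction SNP-rich window fraction.
#' @param maf_min,integrity_min marker filters.
#' @param hotspot_threshold mutation-frequency threshold.
#' @param ld_threshold,ld_bin_bp,ld_max_distance_bp decay settings.
#' @param k_range,cv_folds admixture settings.
#' @param n_components PCA components.
#' @param seed integer pipeline seed.
#' @param out_dir output directory.
#' @return a `slaf_config` list.
#' @export
slaf_config <- function(enzymes = list("RsaI", "HaeIII"),
                        min_len = 314L, max_len = 414L,
                        window_bp = 100000L, top_fraction = 0.01,
                        maf_min = 0.05, integrity_min = 0.8,
                        hotspot_threshold = 0.8,
                        ld_threshold = 0.1, ld_bin_bp = 1000L,
                        ld_max_distance_bp = 500000L,
                        k_range = 1:10, cv_folds = 5L,
                        n_components = 3L,
                        seed = 1L, out_dir = tempfile("slafpop_run_")) {
  check_fraction(top_fraction, "top_fraction")
  check_fraction(maf_min, "maf_min")
  check_fraction(integrity_min, "integrity_min")
  check_fraction(hotspot_threshold, "hotspot_threshold")
  check_fraction(ld_threshold, "ld_threshold")
  if (min_len > max_len) abort_slaf("min_len must be <= max_len")
  if (window_bp <= 0 || ld_bin_bp <= 0) abort_slaf("window widths must be > 0")
  if (is.null(seed)) abort_slaf("a seed is mandatory")
  structure(
    list(enzymes = enzymes, min_len = min_len, max_len = max_len,
         window_bp = window_bp, top_fraction = top_fraction,
         maf_min = maf_min, integrity_min = integrity_min,
         hotspot_threshold = hotspot_threshold,
         ld_threshold = ld_threshold, ld_bin_bp = ld_bin_bp,
         ld_max_distance_bp = ld_max_distance_bp,
         k_range = k_range, cv_folds = cv_folds,
         n_components = n_components,
         seed = as.integer(seed), out_dir = out_dir),
    class = "slaf_config")
}

#' Run the full analysis pipeline
#'
#' Executes digestion -> SNP statistics -> relatedness -> ancestry ->
#' LD/blocks on a genome and genotype panel, writing every stage's outputs
#' and a JSON provenance record (inputs, parameters, seed, package
#' version) under `config$out_dir`. Genome and panel may be given as
#' objects or as FASTA / VCF paths; deterministic stages are bit-identical
#' across reruns with the same config.
#'
#' @param config a [slaf_config()].
#' @param genome a `slaf_genome` or FASTA path.
#' @param gm a [slaf_geno()] or VCF path.
#' @return (invisibly) a list of stage results and output paths.
#' @export
run_pipeline <- function(config, genome, gm) {
  stopifnot(inherits(config, "slaf_config"))
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(gm)) gm <- read_vcf(gm)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(out_dir = config$out_dir)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort_slaf("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    res
  }
  pth <- function(...) file.path(config$out_dir, ...)
  info <- genome_info(genome)

  # digest
  out$tags <- stage("digest", {
    frags <- digest_genome(genome, config$enzymes)
    tags <- select_tags(frags, config$min_len, config$max_len)
    write_tags_bed(tags, pth("tags.bed"))
    write.table(tag_spacing(tags, info), pth("tag_spacing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tags
  })
  out$scheme <- stage("digest", {
    rep <- evaluate_scheme(out$tags, genome, config$window_bp)
    write.table(rep[, setdiff(names(rep), "per_chrom")],
                pth("scheme_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rep
  })

  # snp stats
  out$filtered <- stage("snp_stats", {
    filter_markers(gm, config$maf_min, config$integrity_min)
  })
  out$stats <- stage("snp_stats", {
    st <- marker_stats(out$filtered)
    write.table(st, pth("marker_stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    st
  })
  out$hotspots <- stage("snp_stats", {
    hs <- call_hotspots(out$filtered, config$hotspot_threshold)
    write.table(data.frame(hs$chrom, hs$pos - 1L, hs$pos, hs$marker),
                pth("hotspots.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    hs
  })
  out$windows <- stage("snp_stats", {
    windowed_snp_counts(out$filtered, info, config$window_bp)
  })
  out$rich_regions <- stage("snp_stats", {
    rr <- snp_rich_regions(out$windows, config$top_fraction)
    write.table(data.frame(rr$chrom, rr$start, rr$end, rr$snp_count),
                pth("rich_regions.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    rr
  })

  # relatedness
  out$kinship <- stage("relatedness", {
    km <- kinship_matrix(out$filtered)
    write.table(unclass(km), pth("kinship.tsv"), sep = "\t", quote = FALSE)
    km
  })
  out$tree <- stage("relatedness", {
    pd <- p_distance(out$filtered)
    tr <- neighbor_joining(pd)
    ape::write.tree(tr, pth("nj_tree.nwk"))
    tr
  })
  out$pca <- stage("relatedness", {
    pc <- pca_genotypes(out$filtered, config$n_components)
    write.table(pc$scores, pth("pca_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pc
  })

  # structure
  out$cv <- stage("structure", {
    choose_k(out$filtered, config$k_range, config$cv_folds,
             seed = derive_seed(config$seed, "structure"))
  })
  out$admixture <- stage("structure", {
    fit <- admixture_em(out$filtered, best_k(out$cv),
                        seed = derive_seed(config$seed, "structure"))
    write.table(fit$q, pth("ancestry_q.tsv"), sep = "\t", quote = FALSE)
    write.table(fit$f, pth("ancestry_f.tsv"), sep = "\t", quote = FALSE)
    fit
  })

  # ld / blocks
  out$ld_pairs <- stage("ld_blocks", {
    pr <- pairwise_r2(out$filtered, max_distance_bp = config$ld_max_distance_bp,
                      maf_min = config$maf_min)
    write.table(pr, pth("ld_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pr
  })
  out$decay <- stage("ld_blocks", {
    sc <- ld_decay_scopes(out$ld_pairs, info, config$ld_threshold,
                          config$ld_bin_bp)
    jsonlite::write_json(sc, pth("ld_decay.json"), dataframe = "rows")
    sc
  })
  out$blocks <- stage("ld_blocks", {
    bl <- gabriel_blocks(out$filtered, maf_min = config$maf_min)
    write.table(data.frame(bl$chrom, bl$start_bp - 1L, bl$end_bp),
                pth("blocks.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    summ <- block_summary(summarise_blocks(bl), info)
    write.table(summ, pth("block_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    bl
  })

  prov <- list(
    package = "slafpop",
    version = as.character(utils::packageVersion("slafpop")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    n_accessions = n_accessions(gm),
    n_markers_input = n_markers(gm),
    n_markers_filtered = n_markers(out$filtered))
  jsonlite::write_json(prov, pth("provenance.json"), auto_unbox = TRUE,
                       force = TRUE)
  invisible(out)
}
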