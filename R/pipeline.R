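# End-to-end driver: filter -> bin -> fit -> map -> GC statistics ->
# trait correlations, writing every stage as TSV into a run directory
# together with the effective configuration, a seed log and a MANIFEST.
# Two runs with the same configuration are bit-identical at the TSV level.

#' Default pipeline configuration
#'
#' @param n_bins Number of random bins.
#' @param seed Master seed (binning and any optimizer restarts).
#' @param coverage Codon coverage threshold (fraction of species, or an
#'   absolute count if >= 1).
#' @param scheme Binning scheme: \code{"random"}, \code{"gc_ranked"} or
#'   \code{"chromosome"}.
#' @param exclude_genes,exclude_species Exclusion lists.
#' @param root_freqs,optimize_freqs,conditioning Model options (see
#'   \code{\link{fit_model}}, \code{\link{map_opportunities}}).
#' @param fit_control Extra \code{\link{fit_model}} control entries.
#' @return Named list.
#' @export
pipeline_config <- function(n_bins = 2L, seed = 1L, coverage = 0.87,
                            scheme = "random",
                            exclude_genes = character(),
                            exclude_species = character(),
                            root_freqs = "free", optimize_freqs = FALSE,
                            conditioning = "parent",
                            fit_control = list()) {
  list(n_bins = n_bins, seed = seed, coverage = coverage,
       scheme = scheme, exclude_genes = exclude_genes,
       exclude_species = exclude_species, root_freqs = root_freqs,
       optimize_freqs = optimize_freqs, conditioning = conditioning,
       fit_control = fit_control)
}

.echo_config <- function(config, path) {
  flat <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.list(v)) v <- unlist(v)
    paste0(k, "\t", paste(format(v, digits = 15), collapse = ","))
  }, character(1L))
  writeLines(flat, path)
}

#' Run the full analysis pipeline
#'
#' Stages, mirroring the estimation protocol: species/gene exclusions,
#' codon coverage filtering, gene binning, per-bin model fitting and
#' substitution mapping, category rates with the GC-conservative
#' combination, per-lineage GC statistics, bin aggregation, and trait
#' correlations (Pearson and PIC). All stage outputs are TSVs in
#' \code{out_dir}; the effective configuration is echoed there, and a
#' MANIFEST records which stages completed.
#'
#' @param alignments Named list of per-gene \code{\link{codon_alignment}}s.
#' @param genes Gene metadata (\code{gene_id}, \code{mean_gc},
#'   \code{chromosome}, \code{chromosome_mb}, ...).
#' @param tree Rooted species tree (\code{phylo}).
#' @param traits Raw-scale trait table (may be \code{NULL} to skip
#'   correlations).
#' @param out_dir Output directory (created if needed).
#' @param config List from \code{\link{pipeline_config}}.
#' @return Invisibly, a list with \code{rates} (aggregated rate table),
#'   \code{gcstats} (per-bin list), \code{correlations}, \code{bins}.
#' @export
run_pipeline <- function(alignments, genes, tree, traits = NULL,
                         out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  log_lines <- c(paste0("seed\t", config$seed))
  done <- function(stage) manifest <<- c(manifest, stage)
  .echo_config(config, file.path(out_dir, "config.tsv"))

  ex <- apply_exclusions(alignments, genes,
                         exclude_genes = config$exclude_genes,
                         exclude_species = config$exclude_species)
  alignments <- lapply(ex$alignments, filter_codon_coverage,
                       min_species = config$coverage)
  keep <- vapply(alignments, `[[`, 0L, "n_codons") > 0L
  alignments <- alignments[keep]
  genes <- ex$genes[ex$genes$gene_id %in% names(alignments), ,
                    drop = FALSE]
  log_lines <- c(log_lines,
                 paste0("genes_retained\t", nrow(genes)),
                 paste0("species_retained\t",
                        length(unique(unlist(lapply(alignments, `[[`,
                                                    "species"))))))
  done("filter")

  bins <- switch(config$scheme,
                 random = make_bins(genes$gene_id, config$n_bins,
                                    config$seed),
                 gc_ranked = gc_rank_split(genes, config$n_bins),
                 chromosome = chromosome_split(genes),
                 stop("unknown binning scheme: ", config$scheme))
  .write_tsv(as.data.frame(bins), file.path(out_dir, "bins.tsv"))
  done("bin")

  fit_ctl <- utils::modifyList(
    list(root_freqs = config$root_freqs,
         optimize_freqs = config$optimize_freqs),
    config$fit_control)
  bin_ids <- unique(bins$bin)
  rate_tables <- list(); gc_tables <- list(); count_rows <- list()
  for (b in bin_ids) {
    ids <- bins$gene_id[bins$bin == b]
    concat <- concat_alignments(alignments[ids], ids)
    sub_tree <- ape::keep.tip(tree, intersect(tree$tip.label,
                                              concat$species))
    fit <- fit_model(concat, sub_tree, control = fit_ctl)
    counts <- branch_count_table(fit, conditioning = config$conditioning)
    rates <- category_rates(counts)
    g <- ancestral_gc_weights(fit)
    rates <- gc_conservative_combine(rates, g)
    gc_tables[[as.character(b)]] <- cbind(bin = b, gc_stats(fit, rates))
    rate_tables[[as.character(b)]] <- rates
    count_rows[[as.character(b)]] <- cbind(bin = b, counts)
    log_lines <- c(log_lines,
                   sprintf("bin_%s\tloglik=%.6f kappa=%.6f omega=%.6f %s",
                           b, fit$loglik, fit$model$kappa,
                           fit$model$omega, fit$convergence))
  }
  .write_tsv(do.call(rbind, count_rows), file.path(out_dir, "counts.tsv"))
  .write_tsv(do.call(rbind, lapply(names(rate_tables), function(b) {
    cbind(bin = b, rate_tables[[b]])
  })), file.path(out_dir, "rates_per_bin.tsv"))
  .write_tsv(do.call(rbind, gc_tables), file.path(out_dir, "gcstats.tsv"))
  done("fit_map")

  agg <- aggregate_bins(rate_tables)
  .write_tsv(agg, file.path(out_dir, "rates_genome_wide.tsv"))
  done("aggregate")

  correlations <- NULL
  if (!is.null(traits)) {
    correlations <- rbind(
      correlate_traits_rates(agg, traits, tree, method = "pic"),
      correlate_traits_rates(agg, traits, tree, method = "pearson"))
    .write_tsv(correlations, file.path(out_dir, "correlations.tsv"))
    done("correlate")
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  invisible(list(rates = agg, gcstats = gc_tables,
                 correlations = correlations, bins = bins))
}
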