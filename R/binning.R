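# Dataset assembly: coverage filtering, exclusions, concatenation into
# bins (random, GC-ranked, chromosome-class), and aggregation of per-bin
# or per-gene results into genome-wide lineage rates.

#' Filter codon sites by species coverage
#'
#' Keeps codon columns with a non-gap, non-ambiguous codon in at least
#' \code{min_species} species; the study-style rule (41 of 47 species)
#' generalizes to a fraction of the species count.
#'
#' @param aln A \code{\link{codon_alignment}} or a list of them.
#' @param min_species Absolute count (>= 1) or fraction (< 1) of species.
#' @return Filtered alignment(s), with attribute \code{"n_retained"}; a
#'   gene/alignment left with zero sites is dropped with a warning when a
#'   list is given, and returned empty otherwise.
#' @export
filter_codon_coverage <- function(aln, min_species = 0.87) {
  if (is.list(aln) && !inherits(aln, "codon_alignment")) {
    out <- lapply(aln, filter_codon_coverage, min_species = min_species)
    keep <- vapply(out, `[[`, 0L, "n_codons") > 0L
    if (any(!keep))
      warning(sum(!keep), " alignment(s) dropped: no retained sites")
    return(out[keep])
  }
  n_sp <- length(aln$species)
  thr <- if (min_species < 1) ceiling(min_species * n_sp)
         else as.integer(min_species)
  if (thr > n_sp) stop("coverage threshold exceeds species count")
  cov <- .colSums(!is.na(aln$states), n_sp, aln$n_codons)
  keep <- which(cov >= thr)
  dropped <- setdiff(seq_len(aln$n_codons), keep)
  aln$states <- aln$states[, keep, drop = FALSE]
  aln$n_codons <- length(keep)
  if (!is.null(aln$genes) && length(dropped)) {
    g <- aln$genes
    for (k in seq_len(nrow(g))) {
      rng <- g$start[k]:g$end[k]
      n_kept <- sum(rng %in% keep)
      g$start[k] <- if (k == 1L) 1L else g$end[k - 1L] + 1L
      g$end[k] <- g$start[k] + n_kept - 1L
    }
    aln$genes <- g
  }
  attr(aln, "n_retained") <- length(keep)
  aln
}

#' Exclude genes and species before analysis
#'
#' @param alignments Named list of per-gene \code{\link{codon_alignment}}s.
#' @param genes Gene metadata data frame with a \code{gene_id} column.
#' @param exclude_genes,exclude_species Character vectors (may be empty);
#'   unknown names are ignored with a warning.
#' @return List with filtered \code{alignments} and \code{genes}.
#' @export
apply_exclusions <- function(alignments, genes,
                             exclude_genes = character(),
                             exclude_species = character()) {
  unknown_g <- setdiff(exclude_genes, genes$gene_id)
  if (length(unknown_g))
    warning("unknown gene(s) ignored: ", paste(unknown_g, collapse = ", "))
  all_sp <- unique(unlist(lapply(alignments, `[[`, "species")))
  unknown_s <- setdiff(exclude_species, all_sp)
  if (length(unknown_s))
    warning("unknown species ignored: ",
            paste(unknown_s, collapse = ", "))
  keep <- !(genes$gene_id %in% exclude_genes)
  if (!any(keep)) stop("exclusions remove every gene")
  genes <- genes[keep, , drop = FALSE]
  alignments <- alignments[genes$gene_id]
  if (length(exclude_species)) {
    alignments <- lapply(alignments, function(a) {
      sp_keep <- setdiff(a$species, exclude_species)
      if (length(sp_keep) < 2L) stop("exclusions leave < 2 species")
      a$states <- a$states[sp_keep, , drop = FALSE]
      a$species <- sp_keep
      a
    })
  }
  list(alignments = alignments, genes = genes)
}

#' Random gene bins
#'
#' Shuffles the gene list with the given seed and deals genes round-robin
#' into \code{n_bins} bins (sizes differ by at most one).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_bins Number of bins (<= number of genes).
#' @param seed Seed making the assignment reproducible.
#' @return Data frame of class \code{bin_spec}: columns \code{bin},
#'   \code{gene_id}; attributes \code{scheme}, \code{seed}.
#' @export
make_bins <- function(gene_ids, n_bins, seed = 1L) {
  stopifnot(n_bins >= 1L, n_bins <= length(gene_ids))
  set.seed(seed)
  shuffled <- sample(gene_ids)
  spec <- data.frame(bin = rep_len(seq_len(n_bins), length(gene_ids)),
                     gene_id = shuffled)
  spec <- spec[order(spec$bin), , drop = FALSE]
  rownames(spec) <- NULL
  structure(spec, scheme = "random", seed = seed, class = c("bin_spec",
                                                            "data.frame"))
}

#' GC-ranked gene bins
#'
#' Ranks genes by cross-species mean GC and fills bins in rank order, so
#' bin 1 holds the GC-poorest genes and bin \code{n_bins} the GC-richest;
#' splitting the bins into a low and a high half separates GC-poor from
#' GC-rich genes.
#'
#' @param genes Metadata data frame with \code{gene_id} and
#'   \code{mean_gc}.
#' @param n_bins Number of bins.
#' @return A \code{bin_spec} data frame with an extra \code{gc_group}
#'   column (\code{"low"} / \code{"high"} halves of the bin order).
#' @export
gc_rank_split <- function(genes, n_bins) {
  stopifnot(n_bins >= 1L, n_bins <= nrow(genes))
  ord <- genes[order(genes$mean_gc), , drop = FALSE]
  size <- ceiling(nrow(ord) / n_bins)
  bin <- rep(seq_len(n_bins), each = size)[seq_len(nrow(ord))]
  spec <- data.frame(bin = bin, gene_id = ord$gene_id,
                     gc_group = ifelse(bin <= n_bins / 2, "low", "high"))
  rownames(spec) <- NULL
  structure(spec, scheme = "gc_ranked", class = c("bin_spec",
                                                  "data.frame"))
}

#' Chromosome-class gene bins
#'
#' Two bins: genes on microchromosomes (smaller than \code{micro_max_mb})
#' and genes on macrochromosomes (larger than \code{macro_min_mb}); genes
#' on intermediate chromosomes and on explicitly excluded chromosomes are
#' discarded.
#'
#' @param genes Metadata with \code{gene_id}, \code{chromosome_mb} and
#'   optionally \code{chromosome}.
#' @param micro_max_mb,macro_min_mb Size thresholds in Mb (defaults 16 and
#'   100).
#' @param exclude_chromosomes Chromosome labels dropped regardless of size
#'   (e.g. rearranged or unplaced entries).
#' @return A \code{bin_spec} with \code{bin} in \code{{"micro",
#'   "macro"}}.
#' @export
chromosome_split <- function(genes, micro_max_mb = 16, macro_min_mb = 100,
                             exclude_chromosomes = character()) {
  g <- genes
  if (length(exclude_chromosomes) && "chromosome" %in% names(g))
    g <- g[!(g$chromosome %in% exclude_chromosomes), , drop = FALSE]
  cls <- ifelse(g$chromosome_mb < micro_max_mb, "micro",
                ifelse(g$chromosome_mb > macro_min_mb, "macro", NA))
  spec <- data.frame(bin = cls, gene_id = g$gene_id)[!is.na(cls), ,
                                                     drop = FALSE]
  rownames(spec) <- NULL
  structure(spec, scheme = "chromosome", class = c("bin_spec",
                                                   "data.frame"))
}

#' Genome-wide rates from per-bin rate tables
#'
#' Averages dN and dS across bins per branch and category, then takes the
#' ratio of the averages (not the average of ratios). Bins where a branch
#' and category is undefined are skipped for that entry.
#'
#' @param rate_tables List of \code{\link{category_rates}} outputs (one
#'   per bin), all over the same branch set.
#' @return A rate table of the same shape with an extra \code{n_bins}
#'   column (bins contributing to each entry).
#' @export
aggregate_bins <- function(rate_tables) {
  stopifnot(length(rate_tables) >= 1L)
  all_rt <- do.call(rbind, lapply(seq_along(rate_tables), function(k) {
    rt <- rate_tables[[k]]; rt$.bin <- k; rt
  }))
  key <- interaction(all_rt$branch, all_rt$category, drop = TRUE)
  out <- do.call(rbind, lapply(split(all_rt, key), function(d) {
    ok <- !is.na(d$dN) & !is.na(d$dS)
    dN <- if (any(ok)) mean(d$dN[ok]) else NA_real_
    dS <- if (any(ok)) mean(d$dS[ok]) else NA_real_
    data.frame(branch = d$branch[1L], terminal = d$terminal[1L],
               category = d$category[1L], dN = dN, dS = dS,
               dnds = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
               defined = !is.na(dS) && dS > 0 && !is.na(dN),
               n_bins = sum(ok))
  }))
  rownames(out) <- NULL
  out
}

#' Genome-wide per-species rates from per-gene count tables
#'
#' Gene-by-gene aggregation for analyses with per-gene trees: for every
#' species and category, the summed expected counts over genes divided by
#' the summed opportunities. Genes missing a species simply do not
#' contribute to it.
#'
#' @param count_tables List of \code{\link{branch_count_table}} outputs,
#'   one per gene, with terminal branches labeled by species.
#' @return Data frame (branch = species, category, expected, opportunity,
#'   n_genes) restricted to terminal branches, suitable for
#'   \code{\link{category_rates}}.
#' @export
aggregate_genes <- function(count_tables) {
  stopifnot(length(count_tables) >= 1L)
  term <- do.call(rbind, lapply(count_tables, function(ct) {
    ct[ct$terminal, , drop = FALSE]
  }))
  key <- interaction(term$branch, term$category, drop = TRUE)
  out <- do.call(rbind, lapply(split(term, key), function(d) {
    data.frame(branch = d$branch[1L], terminal = TRUE,
               category = d$category[1L],
               expected = sum(d$expected),
               opportunity = sum(d$opportunity),
               n_genes = nrow(d))
  }))
  rownames(out) <- NULL
  out
}
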