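# Ancestral GC content, equilibrium GC (GC*), and delta-GC per lineage.
#
# Ancestral GC is read off the most-probable (argmax marginal posterior)
# ancestral codon sequence at each internal node; GC* comes from the
# mapped WS and SW substitution rates; delta-GC is their difference,
# non-synonymous rates paired with 0-fold ancestral GC and synonymous
# rates with 4-fold, the standard proxies for selected and neutral sites.

#' Most-probable ancestral codon sequences
#'
#' Argmax of the marginal posterior codon distribution per internal node
#' and site. Ties are broken by the fixed alphabetical codon ordering; the
#' number of tied sites is reported as an attribute.
#'
#' @param fit A \code{\link{codon_fit}}.
#' @return Integer matrix (internal nodes x codon sites) of codon state
#'   indices into \code{genetic_code()$codons}, with node labels as row
#'   names and attribute \code{"n_ties"}.
#' @export
ancestral_sequence <- function(fit) {
  pd <- posterior_node_distributions(fit)
  internal <- seq.int(pd$ntip + 1L, length(pd$posteriors))
  n_ties <- 0L
  m <- vapply(internal, function(v) {
    p <- pd$posteriors[[v]]
    amax <- max.col(t(p), ties.method = "first")
    mx <- p[cbind(amax, seq_len(ncol(p)))]
    n_ties <<- n_ties + sum(colSums(abs(p - rep(mx, each = 61L)) < 1e-12) > 1L)
    amax[pd$pattern_of_site]
  }, integer(length(pd$pattern_of_site)))
  seqs <- if (is.matrix(m)) t(m) else matrix(m, nrow = length(internal))
  rownames(seqs) <- pd$labels[internal]
  attr(seqs, "n_ties") <- n_ties
  seqs
}

#' GC content at degenerate sites of a codon sequence
#'
#' Fraction of G + C among the codon positions whose own codon context
#' puts them in the requested degeneracy class (0-fold: no nucleotide
#' change preserves the amino acid; 4-fold: every change does).
#'
#' @param seq Integer vector of codon state indices (NA allowed) or a
#'   character vector of codons.
#' @param class \code{"0fold"}, \code{"4fold"}, or \code{"all"} (GC over
#'   every position regardless of degeneracy).
#' @param code A \code{\link{genetic_code}}.
#' @return GC fraction in [0, 1], or NA when no position qualifies.
#' @export
gc_at_degenerate_sites <- function(seq, class = c("4fold", "0fold", "all"),
                                   code = genetic_code()) {
  class <- match.arg(class)
  if (is.character(seq)) seq <- match(toupper(seq), code$codons)
  seq <- seq[!is.na(seq)]
  if (!length(seq)) return(NA_real_)
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  strong <- matrix(cmat %in% c("G", "C"), ncol = 3L)
  use <- switch(class,
                "0fold" = code$degeneracy == 0L,
                "4fold" = code$degeneracy == 4L,
                "all" = matrix(TRUE, 61L, 3L))
  n_use <- rowSums(use)
  n_gc <- rowSums(use & strong)
  tot <- sum(n_use[seq])
  if (tot == 0) return(NA_real_)
  sum(n_gc[seq]) / tot
}

#' Equilibrium GC content (GC*) from category rates
#'
#' GC* = rate(WS) / (rate(WS) + rate(SW)), per branch, using the
#' synonymous (dS) or non-synonymous (dN) normalized rates.
#'
#' @param rates Output of \code{\link{category_rates}}.
#' @param coding \code{"syn"} or \code{"nonsyn"}.
#' @return Named numeric vector (NA where both rates are zero or
#'   undefined).
#' @export
equilibrium_gc <- function(rates, coding = c("syn", "nonsyn")) {
  coding <- match.arg(coding)
  col <- if (coding == "syn") "dS" else "dN"
  ws <- rates[rates$category == "WS", ]
  sw <- rates[rates$category == "SW", ]
  sw <- sw[match(ws$branch, sw$branch), ]
  num <- ws[[col]]
  den <- ws[[col]] + sw[[col]]
  out <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  stats::setNames(out, ws$branch)
}

#' Lineage delta-GC
#'
#' Difference between equilibrium GC implied by current substitution
#' fluxes and the ancestral GC content: positive values mean the lineage's
#' base composition is moving toward higher GC.
#'
#' @param gcstar,gc_anc Numeric vectors (recycled names checked if both
#'   named).
#' @return \code{gcstar - gc_anc}, NA where either is undefined.
#' @export
delta_gc <- function(gcstar, gc_anc) {
  if (!is.null(names(gcstar)) && !is.null(names(gc_anc)))
    gc_anc <- gc_anc[names(gcstar)]
  gcstar - gc_anc
}

#' Per-lineage GC statistics table
#'
#' For every terminal branch: ancestral GC at the parent node (over all
#' positions and at 0-fold and 4-fold degenerate sites), current tip GC at
#' 0-/4-fold sites, GC* for synonymous and non-synonymous substitutions,
#' and delta-GC (GC* minus ancestral GC; non-synonymous paired with 0-fold
#' ancestral GC, synonymous with 4-fold).
#'
#' @param fit A \code{\link{codon_fit}}.
#' @param rates Output of \code{\link{category_rates}} on the same fit.
#' @return Data frame keyed by \code{branch} (species label).
#' @export
gc_stats <- function(fit, rates) {
  struct <- fit$struct
  anc <- ancestral_sequence(fit)
  tipstates <- fit$prep$pattern_states[, fit$prep$pattern_of_site,
                                       drop = FALSE]
  gcs_syn <- equilibrium_gc(rates, "syn")
  gcs_non <- equilibrium_gc(rates, "nonsyn")
  tips <- seq_len(struct$ntip)
  parent <- struct$edge[match(tips, struct$edge[, 2L]), 1L]
  out <- lapply(tips, function(v) {
    pa_label <- struct$labels[parent[v]]
    pseq <- anc[pa_label, ]
    tseq <- tipstates[struct$tree$tip.label[v], ]
    b <- struct$labels[v]
    anc0 <- gc_at_degenerate_sites(pseq, "0fold")
    anc4 <- gc_at_degenerate_sites(pseq, "4fold")
    data.frame(branch = b,
               gc_anc_all = gc_at_degenerate_sites(pseq, "all"),
               gc_anc_0fold = anc0, gc_anc_4fold = anc4,
               gc_tip_0fold = gc_at_degenerate_sites(tseq, "0fold"),
               gc_tip_4fold = gc_at_degenerate_sites(tseq, "4fold"),
               gcstar_nonsyn = gcs_non[[b]], gcstar_syn = gcs_syn[[b]],
               dgc_nonsyn = gcs_non[[b]] - anc0,
               dgc_syn = gcs_syn[[b]] - anc4)
  })
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Ancestral GC weights for the GC-conservative combination
#'
#' GC content of the reconstructed sequence at the parent node of each
#' terminal branch, used as the SS weight in
#' \code{\link{gc_conservative_combine}}.
#'
#' @param fit A \code{\link{codon_fit}}.
#' @param positions \code{"all"} (default), \code{"4fold"} or
#'   \code{"0fold"}.
#' @return Named numeric vector keyed by species label.
#' @export
ancestral_gc_weights <- function(fit, positions = c("all", "4fold",
                                                    "0fold")) {
  positions <- match.arg(positions)
  struct <- fit$struct
  anc <- ancestral_sequence(fit)
  tips <- seq_len(struct$ntip)
  parent <- struct$edge[match(tips, struct$edge[, 2L]), 1L]
  g <- vapply(tips, function(v) {
    gc_at_degenerate_sites(anc[struct$labels[parent[v]], ], positions)
  }, numeric(1L))
  stats::setNames(g, struct$labels[tips])
}
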