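#' Codon alignment container
#'
#' Stores a species x codon-site alignment over the 61 sense-codon states.
#' Gaps and ambiguous codons (any codon containing a character outside
#' A, C, G, T) are missing data (\code{NA} states). Codon sites containing
#' an in-frame stop in any species are either masked alignment-wide
#' (default) or raise an error.
#'
#' @param sequences Named character vector of nucleotide sequences (equal
#'   lengths, divisible by 3), or a species x site matrix of codon strings.
#' @param genes Optional data frame of per-gene metadata with columns
#'   \code{gene_id}, \code{start}, \code{end} (1-based codon coordinates)
#'   and any extra columns (e.g. \code{chromosome}, \code{chromosome_mb},
#'   \code{mean_gc}).
#' @param on_stop \code{"mask"} (drop the whole codon column, with a
#'   warning) or \code{"error"}.
#' @param code A \code{\link{genetic_code}}.
#' @return An object of class \code{codon_alignment}: list with
#'   \code{states} (species x site integer matrix, 1..61 or NA),
#'   \code{species}, \code{n_codons}, \code{genes}.
#' @export
codon_alignment <- function(sequences, genes = NULL,
                            on_stop = c("mask", "error"),
                            code = genetic_code()) {
  on_stop <- match.arg(on_stop)
  if (is.matrix(sequences)) {
    codmat <- toupper(sequences)
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must be uniquely named by species")
    len <- unique(nchar(sequences))
    if (length(len) != 1L)
      stop("all sequences must have equal length")
    if (len %% 3L != 0L) {
      bad <- names(sequences)[1L]
      stop("sequence length ", len, " not divisible by 3 (", bad, ")")
    }
    codmat <- t(vapply(toupper(sequences), function(s) {
      substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
    }, character(len / 3L)))
    if (len / 3L == 1L) codmat <- matrix(codmat, ncol = 1L,
                                         dimnames = list(names(sequences)))
  }
  states <- matrix(match(codmat, code$codons), nrow(codmat), ncol(codmat),
                   dimnames = list(rownames(codmat), NULL))
  is_stop <- matrix(codmat %in% code$stops, nrow(codmat))
  # distinguish stops from gaps/ambiguity: both map to NA in `match`
  if (any(is_stop)) {
    bad_cols <- which(apply(is_stop, 2, any))
    if (on_stop == "error")
      stop("in-frame stop codon(s) at codon site(s) ",
           paste(utils::head(bad_cols, 5L), collapse = ", "))
    warning(length(bad_cols), " codon site(s) containing stops masked")
    states <- states[, -bad_cols, drop = FALSE]
    if (!is.null(genes)) genes <- .shift_genes(genes, bad_cols)
  }
  structure(list(states = states, species = rownames(codmat),
                 n_codons = ncol(states), genes = genes),
            class = "codon_alignment")
}

.shift_genes <- function(genes, dropped_cols) {
  # recompute gene start/end after dropping codon columns
  for (k in seq_len(nrow(genes))) {
    rng <- genes$start[k]:genes$end[k]
    kept <- setdiff(rng, dropped_cols)
    before <- sum(dropped_cols < genes$start[k])
    genes$start[k] <- genes$start[k] - before
    genes$end[k] <- genes$start[k] + length(kept) - 1L
  }
  genes
}

#' @exportS3Method base::print
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d species x %d codon sites\n",
              length(x$species), x$n_codons))
  if (!is.null(x$genes))
    cat(sprintf("  %d genes with metadata\n", nrow(x$genes)))
  invisible(x)
}

#' Concatenate codon alignments over a shared species set
#'
#' @param alns List of \code{\link{codon_alignment}} objects. Species sets
#'   may differ; missing species get all-gap rows.
#' @param gene_ids Optional gene identifiers (defaults to list names).
#' @return A \code{codon_alignment} with gene boundaries recorded.
#' @export
concat_alignments <- function(alns, gene_ids = names(alns)) {
  stopifnot(length(alns) >= 1L)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_along(alns))
  species <- sort(unique(unlist(lapply(alns, `[[`, "species"))))
  lens <- vapply(alns, `[[`, integer(1L), "n_codons")
  states <- matrix(NA_integer_, length(species), sum(lens),
                   dimnames = list(species, NULL))
  at <- 0L
  genes <- data.frame(gene_id = gene_ids, start = NA_integer_,
                      end = NA_integer_)
  for (k in seq_along(alns)) {
    a <- alns[[k]]
    if (lens[k] > 0L)
      states[a$species, at + seq_len(lens[k])] <- a$states
    genes$start[k] <- at + 1L
    genes$end[k] <- at + lens[k]
    at <- at + lens[k]
  }
  structure(list(states = states, species = species, n_codons = at,
                 genes = genes), class = "codon_alignment")
}

.codon_strings <- function(aln, code = genetic_code()) {
  # back to codon strings; NA -> "---"
  m <- matrix(code$codons[aln$states], nrow(aln$states),
              dimnames = dimnames(aln$states))
  m[is.na(m)] <- "---"
  m
}

#' Per-species GC content of an alignment
#'
#' Fraction of G + C among non-missing nucleotides, per species.
#' @param aln A \code{\link{codon_alignment}}.
#' @return Named numeric vector.
#' @export
alignment_gc <- function(aln) {
  code <- genetic_code()
  ngc <- vapply(strsplit(code$codons, ""),
                function(x) sum(x %in% c("G", "C")), integer(1L))
  apply(aln$states, 1L, function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) return(NA_real_)
    sum(ngc[s]) / (3 * length(s))
  })
}
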