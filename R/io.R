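# Readers and writers for the standard formats the pipeline consumes:
# FASTA / relaxed PHYLIP alignments, Newick trees (via ape), and
# tab-separated tables.

#' Read a codon alignment
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed sequential:
#'   first line "ntaxa nsites", then "name sequence" lines, whitespace
#'   inside sequences allowed).
#' @param ... Passed to \code{\link{codon_alignment}} (e.g.
#'   \code{on_stop}).
#' @return A \code{\link{codon_alignment}}.
#' @export
read_codon_alignment <- function(path, format = c("fasta", "phylip"),
                                 ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  seqs <- if (format == "fasta") .parse_fasta(lines)
          else .parse_phylip(lines)
  codon_alignment(seqs, ...)
}

.parse_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not a FASTA file: no '>' headers")
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    if (hdr[k] + 1L > ends[k]) return("")
    gsub("\\s", "", paste(lines[(hdr[k] + 1L):ends[k]], collapse = ""))
  }, character(1L))
  if (anyDuplicated(names_))
    stop("duplicate species names in FASTA")
  stats::setNames(seqs, names_)
}

.parse_phylip <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hd <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  n <- hd[1L]
  if (length(lines) < n + 1L) stop("truncated PHYLIP file")
  parts <- strsplit(trimws(lines[2L:(n + 1L)]), "\\s+")
  names_ <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""),
                 character(1L))
  if (anyDuplicated(names_)) stop("duplicate species names in PHYLIP")
  stats::setNames(seqs, names_)
}

#' Write a codon alignment as wrapped FASTA
#'
#' @param aln A \code{\link{codon_alignment}}.
#' @param path Output path.
#' @param width Line wrap (default 60 columns).
#' @export
write_codon_alignment <- function(aln, path, width = 60L) {
  m <- .codon_strings(aln)
  con <- file(path, "w"); on.exit(close(con))
  for (sp in aln$species) {
    s <- paste(m[sp, ], collapse = "")
    writeLines(paste0(">", sp), con)
    if (nchar(s))
      writeLines(substring(s, seq(1L, nchar(s), width),
                           pmin(seq(width, nchar(s) + width - 1L, width),
                                nchar(s))), con)
  }
  invisible(path)
}

#' Read a rooted tree from Newick
#'
#' Unrooted (basal trifurcation) input is accepted; the trifurcation is
#' treated as the root, which is noted in a message.
#'
#' @param path Newick file path.
#' @return An ape \code{phylo}.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ",
                                            path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path)
  if (!ape::is.rooted(tree))
    message("unrooted input: basal multifurcation used as the root")
  tree
}

#' Write a tree as Newick
#' @param tree An ape \code{phylo}.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a life-history trait table
#'
#' TSV with columns \code{species}, \code{body_mass_g},
#' \code{longevity_yr}, \code{maturity_days} (raw scale; transformation
#' happens inside the correlation functions).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_trait_table <- function(path) {
  tt <- .read_tsv(path)
  if (!"species" %in% names(tt)) stop("trait table needs 'species'")
  tt
}

#' Read a gene metadata table
#'
#' TSV with columns \code{gene_id}, \code{chromosome},
#' \code{chromosome_mb}, \code{mean_gc} and optional flags (e.g.
#' \code{z_linked}).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_gene_table <- function(path) {
  gt <- .read_tsv(path)
  if (!"gene_id" %in% names(gt)) stop("gene table needs 'gene_id'")
  gt
}
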