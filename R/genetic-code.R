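#' Universal genetic code machinery
#'
#' Builds the universal genetic code over the 61 sense codons, together with
#' all the lookup tables the codon substitution model needs: amino-acid
#' translation, the stop-codon set, per-codon per-position degeneracy classes
#' (0-, 2-, 3- and 4-fold), and the classification of every
#' single-nucleotide codon change into transition/transversion,
#' synonymous/non-synonymous and GC class (weak-to-strong WS, strong-to-weak
#' SW, strong-to-strong SS, weak-to-weak WW).
#'
#' @return An object of class \code{genetic_code}: a list with elements
#'   \item{codons}{character vector of the 61 sense codons, alphabetical}
#'   \item{aa}{named character vector, amino acid of each sense codon}
#'   \item{stops}{the three stop codons (TAA, TAG, TGA)}
#'   \item{degeneracy}{61 x 3 integer matrix; entry (i, p) is 0, 2, 3 or 4:
#'     the degeneracy class of position p of codon i}
#'   \item{single}{61 x 61 logical; TRUE where codons differ at exactly one
#'     position}
#'   \item{transition}{61 x 61 logical; single-difference pairs whose change
#'     is a transition (A<->G or C<->T)}
#'   \item{nonsyn}{61 x 61 logical; single-difference pairs changing the
#'     amino acid}
#'   \item{gc_class}{61 x 61 integer (NA off the single-difference support);
#'     1 = WS, 2 = SW, 3 = SS, 4 = WW}
#'   \item{category}{61 x 61 integer in 1..8 indexing
#'     \code{category_names()}; NA off support}
#' @export
#' @examples
#' gc <- genetic_code()
#' length(gc$codons)  # 61
genetic_code <- function() .codon_code

#' Names of the eight substitution categories
#'
#' Categories are the cross of coding class (synonymous / non-synonymous)
#' and GC class (WS, SW, SS, WW).
#' @return Character vector of length 8, e.g. \code{"syn_WS"}.
#' @export
category_names <- function() {
  as.vector(outer(c("syn", "nonsyn"), c("WS", "SW", "SS", "WW"),
                  function(a, b) paste(a, b, sep = "_")))
}

.build_code <- function() {
  nt <- c("T", "C", "A", "G")
  # NCBI standard code, first codon position slowest, base order TCAG
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  cod64 <- as.vector(t(outer(
    as.vector(t(outer(nt, nt, paste0))), nt, paste0)))
  # cod64 built first-position slowest in TCAG order; reorder below
  names(aas) <- cod64
  stops <- names(aas)[aas == "*"]
  codons <- sort(setdiff(cod64, stops))
  aa <- aas[codons]

  n <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))  # n x 3

  # degeneracy class per codon position: how many of the 4 nucleotides at
  # that position (codon context fixed) encode the same amino acid
  bases <- c("A", "C", "G", "T")
  degeneracy <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    for (p in 1:3) {
      trip <- cmat[i, ]
      same <- 0L
      for (b in bases) {
        trip[p] <- b
        alt <- paste(trip, collapse = "")
        if (!(alt %in% stops) && aas[alt] == aa[i]) same <- same + 1L
      }
      # same counts the codon itself; classes named 0-, 2-, 3-, 4-fold
      degeneracy[i, p] <- c(0L, 2L, 3L, 4L)[same]
    }
  }

  # pairwise tables over sense codons
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(cmat[, p], cmat[, p], "!=")
  single <- ndiff == 1L
  strong <- c(A = FALSE, C = TRUE, G = TRUE, T = FALSE)
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  transition <- matrix(FALSE, n, n)
  gc_class <- matrix(NA_integer_, n, n)
  for (p in 1:3) {
    dp <- outer(cmat[, p], cmat[, p], "!=") & (ndiff == 1L)
    ts <- outer(purine[cmat[, p]], purine[cmat[, p]], "==")
    transition[dp] <- ts[dp]
    s_from <- matrix(strong[cmat[, p]], n, n)
    s_to <- matrix(strong[cmat[, p]], n, n, byrow = TRUE)
    cl <- ifelse(!s_from & s_to, 1L, ifelse(s_from & !s_to, 2L,
          ifelse(s_from & s_to, 3L, 4L)))
    gc_class[dp] <- cl[dp]
  }
  nonsyn <- single & outer(aa, aa, "!=")
  category <- matrix(NA_integer_, n, n)
  category[single] <- ifelse(nonsyn[single], 1L, 0L) + 1L +
    (gc_class[single] - 1L) * 2L
  dimnames(single) <- dimnames(transition) <- dimnames(nonsyn) <-
    dimnames(gc_class) <- dimnames(category) <- list(codons, codons)
  rownames(degeneracy) <- codons

  structure(list(codons = codons, aa = aa, stops = stops,
                 degeneracy = degeneracy, single = single,
                 transition = transition, nonsyn = nonsyn,
                 gc_class = gc_class, category = category),
            class = "genetic_code")
}

.codon_code <- .build_code()

.gc_class_names <- c("WS", "SW", "SS", "WW")

#' Classify a single-nucleotide codon substitution
#'
#' Assigns a codon change to one of the eight substitution categories used
#' throughout the package: coding class (synonymous vs non-synonymous)
#' crossed with GC class of the changed nucleotide (WS = weak A/T to strong
#' G/C, SW = the reverse, SS, WW).
#'
#' @param codon_from,codon_to Codon strings over A, C, G, T.
#' @param code A \code{\link{genetic_code}} object.
#' @return A list with elements \code{gc_class} (one of "WS", "SW", "SS",
#'   "WW") and \code{coding_class} ("synonymous" or "non-synonymous"), or
#'   \code{NULL} when the codons are identical, differ at more than one
#'   position, or either is a stop codon.
#' @export
#' @examples
#' classify_substitution("AAA", "AAG")  # Lys -> Lys, A -> G: WS synonymous
classify_substitution <- function(codon_from, codon_to,
                                  code = genetic_code()) {
  codon_from <- toupper(codon_from); codon_to <- toupper(codon_to)
  ok <- function(x) nchar(x) == 3L &&
    all(strsplit(x, "")[[1]] %in% c("A", "C", "G", "T"))
  if (!ok(codon_from) || !ok(codon_to))
    stop("codons must be triplets over A, C, G, T")
  if (codon_from %in% code$stops || codon_to %in% code$stops) return(NULL)
  i <- match(codon_from, code$codons); j <- match(codon_to, code$codons)
  if (!code$single[i, j]) return(NULL)
  list(gc_class = .gc_class_names[code$gc_class[i, j]],
       coding_class = if (code$nonsyn[i, j]) "non-synonymous"
                      else "synonymous")
}
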