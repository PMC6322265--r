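# Comparative statistics: trait transformation, Pearson correlations,
# phylogenetically independent contrasts (PIC), and two-group rate
# comparisons. Contrasts come from ape's implementation of Felsenstein's
# recursion; correlations of contrasts go through the origin, the standard
# PIC convention (contrast signs are arbitrary).

#' Log10-transform a life-history trait table
#'
#' @param traits Data frame with a \code{species} column and raw-scale
#'   trait columns (e.g. body mass in g, maximum longevity in yr, age of
#'   sexual maturity in days).
#' @return Same shape, trait columns log10-transformed (non-positive
#'   values become NA with a warning).
#' @export
log10_traits <- function(traits) {
  stopifnot("species" %in% names(traits))
  for (cl in setdiff(names(traits), "species")) {
    x <- traits[[cl]]
    if (!is.numeric(x)) next
    bad <- !is.na(x) & x <= 0
    if (any(bad)) warning("non-positive values set NA in ", cl)
    x[bad] <- NA
    traits[[cl]] <- log10(x)
  }
  traits
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return List of class \code{correlation_result}: \code{R}, \code{p},
#'   \code{n}, \code{method}.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(R = unname(ct$estimate), p = ct$p.value, n = length(x),
                 method = "pearson"), class = "correlation_result")
}

#' @exportS3Method base::print
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: R = %.4f, p = %.3g, n = %d\n",
              x$method, x$R, x$p, x$n))
  invisible(x)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's (1985) standardized contrasts via \code{ape::pic}. Tips
#' without a value are pruned first; zero-length branches get a small
#' floor so the standardization is defined.
#'
#' @param tree Rooted \code{phylo}.
#' @param values Named numeric vector (names = tip labels).
#' @param bl_floor Minimum branch length substituted for zeros.
#' @return Numeric vector of n - 1 contrasts (n = tips used).
#' @export
pic_contrasts <- function(tree, values, bl_floor = 1e-8) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(values)))
  values <- values[!is.na(values)]
  drop <- setdiff(tree$tip.label, names(values))
  if (length(drop)) {
    if (length(tree$tip.label) - length(drop) < 2L)
      stop("fewer than 2 tips with values")
    tree <- ape::drop.tip(tree, drop)
  }
  miss <- setdiff(tree$tip.label, names(values))
  if (length(miss)) stop("missing values for tips: ",
                         paste(miss, collapse = ", "))
  tree$edge.length[tree$edge.length < bl_floor] <- bl_floor
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  ape::pic(values[tree$tip.label], tree)
}

# correlation of two contrast vectors through the origin
.origin_correlation <- function(cx, cy) {
  n <- length(cx)
  if (n < 2L) stop("need at least 2 contrasts")
  R <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  df <- n - 1L
  tstat <- R * sqrt(df / max(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(list(R = R, p = p, n = n + 1L, method = "pic"),
            class = "correlation_result")
}

#' Correlate lineage rates with life-history traits
#'
#' For each trait and rate category: Pearson correlation of the
#' species-level values, either directly or through phylogenetically
#' independent contrasts (both variables contrast-transformed on the same
#' pruned tree, correlation through the origin).
#'
#' @param rates A rate table (\code{\link{category_rates}} or an
#'   aggregate) restricted to terminal branches labeled by species.
#' @param traits Raw-scale trait table (see \code{\link{log10_traits}},
#'   applied internally).
#' @param tree Rooted \code{phylo} (needed for \code{method = "pic"}).
#' @param method \code{"pic"} (default) or \code{"pearson"}.
#' @param categories Rate categories to test.
#' @param value Rate column used (\code{"dnds"}, \code{"dN"} or
#'   \code{"dS"}).
#' @return Data frame: \code{trait}, \code{category}, \code{R}, \code{p},
#'   \code{n}, \code{method}.
#' @export
correlate_traits_rates <- function(rates, traits, tree = NULL,
                                   method = c("pic", "pearson"),
                                   categories = c("total", "conservative",
                                                  "SW", "WS"),
                                   value = "dnds") {
  method <- match.arg(method)
  if (method == "pic" && is.null(tree)) stop("PIC needs the tree")
  lt <- log10_traits(traits)
  trait_cols <- setdiff(names(lt), "species")
  categories <- intersect(categories, unique(rates$category))
  out <- list()
  for (cat in categories) {
    rc <- rates[rates$category == cat & rates$terminal, , drop = FALSE]
    rv <- stats::setNames(rc[[value]], rc$branch)
    for (tr in trait_cols) {
      tv <- stats::setNames(lt[[tr]], lt$species)
      common <- intersect(names(rv)[!is.na(rv)], names(tv)[!is.na(tv)])
      if (length(common) < 3L) next
      res <- if (method == "pearson") {
        pearson_correlation(rv[common], tv[common])
      } else {
        tr_sub <- ape::keep.tip(tree, common)
        cx <- pic_contrasts(tr_sub, rv[common])
        cy <- pic_contrasts(tr_sub, tv[common])
        .origin_correlation(cx, cy)
      }
      out[[paste(cat, tr)]] <- data.frame(
        trait = tr, category = cat, R = res$R, p = res$p, n = res$n,
        method = method)
    }
  }
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Two-group comparison of rates
#'
#' Relative difference of group means (as a percentage of group B's mean)
#' with a Welch unequal-variance t-test.
#'
#' @param values_a,values_b Numeric vectors (n >= 2 each; NAs dropped).
#' @return List: \code{delta_pct} = 100 (mean A - mean B) / mean B,
#'   \code{t}, \code{p}, \code{n_a}, \code{n_b}.
#' @export
group_difference <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(delta_pct = 100 * (mean(values_a) - mean(values_b)) /
         mean(values_b),
       t = unname(tt$statistic), p = tt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}
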