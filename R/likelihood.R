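# Phylogenetic likelihood under the non-stationary YN98 model.
#
# The engine works on site patterns: identical alignment columns are
# collapsed and weighted. Partial likelihoods are rescaled per node
# (column sums) with the log of the scaling accumulated per pattern, the
# standard protection against underflow on long alignments.

.tree_struct <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode_total <- ntip + tr$Nnode
  root <- ntip + 1L
  labels <- character(nnode_total)
  labels[seq_len(ntip)] <- tr$tip.label
  if (!is.null(tr$node.label) && all(nzchar(tr$node.label))) {
    labels[(ntip + 1L):nnode_total] <- tr$node.label
  } else {
    labels[(ntip + 1L):nnode_total] <- paste0("N", (ntip + 1L):nnode_total)
  }
  children_edges <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  internal_postorder <- unique(tr$edge[, 1L])
  list(tree = tr, ntip = ntip, nnode_total = nnode_total, root = root,
       edge = tr$edge, n_edges = nrow(tr$edge),
       edge_length = tr$edge.length, labels = labels,
       children_edges = children_edges,
       internal_postorder = internal_postorder)
}

.prepare_data <- function(aln, struct) {
  sp <- struct$tree$tip.label
  missing <- setdiff(sp, aln$species)
  if (length(missing))
    stop("species in tree but not alignment: ",
         paste(missing, collapse = ", "))
  states <- aln$states[sp, , drop = FALSE]
  key <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  pattern_of_site <- match(key, key[upat])
  pat <- states[, upat, drop = FALSE]
  weights <- tabulate(pattern_of_site, nbins = ncol(pat))
  npat <- ncol(pat)
  tips <- vector("list", struct$ntip)
  for (i in seq_len(struct$ntip)) {
    m <- matrix(0, 61L, npat)
    s <- pat[i, ]
    obs <- which(!is.na(s))
    m[cbind(s[obs], obs)] <- 1
    if (length(obs) < npat) m[, setdiff(seq_len(npat), obs)] <- 1
    tips[[i]] <- m
  }
  list(tips = tips, weights = weights, npat = npat,
       pattern_of_site = pattern_of_site, pattern_states = pat)
}

.edge_P <- function(dec, struct) {
  lapply(struct$edge_length, function(t) .transition_prob(dec, t))
}

# Upward (Felsenstein) pass. Returns per-node partials `up`, per-edge
# contributions C[[e]] = P_e L_child (rescaled), per-edge scale vectors,
# and the per-pattern accumulated log scale.
.up_pass <- function(struct, prep, Plist) {
  up <- vector("list", struct$nnode_total)
  C <- vector("list", struct$n_edges)
  sc <- vector("list", struct$n_edges)
  logsc <- numeric(prep$npat)
  for (e in seq_len(struct$n_edges)) {
    child <- struct$edge[e, 2L]
    Lc <- if (child <= struct$ntip) prep$tips[[child]] else up[[child]]
    Ce <- Plist[[e]] %*% Lc
    s <- .colSums(Ce, 61L, prep$npat)
    s[s <= 0] <- .Machine$double.xmin
    Ce <- Ce * rep(1 / s, each = 61L)
    logsc <- logsc + log(s)
    C[[e]] <- Ce
    sc[[e]] <- s
    p <- struct$edge[e, 1L]
    up[[p]] <- if (is.null(up[[p]])) Ce else up[[p]] * Ce
  }
  list(up = up, C = C, sc = sc, logsc = logsc)
}

.root_loglik <- function(struct, prep, pass, rho) {
  L <- .colSums(rho * pass$up[[struct$root]], 61L, prep$npat)
  sum(prep$weights * (log(L) + pass$logsc))
}

# Downward pass: outer partials O[[node]] (probability of all data outside
# the node's subtree, given the node's state, root frequencies included)
# and per-edge top partials H[[e]] = O[parent] * (sibling contributions).
# Columns are rescaled freely; only per-pattern ratios are used downstream.
.down_pass <- function(struct, prep, Plist, pass, rho) {
  O <- vector("list", struct$nnode_total)
  H <- vector("list", struct$n_edges)
  O[[struct$root]] <- matrix(rho, 61L, prep$npat)
  for (u in rev(struct$internal_postorder)) {
    es <- struct$children_edges[[as.character(u)]]
    for (e in es) {
      h <- O[[u]]
      for (e2 in setdiff(es, e)) h <- h * pass$C[[e2]]
      H[[e]] <- h
      v <- struct$edge[e, 2L]
      Ov <- crossprod(Plist[[e]], h)
      s <- .colSums(Ov, 61L, prep$npat)
      s[s <= 0] <- .Machine$double.xmin
      O[[v]] <- Ov * rep(1 / s, each = 61L)
    }
  }
  list(O = O, H = H)
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein-pruning log-likelihood under a (possibly non-stationary)
#' YN98 model: root partials are weighted by the model's root codon
#' frequencies, which need not equal the process equilibrium. Gaps and
#' ambiguous codons are missing data (partial vectors of ones); an all-gap
#' column contributes exactly zero.
#'
#' @param aln A \code{\link{codon_alignment}}.
#' @param tree A rooted \code{phylo} tree with branch lengths in expected
#'   substitutions per codon site; tip labels must match alignment species.
#' @param model A \code{\link{yn98_model}}.
#' @return The log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  struct <- .tree_struct(tree)
  prep <- .prepare_data(aln, struct)
  dec <- .decompose_generator(model$Q, model$pi)
  Plist <- .edge_P(dec, struct)
  pass <- .up_pass(struct, prep, Plist)
  ll <- .root_loglik(struct, prep, pass, model$root_freqs)
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Marginal posterior state distributions at every node
#'
#' Combines the upward and downward passes under the fitted non-stationary
#' model to give, for every node and site, the marginal posterior
#' probability of each of the 61 codon states given the tip data.
#'
#' @param fit A \code{\link{codon_fit}}.
#' @return A list with \code{posteriors} (list over nodes of 61 x
#'   n-patterns matrices, columns summing to 1), \code{pattern_of_site}
#'   (maps alignment sites to pattern columns), \code{labels} (node
#'   labels), \code{ntip}, and \code{root}.
#' @export
posterior_node_distributions <- function(fit) {
  stopifnot(inherits(fit, "codon_fit"))
  struct <- fit$struct; prep <- fit$prep
  dec <- .decompose_generator(fit$model$Q, fit$model$pi)
  Plist <- .edge_P(dec, struct)
  pass <- .up_pass(struct, prep, Plist)
  down <- .down_pass(struct, prep, Plist, pass, fit$model$root_freqs)
  post <- vector("list", struct$nnode_total)
  for (v in seq_len(struct$nnode_total)) {
    inner <- if (v <= struct$ntip) prep$tips[[v]] else pass$up[[v]]
    p <- down$O[[v]] * inner
    s <- .colSums(p, 61L, prep$npat)
    post[[v]] <- p * rep(1 / s, each = 61L)
  }
  names(post) <- struct$labels
  list(posteriors = post, pattern_of_site = prep$pattern_of_site,
       labels = struct$labels, ntip = struct$ntip, root = struct$root)
}
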