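# Event-based simulator for codon sequence evolution with branch-specific
# selection (omega) and GC-biased gene conversion (gamma), plus the
# trait tables and gene sets the downstream pipeline consumes. Simulation
# is exact (Gillespie per site), and every substitution event is logged,
# so realized per-branch category counts are exact oracles for the
# analytic substitution mapping.

#' Tilt a codon generator for GC-biased gene conversion
#'
#' Multiplies every weak-to-strong rate by \code{gamma} and every
#' strong-to-weak rate by \code{1/gamma}, leaving GC-conservative rates
#' untouched; the diagonal is recomputed. The matrix is deliberately not
#' rescaled: gBGC changes substitution fluxes, not the definition of the
#' clock.
#'
#' @param Q A 61 x 61 codon rate generator.
#' @param gamma gBGC strength (> 0; 1 recovers \code{Q} exactly).
#' @param code A \code{\link{genetic_code}}.
#' @return Tilted generator.
#' @export
gbgc_tilt <- function(Q, gamma, code = genetic_code()) {
  stopifnot(gamma > 0)
  ws <- !is.na(code$gc_class) & code$gc_class == 1L
  sw <- !is.na(code$gc_class) & code$gc_class == 2L
  Qt <- Q
  diag(Qt) <- 0
  Qt[ws] <- Qt[ws] * gamma
  Qt[sw] <- Qt[sw] / gamma
  diag(Qt) <- -rowSums(Qt)
  attr(Qt, "scale") <- attr(Q, "scale")
  Qt
}

# Kimura relative fixation rate for scaled coefficient x: x / (1 - e^-x),
# continuous at 0 (value 1)
.fix_rate <- function(x) ifelse(abs(x) < 1e-8, 1 + x / 2, x / (1 - exp(-x)))

# scaled selection coefficient S solving fix_rate(S) = omega
.omega_to_s <- function(omega) {
  if (omega == 1) return(0)
  stats::uniroot(function(s) .fix_rate(s) - omega, c(-500, 500),
                 tol = 1e-12)$root
}

# Branch generator with gBGC acting through fixation probabilities.
# The branch's omega is read as the relative fixation rate of a
# non-synonymous mutation with scaled selection coefficient S
# (fix_rate(S) = omega); gBGC adds a conversion coefficient +B to every
# W->S mutation and -B to every S->W mutation. Synonymous WS/SW rates are
# multiplied by fix_rate(+-B); non-synonymous WS/SW rates by
# fix_rate(S +- B) / fix_rate(S). GC-conservative rates are untouched.
# This nonlinearity is what lets gBGC distort dN/dS: the boost is
# proportionally larger for deleterious mutations than for neutral ones.
.gbgc_branch_generator <- function(kappa, omega, pi, B,
                                   code = genetic_code()) {
  Q <- build_yn98_matrix(kappa, omega, pi, code)
  if (B == 0) return(Q)
  S <- .omega_to_s(omega)
  ws <- !is.na(code$gc_class) & code$gc_class == 1L
  sw <- !is.na(code$gc_class) & code$gc_class == 2L
  ns <- code$nonsyn
  diag(Q) <- 0
  Q[ws & !ns] <- Q[ws & !ns] * .fix_rate(B)
  Q[sw & !ns] <- Q[sw & !ns] * .fix_rate(-B)
  Q[ws & ns] <- Q[ws & ns] * .fix_rate(S + B) / .fix_rate(S)
  Q[sw & ns] <- Q[sw & ns] * .fix_rate(S - B) / .fix_rate(S)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Map a population-genetic gBGC coefficient to the simulator's tilt
#'
#' Convenience for users thinking in terms of a scaled conversion
#' coefficient B: returns \code{gamma = exp(B / 2)}, which reproduces the
#' WS/SW flux ratio \code{exp(B)} of the fixation-bias formulation while
#' keeping GC-conservative rates fixed.
#'
#' @param B Scaled gBGC coefficient (0 = no gBGC).
#' @return \code{gamma} for \code{\link{gbgc_tilt}}.
#' @export
b_to_gamma <- function(B) exp(B / 2)

#' Simulation configuration
#'
#' @param tree Rooted \code{phylo} with branch lengths (expected
#'   substitutions per codon site under the untilted process).
#' @param kappa Transition/transversion ratio.
#' @param omega Non-synonymous/synonymous ratio: a scalar, or a named
#'   vector keyed by child-node label (tips by species name, internal
#'   nodes by their label) for branch-specific selection.
#' @param gamma gBGC strength per branch, scalar or named vector as for
#'   \code{omega}; 1 means no gBGC. Internally mapped to the scaled
#'   conversion coefficient \code{B = 2 log(gamma)} (the inverse of
#'   \code{\link{b_to_gamma}}), which enters the branch generator through
#'   Kimura fixation probabilities: synonymous WS/SW mutation rates are
#'   multiplied by the relative fixation rate of a mutation with scaled
#'   coefficient +B/-B, and non-synonymous ones by the rate for S +- B
#'   relative to S, where S is the deleterious coefficient implied by the
#'   branch's omega. GC-conservative rates are unaffected.
#' @param theta 3 x 4 process nucleotide frequencies (default uniform).
#' @param rho Root F3X4 frequencies (default \code{theta}: root at the
#'   process equilibrium).
#' @param n_codons Alignment length in codons.
#' @param seed Master seed; every stochastic step derives from it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(tree, kappa = 2, omega = 0.2, gamma = 1,
                       theta = matrix(0.25, 3, 4), rho = theta,
                       n_codons = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), all(omega >= 0), all(gamma > 0),
            n_codons >= 1L)
  structure(list(tree = tree, kappa = kappa, omega = omega,
                 gamma = gamma, theta = .as_theta(theta),
                 rho = .as_theta(rho), n_codons = as.integer(n_codons),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.branch_param <- function(x, labels) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, length(labels)), labels))
  if (is.null(names(x))) stop("per-branch parameters must be named")
  miss <- setdiff(labels, names(x))
  if (length(miss)) stop("missing per-branch parameter for: ",
                         paste(miss, collapse = ", "))
  x[labels]
}

# Gillespie simulation of one branch; returns the child sequence and the
# event log (site, absolute time on the branch, from, to states)
.sim_branch <- function(seq, Q, t) {
  n <- length(seq)
  rate <- -diag(Q)
  ev_site <- integer(0); ev_time <- numeric(0)
  ev_from <- integer(0); ev_to <- integer(0)
  now <- numeric(n)
  w <- stats::rexp(n, rate[seq])
  active <- which(now + w < t)
  now[active] <- now[active] + w[active]
  while (length(active)) {
    for (s in active) {
      i <- seq[s]
      p <- Q[i, ]; p[i] <- 0
      j <- sample.int(61L, 1L, prob = p)
      ev_site <- c(ev_site, s); ev_time <- c(ev_time, now[s])
      ev_from <- c(ev_from, i); ev_to <- c(ev_to, j)
      seq[s] <- j
    }
    w <- stats::rexp(length(active), rate[seq[active]])
    keep <- now[active] + w < t
    now[active[keep]] <- now[active[keep]] + w[keep]
    active <- active[keep]
  }
  list(seq = seq, events = data.frame(site = ev_site, time = ev_time,
                                      from = ev_from, to = ev_to))
}

#' Simulate a codon alignment with branch-specific selection and gBGC
#'
#' Draws a root sequence from the root F3X4 codon frequencies and evolves
#' it down every branch by exact event simulation under that branch's
#' generator: YN98 with the branch's omega, normalized to one expected
#' substitution per site at equilibrium, then gBGC-tilted by the branch's
#' gamma. Every substitution event is recorded and classified.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{alignment} (a \code{\link{codon_alignment}})
#'   and \code{truth}: realized per-branch per-category counts
#'   (\code{counts}), the full event log (\code{events}), \code{root_seq},
#'   and the per-branch generating parameters (\code{params}).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  code <- genetic_code()
  set.seed(cfg$seed)
  struct <- .tree_struct(cfg$tree)
  labels <- struct$labels[struct$edge[, 2L]]
  omega <- .branch_param(cfg$omega, labels)
  gamma <- .branch_param(cfg$gamma, labels)
  pi <- f3x4_frequencies(cfg$theta, code)
  rho <- f3x4_frequencies(cfg$rho, code)
  root_seq <- sample.int(61L, cfg$n_codons, replace = TRUE, prob = rho)
  seqs <- vector("list", struct$nnode_total)
  seqs[[struct$root]] <- root_seq
  counts <- matrix(0, struct$n_edges, 8L,
                   dimnames = list(labels, category_names()))
  events <- vector("list", struct$n_edges)
  # preorder: reverse postorder guarantees the parent sequence exists
  for (e in rev(seq_len(struct$n_edges))) {
    u <- struct$edge[e, 1L]; v <- struct$edge[e, 2L]
    Qb <- .gbgc_branch_generator(cfg$kappa, omega[e], pi,
                                 2 * log(gamma[e]), code)
    sim <- .sim_branch(seqs[[u]], Qb, struct$edge_length[e])
    seqs[[v]] <- sim$seq
    if (nrow(sim$events)) {
      sim$events$category <-
        category_names()[code$category[cbind(sim$events$from,
                                             sim$events$to)]]
      sim$events$branch <- labels[e]
      counts[e, ] <- tabulate(
        code$category[cbind(sim$events$from, sim$events$to)], 8L)
    }
    events[[e]] <- sim$events
  }
  tipmat <- do.call(rbind, lapply(seq_len(struct$ntip), function(v) {
    code$codons[seqs[[v]]]
  }))
  rownames(tipmat) <- struct$tree$tip.label
  aln <- codon_alignment(tipmat, code = code)
  truth <- structure(list(counts = counts,
                          events = do.call(rbind,
                            events[vapply(events, nrow, 0L) > 0]),
                          root_seq = root_seq,
                          params = data.frame(branch = labels,
                                              omega = unname(omega),
                                              gamma = unname(gamma)),
                          tree = struct$tree),
                     class = "sim_truth")
  list(alignment = aln, truth = truth)
}

#' Replay a simulation event log
#'
#' Reapplies the recorded substitution events from the root sequence down
#' the tree and returns the implied tip sequences; used to verify
#' event-log consistency.
#'
#' @param truth The \code{truth} component of
#'   \code{\link{simulate_alignment}}'s result.
#' @return Species x site integer matrix of codon states.
#' @export
replay_events <- function(truth) {
  struct <- .tree_struct(truth$tree)
  labels <- struct$labels[struct$edge[, 2L]]
  seqs <- vector("list", struct$nnode_total)
  seqs[[struct$root]] <- truth$root_seq
  for (e in rev(seq_len(struct$n_edges))) {
    u <- struct$edge[e, 1L]; v <- struct$edge[e, 2L]
    s <- seqs[[u]]
    ev <- truth$events[truth$events$branch == labels[e], , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[order(ev$time), , drop = FALSE]
      for (k in seq_len(nrow(ev))) s[ev$site[k]] <- ev$to[k]
    }
    seqs[[v]] <- s
  }
  out <- do.call(rbind, seqs[seq_len(struct$ntip)])
  rownames(out) <- struct$tree$tip.label
  out
}

# Brownian motion values at the tips (root value 0)
.bm_tips <- function(struct, sd) {
  x <- numeric(struct$nnode_total)
  for (e in rev(seq_len(struct$n_edges))) {
    u <- struct$edge[e, 1L]; v <- struct$edge[e, 2L]
    x[v] <- x[u] + stats::rnorm(1L, 0, sd * sqrt(struct$edge_length[e]))
  }
  stats::setNames(x[seq_len(struct$ntip)], struct$tree$tip.label)
}

#' Generate life-history traits linked to terminal-branch selection
#'
#' Emulates the premise that life-history traits proxy effective
#' population size, which scales the efficacy of selection: each log10
#' trait is an intercept plus \code{slope} times the natural log of the
#' tip's omega, plus Brownian noise accumulated along the tree (so traits
#' carry phylogenetic signal, as independent contrasts assume). Traits are
#' returned on the raw scale.
#'
#' @param tree Rooted \code{phylo}.
#' @param omega Per-terminal-branch omega, named by species (or a scalar).
#' @param slope Link slope on the log10-trait scale per unit ln(omega).
#' @param noise_sd Brownian standard deviation per unit branch length.
#' @param seed Seed.
#' @param intercepts log10-scale intercepts for the three traits.
#' @return Data frame with columns \code{species}, \code{body_mass_g},
#'   \code{longevity_yr}, \code{maturity_days}.
#' @export
generate_traits <- function(tree, omega, slope = 1, noise_sd = 0.25,
                            seed = 1L,
                            intercepts = c(body_mass_g = 2.5,
                                           longevity_yr = 1.2,
                                           maturity_days = 2.6)) {
  stopifnot(is.finite(slope), noise_sd >= 0)
  set.seed(seed)
  struct <- .tree_struct(tree)
  om <- .branch_param(omega, struct$tree$tip.label)
  base <- slope * log(om)
  vals <- lapply(intercepts, function(ic) {
    ic + base + .bm_tips(struct, noise_sd)
  })
  data.frame(species = struct$tree$tip.label,
             body_mass_g = 10^vals[[1L]],
             longevity_yr = 10^vals[[2L]],
             maturity_days = 10^vals[[3L]],
             row.names = NULL)
}

#' Generate a multi-gene set with GC regimes and chromosome classes
#'
#' Simulates per-gene codon alignments on a shared tree from two F3X4
#' regimes (GC-poor and GC-rich genes) and assigns chromosome labels
#' spanning micro (< 16 Mb), intermediate and macro (> 100 Mb) sizes, so
#' every binning scheme downstream is exercised.
#'
#' @param tree Rooted \code{phylo}.
#' @param n_genes Number of genes.
#' @param codons_per_gene Codon length of each gene (recycled).
#' @param prop_gc_rich Proportion of genes from the GC-rich regime.
#' @param theta_low,theta_high F3X4 parameters of the two regimes.
#' @param kappa,omega,gamma Passed to \code{\link{sim_config}}.
#' @param seed Master seed; gene g uses \code{seed + g}.
#' @return List with \code{genes} (metadata: \code{gene_id},
#'   \code{chromosome}, \code{chromosome_mb}, \code{mean_gc},
#'   \code{gc_regime}), \code{alignments} (list of
#'   \code{\link{codon_alignment}}), \code{truths}.
#' @export
make_gene_set <- function(tree, n_genes = 30L, codons_per_gene = 300L,
                          prop_gc_rich = 0.5,
                          theta_low = NULL, theta_high = NULL,
                          kappa = 2, omega = 0.2, gamma = 1, seed = 1L) {
  # default regimes: GC-poor ~ 0.40, GC-rich ~ 0.60
  if (is.null(theta_low))
    theta_low <- matrix(rep(c(0.30, 0.20, 0.20, 0.30), each = 3), 3, 4,
                        dimnames = list(NULL, c("A", "C", "G", "T")))
  if (is.null(theta_high))
    theta_high <- matrix(rep(c(0.20, 0.30, 0.30, 0.20), each = 3), 3, 4,
                         dimnames = list(NULL, c("A", "C", "G", "T")))
  set.seed(seed)
  codons_per_gene <- rep_len(codons_per_gene, n_genes)
  rich <- seq_len(n_genes) <= round(prop_gc_rich * n_genes)
  rich <- sample(rich)
  # chromosome sizes: micro < 16 Mb, intermediate, macro > 100 Mb
  chrom_mb <- sample(c(5, 10, 50, 80, 120, 160), n_genes, replace = TRUE)
  alignments <- vector("list", n_genes)
  truths <- vector("list", n_genes)
  ids <- sprintf("g%03d", seq_len(n_genes))
  for (g in seq_len(n_genes)) {
    cfg <- sim_config(tree, kappa = kappa, omega = omega, gamma = gamma,
                      theta = if (rich[g]) theta_high else theta_low,
                      n_codons = codons_per_gene[g], seed = seed + g)
    sim <- simulate_alignment(cfg)
    alignments[[g]] <- sim$alignment
    truths[[g]] <- sim$truth
  }
  names(alignments) <- names(truths) <- ids
  mean_gc <- vapply(alignments,
                    function(a) mean(alignment_gc(a), na.rm = TRUE),
                    numeric(1L))
  genes <- data.frame(gene_id = ids,
                      chromosome = paste0("chr", chrom_mb, "_",
                                          seq_len(n_genes)),
                      chromosome_mb = chrom_mb,
                      mean_gc = unname(mean_gc),
                      gc_regime = ifelse(rich, "rich", "poor"))
  list(genes = genes, alignments = alignments, truths = truths)
}
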