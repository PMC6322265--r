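# Shared fixtures and independent oracles for the test suite.
# Expensive fitted fixtures are computed once per run and cached.

.fixture_env <- new.env(parent = emptyenv())

balanced8 <- function(b = 0.08) {
  txt <- "(((A:L,B:L):L,(C:L,D:L):L):L,((E:L,F:L):L,(G:L,H:L):L):L);"
  ape::read.tree(text = gsub("L", format(b, digits = 12), txt))
}

tree3 <- function() ape::read.tree(text = "((A:0.2,B:0.3):0.15,C:0.4);")

# one simulated + fitted dataset reused across test files
fixture_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  tr <- balanced8()
  cfg <- sim_config(tr, kappa = 2, omega = 0.3, n_codons = 600,
                    seed = 11L)
  sim <- simulate_alignment(cfg)
  fit <- fit_model(sim$alignment, tr,
                   control = list(root_freqs = "observed",
                                  max_rounds = 6L, tol = 1e-3))
  out <- list(sim = sim, fit = fit, tree = tr)
  .fixture_env$fit <- out
  out
}

# brute-force pruning oracle: sum over all internal-node assignments
enumeration_loglik <- function(aln, tree, model) {
  struct <- condnds:::.tree_struct(tree)
  prep <- condnds:::.prepare_data(aln, struct)
  dec <- condnds:::.decompose_generator(model$Q, model$pi)
  P <- lapply(struct$edge_length,
              function(t) condnds:::.transition_prob(dec, t))
  internal <- sort(unique(struct$edge[, 1L]))
  k <- length(internal)
  rho <- unname(model$root_freqs)
  total <- 0
  for (site in seq_len(aln$n_codons)) {
    pat <- prep$pattern_states[, prep$pattern_of_site[site]]
    lik <- 0
    grid <- do.call(expand.grid, rep(list(1:61), k))
    for (g in seq_len(nrow(grid))) {
      assign_ <- unlist(grid[g, ])
      state_of <- function(node) {
        if (node <= struct$ntip) pat[node]
        else assign_[match(node, internal)]
      }
      term <- rho[state_of(struct$root)]
      for (e in seq_len(struct$n_edges)) {
        u <- state_of(struct$edge[e, 1L])
        v <- struct$edge[e, 2L]
        sv <- state_of(v)
        if (is.na(sv)) {  # missing tip: sum over states = 1
          next
        }
        term <- term * P[[e]][u, sv]
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# Monte-Carlo trajectory oracle: forward paths from `start`, returning
# end states and per-path labeled counts
mc_paths <- function(Q, start, t, label, n_paths) {
  ends <- integer(n_paths); counts <- numeric(n_paths)
  n <- nrow(Q)
  for (r in seq_len(n_paths)) {
    s <- start; now <- 0; k <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- stats::rexp(1L, rate)
      if (now + w > t) break
      now <- now + w
      j <- sample.int(n, 1L, prob = pmax(Q[s, ], 0) *
                        (seq_len(n) != s))
      if (label[s, j]) k <- k + 1
      s <- j
    }
    ends[r] <- s; counts[r] <- k
  }
  list(ends = ends, counts = counts)
}

# independent PIC recursion (Felsenstein 1985), no ape
hand_pic <- function(tree, values) {
  struct <- condnds:::.tree_struct(tree)
  x <- numeric(struct$nnode_total)
  v <- struct$edge_length
  x[seq_len(struct$ntip)] <- values[struct$tree$tip.label]
  vnode <- numeric(struct$nnode_total)
  contrasts <- numeric(0)
  for (u in struct$internal_postorder) {
    es <- struct$children_edges[[as.character(u)]]
    stopifnot(length(es) == 2L)
    c1 <- struct$edge[es[1L], 2L]; c2 <- struct$edge[es[2L], 2L]
    v1 <- v[es[1L]] + vnode[c1]; v2 <- v[es[2L]] + vnode[c2]
    contrasts <- c(contrasts, (x[c1] - x[c2]) / sqrt(v1 + v2))
    x[u] <- (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    vnode[u] <- v1 * v2 / (v1 + v2)
  }
  contrasts
}

# tree-wide category dN/dS: counts summed over branches before ratios
treewide_dnds <- function(counts, branches = NULL) {
  if (!is.null(branches)) counts <- counts[counts$branch %in% branches, ]
  sp <- strsplit(counts$category, "_")
  counts$coding <- vapply(sp, `[`, "", 1L)
  counts$gc <- vapply(sp, `[`, "", 2L)
  per <- function(gc_levels) {
    dn <- sum(counts$expected[counts$coding == "nonsyn" &
                                counts$gc %in% gc_levels]) /
      sum(counts$opportunity[counts$coding == "nonsyn" &
                               counts$gc %in% gc_levels])
    ds <- sum(counts$expected[counts$coding == "syn" &
                                counts$gc %in% gc_levels]) /
      sum(counts$opportunity[counts$coding == "syn" &
                               counts$gc %in% gc_levels])
    dn / ds
  }
  c(WS = per("WS"), SW = per("SW"), SS = per("SS"), WW = per("WW"),
    total = per(c("WS", "SW", "SS", "WW")))
}

quick_fit <- function(aln, tree, ...) {
  fit_model(aln, tree, control = utils::modifyList(
    list(root_freqs = "observed", max_rounds = 6L, tol = 1e-3),
    list(...)))
}
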