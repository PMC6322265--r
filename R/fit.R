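# Maximum-likelihood estimation of the non-stationary YN98 model:
# branch lengths, kappa, omega, process F3X4 frequencies and root F3X4
# frequencies. The schedule alternates a bounded quasi-Newton step on the
# substitution parameters with one-dimensional Brent optimization of each
# branch length (exact outer/inner partials recomputed per branch), until
# the log-likelihood improvement falls below tolerance.

.freq_to_par <- function(theta) {
  # multinomial logit per codon position, T as reference
  t(apply(theta, 1L, function(p) log(pmax(p[1:3], 1e-8) / max(p[4], 1e-8))))
}

.par_to_freq <- function(x) {
  th <- t(apply(matrix(x, 3L, 3L, byrow = TRUE), 1L, function(r) {
    e <- exp(c(r, 0)); e / sum(e)
  }))
  colnames(th) <- c("A", "C", "G", "T")
  th
}

.observed_theta <- function(aln, code = genetic_code(), eps = 0.5) {
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  idx <- matrix(match(cmat, c("A", "C", "G", "T")), ncol = 3L)
  s <- aln$states[!is.na(aln$states)]
  th <- vapply(1:3, function(p) {
    (tabulate(idx[s, p], 4L) + eps) / (length(s) + 4 * eps)
  }, numeric(4L))
  th <- t(th)
  colnames(th) <- c("A", "C", "G", "T")
  th
}

#' Fit the non-stationary YN98 model by maximum likelihood
#'
#' Two groups of parameters are optimized in alternation: the substitution
#' parameters (kappa, omega, optionally the process and root F3X4
#' frequencies) with bounded L-BFGS-B, and the branch lengths one at a time
#' with Brent's method, each branch against exact outer/inner partial
#' likelihoods. Branch lengths are constrained to [1e-6, 10].
#'
#' @param aln A \code{\link{codon_alignment}} with at least 2 species.
#' @param topology Rooted \code{phylo} tree; its branch lengths are the
#'   starting point of the optimization (zero/absent lengths start at 0.1).
#' @param init Optional list of starting values: \code{kappa},
#'   \code{omega}, \code{theta}, \code{rho}.
#' @param control List of optimizer settings: \code{tol} (log-likelihood
#'   improvement threshold per round, default \code{1e-6}),
#'   \code{max_rounds} (default 50), \code{param_maxit} (L-BFGS-B
#'   iterations per round, default 100), \code{optimize_freqs} (optimize
#'   the process F3X4 frequencies; default \code{FALSE}, which fixes them
#'   at the observed position-specific frequencies, the usual empirical
#'   F3X4 convention), \code{root_freqs} (\code{"free"} to optimize the
#'   root F3X4 parameters by ML, \code{"observed"} to fix them at observed
#'   frequencies, \code{"stationary"} to tie them to the process
#'   frequencies; default \code{"free"}), \code{optimize_branches}
#'   (default \code{TRUE}; \code{FALSE} keeps the input tree's branch
#'   lengths fixed, for workflows where they are estimated upstream).
#' @return An object of class \code{codon_fit}: \code{model} (the fitted
#'   \code{\link{yn98_model}}), \code{tree} (with optimized branch
#'   lengths), \code{loglik}, \code{convergence} (\code{"converged"} or
#'   \code{"max_rounds"}), \code{n_rounds}, plus internal pattern data
#'   reused by the mapping functions.
#' @export
fit_model <- function(aln, topology, init = list(), control = list()) {
  ctl <- utils::modifyList(list(
    tol = 1e-6, max_rounds = 50L, param_maxit = 100L,
    optimize_freqs = FALSE, root_freqs = "free",
    optimize_branches = TRUE,
    min_bl = 1e-6, max_bl = 10), control)
  stopifnot(length(aln$species) >= 2L)
  struct <- .tree_struct(topology)
  bl <- struct$edge_length
  bl[!is.finite(bl) | bl <= 0] <- 0.1
  bl <- pmin(pmax(bl, ctl$min_bl), ctl$max_bl)
  struct$edge_length <- bl
  prep <- .prepare_data(aln, struct)
  if (prep$npat < 1L) stop("no retained sites")

  th_obs <- .observed_theta(aln)
  kappa <- if (!is.null(init$kappa)) init$kappa else 2
  omega <- if (!is.null(init$omega)) init$omega else 0.5
  theta <- if (!is.null(init$theta)) .as_theta(init$theta) else th_obs
  rho <- if (!is.null(init$rho)) .as_theta(init$rho) else th_obs

  pack <- function() {
    p <- c(log(kappa), log(omega))
    lo <- c(log(1e-3), log(1e-4)); hi <- c(log(1e3), log(1e2))
    if (ctl$optimize_freqs) {
      p <- c(p, as.vector(t(.freq_to_par(theta))))
      lo <- c(lo, rep(-20, 9L)); hi <- c(hi, rep(20, 9L))
    }
    if (ctl$root_freqs == "free") {
      p <- c(p, as.vector(t(.freq_to_par(rho))))
      lo <- c(lo, rep(-20, 9L)); hi <- c(hi, rep(20, 9L))
    }
    list(p = p, lo = lo, hi = hi)
  }
  unpack <- function(p) {
    kappa <<- exp(p[1L]); omega <<- exp(p[2L])
    at <- 2L
    if (ctl$optimize_freqs) { theta <<- .par_to_freq(p[at + 1:9]); at <- at + 9L }
    if (ctl$root_freqs == "free") rho <<- .par_to_freq(p[at + 1:9])
    if (ctl$root_freqs == "stationary") rho <<- theta
  }

  cur_model <- function() yn98_model(kappa, omega, theta, rho)

  full_ll <- function(model, edge_length = struct$edge_length) {
    dec <- .decompose_generator(model$Q, model$pi)
    st <- struct; st$edge_length <- edge_length
    Plist <- .edge_P(dec, st)
    pass <- .up_pass(st, prep, Plist)
    .root_loglik(st, prep, pass, model$root_freqs)
  }

  nll_par <- function(p) {
    unpack(p)
    m <- cur_model()
    ll <- tryCatch(full_ll(m), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ll <- full_ll(cur_model())
  ll_init <- ll
  converged <- FALSE
  round <- 0L
  while (round < ctl$max_rounds) {
    round <- round + 1L
    ll_before <- ll
    # (a) substitution parameters
    pk <- pack()
    opt <- stats::optim(pk$p, nll_par, method = "L-BFGS-B",
                        lower = pk$lo, upper = pk$hi,
                        control = list(maxit = ctl$param_maxit))
    unpack(opt$par)
    model <- cur_model()
    dec <- .decompose_generator(model$Q, model$pi)
    # (b) branch lengths, one Brent search each, fresh partials per branch
    for (e in if (ctl$optimize_branches) seq_len(struct$n_edges)
              else integer(0)) {
      Plist <- .edge_P(dec, struct)
      pass <- .up_pass(struct, prep, Plist)
      down <- .down_pass(struct, prep, Plist, pass, model$root_freqs)
      child <- struct$edge[e, 2L]
      Lc <- if (child <= struct$ntip) prep$tips[[child]]
            else pass$up[[child]]
      He <- down$H[[e]]
      f <- function(t) {
        v <- .colSums(He * (.transition_prob(dec, t) %*% Lc),
                      61L, prep$npat)
        v[v <= 0] <- .Machine$double.xmin
        -sum(prep$weights * log(v))
      }
      o <- stats::optimize(f, c(ctl$min_bl, ctl$max_bl), tol = 1e-7)
      if (o$objective <= f(struct$edge_length[e]))
        struct$edge_length[e] <- o$minimum
    }
    ll <- full_ll(cur_model())
    if (ll - ll_before < ctl$tol) { converged <- TRUE; break }
  }
  model <- cur_model()
  if (ll < ll_init - 1e-8)
    warning("optimization ended below its starting log-likelihood")
  tree <- struct$tree
  tree$edge.length <- struct$edge_length
  structure(list(model = model, tree = tree, loglik = ll,
                 loglik_init = ll_init,
                 convergence = if (converged) "converged" else "max_rounds",
                 n_rounds = round, control = ctl,
                 struct = struct, prep = prep, aln_species = aln$species),
            class = "codon_fit")
}

#' @exportS3Method base::print
print.codon_fit <- function(x, ...) {
  cat("Fitted non-stationary YN98 model\n")
  cat(sprintf("  log-likelihood: %.4f (%s, %d rounds)\n",
              x$loglik, x$convergence, x$n_rounds))
  cat(sprintf("  kappa = %.4g, omega = %.4g\n",
              x$model$kappa, x$model$omega))
  invisible(x)
}
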