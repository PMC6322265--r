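# Substitution mapping: posterior expected numbers of labeled
# substitutions per branch under the fitted model, and the corresponding
# expected numbers under the neutralized (omega = 1) model from the same
# ancestral scenarios. Their ratios give category-specific dN and dS.

.category_masks <- function(code = genetic_code()) {
  out <- lapply(seq_len(8L), function(k) {
    m <- !is.na(code$category) & code$category == k
    m
  })
  names(out) <- category_names()
  out
}

# J(t)_ab = integral_0^t exp(l_a s) exp(l_b (t-s)) ds, the eigen-domain
# kernel of the labeled-count convolution integral
.count_kernel <- function(values, t) {
  n <- length(values)
  la <- matrix(values, n, n)
  lb <- t(la)
  d <- la - lb
  small <- abs(d) < 1e-10
  J <- matrix(0, n, n)
  J[!small] <- (exp(la[!small] * t) - exp(lb[!small] * t)) / d[!small]
  J[small] <- t * exp((la[small] + lb[small]) / 2 * t)
  J
}

# U(t) = integral_0^t exp(Qs) L exp(Q(t-s)) ds via the decomposition
.count_integral_eigen <- function(dec, L, t) {
  G <- dec$B %*% L %*% dec$A
  dec$A %*% (G * .count_kernel(dec$values, t)) %*% dec$B
}

# Uniformization fallback for the same integral, truncation error < tol
.count_integral_unif <- function(Q, L, t, tol = 1e-10) {
  n <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0 || t <= 0) return(matrix(0, n, n))
  R <- diag(n) + Q / mu
  N <- max(10L, stats::qpois(1 - tol, mu * t) + 10L)
  U <- matrix(0, n, n)
  S <- L            # S_m = sum_{a+b=m} R^a L R^b, recursion S_m = R S_{m-1} + L R^m
  Rm <- diag(n)     # R^m
  for (m in 0:N) {
    U <- U + stats::dpois(m + 1L, mu * t) / mu * S
    Rm <- Rm %*% R
    S <- R %*% S + L %*% Rm
  }
  U
}

# integral_0^t exp(Qs) ds by uniformization
.int_exp_unif <- function(Q, t, tol = 1e-12) {
  n <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0 || t <= 0) return(diag(t, n))
  R <- diag(n) + Q / mu
  N <- max(10L, stats::qpois(1 - tol, mu * t) + 10L)
  U <- matrix(0, n, n)
  Rm <- diag(n)
  for (m in 0:N) {
    U <- U + Rm * stats::ppois(m, mu * t, lower.tail = FALSE) / mu
    Rm <- Rm %*% R
  }
  U
}

.int_exp_eigen <- function(dec, t) {
  g <- ifelse(abs(dec$values) < 1e-10, t + dec$values * t^2 / 2,
              (exp(dec$values * t) - 1) / dec$values)
  dec$A %*% (g * dec$B)
}

#' Expected number of labeled substitutions on a branch
#'
#' Analytic expectation of the number of transitions i -> j with
#' \code{label[i, j]} true, over a branch of length \code{t} under
#' generator \code{Q}. With only a starting distribution the expectation
#' is unconditional on the end state (the form used for neutral
#' opportunities); with \code{to} supplied the expectation is
#' endpoint-conditioned via the convolution integral, with endpoint pairs
#' weighted by \code{from_i P_ij(t) to_j}.
#'
#' @param Q Rate generator (rows sum to 0).
#' @param t Branch length (>= 0).
#' @param label Logical matrix, TRUE for counted transitions (diagonal
#'   ignored).
#' @param from Probability distribution over starting states.
#' @param to Optional vector of end-state weights (e.g. an indicator of the
#'   observed end state, or a partial likelihood).
#' @param method \code{"auto"} (eigendecomposition when the spectrum is
#'   well separated, otherwise uniformization), \code{"eigen"} or
#'   \code{"uniformization"}.
#' @return Expected labeled count (numeric scalar).
#' @export
expected_labeled_counts <- function(Q, t, label, from, to = NULL,
                                    method = c("auto", "eigen",
                                               "uniformization")) {
  method <- match.arg(method)
  stopifnot(t >= 0, nrow(Q) == ncol(Q), all(dim(label) == dim(Q)))
  if (t == 0) return(0)
  L <- Q * (label & !diag(TRUE, nrow(Q)))
  dec <- if (method == "uniformization") list(method = "uniformization", Q = Q)
         else .decompose_generator(Q)
  if (method == "eigen" && dec$method == "uniformization")
    stop("eigendecomposition unreliable for this generator")
  if (is.null(to)) {
    IntE <- if (dec$method == "uniformization") .int_exp_unif(Q, t)
            else .int_exp_eigen(dec, t)
    return(sum(from * (IntE %*% rowSums(L))))
  }
  U <- if (dec$method == "uniformization") .count_integral_unif(Q, L, t)
       else .count_integral_eigen(dec, L, t)
  P <- .transition_prob(dec, t)
  w <- outer(from, to) * P
  s <- sum(w)
  if (s <= 0) stop("endpoint weighting has zero mass")
  keep <- P > 0
  sum(w[keep] / P[keep] * U[keep]) / s
}

# shared per-fit context for the two mapping passes
.map_context <- function(fit) {
  struct <- fit$struct; prep <- fit$prep; model <- fit$model
  dec <- .decompose_generator(model$Q, model$pi)
  Plist <- .edge_P(dec, struct)
  pass <- .up_pass(struct, prep, Plist)
  down <- .down_pass(struct, prep, Plist, pass, model$root_freqs)
  list(struct = struct, prep = prep, model = model, dec = dec,
       Plist = Plist, pass = pass, down = down,
       masks = .category_masks(model$code))
}

.branch_frame <- function(struct) {
  child <- struct$edge[, 2L]
  data.frame(branch = struct$labels[child],
             terminal = child <= struct$ntip)
}

#' Posterior expected substitution counts per branch and category
#'
#' For every branch, the posterior expected number of substitutions in each
#' of the eight categories (synonymous / non-synonymous crossed with WS,
#' SW, SS, WW) under the fitted model, conditioning on the tip data and
#' summing over sites. The eight categories partition all substitutions,
#' so their sum equals the total expected count on the branch.
#'
#' @param fit A \code{\link{codon_fit}}.
#' @return Data frame with columns \code{branch} (child-node label),
#'   \code{terminal}, \code{category}, \code{count}.
#' @export
map_counts <- function(fit) {
  cx <- .map_context(fit)
  struct <- cx$struct; prep <- cx$prep
  cats <- category_names()
  res <- vector("list", struct$n_edges)
  unif <- cx$dec$method == "uniformization"
  for (e in seq_len(struct$n_edges)) {
    t <- struct$edge_length[e]
    child <- struct$edge[e, 2L]
    Lv <- if (child <= struct$ntip) prep$tips[[child]]
          else cx$pass$up[[child]]
    He <- cx$down$H[[e]]
    nrm <- .colSums(He * cx$pass$C[[e]], 61L, prep$npat) * cx$pass$sc[[e]]
    coef <- prep$weights / nrm
    WW <- (He * rep(coef, each = 61L)) %*% t(Lv)
    cnt <- vapply(seq_len(8L), function(k) {
      L <- cx$model$Q * cx$masks[[k]]
      U <- if (unif) .count_integral_unif(cx$model$Q, L, t)
           else .count_integral_eigen(cx$dec, L, t)
      sum(WW * U)
    }, numeric(1L))
    res[[e]] <- cnt
  }
  bf <- .branch_frame(struct)
  data.frame(branch = rep(bf$branch, each = 8L),
             terminal = rep(bf$terminal, each = 8L),
             category = rep(cats, struct$n_edges),
             count = unlist(res))
}

#' Neutral-model expected substitution counts (opportunities)
#'
#' For every branch and category, the expected number of substitutions a
#' neutralized model (omega = 1, same kappa, frequencies and time scale as
#' the fit) would perform from the same ancestral scenarios: the
#' parent-node posterior state distribution under the fitted model is
#' propagated along the branch under the neutral process, unconditional on
#' the observed child states.
#'
#' @param fit A \code{\link{codon_fit}}.
#' @param conditioning \code{"parent"} (default; neutral process started
#'   from the parent posterior, free run along the branch) or
#'   \code{"joint"} (endpoint-conditioned on the fitted model's joint
#'   parent/child posterior; provided for comparison, makes the
#'   normalization tautological at omega = 1).
#' @return Data frame with columns \code{branch}, \code{terminal},
#'   \code{category}, \code{count}.
#' @export
map_opportunities <- function(fit, conditioning = c("parent", "joint")) {
  conditioning <- match.arg(conditioning)
  cx <- .map_context(fit)
  struct <- cx$struct; prep <- cx$prep
  mod_n <- neutralize(cx$model)
  dec_n <- .decompose_generator(mod_n$Q, mod_n$pi)
  unif <- dec_n$method == "uniformization"
  rmat <- vapply(cx$masks, function(m) rowSums(mod_n$Q * m), numeric(61L))
  res <- vector("list", struct$n_edges)
  for (e in seq_len(struct$n_edges)) {
    t <- struct$edge_length[e]
    u <- struct$edge[e, 1L]
    pu <- cx$down$O[[u]] * cx$pass$up[[u]]
    pu <- pu * rep(1 / .colSums(pu, 61L, prep$npat), each = 61L)
    pbar <- as.vector(pu %*% prep$weights)
    if (conditioning == "parent") {
      IntE <- if (unif) .int_exp_unif(mod_n$Q, t) else .int_exp_eigen(dec_n, t)
      res[[e]] <- as.vector(crossprod(pbar, IntE %*% rmat))
    } else {
      child <- struct$edge[e, 2L]
      Lv <- if (child <= struct$ntip) prep$tips[[child]]
            else cx$pass$up[[child]]
      He <- cx$down$H[[e]]
      nrm <- .colSums(He * cx$pass$C[[e]], 61L, prep$npat) * cx$pass$sc[[e]]
      WW <- (He * rep(prep$weights / nrm, each = 61L)) %*% t(Lv)
      Pn <- .transition_prob(dec_n, t)
      Pf <- .transition_prob(cx$dec, t)
      keep <- Pn > 0 & Pf > 0
      res[[e]] <- vapply(seq_len(8L), function(k) {
        L <- mod_n$Q * cx$masks[[k]]
        U <- if (unif) .count_integral_unif(mod_n$Q, L, t)
             else .count_integral_eigen(dec_n, L, t)
        sum(WW[keep] * Pf[keep] * U[keep] / Pn[keep])
      }, numeric(1L))
    }
  }
  bf <- .branch_frame(struct)
  data.frame(branch = rep(bf$branch, each = 8L),
             terminal = rep(bf$terminal, each = 8L),
             category = rep(category_names(), struct$n_edges),
             count = unlist(res))
}

#' Branch count table: fitted expectations and neutral opportunities
#'
#' Convenience wrapper running \code{\link{map_counts}} and
#' \code{\link{map_opportunities}} and merging them.
#'
#' @param fit A \code{\link{codon_fit}}.
#' @param conditioning Passed to \code{\link{map_opportunities}}.
#' @return Data frame with columns \code{branch}, \code{terminal},
#'   \code{category}, \code{expected}, \code{opportunity}.
#' @export
branch_count_table <- function(fit, conditioning = "parent") {
  obs <- map_counts(fit)
  opp <- map_opportunities(fit, conditioning)
  obs$opportunity <- opp$count[match(
    paste(obs$branch, obs$category),
    paste(opp$branch, opp$category))]
  names(obs)[names(obs) == "count"] <- "expected"
  obs
}

#' Category-specific dN, dS and dN/dS per branch
#'
#' Normalizes the mapped expectations by the neutral opportunities:
#' dX(branch, class) = expected / opportunity, separately for synonymous
#' (dS) and non-synonymous (dN) substitutions in each GC class, plus the
#' all-categories total (summing numerators and denominators). Ratios with
#' a zero opportunity or zero dS are flagged undefined, not dropped.
#'
#' @param counts Output of \code{\link{branch_count_table}}.
#' @return Data frame with columns \code{branch}, \code{terminal},
#'   \code{category} (WS, SW, SS, WW, total), \code{dN}, \code{dS},
#'   \code{dnds}, \code{defined}.
#' @export
category_rates <- function(counts) {
  stopifnot(all(c("branch", "category", "expected", "opportunity")
                %in% names(counts)))
  sp <- strsplit(counts$category, "_")
  counts$coding <- vapply(sp, `[`, "", 1L)
  counts$gc <- vapply(sp, `[`, "", 2L)
  out <- list()
  for (b in unique(counts$branch)) {
    cb <- counts[counts$branch == b, ]
    one <- function(gc_levels, label) {
      num_n <- sum(cb$expected[cb$coding == "nonsyn" & cb$gc %in% gc_levels])
      den_n <- sum(cb$opportunity[cb$coding == "nonsyn" & cb$gc %in% gc_levels])
      num_s <- sum(cb$expected[cb$coding == "syn" & cb$gc %in% gc_levels])
      den_s <- sum(cb$opportunity[cb$coding == "syn" & cb$gc %in% gc_levels])
      dN <- if (den_n > 0) num_n / den_n else NA_real_
      dS <- if (den_s > 0) num_s / den_s else NA_real_
      dnds <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
      data.frame(branch = b, terminal = cb$terminal[1L], category = label,
                 dN = dN, dS = dS, dnds = dnds,
                 defined = !is.na(dnds))
    }
    out[[b]] <- rbind(one("WS", "WS"), one("SW", "SW"), one("SS", "SS"),
                      one("WW", "WW"),
                      one(c("WS", "SW", "SS", "WW"), "total"))
  }
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' GC-conservative dN, dS and dN/dS
#'
#' Combines the strong-to-strong and weak-to-weak rates of each branch into
#' the GC-conservative statistic, weighting by the GC content at the
#' branch's parent node: rate_cons = g * rate(SS) + (1 - g) * rate(WW),
#' applied to dN and dS separately, with the ratio taken after combining.
#' gBGC changes neither SS nor WW fluxes, so this dN/dS is robust to it.
#'
#' @param rates Output of \code{\link{category_rates}}.
#' @param ancestral_gc Named numeric vector in [0, 1]: GC content at the
#'   parent node of each branch to combine (typically from
#'   \code{\link{gc_stats}} or \code{\link{ancestral_sequence}}).
#' @return \code{rates} with additional \code{"conservative"} rows for the
#'   branches named in \code{ancestral_gc}.
#' @export
gc_conservative_combine <- function(rates, ancestral_gc) {
  stopifnot(is.numeric(ancestral_gc), !is.null(names(ancestral_gc)))
  if (any(is.na(ancestral_gc)) ||
      any(ancestral_gc < 0 | ancestral_gc > 1))
    stop("ancestral GC must be in [0, 1] and non-missing")
  miss <- setdiff(names(ancestral_gc), rates$branch)
  if (length(miss)) stop("branches not in rate table: ",
                         paste(miss, collapse = ", "))
  add <- lapply(names(ancestral_gc), function(b) {
    g <- ancestral_gc[[b]]
    ss <- rates[rates$branch == b & rates$category == "SS", ]
    ww <- rates[rates$branch == b & rates$category == "WW", ]
    dN <- g * ss$dN + (1 - g) * ww$dN
    dS <- g * ss$dS + (1 - g) * ww$dS
    data.frame(branch = b, terminal = ss$terminal,
               category = "conservative", dN = dN, dS = dS,
               dnds = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
               defined = !is.na(dS) && dS > 0 && !is.na(dN))
  })
  out <- rbind(rates, do.call(rbind, add))
  rownames(out) <- NULL
  out
}
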