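#' F3X4 equilibrium codon frequencies
#'
#' Builds the 61 sense-codon frequency vector from three position-specific
#' nucleotide frequency vectors, product over positions, with stop-codon
#' mass removed and the result renormalized.
#'
#' @param theta A 3 x 4 numeric matrix (rows = codon positions, columns =
#'   A, C, G, T) or a list of three 4-vectors; each row/vector must sum to 1.
#' @param code A \code{\link{genetic_code}} object.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
#' @examples
#' theta <- matrix(0.25, 3, 4)
#' range(f3x4_frequencies(theta))  # all 1/61
f3x4_frequencies <- function(theta, code = genetic_code()) {
  theta <- .as_theta(theta)
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  idx <- matrix(match(cmat, c("A", "C", "G", "T")), ncol = 3)
  p <- theta[1, idx[, 1]] * theta[2, idx[, 2]] * theta[3, idx[, 3]]
  s <- sum(p)
  if (s <= 0) stop("theta assigns zero mass to every sense codon")
  stats::setNames(p / s, code$codons)
}

.as_theta <- function(theta) {
  if (is.list(theta)) theta <- do.call(rbind, theta)
  theta <- as.matrix(theta)
  if (!all(dim(theta) == c(3L, 4L)))
    stop("theta must be 3 positions x 4 nucleotides (A, C, G, T)")
  if (any(theta < 0)) stop("theta entries must be non-negative")
  rs <- rowSums(theta)
  if (any(abs(rs - 1) > 1e-8)) stop("each theta row must sum to 1")
  colnames(theta) <- c("A", "C", "G", "T")
  theta
}

#' YN98 codon rate generator
#'
#' Builds the 61 x 61 rate matrix of the Yang-Nielsen (1998) codon model:
#' only single-nucleotide changes between sense codons have positive rate,
#' proportional to the target codon's equilibrium frequency, multiplied by
#' \code{kappa} for transitions and \code{omega} for non-synonymous changes.
#' The generator is scaled so that the expected substitution rate at the
#' equilibrium frequencies \code{pi} is 1 (branch lengths are then expected
#' substitutions per codon site).
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Non-synonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium codon frequencies (length 61, sums to 1), usually
#'   from \code{\link{f3x4_frequencies}}.
#' @param code A \code{\link{genetic_code}}.
#' @param scale Optional fixed scaling constant. By default the matrix is
#'   normalized by its own mean rate at \code{pi}; passing a number divides
#'   by that constant instead (used to keep a neutralized matrix on the
#'   fitted matrix's time scale).
#' @return The rate matrix with attribute \code{"scale"}, the normalizing
#'   constant that was divided out.
#' @export
build_yn98_matrix <- function(kappa, omega, pi, code = genetic_code(),
                              scale = NULL) {
  stopifnot(kappa >= 0, omega >= 0, length(pi) == 61L)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  n <- 61L
  Q <- matrix(0, n, n, dimnames = list(code$codons, code$codons))
  Q[code$single] <- rep(pi, each = n)[code$single]
  Q[code$transition] <- Q[code$transition] * kappa
  Q[code$nonsyn] <- Q[code$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (is.null(scale)) scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate model: zero mean substitution rate")
  Q <- Q / scale
  attr(Q, "scale") <- scale
  Q
}

#' Non-stationary YN98 model object
#'
#' Bundles the YN98 parameters with the F3X4 process frequencies and a
#' separate F3X4 parameterization of the root codon frequencies. The root
#' frequencies are what make the model non-stationary: the chain starts at
#' \code{rho}-derived frequencies rather than at the process equilibrium.
#'
#' @param kappa,omega YN98 rate ratios.
#' @param theta 3 x 4 process nucleotide frequencies (see
#'   \code{\link{f3x4_frequencies}}).
#' @param rho Root F3X4 frequencies; defaults to \code{theta} (stationary
#'   model).
#' @param code A \code{\link{genetic_code}}.
#' @return An object of class \code{yn98_model} with fields \code{kappa},
#'   \code{omega}, \code{theta}, \code{rho}, \code{pi} (process codon
#'   frequencies), \code{root_freqs} (root codon frequencies), \code{Q}
#'   (scaled generator) and \code{scale} (the normalizing constant).
#' @export
yn98_model <- function(kappa, omega, theta, rho = theta,
                       code = genetic_code()) {
  theta <- .as_theta(theta); rho <- .as_theta(rho)
  pi <- f3x4_frequencies(theta, code)
  Q <- build_yn98_matrix(kappa, omega, pi, code)
  structure(list(kappa = kappa, omega = omega, theta = theta, rho = rho,
                 pi = pi, root_freqs = f3x4_frequencies(rho, code),
                 Q = Q, scale = attr(Q, "scale"), code = code),
            class = "yn98_model")
}

#' @exportS3Method base::print
print.yn98_model <- function(x, ...) {
  cat("Non-stationary YN98 (F3X4) codon model\n")
  cat(sprintf("  kappa = %.4g, omega = %.4g\n", x$kappa, x$omega))
  cat(sprintf("  process GC = %.3f, root GC = %.3f\n",
              .theta_gc(x$theta), .theta_gc(x$rho)))
  invisible(x)
}

.theta_gc <- function(theta) mean(theta[, "C"] + theta[, "G"])

#' Neutralize a fitted model (set omega = 1, keep the clock)
#'
#' Returns the same model with the non-synonymous/synonymous ratio replaced
#' by 1. The neutralized generator is deliberately NOT rescaled: it is
#' divided by the fitted model's scaling constant so the two processes share
#' one time axis per branch, making fitted counts and neutral opportunity
#' counts directly comparable.
#'
#' @param model A \code{\link{yn98_model}}.
#' @return A \code{yn98_model} with \code{omega = 1} and \code{Q} on the
#'   input model's time scale.
#' @export
neutralize <- function(model) {
  stopifnot(inherits(model, "yn98_model"))
  Q <- build_yn98_matrix(model$kappa, 1, model$pi, model$code,
                         scale = model$scale)
  out <- model
  out$omega <- 1
  out$Q <- Q
  out
}

# Spectral machinery -------------------------------------------------------

# Decomposition of a generator Q for fast exp(Qt) and labeled-count
# integrals. Reversible generators (pi_i Q_ij = pi_j Q_ji, pi > 0) go
# through a symmetric eigenproblem; anything else through a general eigen
# decomposition, with uniformization as the fallback when eigenvalues are
# too close to be trusted.
.decompose_generator <- function(Q, pi = NULL, gap_tol = 1e-9) {
  n <- nrow(Q)
  if (!is.null(pi) && all(pi > 1e-12)) {
    flux <- pi * Q
    if (max(abs(flux - t(flux))) < 1e-10 * max(abs(flux))) {
      d <- sqrt(pi)
      S <- (d * Q) * rep(1 / d, each = n)  # diag(d) Q diag(1/d)
      S <- (S + t(S)) / 2
      e <- eigen(S, symmetric = TRUE)
      return(list(values = e$values,
                  A = e$vectors / d,            # diag(1/d) U
                  B = t(e$vectors) * rep(d, each = n),  # U' diag(d)
                  method = "symmetric"))
    }
  }
  e <- eigen(Q)
  if (max(abs(Im(e$values))) < 1e-9 &&
      min(diff(sort(Re(e$values)))) > gap_tol &&
      abs(Re(det(e$vectors))) > 1e-12) {
    A <- Re(e$vectors)
    return(list(values = Re(e$values), A = A, B = solve(A),
                method = "general"))
  }
  list(Q = Q, method = "uniformization")
}

# exp(Q t) from a decomposition; tiny negative entries are clipped to zero,
# larger ones are an error.
.transition_prob <- function(dec, t) {
  if (dec$method == "uniformization") {
    P <- as.matrix(Matrix::expm(dec$Q * t))
  } else {
    P <- dec$A %*% (exp(dec$values * t) * dec$B)
  }
  if (min(P) < -1e-8) stop("negative transition probability: ", min(P))
  P[P < 0] <- 0
  P
}
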