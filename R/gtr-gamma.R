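#' @useDynLib phyplace, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# State order is fixed as A, C, G, T everywhere in the package.
DNA_STATES <- c("A", "C", "G", "T")

# Exchangeability order: AC, AG, AT, CG, CT, GT (upper triangle by rows).
EXCH_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a GTR+Gamma substitution model
#'
#' Builds the generalized time-reversible (GTR) instantaneous rate matrix
#' from six exchangeabilities and four stationary base frequencies, together
#' with discrete-Gamma rate heterogeneity across sites. The rate matrix is
#' normalized so that one unit of branch length corresponds to one expected
#' substitution per site at the stationary distribution.
#'
#' @param exchangeabilities Numeric vector of 6 positive relative rates in
#'   the order AC, AG, AT, CG, CT, GT.
#' @param pi Numeric vector of 4 stationary frequencies (A, C, G, T) summing
#'   to 1.
#' @param alpha Shape of the Gamma distribution of among-site rates
#'   (`> 0`). Large values approach rate homogeneity.
#' @param n_categories Number of equal-probability discrete rate categories
#'   (default 4, the field convention).
#'
#' @return An object of class `gtr_gamma` with components `Q` (normalized
#'   4x4 rate matrix, rows summing to zero), `pi`, `exchangeabilities`,
#'   `alpha`, `n_categories`, `rates` (category rates with mean 1), and
#'   `eigen` (the reversible eigendecomposition used to compute transition
#'   probabilities).
#' @examples
#' jc <- gtr_gamma_model(rep(1, 6), rep(0.25, 4), alpha = 1)
#' transition_matrix(jc, t = 0.1)
#' @export
gtr_gamma_model <- function(exchangeabilities, pi, alpha = 1,
                            n_categories = 4L) {
  exchangeabilities <- as.numeric(exchangeabilities)
  pi <- as.numeric(pi)
  if (length(exchangeabilities) != 6L || any(!is.finite(exchangeabilities)) ||
      any(exchangeabilities <= 0)) {
    stop("exchangeabilities must be 6 positive finite numbers (AC,AG,AT,CG,CT,GT)")
  }
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0)) {
    stop("pi must be 4 positive finite frequencies")
  }
  if (abs(sum(pi) - 1) > 1e-6) {
    stop("frequencies must sum to 1")
  }
  pi <- pi / sum(pi)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")

  Q <- build_rate_matrix(exchangeabilities, pi)
  rates <- discrete_gamma_rates(alpha, n_categories)

  # Reversible eigendecomposition: symmetrize S = D^{1/2} Q D^{-1/2} with
  # D = diag(pi); S is symmetric, so eigen() is stable and
  # P(t) = A exp(diag(lambda) t) B with A = D^{-1/2} V, B = V' D^{1/2}.
  sq <- sqrt(pi)
  S <- (sq * Q) %*% diag(1 / sq)  # diag(sq) %*% Q %*% diag(1/sq)
  S <- (S + t(S)) / 2             # enforce exact symmetry
  es <- eigen(S, symmetric = TRUE)
  A <- diag(1 / sq) %*% es$vectors
  B <- t(es$vectors) %*% diag(sq)

  structure(
    list(Q = Q, pi = pi, exchangeabilities = stats::setNames(exchangeabilities, EXCH_NAMES),
         alpha = alpha, n_categories = n_categories, rates = rates,
         eigen = list(lambda = es$values, A = A, B = B)),
    class = "gtr_gamma")
}

#' @export
print.gtr_gamma <- function(x, ...) {
  cat("GTR+Gamma substitution model\n")
  cat("  base frequencies (A,C,G,T):", format(x$pi, digits = 4), "\n")
  cat("  exchangeabilities:", paste0(EXCH_NAMES, "=", format(x$exchangeabilities, digits = 4),
                                     collapse = " "), "\n")
  cat("  gamma shape:", format(x$alpha, digits = 4),
      " categories:", x$n_categories, "\n")
  invisible(x)
}

#' Build the normalized GTR rate matrix
#'
#' Off-diagonals are `Q[i, j] = s[i, j] * pi[j]` with `s` the symmetric
#' matrix of exchangeabilities; the diagonal makes rows sum to zero and the
#' whole matrix is rescaled so that `-sum(pi * diag(Q)) == 1`, i.e. branch
#' lengths are in expected substitutions per site.
#'
#' @inheritParams gtr_gamma_model
#' @return A 4x4 numeric matrix with rows/columns ordered A, C, G, T.
#' @export
build_rate_matrix <- function(exchangeabilities, pi) {
  if (any(exchangeabilities <= 0) || any(pi <= 0)) {
    stop("exchangeabilities and pi must be positive")
  }
  s <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  # upper.tri fills column by column: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),
  # i.e. AC, AG, CG, AT, CT, GT -- reorder the AC,AG,AT,CG,CT,GT input.
  s[upper.tri(s)] <- exchangeabilities[c(1L, 2L, 4L, 3L, 5L, 6L)]
  s <- s + t(s)
  Q <- s * rep(pi, each = 4)            # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

#' Transition probability matrix P(t)
#'
#' Computes `P(t) = exp(Q * t * rate)` through the reversible
#' eigendecomposition stored in the model, which is numerically stable for
#' any branch length.
#'
#' @param model A `gtr_gamma` model.
#' @param t Branch length in expected substitutions per site (`>= 0`).
#' @param rate Multiplicative rate (e.g. a Gamma category rate; default 1).
#' @return A 4x4 row-stochastic matrix ordered A, C, G, T.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "gtr_gamma"))
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  e <- model$eigen
  P <- e$A %*% (exp(e$lambda * t * rate) * e$B)
  # clip tiny negative round-off
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' Discrete-Gamma category rates
#'
#' Splits a Gamma(shape = alpha, mean = 1) distribution into `k`
#' equal-probability slices and returns the mean rate of each slice, so the
#' mean across categories is exactly 1. Using slice means (rather than
#' medians) preserves the mean substitution rate.
#'
#' @param alpha Gamma shape parameter (`> 0`).
#' @param k Number of categories (`>= 1`).
#' @return Numeric vector of `k` increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  # Quantile boundaries of Gamma(alpha, rate = alpha); the mean of each
  # slice follows from E[X; X <= q] = F_{alpha+1}(q) for mean-1 Gamma.
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  Fup <- stats::pgamma(c(q, Inf), shape = alpha + 1, rate = alpha)
  Flo <- c(0, Fup[-k])
  rates <- k * (Fup - Flo)
  rates / mean(rates)  # exact mean 1 against quadrature round-off
}

# Precompute per-category transition matrices for one length; internal.
category_pmats <- function(model, t) {
  lapply(model$rates, function(r) transition_matrix(model, t, r))
}
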