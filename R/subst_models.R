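#' GTR-family nucleotide substitution model
#'
#' Holds the six exchangeabilities (order AC, AG, AT, CG, CT, GT; GT is the
#' reference and is rescaled to 1), the stationary base frequencies, the
#' gamma shape of among-site rate variation and the proportion of
#' invariable sites. The derived rate matrix is normalized so branch
#' lengths are in expected substitutions per site at stationarity.
#'
#' @param exch numeric length 6, non-negative exchangeabilities
#'   (AC, AG, AT, CG, CT, GT). Default: all equal (Jukes-Cantor limit).
#' @param base_freq numeric length 4 (A, C, G, T), positive, summing to 1.
#' @param gamma_shape positive shape of the discrete-gamma rate mixture, or
#'   `NA` to switch rate variation off.
#' @param p_inv proportion of invariable sites in `[0, 1)`.
#' @param k number of discrete gamma categories (default 4).
#' @return an object of class `subst_model`.
#' @export
#' @examples
#' m <- substitution_model() # Jukes-Cantor
#' gtr <- substitution_model(
#'   exch = c(1.2, 4, 0.8, 1.1, 4.5, 1),
#'   base_freq = c(0.3, 0.2, 0.2, 0.3), gamma_shape = 0.5, p_inv = 0.1
#' )
substitution_model <- function(exch = rep(1, 6),
                               base_freq = rep(0.25, 4),
                               gamma_shape = NA_real_,
                               p_inv = 0,
                               k = 4L) {
  exch <- as.numeric(exch)
  base_freq <- as.numeric(base_freq)
  if (length(exch) != 6L || any(exch < 0) || exch[6] <= 0) {
    stop_ct("exch must be 6 non-negative rates with GT (the reference) > 0")
  }
  if (length(base_freq) != 4L || any(base_freq <= 0)) {
    stop_ct("base frequencies must be 4 positive numbers")
  }
  if (abs(sum(base_freq) - 1) > 1e-8) {
    stop_ct("base frequencies must sum to 1 (got ", sum(base_freq), ")")
  }
  base_freq <- base_freq / sum(base_freq)
  if (!is.na(gamma_shape) && gamma_shape <= 0) stop_ct("gamma_shape must be > 0")
  if (p_inv < 0 || p_inv >= 1) stop_ct("p_inv must be in [0, 1)")
  structure(
    list(
      exch = exch / exch[6],
      base_freq = base_freq,
      gamma_shape = as.numeric(gamma_shape),
      p_inv = as.numeric(p_inv),
      k = as.integer(if (is.na(gamma_shape)) 1L else k)
    ),
    class = "subst_model"
  )
}

#' @export
print.subst_model <- function(x, ...) {
  cat("GTR-family substitution model\n")
  cat(
    "  exchangeabilities (AC AG AT CG CT GT):",
    paste(signif(x$exch, 4), collapse = " "), "\n"
  )
  cat("  base frequencies (A C G T):", paste(signif(x$base_freq, 4), collapse = " "), "\n")
  if (is.na(x$gamma_shape)) {
    cat("  rate variation: off\n")
  } else {
    cat("  gamma shape:", signif(x$gamma_shape, 4), "with", x$k, "categories\n")
  }
  cat("  p_inv:", signif(x$p_inv, 4), "\n")
  invisible(x)
}

#' Instantaneous rate matrix of a model
#'
#' `Q[i, j] = s_ij * pi_j` off the diagonal, diagonal set so rows sum to
#' zero, and the whole matrix scaled so the expected substitution rate at
#' stationarity, `-sum_i pi_i Q_ii`, equals 1.
#'
#' @param model a [substitution_model()].
#' @return a 4x4 matrix with dimnames `A C G T`.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "subst_model"))
  pi <- model$base_freq
  s <- model$exch
  Q <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    i <- pairs[p, 1]
    j <- pairs[p, 2]
    Q[i, j] <- s[p] * pi[j]
    Q[j, i] <- s[p] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

DNA_STATES <- c("A", "C", "G", "T")

# Eigendecomposition of the pi-symmetrized rate matrix; P(t) = A e^{L t} B.
# Cached computation used by the likelihood kernel and simulators.
model_eigen <- function(model) {
  Q <- build_rate_matrix(model)
  pi <- model$base_freq
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2 # enforce exact symmetry against round-off
  eig <- eigen(S, symmetric = TRUE)
  list(
    A = diag(1 / d) %*% eig$vectors,
    B = t(eig$vectors) %*% diag(d),
    lambda = eig$values,
    Q = Q
  )
}

#' Transition probability matrix over a branch
#'
#' `P = exp(Q * t * rate)`, computed by eigendecomposition of the
#' symmetrized reversible rate matrix.
#'
#' @param model a [substitution_model()], or a valid 4x4 reversible rate
#'   matrix (stationary frequencies are then recovered from its null space).
#' @param t branch length (expected substitutions/site), `>= 0`.
#' @param rate relative rate multiplier, `>= 0` (default 1).
#' @return a 4x4 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0) stop_ct("branch length must be >= 0, got ", t)
  if (rate < 0) stop_ct("rate multiplier must be >= 0")
  if (is.matrix(model)) {
    eg <- eigen(t(model))
    i0 <- which.min(abs(eg$values))
    pi <- Re(eg$vectors[, i0])
    pi <- pi / sum(pi)
    d <- sqrt(pi)
    S <- diag(d) %*% model %*% diag(1 / d)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    A <- diag(1 / d) %*% es$vectors
    B <- t(es$vectors) %*% diag(d)
    lambda <- es$values
  } else {
    eg <- model_eigen(model)
    A <- eg$A
    B <- eg$B
    lambda <- eg$lambda
  }
  P <- A %*% diag(exp(lambda * t * rate)) %*% B
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of a Gamma distribution with mean 1
#' (shape = rate = `alpha`), each category represented by its conditional
#' mean, the convention of the standard phylogenetics tools. The weighted
#' mean of the returned rates is exactly 1.
#'
#' @param alpha positive gamma shape.
#' @param k number of categories, `>= 1`.
#' @return numeric vector of `k` rate multipliers (equal weights `1/k`).
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop_ct("alpha must be > 0, got ", alpha)
  k <- as.integer(k)
  if (k < 1L) stop_ct("k must be >= 1")
  if (k == 1L) {
    return(1)
  }
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # conditional mean over each bin via the incomplete-gamma identity:
  # E[X; a<X<b] for Gamma(a=alpha, rate=alpha) = F_{alpha+1}(b) - F_{alpha+1}(a)
  cdf1 <- stats::pgamma(breaks, shape = alpha + 1, rate = alpha)
  r <- k * diff(cdf1)
  r / mean(r)
}
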