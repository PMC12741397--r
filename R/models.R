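# Nucleotide substitution models: GTR family with invariant sites and
# discrete-gamma rate variation. The rate matrix Q is scaled so that the
# mean substitution rate at stationarity is 1 among variable sites, so
# branch lengths are in expected substitutions per (variable) site.

#' Construct a GTR(+I)+Gamma substitution model
#'
#' General time-reversible model with optional proportion of invariant
#' sites and discrete-gamma among-site rate variation (category means).
#' The instantaneous rate matrix satisfies detailed balance
#' \eqn{\pi_i q_{ij} = \pi_j q_{ji}} and is scaled to mean rate 1 at
#' stationarity.
#'
#' @param rates six exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @param freq stationary base frequencies (A, C, G, T); must sum to 1.
#' @param pinv proportion of invariant sites in `[0, 1)`.
#' @param alpha gamma shape for among-site rate variation; `Inf` disables
#'   rate variation.
#' @param ncat number of discrete gamma categories (ignored when
#'   `alpha = Inf`).
#' @return an object of class `subst_model`.
#' @examples
#' m <- subst_model(rep(1, 6), rep(0.25, 4))   # Jukes-Cantor
#' transition_matrix(m, 0.1)
#' @export
subst_model <- function(rates, freq, pinv = 0, alpha = Inf, ncat = 4L) {
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(freq) == 4L, all(freq > 0))
  if (abs(sum(freq) - 1) > 1e-8)
    stop("base frequencies must sum to 1")
  if (pinv < 0 || pinv >= 1) stop("pinv must be in [0, 1)")
  if (alpha <= 0) stop("alpha must be > 0")
  freq <- as.numeric(freq) / sum(freq)
  names(freq) <- BASES

  # Q[i, j] = s_ij * pi_j for i != j; rows sum to zero.
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  s <- matrix(0, 4, 4)
  s[lower.tri(s)] <- 0
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- rates[k] * freq[j]
    Q[j, i] <- rates[k] * freq[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu

  # Symmetric eigendecomposition via B = D Q D^-1 with D = diag(sqrt(pi)).
  d <- sqrt(freq)
  B <- (d %o% (1 / d)) * Q
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  U <- (1 / d) * eg$vectors          # rows scaled: D^-1 U
  V <- t(eg$vectors * d)             # U^T D

  if (is.finite(alpha)) {
    cat_rates <- gamma_cat_rates(alpha, ncat)
  } else {
    cat_rates <- 1
  }
  structure(list(rates = as.numeric(rates), freq = freq, pinv = pinv,
                 alpha = alpha, ncat = length(cat_rates),
                 cat_rates = cat_rates,
                 cat_weights = rep(1 / length(cat_rates), length(cat_rates)),
                 Q = Q, eig = list(U = U, V = V, lambda = eg$values)),
            class = "subst_model")
}

#' @rdname subst_model
#' @param kappa transition/transversion rate ratio for the HKY model.
#' @export
hky_model <- function(kappa, freq = rep(0.25, 4), pinv = 0, alpha = Inf,
                      ncat = 4L) {
  subst_model(c(1, kappa, 1, 1, kappa, 1), freq, pinv, alpha, ncat)
}

#' @rdname subst_model
#' @export
jc_model <- function(pinv = 0, alpha = Inf, ncat = 4L) {
  subst_model(rep(1, 6), rep(0.25, 4), pinv, alpha, ncat)
}

#' @export
print.subst_model <- function(x, ...) {
  type <- if (all(x$rates == x$rates[1])) "JC/F81" else
    if (all(x$rates[c(1, 3, 4, 6)] == x$rates[1]) &&
        x$rates[2] == x$rates[5]) "HKY" else "GTR"
  cat(sprintf("%s substitution model: pinv = %.3g, alpha = %s, %d categories\n",
              type, x$pinv,
              if (is.finite(x$alpha)) sprintf("%.3g", x$alpha) else "Inf",
              x$ncat))
  invisible(x)
}

#' Discrete-gamma category rates (category means)
#'
#' Mean rates of `k` equal-probability bins of a Gamma(shape, rate = shape)
#' distribution, so the category rates average 1.
#'
#' @param alpha gamma shape.
#' @param k number of categories.
#' @return numeric vector of length `k` with mean 1.
#' @export
gamma_cat_rates <- function(alpha, k = 4L) {
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                     rate = alpha)
  m <- k * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  m / mean(m) * 1   # guard rounding; mean is 1 analytically
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [subst_model].
#' @param t branch length in expected substitutions per site (must be
#'   `>= 0`).
#' @param rate optional rate multiplier (e.g. a gamma category rate).
#' @return a 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (t < 0) stop("branch length t must be >= 0")
  e <- exp(model$eig$lambda * t * rate)
  P <- model$eig$U %*% (e * model$eig$V)
  P[P < 0] <- 0
  dimnames(P) <- list(BASES, BASES)
  P
}
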