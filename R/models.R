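#' Discrete-gamma rate categories
#'
#' Equal-probability categories represented by their conditional means (the
#' MEGA/PhyML convention): category boundaries are gamma quantiles and each
#' category's rate is the mean of the gamma density between its boundaries,
#' so the category rates average exactly 1.
#'
#' @param shape Gamma shape `alpha > 0` (mean fixed at 1).
#' @param ncat Number of categories (default 5).
#' @return Numeric vector of `ncat` relative rates with mean 1.
#' @export
discrete_gamma <- function(shape, ncat = 5L) {
  stopifnot(shape > 0, ncat >= 1L)
  if (ncat == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape, rate = shape)
  r <- ncat * diff(stats::pgamma(b, shape + 1, rate = shape))
  r / mean(r) * 1  # guard against quantile round-off; mean is 1 analytically
}

#' Substitution model over an arbitrary alphabet
#'
#' A reversible GTR-type model: symmetric exchangeabilities, equilibrium
#' frequencies, optional discrete-gamma rate variation (`shape`, `ncat`) and
#' an optional proportion of invariant sites. The rate matrix is normalized
#' to one expected substitution per unit branch length averaged over the
#' full rate mixture (the invariant class rescales the gamma rates by
#' `1/(1 - p_inv)`).
#'
#' @param alphabet One of the package alphabets (see [alphabet_states()]).
#' @param exchangeabilities Upper-triangle vector (length `k(k-1)/2`, row
#'   major) or full symmetric matrix; default all equal (F81-like).
#' @param freqs Equilibrium frequencies (default uniform). Zero entries are
#'   floored at 1e-4 and renormalized so the model stays irreducible.
#' @param shape Gamma shape; `NULL` for rate homogeneity.
#' @param ncat Gamma categories (default 5).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return Object of class `subst_model`.
#' @export
subst_model <- function(alphabet, exchangeabilities = NULL, freqs = NULL,
                        shape = NULL, ncat = 5L, p_inv = 0) {
  states <- alphabet_states(alphabet)
  k <- length(states)
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  if (!is.null(names(freqs))) freqs <- freqs[states]
  stopifnot(length(freqs) == k, all(freqs >= 0), abs(sum(freqs) - 1) < 1e-6)
  freqs <- pmax(freqs, 1e-4)
  freqs <- freqs / sum(freqs)
  S <- matrix(0, k, k, dimnames = list(states, states))
  if (is.null(exchangeabilities)) exchangeabilities <- rep(1, k * (k - 1) / 2)
  if (is.matrix(exchangeabilities)) {
    S[] <- exchangeabilities
  } else {
    ## row-major upper-triangle order: (1,2),(1,3),...,(1,k),(2,3),...
    stopifnot(length(exchangeabilities) == k * (k - 1) / 2)
    m <- matrix(0, k, k)
    idx <- which(upper.tri(m), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    m[idx] <- exchangeabilities
    S <- m + t(m)
    dimnames(S) <- list(states, states)
  }
  S <- (S + t(S)) / 2
  diag(S) <- 0
  stopifnot(all(S >= 0), p_inv >= 0, p_inv < 1)
  structure(list(alphabet = alphabet, states = states, k = k,
                 S = S, freqs = stats::setNames(freqs, states),
                 shape = shape, ncat = as.integer(ncat), p_inv = p_inv),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%d-state reversible model on %s%s%s\n", x$k, x$alphabet,
              if (!is.null(x$shape)) sprintf(" +G(shape=%.3g, %d cat)", x$shape, x$ncat) else "",
              if (x$p_inv > 0) sprintf(" +I(%.3g)", x$p_inv) else ""))
  invisible(x)
}

#' GTR model constructor
#'
#' @param alphabet Alphabet (`nt4` by default; `RY2`/`aa4`/`aa6` give the
#'   GTR analogue on the recoded states; on `RY2` GTR reduces to an
#'   F81-like two-state model).
#' @inheritParams subst_model
#' @return A [subst_model()].
#' @export
model_gtr <- function(alphabet = "nt4", exchangeabilities = NULL, freqs = NULL,
                      shape = NULL, ncat = 5L, p_inv = 0) {
  subst_model(alphabet, exchangeabilities, freqs, shape, ncat, p_inv)
}

#' JTT amino-acid model
#'
#' Jones-Taylor-Thornton replacement model; `freqs = NULL` uses the JTT
#' equilibrium frequencies, while supplying [empirical_freqs()] of an
#' alignment gives the +F variant.
#'
#' @inheritParams subst_model
#' @return A [subst_model()] on `aa20`.
#' @export
model_jtt <- function(freqs = NULL, shape = NULL, ncat = 5L, p_inv = 0) {
  if (is.null(freqs)) freqs <- stats::setNames(.jtt_freqs, .alphabets$aa20)
  subst_model("aa20", .jtt_exchangeabilities, freqs, shape, ncat, p_inv)
}

#' Empirical state frequencies of an alignment
#'
#' @param aln An [alignment()].
#' @return Named frequency vector over the alignment's alphabet (gaps and
#'   missing symbols excluded from the denominator).
#' @export
empirical_freqs <- function(aln) {
  states <- .alphabets[[attr(aln, "alphabet")]]
  sym <- unclass(aln)
  sym <- sym[sym %in% states]
  tab <- table(factor(sym, levels = states))
  stats::setNames(as.vector(tab) / length(sym), states)
}

## Eigen-decomposition of the normalized rate matrix, exploiting
## reversibility for numerical stability.
model_eigen <- function(model) {
  bf <- model$freqs
  Q <- model$S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q <- Q / mu
  d <- sqrt(bf)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(lambda = eig$values,
       U = diag(1 / d) %*% eig$vectors,
       Uinv = t(eig$vectors) %*% diag(d),
       bf = as.numeric(bf))
}

## Rate mixture (gamma categories plus optional invariant class), mean 1.
mixture_rates <- function(model) {
  if (is.null(model$shape)) {
    r <- 1
    w <- 1
  } else {
    r <- discrete_gamma(model$shape, model$ncat)
    w <- rep(1 / model$ncat, model$ncat)
  }
  if (model$p_inv > 0) {
    r <- c(0, r / (1 - model$p_inv))
    w <- c(model$p_inv, (1 - model$p_inv) * w)
  }
  list(rates = r, weights = w)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Qt)` for the model's normalized rate matrix, mainly for
#' inspection and simulation.
#'
#' @param model A [subst_model()].
#' @param t Branch length (expected substitutions per site at relative
#'   rate 1).
#' @param rate Relative rate multiplier.
#' @return `k x k` stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  eig <- model_eigen(model)
  if (t * rate <= 0) return(diag(model$k))
  P <- eig$U %*% diag(exp(eig$lambda * t * rate)) %*% eig$Uinv
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}
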