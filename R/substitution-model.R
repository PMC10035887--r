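#' Build an empirical amino-acid substitution model
#'
#' Constructs a time-reversible rate matrix \eqn{Q_{ij} = s_{ij}\pi_j}
#' (\eqn{i \neq j}) from published exchangeabilities \eqn{s_{ij}} and
#' stationary frequencies \eqn{\pi}, with diagonal entries set so rows sum
#' to zero and the whole matrix scaled to one expected substitution per
#' unit time at stationarity. Because \eqn{Q} is reversible it is similar
#' to a symmetric matrix; the (real) eigendecomposition is computed once
#' via the \eqn{\Pi^{1/2} Q \Pi^{-1/2}} symmetrisation and cached, so that
#' \eqn{P(t) = V e^{\Lambda t} V^{-1}} can be evaluated cheaply for any
#' branch length and rate multiplier.
#'
#' @param name one of \code{"JTT"} (default), \code{"WAG"}, \code{"LG"}
#' @param frequencies optional length-20 vector of stationary frequencies
#'   (order ARNDCQEGHILKMFPSTWYV) overriding the model's own; must sum to 1
#' @return a \linkS4class{SubstitutionModel}
#' @examples
#' m <- substitutionModel("JTT")
#' rowSums(transitionMatrix(m, 0.5))   # all 1
#' @export
substitutionModel <- function(name = c("JTT", "WAG", "LG"),
                              frequencies = NULL) {
  name <- match.arg(name)
  entry <- .model_registry[[name]]
  p <- if (is.null(frequencies)) entry$freqs else frequencies
  if (length(p) != 20L || any(p <= 0) || abs(sum(p) - 1) > 1e-6)
    stop("frequencies must be 20 positive values summing to 1")
  p <- p / sum(p)

  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- entry$rates
  S <- S + t(S)
  Q <- S * rep(p, each = 20L)          # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(p * diag(Q))           # expected rate at stationarity
  Q <- Q / scale
  dimnames(Q) <- list(.AA_ALPHABET, .AA_ALPHABET)
  names(p) <- .AA_ALPHABET

  sq <- sqrt(p)
  Sym <- Q * (sq %o% (1 / sq))         # D^1/2 Q D^-1/2, symmetric
  eg <- eigen((Sym + t(Sym)) / 2, symmetric = TRUE)
  V <- eg$vectors / sq                 # row-scale: D^-1/2 U
  Vinv <- t(eg$vectors * sq)           # U' D^1/2

  new("SubstitutionModel", name = name, Q = Q, frequencies = p,
      eigenSystem = list(values = eg$values, vectors = V, inverse = Vinv))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a \linkS4class{SubstitutionModel}
#' @param t non-negative evolutionary distance (branch length times rate
#'   multiplier)
#' @return 20x20 stochastic matrix
#' @export
transitionMatrix <- function(model, t) {
  stopifnot(is(model, "SubstitutionModel"), t >= 0)
  es <- model@eigenSystem
  P <- es$vectors %*% (exp(es$values * t) * es$inverse)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model@Q)
  P
}

#' Stationary frequencies of a substitution model
#' @param model a \linkS4class{SubstitutionModel}
#' @export
stationaryFrequencies <- function(model) model@frequencies
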