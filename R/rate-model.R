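#' Empirical amino-acid rate models
#'
#' A rate model couples a symmetric exchangeability matrix `S` with
#' equilibrium frequencies `pi` into the reversible rate matrix
#' `Q[i,j] = S[i,j] * pi[j]` (off-diagonal), diagonal chosen so rows sum to
#' zero, and globally scaled so the expected substitution rate at
#' stationarity, `-sum(pi * diag(Q))`, is exactly one — distances are then
#' in expected substitutions per site. Because the model is reversible, the
#' similarity transform `diag(sqrt(pi)) Q diag(1/sqrt(pi))` is symmetric;
#' its eigensystem is computed once and cached so that transition matrices
#' `P(t) = expm(Q t)` cost one 20x20 reconstruction per evaluation.
#'
#' @name rate_model
NULL

#' Build an amino-acid rate model
#'
#' @param name Model name; `"JTT"` (Jones-Taylor-Thornton 1992 empirical
#'   model, constants as distributed in PAML's `jones.dat`) is currently the
#'   only built-in.
#' @param frequencies Optional length-20 replacement for the model's
#'   equilibrium frequencies (e.g. data-derived frequencies), in
#'   `ARNDCQEGHILKMFPSTWYV` order; renormalised to sum to one.
#' @return A `rate_model`: list with `name`, `S` (20x20 symmetric), `pi`
#'   (length 20), `Q` (scaled rate matrix) and the cached eigensystem used
#'   by [transition_probabilities()].
#' @export
#' @examples
#' m <- build_rate_matrix("JTT")
#' range(rowSums(m$Q))            # zero rows
#' -sum(m$pi * diag(m$Q))         # unit expected rate
build_rate_matrix <- function(name = "JTT", frequencies = NULL) {
  supported <- "JTT"
  if (!name %in% supported) {
    stop("unknown model '", name, "'; supported models: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  S <- matrix(0, 20L, 20L, dimnames = list(AA_LETTERS, AA_LETTERS))
  S[upper.tri(S)] <- 0
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    S[i, j] <- JTT_LOWER[[k]]
    k <- k + 1L
  }
  S <- S + t(S)
  pi <- if (is.null(frequencies)) unname(JTT_FREQS) else as.numeric(frequencies)
  if (length(pi) != 20L || any(pi <= 0)) {
    stop("frequencies must be 20 positive numbers", call. = FALSE)
  }
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # symmetrised generator: real spectrum guaranteed by reversibility
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = 20L))
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  structure(list(name = name, S = S, pi = pi, Q = Q,
                 eigenvalues = es$values,
                 # P(t) = U diag(exp(lambda t)) W, with U = D^-1/2 V,
                 # W = V' D^1/2
                 U = es$vectors / sq,
                 W = t(es$vectors * sq)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Reversible amino-acid rate model:", x$name,
      "(unit expected rate; 20 states)\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model A [build_rate_matrix()] model.
#' @param t Evolutionary distance in expected substitutions per site
#'   (`t >= 0`).
#' @return 20x20 stochastic matrix `exp(Q t)`; tiny negative entries from
#'   round-off are clamped to zero.
#' @export
#' @examples
#' m <- build_rate_matrix("JTT")
#' P <- transition_probabilities(m, 0.5)
#' rowSums(P)
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("t must be a single non-negative number", call. = FALSE)
  }
  P <- model$U %*% (exp(model$eigenvalues * t) * model$W)
  P[P < 0] <- 0
  dimnames(P) <- list(AA_LETTERS, AA_LETTERS)
  P
}
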