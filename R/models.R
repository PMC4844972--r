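#' Empirical amino-acid substitution model
#'
#' Builds a reversible 20-state rate matrix from published exchangeabilities
#' and equilibrium frequencies. `"WAG"` and `"JTT"` use the model data shipped
#' with phangorn (model frequencies, not observed +F frequencies); `"Poisson"`
#' is the equal-rates, equal-frequencies model. The rate matrix Q is scaled so
#' that the expected substitution rate at equilibrium is 1, making branch
#' lengths expected substitutions per site.
#'
#' @param name `"WAG"`, `"JTT"` or `"Poisson"`.
#' @return Object of class `kai_submodel`: list with `name`, `freqs` (named),
#'   `Q` (20x20, rows sum to zero, mean rate 1), and a cached symmetric
#'   eigendecomposition used to compute transition matrices.
#' @export
substitution_model <- function(name = c("WAG", "JTT", "Poisson")) {
  name <- match.arg(name)
  if (name == "Poisson") {
    pi <- setNames(rep(1 / 20, 20L), AA_ALPHABET)
    ex <- matrix(1, 20L, 20L)
  } else {
    env <- new.env()
    local({
      getModelAA <- get("getModelAA", envir = asNamespace("phangorn"))
      getModelAA(name, bf = TRUE, Q = TRUE)
      assign("Q", Q, envir = env); assign("bf", bf, envir = env)
    })
    pi <- setNames(as.numeric(env$bf), AA_ALPHABET)
    ex <- matrix(0, 20L, 20L)
    ex[lower.tri(ex)] <- env$Q
    ex <- ex + t(ex)
  }
  dimnames(ex) <- list(AA_ALPHABET, AA_ALPHABET)
  Q <- ex * rep(pi, each = 20L)   # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))        # expected rate at equilibrium
  Q <- Q / mu
  # reversible Q is similar to a symmetric matrix: B = D^{1/2} Q D^{-1/2}
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq)) * 1  # elementwise: sq_i * Q_ij / sq_j
  B <- (B + t(B)) / 2             # enforce symmetry against rounding
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = name, freqs = pi, exchangeabilities = ex, Q = Q,
                 eig_values = eig$values, eig_vectors = eig$vectors),
            class = "kai_submodel")
}

#' @export
print.kai_submodel <- function(x, ...) {
  cat(sprintf("<kai_submodel> %s (mean rate 1; 20 states)\n", x$name))
  invisible(x)
}

#' Transition probability matrix exp(Q t)
#'
#' @param model A [substitution_model()].
#' @param t Branch length times rate multiplier (expected substitutions/site).
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "kai_submodel"), t >= 0)
  sq <- sqrt(model$freqs)
  U <- model$eig_vectors
  # P(t) = D^{-1/2} U exp(L t) U^T D^{1/2}
  P <- ((1 / sq) * U) %*% (exp(model$eig_values * t) * (t(U) * rep(sq, each = 20L)))
  P[P < 0] <- 0
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P
}
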