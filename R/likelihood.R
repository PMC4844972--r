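# Felsenstein pruning over one tree for a character matrix, vectorized over
# columns. Returns per-column log-likelihood. Gaps/X are fully ambiguous.
# `charmat`: species x column character matrix, rows named by tip label.
prune_loglik <- function(tree, model, charmat, rate = 1) {
  stopifnot(inherits(model, "kai_submodel"), rate > 0)
  ntip <- length(tree$tip.label)
  ncol_ <- ncol(charmat)
  if (!all(tree$tip.label %in% rownames(charmat)))
    stop("character matrix does not cover all tips")
  charmat <- charmat[tree$tip.label, , drop = FALSE]
  if (ntip == 1L) {
    # single-taxon tree: likelihood is the equilibrium frequency
    idx <- match(charmat[1L, ], AA_ALPHABET)
    return(ifelse(is.na(idx), 0, log(model$freqs[idx])))
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  # partial likelihoods, one 20 x ncol matrix per node; scaling per column
  partial <- vector("list", nnode)
  logscale <- matrix(0, 1L, ncol_)
  tipcond <- function(chars) {
    L <- matrix(0, 20L, length(chars))
    idx <- match(chars, AA_ALPHABET)
    amb <- is.na(idx)
    L[cbind(idx[!amb], which(!amb))] <- 1
    L[, amb] <- 1
    L
  }
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2L]; parent <- tr$edge[k, 1L]
    Lc <- if (child <= ntip) tipcond(charmat[child, ]) else partial[[child]]
    P <- transition_matrix(model, rate * tr$edge.length[k])
    up <- P %*% Lc
    if (is.null(partial[[parent]])) partial[[parent]] <- up
    else partial[[parent]] <- partial[[parent]] * up
    # rescale to avoid underflow on deep trees
    mx <- apply(partial[[parent]], 2L, max)
    mx[mx == 0] <- 1
    partial[[parent]] <- sweep(partial[[parent]], 2L, mx, "/")
    logscale <- logscale + log(mx)
  }
  root <- tr$edge[nrow(tr$edge), 1L]
  lik <- colSums(model$freqs * partial[[root]])
  as.numeric(log(lik) + logscale)
}

#' Log-likelihood of one alignment column on a tree
#'
#' Felsenstein pruning with transition matrices `exp(Q * rate * t)` and root
#' weighting by the model's equilibrium frequencies. Gaps and `X` are treated
#' as fully ambiguous states. The result is invariant to the (arbitrary)
#' rooting of the unrooted tree because the model is reversible.
#'
#' @param tree `phylo` tree whose tip labels name the species.
#' @param model A [substitution_model()].
#' @param column Named character vector: residue per species.
#' @param rate Positive rate multiplier applied to all branch lengths.
#' @return Natural-log likelihood (scalar).
#' @export
column_likelihood <- function(tree, model, column, rate = 1) {
  if (rate <= 0) stop("rate must be positive")
  cm <- matrix(toupper(column), ncol = 1L,
               dimnames = list(names(column), NULL))
  ll <- prune_loglik(tree, model, cm, rate)
  if (!is.finite(ll)) stop("non-finite likelihood for column")
  ll
}

#' Means of equal-probability discrete-gamma rate categories
#'
#' Mean-1 discretization of a gamma rate distribution into `k` categories of
#' equal prior weight, used by [site_relative_rates()].
#'
#' @param shape Gamma shape parameter, > 0.
#' @param k Number of categories.
#' @return Numeric vector of `k` category means (mean 1).
#' @export
discrete_gamma_means <- function(shape, k) {
  stopifnot(shape > 0, k >= 1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  # mean of a gamma(shape, rate=shape) slice, via the shape+1 cdf identity
  m <- k * (pgamma(q[-1], shape + 1, rate = shape) -
            pgamma(q[-(k + 1)], shape + 1, rate = shape))
  m / mean(m) * 1  # guard rounding; already mean 1 analytically
}

#' Per-column relative evolution rates (RERs)
#'
#' Empirical-Bayes site rates under a discrete-gamma prior: for equal-weight
#' rate categories with means `r_k` (mean-1 discretization), each column's
#' rate is the posterior mean `sum r_k L(col | r_k) / sum L(col | r_k)`.
#' Estimates are rescaled so the mean over scored columns is exactly 1 —
#' the "relative" in RER; conserved columns score well below 1. Columns that
#' are entirely gaps are reported `NA` and excluded from the normalization.
#'
#' @param tree `phylo` tree covering the alignment's species.
#' @param concat A [concatenate_alignments()] object (or [msa()]).
#' @param model A [substitution_model()].
#' @param gamma_shape Shape of the gamma rate prior (default 1).
#' @param n_categories Number of discrete categories (default 8).
#' @return Object of class `kai_rates`: data frame with `col`, `protein`,
#'   `ref_number`, `rer`; attribute `"category_means"`.
#' @export
site_relative_rates <- function(tree, concat, model,
                                gamma_shape = 1, n_categories = 8) {
  m <- if (inherits(concat, "kai_msa")) msa_matrix(concat)
       else concat_matrix(concat)
  if (!setequal(tree$tip.label, rownames(m)))
    stop("tree tips and alignment species differ")
  cm <- m  # species x column, as prune_loglik expects
  rk <- discrete_gamma_means(gamma_shape, n_categories)
  ll <- vapply(rk, function(r) prune_loglik(tree, model, cm, r),
               numeric(ncol(cm)))
  # posterior mean per column with equal category weights
  mx <- apply(ll, 1L, max)
  w <- exp(ll - mx)
  post <- as.numeric((w %*% rk) / rowSums(w))
  allgap <- colSums(!(matrix(cm %in% GAP_CHARS, nrow = nrow(cm)))) == 0L
  post[allgap] <- NA_real_
  post <- post / mean(post, na.rm = TRUE)
  if (inherits(concat, "kai_concat")) {
    prot <- column_protein(concat)
    rn <- if (is.null(concat$ref_map)) NA_integer_ else concat$ref_map$ref_number
  } else {
    prot <- rep(concat$protein, ncol(cm)); rn <- NA_integer_
  }
  structure(data.frame(col = seq_len(ncol(cm)), protein = prot,
                       ref_number = rn, rer = post),
            class = c("kai_rates", "data.frame"),
            category_means = rk, gamma_shape = gamma_shape)
}
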