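# Shared fixtures and independent oracles used across the test files.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# a tiny 3-protein alignment over 4 species, used by seqio tests
tiny_msas <- function() {
  list(
    msa(c(s1 = "ACDEF", s2 = "ACDEF", s3 = "ACDQF", s4 = "AC-EF"), "KaiA"),
    msa(c(s1 = "KLM", s2 = "KLM", s3 = "KIM", s4 = "KLM"), "KaiB"),
    msa(c(s1 = "WYVRNDT", s2 = "WYVRNDT", s3 = "WYVRHDT", s4 = "WYVRNDT"),
        "KaiC"))
}

# Exhaustive-enumeration likelihood oracle: sums over all internal-node state
# assignments. Only feasible for trees with very few internal nodes.
brute_force_loglik <- function(tree, model, column, rate = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  internals <- (ntip + 1L):(ntip + tree$Nnode)
  states <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model, rate * tree$edge.length[e]))
  root <- tree$edge[nrow(tree$edge), 1L]
  tipidx <- match(toupper(column[tree$tip.label]), aa20)
  tot <- 0
  for (r in seq_len(nrow(states))) {
    st <- integer(ntip + tree$Nnode)
    st[seq_len(ntip)] <- tipidx
    st[internals] <- states[r, ]
    pr <- unname(model$freqs[st[root]])
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * Ps[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
    tot <- tot + pr
  }
  log(tot)
}

# From-definition Pearson/t/p oracle on complete data
pearson_oracle <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  list(n = n, r = r, t = t, p = p, significant = p < alpha)
}

# All 15 unrooted 5-taxon topologies with least-squares branch lengths;
# returns the topology minimizing the residual sum of squares.
best_ls_tree_5 <- function(D) {
  ids <- rownames(D)
  stopifnot(length(ids) == 5L)
  topos <- list()
  # every unrooted binary 5-taxon tree is a caterpillar: ((a,b),c,(d,e))
  combs <- utils::combn(5L, 2L)
  seen <- character(0)
  for (k in seq_len(ncol(combs))) {
    ab <- combs[, k]
    rest <- setdiff(1:5, ab)
    for (c1 in rest) {
      de <- setdiff(rest, c1)
      key <- paste(sort(c(paste(sort(ab), collapse = ","),
                          paste(sort(de), collapse = ","))), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      nwk <- sprintf("((%s,%s),%s,(%s,%s));", ids[ab[1]], ids[ab[2]],
                     ids[c1], ids[de[1]], ids[de[2]])
      topos[[length(topos) + 1L]] <- ape::read.tree(text = nwk)
    }
  }
  stopifnot(length(topos) == 15L)
  dv <- D[t(utils::combn(5L, 2L))]
  best <- NULL; best_ss <- Inf
  for (tr in topos) {
    # design matrix: which edges lie on the path between each tip pair
    ne <- nrow(tr$edge)
    X <- matrix(0, ncol(utils::combn(5L, 2L)), ne)
    pairs <- utils::combn(5L, 2L)
    for (pcol in seq_len(ncol(pairs))) {
      i <- match(ids[pairs[1, pcol]], tr$tip.label)
      j <- match(ids[pairs[2, pcol]], tr$tip.label)
      pth <- ape::nodepath(tr, i, j)
      for (s in seq_len(length(pth) - 1L)) {
        e <- which((tr$edge[, 1] == pth[s] & tr$edge[, 2] == pth[s + 1]) |
                   (tr$edge[, 2] == pth[s] & tr$edge[, 1] == pth[s + 1]))
        X[pcol, e] <- 1
      }
    }
    fit <- stats::lm.fit(X, dv)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) { best_ss <- ss; best <- tr; best$edge.length <- fit$coefficients }
  }
  list(tree = best, ss = best_ss)
}

# bisection oracle for the 1:1 free-ligand quadratic
free_ligand_bisect <- function(a_tot, b_tot, kd, tol = 1e-12) {
  f <- function(A) A^2 + (b_tot - a_tot + kd) * A - kd * a_tot
  if (kd == 0) return(max(0, a_tot - b_tot))
  stats::uniroot(f, c(0, a_tot + kd + 1), tol = tol)$root
}

# membership check against a kai_contacts data frame, orientation-free
in_contact_df <- function(cm, pi, ri, pj, rj) {
  any((cm$protein_i == pi & cm$res_i == ri &
       cm$protein_j == pj & cm$res_j == rj) |
      (cm$protein_i == pj & cm$res_i == rj &
       cm$protein_j == pi & cm$res_j == ri))
}

# scalar Robinson-Foulds distance
rf_dist <- function(a, b) as.numeric(ape::dist.topo(a, b))
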