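#' Pairwise protein distances from a concatenated alignment
#'
#' Distances are computed over the columns where both sequences have a
#' standard residue (gaps and `X` excluded pairwise). Available corrections:
#'
#' * `"p"` — raw proportion of mismatching sites;
#' * `"poisson"` — `-log(1 - p)`;
#' * `"kimura_protein"` — `-log(1 - p - 0.2 p^2)`, the classic protein-distance
#'   correction used by alignment viewers and tree tools.
#'
#' Pairs whose correction is undefined (argument of the log non-positive) are
#' returned as `NA` and flagged as saturated with a warning.
#'
#' @param concat A [concatenate_alignments()] object (or [msa()]).
#' @param correction Distance correction.
#' @return Object of class `kai_dist`: list with `ids`, symmetric matrix `d`
#'   and `correction`. `attr(, "saturated")` marks saturated pairs.
#' @export
protein_distances <- function(concat,
                              correction = c("p", "poisson", "kimura_protein")) {
  correction <- match.arg(correction)
  m <- if (inherits(concat, "kai_msa")) msa_matrix(concat)
       else concat_matrix(concat)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 species")
  ids <- rownames(m)
  obs <- !(matrix(m %in% GAP_CHARS, nrow = n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- obs[i, ] & obs[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   ids[i], ids[j]))
    p <- sum(m[i, comp] != m[j, comp]) / nc
    val <- switch(correction,
      p = p,
      poisson = if (p >= 1) NA_real_ else -log(1 - p),
      kimura_protein = {
        arg <- 1 - p - 0.2 * p^2
        if (arg <= 0) NA_real_ else -log(arg)
      })
    if (is.na(val)) sat[i, j] <- sat[j, i] <- TRUE
    d[i, j] <- d[j, i] <- val
  }
  if (any(sat))
    warning(sum(sat) / 2, " saturated pair(s) flagged (distance undefined)")
  structure(list(ids = ids, d = d, correction = correction),
            class = "kai_dist", saturated = sat)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: the pair minimizing the rate-
#' corrected criterion `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined at each
#' step, with branch lengths from the usual formulas. Ties are broken by the
#' lowest original species-index pair. Negative branch-length estimates are
#' clamped to zero and the deficit moved to the sister branch, preserving the
#' path length between the joined taxa. With two taxa the single edge is split
#' evenly.
#'
#' @param d A [protein_distances()] object, a `dist`, or a symmetric numeric
#'   matrix with species names.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "kai_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite (saturated?) entries")
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 edge.length = rep(d[1L, 2L] / 2, 2L),
                 tip.label = ids, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  n_tip <- n
  n_node_max <- 2L * n_tip - 2L
  edge <- matrix(0L, 0L, 2L); elen <- numeric(0)
  # active nodes: tree-node id, plus original index used for tie-breaking
  act_node <- seq_len(n_tip)
  act_orig <- seq_len(n_tip)
  D <- d
  next_node <- n_tip + 1L  # internal ids assigned upward; remapped at the end
  int_id <- integer(0)
  while (length(act_node) > 2L) {
    r <- length(act_node)
    R <- rowSums(D)
    Qc <- (r - 2) * D - outer(R, R, `+`)
    diag(Qc) <- Inf
    # tie-break: lowest original-index pair, lexicographically
    best <- which(Qc == min(Qc), arr.ind = TRUE)
    key <- t(apply(best, 1L, function(ij)
      sort(act_orig[ij])))
    ord <- order(key[, 1L], key[, 2L])
    pick <- best[ord[1L], ]
    i <- min(pick); j <- max(pick)
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    # clamp negatives, moving the deficit to the sister edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    u <- next_node; next_node <- next_node + 1L
    int_id <- c(int_id, u)
    edge <- rbind(edge, c(u, act_node[i]), c(u, act_node[j]))
    elen <- c(elen, vi, vj)
    Dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], Dnew[keep]),
               c(Dnew[keep], 0))
    act_node <- c(act_node[keep], u)
    act_orig <- c(act_orig[keep], min(act_orig[c(i, j)]))
  }
  # final join of the last two lineages by a single edge
  edge <- rbind(edge, c(act_node[2L], act_node[1L]))
  elen <- c(elen, max(D[1L, 2L], 0))
  # remap internal ids so the root (last created node) is n_tip + 1, ape-style
  all_int <- sort(unique(edge[edge > n_tip]))
  # make the final node the root: relabel by traversal from it
  root <- act_node[2L]
  if (root <= n_tip) { # last lineage was a tip: root the edge at the internal end
    root <- act_node[1L]
    edge[nrow(edge), ] <- c(root, act_node[2L])
  }
  remap <- integer(max(all_int))
  remap[root] <- n_tip + 1L
  nxt <- n_tip + 2L
  for (u in rev(all_int)) if (u != root) { remap[u] <- nxt; nxt <- nxt + 1L }
  edge2 <- edge
  edge2[edge > n_tip] <- remap[edge[edge > n_tip]]
  tree <- list(edge = edge2, edge.length = unname(elen), tip.label = ids,
               Nnode = length(all_int))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}
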