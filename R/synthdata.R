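#' Simulate a Yule (pure-birth) tree
#'
#' Topology and node times from a pure-birth process conditioned on the number
#' of tips, with branch lengths rescaled so the mean root-to-tip path length
#' equals `tree_height` (expected substitutions per site). Deterministic for a
#' given seed.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param tree_height Target mean root-to-tip path length.
#' @param seed Integer seed (mandatory: generators are reproducible by
#'   construction).
#' @return A `phylo` tree with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, tree_height = 0.5, seed) {
  stopifnot(n_taxa >= 2, tree_height > 0)
  set.seed(seed)
  tree <- if (n_taxa == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = c(1, 1), tip.label = c("t1", "t2"), Nnode = 1L)
    class(tr) <- "phylo"
    tr
  } else {
    ape::rphylo(n_taxa, birth = 1, death = 0)
  }
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  depth <- mean(ape::node.depth.edgelength(tree)[seq_len(n_taxa)])
  tree$edge.length <- tree$edge.length * tree_height / depth
  tree
}

# Exact CTMC simulation of one site along one branch, returning the sequence
# of (time, new_state) substitution events and the final state.
sim_branch_events <- function(state, len, rate, model) {
  Q <- model$Q
  events_t <- numeric(0); events_s <- integer(0)
  t <- 0
  repeat {
    lambda <- -Q[state, state] * rate
    if (lambda <= 0) break
    t <- t + rexp(1L, lambda)
    if (t >= len) break
    probs <- Q[state, ]
    probs[state] <- 0
    state <- sample.int(20L, 1L, prob = probs)
    events_t <- c(events_t, t); events_s <- c(events_s, state)
  }
  list(state = state, times = events_t, states = events_s)
}

# property-matched resampling: choose the residue whose (signed) scale value
# best matches the driver residue's value, by rank, with a softmax temperature
coupled_residue <- function(driver_state, scale_values, sign, temperature) {
  rk <- rank(scale_values, ties.method = "first")
  target <- if (sign > 0) rk[driver_state] else 21L - rk[driver_state]
  w <- exp(-abs(rk - target) / temperature)
  sample.int(20L, 1L, prob = w)
}

#' Simulate protein alignments with known rates and planted co-varying pairs
#'
#' Columns evolve independently along the tree under the substitution model,
#' with per-site rate multipliers drawn from a mean-1 gamma distribution.
#' For each planted pair `(i, j)`, column `i` evolves by explicit event
#' simulation and, at every substitution event at `i`, column `j`'s state is
#' (with probability `coupling`) replaced by a residue whose property value
#' rank-matches the new residue at `i` (sign `+`) or its rank reflection
#' (sign `-`); between such events `j` evolves neutrally. Coupling is thus
#' event-driven and survives the phylogenetic structure, as real compensatory
#' covariation does.
#'
#' The output mimics a concatenated clock-protein alignment: `n_sites` columns
#' per protein block, one block per entry of `proteins`, all sharing the same
#' taxa.
#'
#' @param tree A `phylo` tree (e.g. [simulate_tree()]).
#' @param n_sites Sites per protein block.
#' @param proteins Character vector of block names.
#' @param model A [substitution_model()].
#' @param gamma_shape Shape of the mean-1 gamma rate distribution; `Inf`
#'   gives rate 1 for all sites.
#' @param coupled_pairs Data frame with columns `col_i`, `col_j` (global
#'   column indices), `scale` (property scale name), `coupling` (kappa in
#'   `[0, 1]`) and `sign` (+1/-1). `NULL` for none.
#' @param temperature Softmax temperature of the rank matching.
#' @param invariant_cols Optional columns forced to rate 0 (invariant).
#' @param seed Integer seed.
#' @return List with `msas` (list of [msa()]), `concat` (their
#'   concatenation), and `truth` (list: `tree`, `rates`, `coupled_pairs`).
#' @export
simulate_alignment <- function(tree, n_sites = 100, proteins = c("KaiA", "KaiB", "KaiC"),
                               model = substitution_model("WAG"),
                               gamma_shape = 1, coupled_pairs = NULL,
                               temperature = 1.5, invariant_cols = NULL,
                               seed = 1) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  set.seed(seed)
  n_col <- n_sites * length(proteins)
  if (!is.null(coupled_pairs)) {
    stopifnot(all(c("col_i", "col_j", "scale", "coupling", "sign") %in%
                    names(coupled_pairs)))
    cols <- c(coupled_pairs$col_i, coupled_pairs$col_j)
    if (any(cols < 1L | cols > n_col)) stop("coupled pair column out of range")
    if (anyDuplicated(cols)) stop("coupled pair columns must be distinct")
    if (any(coupled_pairs$coupling < 0 | coupled_pairs$coupling > 1))
      stop("coupling must be in [0, 1]")
  }
  rates <- if (is.finite(gamma_shape))
    rgamma(n_col, shape = gamma_shape, rate = gamma_shape)
  else rep(1, n_col)
  # planted columns carry the mean rate: a pair planted in a (nearly)
  # invariant column is undetectable by construction and would benchmark the
  # rate lottery rather than the coupling
  if (!is.null(coupled_pairs))
    rates[c(coupled_pairs$col_i, coupled_pairs$col_j)] <- 1
  if (!is.null(invariant_cols)) rates[invariant_cols] <- 0
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tr$Nnode
  pi <- model$freqs
  # states[node, col]
  states <- matrix(NA_integer_, nnode, n_col)
  states[root, ] <- sample.int(20L, n_col, replace = TRUE, prob = pi)
  driver_of <- integer(n_col)   # 0 = independent; else index into coupled_pairs
  if (!is.null(coupled_pairs)) driver_of[coupled_pairs$col_j] <- seq_len(nrow(coupled_pairs))
  scale_cache <- lapply(seq_len(NROW(coupled_pairs)), function(k)
    property_scale(coupled_pairs$scale[k])[AA_ALPHABET])
  # pre-order traversal: parent states known before children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    len <- tr$edge.length[e]
    for (col in seq_len(n_col)) {
      k <- driver_of[col]
      if (k == 0L) {
        # plain endpoint sampling unless this column drives a coupled pair
        kk <- if (!is.null(coupled_pairs))
          match(col, coupled_pairs$col_i, nomatch = 0L) else 0L
        if (kk == 0L) {
          if (rates[col] == 0) { states[child, col] <- states[parent, col]; next }
          P <- transition_matrix(model, rates[col] * len)
          states[child, col] <- sample.int(20L, 1L, prob = P[states[parent, col], ])
        }
        # driver columns are handled together with their partner below
      }
    }
    # coupled pairs: event simulation of the driver, overwriting the partner
    if (!is.null(coupled_pairs)) for (k in seq_len(nrow(coupled_pairs))) {
      ci <- coupled_pairs$col_i[k]; cj <- coupled_pairs$col_j[k]
      sim_i <- sim_branch_events(states[parent, ci], len, rates[ci], model)
      states[child, ci] <- sim_i$state
      # partner evolves neutrally between driver events, segment by segment
      sj <- states[parent, cj]
      t0 <- 0
      sc <- scale_cache[[k]]
      kap <- coupled_pairs$coupling[k]
      # a coupled site substitutes mostly together with its partner: its
      # independent (non-compensatory) rate shrinks with the coupling
      r_free <- rates[cj] * (1 - kap)
      for (ev in seq_along(sim_i$times)) {
        dt <- sim_i$times[ev] - t0
        if (r_free > 0 && dt > 0) {
          P <- transition_matrix(model, r_free * dt)
          sj <- sample.int(20L, 1L, prob = P[sj, ])
        }
        if (runif(1L) < kap)
          sj <- coupled_residue(sim_i$states[ev], sc,
                                coupled_pairs$sign[k], temperature)
        t0 <- sim_i$times[ev]
      }
      if (r_free > 0 && len - t0 > 0) {
        P <- transition_matrix(model, r_free * (len - t0))
        sj <- sample.int(20L, 1L, prob = P[sj, ])
      }
      states[child, cj] <- sj
    }
  }
  tipmat <- matrix(AA_ALPHABET[states[seq_len(ntip), ]], ntip, n_col)
  rownames(tipmat) <- tr$tip.label
  msas <- lapply(seq_along(proteins), function(b) {
    idx <- ((b - 1L) * n_sites + 1L):(b * n_sites)
    msa(tipmat[, idx, drop = FALSE], protein = proteins[b])
  })
  names(msas) <- proteins
  concat <- concatenate_alignments(msas)
  list(msas = msas, concat = concat,
       truth = list(tree = tr, rates = rates, coupled_pairs = coupled_pairs))
}

#' Write a minimal synthetic structure as a PDB file
#'
#' Places one side-chain-like CB atom (plus a CA atom at the same position)
#' per residue at the given coordinates and writes fixed-width ATOM records,
#' readable by any PDB parser. Used as a stand-in complex structure for
#' contact-map tests.
#'
#' @param residues Data frame with `protein`, `ref_number`, `x`, `y`, `z`
#'   (Angstroms) and optionally `chain` (default: one chain per protein,
#'   A, B, ...).
#' @param path Output file path.
#' @return `path`, invisibly; the chain-to-protein mapping is attached as
#'   attribute `"chain_to_protein"`.
#' @export
toy_structure <- function(residues, path = tempfile(fileext = ".pdb")) {
  stopifnot(all(c("protein", "ref_number", "x", "y", "z") %in% names(residues)))
  if (anyDuplicated(residues[, c("protein", "ref_number")]))
    stop("duplicate residue identifiers in toy structure")
  if (any(!is.finite(as.matrix(residues[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  prots <- unique(residues$protein)
  chain_of <- setNames(LETTERS[seq_along(prots)], prots)
  if (is.null(residues$chain)) residues$chain <- chain_of[residues$protein]
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(residues))) {
    for (atom in c("CA", "CB")) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, atom, "ALA", residues$chain[i], residues$ref_number[i],
        residues$x[i], residues$y[i], residues$z[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  attr(path, "chain_to_protein") <- setNames(names(chain_of), chain_of)
  invisible(path)
}

#' Synthetic oscillation trajectory with known period
#'
#' Produces a `kai_trajectory`-shaped data frame whose `pP` channel carries a
#' sinusoid of the requested period, optionally with a second harmonic
#' (same fundamental) or additive Gaussian noise — fixtures for validating
#' period extraction.
#'
#' @param period Oscillation period (h), > 0.
#' @param waveform `"sine"`, `"harmonic"` or `"noisy"`.
#' @param noise_sd Noise standard deviation (fraction units) for `"noisy"`.
#' @param seed Integer seed (used by the noisy variant).
#' @param t_end,dt_out Time grid (h).
#' @param baseline,amplitude Mean level and half peak-to-trough swing of `pP`.
#' @return Data frame `time`, `pP` of class `kai_trajectory`.
#' @export
oscillation_fixture <- function(period, waveform = c("sine", "harmonic", "noisy"),
                                noise_sd = 0.005, seed = 1,
                                t_end = 480, dt_out = 0.05,
                                baseline = 0.45, amplitude = 0.2) {
  stopifnot(period > 0)
  waveform <- match.arg(waveform)
  set.seed(seed)
  t <- seq(0, t_end, by = dt_out)
  y <- baseline + amplitude * sin(2 * pi * t / period)
  if (waveform == "harmonic")
    y <- y + 0.3 * amplitude * sin(4 * pi * t / period + 0.7)
  if (waveform == "noisy")
    y <- y + rnorm(length(t), sd = noise_sd)
  structure(data.frame(time = t, pP = y),
            class = c("kai_trajectory", "data.frame"))
}
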