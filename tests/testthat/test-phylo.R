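test_that("protein distances follow the pairwise-deletion formulas", {
  m <- msa(c(a = "AAAA", b = "AAAL", c = "AA-L"), "P")
  cc <- concatenate_alignments(list(m))
  dp <- protein_distances(cc, "p")
  expect_equal(dp$d["a", "a"], 0)
  expect_equal(dp$d["a", "b"], 0.25)         # 1 mismatch / 4 sites
  expect_equal(dp$d["a", "c"], 1 / 3)        # gap column dropped pairwise
  expect_equal(dp$d, t(dp$d))
  dpois <- protein_distances(cc, "poisson")
  expect_equal(dpois$d["a", "b"], -log(0.75), tolerance = 1e-12)
  dkim <- protein_distances(cc, "kimura_protein")
  expect_equal(dkim$d["a", "b"], -log(1 - 0.25 - 0.2 * 0.25^2),
               tolerance = 1e-12)
  # identical sequences: zero under all corrections
  m2 <- msa(c(a = "ACDE", b = "ACDE"), "P")
  for (corr in c("p", "poisson", "kimura_protein"))
    expect_equal(protein_distances(concatenate_alignments(list(m2)),
                                   corr)$d["a", "b"], 0)
  # saturated pair flagged, not silently dropped
  m3 <- msa(c(a = "AAAA", b = "LLLL"), "P")
  expect_warning(ds <- protein_distances(concatenate_alignments(list(m3)),
                                         "poisson"), "saturated")
  expect_true(is.na(ds$d["a", "b"]))
  # disjoint coverage is an error
  m4 <- msa(c(a = "AA--", b = "--LL"), "P")
  expect_error(protein_distances(concatenate_alignments(list(m4))),
               "no comparable columns")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(rf_dist(ape::unroot(tr), ape::unroot(est)), 0,
                 info = sprintf("rep %d (n=%d)", rep, n))
    expect_equal(sort(est$edge.length),
                 sort(ape::unroot(tr)$edge.length), tolerance = 1e-8)
  }
})

test_that("NJ edge cases: two taxa, asymmetry, cross-check against ape", {
  D2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- nj_tree(D2)
  expect_equal(t2$edge.length, c(0.1, 0.1))
  Dbad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                      c("a", "b")))
  expect_error(nj_tree(Dbad), "symmetric")
  set.seed(5)
  D <- as.matrix(dist(matrix(rnorm(48), 8)))
  expect_equal(rf_dist(ape::unroot(nj_tree(D)), ape::unroot(ape::nj(D))), 0)
})

test_that("NJ matches the brute-force least-squares tree on 5 taxa", {
  set.seed(17)
  for (rep in 1:5) {
    tr <- ape::rtree(5)
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    ora <- best_ls_tree_5(D)
    expect_lt(ora$ss, 1e-16)
    expect_equal(rf_dist(ape::unroot(est), ape::unroot(ora$tree)), 0)
  }
})

test_that("pruning likelihood equals exhaustive state enumeration", {
  set.seed(23)
  mod <- substitution_model("WAG")
  for (rep in 1:3) {
    tr <- ape::rtree(4)
    col <- setNames(sample(aa20, 4, replace = TRUE), tr$tip.label)
    for (rate in c(0.3, 1, 2.5))
      expect_equal(column_likelihood(tr, mod, col, rate),
                   brute_force_loglik(tr, mod, col, rate),
                   tolerance = 1e-10)
  }
  # also with an ambiguous (gap) tip
  tr <- ape::rtree(4)
  col <- setNames(c("A", "-", "W", "A"), tr$tip.label)
  expect_equal(column_likelihood(tr, mod, col),
               brute_force_loglik4_gap <- {
                 # enumerate the gap tip over all states too
                 tot <- 0
                 for (s in aa20) {
                   col2 <- col; col2[2] <- s
                   tot <- tot + exp(brute_force_loglik(tr, mod, col2))
                 }
                 log(tot)
               }, tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting and behaves in limits", {
  set.seed(31)
  mod <- substitution_model("WAG")
  tr <- ape::rtree(6)
  col <- setNames(sample(aa20, 6, replace = TRUE), tr$tip.label)
  base <- column_likelihood(tr, mod, col)
  for (og in tr$tip.label[c(1, 3, 5)]) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(column_likelihood(rr, mod, col), base, tolerance = 1e-9)
  }
  # rate -> 0 on an invariant column approaches log pi of the residue
  inv <- setNames(rep("W", 6), tr$tip.label)
  expect_equal(column_likelihood(tr, mod, inv, rate = 1e-9),
               log(mod$freqs[["W"]]), tolerance = 1e-6)
  expect_error(column_likelihood(tr, mod, col, rate = 0), "positive")
})

test_that("discrete gamma categories match the reference discretization", {
  for (shape in c(0.3, 1, 2.7)) for (k in c(4L, 8L)) {
    m <- discrete_gamma_means(shape, k)
    expect_equal(mean(m), 1, tolerance = 1e-12)
    expect_equal(m, phangorn::discrete.gamma(shape, k), tolerance = 1e-9)
  }
})

test_that("site rates are mean-normalized, permutation-equivariant, and rank conserved columns low", {
  set.seed(41)
  mod <- substitution_model("WAG")
  tr <- simulate_tree(16, tree_height = 1.0, seed = 42)
  sim <- simulate_alignment(tr, n_sites = 40, proteins = "P1", model = mod,
                            gamma_shape = 1, invariant_cols = c(3L, 17L),
                            seed = 43)
  rer <- site_relative_rates(tr, sim$concat, mod)
  expect_equal(mean(rer$rer, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(all(rer$rer >= 0, na.rm = TRUE))
  # invariant-by-construction columns score far below the mean
  expect_lt(rer$rer[3], 0.35)
  expect_lt(rer$rer[17], 0.35)
  # permuting columns permutes the RERs identically
  perm <- sample(sim$concat$n_col)
  shuf <- sim$concat
  mshuf <- concat_mat <- do.call(rbind, strsplit(shuf$seqs, ""))
  shuf$seqs <- setNames(apply(mshuf[, perm, drop = FALSE], 1, paste0,
                              collapse = ""), shuf$ids)
  rer2 <- site_relative_rates(tr, shuf, mod)
  expect_equal(rer2$rer, rer$rer[perm], tolerance = 1e-9)
})

test_that("site-rate estimates recover simulated gamma rates", {
  mod <- substitution_model("WAG")
  tr <- simulate_tree(64, tree_height = 1.0, seed = 11)
  sim <- simulate_alignment(tr, n_sites = 200, proteins = "P1", model = mod,
                            gamma_shape = 1, seed = 12)
  rer <- site_relative_rates(tr, sim$concat, mod)
  rho <- cor(rer$rer, sim$truth$rates, method = "spearman")
  expect_gte(rho, 0.7)
})

test_that("substitution models are proper mean-1 reversible rate matrices", {
  for (nm in c("WAG", "JTT", "Poisson")) {
    mod <- substitution_model(nm)
    expect_lt(max(abs(rowSums(mod$Q))), 1e-12)
    expect_equal(-sum(mod$freqs * diag(mod$Q)), 1, tolerance = 1e-12)
    # detailed balance pi_i Q_ij = pi_j Q_ji
    F <- mod$freqs * mod$Q
    expect_lt(max(abs(F - t(F))), 1e-12)
    P <- transition_matrix(mod, 0.7)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0))
  }
  expect_gt(max(abs(substitution_model("WAG")$Q -
                    substitution_model("JTT")$Q)), 0.01)
})
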