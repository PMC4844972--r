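test_that("property scales cover the alphabet and order sensibly", {
  for (nm in c("volume", "polarity", "hydrophobicity")) {
    sc <- property_scale(nm)
    expect_setequal(names(sc), aa20)
    expect_true(all(is.finite(sc)))
  }
  v <- property_scale("volume")
  expect_lt(v[["G"]], v[["W"]])  # glycine smaller than tryptophan
  expect_error(property_scale(c(A = 1)), "missing amino acids")
})

test_that("column encoding propagates missingness", {
  cc <- concatenate_alignments(list(msa(c(a = "GA-", b = "GA-", c = "-AX",
                                          d = "WAG"), "P")))
  v <- property_scale("volume")
  enc <- encode_column(cc, 1, v)
  expect_equal(enc, unname(c(v["G"], v["G"], NA, v["W"])))
  expect_true(all(is.na(encode_column(cc, 3, v)[1:3])))
  expect_equal(length(unique(encode_column(cc, 2, v))), 1L)  # constant column
})

test_that("column filters implement coverage and variability thresholds", {
  cc <- concatenate_alignments(list(msa(
    c(a = "AALA", b = "AILA", c = "AL-A", d = "ALIA", e = "ALLA",
      f = "ALLA", g = "ALLA", h = "ALLA", i = "ALLA", j = "ALLA",
      k = "ALLA", l = "ALLA", m = "ALLA", n = "ALLA", o = "ALLA",
      p = "ALLA", q = "ALLA", r = "ALLA", s = "ALLA", t = "ALLA"), "P")))
  # col1: invariant -> out; col2: 2 types, 0% gaps -> in;
  # col3: 5% gaps at threshold 5% -> in; col4: invariant -> out
  expect_equal(eligible_columns(cc), c(2L, 3L))
  # 6% gaps fails a 5% threshold
  expect_false(3L %in% eligible_columns(cc, gap_threshold = 0.04))
})

test_that("pair correlation matches the from-definition oracle", {
  expect_equal(pair_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5,
               tolerance = 1e-12)
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(5:80, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    rec <- pair_correlation(x, y)
    ora <- pearson_oracle(x, y)
    expect_equal(rec$r, ora$r, tolerance = 1e-12)
    expect_equal(rec$t_stat, ora$t, tolerance = 1e-12)
    expect_equal(rec$p_value, ora$p, tolerance = 1e-12)
    expect_equal(rec$significant, ora$significant)
  }
  # perfect correlation is significant for n >= 3
  x <- c(1, 2, 5)
  expect_true(pair_correlation(x, x)$significant)
  expect_equal(pair_correlation(x, x)$r, 1)
  # undefined cases flagged not significant
  expect_false(pair_correlation(c(1, 2), c(1, 2))$significant)
  expect_false(pair_correlation(c(1, 1, 1), c(1, 2, 3))$significant)
  expect_true(is.na(pair_correlation(c(1, NA, 3, NA), c(NA, 2, NA, 4))$r))
})

test_that("type-I error is calibrated on i.i.d. null vectors", {
  set.seed(62)
  n <- 65L; reps <- 1e4L
  x <- matrix(rnorm(n * reps), n)
  y <- matrix(rnorm(n * reps), n)
  r <- colSums(scale(x) * scale(y)) / (n - 1)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 0.01)  # 0.05 +/- 0.01 absolute
  # spot-check the vectorized null against pair_correlation on a few draws
  for (k in c(1L, 17L, 4242L))
    expect_equal(pair_correlation(x[, k], y[, k])$p_value, p[k],
                 tolerance = 1e-12)
})

test_that("scan agrees with pair_correlation and flags trivial duplicates", {
  set.seed(63)
  rows <- replicate(12, paste0(sample(c("A", "L", "V", "F"), 6, TRUE),
                               collapse = ""))
  names(rows) <- paste0("s", 1:12)
  cc <- concatenate_alignments(list(msa(rows, "P")))
  recs <- scan_pairs(cc, scales = "volume", variability_threshold = 2)
  for (k in head(seq_len(nrow(recs)), 10)) {
    x <- encode_column(cc, recs$col_i[k], "volume")
    y <- encode_column(cc, recs$col_j[k], "volume")
    ref <- pair_correlation(x, y)
    expect_equal(recs$r[k], ref$r, tolerance = 1e-12)
    expect_equal(recs$p_value[k], ref$p_value, tolerance = 1e-12)
  }
  expect_true(!is.unsorted(recs$p_value, na.rm = TRUE))
  # two copies of the same column correlate perfectly on every scale
  dup <- msa(c(a = "AA", b = "LL", c = "VV", d = "AA"), "P")
  ccd <- concatenate_alignments(list(dup))
  rd <- scan_pairs(ccd, scales = c("volume", "polarity", "hydrophobicity"))
  expect_true(all(rd$r == 1))
  # empty eligible set warns and returns an empty record set
  inv <- concatenate_alignments(list(msa(c(a = "AA", b = "AA", c = "AA"), "P")))
  expect_warning(r0 <- scan_pairs(inv), "eligible")
  expect_equal(nrow(r0), 0L)
})

test_that("a strongly coupled planted pair ranks first in the scan", {
  mod <- substitution_model("WAG")
  tr <- simulate_tree(64, tree_height = 1.0, seed = 71)
  pairs <- data.frame(col_i = 5L, col_j = 25L, scale = "volume",
                      coupling = 0.9, sign = 1)
  sim <- simulate_alignment(tr, n_sites = 40, proteins = "P1", model = mod,
                            gamma_shape = 1, coupled_pairs = pairs, seed = 72)
  recs <- scan_pairs(sim$concat, scales = "volume")
  top <- recs[1L, ]
  expect_setequal(c(top$col_i, top$col_j), c(5L, 25L))
  expect_true(top$significant)
})

test_that("detection power increases with coupling strength", {
  mod <- substitution_model("WAG")
  pairs0 <- data.frame(col_i = seq(1, 20, 2), col_j = seq(2, 20, 2),
                       scale = "volume", coupling = NA, sign = 1)
  # pooled over three tree/alignment replicates to stabilize the estimate
  power <- sapply(c(0.3, 0.6, 0.9), function(kap) {
    hits <- unlist(lapply(73:75, function(s) {
      tr <- simulate_tree(48, tree_height = 1.0, seed = s)
      pairs <- pairs0; pairs$coupling <- kap
      sim <- simulate_alignment(tr, n_sites = 50, proteins = "P1",
                                model = mod, coupled_pairs = pairs,
                                seed = s + 1000)
      recs <- scan_pairs(sim$concat, scales = "volume")
      key <- paste(pmin(recs$col_i, recs$col_j),
                   pmax(recs$col_i, recs$col_j))
      hit <- recs$significant[match(paste(pairs$col_i, pairs$col_j), key)]
      hit[is.na(hit)] <- FALSE
      hit
    }))
    mean(hits)
  })
  expect_true(all(diff(power) >= 0))
})

test_that("Benjamini-Hochberg option only tightens the significant set", {
  set.seed(75)
  rows <- replicate(20, paste0(sample(c("A", "L", "V"), 8, TRUE),
                               collapse = ""))
  names(rows) <- paste0("s", 1:20)
  cc <- concatenate_alignments(list(msa(rows, "P")))
  plain <- scan_pairs(cc, scales = "volume")
  bh <- scan_pairs(cc, scales = "volume", adjust = "BH")
  expect_lte(sum(bh$significant), sum(plain$significant))
})
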