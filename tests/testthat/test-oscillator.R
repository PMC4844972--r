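test_that("free KaiA after sequestration matches clamp and equilibrium limits", {
  p <- oscillator_params()  # kd_seq = 0: stoichiometric clamp
  expect_equal(active_kaia(c(S = 0), p), 1.3)
  expect_equal(active_kaia(c(S = 1.0), p), 0)        # 1.3 - 2*1.0 < 0
  expect_equal(active_kaia(c(S = 0.4), p), 0.5)
  # near-zero sequestration constant converges to the clamp uniformly in S;
  # the worst case sits at the stoichiometric corner, where the deviation is
  # sqrt(kd_seq * A_tot)
  for (kds in c(1e-6, 1e-8)) {
    pk <- oscillator_params(kd_seq = kds)
    sgrid <- seq(0, 1.5, by = 0.01)
    clamp <- pmax(0, 1.3 - 2 * sgrid)
    eq <- vapply(sgrid, function(s) active_kaia(c(S = s), pk), numeric(1))
    expect_lt(max(abs(eq - clamp)), sqrt(kds * 1.3) + 1e-9)
  }
  p6 <- oscillator_params(kd_seq = 1e-6)
  expect_equal(active_kaia(c(S = 1.0), p6), 0, tolerance = 1e-3)
  # finite sequestration constant agrees with the bisection oracle
  p1 <- oscillator_params(kd_seq = 1.0)
  expect_equal(active_kaia(c(S = 0.5), p1),
               free_ligand_bisect(1.3, 1.0, 1.0), tolerance = 1e-10)
})

test_that("the stimulation function reproduces the reference law at the reference point", {
  p <- oscillator_params(kd = 1.0)  # reference kd at 1X totals
  a <- seq(0, 1.3, by = 0.05)
  expect_equal(kaia_stimulus(a, p), a / (0.43 + a), tolerance = 1e-9)
  # away from the reference kd it deviates but stays a saturation in [0, 1)
  p01 <- oscillator_params(kd = 0.1)
  f01 <- kaia_stimulus(a, p01)
  expect_true(all(f01 >= 0 & f01 < 1))
  expect_true(all(diff(f01) > -1e-12))
  expect_equal(kaia_stimulus(1.3, p01), 1.3 / (0.43 + 1.3), tolerance = 1e-9)
})

test_that("phosphoform derivatives respect the balance equations", {
  p <- oscillator_params()
  zero_rates <- lapply(reference_rates(), function(r) c(k0 = 0, kA = 0))
  pz <- oscillator_params(rates = zero_rates)
  expect_equal(unname(phosphoform_derivatives(c(T = 0.5, D = 0.5, S = 0.5), pz)),
               c(0, 0, 0))
  # finite-difference check along an integrated path
  traj <- integrate_oscillator(p, t_end = 30, dt_out = 0.01)
  for (i in c(500, 1500, 2500)) {
    st <- c(T = traj$T[i], D = traj$D[i], S = traj$S[i])
    num <- c(traj$T[i + 1] - traj$T[i - 1],
             traj$D[i + 1] - traj$D[i - 1],
             traj$S[i + 1] - traj$S[i - 1]) / 0.02
    expect_equal(unname(phosphoform_derivatives(st, p)), num,
                 tolerance = 1e-3)
  }
  # mis-parameterization guard: a rate driven negative is reported
  bad <- reference_rates(); bad$DS["kA"] <- -5
  expect_error(phosphoform_derivatives(c(T = 0, D = 0, S = 0),
                                       oscillator_params(rates = bad)),
               "negative transition rate.*DS")
})

test_that("integration conserves phosphoform mass and sustains oscillation", {
  p <- oscillator_params(kd = 1.0)
  traj <- integrate_oscillator(p)
  expect_lt(max(abs(traj$U + traj$T + traj$S + traj$D - 3.4)), 1e-6 * 3.4)
  expect_true(all(traj$pP >= 0 & traj$pP <= 1))
  late <- traj$pP[traj$time >= 240]
  expect_gt(diff(range(late)), 0.05)   # sustained, not damped
  # zero rates give a constant trajectory
  pz <- oscillator_params(rates = lapply(reference_rates(),
                                         function(r) c(k0 = 0, kA = 0)))
  tz <- integrate_oscillator(pz, init = c(T = 0.3, D = 0.2, S = 0.1),
                             t_end = 10, dt_out = 0.5)
  expect_lt(max(abs(tz$T - 0.3)), 1e-8)
  expect_lt(max(abs(tz$S - 0.1)), 1e-8)
})

test_that("the extracted period is integrator- and protocol-independent", {
  p <- oscillator_params(kd = 1.0)
  base <- extract_period(integrate_oscillator(p))
  expect_true(base$oscillating)
  # halving the integration tolerance moves the period by < 1e-3 h
  tight <- extract_period(integrate_oscillator(p, rtol = 5e-9, atol = 5e-11))
  expect_lt(abs(tight$period - base$period), 1e-3)
  # doubling t_end (longer sampling window, same transient)
  long <- extract_period(integrate_oscillator(p, t_end = 960))
  expect_lt(abs(long$period - base$period), 1e-3)
  # halving the output step
  fine <- extract_period(integrate_oscillator(p, dt_out = 0.025))
  expect_lt(abs(fine$period - base$period), 1e-3)
  # basin robustness: perturbed initial conditions converge to the same cycle
  set.seed(111)
  for (rep in 1:3) {
    init <- c(T = runif(1, 0, 0.8), D = runif(1, 0, 0.8),
              S = runif(1, 0, 0.8))
    pe <- extract_period(integrate_oscillator(p, init = init))
    expect_lt(abs(pe$period - base$period), 1e-3)
  }
})

test_that("period extraction is exact on constructed signals", {
  s21 <- oscillation_fixture(21, "sine")
  expect_equal(extract_period(s21)$period, 21, tolerance = 0.01 / 21)
  s24 <- oscillation_fixture(24, "sine")
  expect_equal(extract_period(s24)$period, 24, tolerance = 0.01 / 24)
  # a second harmonic of the same fundamental does not change the period
  sh <- oscillation_fixture(21, "harmonic")
  expect_equal(extract_period(sh)$period, 21, tolerance = 0.02 / 21)
  # noise at 2% of amplitude moves the estimate by < 0.1 h
  sn <- oscillation_fixture(21, "noisy", noise_sd = 0.004, seed = 5)
  expect_lt(abs(extract_period(sn)$period - 21), 0.1)
  # constant signal: not oscillating
  flat <- data.frame(time = seq(0, 480, 0.05), pP = 0.5)
  expect_false(extract_period(flat)$oscillating)
  # too few peaks after the transient: not oscillating
  slow <- oscillation_fixture(120, "sine")
  expect_false(extract_period(slow)$oscillating)
})

test_that("the concentration scan measures robustness per dissociation constant", {
  # a single scale has zero period range by definition
  one <- concentration_scan(oscillator_params(), scales = 1, kds = 1.0)
  expect_equal(attr(one, "robustness")$range_over_median, 0)
  sc <- concentration_scan(oscillator_params(), scales = c(0.5, 1, 2, 4),
                           kds = c(1.0, 0.1))
  expect_equal(nrow(sc), 8L)
  rob <- attr(sc, "robustness")
  expect_true(all(sc$oscillating))
  expect_lt(rob$range_over_median[rob$kd == 0.1],
            rob$range_over_median[rob$kd == 1.0])
  p01 <- sc$period[sc$kd == 0.1]
  expect_lt(max(p01) - min(p01), 1)
})
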