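# Default phosphoform rate constants of the reference four-state model
# (h^-1): base rate k0 and KaiA-stimulated span kA for the eight transitions
# U->T, T->D, S->D, U->S (phosphorylation) and T->U, D->T, D->S, S->U
# (dephosphorylation). The stimulated rate is k0 + kA * f with f in [0, 1).
reference_rates <- function() {
  list(
    UT = c(k0 = 0.00, kA = 0.479077),
    TD = c(k0 = 0.00, kA = 0.212923),
    SD = c(k0 = 0.00, kA = 0.505692),
    US = c(k0 = 0.00, kA = 0.0532308),
    TU = c(k0 = 0.21, kA = 0.0798462),
    DT = c(k0 = 0.00, kA = 0.173000),
    DS = c(k0 = 0.31, kA = -0.319385),
    SU = c(k0 = 0.11, kA = -0.133077))
}

#' Parameters of the phosphoform oscillator with explicit KaiA-KaiC binding
#'
#' The model tracks the three phosphorylated KaiC forms T (T432 only),
#' D (both sites) and S (S431 only) in uM, with U given by conservation.
#' Each transition rate is `k0 + kA * f(A)` where `f` is the KaiA stimulation
#' function.
#'
#' KaiA enters in two ways:
#' * **Sequestration** (KaiB-mediated inhibition): S-form KaiC captures
#'   KaiA with stoichiometry `m` per S monomer. The capture is effectively
#'   irreversible; the available KaiA is `free_ligand(kaiA_tot, m*S, kd_seq)`
#'   with `kd_seq = 0` (the stoichiometric clamp of the reference model) by
#'   default.
#' * **Stimulation**: the available KaiA binds the KaiC C-terminal tails
#'   (capacity `m * kaiC_tot` in KaiA-monomer equivalents) with dissociation
#'   constant `kd` — the constant the concentration-robustness analysis
#'   varies. The stimulation function maps the free-KaiA binding signal
#'   through the reference operating point (`kaiA 1.3, kaiC 3.4 uM,
#'   kd_ref = 1.0 uM`), so that at `kd = kd_ref` and 1X concentrations the
#'   model reproduces the reference saturation `A/(K_half + A)` exactly,
#'   while for `kd -> 0` the stimulation depends on concentration ratios
#'   only, which is what makes the period robust to proportional changes of
#'   all totals. See the package vignette for the derivation.
#'
#' @param kd Dissociation constant of the stimulatory KaiA-KaiC binding (uM).
#' @param kd_seq Dissociation constant of the sequestration step (uM);
#'   0 = stoichiometric clamp.
#' @param kaiA_tot,kaiB_tot,kaiC_tot Total concentrations (uM); defaults are
#'   the standard 1X in-vitro mixture 1.3/3.4/3.4. KaiB is carried for
#'   bookkeeping (it scales with 1X) but is implicit in the equations: its
#'   action is the sequestration term.
#' @param m Sequestration/binding stoichiometry (KaiA monomers per KaiC
#'   monomer; 2 = one KaiA dimer).
#' @param k_half Half-saturation of the reference stimulation function (uM).
#' @param rates List of eight `c(k0, kA)` pairs, as [reference_rates()].
#' @param ref Reference operating point `list(kaiA, kaiC, kd)` anchoring the
#'   stimulation calibration.
#' @return Object of class `kai_osc_params`.
#' @export
oscillator_params <- function(kd = 1.0, kd_seq = 0,
                              kaiA_tot = 1.3, kaiB_tot = 3.4, kaiC_tot = 3.4,
                              m = 2, k_half = 0.43,
                              rates = reference_rates(),
                              ref = list(kaiA = 1.3, kaiC = 3.4, kd = 1.0)) {
  stopifnot(kd > 0, kd_seq >= 0, kaiA_tot >= 0, kaiB_tot >= 0, kaiC_tot >= 0,
            m > 0, k_half > 0)
  need <- c("UT", "TD", "SD", "US", "TU", "DT", "DS", "SU")
  if (!all(need %in% names(rates)))
    stop("rates must contain: ", paste(need, collapse = ", "))
  structure(list(kd = kd, kd_seq = kd_seq, kaiA_tot = kaiA_tot,
                 kaiB_tot = kaiB_tot, kaiC_tot = kaiC_tot, m = m,
                 k_half = k_half, rates = rates, ref = ref),
            class = "kai_osc_params")
}

#' @export
print.kai_osc_params <- function(x, ...) {
  cat(sprintf(
    "<kai_osc_params> kd = %g uM, totals A/B/C = %g/%g/%g uM, m = %g\n",
    x$kd, x$kaiA_tot, x$kaiB_tot, x$kaiC_tot, x$m))
  invisible(x)
}

#' Scale all protein totals proportionally
#'
#' @param params A [oscillator_params()].
#' @param scale Positive factor applied to KaiA, KaiB and KaiC totals
#'   (protein ratios fixed).
#' @return Scaled parameter object.
#' @export
scale_totals <- function(params, scale) {
  stopifnot(inherits(params, "kai_osc_params"), scale > 0)
  params$kaiA_tot <- params$kaiA_tot * scale
  params$kaiB_tot <- params$kaiB_tot * scale
  params$kaiC_tot <- params$kaiC_tot * scale
  params
}

#' Free (unsequestered) KaiA
#'
#' Solves the 1:1 binding of KaiA to the sequestering sites contributed by
#' S-form KaiC (`m * S`) at the sequestration constant `kd_seq`. With
#' `kd_seq = 0` this is the stoichiometric clamp
#' `max(0, kaiA_tot - m * S)` of the reference model.
#'
#' @param state Named vector or list with element `S` (uM), or a numeric S.
#' @param params A [oscillator_params()].
#' @return Free KaiA (uM).
#' @export
active_kaia <- function(state, params) {
  S <- if (is.numeric(state) && is.null(names(state)) && length(state) == 1L)
    state else state[["S"]]
  stopifnot(S >= -1e-12)
  free_ligand(params$kaiA_tot, params$m * max(S, 0), params$kd_seq)
}

# inverse of free_ligand in its first argument (v = free -> total needed is
# not what we want; this inverts free as a function of *available* ligand):
# if v = free_ligand(a, B, K) then a = v (v + B + K) / (v + K).
invert_free_ligand <- function(v, b_tot, kd) v * (v + b_tot + kd) / (v + kd)

#' KaiA stimulation function
#'
#' Maps available (unsequestered) KaiA to the stimulation factor `f` in
#' `k = k0 + kA * f`. The available KaiA equilibrates with the KaiC tail pool
#' (capacity `m * kaiC_tot`) at dissociation constant `kd`; the relative
#' binding signal `z = A_free(A_avail)/A_free(kaiA_tot)` is mapped through
#' the reference operating point and fed to the reference saturation
#' `A_eff/(k_half + A_eff)`. At `kd = ref$kd` and reference totals,
#' `f` equals the reference model's `A_avail/(k_half + A_avail)` identically.
#'
#' @param a_avail Available KaiA after sequestration (uM); vectorized.
#' @param params A [oscillator_params()].
#' @return Stimulation factor in `[0, 1)`.
#' @export
kaia_stimulus <- function(a_avail, params) {
  p <- params
  b <- p$m * p$kaiC_tot
  z <- free_ligand(a_avail, b, p$kd) / free_ligand(p$kaiA_tot, b, p$kd)
  b_ref <- p$m * p$ref$kaiC
  v_ref <- free_ligand(p$ref$kaiA, b_ref, p$ref$kd)
  a_eff <- invert_free_ligand(v_ref * z, b_ref, p$ref$kd)
  a_eff / (p$k_half + a_eff)
}

transition_rates <- function(f, rates) {
  k <- vapply(rates, function(r) r[["k0"]] + r[["kA"]] * f, numeric(1))
  if (any(k < -1e-12))
    stop("negative transition rate for ",
         paste(names(rates)[k < -1e-12], collapse = ", "),
         " (mis-parameterization?)")
  pmax(k, 0)
}

#' Time derivatives of the phosphoform concentrations
#'
#' Mass-balance equations of the four-state cycle with U eliminated by
#' conservation (`U = kaiC_tot - T - D - S`).
#'
#' @param state Named numeric vector `c(T = , D = , S = )` (uM).
#' @param params A [oscillator_params()].
#' @return Named vector `c(dT, dD, dS)` in uM/h.
#' @export
phosphoform_derivatives <- function(state, params) {
  T_ <- state[["T"]]; D_ <- state[["D"]]; S_ <- state[["S"]]
  U_ <- params$kaiC_tot - T_ - D_ - S_
  f <- kaia_stimulus(active_kaia(c(S = S_), params), params)
  k <- transition_rates(f, params$rates)
  c(dT = k[["UT"]] * U_ + k[["DT"]] * D_ - k[["TU"]] * T_ - k[["TD"]] * T_,
    dD = k[["TD"]] * T_ + k[["SD"]] * S_ - k[["DT"]] * D_ - k[["DS"]] * D_,
    dS = k[["US"]] * U_ + k[["DS"]] * D_ - k[["SU"]] * S_ - k[["SD"]] * S_)
}

#' Integrate the phosphoform oscillator
#'
#' Adaptive stiff-aware integration (deSolve's `lsoda`) at relative tolerance
#' `1e-8`, with dense output on a regular grid. The default initial state is
#' fully dephosphorylated KaiC, mirroring the in-vitro protocol.
#'
#' @param params A [oscillator_params()].
#' @param init Named initial state `c(T = , D = , S = )` (uM).
#' @param t_end Integration end time (h).
#' @param dt_out Output grid step (h).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `kai_trajectory`: data frame `time`, `U`, `T`,
#'   `S`, `D`, `pP` (phosphorylated fraction `(T+D+S)/kaiC_tot`).
#' @export
integrate_oscillator <- function(params, init = c(T = 0, D = 0, S = 0),
                                 t_end = 480, dt_out = 0.05,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kai_osc_params"), t_end > 0, dt_out > 0)
  # flattened copies of what the derivative needs, avoiding per-step list
  # traversal; same arithmetic as phosphoform_derivatives()
  ord <- c("UT", "TD", "SD", "US", "TU", "DT", "DS", "SU")
  k0 <- vapply(params$rates[ord], `[[`, numeric(1), "k0")
  kA <- vapply(params$rates[ord], `[[`, numeric(1), "kA")
  ctot <- params$kaiC_tot; atot <- params$kaiA_tot
  m <- params$m; kdseq <- params$kd_seq; kd <- params$kd
  khalf <- params$k_half
  b <- m * ctot
  b_ref <- params$m * params$ref$kaiC
  v_rep <- free_ligand(atot, b, kd)
  v_ref <- free_ligand(params$ref$kaiA, b_ref, params$ref$kd)
  kd_ref <- params$ref$kd
  deriv <- function(t, y, p) {
    T_ <- y[1L]; D_ <- y[2L]; S_ <- y[3L]
    U_ <- ctot - T_ - D_ - S_
    a_av <- free_ligand(atot, m * max(S_, 0), kdseq)
    z <- free_ligand(a_av, b, kd) / v_rep
    v <- v_ref * z
    a_eff <- v * (v + b_ref + kd_ref) / (v + kd_ref)
    f <- a_eff / (khalf + a_eff)
    k <- pmax(k0 + kA * f, 0)
    list(c(k[1L] * U_ + k[6L] * D_ - k[5L] * T_ - k[2L] * T_,
           k[2L] * T_ + k[3L] * S_ - k[6L] * D_ - k[7L] * D_,
           k[4L] * U_ + k[7L] * D_ - k[8L] * S_ - k[3L] * S_))
  }
  # parameter sanity: the guarded public derivative must agree at the start
  chk <- phosphoform_derivatives(c(T = unname(init[["T"]]),
                                   D = unname(init[["D"]]),
                                   S = unname(init[["S"]])), params)
  stopifnot(max(abs(chk - unlist(deriv(0, unname(init[c("T", "D", "S")]),
                                       NULL)[[1L]]))) < 1e-9)
  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::ode(unname(init[c("T", "D", "S")]), times, deriv, params,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed at t = ", max(out[, 1L]))
  df <- data.frame(time = out[, 1L], T = out[, 2L], D = out[, 3L],
                   S = out[, 4L])
  df$U <- params$kaiC_tot - df$T - df$D - df$S
  bad <- abs(df$U + df$T + df$D + df$S - params$kaiC_tot) >
    1e-6 * max(params$kaiC_tot, 1)
  if (any(bad)) stop("phosphoform mass conservation violated")
  df$pP <- (df$T + df$D + df$S) / params$kaiC_tot
  df <- df[, c("time", "U", "T", "S", "D", "pP")]
  structure(df, class = c("kai_trajectory", "data.frame"), params = params)
}

#' Extract the oscillation period from a trajectory
#'
#' Detects local maxima of the phosphorylated fraction after discarding the
#' transient, refines each peak by quadratic interpolation through its
#' three-point neighborhood, and reports the mean peak-to-peak interval. A
#' trajectory qualifies as oscillating when at least 5 peaks remain after the
#' transient and the peak-to-trough amplitude is non-negligible.
#'
#' @param traj A [integrate_oscillator()] trajectory, or any data frame with
#'   `time` and `pP` columns.
#' @param transient Initial time span to discard (h).
#' @param min_amplitude Minimum mean peak-to-trough amplitude (fraction of
#'   total KaiC) to call the trajectory oscillating.
#' @param smooth Width (h) of a centered moving-average filter applied before
#'   peak detection; suppresses spurious maxima on noisy signals while leaving
#'   smooth ODE output and peak positions unchanged. 0 disables.
#' @return Object of class `kai_period`: list with `period` (h), `period_sd`,
#'   `amplitude`, `n_peaks`, `oscillating`.
#' @export
extract_period <- function(traj, transient = 240, min_amplitude = 0.01,
                           smooth = 1) {
  stopifnot(all(c("time", "pP") %in% names(traj)))
  keep <- traj$time >= transient
  t <- traj$time[keep]; y <- traj$pP[keep]
  if (length(t) < 7L) stop("trajectory shorter than the transient")
  if (smooth > 0 && length(t) > 3L) {
    dt <- t[2L] - t[1L]
    w <- max(1L, round(smooth / dt))
    if (w %% 2L == 0L) w <- w + 1L
    if (w >= 3L && w < length(y)) {
      ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
      ok <- !is.na(ys)
      t <- t[ok]; y <- ys[ok]
    }
  }
  not_osc <- structure(list(period = NA_real_, period_sd = NA_real_,
                            amplitude = NA_real_, n_peaks = 0L,
                            oscillating = FALSE), class = "kai_period")
  if (diff(range(y)) < min_amplitude) return(not_osc)
  # segment the record into cycles by upward midline crossings with
  # hysteresis, so that small-scale noise cannot split a cycle; one local
  # maximum (and minimum) is then taken per cycle and refined by quadratic
  # interpolation through its three-point neighborhood
  mid <- (max(y) + min(y)) / 2
  hyst <- 0.1 * (max(y) - min(y)) / 2
  armed <- y[1L] < mid - hyst
  up <- integer(0)
  for (i in 2:length(y)) {
    if (armed && y[i - 1L] < mid && y[i] >= mid) {
      up <- c(up, i)
      armed <- FALSE
    } else if (!armed && y[i] < mid - hyst) armed <- TRUE
  }
  if (length(up) < 6L) {  # fewer than 5 complete cycles
    not_osc$n_peaks <- max(0L, length(up) - 1L)
    return(not_osc)
  }
  refine <- function(i) {
    if (i <= 1L || i >= length(y)) return(t[i])
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom == 0) t[i] else t[i] + 0.5 * (y1 - y3) / denom * (t[i] - t[i - 1L])
  }
  ncyc <- length(up) - 1L
  tp <- numeric(ncyc); pkv <- numeric(ncyc); trv <- numeric(ncyc)
  for (c. in seq_len(ncyc)) {
    seg <- up[c.]:(up[c. + 1L] - 1L)
    ip <- seg[which.max(y[seg])]
    it <- seg[which.min(y[seg])]
    tp[c.] <- refine(ip)
    pkv[c.] <- y[ip]; trv[c.] <- y[it]
  }
  amp <- mean(pkv) - mean(trv)
  if (!is.finite(amp) || amp < min_amplitude) return(not_osc)
  per <- diff(tp)
  structure(list(period = mean(per), period_sd = sd(per), amplitude = amp,
                 n_peaks = ncyc, oscillating = TRUE),
            class = "kai_period")
}

#' @export
print.kai_period <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf("<kai_period> %.2f h (sd %.3g, %d peaks, amplitude %.3f)\n",
                x$period, x$period_sd, x$n_peaks, x$amplitude))
  else cat("<kai_period> not oscillating\n")
  invisible(x)
}

#' Concentration-robustness scan of the oscillation period
#'
#' For every combination of dissociation constant and concentration scale
#' factor, multiplies all three protein totals by the factor (ratios fixed),
#' integrates the oscillator and extracts the period. The per-`kd` robustness
#' metric is the period range divided by the median period across scales
#' (plus the coefficient of variation); non-oscillating cells are recorded
#' and excluded from the metric with a warning.
#'
#' @param params Baseline (1X) [oscillator_params()].
#' @param scales Concentration scale factors.
#' @param kds Dissociation constants to scan (uM).
#' @param t_end,transient Passed to the integrator / period extraction.
#' @param dt_out Output grid step (h).
#' @return Object of class `kai_scan`: data frame `kd`, `scale`, `period`,
#'   `amplitude`, `oscillating`; attribute `"robustness"` is a data frame
#'   `kd`, `range_over_median`, `cv`, `n_oscillating`.
#' @export
concentration_scan <- function(params = oscillator_params(),
                               scales = c(0.5, 1, 2, 4), kds = c(1.0, 0.1),
                               t_end = 480, transient = 240, dt_out = 0.05) {
  stopifnot(all(scales > 0), all(kds > 0))
  grid <- expand.grid(scale = scales, kd = kds)[, c("kd", "scale")]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$kd <- grid$kd[i]
    p <- scale_totals(p, grid$scale[i])
    pe <- extract_period(integrate_oscillator(p, t_end = t_end,
                                              dt_out = dt_out),
                         transient = transient)
    data.frame(kd = grid$kd[i], scale = grid$scale[i], period = pe$period,
               amplitude = pe$amplitude, oscillating = pe$oscillating)
  })
  res <- do.call(rbind, res)
  if (any(!res$oscillating))
    warning(sum(!res$oscillating),
            " non-oscillating cell(s) excluded from the robustness metric")
  rob <- do.call(rbind, lapply(split(res, res$kd), function(d) {
    per <- d$period[d$oscillating]
    data.frame(kd = d$kd[1L],
               range_over_median = if (length(per) >= 1L)
                 (max(per) - min(per)) / median(per) else NA_real_,
               cv = if (length(per) >= 2L) sd(per) / mean(per)
                    else if (length(per) == 1L) 0 else NA_real_,
               n_oscillating = length(per))
  }))
  rob <- rob[order(-rob$kd), ]
  rownames(rob) <- NULL
  structure(res, class = c("kai_scan", "data.frame"), robustness = rob)
}

#' @export
print.kai_scan <- function(x, ...) {
  cat("<kai_scan>\n")
  print.data.frame(x)
  cat("robustness (period range / median across scales):\n")
  print.data.frame(attr(x, "robustness"))
  invisible(x)
}
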