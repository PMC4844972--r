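#' Two-step KaiA-KaiC binding scheme
#'
#' The dynamic-interaction hypothesis represents KaiA-KaiC binding as an
#' encounter step followed by a conformational isomerization:
#' `A + C <-> A.C <-> A'.C'`, where the primed species are the states after
#' conformational change. `K1` (in uM) is the dissociation constant of the
#' encounter step, `[A][C]/[A.C]`; `K2` (dimensionless) is the isomerization
#' ratio `[A.C]/[A'.C']` at equilibrium.
#'
#' @param k1 Encounter-step dissociation constant (uM), > 0.
#' @param k2 Isomerization ratio `[A.C]/[A'.C']`, > 0.
#' @return Object of class `kai_two_step`.
#' @export
two_step_scheme <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  structure(list(k1 = k1, k2 = k2), class = "kai_two_step")
}

#' Equilibrium of the two-step binding scheme
#'
#' Solves for the unique equilibrium satisfying `[A][C]/[A.C] = K1`,
#' `[A.C]/[A'.C'] = K2` and both conservation laws, by a monotone
#' one-dimensional root solve on the total complex concentration, bracketed in
#' `[0, min(A_tot, C_tot)]`.
#'
#' @param scheme A [two_step_scheme()].
#' @param a_tot,c_tot Total concentrations (uM), >= 0.
#' @param tol Relative convergence tolerance.
#' @return Object of class `kai_equilibrium`: list with free `A`, `C`,
#'   complexes `AC`, `APCP`, and the totals.
#' @export
solve_two_step <- function(scheme, a_tot, c_tot, tol = 1e-12) {
  stopifnot(inherits(scheme, "kai_two_step"), a_tot >= 0, c_tot >= 0)
  k1 <- scheme$k1; k2 <- scheme$k2
  # x = [A.C] + [A'.C'];  [A.C] = x k2/(1+k2)
  hi <- min(a_tot, c_tot)
  if (hi == 0) {
    st <- list(A = a_tot, C = c_tot, AC = 0, APCP = 0,
               a_tot = a_tot, c_tot = c_tot)
    return(structure(st, class = "kai_equilibrium"))
  }
  g <- function(x) (a_tot - x) * (c_tot - x) - k1 * x * k2 / (1 + k2)
  # g is strictly decreasing on [0, hi]; g(0) > 0 >= g(hi)
  root <- uniroot(g, c(0, hi), tol = max(tol * hi, .Machine$double.eps * 4))
  x <- root$root
  if (abs(g(x)) > 1e-8 * (a_tot * c_tot + k1 * hi + 1))
    stop(sprintf(
      "equilibrium solve did not converge (bracket [0, %g], residual %g)",
      hi, g(x)))
  st <- list(A = a_tot - x, C = c_tot - x,
             AC = x * k2 / (1 + k2), APCP = x / (1 + k2),
             a_tot = a_tot, c_tot = c_tot)
  structure(st, class = "kai_equilibrium")
}

#' Apparent and combined dissociation constants of the two-step scheme
#'
#' When the two complex states cannot be distinguished experimentally, the
#' measured ("fitted") dissociation constant pools them:
#' `K_Dfit = [A][C]/([A.C] + [A'.C'])`. The per-state apparent constants are
#' `K_Dapp1 = [A][C]/[A.C]` and `K_Dapp2 = [A][C]/[A'.C']`. These satisfy the
#' harmonic identity `1/K_Dfit = 1/K_Dapp1 + 1/K_Dapp2`, hence there is a
#' `gamma` in (0,1) with `K_Dfit = gamma K_Dapp1 = (1-gamma) K_Dapp2`
#' (`gamma = K_Dapp2/(K_Dapp1 + K_Dapp2)`), and `K_Dfit` is strictly smaller
#' than either apparent constant whenever both complexes are populated.
#'
#' @param state A [solve_two_step()] equilibrium.
#' @return List of class `kai_binding_constants`: `kd_app1`, `kd_app2`,
#'   `kd_fit` (uM) and `gamma`.
#' @export
binding_constants <- function(state) {
  stopifnot(inherits(state, "kai_equilibrium"))
  if (state$AC + state$APCP <= 0)
    stop("no complex formed; dissociation constants undefined")
  num <- state$A * state$C
  kd1 <- num / state$AC
  kd2 <- num / state$APCP
  kdf <- num / (state$AC + state$APCP)
  structure(list(kd_app1 = kd1, kd_app2 = kd2, kd_fit = kdf,
                 gamma = kd2 / (kd1 + kd2)),
            class = "kai_binding_constants")
}

#' @export
print.kai_binding_constants <- function(x, ...) {
  cat(sprintf(
    "<kai_binding_constants> K_Dapp1 = %.4g uM, K_Dapp2 = %.4g uM, K_Dfit = %.4g uM, gamma = %.4f\n",
    x$kd_app1, x$kd_app2, x$kd_fit, x$gamma))
  invisible(x)
}

#' Free ligand concentration for 1:1 binding
#'
#' Unique nonnegative root of `A^2 + (B_tot - A_tot + K_D) A - K_D A_tot = 0`
#' for a ligand A binding a pool of `B_tot` sites with dissociation constant
#' `K_D`, evaluated in the cancellation-free (citardauq) form so that the
#' small-`K_D` regime is computed accurately. `K_D = 0` returns the
#' stoichiometric limit `max(0, A_tot - B_tot)`. Vectorized over all three
#' arguments.
#'
#' @param a_tot Total ligand (uM), >= 0.
#' @param b_tot Total binding sites (uM), >= 0.
#' @param kd Dissociation constant (uM), >= 0.
#' @return Free ligand concentration (uM).
#' @export
free_ligand <- function(a_tot, b_tot, kd) {
  stopifnot(all(a_tot >= 0), all(b_tot >= 0), all(kd >= 0))
  n <- max(length(a_tot), length(b_tot), length(kd))
  a_tot <- rep_len(a_tot, n); b_tot <- rep_len(b_tot, n)
  kd <- rep_len(kd, n)
  b <- b_tot - a_tot + kd
  disc <- sqrt(b^2 + 4 * kd * a_tot)
  ifelse(b >= 0,
         ifelse(b + disc > 0, 2 * kd * a_tot / (b + disc), 0),
         (disc - b) / 2)
}

#' Rescale a dissociation constant from a complex half-life change
#'
#' If extending the interaction time increases the complex half-life
#' `t_1/2 = ln(2)/k_off` by a given fold while the association rate is
#' unchanged, the dissociation constant is smaller by the same fold:
#' `K_D = K_D_reported / fold`. This is the estimate that turns a reported
#' 2.5 uM constant with a ~20-fold half-life increase into ~0.1 uM.
#'
#' @param kd_reported Reported dissociation constant (uM), > 0.
#' @param halflife_fold_increase Fold increase of the complex half-life, > 0.
#' @return Rescaled dissociation constant (uM).
#' @export
kd_rescale_from_halflife <- function(kd_reported, halflife_fold_increase) {
  stopifnot(kd_reported > 0, halflife_fold_increase > 0)
  kd_reported / halflife_fold_increase
}
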