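# Forward model of the irreversible two-tissue compartment system.
#
# All tissue curves are evaluated through two exponential integral
# primitives,
#   E(z, t) = int_0^t e^{z s} ds,   D(z, t) = int_0^t s e^{z s} ds,
# computed with expm1-based, cancellation-free branches. Expanding E and D
# reproduces term by term the explicit five-term closed form of the tissue
# response, including the degenerate branches mu_j = 0 (a term linear in t)
# and k2 + k3 + mu_j = 0 (a t*exp(-(k2+k3) t) term).

# E(z, t): exact limit t at z = 0; expm1 is stable for all other z.
exp_int <- function(z, t) {
  if (z == 0) return(t)
  expm1(z * t) / z
}

# D(z, t): the direct formula (t e^{zt} - E)/z cancels catastrophically for
# |z t| small; switch to the series t^2 (1/2 + zt/3 + (zt)^2/8 + (zt)^3/30)
# there (truncation error < 1e-14 relative at |z t| < 1e-3).
exp_int_s <- function(z, t) {
  zt <- z * t
  small <- abs(zt) < 1e-3
  out <- numeric(length(t))
  if (any(small)) {
    u <- zt[small]
    out[small] <- t[small]^2 * (0.5 + u / 3 + u^2 / 8 + u^3 / 30)
  }
  if (any(!small)) {
    tt <- t[!small]
    out[!small] <- (tt * exp(z * tt) - expm1(z * tt) / z) / z
  }
  out
}

#' Evaluate a polyexponential curve
#'
#' @param curve a [polyexp()] object.
#' @param t time or time vector (min).
#' @return \eqn{\sum_j \lambda_j e^{\mu_j t}} elementwise; 0 for a degree-0
#'   curve.
#' @export
eval_polyexp <- function(curve, t) {
  stopifnot(inherits(curve, "petkin_polyexp"))
  if (curve$degree == 0) return(rep(0, length(t)))
  drop(exp(outer(t, curve$mus)) %*% curve$lambdas)
}

#' Evaluate the biexponential parent plasma fraction
#'
#' @param params a [plasma_fraction()] object.
#' @param t time or time vector (min).
#' @return \eqn{A e^{\xi_1 t} + (1-A) e^{\xi_2 t}}; equals 1 at t = 0.
#' @export
eval_plasma_fraction <- function(params, t) {
  stopifnot(inherits(params, "petkin_fraction"))
  params$A * exp(params$xi1 * t) + (1 - params$A) * exp(params$xi2 * t)
}

#' Solve the two-tissue compartment system for one region
#'
#' Closed-form solution of the irreversible model
#' \deqn{C_F' = K_1 C_P - (k_2 + k_3) C_F, \quad C_B' = k_3 C_F,}
#' with zero initial conditions and polyexponential input. Returns the free,
#' bound and total tissue concentrations at the requested times.
#'
#' @param K a [kinetic_params()] object.
#' @param cp a [polyexp()] input curve.
#' @param times evaluation times (min).
#' @return A list of class `petkin_compartments` with numeric vectors `CF`,
#'   `CB` and `CT = CF + CB`.
#' @export
solve_compartments <- function(K, cp, times) {
  stopifnot(inherits(K, "petkin_kinetics"), inherits(cp, "petkin_polyexp"))
  kappa <- K$k2 + K$k3
  if (kappa == 0) stop("k2 + k3 must be nonzero", call. = FALSE)
  times <- as.numeric(times)
  if (cp$degree == 0) {
    z <- rep(0, length(times))
    return(structure(list(CF = z, CB = z, CT = z, times = times),
                     class = "petkin_compartments"))
  }
  ekt <- exp(-kappa * times)
  S1 <- numeric(length(times))  # e^{-kappa t} int_0^t e^{kappa s} C_P(s) ds
  S2 <- numeric(length(times))  # int_0^t C_P(s) ds
  for (j in seq_len(cp$degree)) {
    S1 <- S1 + cp$lambdas[j] * ekt * exp_int(kappa + cp$mus[j], times)
    S2 <- S2 + cp$lambdas[j] * exp_int(cp$mus[j], times)
  }
  CF <- K$K1 * S1
  CB <- K$K1 * K$k3 / kappa * (S2 - S1)
  structure(list(CF = CF, CB = CB, CT = CF + CB, times = times),
            class = "petkin_compartments")
}

#' Closed-form total tissue concentration
#'
#' Evaluates the explicit closed form of the tissue response
#' \eqn{C_T = C_F + C_B} for a polyexponential input, including the
#' degenerate branches \eqn{\mu_j = 0} and \eqn{k_2 + k_3 + \mu_j = 0}
#' (which contribute terms linear in t and proportional to
#' \eqn{t e^{-(k_2+k_3)t}}, respectively).
#'
#' @inheritParams solve_compartments
#' @return numeric vector of tissue concentrations at `times`.
#' @export
ct_closed_form <- function(K, cp, times) {
  solve_compartments(K, cp, times)$CT
}

#' Whole-blood concentration from plasma concentration and parent fraction
#'
#' @param cp_values plasma concentration values \eqn{C_P(t)}.
#' @param f_values parent-fraction values \eqn{f(t)}, all `> 0`.
#' @return \eqn{C_{WB} = C_P / f} elementwise.
#' @export
c_wb <- function(cp_values, f_values) {
  if (any(f_values == 0)) stop("parent fraction must be nonzero", call. = FALSE)
  cp_values / f_values
}

#' Blood-volume mixing of tissue and whole-blood signal
#'
#' @param ct_values tissue concentration values.
#' @param cwb_values whole-blood concentration values.
#' @param VB fractional blood volume in `[0, 1]` (typically `<= 0.05`).
#' @return \eqn{C_{PET} = (1-V_B) C_T + V_B C_{WB}}.
#' @export
c_pet <- function(ct_values, cwb_values, VB) {
  if (VB < 0 || VB > 1) stop("`VB` must be in [0, 1]", call. = FALSE)
  (1 - VB) * ct_values + VB * cwb_values
}

#' Invert the blood-volume mixing
#'
#' Exact left inverse of [c_pet()] on noiseless inputs.
#'
#' @param cpet_values mixed (voxel/ROI) PET values.
#' @param cwb_values whole-blood concentration values.
#' @param VB fractional blood volume, `< 1`.
#' @return tissue values \eqn{(C_{PET} - V_B C_{WB}) / (1 - V_B)}.
#' @export
pet_to_tissue <- function(cpet_values, cwb_values, VB) {
  if (VB >= 1) stop("`VB` must be < 1", call. = FALSE)
  (cpet_values - VB * cwb_values) / (1 - VB)
}

#' Joint forward operator F = (F1, F2)
#'
#' Maps a parameter vector to the stacked measurement prediction: `F1` stacks
#' the closed-form tissue curves per region (row-major by region) at the
#' tissue times `t`; `F2` stacks the whole-blood consistency residuals
#' \eqn{C_{WB}(s_l) f_m(s_l) - C_P(s_l)} at the blood sample times `s`. The
#' whole-blood samples `cwb_data` are measured data and are never recomputed
#' from the parameters.
#'
#' @param pv a [param_vector()].
#' @param schedule a [measurement_schedule()].
#' @param cwb_data whole-blood samples at `schedule$s`.
#' @return numeric vector of length `n*T + q`.
#' @export
forward_operator <- function(pv, schedule, cwb_data) {
  stopifnot(inherits(pv, "petkin_params"), inherits(schedule, "petkin_schedule"))
  if (length(cwb_data) != length(schedule$s)) {
    stop("`cwb_data` must have one value per blood sample time", call. = FALSE)
  }
  f1 <- unlist(lapply(pv$regions, function(K) {
    ct_closed_form(K, pv$polyexp, schedule$t)
  }), use.names = FALSE)
  f2 <- cwb_data * eval_plasma_fraction(pv$fraction, schedule$s) -
    eval_polyexp(pv$polyexp, schedule$s)
  c(f1, f2)
}
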