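# User-facing wrappers around the compiled model right-hand side.

#' Steady-state gating curves and time constants
#'
#' Evaluates every voltage-dependent quantity of the model at the supplied
#' voltages: the ICa-L activation (\code{d_inf}) and inactivation
#' (\code{f_inf}) steady states (translated by \code{dV_d} and \code{dV_f}
#' respectively), the IK activation steady state (\code{x_inf}), the gate
#' time constants (\code{tau_d} scaled by \code{alpha}, \code{tau_f} scaled
#' by \code{beta}), and the instantaneous curves \code{Xi_inf},
#' \code{K1_inf}, \code{Kp_inf}. A nonzero \code{f_pedestal} p maps
#' \code{f_inf} to p + (1-p) f_inf, modelling incomplete inactivation.
#'
#' @param V voltage(s), mV; must be finite.
#' @param params an \code{ead_params} object.
#' @return a data.frame with one row per voltage and columns \code{V},
#'   \code{d_inf}, \code{f_inf}, \code{x_inf}, \code{tau_d}, \code{tau_f},
#'   \code{tau_x}, \code{Xi_inf}, \code{K1_inf}, \code{Kp_inf}.
#' @export
gating_curves <- function(V, params = ead_params()) {
  if (!is.numeric(V) || !all(is.finite(V))) stop("V must be finite numeric")
  m <- cpp_gating(as.numeric(V), .pvec(params))
  out <- as.data.frame(m)
  cbind(V = as.numeric(V), out)
}

#' Ionic membrane currents at a state
#'
#' @param state numeric vector \code{c(V, d, f, x)} or a named list.
#' @param params an \code{ead_params} object.
#' @return named numeric vector of the five currents (uA/cm^2):
#'   \code{ICaL}, \code{IK}, \code{IK1}, \code{IKp}, \code{Ib}.
#' @export
ionic_currents <- function(state, params = ead_params()) {
  s <- .as_state(state)
  cpp_currents(s, .pvec(params))
}

.as_state <- function(state) {
  if (is.list(state)) state <- unlist(state[c("V", "d", "f", "x")])
  state <- as.numeric(state)
  if (length(state) != 4 || !all(is.finite(state)))
    stop("state must be four finite numbers (V, d, f, x)")
  state
}

#' Stimulus current waveform
#'
#' Mollified square pulse: the product of two logistic ramps of width
#' \code{stim_smooth}, giving a continuously differentiable approximation of
#' a \code{stim_amp} x \code{stim_dur} rectangle starting at
#' \code{stim_onset}.
#'
#' @param t time(s), ms.
#' @param params an \code{ead_params} object.
#' @return stimulus current (uA/cm^2) at each time.
#' @export
stimulus_current <- function(t, params = ead_params()) {
  cpp_stimulus(as.numeric(t), .pvec(params))
}

#' Model right-hand side
#'
#' Time derivative of the state \code{(V, d, f, x)}:
#' \code{Cm dV/dt = -(ICaL + IK + IK1 + IKp + Ib) + Istim} and first-order
#' gate relaxation \code{dj/dt = (j_inf(V) - j) / tau_j(V)}.
#'
#' @param t time, ms (enters only through the stimulus).
#' @param state numeric \code{c(V, d, f, x)}.
#' @param params an \code{ead_params} object.
#' @param use_stim include the stimulus term?
#' @return numeric derivative vector \code{c(dV, dd, df, dx)}.
#' @export
model_rhs <- function(t, state, params = ead_params(), use_stim = TRUE) {
  s <- .as_state(state)
  out <- cpp_rhs(as.numeric(t), s, .pvec(params), use_stim)
  names(out) <- c("V", "d", "f", "x")
  out
}

#' Window-region overlap area
#'
#' Integral over voltage of d_inf(V) * f_inf(V), a scalar measure of the
#' ICa-L window region. Broadening shifts (dV_d < 0 or dV_f > 0) increase
#' it.
#'
#' @param params an \code{ead_params} object.
#' @param Vlim integration range, mV.
#' @param n quadrature points (trapezoid rule).
#' @return scalar area (mV).
#' @export
window_area <- function(params = ead_params(), Vlim = c(-80, 20), n = 4001) {
  V <- seq(Vlim[1], Vlim[2], length.out = n)
  g <- cpp_gating(V, .pvec(params))
  y <- g[, "d_inf"] * g[, "f_inf"]
  sum((y[-1] + y[-n]) / 2) * diff(Vlim) / (n - 1)
}

#' Steady-state current balance
#'
#' Total membrane current with every gate at its steady-state curve; its
#' roots in V are the full-system equilibria.
#'
#' @param V voltage(s), mV.
#' @param params an \code{ead_params} object.
#' @return total current (uA/cm^2) at each voltage.
#' @export
ss_current <- function(V, params = ead_params()) {
  cpp_ss_current(as.numeric(V), .pvec(params))
}
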