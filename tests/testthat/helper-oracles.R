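# Independent oracles used by the tests. These deliberately avoid the
# package's own integration / detection code paths.

# fixed-step classical RK4 on the full model right-hand side
rk4_integrate <- function(params, y0, t_end, h = 0.01, use_stim = TRUE) {
  n <- ceiling(t_end / h)
  y <- y0
  t <- 0
  for (i in seq_len(n)) {
    k1 <- model_rhs(t, y, params, use_stim)
    k2 <- model_rhs(t + h / 2, y + h / 2 * k1, params, use_stim)
    k3 <- model_rhs(t + h / 2, y + h / 2 * k2, params, use_stim)
    k4 <- model_rhs(t + h, y + h * k3, params, use_stim)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# independent 1-D scan for the rest equilibrium: gates at steady state,
# lowest-voltage root of the total-current balance
scan_rest_state <- function(params, Vrange = c(-100, -60), n = 2001) {
  Vs <- seq(Vrange[1], Vrange[2], length.out = n)
  S <- ss_current(Vs, params)
  i <- which(S[-1] * S[-n] < 0)[1]
  V <- uniroot(function(v) ss_current(v, params), c(Vs[i], Vs[i + 1]),
               tol = 1e-13)$root
  g <- gating_curves(V, params)
  c(V = V, d = g$d_inf, f = g$f_inf, x = g$x_inf)
}

# brute-force EAD count: scan every sign change of the numerical dV/dt on
# the dense output, then apply the same gate/prominence/window filters as
# the detector, implemented independently
brute_force_ead_count <- function(traj, v_gate = -45, prominence = 1,
                                  upstroke_window = 250) {
  t <- traj$times
  V <- traj$states[, "V"]
  dV <- diff(V) / diff(t)
  s <- sign(dV); s[s == 0] <- 1
  peaks <- which(diff(s) == -2 | (s[-length(s)] > 0 & s[-1] < 0)) + 1L
  on_t <- traj$params$stim_onset
  after <- which(t >= on_t)
  if (!length(after) || max(V[after]) < v_gate) return(0L)
  i_up <- after[which.max(V[after])]
  below <- which(V < v_gate & seq_along(V) > i_up)
  i_cross <- if (length(below)) below[1] else length(V)
  count <- 0L
  for (ip in peaks) {
    if (ip <= i_up || ip >= i_cross) next
    if (V[ip] <= v_gate) next
    if (t[ip] <= on_t + upstroke_window) next
    # prominence: drop to the lowest point on each side before a higher peak
    jl <- ip
    minl <- V[ip]
    while (jl > i_up && V[jl] <= V[ip]) { minl <- min(minl, V[jl]); jl <- jl - 1 }
    jr <- ip
    minr <- V[ip]
    while (jr < i_cross && V[jr] <= V[ip]) { minr <- min(minr, V[jr]); jr <- jr + 1 }
    if (V[ip] - max(minl, minr) >= prominence) count <- count + 1L
  }
  count
}

classify_preset <- function(..., t_end = 10000) {
  classify_response(integrate_model(ead_params(...), t_end = t_end))
}
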