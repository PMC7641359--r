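p_def <- ead_params()

test_that("gating curves are sigmoid, bounded, and obey the shift identity", {
  V <- seq(-100, 60, by = 0.5)
  g <- gating_curves(V, p_def)
  for (col in c("d_inf", "f_inf", "x_inf", "Xi_inf", "K1_inf", "Kp_inf")) {
    expect_true(all(g[[col]] >= 0 & g[[col]] <= 1), info = col)
  }
  for (col in c("tau_d", "tau_f", "tau_x"))
    expect_true(all(g[[col]] > 0), info = col)
  expect_true(all(diff(g$d_inf) > 0))   # activation increases with V
  expect_true(all(diff(g$f_inf) < 0))   # inactivation decreases with V
  # translation identity at machine precision, several shifts
  for (s in c(-3.6, -2.08, 1.04, 5.4)) {
    gd <- gating_curves(V, ead_params(dV_d = s))
    gf <- gating_curves(V, ead_params(dV_f = s))
    g0 <- gating_curves(V - s, p_def)
    expect_equal(gd$d_inf, g0$d_inf, tolerance = 1e-14)
    expect_equal(gf$f_inf, g0$f_inf, tolerance = 1e-14)
  }
  # half-activation: d_inf passes through 1/2 at its V1/2, and a shift
  # moves that voltage by exactly the shift
  v_half <- uniroot(function(v) gating_curves(v, p_def)$d_inf - 0.5,
                    c(-60, 20), tol = 1e-12)$root
  expect_equal(gating_curves(v_half, p_def)$d_inf, 0.5, tolerance = 1e-9)
  expect_equal(gating_curves(v_half - 3.6,
                             ead_params(dV_d = -3.6))$d_inf, 0.5,
               tolerance = 1e-9)
  expect_error(gating_curves(NaN, p_def), "finite")
})

test_that("pedestal lifts the inactivation floor", {
  V <- seq(-100, 60, by = 1)
  g <- gating_curves(V, ead_params(f_pedestal = 0.2))
  expect_true(all(g$f_inf >= 0.2))
  expect_true(all(g$f_inf <= 1))
  expect_true(all(diff(g$f_inf) < 0))
})

test_that("window area grows with broadening shifts, monotonically", {
  a0 <- window_area(p_def)
  a_broad <- window_area(ead_params(dV_d = -2.08, dV_f = 2.08))
  expect_gt(a_broad, a0)
  # strictly decreasing in dV_d, strictly increasing in dV_f
  ad <- vapply(c(-2, -1, 0, 1, 2),
               function(s) window_area(ead_params(dV_d = s)), numeric(1))
  af <- vapply(c(-2, -1, 0, 1, 2),
               function(s) window_area(ead_params(dV_f = s)), numeric(1))
  expect_true(all(diff(ad) < 0))
  expect_true(all(diff(af) > 0))
})

test_that("currents vanish at their reversal potentials and balance at rest", {
  cur <- ionic_currents(c(p_def$VCa, 0.7, 0.3, 0.5), p_def)
  expect_equal(unname(cur[["ICaL"]]), 0)
  cur <- ionic_currents(c(p_def$VK, 0.7, 0.3, 0.5), p_def)
  expect_equal(unname(cur[["IK"]]), 0)
  # rest state from the independent 1-D scan oracle
  e1 <- scan_rest_state(p_def)
  expect_lt(abs(sum(ionic_currents(e1, p_def))), 1e-8)
})

test_that("stimulus waveform: plateau amplitude, off-pulse decay, integral", {
  t_mid <- p_def$stim_onset + p_def$stim_dur / 2
  expect_equal(stimulus_current(t_mid, p_def), 70, tolerance = 0.01)
  expect_lt(stimulus_current(p_def$stim_onset - 5, p_def), 1e-6)
  expect_lt(stimulus_current(0, p_def), 1e-6)
  tt <- seq(0, 100, by = 1e-3)
  integ <- sum(stimulus_current(tt, p_def)) * 1e-3
  expect_equal(integ, p_def$stim_amp * p_def$stim_dur, tolerance = 0.01)
  # continuously differentiable: numerical derivative bounded by amp/width
  dd <- diff(stimulus_current(seq(19, 23, by = 1e-4), p_def)) / 1e-4
  expect_lt(max(abs(dd)), 70 / p_def$stim_smooth)
})

test_that("right-hand side: equilibrium, gate quasi-equilibrium, stimulus linearity", {
  e1 <- scan_rest_state(p_def)
  expect_lt(max(abs(model_rhs(0, e1, p_def, use_stim = FALSE))), 1e-8)
  # a gate placed at its steady state has zero derivative
  g <- gating_curves(-20, p_def)
  r <- model_rhs(0, c(-20, g$d_inf, 0.5, 0.5), p_def, use_stim = FALSE)
  expect_equal(unname(r[["d"]]), 0, tolerance = 1e-14)
  # during the plateau the stimulus adds exactly stim_amp/Cm to dV/dt
  s <- c(-20, 0.3, 0.5, 0.2)
  t_mid <- p_def$stim_onset + p_def$stim_dur / 2
  r_on <- model_rhs(t_mid, s, p_def, use_stim = TRUE)
  r_off <- model_rhs(t_mid, s, p_def, use_stim = FALSE)
  expect_equal(unname(r_on[["V"]] - r_off[["V"]]),
               stimulus_current(t_mid, p_def) / p_def$Cm, tolerance = 1e-12)
  expect_error(model_rhs(0, c(Inf, 0.5, 0.5, 0.5), p_def), "finite")
})

test_that("tau_d and tau_f scale by alpha and beta; shifts leave taus alone", {
  V <- seq(-80, 40, by = 5)
  g1 <- gating_curves(V, p_def)
  g2 <- gating_curves(V, ead_params(alpha = 0.5, beta = 2.5))
  expect_equal(g2$tau_d, 0.5 * g1$tau_d, tolerance = 1e-14)
  expect_equal(g2$tau_f, 2.5 * g1$tau_f, tolerance = 1e-14)
  expect_equal(g2$tau_x, g1$tau_x, tolerance = 1e-14)
  g3 <- gating_curves(V, ead_params(dV_d = -3, dV_f = 3))
  expect_equal(g3$tau_d, g1$tau_d, tolerance = 1e-14)
  expect_equal(g3$tau_f, g1$tau_f, tolerance = 1e-14)
})
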