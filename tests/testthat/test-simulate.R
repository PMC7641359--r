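p_def <- ead_params()
p_208 <- preset_params("fig3_2.08")

test_that("adaptive integrator agrees with a fixed-step RK4 oracle", {
  # short horizon through the stimulus and upstroke, the hardest segment
  e1 <- scan_rest_state(p_def)
  y_rk4 <- rk4_integrate(p_def, e1, 60, h = 0.005)
  tr <- integrate_model(p_def, t_end = 60, out_dt = 60)
  y_dp <- tr$states[nrow(tr$states), ]
  expect_lt(abs(y_rk4[["V"]] - y_dp[["V"]]), 1e-4)
  expect_lt(max(abs(y_rk4[c("d", "f", "x")] - y_dp[c("d", "f", "x")])),
            1e-6)
})

test_that("without a stimulus the rest state is held for the full horizon", {
  p0 <- ead_params(stim_amp = 0)
  tr <- integrate_model(p0, t_end = 10000)
  e1 <- scan_rest_state(p0)
  expect_lt(max(abs(tr$states[, "V"] - e1[["V"]])), 1e-6)
})

test_that("gates stay in [0,1] along stimulated trajectories", {
  for (p in list(p_def, p_208, ead_params(Ko = 2.0))) {
    tr <- integrate_model(p, t_end = 4000)
    expect_true(all(tr$states[, c("d", "f", "x")] >= 0))
    expect_true(all(tr$states[, c("d", "f", "x")] <= 1))
    expect_true(all(diff(tr$times) > 0))
    expect_identical(tr$times[1], 0)
  }
})

test_that("equilibria: location, residuals, labels, stability", {
  eqs <- find_equilibria(p_def)
  expect_equal(length(eqs), 3)
  expect_equal(eqs[[1]]$label, "E1")
  expect_match(eqs[[1]]$stability, "stable")
  for (e in eqs) {
    r <- model_rhs(0, e$state, p_def, use_stim = FALSE)
    expect_lt(max(abs(r)), 1e-8)
  }
  # independent oracle for E1
  expect_equal(unname(eqs[[1]]$state[["V"]]),
               unname(scan_rest_state(p_def)[["V"]]), tolerance = 1e-9)
  # the middle root is the saddle E3
  labs <- vapply(eqs, `[[`, "", "label")
  expect_true("E3" %in% labs)
  # EAD-capable preset: E2 is a stable spiral with a complex pair
  eqs2 <- find_equilibria(p_208)
  e2 <- Filter(function(e) e$label == "E2", eqs2)[[1]]
  expect_true(any(abs(Im(e2$eigenvalues)) > 0))
  expect_equal(e2$stability, "stable spiral")
})

test_that("eigen_period: closed form and error on real spectrum", {
  fake <- list(eigenvalues = c(-0.01 + 2i * pi / 100, -0.01 - 2i * pi / 100,
                               -0.3, -0.05))
  expect_equal(eigen_period(fake), 100)
  expect_error(eigen_period(list(eigenvalues = c(-1, -2, -3, -4))),
               "no oscillatory")
})

test_that("classification across the symmetric ray matches the stated outcomes", {
  f0 <- classify_preset()
  expect_equal(f0$classification, "NO_EADS")
  expect_equal(f0$ead_count, 0L)
  f2 <- classify_response(integrate_model(p_208, t_end = 10000))
  expect_equal(f2$classification, "EADS")
  expect_equal(f2$ead_count, 2L)
  f3 <- classify_preset(dV_d = -3.12, dV_f = 3.12)
  expect_equal(f3$classification, "REPOL_FAILURE")
  expect_true(is.infinite(f3$apd))
  # no stimulus -> no upstroke -> NO_EADS with count 0
  fn <- classify_response(integrate_model(ead_params(stim_amp = 0),
                                          t_end = 500))
  expect_equal(fn$classification, "NO_EADS")
  expect_equal(fn$ead_count, 0L)
})

test_that("detector equals the brute-force dV/dt oracle on the preset library", {
  for (nm in c("default", "fig3_1.04", "fig3_2.08", "fig9b",
               "hypokalemia_b2", "fig7c")) {
    tr <- integrate_model(preset_params(nm), t_end = 10000)
    expect_equal(classify_response(tr)$ead_count, brute_force_ead_count(tr),
                 info = nm)
  }
})

test_that("halving solver tolerances changes neither class nor peak times (> 1 ms)", {
  for (nm in c("fig3_2.08", "hypokalemia_b2")) {
    p <- preset_params(nm)
    a <- classify_response(integrate_model(p, t_end = 10000))
    b <- classify_response(integrate_model(p, t_end = 10000,
                                           rtol = 5e-9, atol = 5e-11))
    expect_equal(a$classification, b$classification, info = nm)
    expect_equal(a$ead_count, b$ead_count, info = nm)
    expect_lt(max(abs(a$ead_peak_times - b$ead_peak_times)), 1)
  }
})

test_that("E2 eigen-period approximates the second EAD duration", {
  eqs <- find_equilibria(p_208)
  e2 <- Filter(function(e) e$label == "E2", eqs)[[1]]
  per <- eigen_period(e2)
  f <- classify_response(integrate_model(p_208, t_end = 10000))
  expect_equal(f$ead_count, 2L)
  expect_lt(abs(per - f$ead_durations[2]) / per, 0.05)
})

test_that("trajectory CSV round-trips", {
  tr <- integrate_model(p_def, t_end = 100, out_dt = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$times, tr$times, tolerance = 1e-12)
  expect_equal(tr2$states, tr$states, tolerance = 1e-12)
  expect_equal(tr2$params$gCa, tr$params$gCa)
})
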